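#' Construct a chemical-potential schedule
#'
#' Either a constant chemical potential, or the sigmoidal-jump policy
#' `mu(nu) = mu0 - delta / (1 + exp(-(nu - nuC) / sigma))`: the effective
#' chemical potential stays near `mu0` while the substrate is mostly wet,
#' then drops by `delta` around the critical dried coverage `nuC` (over a
#' width `sigma` in nu), driving fast terminal drying of the remaining
#' solvent and the growth of secondary, finer structure.
#'
#' @param kind `"constant"` or `"sigmoidal"`.
#' @param mu0 initial chemical potential; values at or above -3 (outside
#'   the vapor regime) trigger a warning.
#' @param delta jump magnitude, `>= 0` (ignored for `"constant"`).
#' @param sigma jump sharpness in nu, `> 0` (ignored for `"constant"`).
#' @param nuC critical dried coverage in (0, 1) (ignored for `"constant"`).
#' @return A [MuSchedule-class].
#' @examples
#' sched <- muSchedule("sigmoidal", mu0 = -3.45, delta = 0.15,
#'                     sigma = 0.01, nuC = 0.15)
#' muOfNu(sched, 0.15) # midpoint: mu0 - delta/2
#' @export
muSchedule <- function(kind = c("constant", "sigmoidal"), mu0 = -3.7,
                       delta = 0.15, sigma = 0.01, nuC = 0.15) {
  kind <- match.arg(kind)
  if (mu0 >= -3) {
    warning("mu0 >= -3 is outside the vapor regime (mu < -3)")
  }
  new("MuSchedule",
    kind = kind, mu0 = as.numeric(mu0), delta = as.numeric(delta),
    sigma = as.numeric(sigma), nuC = as.numeric(nuC)
  )
}

#' Evaluate a schedule at a dried fraction
#'
#' @param schedule a [MuSchedule-class].
#' @param nu dried-substrate fraction(s) in `[0, 1]`; vectorized.
#' @return The chemical potential(s), in `[mu0 - delta, mu0]`.
#' @examples
#' sched <- muSchedule("sigmoidal", mu0 = -3.45, delta = 0.15,
#'                     sigma = 0.01, nuC = 0.15)
#' muOfNu(sched, c(0, 0.15, 1))
#' @export
muOfNu <- function(schedule, nu) {
  stopifnot(is(schedule, "MuSchedule"))
  if (any(!is.finite(nu)) || any(nu < 0) || any(nu > 1)) {
    stop("nu must lie in [0, 1]")
  }
  if (schedule@kind == "constant") {
    return(rep(schedule@mu0, length(nu)))
  }
  schedule@mu0 -
    schedule@delta / (1 + exp(-(nu - schedule@nuC) / schedule@sigma))
}

#' Tabulate a schedule on a nu grid
#'
#' @param schedule a [MuSchedule-class].
#' @param n number of grid points on `[0, 1]` (default 101).
#' @return A data.frame with columns `nu` and `mu`.
#' @export
muTable <- function(schedule, n = 101L) {
  nu <- seq(0, 1, length.out = n)
  data.frame(nu = nu, mu = muOfNu(schedule, nu))
}

setMethod("show", "MuSchedule", function(object) {
  if (object@kind == "constant") {
    cat(sprintf("MuSchedule: constant mu = %g\n", object@mu0))
  } else {
    cat(sprintf(
      "MuSchedule: sigmoidal, mu0 = %g, delta = %g, sigma = %g, nuC = %g\n",
      object@mu0, object@delta, object@sigma, object@nuC
    ))
  }
})
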