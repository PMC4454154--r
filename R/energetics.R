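#' Construct interaction parameters
#'
#' Builds an [InteractionParams-class] with the bulk-like substrate
#' convention (`epsLS = epsLL`, `epsNS = epsLN`) unless overridden, and the
#' coordination-consistency scale `c = 1/(1 + sqrt(2))`. With the defaults
#' (`epsLL = 1` fixing the energy unit) bulk liquid/vapor coexistence sits
#' at `mu = -3`, so the vapor regime is `mu < -3`.
#'
#' @param epsLL liquid-liquid coupling (default 1, the energy unit).
#' @param epsLN liquid-particle coupling (default 1.5).
#' @param epsNN particle-particle coupling (default 2).
#' @param kT thermal energy in `epsLL` units (default 0.2).
#' @param epsLS liquid-substrate coupling; defaults to `epsLL`.
#' @param epsNS particle-substrate coupling; defaults to `epsLN`.
#' @param scale pair-sum scaling factor (default `1/(1 + sqrt(2))`).
#' @return An [InteractionParams-class].
#' @examples
#' p <- interactionParams(epsNN = 2, kT = 0.2)
#' @export
interactionParams <- function(epsLL = 1, epsLN = 1.5, epsNN = 2, kT = 0.2,
                              epsLS = epsLL, epsNS = epsLN,
                              scale = 1 / (1 + sqrt(2))) {
  new("InteractionParams",
    epsLL = as.numeric(epsLL), epsLN = as.numeric(epsLN),
    epsNN = as.numeric(epsNN), epsLS = as.numeric(epsLS),
    epsNS = as.numeric(epsNS), kT = as.numeric(kT),
    scale = as.numeric(scale)
  )
}

setMethod("show", "InteractionParams", function(object) {
  cat(sprintf(
    "InteractionParams: epsLL = %g, epsLN = %g, epsNN = %g, epsLS = %g, epsNS = %g\n",
    object@epsLL, object@epsLN, object@epsNN, object@epsLS, object@epsNS
  ))
  cat(sprintf("  kT = %g, scale = %.6f\n", object@kT, object@scale))
})

# 4x4 coupling lookup by cell code + 1; vapor couples to nothing and the
# substrate-substrate entry is zero (those pairs never change).
epsMatrix <- function(params) {
  m <- matrix(0, 4, 4)
  L <- .LIQ + 1L
  N <- .PAR + 1L
  S <- .SUB + 1L
  m[L, L] <- params@epsLL
  m[L, N] <- m[N, L] <- params@epsLN
  m[N, N] <- params@epsNN
  m[L, S] <- m[S, L] <- params@epsLS
  m[N, S] <- m[S, N] <- params@epsNS
  m
}

#' Total lattice-gas energy (reference Hamiltonian)
#'
#' Evaluates the full Hamiltonian
#' `E = -c * sum_pairs w_ij * eps(kind_i, kind_j) - mu * n_liquid`,
#' where the pair sum runs once over every unordered nearest (weight 1) and
#' next-nearest (weight `1/sqrt(2)`) pair, substrate-substrate pairs are
#' excluded, and cells outside the grid contribute nothing. This is the slow
#' reference implementation used to validate the incremental move energies;
#' the simulation loop never calls it.
#'
#' @param state a [LatticeState-class].
#' @param params an [InteractionParams-class].
#' @param mu chemical potential.
#' @return The total energy (numeric scalar).
#' @examples
#' s <- buildInitialState(8, 0.25, 0)
#' totalEnergy(s, interactionParams(), mu = -3.5)
#' @export
totalEnergy <- function(state, params, mu) {
  stopifnot(is(state, "LatticeState"), is(params, "InteractionParams"),
            is.finite(mu))
  g <- state@grid
  D <- state@D
  nl <- state@H + 1L
  eps <- epsMatrix(params)
  off <- neighborOffsets()
  pairSum <- 0
  for (m in seq_len(nrow(off))) {
    xs <- ((seq_len(D) - 1L + off[m, "dx"]) %% D) + 1L
    ys <- ((seq_len(D) - 1L + off[m, "dy"]) %% D) + 1L
    dl <- off[m, "dl"]
    src <- which(seq_len(nl) + dl >= 1L & seq_len(nl) + dl <= nl)
    if (!length(src)) next
    ki <- g[, , src, drop = FALSE]
    kj <- g[xs, ys, src + dl, drop = FALSE]
    pairSum <- pairSum +
      off[m, "weight"] * sum(eps[cbind(c(ki) + 1L, c(kj) + 1L)])
  }
  # every in-grid unordered pair is visited twice across the offset set
  unname(-params@scale * pairSum / 2 - mu * sum(g == .LIQ))
}

#' Energy change of an evaporation/condensation flip
#'
#' Incremental Hamiltonian change of toggling one cell between liquid and
#' vapor, computed from the 18-neighbor stencil only. For a liquid cell
#' buried in bulk liquid the change is `6 * epsLL + mu` with the default
#' scale; for an isolated liquid cell it is `mu`.
#'
#' @param state a [LatticeState-class].
#' @param cell integer `c(x, y, layer)`, 1-based, layer 1 = substrate; the
#'   cell must hold liquid or vapor.
#' @param params an [InteractionParams-class].
#' @param mu chemical potential.
#' @return The energy change of the toggle (numeric scalar).
#' @export
deltaFlip <- function(state, cell, params, mu) {
  cell <- as.integer(cell)
  k <- state@grid[cell[1], cell[2], cell[3]]
  if (!k %in% c(.LIQ, .VAP)) {
    stop("deltaFlip requires a liquid or vapor cell")
  }
  cpp_delta_flip(
    as.integer(state@grid), state@D, state@H,
    cell[1] - 1L, cell[2] - 1L, cell[3] - 1L,
    epsMatrix(params), params@scale, mu
  )
}

#' Energy change of a particle/liquid swap
#'
#' Incremental Hamiltonian change of exchanging a particle with a
#' nearest-neighbor liquid cell. The chemical-potential term cancels (the
#' liquid count is unchanged), so the result is independent of mu.
#'
#' @param state a [LatticeState-class].
#' @param particleCell integer `c(x, y, layer)` holding a particle.
#' @param liquidCell integer `c(x, y, layer)` holding liquid, nearest
#'   neighbor of `particleCell` (lateral wrapping allowed).
#' @param params an [InteractionParams-class].
#' @return The energy change of the swap (numeric scalar).
#' @export
deltaSwap <- function(state, particleCell, liquidCell, params) {
  p <- as.integer(particleCell)
  q <- as.integer(liquidCell)
  if (state@grid[p[1], p[2], p[3]] != .PAR) {
    stop("particleCell does not hold a particle")
  }
  if (state@grid[q[1], q[2], q[3]] != .LIQ) {
    stop("liquidCell does not hold liquid")
  }
  D <- state@D
  dlat <- function(a, b) min((a - b) %% D, (b - a) %% D)
  d <- dlat(p[1], q[1]) + dlat(p[2], q[2]) + abs(p[3] - q[3])
  if (d != 1L) stop("cells are not nearest neighbors")
  cpp_delta_swap(
    as.integer(state@grid), state@D, state@H,
    p[1] - 1L, p[2] - 1L, p[3] - 1L,
    q[1] - 1L, q[2] - 1L, q[3] - 1L,
    epsMatrix(params), params@scale
  )
}
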