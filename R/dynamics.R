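#' Metropolis acceptance rule
#'
#' Accepts a proposed move iff `u < min(1, exp(-deltaE / kT))`, so downhill
#' and energy-neutral moves are always accepted and uphill moves with
#' probability `exp(-deltaE / kT)`. Vectorized over `deltaE` and `u`.
#'
#' @param deltaE energy change(s) of the proposed move.
#' @param kT thermal energy, `> 0`.
#' @param u uniform draw(s) in `[0, 1)`.
#' @return Logical: accept or reject.
#' @examples
#' metropolisAccept(-1, 0.2, 0.999) # downhill: always TRUE
#' metropolisAccept(0.2 * log(2), 0.2, c(0.49, 0.51)) # p = 0.5
#' @export
metropolisAccept <- function(deltaE, kT, u) {
  if (!is.numeric(kT) || length(kT) != 1L || kT <= 0) {
    stop("kT must be a single positive number")
  }
  if (any(u < 0) || any(u >= 1)) stop("u must lie in [0, 1)")
  u < exp(-deltaE / kT)
}

#' Construct dynamics settings
#'
#' @param nMov particle move attempts per particle per step (default 20).
#' @param maxSteps Monte Carlo step budget (default 10000).
#' @param seed seed of the dynamics random-number stream (default 1).
#' @param schedule a [MuSchedule-class]; default constant `mu = -3.7`.
#' @return A [DynamicsConfig-class].
#' @export
dynamicsConfig <- function(nMov = 20L, maxSteps = 10000L, seed = 1L,
                           schedule = muSchedule("constant", mu0 = -3.7)) {
  new("DynamicsConfig",
    nMov = as.integer(nMov), maxSteps = as.integer(maxSteps),
    seed = as.integer(seed), schedule = schedule
  )
}

#' One evaporation/condensation sweep
#'
#' Visits every liquid and vapor cell exactly once in a freshly shuffled
#' order; each visit proposes the liquid/vapor toggle, evaluates the
#' incremental energy change and applies the Metropolis rule, with accepted
#' toggles taking effect immediately (sequential updating).
#'
#' @param state a [LatticeState-class].
#' @param params an [InteractionParams-class] (supplies `kT`).
#' @param mu chemical potential for this sweep.
#' @param seed seed for this sweep's random stream.
#' @return A list with `state` (the updated [LatticeState-class]) and
#'   `accepted` (number of accepted toggles).
#' @export
sweepFluid <- function(state, params, mu, seed = 1L) {
  res <- cpp_sweep_fluid(
    as.integer(state@grid), state@D, state@H,
    epsMatrix(params), params@scale, mu, params@kT, as.double(seed)
  )
  grid <- array(res$grid, dim = dim(state@grid))
  list(state = replaceGrid(state, grid), accepted = res$accepted)
}

#' One particle random-walk phase
#'
#' Each particle receives `nMov` attempts; every attempt draws one of the 6
#' nearest directions uniformly (the direction is drawn before checking the
#' target, so immobile particles consume draws identically). If the target
#' cell is liquid the swap energy is evaluated and the Metropolis rule
#' applied; otherwise the attempt is a no-op rejection. The particle count
#' never changes.
#'
#' @param state a [LatticeState-class].
#' @param params an [InteractionParams-class] (supplies `kT`).
#' @param nMov attempts per particle.
#' @param seed seed for this phase's random stream.
#' @return A list with `state` and `accepted` (accepted swaps).
#' @export
sweepParticles <- function(state, params, nMov, seed = 1L) {
  res <- cpp_sweep_particles(
    as.integer(state@grid), state@D, state@H,
    epsMatrix(params), params@scale, params@kT, as.integer(nMov),
    as.double(seed)
  )
  grid <- array(res$grid, dim = dim(state@grid))
  list(state = replaceGrid(state, grid), accepted = res$accepted)
}

#' Run the drying simulation
#'
#' Executes the Monte Carlo loop: at every step the dried fraction nu is
#' measured, the chemical potential is set to `schedule(nu)`, the
#' evaporation/condensation sweep runs over all fluid cells, and each
#' particle makes `nMov` random-walk attempts within the liquid. The run
#' stops when the film is fully evaporated (zero liquid) or at `maxSteps`.
#' The particle count and the substrate layer are invariant, and a run is
#' fully reproducible from its seed.
#'
#' @param state the initial [LatticeState-class].
#' @param params an [InteractionParams-class].
#' @param config a [DynamicsConfig-class].
#' @param snapshotInterval if positive, keep a copy of the state every this
#'   many steps (default 0: off).
#' @return A [SimulationResult-class] holding the final state and the
#'   per-step [RunTrace-class].
#' @examples
#' s <- buildInitialState(16, 0.25, 0.01, seed = 1)
#' res <- runSimulation(s, interactionParams(kT = 0.2),
#'                      dynamicsConfig(nMov = 5, maxSteps = 200, seed = 1))
#' utils::tail(traceRecords(runTrace(res)), 3)
#' @export
runSimulation <- function(state, params, config, snapshotInterval = 0L) {
  stopifnot(is(state, "LatticeState"), is(params, "InteractionParams"),
            is(config, "DynamicsConfig"))
  sched <- config@schedule
  res <- cpp_run(
    as.integer(state@grid), state@D, state@H,
    epsMatrix(params), params@scale, params@kT,
    config@nMov, config@maxSteps, as.double(config@seed),
    if (sched@kind == "sigmoidal") 1L else 0L,
    sched@mu0, sched@delta, sched@sigma, sched@nuC,
    as.integer(snapshotInterval)
  )
  grid <- array(res$grid, dim = dim(state@grid))
  final <- replaceGrid(state, grid, stepIndex = res$steps)
  trace <- new("RunTrace", records = data.frame(
    step = res$step, mu = res$mu, nu = res$nu,
    liquidFraction = res$liquidFraction,
    acceptedFlips = res$acceptedFlips, acceptedSwaps = res$acceptedSwaps
  ))
  snaps <- list()
  if (length(res$snapshotSteps)) {
    snaps <- lapply(seq_along(res$snapshotSteps), function(i) {
      replaceGrid(state, array(res$snapshots[[i]], dim = dim(state@grid)),
        stepIndex = res$snapshotSteps[i]
      )
    })
  }
  new("SimulationResult",
    state = final, trace = trace, params = params, config = config,
    snapshots = snaps
  )
}

#' @rdname accessors
#' @export
setMethod("traceRecords", "RunTrace", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("finalState", "SimulationResult", function(x) x@state)

#' @rdname accessors
#' @export
setMethod("runTrace", "SimulationResult", function(x) x@trace)

setMethod("show", "RunTrace", function(object) {
  n <- nrow(object@records)
  cat(sprintf("RunTrace: %d steps\n", n))
  if (n) {
    last <- object@records[n, ]
    cat(sprintf(
      "  final: nu = %.4f, mu = %.4f, liquid fraction = %.4f\n",
      last$nu, last$mu, last$liquidFraction
    ))
  }
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult\n")
  show(object@state)
  show(object@trace)
})
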