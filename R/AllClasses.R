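#' LatticeState: the 3D simulation grid
#'
#' Holds the evolving cell grid of the drying simulation. The grid is a
#' `D x D x (H+1)` integer array of cell codes (see [cellKinds()]); slice
#' `[, , 1]` is the substrate layer and slices `2..H+1` are the `H` fluid
#' layers. Lateral boundaries are periodic (toroidal); the vertical
#' direction is not.
#'
#' @slot grid integer array of cell codes, dim `c(D, D, H + 1)`.
#' @slot D integer, lattice base side (cells).
#' @slot H integer, number of fluid layers above the substrate.
#' @slot z numeric, side-wall aspect ratio used to derive `H = round(z * D)`.
#' @slot particleCount integer, number of particle cells (conserved).
#' @slot stepIndex integer, Monte Carlo step the grid corresponds to.
#' @slot seed integer, seed used for the initial configuration.
#'
#' @seealso [buildInitialState()], [runSimulation()], [driedFraction()]
#' @export
setClass("LatticeState",
  representation(
    grid = "array", D = "integer", H = "integer", z = "numeric",
    particleCount = "integer", stepIndex = "integer", seed = "integer"
  )
)

setValidity("LatticeState", function(object) {
  g <- object@grid
  d <- dim(g)
  if (length(d) != 3L || d[1] != object@D || d[2] != object@D ||
      d[3] != object@H + 1L) {
    return("grid dimensions do not match D and H")
  }
  if (!all(g %in% 0:3)) {
    return("grid contains codes outside 0..3")
  }
  if (!all(g[, , 1] == .SUB)) {
    return("layer 0 must be entirely substrate")
  }
  if (any(g[, , -1, drop = FALSE] == .SUB)) {
    return("substrate must not appear above layer 0")
  }
  if (sum(g == .PAR) != object@particleCount) {
    return("particleCount does not equal the number of particle cells")
  }
  TRUE
})

#' InteractionParams: lattice-gas couplings and temperature
#'
#' Pairwise interaction energies of the lattice-gas Hamiltonian, the thermal
#' energy `kT` (dimensionless, in units of `epsLL`), and the
#' coordination-consistency scale `c = 1/(1 + sqrt(2))` that makes the
#' effective 18-neighbor coordination equal the 6 of a nearest-only model,
#' keeping liquid/vapor coexistence at `mu = -3` for `epsLL = 1`.
#'
#' Substrate couplings default to the bulk-like convention
#' `epsLS = epsLL`, `epsNS = epsLN`; vapor couples to nothing and
#' substrate-substrate pairs never contribute.
#'
#' @slot epsLL numeric, liquid-liquid coupling (the energy unit, default 1).
#' @slot epsLN numeric, liquid-particle coupling.
#' @slot epsNN numeric, particle-particle coupling.
#' @slot epsLS numeric, liquid-substrate coupling.
#' @slot epsNS numeric, particle-substrate coupling.
#' @slot kT numeric, thermal energy, must be positive.
#' @slot scale numeric, the pair-sum scaling factor c.
#'
#' @seealso [interactionParams()], [totalEnergy()]
#' @export
setClass("InteractionParams",
  representation(
    epsLL = "numeric", epsLN = "numeric", epsNN = "numeric",
    epsLS = "numeric", epsNS = "numeric", kT = "numeric", scale = "numeric"
  )
)

setValidity("InteractionParams", function(object) {
  for (s in c("epsLL", "epsLN", "epsNN", "epsLS", "epsNS", "kT", "scale")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      return(sprintf("%s must be a single finite number", s))
    }
  }
  if (object@kT <= 0) return("kT must be positive")
  TRUE
})

#' MuSchedule: chemical-potential policy
#'
#' Supplies the effective chemical potential as a function of the
#' dried-substrate fraction nu: either a constant `mu0`, or the sigmoidal
#' jump `mu(nu) = mu0 - delta / (1 + exp(-(nu - nuC) / sigma))` that drops
#' from `mu0` towards `mu0 - delta` around the critical coverage `nuC`,
#' triggering rapid final dry-out.
#'
#' @slot kind character, `"constant"` or `"sigmoidal"`.
#' @slot mu0 numeric, initial chemical potential (vapor regime is `mu < -3`).
#' @slot delta numeric `>= 0`, total magnitude of the jump.
#' @slot sigma numeric `> 0`, sharpness of the jump in nu.
#' @slot nuC numeric in (0, 1), critical dried coverage.
#'
#' @seealso [muSchedule()], [muOfNu()]
#' @export
setClass("MuSchedule",
  representation(
    kind = "character", mu0 = "numeric", delta = "numeric",
    sigma = "numeric", nuC = "numeric"
  )
)

setValidity("MuSchedule", function(object) {
  if (!object@kind %in% c("constant", "sigmoidal")) {
    return("kind must be 'constant' or 'sigmoidal'")
  }
  if (!is.finite(object@mu0)) return("mu0 must be finite")
  if (object@kind == "sigmoidal") {
    if (object@delta < 0) return("delta must be >= 0")
    if (object@sigma <= 0) return("sigma must be > 0")
    if (object@nuC <= 0 || object@nuC >= 1) return("nuC must lie in (0, 1)")
  }
  TRUE
})

#' DynamicsConfig: Monte Carlo run settings
#'
#' @slot nMov integer `>= 0`, particle move attempts per particle per step.
#' @slot maxSteps integer `>= 1`, step budget.
#' @slot seed integer, seed of the dynamics random-number stream.
#' @slot schedule a [MuSchedule-class] object.
#'
#' @seealso [dynamicsConfig()], [runSimulation()]
#' @export
setClass("DynamicsConfig",
  representation(
    nMov = "integer", maxSteps = "integer", seed = "integer",
    schedule = "MuSchedule"
  )
)

setValidity("DynamicsConfig", function(object) {
  if (object@nMov < 0L) return("nMov must be >= 0")
  if (object@maxSteps < 1L) return("maxSteps must be >= 1")
  TRUE
})

#' RunTrace: per-step observables of a simulation run
#'
#' One record per Monte Carlo step: the step index, the chemical potential
#' used (equal to `schedule(nu)` of the same step), the dried fraction nu
#' measured at the start of the step, the liquid fraction after the step,
#' and the accepted flip/swap counts.
#'
#' @slot records data.frame with columns `step`, `mu`, `nu`,
#'   `liquidFraction`, `acceptedFlips`, `acceptedSwaps`.
#' @seealso [runSimulation()], [writeRunTrace()]
#' @export
setClass("RunTrace", representation(records = "data.frame"))

setValidity("RunTrace", function(object) {
  need <- c("step", "mu", "nu", "liquidFraction", "acceptedFlips",
            "acceptedSwaps")
  if (!all(need %in% names(object@records))) {
    return("records must have columns step, mu, nu, liquidFraction, acceptedFlips, acceptedSwaps")
  }
  lf <- object@records$liquidFraction
  if (length(lf) && (min(lf) < 0 || max(lf) > 1)) {
    return("liquidFraction must lie in [0, 1]")
  }
  TRUE
})

#' SimulationResult: final state plus trace of a run
#'
#' @slot state the final [LatticeState-class].
#' @slot trace the [RunTrace-class] of the run.
#' @slot params the [InteractionParams-class] used.
#' @slot config the [DynamicsConfig-class] used.
#' @slot snapshots list of intermediate [LatticeState-class] objects taken
#'   every `snapshotInterval` steps (empty when snapshots were off).
#' @seealso [runSimulation()]
#' @export
setClass("SimulationResult",
  representation(
    state = "LatticeState", trace = "RunTrace",
    params = "InteractionParams", config = "DynamicsConfig",
    snapshots = "list"
  )
)

#' HeightMap: 2D projection of a deposit pattern
#'
#' A `D x D` matrix of column particle counts (heights, lattice cells), with
#' an optional physical calibration `cellSize` in nm per lattice unit used
#' when reporting physical areas.
#'
#' @slot grid integer matrix of non-negative heights.
#' @slot cellSize numeric, nm per lattice unit (default 1).
#' @seealso [projectHeight()], [labelGrains()], [holeHistogram()]
#' @export
setClass("HeightMap", representation(grid = "matrix", cellSize = "numeric"))

setValidity("HeightMap", function(object) {
  if (any(object@grid < 0)) return("heights must be non-negative")
  if (length(object@cellSize) != 1L || object@cellSize <= 0) {
    return("cellSize must be a single positive number")
  }
  TRUE
})

#' GrainTable: labeled-grain statistics of a pattern
#'
#' One row per connected grain surviving the minimum-size filter, with areas
#' in cells and physical units, the centroid, and the maximum height.
#'
#' @slot grains data.frame with columns `grainId`, `areaCells`, `areaPhys`,
#'   `centroidX`, `centroidY`, `maxHeight`.
#' @slot minAreaCells integer, the minimum-area filter applied.
#' @slot connectivity integer, 4 or 8.
#' @slot periodic logical, whether lateral wrapping was used.
#' @slot cellSize numeric, calibration inherited from the height map.
#' @seealso [labelGrains()], [grainSummary()]
#' @export
setClass("GrainTable",
  representation(
    grains = "data.frame", minAreaCells = "integer",
    connectivity = "integer", periodic = "logical", cellSize = "numeric"
  )
)

#' HoleHistogram: total hole area per size range
#'
#' Holes are connected components of the unoccupied projection; each hole's
#' area is accumulated into its size bin, so a bin holds the total area
#' covered by all holes in that size range. `gapRanges` lists the maximal
#' runs of empty bins strictly between the lowest and highest occupied bins
#' -- the signature of a dual-scale (cellular-network) pattern.
#'
#' @slot binEdges numeric, strictly increasing edges; bin i is
#'   `[edge_i, edge_{i+1})`.
#' @slot totalArea numeric, total hole area per bin (cells).
#' @slot gapRanges two-column matrix of gap `[low, high)` edges.
#' @slot holeAreas numeric, the individual hole areas (cells).
#' @slot connectivity integer, hole connectivity used (4 or 8).
#' @slot periodic logical.
#' @seealso [holeHistogram()], [detectDualScale()]
#' @export
setClass("HoleHistogram",
  representation(
    binEdges = "numeric", totalArea = "numeric", gapRanges = "matrix",
    holeAreas = "numeric", connectivity = "integer", periodic = "logical"
  )
)

setValidity("HoleHistogram", function(object) {
  if (any(diff(object@binEdges) <= 0)) {
    return("binEdges must be strictly increasing")
  }
  if (length(object@totalArea) != length(object@binEdges) - 1L) {
    return("totalArea must have one entry per bin")
  }
  TRUE
})
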