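#' @name accessors
#' @title Accessors for evapKMC objects
#' @description Slot accessors for the S4 containers; user code should use
#'   these rather than reaching into slots.
#' @param x an evapKMC S4 object.
#' @return The corresponding component (see the individual generics).
NULL

#' @describeIn accessors the lattice base side D (cells).
#' @export
setGeneric("baseSide", function(x) standardGeneric("baseSide"))

#' @describeIn accessors the number of fluid layers H.
#' @export
setGeneric("filmHeight", function(x) standardGeneric("filmHeight"))

#' @describeIn accessors the raw cell-code array / height matrix.
#' @export
setGeneric("latticeGrid", function(x) standardGeneric("latticeGrid"))

#' @describeIn accessors the conserved particle count.
#' @export
setGeneric("particleCount", function(x) standardGeneric("particleCount"))

#' @describeIn accessors the Monte Carlo step index of a state.
#' @export
setGeneric("stepIndex", function(x) standardGeneric("stepIndex"))

#' Dried-substrate fraction nu
#'
#' Fraction of lateral sites whose first fluid layer (the cell directly on
#' the substrate) holds no liquid: vapor- or particle-covered substrate
#' counts as dried. This is the order parameter driving the sigmoidal
#' chemical-potential schedule.
#'
#' @param state a [LatticeState-class].
#' @return A number in `[0, 1]`.
#' @examples
#' s <- buildInitialState(8, 0.25, 0)
#' driedFraction(s) # 0 for a fresh all-liquid film
#' @export
setGeneric("driedFraction", function(state) standardGeneric("driedFraction"))

#' Liquid fraction of the film
#'
#' Liquid cells divided by the fluid volume `D^2 * H`; reaches 0 when the
#' film is fully evaporated (the termination condition of a run).
#'
#' @param state a [LatticeState-class].
#' @return A number in `[0, 1]`.
#' @export
setGeneric("liquidFraction", function(state) standardGeneric("liquidFraction"))

#' Project a lattice state to a height map
#'
#' Counts particle cells per lateral column, producing the AFM-like 2D view
#' of the deposit; the map total equals the particle count.
#'
#' @param state a [LatticeState-class].
#' @param cellSize physical calibration, nm per lattice unit (default 1).
#' @return A [HeightMap-class].
#' @export
setGeneric("projectHeight", function(state, cellSize = 1) {
  standardGeneric("projectHeight")
})

#' @describeIn accessors the per-step trace records as a data.frame.
#' @export
setGeneric("traceRecords", function(x) standardGeneric("traceRecords"))

#' @describeIn accessors the final state of a simulation result.
#' @export
setGeneric("finalState", function(x) standardGeneric("finalState"))

#' @describeIn accessors the [RunTrace-class] of a simulation result.
#' @export
setGeneric("runTrace", function(x) standardGeneric("runTrace"))

#' @describeIn accessors the physical calibration (nm per lattice unit).
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @describeIn accessors per-grain rows of a [GrainTable-class].
#' @export
setGeneric("grainTable", function(x) standardGeneric("grainTable"))

#' Summary statistics of a grain table
#'
#' Count plus min/max/mean/standard deviation of grain areas, in lattice
#' cells and in physical units. The standard deviation uses the population
#' convention (divide by n), matching typical grain-analysis software.
#'
#' @param x a [GrainTable-class].
#' @return A one-row data.frame with columns `count`, `minArea`, `maxArea`,
#'   `meanArea`, `sdArea`, `minAreaPhys`, `maxAreaPhys`, `meanAreaPhys`,
#'   `sdAreaPhys`. Area statistics are `NA` when the table is empty.
#' @export
setGeneric("grainSummary", function(x) standardGeneric("grainSummary"))

#' @describeIn accessors the gap ranges (empty-bin runs) of a histogram.
#' @export
setGeneric("gapRanges", function(x) standardGeneric("gapRanges"))

#' @describeIn accessors the bin edges of a histogram.
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @describeIn accessors total hole area per bin.
#' @export
setGeneric("binTotals", function(x) standardGeneric("binTotals"))

#' @describeIn accessors the individual hole areas behind a histogram.
#' @export
setGeneric("holeAreas", function(x) standardGeneric("holeAreas"))
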