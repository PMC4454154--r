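#' Build the initial film state
#'
#' Constructs the starting configuration of a drying run: a `D x D` substrate
#' layer under `H = round(z * D)` fluid layers, with `round(phi * D^2 * H)`
#' particle cells placed uniformly at random (seeded, without replacement)
#' among the fluid cells and every remaining fluid cell liquid. There is no
#' vapor initially: the film is full.
#'
#' @param D lattice base side, integer `>= 4`.
#' @param z side-wall aspect ratio; the film height is `H = round(z * D)`
#'   and must be at least 2.
#' @param phi particle volume fraction in `[0, 1)`.
#' @param seed integer seed for the particle placement (default 1).
#' @return A [LatticeState-class].
#' @examples
#' s <- buildInitialState(8, 0.25, 0.5, seed = 1)
#' particleCount(s) # 64 of the 128 fluid cells
#' @export
buildInitialState <- function(D, z, phi, seed = 1L) {
  D <- as.integer(D)
  if (is.na(D) || D < 4L) stop("D must be an integer >= 4")
  if (!is.numeric(z) || z <= 0) stop("z must be positive")
  if (!is.numeric(phi) || phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  H <- as.integer(round(z * D))
  if (H < 2L) stop("film too thin to simulate: round(z * D) must be >= 2")

  nFluid <- as.double(D) * D * H
  nPart <- as.integer(round(phi * nFluid))
  if (phi > 0 && nPart == 0L) {
    warning("phi > 0 but rounds to zero particles for this geometry")
  }

  grid <- array(.LIQ, dim = c(D, D, H + 1L))
  grid[, , 1L] <- .SUB
  if (nPart > 0L) {
    idx <- withSeed(seed, sample.int(as.integer(nFluid), nPart))
    grid[as.integer(D) * D + idx] <- .PAR # offset past the substrate layer
  }
  new("LatticeState",
    grid = grid, D = D, H = H, z = as.numeric(z),
    particleCount = nPart, stepIndex = 0L, seed = as.integer(seed)
  )
}

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
withSeed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Neighbor topology of the cubic lattice
#'
#' The interaction stencil: 6 nearest offsets (axis unit steps, weight 1)
#' and 12 next-nearest offsets (face diagonals, weight `1/sqrt(2)`, the
#' inverse-distance scaling). Both sets are closed under negation.
#'
#' @return A list with elements `nearest` (6 x 3 integer matrix),
#'   `nextNearest` (12 x 3), and `nextNearestWeight` (`1/sqrt(2)`).
#' @examples
#' topo <- neighborTopology()
#' nrow(topo$nearest) # 6
#' @export
neighborTopology <- function() {
  near <- rbind(
    c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
    c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L)
  )
  s <- rbind(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  nn <- rbind(
    cbind(s[, 1], s[, 2], 0L),
    cbind(s[, 1], 0L, s[, 2]),
    cbind(0L, s[, 1], s[, 2])
  )
  colnames(near) <- colnames(nn) <- c("dx", "dy", "dl")
  list(nearest = near, nextNearest = nn, nextNearestWeight = 1 / sqrt(2))
}

# 18 x 4 matrix (dx, dy, dl, weight), nearest first.
neighborOffsets <- function() {
  topo <- neighborTopology()
  cbind(
    rbind(topo$nearest, topo$nextNearest),
    weight = c(rep(1, 6), rep(topo$nextNearestWeight, 12))
  )
}

#' Enumerate the 18 neighbors of a cell
#'
#' Returns the interaction stencil around one cell, with lateral coordinates
#' wrapped modulo D and vertical neighbors outside the grid flagged
#' `exterior` (they behave as vapor: zero coupling). Coordinates are 1-based;
#' `layer = 1` is the substrate slice.
#'
#' @param cell integer vector `c(x, y, layer)` within the grid.
#' @param D lattice base side.
#' @param H number of fluid layers (layers run 1..H+1).
#' @return A data.frame with 18 rows and columns `x`, `y`, `layer`,
#'   `weight`, `exterior`; `x`, `y`, `layer` are `NA` for exterior entries.
#' @examples
#' nb <- neighborsOf(c(1, 1, 2), D = 8, H = 2)
#' sum(!nb$exterior)
#' @export
neighborsOf <- function(cell, D, H) {
  cell <- as.integer(cell)
  D <- as.integer(D)
  H <- as.integer(H)
  if (length(cell) != 3L) stop("cell must be c(x, y, layer)")
  if (cell[1] < 1L || cell[1] > D || cell[2] < 1L || cell[2] > D ||
      cell[3] < 1L || cell[3] > H + 1L) {
    stop("cell index out of grid bounds")
  }
  off <- neighborOffsets()
  x <- ((cell[1] - 1L + off[, "dx"]) %% D) + 1L
  y <- ((cell[2] - 1L + off[, "dy"]) %% D) + 1L
  l <- cell[3] + off[, "dl"]
  ext <- l < 1L | l > H + 1L
  x[ext] <- NA_integer_
  y[ext] <- NA_integer_
  l[ext] <- NA_integer_
  data.frame(
    x = x, y = y, layer = l, weight = off[, "weight"], exterior = ext
  )
}

#' @rdname driedFraction
#' @export
setMethod("driedFraction", "LatticeState", function(state) {
  mean(state@grid[, , 2L] != .LIQ)
})

#' @rdname liquidFraction
#' @export
setMethod("liquidFraction", "LatticeState", function(state) {
  sum(state@grid == .LIQ) / (as.double(state@D) * state@D * state@H)
})

#' @rdname accessors
#' @export
setMethod("baseSide", "LatticeState", function(x) x@D)

#' @rdname accessors
#' @export
setMethod("filmHeight", "LatticeState", function(x) x@H)

#' @rdname accessors
#' @export
setMethod("latticeGrid", "LatticeState", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("particleCount", "LatticeState", function(x) x@particleCount)

#' @rdname accessors
#' @export
setMethod("stepIndex", "LatticeState", function(x) x@stepIndex)

setMethod("show", "LatticeState", function(object) {
  cat(sprintf(
    "LatticeState: D = %d, H = %d (z = %g), step %d\n",
    object@D, object@H, object@z, object@stepIndex
  ))
  cat(sprintf(
    "  particles: %d  liquid fraction: %.4f  dried fraction: %.4f\n",
    object@particleCount, liquidFraction(object), driedFraction(object)
  ))
})

# Rebuild a state around a modified grid, keeping geometry metadata.
replaceGrid <- function(state, grid, stepIndex = state@stepIndex) {
  new("LatticeState",
    grid = grid, D = state@D, H = state@H, z = state@z,
    particleCount = sum(grid == .PAR), stepIndex = as.integer(stepIndex),
    seed = state@seed
  )
}
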