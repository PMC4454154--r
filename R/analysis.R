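#' @rdname projectHeight
#' @export
setMethod("projectHeight", "LatticeState", function(state, cellSize = 1) {
  D <- state@D
  h <- matrix(0L, D, D)
  for (l in seq_len(state@H) + 1L) {
    h <- h + (state@grid[, , l] == .PAR)
  }
  new("HeightMap", grid = h, cellSize = as.numeric(cellSize))
})

#' Construct a height map from a matrix
#'
#' @param grid matrix of non-negative integer heights.
#' @param cellSize physical calibration, nm per lattice unit.
#' @return A [HeightMap-class].
#' @export
heightMap <- function(grid, cellSize = 1) {
  storage.mode(grid) <- "integer"
  new("HeightMap", grid = grid, cellSize = as.numeric(cellSize))
}

#' @rdname accessors
#' @export
setMethod("latticeGrid", "HeightMap", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("cellSize", "HeightMap", function(x) x@cellSize)

setMethod("show", "HeightMap", function(object) {
  cat(sprintf(
    "HeightMap: %d x %d, coverage %d columns, max height %d, cellSize %g nm\n",
    nrow(object@grid), ncol(object@grid), sum(object@grid > 0),
    max(object@grid), object@cellSize
  ))
})

#' Label grains and compute their statistics
#'
#' Grains are connected components of the occupied projection (`height > 0`)
#' under 4- or 8-connectivity, with lateral periodic wrapping (simulation
#' mode) or without (image mode). Components smaller than `minAreaCells`,
#' and optionally lower than `minMaxHeight`, are filtered out before
#' statistics are computed -- the analogue of the height/size filtering
#' applied to AFM grain images.
#'
#' Centroids are arithmetic means of the member-cell coordinates; for a
#' grain wrapping across the periodic seam the centroid is reported in
#' unwrapped coordinates relative to the grain's first cell.
#'
#' @param hmap a [HeightMap-class].
#' @param minAreaCells drop grains smaller than this many cells (default 0).
#' @param connectivity 4 or 8 (default 8: diagonal contact joins grains).
#' @param periodic logical; wrap laterally (default FALSE).
#' @param minMaxHeight drop grains whose maximum height is below this
#'   (default 0: keep all).
#' @return A [GrainTable-class].
#' @examples
#' gt <- labelGrains(makeFixture("two_blobs", 8))
#' grainSummary(gt) # 2 grains of 4 cells each
#' @export
labelGrains <- function(hmap, minAreaCells = 0L, connectivity = 8L,
                        periodic = FALSE, minMaxHeight = 0L) {
  stopifnot(is(hmap, "HeightMap"), connectivity %in% c(4L, 8L),
            minAreaCells >= 0L)
  h <- hmap@grid
  lab <- cpp_label((h > 0) + 0L, as.integer(connectivity), periodic)
  k <- max(lab)
  if (k == 0L) {
    grains <- data.frame(
      grainId = integer(), areaCells = integer(), areaPhys = numeric(),
      centroidX = numeric(), centroidY = numeric(), maxHeight = integer()
    )
  } else {
    idx <- which(lab > 0)
    lv <- lab[idx]
    xs <- row(lab)[idx]
    ys <- col(lab)[idx]
    area <- tabulate(lv, nbins = k)
    f <- factor(lv, levels = seq_len(k))
    maxh <- vapply(split(h[idx], f), max, integer(1))
    cx <- centroidOf(split(xs, f), nrow(h), periodic)
    cy <- centroidOf(split(ys, f), ncol(h), periodic)
    grains <- data.frame(
      grainId = seq_len(k), areaCells = area,
      areaPhys = area * hmap@cellSize^2,
      centroidX = cx, centroidY = cy, maxHeight = as.integer(maxh)
    )
    keep <- grains$areaCells >= minAreaCells & grains$maxHeight >= minMaxHeight
    grains <- grains[keep, , drop = FALSE]
    grains$grainId <- seq_len(nrow(grains))
    rownames(grains) <- NULL
  }
  new("GrainTable",
    grains = grains, minAreaCells = as.integer(minAreaCells),
    connectivity = as.integer(connectivity), periodic = periodic,
    cellSize = hmap@cellSize
  )
}

# Per-label coordinate mean; in periodic mode coordinates are unwrapped
# towards each grain's first cell before averaging.
centroidOf <- function(coordByLabel, D, periodic) {
  vapply(coordByLabel, function(v) {
    if (periodic) {
      ref <- v[1]
      d <- (v - ref) %% D
      d[d > D / 2] <- d[d > D / 2] - D
      ((ref + mean(d) - 1) %% D) + 1
    } else {
      mean(v)
    }
  }, numeric(1))
}

#' @rdname accessors
#' @export
setMethod("grainTable", "GrainTable", function(x) x@grains)

#' @rdname grainSummary
#' @export
setMethod("grainSummary", "GrainTable", function(x) {
  a <- x@grains$areaCells
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  if (length(a) == 0L) {
    s <- data.frame(
      count = 0L, minArea = NA_real_, maxArea = NA_real_,
      meanArea = NA_real_, sdArea = NA_real_
    )
  } else {
    s <- data.frame(
      count = length(a), minArea = min(a), maxArea = max(a),
      meanArea = mean(a), sdArea = popSd(a)
    )
  }
  cs2 <- x@cellSize^2
  s$minAreaPhys <- s$minArea * cs2
  s$maxAreaPhys <- s$maxArea * cs2
  s$meanAreaPhys <- s$meanArea * cs2
  s$sdAreaPhys <- s$sdArea * cs2
  s
})

setMethod("show", "GrainTable", function(object) {
  s <- grainSummary(object)
  cat(sprintf(
    "GrainTable: %d grains (connectivity %d, %s, min area %d)\n",
    s$count, object@connectivity,
    if (object@periodic) "periodic" else "image mode", object@minAreaCells
  ))
  if (s$count > 0) {
    cat(sprintf(
      "  area cells: min %g, max %g, mean %.2f, sd %.2f\n",
      s$minArea, s$maxArea, s$meanArea, s$sdArea
    ))
  }
})

#' Hole-size histogram of a pattern
#'
#' Holes are connected components of the unoccupied projection
#' (`height == 0`), labeled with the connectivity complementary to the
#' grains' (holes 4-connected when grains are 8-connected, and vice versa,
#' the standard digital-topology duality). Each hole's area is accumulated
#' into its size bin as total area, so the histogram shows how much of the
#' surface the holes in each size range cover; `gapRanges` records the
#' maximal runs of empty bins strictly between the lowest and highest
#' occupied bins. Dual-scale cellular patterns show two occupied ranges
#' separated by such a gap.
#'
#' @param hmap a [HeightMap-class].
#' @param binEdges strictly increasing bin edges (areas, cells); default:
#'   logarithmically spaced bins from 1 to `D^2` (see `nBins`).
#' @param grainConnectivity 4 or 8 (default 8); holes use the complement.
#' @param periodic logical; wrap laterally (default FALSE).
#' @param nBins number of default log-spaced bins (default 12).
#' @return A [HoleHistogram-class].
#' @examples
#' hist <- holeHistogram(makeFixture("holes_mix", 16),
#'                       binEdges = c(1, 10, 30, 100))
#' binTotals(hist) # 7, 0, 40
#' @export
holeHistogram <- function(hmap, binEdges = NULL, grainConnectivity = 8L,
                          periodic = FALSE, nBins = 12L) {
  stopifnot(is(hmap, "HeightMap"), grainConnectivity %in% c(4L, 8L))
  holeConn <- if (grainConnectivity == 8L) 4L else 8L
  h <- hmap@grid
  if (is.null(binEdges)) {
    top <- as.double(nrow(h)) * ncol(h)
    binEdges <- exp(seq(log(1), log(top + 1), length.out = nBins + 1L))
  }
  if (any(diff(binEdges) <= 0)) stop("binEdges must be strictly increasing")
  lab <- cpp_label((h == 0) + 0L, holeConn, periodic)
  areas <- if (max(lab) > 0L) tabulate(lab[lab > 0L]) else numeric(0)
  nb <- length(binEdges) - 1L
  totals <- numeric(nb)
  if (length(areas)) {
    bin <- findInterval(areas, binEdges)
    inb <- bin >= 1L & bin <= nb & areas < binEdges[nb + 1L]
    for (b in unique(bin[inb])) {
      totals[b] <- sum(areas[inb & bin == b])
    }
  }
  occ <- which(totals > 0)
  gaps <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("low", "high")))
  if (length(occ) >= 2L) {
    inner <- setdiff(seq(min(occ), max(occ)), occ)
    if (length(inner)) {
      runs <- split(inner, cumsum(c(1, diff(inner) != 1)))
      gaps <- do.call(rbind, lapply(runs, function(r) {
        c(binEdges[min(r)], binEdges[max(r) + 1L])
      }))
      colnames(gaps) <- c("low", "high")
      rownames(gaps) <- NULL
    }
  }
  new("HoleHistogram",
    binEdges = as.numeric(binEdges), totalArea = totals, gapRanges = gaps,
    holeAreas = as.numeric(areas), connectivity = holeConn,
    periodic = periodic
  )
}

#' @rdname accessors
#' @export
setMethod("binEdges", "HoleHistogram", function(x) x@binEdges)

#' @rdname accessors
#' @export
setMethod("binTotals", "HoleHistogram", function(x) x@totalArea)

#' @rdname accessors
#' @export
setMethod("gapRanges", "HoleHistogram", function(x) x@gapRanges)

#' @rdname accessors
#' @export
setMethod("holeAreas", "HoleHistogram", function(x) x@holeAreas)

setMethod("show", "HoleHistogram", function(object) {
  cat(sprintf(
    "HoleHistogram: %d bins, %d holes, total hole area %g\n",
    length(object@totalArea), length(object@holeAreas),
    sum(object@holeAreas)
  ))
  if (nrow(object@gapRanges)) {
    cat(sprintf("  gaps: %s\n", paste(
      apply(object@gapRanges, 1, function(r) {
        sprintf("[%g, %g)", r[1], r[2])
      }),
      collapse = ", "
    )))
  }
})

#' Detect a dual-scale hole pattern
#'
#' TRUE iff some gap in the histogram separates two occupied bin groups that
#' each carry at least `minFraction` of the total hole area -- i.e. holes
#' live at two well-separated characteristic size ranges, the signature of
#' the cellular-network (primary + secondary grain) morphology.
#'
#' @param hist a [HoleHistogram-class], ideally computed on at least 8
#'   log-spaced bins so the two scales can separate.
#' @param minFraction minimum area fraction each side must carry
#'   (default 0.05).
#' @return Logical.
#' @examples
#' hist <- holeHistogram(makeFixture("holes_mix", 16),
#'                       binEdges = c(1, 10, 30, 100))
#' detectDualScale(hist)
#' @export
detectDualScale <- function(hist, minFraction = 0.05) {
  stopifnot(is(hist, "HoleHistogram"))
  totals <- hist@totalArea
  total <- sum(totals)
  if (total == 0 || nrow(hist@gapRanges) == 0L) {
    return(FALSE)
  }
  for (g in seq_len(nrow(hist@gapRanges))) {
    low <- hist@gapRanges[g, 1]
    below <- sum(totals[hist@binEdges[-length(hist@binEdges)] < low])
    above <- total - below
    if (below >= minFraction * total && above >= minFraction * total) {
      return(TRUE)
    }
  }
  FALSE
}

#' Deterministic test patterns
#'
#' Small height maps with known grain/hole ground truth, used throughout the
#' test suite as stand-ins for AFM images:
#' \describe{
#'   \item{checkerboard}{alternating occupied cells; `D^2/2` single-cell
#'     grains at 4-connectivity.}
#'   \item{single_blob}{one 3x3 block of height 2 in the middle.}
#'   \item{two_blobs}{two disjoint 2x2 blocks of height 1.}
#'   \item{seam_grain}{a 2x2-per-side block spanning the lateral seam: one
#'     grain with periodic wrapping, two without.}
#'   \item{holes_mix}{a covered surface with holes of areas 2, 2, 3 and 40
#'     (requires `D >= 16`).}
#' }
#'
#' @param name one of the pattern names above.
#' @param D base side, `>= 8`.
#' @return A [HeightMap-class].
#' @export
makeFixture <- function(name = c("checkerboard", "single_blob", "two_blobs",
                                 "seam_grain", "holes_mix"), D = 8L) {
  name <- match.arg(name)
  D <- as.integer(D)
  if (D < 8L) stop("D must be >= 8")
  h <- matrix(0L, D, D)
  if (name == "checkerboard") {
    h[(row(h) + col(h)) %% 2L == 0L] <- 1L
  } else if (name == "single_blob") {
    m <- D %/% 2L
    h[(m - 1L):(m + 1L), (m - 1L):(m + 1L)] <- 2L
  } else if (name == "two_blobs") {
    h[2:3, 2:3] <- 1L
    h[(D - 2L):(D - 1L), (D - 2L):(D - 1L)] <- 1L
  } else if (name == "seam_grain") {
    h[c(1L, D), 4:5] <- 1L
  } else if (name == "holes_mix") {
    if (D < 16L) stop("holes_mix requires D >= 16")
    h[] <- 1L
    h[2L, 2:3] <- 0L # area 2
    h[2L, 6:7] <- 0L # area 2
    h[5L, 2:3] <- 0L # area 3 (L-shape)
    h[6L, 2L] <- 0L
    h[9:13, 3:10] <- 0L # area 40
  }
  heightMap(h)
}
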