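#' Write a lattice snapshot as plain text
#'
#' Serializes a [LatticeState-class] to a self-describing text format: a
#' header of `key value` lines (`D`, `H`, `z`, `stepIndex`, `seed`) followed
#' by one block per layer (`layer k` then `D` rows of `D` cell-code digits,
#' row r giving cells `x = 1..D` at `y = r`). Round-trips losslessly.
#'
#' @param state a [LatticeState-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readStateSnapshot()]
#' @export
writeStateSnapshot <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# evapKMC lattice snapshot v1",
    paste("D", state@D), paste("H", state@H), paste("z", format(state@z)),
    paste("stepIndex", state@stepIndex), paste("seed", state@seed)
  ), con)
  for (l in seq_len(state@H + 1L)) {
    writeLines(paste("layer", l - 1L), con)
    slab <- state@grid[, , l]
    writeLines(apply(slab, 2, paste, collapse = ""), con)
  }
  invisible(path)
}

#' Read a lattice snapshot written by [writeStateSnapshot()]
#'
#' @param path snapshot file path.
#' @return A [LatticeState-class].
#' @export
readStateSnapshot <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  kv <- function(key) {
    hit <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (!length(hit)) stop(sprintf("snapshot is missing '%s'", key))
    sub(paste0("^", key, " "), "", hit[1])
  }
  D <- as.integer(kv("D"))
  H <- as.integer(kv("H"))
  z <- as.numeric(kv("z"))
  grid <- array(.VAP, dim = c(D, D, H + 1L))
  layerAt <- grep("^layer ", lines)
  if (length(layerAt) != H + 1L) stop("snapshot has a malformed layer count")
  for (b in seq_along(layerAt)) {
    l <- as.integer(sub("^layer ", "", lines[layerAt[b]])) + 1L
    rows <- lines[(layerAt[b] + 1L):(layerAt[b] + D)]
    m <- vapply(rows, function(r) {
      as.integer(strsplit(r, "")[[1]])
    }, integer(D))
    grid[, , l] <- m # columns of m are snapshot rows (y); m is x-by-y
  }
  new("LatticeState",
    grid = grid, D = D, H = H, z = z,
    particleCount = sum(grid == .PAR),
    stepIndex = as.integer(kv("stepIndex")), seed = as.integer(kv("seed"))
  )
}

#' Write a height map as TSV
#'
#' Plain tab-separated integers, one line per `y` row; no header. The
#' physical calibration is not stored (pass `cellSize` when reading).
#'
#' @param hmap a [HeightMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHeightMapTSV <- function(hmap, path) {
  write.table(t(hmap@grid), path,
    sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a height map from TSV
#'
#' @param path TSV file written by [writeHeightMapTSV()] (or any plain-text
#'   integer grid with one `y` row per line).
#' @param cellSize physical calibration, nm per lattice unit.
#' @return A [HeightMap-class].
#' @export
readHeightMapTSV <- function(path, cellSize = 1) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  heightMap(t(m), cellSize = cellSize)
}

#' Write a height map as PGM
#'
#' Portable graymap export: binary `P5` by default or ASCII `P2`; heights
#' are the gray values, so heights above 255 are rejected.
#'
#' @param hmap a [HeightMap-class].
#' @param path output file path.
#' @param ascii write ASCII `P2` instead of binary `P5` (default FALSE).
#' @return `path`, invisibly.
#' @export
writePGM <- function(hmap, path, ascii = FALSE) {
  h <- t(hmap@grid) # PGM raster rows top-to-bottom = y rows
  if (max(h) > 255L) stop("PGM export supports heights up to 255")
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(h), nrow(h)), "255"), con)
    write.table(h, con,
      sep = " ", row.names = FALSE, col.names = FALSE,
      quote = FALSE
    )
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(h), nrow(h)), con,
      eos = NULL
    )
    writeBin(as.raw(as.vector(t(h))), con)
  }
  invisible(path)
}

#' Read a PGM height map
#'
#' Accepts ASCII `P2` and binary `P5` graymaps; gray values are interpreted
#' as heights, optionally thresholded.
#'
#' @param path PGM file path.
#' @param cellSize physical calibration, nm per lattice unit.
#' @param threshold if not `NULL`, values below it are set to 0.
#' @return A [HeightMap-class].
#' @export
readPGM <- function(path, cellSize = 1, threshold = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pgmTokens(con, 4L)
  magic <- tok[1]
  w <- as.integer(tok[2])
  ht <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  if (!magic %in% c("P2", "P5") || is.na(w) || is.na(ht) || is.na(maxval)) {
    stop("not a supported PGM (P2/P5) file")
  }
  n <- w * ht
  vals <- if (magic == "P5") {
    if (maxval > 255L) {
      raw16 <- readBin(con, "raw", n * 2L)
      as.integer(raw16[c(TRUE, FALSE)]) * 256L +
        as.integer(raw16[c(FALSE, TRUE)])
    } else {
      as.integer(readBin(con, "raw", n))
    }
  } else {
    as.integer(scan(con, what = integer(), n = n, quiet = TRUE))
  }
  if (length(vals) != n) stop("PGM pixel data is truncated")
  if (!is.null(threshold)) vals[vals < threshold] <- 0L
  m <- matrix(vals, nrow = ht, ncol = w, byrow = TRUE) # raster rows
  heightMap(t(m), cellSize = cellSize)
}

# Read the next `n` whitespace-separated header tokens, honoring `#`
# comments, leaving the connection at the first pixel byte.
pgmTokens <- function(con, n) {
  tok <- character(0)
  cur <- ""
  inComment <- FALSE
  while (length(tok) < n || nchar(cur)) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (!length(ch) || !nchar(ch)) break
    if (inComment) {
      if (ch == "\n") inComment <- FALSE
      next
    }
    if (ch == "#") {
      inComment <- TRUE
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (nchar(cur)) {
        tok <- c(tok, cur)
        cur <- ""
        if (length(tok) == n) break # the single whitespace after maxval
      }
    } else {
      cur <- paste0(cur, ch)
    }
  }
  tok
}

#' Write a run trace as TSV
#'
#' @param trace a [RunTrace-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRunTrace <- function(trace, path) {
  write.table(trace@records, path,
    sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  invisible(path)
}

#' Read a run trace TSV
#'
#' @param path file written by [writeRunTrace()].
#' @return A [RunTrace-class].
#' @export
readRunTrace <- function(path) {
  new("RunTrace", records = read.table(path, sep = "\t", header = TRUE))
}

#' Default run configuration
#'
#' The full set of simulation parameters with their defaults, as a named
#' list; this is the schema of the YAML config file. Defaults mirror the
#' published dot-pattern study conditions at analysis scale.
#'
#' @return A named list.
#' @export
defaultRunConfig <- function() {
  list(
    D = 128L, z = 0.0625, phi = 0.005,
    epsLL = 1, epsLN = 1.5, epsNN = 2, kT = 0.2,
    nMov = 20L, schedule = "constant",
    mu0 = -3.7, delta = 0.15, sigma = 0.01, nuC = 0.15,
    seed = 1L, maxSteps = 10000L, snapshotInterval = 0L,
    cellSize = 1
  )
}

#' Read a run configuration file
#'
#' YAML `key: value` document; missing keys take the defaults of
#' [defaultRunConfig()], unknown keys are an error.
#'
#' @param path YAML file path.
#' @return The effective (post-default) configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  mergeRunConfig(user)
}

#' Merge partial settings over the defaults
#'
#' @param user named list of overrides (possibly empty).
#' @return The effective configuration list.
#' @export
mergeRunConfig <- function(user = list()) {
  cfg <- defaultRunConfig()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) cfg[[k]] <- user[[k]]
  for (k in c("D", "nMov", "seed", "maxSteps", "snapshotInterval")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  if (!cfg$schedule %in% c("constant", "sigmoidal")) {
    stop("schedule must be 'constant' or 'sigmoidal'")
  }
  cfg
}

#' Write a configuration file
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' Run a simulation from a configuration
#'
#' Builds the initial state, runs the dynamics, and (optionally) writes the
#' run artifacts into `outputDir`: `trace.tsv`, `final_snapshot.txt`,
#' `heightmap.tsv`, the echoed effective `config.yaml`, a `summary.json`,
#' and periodic snapshots every `snapshotInterval` steps when that is
#' positive.
#'
#' @param config a configuration list (see [defaultRunConfig()]) or the
#'   path of a YAML config file.
#' @param outputDir output directory, created if needed; `NULL` (default)
#'   writes nothing.
#' @param quiet suppress progress messages (default TRUE).
#' @return A [SimulationResult-class], invisibly when writing.
#' @export
runFromConfig <- function(config, outputDir = NULL, quiet = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- mergeRunConfig(config)
  state <- buildInitialState(config$D, config$z, config$phi,
    seed = config$seed
  )
  params <- interactionParams(
    epsLL = config$epsLL, epsLN = config$epsLN, epsNN = config$epsNN,
    kT = config$kT
  )
  sched <- if (config$schedule == "sigmoidal") {
    muSchedule("sigmoidal",
      mu0 = config$mu0, delta = config$delta,
      sigma = config$sigma, nuC = config$nuC
    )
  } else {
    muSchedule("constant", mu0 = config$mu0)
  }
  cfg <- dynamicsConfig(
    nMov = config$nMov, maxSteps = config$maxSteps,
    seed = config$seed, schedule = sched
  )
  if (!quiet) {
    message(sprintf(
      "running: D = %d, H = %d, phi = %g, %s schedule",
      config$D, filmHeight(state), config$phi, config$schedule
    ))
  }
  res <- runSimulation(state, params, cfg,
    snapshotInterval = config$snapshotInterval
  )
  if (is.null(outputDir)) {
    return(res)
  }
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  for (snap in res@snapshots) {
    writeStateSnapshot(
      snap,
      file.path(outputDir, sprintf("snapshot_%06d.txt", stepIndex(snap)))
    )
  }
  writeRunTrace(runTrace(res), file.path(outputDir, "trace.tsv"))
  writeStateSnapshot(finalState(res), file.path(outputDir, "final_snapshot.txt"))
  hmap <- projectHeight(finalState(res), cellSize = config$cellSize)
  writeHeightMapTSV(hmap, file.path(outputDir, "heightmap.tsv"))
  writeRunConfig(config, file.path(outputDir, "config.yaml"))
  rec <- traceRecords(runTrace(res))
  summary <- list(
    steps = stepIndex(finalState(res)),
    terminated = utils::tail(rec$liquidFraction, 1) == 0,
    finalNu = driedFraction(finalState(res)),
    particleCount = particleCount(finalState(res)),
    coverageColumns = sum(latticeGrid(hmap) > 0)
  )
  jsonlite::write_json(summary, file.path(outputDir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(res)
}
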