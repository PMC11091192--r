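## File formats: dense contact matrices with a self-describing header,
## bedGraph tracks and BED6 anchors (via rtracklayer), XYZ-like
## trajectories, JSON model files and run manifests.
##
## Coordinates are 0-based half-open everywhere (BED/bedGraph native).

#' Write a contact map as a dense headered matrix
#'
#' Plain-text format: comment header lines `# chrom4d_matrix`, `# n=`,
#' `# bin_bp=`, `# threshold=`, `# n_conformations=`, then `n`
#' whitespace-separated rows at full float precision.
#'
#' @param map a [ContactMap-class]
#' @param path output file.
#' @export
writeContactMap <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) if (is.na(x)) "NA" else sprintf("%.17g", x)
  writeLines(c("# chrom4d_matrix",
               sprintf("# n=%d", nrow(map@map)),
               paste0("# bin_bp=", fmt(map@binBp)),
               paste0("# threshold=", fmt(map@threshold)),
               sprintf("# n_conformations=%d", map@nConformations)), con)
  utils::write.table(format(map@map, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

headerField <- function(lines, key) {
  hit <- grep(sprintf("^# %s=", key), lines, value = TRUE)
  if (!length(hit)) stop("malformed header: missing field '", key, "'")
  val <- sub(sprintf("^# %s=", key), "", hit[1])
  if (val %in% c("NA", "nan", "-nan")) NA_real_ else as.numeric(val)
}

#' Read a dense headered contact matrix
#'
#' @param path input file written by [writeContactMap()] (or any dense
#'   matrix with the same header).
#' @param expectedBinBp optional bin-size check; a mismatch is an error.
#' @return a [ContactMap-class]
#' @export
readContactMap <- function(path, expectedBinBp = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  n <- as.integer(headerField(hdr, "n"))
  binBp <- headerField(hdr, "bin_bp")
  thr <- headerField(hdr, "threshold")
  nconf <- as.integer(headerField(hdr, "n_conformations"))
  if (!is.null(expectedBinBp) && !is.na(binBp) && binBp != expectedBinBp)
    stop("bin_bp=", binBp, " does not match the expected grid of ",
         expectedBinBp, " bp")
  m <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")]))
  dimnames(m) <- NULL
  if (nrow(m) != n || ncol(m) != n)
    stop("matrix shape does not match the header n=", n)
  if (max(abs(m - t(m))) > 1e-8) stop("matrix is not symmetric")
  new("ContactMap", map = m, binBp = binBp, threshold = thr,
      nConformations = nconf)
}

#' Write an epigenetic track as bedGraph
#'
#' One interval per bin, 0-based half-open, on a synthetic chromosome
#' name.
#'
#' @param track an [EpiTrack-class]
#' @param path output file.
#' @param chrom chromosome name used in the file.
#' @export
writeBedGraphTrack <- function(track, path, chrom = "chrS") {
  n <- length(track@values)
  gr <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(start = (seq_len(n) - 1) * track@binBp + 1,
                     width = track@binBp),
    score = track@values)
  rtracklayer::export.bedGraph(gr, path)
}

#' Read a bedGraph file into intervals
#'
#' @param path bedGraph file.
#' @return data.frame with 0-based half-open `start`, `end` and `value`,
#'   suitable for [binTrack()].
#' @export
readBedGraphTrack <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             value = gr$score)
}

#' Write anchors as BED6
#'
#' One line per anchor: interval of one bead, `score = round(1000 * p)`,
#' strand `+` for forward, `-` for reverse, `.` for bidirectional.
#'
#' @param anchors an [AnchorSet-class]
#' @param path output file.
#' @param binBp bp per bead.
#' @param chrom chromosome name.
#' @export
writeAnchorsBed <- function(anchors, path, binBp = 500, chrom = "chrS") {
  n <- length(anchors@bead)
  strand <- c(forward = "+", reverse = "-", bidirectional = ".")
  df <- data.frame(chrom = rep(chrom, n),
                   start = anchors@bead * binBp,
                   end = (anchors@bead + 1) * binBp,
                   name = if (n) paste0("anchor", seq_len(n)) else character(0),
                   score = as.integer(round(1000 * anchors@prob)),
                   strand = unname(strand[anchors@orientation]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read BED6 anchors
#'
#' @param path BED6 file (strand = orientation, score/1000 = probability).
#' @param binBp bp per bead (bead index = start / binBp).
#' @return an [AnchorSet-class]
#' @export
readAnchorsBed <- function(path, binBp = 500) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  if (any(df$start %% binBp != 0))
    stop("anchor starts are not aligned to the ", binBp, " bp bead grid")
  orient <- c("+" = "forward", "-" = "reverse", "." = "bidirectional")[
    as.character(df$strand)]
  if (anyNA(orient)) stop("BED strand column must be '+', '-' or '.'")
  anchorSet(df$start %/% binBp, unname(orient), df$score / 1000)
}

#' Write a trajectory as XYZ-like text
#'
#' One block per frame: an atom-count line, a comment line carrying the
#' time stamp and metadata (`t=... boxL=... g=... replica=...`), then one
#' `C x y z` line per bead at full float precision, so that write/read
#' round-trips exactly.
#'
#' @param trajectory a [Trajectory-class]
#' @param path output file.
#' @export
writeTrajectoryXYZ <- function(trajectory, path) {
  fr <- trajectory@frames
  n <- dim(fr)[1]; nf <- dim(fr)[3]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("t=%.17g boxL=%.17g g=%.17g replica=%d",
                       trajectory@times[f], trajectory@boxL, trajectory@g,
                       trajectory@replicaId), con)
    writeLines(sprintf("C %.17g %.17g %.17g", fr[, 1, f], fr[, 2, f],
                       fr[, 3, f]), con)
  }
}

#' Read an XYZ-like trajectory
#' @param path file written by [writeTrajectoryXYZ()].
#' @return a [Trajectory-class]
#' @export
readTrajectoryXYZ <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); times <- numeric(0)
  boxL <- NA_real_; g <- NA_real_; repl <- 1L
  while (pos <= length(lines)) {
    n <- as.integer(lines[pos])
    meta <- lines[pos + 1L]
    getv <- function(key) as.numeric(sub(sprintf(".*%s=([^ ]+).*", key),
                                         "\\1", meta))
    times <- c(times, getv("t"))
    boxL <- getv("boxL"); g <- getv("g"); repl <- as.integer(getv("replica"))
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- do.call(rbind, strsplit(block, " ", fixed = TRUE))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(parts[, 2:4]), ncol = 3)
    pos <- pos + 2L + n
  }
  arr <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  new("Trajectory", frames = arr, binderFrames = NULL, times = times,
      replicaId = repl, boxL = boxL, g = g)
}

#' Write a polymer model as self-describing JSON
#'
#' Sections: beads (types, g, rInt, inert tails), affinities, anchors and
#' extrusion parameters, at full float precision.
#'
#' @param model a [PolymerModel-class]
#' @param path output file.
#' @export
writePolymerModel <- function(model, path) {
  obj <- list(
    format = "chrom4d_model",
    beads = list(n = model@nBeads, types = model@beadTypes, g = model@g,
                 rInt = model@rInt, inertTail = model@inertTail),
    binders = list(types = model@binderTypes),
    affinity = lapply(seq_len(nrow(model@affinity)), function(i)
      as.numeric(model@affinity[i, ])),
    anchors = list(bead = model@anchors@bead,
                   orientation = model@anchors@orientation,
                   prob = model@anchors@prob),
    extrusion = list(nExtruders = model@extrusion@nExtruders,
                     stepInterval = model@extrusion@stepInterval,
                     kOff = model@extrusion@kOff,
                     oneSided = model@extrusion@oneSided))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
}

#' Read a polymer model JSON file
#' @param path file written by [writePolymerModel()].
#' @return a [PolymerModel-class]
#' @export
readPolymerModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "chrom4d_model"))
    stop("not a chrom4d model file (missing format tag)")
  aff <- if (is.matrix(obj$affinity)) obj$affinity else
    do.call(rbind, lapply(obj$affinity, as.numeric))
  aff <- matrix(as.numeric(aff), nrow = length(obj$binders$types))
  rownames(aff) <- obj$binders$types
  anch <- anchorSet(obj$anchors$bead, obj$anchors$orientation,
                    obj$anchors$prob)
  ex <- new("ExtrusionParams",
            nExtruders = as.integer(obj$extrusion$nExtruders),
            stepInterval = as.integer(obj$extrusion$stepInterval),
            kOff = obj$extrusion$kOff, oneSided = obj$extrusion$oneSided)
  newPolymerModel(obj$beads$types, obj$binders$types, aff, g = obj$beads$g,
                  rInt = obj$beads$rInt, anchors = anch, extrusion = ex,
                  inertTail = obj$beads$inertTail)
}

#' Write a run manifest
#'
#' Every command-line run records exactly one manifest: command,
#' arguments, seeds, package version, input/output paths and a timestamp.
#'
#' @param command subcommand name.
#' @param args named list of parsed arguments.
#' @param seed integer seed in force.
#' @param inputs,outputs character vectors of paths.
#' @param path manifest destination (JSON).
#' @export
writeRunManifest <- function(command, args, seed, inputs, outputs, path) {
  obj <- list(command = command, args = args, seed = seed,
              version = as.character(utils::packageVersion("chrom4d")),
              inputs = inputs, outputs = outputs,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
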