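## Binding-profile TSV I/O: long format (type, bead, count).

#' Write a binding profile as TSV
#'
#' Long format with columns `type`, `bead` (0-based), `count`; only
#' nonzero entries are written.
#'
#' @param profile a [BindingProfile-class]
#' @param path output file.
#' @export
writeBindingProfile <- function(profile, path) {
  P <- profile@counts
  idx <- which(P > 0, arr.ind = TRUE)
  df <- data.frame(type = profile@typeLabels[idx[, 1]],
                   bead = idx[, 2] - 1L,
                   count = P[idx])
  df <- df[order(df$type, df$bead), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chrom4d_profile n_beads=%d bin_bp=%.17g",
                     ncol(P), profile@binBp), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a binding profile TSV
#' @param path file written by [writeBindingProfile()].
#' @return a [BindingProfile-class]
#' @export
readBindingProfile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!grepl("^# chrom4d_profile", hdr)) stop("not a chrom4d profile file")
  n <- as.integer(sub(".*n_beads=([0-9]+).*", "\\1", hdr))
  binBp <- as.numeric(sub(".*bin_bp=([^ ]+).*", "\\1", hdr))
  df <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  types <- sort(unique(df$type))
  P <- matrix(0L, length(types), n)
  P[cbind(match(df$type, types), df$bead + 1L)] <- as.integer(df$count)
  new("BindingProfile", counts = P, binBp = binBp, typeLabels = types)
}
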