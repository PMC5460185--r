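## File formats (all plain text, documented in README):
##   dense-tsv : tab-separated floats, no header, row i = bin i (0-based)
##   coo-tsv   : sparse upper-triangle triplets `bin1 bin2 value` with a
##               header line `# chrom=<c> bin_size=<b> n_bins=<n>`
##   conformations : `# chrom=<c> bin_size=<b> n_bins=<n> n_models=<m>`
##               then `model bin x y z` (model and bin 0-based, um)
## BED / bedGraph input is parsed by rtracklayer; both are 0-based
## half-open on disk, matching the internal convention.

fmt_num <- function(x) sprintf("%.17g", x)

## Locate the first malformed line of a whitespace-delimited file so parse
## errors can name it. `n_fields` = minimum field count; `numeric_fields` =
## indices that must parse as numbers.
first_bad_line <- function(path, n_fields, numeric_fields) {
  lines <- readLines(path, warn = FALSE)
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#") || startsWith(ln, "track"))
      next
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(f) < n_fields) return(k)
    if (anyNA(suppressWarnings(as.numeric(f[numeric_fields])))) return(k)
  }
  NA_integer_
}

#' Read a per-chromosome Hi-C contact matrix
#'
#' Supports two plain-text dialects: `dense-tsv` (tab-separated floats, no
#' header, row i = bin i) and `coo-tsv` (sparse cooler-style triplets with a
#' metadata header). Matrices must be square and non-negative; asymmetries
#' are averaged away with a warning.
#'
#' @param path File path.
#' @param format `"dense-tsv"` or `"coo-tsv"`.
#' @param chrom Chromosome name. Required for `dense-tsv`; for `coo-tsv` it
#'   is checked against the file header when given.
#' @param bin_size Bin size in bp (required for `dense-tsv`).
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("dense-tsv", "coo-tsv"),
                                chrom = NULL, bin_size = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense-tsv") {
    if (is.null(chrom) || is.null(bin_size))
      stop("dense-tsv input needs explicit chrom and bin_size")
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    C <- as.matrix(dt)
    if (nrow(C) != ncol(C))
      stop(sprintf("non-square matrix: %d rows x %d columns", nrow(C), ncol(C)))
    contact_matrix(C, bin_table(chrom, bin_size, nrow(C)))
  } else {
    hdr <- readLines(path, n = 1L)
    m <- regmatches(hdr, gregexpr("(chrom|bin_size|n_bins)=[^ \t]+", hdr))[[1]]
    kv <- strsplit(m, "=", fixed = TRUE)
    meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    if (!all(c("chrom", "bin_size", "n_bins") %in% names(meta)))
      stop("coo-tsv header must carry chrom=, bin_size=, n_bins=")
    if (!is.null(chrom) && !identical(chrom, unname(meta[["chrom"]])))
      stop(sprintf("chromosome %s not present (file has %s)", chrom, meta[["chrom"]]))
    n <- as.integer(meta[["n_bins"]])
    dt <- data.table::fread(path, header = FALSE, skip = 1L,
                            col.names = c("i", "j", "value"))
    if (nrow(dt) && (max(dt$i, dt$j) >= n || min(dt$i, dt$j) < 0))
      stop("bin index out of range in coo-tsv body")
    C <- matrix(0, n, n)
    C[cbind(dt$i + 1L, dt$j + 1L)] <- dt$value
    C[cbind(dt$j + 1L, dt$i + 1L)] <- dt$value
    contact_matrix(C, bin_table(unname(meta[["chrom"]]), as.numeric(meta[["bin_size"]]), n))
  }
}

#' Write a contact matrix
#'
#' @param mat A `ContactMatrix`.
#' @param path Output path.
#' @param format `"dense-tsv"` or `"coo-tsv"` (upper triangle incl. diagonal,
#'   zeros omitted). Values are written with full round-trip precision.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(mat, path, format = c("dense-tsv", "coo-tsv")) {
  format <- match.arg(format)
  C <- mat$C
  if (format == "dense-tsv") {
    lines <- apply(C, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  } else {
    b <- mat$bins
    idx <- which(upper.tri(C, diag = TRUE) & C != 0, arr.ind = TRUE)
    lines <- c(sprintf("# chrom=%s bin_size=%s n_bins=%d",
                       b$chrom, fmt_num(b$bin_size), b$n_bins),
               sprintf("%d\t%d\t%s", idx[, 1L] - 1L, idx[, 2L] - 1L,
                       fmt_num(C[idx])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Bin a bedGraph track onto a chromosome binning
#'
#' Interval values are averaged into bins with length weighting; bins with
#' no coverage are masked (`NA`).
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param bins Target [bin_table()].
#' @param name Track name; defaults to the file name.
#' @return A [genome_track()].
#' @export
read_track <- function(path, bins, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) {
                   bad <- first_bad_line(path, 4L, 2:4)
                   stop(sprintf("malformed bedGraph line %s in %s: %s",
                                ifelse(is.na(bad), "?", bad), path,
                                conditionMessage(e)), call. = FALSE)
                 })
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == bins$chrom]
  n <- bins$n_bins
  bs <- bins$bin_size
  if (length(gr) == 0)
    return(genome_track(rep(NA_real_, n), bins, name))
  s <- pmax(GenomicRanges::start(gr) - 1, 0)   # back to 0-based half-open
  e <- pmin(GenomicRanges::end(gr), n * bs)
  v <- gr$score
  keep <- e > s
  s <- s[keep]; e <- e[keep]; v <- v[keep]
  if (any(e > n * bs + bs)) stop("interval beyond chromosome extent")
  fb <- floor(s / bs)
  lb <- floor((e - 1) / bs)
  k <- lb - fb + 1
  bin <- rep(fb, k) + sequence(k) - 1
  s2 <- rep(s, k); e2 <- rep(e, k); v2 <- rep(v, k)
  ps <- pmax(s2, bin * bs)
  pe <- pmin(e2, (bin + 1) * bs)
  w <- pe - ps
  wsum <- rep(0, n); vsum <- rep(0, n)
  agg_w <- rowsum(w, bin)
  agg_v <- rowsum(w * v2, bin)
  ids <- as.integer(rownames(agg_w)) + 1L
  wsum[ids] <- agg_w[, 1L]; vsum[ids] <- agg_v[, 1L]
  vals <- ifelse(wsum > 0, vsum / wsum, NA_real_)
  genome_track(vals, bins, name)
}

#' Write a track as bedGraph (masked bins omitted)
#' @param track A `GenomeTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  b <- track$bins
  i <- which(!is.na(track$values)) - 1L
  writeLines(sprintf("%s\t%s\t%s\t%s", b$chrom, fmt_num(i * b$bin_size),
                     fmt_num((i + 1) * b$bin_size), fmt_num(track$values[i + 1L])),
             path)
  invisible(path)
}

#' Centered moving-average smoothing of a track
#'
#' Averages unmasked values in a centered window. `window_bp` must be a
#' positive multiple of the bin size; even bin counts are rounded down to
#' the nearest odd window so the window stays centered.
#'
#' @param track A `GenomeTrack`.
#' @param window_bp Window width in bp.
#' @return Smoothed `GenomeTrack`.
#' @export
smooth_track <- function(track, window_bp) {
  bs <- track$bins$bin_size
  if (window_bp < bs) stop("smoothing window must be at least one bin")
  if (window_bp %% bs != 0) stop("window_bp must be a multiple of bin_size")
  h <- floor((window_bp / bs - 1) / 2)
  if (h == 0) return(track)
  v <- track$values
  n <- length(v)
  out <- vapply(seq_len(n), function(i) {
    win <- v[max(1, i - h):min(n, i + h)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  genome_track(out, track$bins, track$name)
}

#' Read labelled segments from BED
#'
#' @param path BED file (>= 3 columns; column 4, when present, is the label).
#' @param chrom Optional chromosome filter.
#' @param validate Reject overlapping segments (default `TRUE`).
#' @return A [segment_list()].
#' @export
read_segments <- function(path, chrom = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) {
                   bad <- first_bad_line(path, 3L, 2:3)
                   stop(sprintf("malformed BED line %s in %s: %s",
                                ifelse(is.na(bad), "?", bad), path,
                                conditionMessage(e)), call. = FALSE)
                 })
  if (!is.null(chrom))
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (length(gr) == 0) stop("no segments", if (!is.null(chrom)) paste0(" on ", chrom))
  lab <- if (!is.null(gr$name)) gr$name else "segment"
  segment_list(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
               lab, validate = validate)
}

#' Write segments as BED4
#' @param segments A `SegmentList`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  writeLines(sprintf("%s\t%s\t%s\t%s", segments$chrom, fmt_num(segments$start),
                     fmt_num(segments$end), segments$label), path)
  invisible(path)
}

#' Write a conformation ensemble as a plain-text table
#'
#' Format: one metadata header line, then columns
#' `model bin x y z` (0-based ids, coordinates in micrometres, full
#' round-trip precision). [read_conformations()] inverts it losslessly.
#'
#' @param ens An `Ensemble` (or single `Conformation`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conformations <- function(ens, path) {
  if (inherits(ens, "Conformation")) ens <- ensemble(list(ens))
  b <- ens[[1]]$bins
  lines <- c(sprintf("# chrom=%s bin_size=%s n_bins=%d n_models=%d",
                     b$chrom, fmt_num(b$bin_size), b$n_bins, length(ens)))
  body <- lapply(seq_along(ens), function(m) {
    xyz <- ens[[m]]$coords
    sprintf("%d\t%d\t%s\t%s\t%s", m - 1L, seq_len(nrow(xyz)) - 1L,
            fmt_num(xyz[, 1]), fmt_num(xyz[, 2]), fmt_num(xyz[, 3]))
  })
  writeLines(c(lines, unlist(body)), path)
  invisible(path)
}

#' Read a conformation ensemble written by [write_conformations()]
#' @param path File path.
#' @return An `Ensemble`.
#' @export
read_conformations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, gregexpr("(chrom|bin_size|n_bins|n_models)=[^ \t]+", hdr))[[1]]
  kv <- strsplit(m, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  if (!all(c("chrom", "bin_size", "n_bins", "n_models") %in% names(meta)))
    stop("conformation header must carry chrom=, bin_size=, n_bins=, n_models=")
  bad <- first_bad_line(path, 5L, 1:5)
  if (!is.na(bad)) stop(sprintf("malformed conformation line %d (need model bin x y z)", bad))
  dt <- data.table::fread(path, header = FALSE, skip = 1L,
                          col.names = c("model", "bin", "x", "y", "z"))
  n <- as.integer(meta[["n_bins"]])
  bins <- bin_table(unname(meta[["chrom"]]), as.numeric(meta[["bin_size"]]), n)
  models <- lapply(sort(unique(dt$model)), function(m) {
    d <- dt[dt$model == m, ]
    if (nrow(d) != n) stop(sprintf("model %d has %d beads, expected %d", m, nrow(d), n))
    d <- d[order(d$bin), ]
    conformation(cbind(d$x, d$y, d$z), bins)
  })
  if (length(models) != as.integer(meta[["n_models"]]))
    stop("model count does not match header")
  ensemble(models)
}
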