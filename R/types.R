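#' Binned genomic axis for one chromosome
#'
#' A `BinTable` describes a contiguous, non-overlapping 0-based half-open
#' binning of a single chromosome: bin `i` (0-based) covers
#' `[i * bin_size, (i + 1) * bin_size)`.
#'
#' @param chrom Chromosome name (e.g. `"chr1"`).
#' @param bin_size Bin width in bp (single positive integer).
#' @param n_bins Number of bins (>= 2).
#' @return An object of class `BinTable`.
#' @export
bin_table <- function(chrom, bin_size, n_bins) {
  bin_size <- as.numeric(bin_size)
  n_bins <- as.integer(n_bins)
  stopifnot(length(chrom) == 1L, is.character(chrom), nzchar(chrom))
  if (!is.finite(bin_size) || bin_size <= 0 || bin_size != round(bin_size))
    stop("bin_size must be a positive integer number of bp")
  if (is.na(n_bins) || n_bins < 2L)
    stop("n_bins must be >= 2")
  structure(list(chrom = chrom, bin_size = bin_size, n_bins = n_bins),
            class = "BinTable")
}

#' @export
print.BinTable <- function(x, ...) {
  cat(sprintf("BinTable: %s, %d bins of %s bp (%.1f Mb)\n",
              x$chrom, x$n_bins, format(x$bin_size, big.mark = ","),
              x$n_bins * x$bin_size / 1e6))
  invisible(x)
}

#' Start coordinates (bp) of each bin
#' @param bins A `BinTable`.
#' @return Numeric vector of 0-based bin start positions.
#' @export
bin_starts <- function(bins) (seq_len(bins$n_bins) - 1) * bins$bin_size

same_bins <- function(a, b) {
  identical(a$chrom, b$chrom) && a$bin_size == b$bin_size && a$n_bins == b$n_bins
}

#' Symmetric binned contact-frequency matrix
#'
#' Wraps an `n_bins x n_bins` non-negative matrix of Hi-C contact
#' frequencies together with its [bin_table()]. Asymmetries beyond a small
#' relative tolerance are symmetrized by averaging, with a warning; the
#' diagonal is carried along but never used as a restraint source.
#'
#' @param C Square numeric matrix of contact frequencies.
#' @param bins A `BinTable` with `n_bins == nrow(C)`.
#' @param tol Relative tolerance for silent symmetrization.
#' @return An object of class `ContactMatrix` with fields `C` and `bins`.
#' @export
contact_matrix <- function(C, bins, tol = 1e-8) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("contact matrix must be square")
  if (!is.numeric(C) || anyNA(C)) stop("contact matrix must be numeric without NA")
  if (any(C < 0)) stop("contact frequencies must be non-negative")
  if (nrow(C) != bins$n_bins) stop("matrix dimension does not match BinTable")
  asym <- max(abs(C - t(C)))
  scale <- max(abs(C), 1e-300)
  if (asym > tol * scale) {
    warning(sprintf(
      "asymmetric contact matrix (max |C - t(C)| = %.3g); symmetrizing by averaging",
      asym))
  }
  C <- (C + t(C)) / 2
  dimnames(C) <- NULL
  structure(list(C = C, bins = bins), class = "ContactMatrix")
}

## internal fast path for matrices that are symmetric by construction
new_contact_matrix <- function(C, bins) {
  dimnames(C) <- NULL
  structure(list(C = C, bins = bins), class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d x %d bins (%s bp), total %.4g\n",
              x$bins$chrom, x$bins$n_bins, x$bins$n_bins,
              format(x$bins$bin_size, big.mark = ","), sum(x$C)))
  invisible(x)
}

#' Per-bin genome track with missing-value mask
#'
#' Values are stored per bin; `NA` marks missing (masked) bins, which are
#' excluded from every downstream statistic.
#'
#' @param values Numeric vector, one value per bin; `NA` = masked.
#' @param bins A `BinTable`.
#' @param name Track label.
#' @return An object of class `GenomeTrack`.
#' @export
genome_track <- function(values, bins, name = "track") {
  values <- as.numeric(values)
  if (length(values) != bins$n_bins)
    stop("track length must equal n_bins")
  structure(list(values = values, bins = bins, name = name),
            class = "GenomeTrack")
}

#' @export
print.GenomeTrack <- function(x, ...) {
  cat(sprintf("GenomeTrack '%s': %d bins, %d masked\n",
              x$name, x$bins$n_bins, sum(is.na(x$values))))
  invisible(x)
}

#' Labelled genomic segments (0-based half-open)
#'
#' @param chrom Chromosome name(s), recycled.
#' @param start,end Interval bounds in bp, 0-based half-open, `start < end`.
#' @param label Segment labels (e.g. PMD / non-PMD, or type A / B).
#' @param validate If `TRUE`, reject overlapping segments on one chromosome.
#' @return A `data.frame` of class `SegmentList` with columns
#'   `chrom`, `start`, `end`, `label`.
#' @export
segment_list <- function(chrom, start, end, label = "segment", validate = TRUE) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), label = as.character(label),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0)) stop("segment start must be >= 0")
  if (any(df$start >= df$end)) stop("segments must satisfy start < end")
  if (validate) {
    for (ch in unique(df$chrom)) {
      s <- df[df$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop(sprintf("overlapping segments on %s", ch))
    }
  }
  class(df) <- c("SegmentList", "data.frame")
  df
}

#' Single 3D conformation of a binned chromosome
#'
#' @param coords `n_bins x 3` matrix of bead coordinates in micrometres.
#' @param bins A `BinTable`.
#' @param seed Optional RNG seed the conformation was generated from.
#' @return An object of class `Conformation`.
#' @export
conformation <- function(coords, bins, seed = NA_integer_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  if (nrow(coords) != bins$n_bins)
    stop("coordinate count does not match BinTable")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  dimnames(coords) <- NULL
  structure(list(coords = coords, bins = bins, seed = seed),
            class = "Conformation")
}

#' @export
print.Conformation <- function(x, ...) {
  cat(sprintf("Conformation: %d beads (%s), Rg = %.3f um\n",
              x$bins$n_bins, x$bins$chrom, radius_of_gyration(x)))
  invisible(x)
}

#' Collection of conformations of the same chromosome
#'
#' @param models Non-empty list of [conformation()] objects on identical bins.
#' @return An object of class `Ensemble` (a list of `Conformation`s).
#' @export
ensemble <- function(models) {
  if (length(models) == 0) stop("ensembles must be non-empty")
  if (!all(vapply(models, inherits, logical(1), "Conformation")))
    stop("all models must be Conformation objects")
  b <- models[[1]]$bins
  if (!all(vapply(models, function(m) same_bins(m$bins, b), logical(1))))
    stop("all models must share one BinTable")
  structure(models, class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d models x %d beads (%s)\n",
              length(x), x[[1]]$bins$n_bins, x[[1]]$bins$chrom))
  invisible(x)
}

#' Radius of gyration of a conformation (micrometres)
#' @param conf A `Conformation`.
#' @return Scalar radius of gyration.
#' @export
radius_of_gyration <- function(conf) {
  x <- sweep(conf$coords, 2, colMeans(conf$coords))
  sqrt(mean(rowSums(x^2)))
}
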