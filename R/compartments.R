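#' Observed/expected normalization of a contact matrix
#'
#' Divides each entry by the mean contact at its genomic separation
#' (including the diagonal), removing the distance-decay trend. Separations
#' whose mean is zero are masked (`NA`). The result is symmetric and
#' invariant to global rescaling of the matrix.
#'
#' @param mat A `ContactMatrix` with >= 2 bins.
#' @return An `n x n` numeric matrix (plain matrix, `NA` = masked).
#' @export
observed_over_expected <- function(mat) {
  C <- mat$C
  n <- nrow(C)
  if (n < 2) stop("need >= 2 bins")
  sep <- abs(row(C) - col(C))
  means <- vapply(0:(n - 1), function(k) mean(C[sep == k]), numeric(1))
  expd <- means[sep + 1L]
  oe <- ifelse(expd > 0, C / expd, NA_real_)
  matrix(oe, n, n)
}

#' Pearson correlation matrix of O/E rows
#'
#' Entry (i, j) is the Pearson correlation of rows i and j of the O/E
#' matrix over jointly unmasked columns; the plaid sign pattern of this
#' matrix is the signature of two-compartment segregation. Bins with
#' constant or all-missing rows are masked.
#'
#' @param oe O/E matrix from [observed_over_expected()].
#' @return Symmetric correlation matrix with unit diagonal (`NA` = masked).
#' @export
correlation_matrix <- function(oe) {
  n <- nrow(oe)
  sds <- apply(oe, 1, stats::sd, na.rm = TRUE)
  ok <- !is.na(sds) & sds > 0
  corr <- matrix(NA_real_, n, n)
  if (any(ok)) {
    corr[ok, ok] <- suppressWarnings(
      stats::cor(t(oe[ok, ok, drop = FALSE]), use = "pairwise.complete.obs"))
  }
  diag(corr)[ok] <- 1
  corr
}

#' Call A/B compartments by spectral clustering
#'
#' Two-way spectral split of the bin-bin correlation matrix: the leading
#' eigenvector of the column-centered (re-symmetrized) correlation matrix
#' is computed and its entries are clustered with 2-means. The eigenvector
#' sign is arbitrary, so the cluster with the higher mean value of a
#' user-supplied orientation track (CpG density or GC content recommended
#' — compartment A is CpG-enriched) is labeled A. Masked bins stay
#' unassigned.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param orientation A `GenomeTrack` on the same bins used only to decide
#'   which cluster is A.
#' @param bins The `BinTable` of the matrix.
#' @param seed Seed for the 2-means step.
#' @return Object of class `CompartmentProfile`: `bins`, `label`
#'   (`"A"`/`"B"`/`"unassigned"` per bin), `eigenvector`,
#'   `orientation_track` (name).
#' @export
call_compartments <- function(corr, orientation, bins, seed = 1L) {
  n <- nrow(corr)
  if (orientation$bins$n_bins != n) stop("orientation track on different bins")
  ok <- which(colSums(!is.na(corr)) > 1)
  K <- corr[ok, ok, drop = FALSE]
  K[is.na(K)] <- 0
  Kc <- sweep(K, 2, colMeans(K))
  Kc <- (Kc + t(Kc)) / 2
  ev <- eigen(Kc, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (ev$values[1] < 0.05 * length(ok))
    warning("degenerate spectral split: correlation matrix has no two-block structure")
  set.seed(seed)
  km <- stats::kmeans(v, centers = 2, nstart = 10)
  label <- rep("unassigned", n)
  m1 <- mean(orientation$values[ok][km$cluster == 1], na.rm = TRUE)
  m2 <- mean(orientation$values[ok][km$cluster == 2], na.rm = TRUE)
  if (isTRUE(all.equal(m1, m2)))
    stop("orientation-track means are equal between clusters; choose labels explicitly")
  a_cluster <- if (m1 > m2) 1L else 2L
  label[ok] <- ifelse(km$cluster == a_cluster, "A", "B")
  structure(list(bins = bins, label = label,
                 eigenvector = {
                   full <- rep(NA_real_, n); full[ok] <- v; full
                 },
                 orientation_track = orientation$name),
            class = "CompartmentProfile")
}

#' @export
print.CompartmentProfile <- function(x, ...) {
  tb <- table(factor(x$label, c("A", "B", "unassigned")))
  cat(sprintf("CompartmentProfile: %s, %d A / %d B / %d unassigned bins (oriented by %s)\n",
              x$bins$chrom, tb[["A"]], tb[["B"]], tb[["unassigned"]],
              x$orientation_track))
  invisible(x)
}

#' Per-bin degree of compartmentalization
#'
#' For each bin, the (natural) log ratio of its mean normalized (O/E)
#' contact with compartment-A bins to that with compartment-B bins,
#' excluding self in both means. Deep-A bins are strongly positive, deep-B
#' bins strongly negative, and compartment boundaries sit near zero. A
#' pseudocount of `eps_factor x mean(O/E)` keeps the log finite for bins
#' with no contacts to one class. Scale-invariant in the input matrix.
#'
#' @param mat A `ContactMatrix`.
#' @param profile A `CompartmentProfile` with both labels present.
#' @param eps_factor Pseudocount factor (default 1e-6).
#' @return A `GenomeTrack` (`NA` on bins with no assigned partners).
#' @export
degree_of_compartmentalization <- function(mat, profile, eps_factor = 1e-6) {
  oe <- observed_over_expected(mat)
  a <- profile$label == "A"
  b <- profile$label == "B"
  if (!any(a) || !any(b)) stop("profile must contain both A and B bins")
  eps <- eps_factor * mean(oe, na.rm = TRUE)
  n <- nrow(oe)
  deg <- vapply(seq_len(n), function(i) {
    ai <- a; bi <- b
    ai[i] <- FALSE; bi[i] <- FALSE
    ma <- mean(oe[i, ai], na.rm = TRUE)
    mb <- mean(oe[i, bi], na.rm = TRUE)
    if (!is.finite(ma) || !is.finite(mb)) return(NA_real_)
    log((ma + eps) / (mb + eps))
  }, numeric(1))
  deg[profile$label == "unassigned"] <- NA_real_
  genome_track(deg, profile$bins, name = "degree_of_compartmentalization")
}

#' Correlate the degree of compartmentalization with a genome feature
#'
#' Optionally smooths the feature track with [smooth_track()] (the window
#' sizes of the reference analysis range from 50 kb to 2 Mb depending on
#' the feature), then computes the masked Pearson correlation.
#'
#' @param degree Degree track from [degree_of_compartmentalization()].
#' @param feature Feature `GenomeTrack` on the same bins.
#' @param window_bp Optional smoothing window for the feature (bp).
#' @return Pearson correlation over jointly unmasked bins.
#' @export
track_correlation <- function(degree, feature, window_bp = NULL) {
  if (!same_bins(degree$bins, feature$bins)) stop("tracks on different bins")
  if (!is.null(window_bp)) feature <- smooth_track(feature, window_bp)
  masked_pearson(degree$values, feature$values)
}

#' Fraction of segment length overlapping one compartment label
#'
#' Length-weighted overlap: total bp of the segments falling in bins with
#' the queried label divided by total segment bp (the statistic behind
#' "95.5% of LAD length in compartment B"-style summaries).
#'
#' @param segments A `SegmentList` on the profile's chromosome.
#' @param profile A `CompartmentProfile`.
#' @param label `"A"` or `"B"` (or `"unassigned"`).
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(segments, profile, label = c("A", "B", "unassigned")) {
  label <- match.arg(label)
  segs <- segments[segments$chrom == profile$bins$chrom, , drop = FALSE]
  bs <- profile$bins$bin_size
  n <- profile$bins$n_bins
  total <- sum(segs$end - segs$start)
  if (nrow(segs) == 0 || total <= 0) stop("zero total segment length on this chromosome")
  hit <- 0
  for (r in seq_len(nrow(segs))) {
    s <- segs$start[r]; e <- segs$end[r]
    fb <- floor(s / bs); lb <- min(floor((e - 1) / bs), n - 1)
    if (lb < fb) next
    for (bin in fb:lb) {
      if (profile$label[bin + 1L] == label)
        hit <- hit + min(e, (bin + 1) * bs) - max(s, bin * bs)
    }
  }
  hit / total
}
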