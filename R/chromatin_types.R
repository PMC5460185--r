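#' Log-spaced genomic-distance bins for variance features
#'
#' Two-sided defaults: 4 bins per decade from two bin widths up to
#' `max_bp` (300 kb, the minimum classifiable segment length, so every
#' classified segment yields a complete feature vector).
#'
#' @param bin_size Matrix bin size in bp.
#' @param min_bp Smallest separation (default `2 * bin_size`).
#' @param max_bp Largest separation (default 3e5).
#' @param bins_per_decade Bin density (default 4).
#' @return Numeric vector of bin edges in bp (half-open bins
#'   `[e_k, e_{k+1})`).
#' @export
variance_feature_bins <- function(bin_size, min_bp = 2 * bin_size,
                                  max_bp = 3e5, bins_per_decade = 4) {
  if (max_bp <= min_bp) stop("max_bp must exceed min_bp")
  k <- ceiling(bins_per_decade * log10(max_bp / min_bp))
  edges <- min_bp * 10^(seq(0, k) / bins_per_decade)
  edges[length(edges)] <- max_bp * (1 + 1e-9)  # close the last bin
  edges
}

segment_bin_range <- function(segment_start, segment_end, bin_size) {
  a <- floor(segment_start / bin_size)
  b <- ceiling(segment_end / bin_size) - 1
  c(a, b)  # 0-based inclusive bin range
}

#' Log-variance contact features of one segment
#'
#' For each log-spaced genomic-distance bin, the population variance of the
#' intra-segment contact entries at those separations, reported as
#' `log(eps + variance)`. Uniform-contact (type B-like) segments give
#' features near `log(eps)`; segments with nested interaction squares
#' (type A-like) give much larger values. Distance bins with fewer than two
#' entries are masked.
#'
#' @param mat A `ContactMatrix`.
#' @param segment One row of a `SegmentList` (or a list with `start`,
#'   `end` in bp on the matrix chromosome).
#' @param distance_bins Edges from [variance_feature_bins()].
#' @param eps Pseudo-variance added inside the log; default
#'   `1e-8 * mean(C)^2`, tied to the global contact scale so features are
#'   scale-equivariant.
#' @return Object of class `VarianceFeatureVector`: `values`, `edges`,
#'   `n_entries` per bin, `start`, `end`.
#' @export
variance_features <- function(mat, segment,
                              distance_bins = variance_feature_bins(mat$bins$bin_size),
                              eps = 1e-8 * mean(mat$C)^2) {
  bs <- mat$bins$bin_size
  rng <- segment_bin_range(segment$start, segment$end, bs)
  if (rng[2] - rng[1] + 1 < 2) stop("segment must span at least 2 bins")
  if (rng[1] < 0 || rng[2] >= mat$bins$n_bins) stop("segment outside matrix")
  sub <- mat$C[(rng[1]:rng[2]) + 1L, (rng[1]:rng[2]) + 1L, drop = FALSE]
  m <- nrow(sub)
  sep_bp <- (col(sub) - row(sub)) * bs
  ut <- sep_bp > 0
  nb <- length(distance_bins) - 1L
  vals <- rep(NA_real_, nb)
  cnt <- integer(nb)
  for (k in seq_len(nb)) {
    sel <- ut & sep_bp >= distance_bins[k] & sep_bp < distance_bins[k + 1L]
    v <- sub[sel]
    cnt[k] <- length(v)
    if (length(v) >= 2) {
      pv <- mean((v - mean(v))^2)  # population variance
      vals[k] <- log(eps + pv)
    }
  }
  structure(list(values = vals, edges = distance_bins, n_entries = cnt,
                 start = segment$start, end = segment$end),
            class = "VarianceFeatureVector")
}

#' Feature matrix for a segment cohort
#'
#' @param mat A `ContactMatrix`.
#' @param segments A `SegmentList` on the matrix chromosome.
#' @param distance_bins Edges from [variance_feature_bins()].
#' @param eps Passed to [variance_features()].
#' @return Numeric matrix, one row per segment (NA = masked feature).
#' @export
segment_features <- function(mat, segments,
                             distance_bins = variance_feature_bins(mat$bins$bin_size),
                             eps = 1e-8 * mean(mat$C)^2) {
  t(vapply(seq_len(nrow(segments)), function(r)
    variance_features(mat, segments[r, ], distance_bins, eps)$values,
    numeric(length(distance_bins) - 1L)))
}

#' Seed chromatin-type labels with 2-means on long segments
#'
#' Clusters the feature vectors of all segments at least `min_length` long
#' into two sets with k-means (k = 2). The set with the larger mean feature
#' value — more intra-segment contact variance, i.e. localized interaction
#' domains — is labeled "A", the uniform-contact set "B".
#'
#' @param features Feature matrix from [segment_features()].
#' @param lengths Segment lengths in bp.
#' @param min_length Minimum training length (default 500 kb).
#' @param seed RNG seed for k-means initialization.
#' @return Character vector over all segments: `"A"`/`"B"` for long
#'   segments, `NA` otherwise; attribute `long` holds the row indices used.
#' @export
seed_labels_kmeans <- function(features, lengths, min_length = 5e5, seed = 1L) {
  long <- which(lengths >= min_length)
  if (length(long) < 2) stop("need >= 2 segments of at least min_length")
  X <- features[long, , drop = FALSE]
  use <- colSums(is.na(X)) == 0
  if (!any(use)) stop("no complete feature columns among long segments")
  set.seed(seed)
  km <- stats::kmeans(X[, use, drop = FALSE], centers = 2, nstart = 10)
  a_cluster <- which.max(vapply(1:2, function(k)
    mean(X[km$cluster == k, use, drop = FALSE]), numeric(1)))
  out <- rep(NA_character_, nrow(features))
  out[long] <- ifelse(km$cluster == a_cluster, "A", "B")
  attr(out, "long") <- long
  out
}

## Two-class LDA on standardized features: class means + pooled covariance,
## shrunk toward its diagonal when ill-conditioned.
fit_lda <- function(X, y, shrink = 1e-4) {
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("training data must contain exactly two classes")
  mu <- lapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]))
  n <- nrow(X)
  Sp <- Reduce(`+`, lapply(classes, function(k) {
    Xi <- X[y == k, , drop = FALSE]
    crossprod(sweep(Xi, 2, colMeans(Xi)))
  })) / (n - 2)
  Sp <- (1 - shrink) * Sp + shrink * diag(diag(Sp), ncol(X))
  ## fall back to stronger shrinkage if still singular
  winv <- tryCatch(solve(Sp, mu[[1]] - mu[[2]]), error = function(e) {
    Sp2 <- 0.9 * Sp + 0.1 * diag(mean(diag(Sp)), ncol(X))
    solve(Sp2, mu[[1]] - mu[[2]])
  })
  pri <- vapply(classes, function(k) mean(y == k), numeric(1))
  b <- sum(winv * (mu[[1]] + mu[[2]])) / 2 - log(pri[1] / pri[2])
  list(w = winv, b = b, classes = classes, means = mu, priors = pri)
}

lda_predict <- function(fit, X) {
  score <- as.vector(X %*% fit$w) - fit$b
  ifelse(score > 0, fit$classes[1], fit$classes[2])
}

#' Train the two-type LDA chromatin classifier
#'
#' Standardizes features, splits the labelled segments 80/20 into train and
#' test sets, fits a two-class linear discriminant (class means + pooled
#' covariance with diagonal shrinkage), and reports the 5-fold
#' cross-validation loss on the training set and the held-out test error.
#' All randomness (split, fold assignment) is governed by `seed`.
#'
#' @param features Feature matrix (rows = segments).
#' @param labels `"A"`/`"B"` labels (e.g. from [seed_labels_kmeans()]);
#'   rows with `NA` labels are ignored.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param cv_folds Number of CV folds (default 5).
#' @param seed RNG seed.
#' @param distance_bins Feature-bin edges recorded in the model so
#'   training and application always agree.
#' @param eps Feature pseudo-variance recorded in the model.
#' @return Object of class `SegmentTypeModel`: LDA weights, feature
#'   standardization, split indices, `cv_loss`, `test_error`.
#' @export
train_lda <- function(features, labels, test_fraction = 0.2, cv_folds = 5L,
                      seed = 1L, distance_bins = NULL, eps = NULL) {
  lab_rows <- which(!is.na(labels))
  X <- features[lab_rows, , drop = FALSE]
  y <- labels[lab_rows]
  use <- colSums(is.na(X)) == 0
  X <- X[, use, drop = FALSE]
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center, scale_)
  set.seed(seed)
  n <- nrow(Xs)
  test_idx <- sort(sample(n, round(test_fraction * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(unique(y[train_idx])) < 2) stop("training set must contain both classes")
  folds <- sample(rep(seq_len(cv_folds), length.out = length(train_idx)))
  cv_err <- vapply(seq_len(cv_folds), function(f) {
    tr <- train_idx[folds != f]
    va <- train_idx[folds == f]
    fit <- fit_lda(Xs[tr, , drop = FALSE], y[tr])
    mean(lda_predict(fit, Xs[va, , drop = FALSE]) != y[va])
  }, numeric(1))
  fit <- fit_lda(Xs[train_idx, , drop = FALSE], y[train_idx])
  test_error <- if (length(test_idx))
    mean(lda_predict(fit, Xs[test_idx, , drop = FALSE]) != y[test_idx]) else NA_real_
  structure(list(fit = fit, feature_cols = use, center = center,
                 scale = scale_, distance_bins = distance_bins, eps = eps,
                 rows = lab_rows, train_idx = train_idx, test_idx = test_idx,
                 cv_loss = mean(cv_err), cv_fold_errors = cv_err,
                 test_error = test_error, seed = seed),
            class = "SegmentTypeModel")
}

#' @export
print.SegmentTypeModel <- function(x, ...) {
  cat(sprintf("SegmentTypeModel: %d features, %d train / %d test segments, CV loss %.3g%%, test error %.3g%%\n",
              sum(x$feature_cols), length(x$train_idx), length(x$test_idx),
              100 * x$cv_loss, 100 * x$test_error))
  invisible(x)
}

#' Apply a trained type model to segments
#'
#' Segments shorter than `min_length` (default 300 kb) are labelled
#' `"unassigned"`; the rest get the LDA decision.
#'
#' @param model A `SegmentTypeModel`.
#' @param features Feature matrix computed with the model's distance bins.
#' @param segments The matching `SegmentList`.
#' @param min_length Minimum classifiable length in bp.
#' @return A `SegmentList` with `label` replaced by the type call.
#' @export
classify_segments <- function(model, features, segments, min_length = 3e5) {
  if (ncol(features) != length(model$feature_cols))
    stop("feature length does not match the model's feature-bin definition")
  X <- features[, model$feature_cols, drop = FALSE]
  Xs <- scale(X, model$center, model$scale)
  lab <- rep("unassigned", nrow(features))
  ok <- (segments$end - segments$start) >= min_length & rowSums(is.na(Xs)) == 0
  if (any(ok)) lab[ok] <- lda_predict(model$fit, Xs[ok, , drop = FALSE])
  out <- segments
  out$label <- lab
  out
}

#' End-to-end synthetic chromatin-type classification experiment
#'
#' Simulates a cohort of two-type domains in batches (one modest contact
#' matrix per batch, so memory stays flat), extracts log-variance features
#' on a shared distance-bin grid with a shared pseudo-variance, seeds
#' labels with 2-means on the long segments, and trains the LDA classifier
#' with an 80/20 split and 5-fold cross-validation. All randomness derives
#' from `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param n_segments Total cohort size (default 1100, all >= 500 kb under
#'   the default spec).
#' @param batch_size Segments per simulated matrix.
#' @param seed Base seed; batch `b` uses `seed * 1000 + b`.
#' @return List: `model` (a `SegmentTypeModel`), `features`, `lengths`,
#'   `true_labels`, `seed_labels`, and `seed_accuracy` (k-means vs truth on
#'   long segments).
#' @export
typed_cohort_experiment <- function(spec = synthetic_spec(), n_segments = 1100L,
                                    batch_size = 44L, seed = 7L) {
  n_batches <- ceiling(n_segments / batch_size)
  feats <- list(); lens <- list(); truth <- list()
  eps <- NULL
  dbins <- variance_feature_bins(spec$seg_bin_size)
  for (b in seq_len(n_batches)) {
    take <- min(batch_size, n_segments - (b - 1L) * batch_size)
    sim <- make_typed_segments(spec, n_segments = batch_size,
                               seed = seed * 1000L + b)
    if (is.null(eps)) eps <- 1e-8 * mean(sim$matrix$C)^2
    f <- segment_features(sim$matrix, sim$segments, dbins, eps = eps)
    feats[[b]] <- f[seq_len(take), , drop = FALSE]
    segs <- sim$segments[seq_len(take), , drop = FALSE]
    lens[[b]] <- segs$end - segs$start
    truth[[b]] <- segs$label
  }
  features <- do.call(rbind, feats)
  lengths <- unlist(lens)
  true_labels <- unlist(truth)
  seed_labels <- seed_labels_kmeans(features, lengths, seed = seed)
  long <- attr(seed_labels, "long")
  model <- train_lda(features, seed_labels, test_fraction = 0.2, cv_folds = 5L,
                     seed = seed, distance_bins = dbins, eps = eps)
  list(model = model, features = features, lengths = lengths,
       true_labels = true_labels, seed_labels = seed_labels,
       seed_accuracy = mean(seed_labels[long] == true_labels[long]))
}

#' Length-weighted composition of types against a reference classification
#'
#' Cross-tabulates segment length by (type, reference class). The reference
#' can be another `SegmentList` (e.g. PMD/non-PMD calls) or a
#' `CompartmentProfile` (A/B bins).
#'
#' @param types A `SegmentList` whose `label` holds the type calls.
#' @param reference A `SegmentList` or `CompartmentProfile`.
#' @return List with `lengths` (bp contingency matrix) and `row_fractions`.
#' @export
type_composition <- function(types, reference) {
  if (nrow(types) == 0) stop("empty type list")
  ref_class_at <- if (inherits(reference, "CompartmentProfile")) {
    bs <- reference$bins$bin_size
    function(chrom, pos) {
      if (chrom != reference$bins$chrom) return(NA_character_)
      bin <- floor(pos / bs) + 1
      if (bin < 1 || bin > reference$bins$n_bins) return(NA_character_)
      reference$label[bin]
    }
  } else {
    if (nrow(reference) == 0) stop("empty reference")
    function(chrom, pos) {
      hit <- reference$chrom == chrom & reference$start <= pos & pos < reference$end
      if (any(hit)) reference$label[which(hit)[1]] else NA_character_
    }
  }
  cells <- list()
  for (r in seq_len(nrow(types))) {
    s <- types$start[r]; e <- types$end[r]; ty <- types$label[r]
    ## split the segment at kilobase steps bounded by reference breakpoints:
    ## walk in bin/segment-aligned pieces
    pos <- s
    while (pos < e) {
      rc <- ref_class_at(types$chrom[r], pos)
      ## piece extends to the next reference boundary
      nxt <- if (inherits(reference, "CompartmentProfile")) {
        (floor(pos / reference$bins$bin_size) + 1) * reference$bins$bin_size
      } else {
        cand <- c(reference$end[reference$chrom == types$chrom[r] &
                                reference$start <= pos & pos < reference$end],
                  reference$start[reference$chrom == types$chrom[r] &
                                  reference$start > pos])
        if (length(cand)) min(cand) else e
      }
      nxt <- min(nxt, e)
      key <- paste(ty, ifelse(is.na(rc), "none", rc), sep = "\r")
      cells[[key]] <- (if (is.null(cells[[key]])) 0 else cells[[key]]) + (nxt - pos)
      pos <- nxt
    }
  }
  keys <- do.call(rbind, strsplit(names(cells), "\r", fixed = TRUE))
  tt <- sort(unique(keys[, 1])); rr <- sort(unique(keys[, 2]))
  M <- matrix(0, length(tt), length(rr), dimnames = list(tt, rr))
  for (k in seq_along(cells)) M[keys[k, 1], keys[k, 2]] <- cells[[k]]
  list(lengths = M, row_fractions = M / rowSums(M))
}
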