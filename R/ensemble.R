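pair_distances <- function(conf, i, j) {
  sqrt(rowSums((conf$coords[i, , drop = FALSE] - conf$coords[j, , drop = FALSE])^2))
}

#' Restraint-satisfaction summary of an ensemble
#'
#' Fraction of (model, restrained pair) distances falling within
#' `[lo, hi] x` the restraint distance, bounds inclusive — the ensemble
#' consistency statistic of the modeling workflow (the reference analysis
#' reports 86.4% within 0.5- to 2-fold on real chromosome-1 data).
#'
#' @param ens An `Ensemble` (or single `Conformation`).
#' @param restraints A `RestraintSet` (must be non-empty).
#' @param lo,hi Ratio bounds (defaults 0.5 and 2).
#' @return Object of class `EnsembleSummary`: `n_models`,
#'   `satisfaction_fraction`, `per_model` fractions, and `ratio_hist`
#'   (a [hist()]-style histogram of d/dbar on log2 breaks).
#' @export
satisfaction <- function(ens, restraints, lo = 0.5, hi = 2.0) {
  if (inherits(ens, "Conformation")) ens <- ensemble(list(ens))
  if (length(restraints$i) == 0) stop("empty restraint set")
  ratios <- lapply(ens, function(m)
    pair_distances(m, restraints$i, restraints$j) / restraints$target)
  per_model <- vapply(ratios, function(r) mean(r >= lo & r <= hi), numeric(1))
  all_r <- unlist(ratios)
  h <- graphics::hist(log2(pmax(all_r, 2^-10)),
                      breaks = seq(-10, max(10, ceiling(max(log2(pmax(all_r, 1))))),
                                   by = 0.25),
                      plot = FALSE)
  structure(list(n_models = length(ens),
                 satisfaction_fraction = mean(all_r >= lo & all_r <= hi),
                 per_model = per_model, ratio_hist = h, lo = lo, hi = hi),
            class = "EnsembleSummary")
}

#' @export
print.EnsembleSummary <- function(x, ...) {
  cat(sprintf("EnsembleSummary: %d models, %.1f%% of distances within [%g, %g] x restraint\n",
              x$n_models, 100 * x$satisfaction_fraction, x$lo, x$hi))
  invisible(x)
}

#' Regenerate a modeled Hi-C matrix from an ensemble
#'
#' Inverse of the restraint conversion: every pairwise distance in every
#' model is mapped back to a contact frequency through the log-log decay
#' curve ([distance_to_contact()]; out-of-range distances are clamped to
#' the curve ends), and entries are averaged over models. The diagonal is
#' set to zero.
#'
#' @param ens An `Ensemble` (or single `Conformation`).
#' @param curve A `DecayCurve`.
#' @param model A [scaling_model()].
#' @return A symmetric `ContactMatrix` of modeled contact frequencies.
#' @export
inverse_map <- function(ens, curve, model = scaling_model()) {
  if (inherits(ens, "Conformation")) ens <- ensemble(list(ens))
  n <- ens[[1]]$bins$n_bins
  acc <- matrix(0, n, n)
  for (m in ens) {
    D <- as.matrix(stats::dist(m$coords))
    cm <- matrix(0, n, n)
    ut <- upper.tri(D)
    cm[ut] <- distance_to_contact(D[ut], curve, model)
    acc <- acc + cm + t(cm)
  }
  contact_matrix(acc / length(ens), ens[[1]]$bins)
}

kabsch_rmsd <- function(A, B, reflect) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  sv <- svd(crossprod(Bc, Ac))
  rms_with <- function(s) {
    R <- sv$u %*% diag(s) %*% t(sv$v)
    sqrt(mean(rowSums((Bc %*% R - Ac)^2)))
  }
  d <- sign(det(sv$v) * det(sv$u))
  proper <- rms_with(c(1, 1, d))        # best proper rotation
  if (!reflect) return(proper)
  min(proper, rms_with(c(1, 1, -d)))    # also allow improper rotations
}

#' Minimal RMSD between two conformations
#'
#' Root-mean-square deviation after optimal superposition (translation +
#' proper rotation, Kabsch). Because Hi-C cannot distinguish mirror images,
#' `allow_reflection = TRUE` also minimizes over improper rotations.
#'
#' @param a,b `Conformation`s with equal bead counts.
#' @param allow_reflection Also allow improper rotations (default `FALSE`).
#' @return RMSD in micrometres.
#' @export
rmsd <- function(a, b, allow_reflection = FALSE) {
  if (nrow(a$coords) != nrow(b$coords)) stop("bead counts differ")
  kabsch_rmsd(a$coords, b$coords, allow_reflection)
}

#' Cluster an ensemble by pairwise RMSD
#'
#' Average-linkage hierarchical clustering of the pairwise RMSD matrix.
#' The representative model is the member of the largest cluster with the
#' smallest mean RMSD to the other members of its cluster (the centroid
#' notion of the reference analysis). Mirror-image ambiguity is absorbed by
#' computing RMSD with reflections allowed by default.
#'
#' @param ens An `Ensemble` with >= 2 models.
#' @param n_clusters Number of clusters (default 2).
#' @param allow_reflection Use reflection-invariant RMSD (default `TRUE`).
#' @return Object of class `ClusterResult`: `rmsd` matrix, `labels`,
#'   `representative` (model index).
#' @export
cluster_ensemble <- function(ens, n_clusters = 2L, allow_reflection = TRUE) {
  n <- length(ens)
  if (n < 2) stop("need >= 2 models to cluster")
  if (n_clusters > n) stop("n_clusters exceeds number of models")
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- rmsd(ens[[i]], ens[[j]], allow_reflection)
  }
  labels <- stats::cutree(stats::hclust(stats::as.dist(M), method = "average"),
                          k = n_clusters)
  main <- as.integer(names(which.max(table(labels))))
  members <- which(labels == main)
  mean_to_others <- vapply(members, function(i) {
    if (length(members) == 1) 0 else mean(M[i, setdiff(members, i)])
  }, numeric(1))
  structure(list(rmsd = M, labels = labels,
                 representative = members[which.min(mean_to_others)]),
            class = "ClusterResult")
}

#' Local spatial density around each bead
#'
#' Number of other beads within a Euclidean radius of each bead — the
#' per-segment crowding estimate used to compare compartment compactness.
#'
#' @param conf A `Conformation`.
#' @param radius Radius in micrometres (> 0); defaults to 5x the mean
#'   bonded distance when a `RestraintSet` is supplied via `restraints`.
#' @param restraints Optional `RestraintSet` used only for the default
#'   radius.
#' @return A `GenomeTrack` of integer counts.
#' @export
local_density <- function(conf, radius = NULL, restraints = NULL) {
  if (is.null(radius)) {
    if (is.null(restraints)) stop("give a radius or a RestraintSet")
    radius <- 5 * mean(restraints$d_eq)
  }
  if (radius <= 0) stop("radius must be > 0")
  D <- as.matrix(stats::dist(conf$coords))
  counts <- rowSums(D <= radius) - 1L
  genome_track(counts, conf$bins, name = sprintf("density_r%.3g", radius))
}
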