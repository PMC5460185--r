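#' Power-law scaling between genomic and spatial distance
#'
#' Encodes the mapping `d(l) = 2R (l/L)^(1/3)` from genomic separation `l`
#' (bp) to expected spatial distance (micrometres), with `R` the nuclear
#' radius and `L` the total genome length. The 1/3 exponent reflects the
#' space-filling packing of interphase chromatin seen in 3D-FISH.
#'
#' @param R_um Nuclear radius in micrometres (default 10).
#' @param L_bp Total genomic length in bp (default 6e9, the diploid-scale
#'   human genome).
#' @return An object of class `ScalingModel`.
#' @export
scaling_model <- function(R_um = 10, L_bp = 6e9) {
  if (R_um <= 0 || L_bp <= 0) stop("R_um and L_bp must be positive")
  structure(list(R = R_um, L = L_bp, exponent = 1 / 3), class = "ScalingModel")
}

#' Expected spatial distance at a genomic separation
#'
#' @param l Genomic distance(s) in bp, strictly positive.
#' @param model A [scaling_model()].
#' @return Distance(s) in micrometres, `2R (l/L)^(1/3)`.
#' @export
expected_distance <- function(l, model = scaling_model()) {
  if (any(l <= 0)) stop("genomic distance must be > 0")
  2 * model$R * (l / model$L)^model$exponent
}

#' Empirical contact decay curve C(l)
#'
#' Mean contact frequency as a function of genomic separation. Short-range
#' separations (up to `cutoff_bp`) get one knot per diagonal; beyond the
#' cutoff, where Hi-C counts are sparse and noisy, diagonals are pooled
#' into log-spaced distance bins (`bins_per_decade`). Zero-mean separations
#' are dropped. Because real curves wiggle, a non-increasing fit in log-log
#' space (pool-adjacent-violators via [stats::isoreg()]) is stored alongside
#' the raw means and used for all interpolation.
#'
#' @param mat A `ContactMatrix` with >= 2 bins.
#' @param cutoff_bp Separation below which every diagonal is its own knot.
#' @param bins_per_decade Log-bin density beyond the cutoff.
#' @return Object of class `DecayCurve`: fields `l` (bp), `C` (raw means),
#'   `C_fit` (monotone fit), `n` (entry counts per knot).
#' @export
decay_curve <- function(mat, cutoff_bp = 2e6, bins_per_decade = 10) {
  C <- mat$C
  n <- nrow(C)
  bs <- mat$bins$bin_size
  ksep <- seq_len(n - 1L)
  dmean <- vapply(ksep, function(k) {
    v <- C[cbind(seq_len(n - k), seq_len(n - k) + k)]
    mean(v)
  }, numeric(1))
  dcount <- n - ksep
  if (all(dmean == 0)) stop("degenerate matrix: all off-diagonal contacts are zero")
  kcut <- max(1L, floor(cutoff_bp / bs))
  near <- ksep <= kcut
  l <- (ksep * bs)[near]
  Cm <- dmean[near]
  cnt <- dcount[near]
  if (any(!near)) {
    lf <- log10(ksep[!near] * bs)
    grp <- floor(lf * bins_per_decade)
    w <- dcount[!near]
    Cg <- rowsum(dmean[!near] * w, grp)[, 1] / rowsum(w, grp)[, 1]
    lg <- 10^(rowsum(lf * w, grp)[, 1] / rowsum(w, grp)[, 1])
    ng <- rowsum(w, grp)[, 1]
    l <- c(l, lg); Cm <- c(Cm, Cg); cnt <- c(cnt, ng)
  }
  keep <- Cm > 0
  l <- l[keep]; Cm <- Cm[keep]; cnt <- cnt[keep]
  if (length(l) < 1) stop("degenerate matrix: no usable decay knots")
  ## enforce monotone non-increasing C(l) in log-log space
  if (length(l) > 1) {
    iso <- stats::isoreg(log(l), -log(Cm))
    Cfit <- exp(-iso$yf[order(order(log(l)))])
  } else Cfit <- Cm
  structure(list(l = l, C = Cm, C_fit = Cfit, n = cnt), class = "DecayCurve")
}

#' Construct a decay curve analytically from a power law
#'
#' Convenience for forward simulation and round-trip checks: knots follow
#' `C(l) = depth * (l / l_ref)^(-gamma)` exactly, paired with the scaling-law
#' distances, so the contact-to-distance map has no estimation error.
#'
#' @param model A [scaling_model()].
#' @param l Grid of genomic separations in bp.
#' @param depth Expected contact count at `l_ref`.
#' @param gamma Decay exponent (> 0).
#' @param l_ref Reference separation in bp (default 1 Mb).
#' @return A `DecayCurve`.
#' @export
analytic_decay_curve <- function(model, l, depth = 20, gamma = 1, l_ref = 1e6) {
  Cm <- depth * (l / l_ref)^(-gamma)
  structure(list(l = l, C = Cm, C_fit = Cm, n = rep(1, length(l))),
            class = "DecayCurve")
}

## Interpolation table: strictly decreasing log C vs increasing log d.
## Flat isotonic runs are collapsed to one knot at the geometric-mean
## distance so the map stays single-valued.
curve_table <- function(curve, model) {
  d <- expected_distance(curve$l, model)
  logd <- log(d); logC <- log(curve$C_fit)
  o <- order(logd)
  logd <- logd[o]; logC <- logC[o]
  grp <- cumsum(c(TRUE, diff(logC) != 0))
  list(logC = rowsum(logC, grp)[, 1] / tabulate(grp),
       logd = rowsum(logd, grp)[, 1] / tabulate(grp))
}

loglin_interp <- function(x, xs, ys) {
  ## linear interpolation; out-of-range points extrapolate with the global
  ## slope of the table, which is robust to flat or noisy edge segments
  if (length(xs) == 1L) return(rep(ys, length(x)))
  out <- stats::approx(xs, ys, xout = x, rule = 2)$y
  lo <- x < min(xs); hi <- x > max(xs)
  k <- length(xs)
  if (any(lo) || any(hi)) {
    sl <- (ys[k] - ys[1]) / (xs[k] - xs[1])
    if (any(lo)) out[lo] <- ys[1] + sl * (x[lo] - xs[1])
    if (any(hi)) out[hi] <- ys[k] + sl * (x[hi] - xs[k])
  }
  out
}

#' Map contact frequencies to restraint distances
#'
#' Log-log linear interpolation between the decay-curve knots `(C(l), d(l))`:
#' a contact equal to a knot value maps exactly to the scaling-law distance
#' of that knot. Outside the observed contact range the map extrapolates
#' log-linearly and is clamped to `[d(l_min), 2R]`.
#'
#' @param c Contact frequency(ies), strictly positive.
#' @param curve A [decay_curve()].
#' @param model A [scaling_model()].
#' @return Distance(s) in micrometres; monotone non-increasing in `c`.
#' @export
contact_to_distance <- function(c, curve, model = scaling_model()) {
  if (any(c <= 0)) stop("contact frequency must be > 0")
  tab <- curve_table(curve, model)
  ## logC is decreasing in logd; interpolate on reversed axes
  d <- exp(loglin_interp(log(c), rev(tab$logC), rev(tab$logd)))
  pmin(pmax(d, exp(min(tab$logd))), 2 * model$R)
}

#' Inverse map: spatial distances to contact frequencies
#'
#' The inverse of [contact_to_distance()] on the same curve; distances
#' outside the curve's range are clamped to its ends.
#'
#' @param d Distance(s) in micrometres, strictly positive.
#' @param curve A [decay_curve()].
#' @param model A [scaling_model()].
#' @return Contact frequency(ies).
#' @export
distance_to_contact <- function(d, curve, model = scaling_model()) {
  if (any(d <= 0)) stop("distance must be > 0")
  tab <- curve_table(curve, model)
  logd <- pmin(pmax(log(d), min(tab$logd)), max(tab$logd))
  exp(loglin_interp(logd, tab$logd, tab$logC))
}

#' Smooth long-range contacts over aligned blocks
#'
#' Entries at genomic separations beyond `genomic_cutoff` are replaced by
#' the mean of their enclosing aligned `block_bp x block_bp` block
#' (computed over the beyond-cutoff entries of the block, so the operation
#' is idempotent and leaves near-diagonal entries bit-identical). This
#' suppresses the low signal/noise of distal Hi-C counts before restraint
#' conversion.
#'
#' @param mat A `ContactMatrix`.
#' @param genomic_cutoff Separation (bp) beyond which smoothing applies.
#' @param block_bp Block edge in bp; must be a multiple of the bin size and
#'   at most `genomic_cutoff`.
#' @return A smoothed `ContactMatrix`.
#' @export
smooth_long_range <- function(mat, genomic_cutoff = 2e6, block_bp = 2e5) {
  bs <- mat$bins$bin_size
  if (block_bp < bs) stop("block must span at least one bin")
  if (block_bp %% bs != 0) stop("block_bp must be a multiple of bin_size")
  if (genomic_cutoff < block_bp) stop("genomic_cutoff must be >= block_bp")
  C <- mat$C
  n <- nrow(C)
  bpb <- block_bp / bs
  idx <- which(upper.tri(C), arr.ind = TRUE)
  far <- (idx[, 2] - idx[, 1]) * bs > genomic_cutoff
  if (any(far)) {
    fi <- idx[far, 1]; fj <- idx[far, 2]
    key <- paste(ceiling(fi / bpb), ceiling(fj / bpb))
    means <- rowsum(C[cbind(fi, fj)], key)[, 1] / rowsum(rep(1, length(fi)), key)[, 1]
    C[cbind(fi, fj)] <- means[key]
    C[cbind(fj, fi)] <- means[key]
  }
  contact_matrix(C, mat$bins)
}

#' Convert a contact matrix into a distance-restraint set
#'
#' Applies long-range block smoothing, builds the decay curve, and maps
#' every pair with contact above `min_contact` to a target distance via
#' [contact_to_distance()]. Equilibrium distances for consecutive beads come
#' from the same map applied to the first off-diagonal; a consecutive pair
#' with zero contact falls back to the scaling-law distance at one bin size
#' (with a warning) so the chain never breaks. Priority weights are
#' `w = 1/d_target^2`, giving Hi-C reproduction at shorter distances higher
#' priority.
#'
#' @param mat A `ContactMatrix`.
#' @param model A [scaling_model()].
#' @param min_contact Contacts must exceed this to be restrained (default 0).
#' @param smooth Apply [smooth_long_range()] first (default `TRUE`).
#' @param genomic_cutoff,block_bp Passed to [smooth_long_range()].
#' @param curve Optional pre-built `DecayCurve`; built from the (smoothed)
#'   matrix when `NULL`.
#' @return Object of class `RestraintSet`: fields `i`, `j` (1-based bead
#'   indices, `i < j`), `target` and `weight` per restraint, `d_eq` (length
#'   `n_bins - 1`), `bins`, `curve`, `model`.
#' @export
build_restraints <- function(mat, model = scaling_model(), min_contact = 0,
                             smooth = TRUE, genomic_cutoff = 2e6,
                             block_bp = 2e5, curve = NULL) {
  if (smooth && (mat$bins$n_bins - 1) * mat$bins$bin_size > genomic_cutoff)
    mat <- smooth_long_range(mat, genomic_cutoff, block_bp)
  if (is.null(curve)) curve <- decay_curve(mat, cutoff_bp = genomic_cutoff)
  C <- mat$C
  n <- nrow(C)
  idx <- which(upper.tri(C) & C > min_contact & C > 0, arr.ind = TRUE)
  target <- contact_to_distance(C[idx], curve, model)
  cc <- C[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)]
  d_eq <- rep(NA_real_, n - 1L)
  pos <- cc > 0
  if (any(pos)) d_eq[pos] <- contact_to_distance(cc[pos], curve, model)
  if (any(!pos)) {
    warning(sprintf("%d consecutive pair(s) with zero contact; using scaling-law distance at one bin", sum(!pos)))
    d_eq[!pos] <- expected_distance(mat$bins$bin_size, model)
  }
  structure(list(i = unname(idx[, 1]), j = unname(idx[, 2]),
                 target = unname(target), weight = unname(1 / target^2),
                 d_eq = d_eq, bins = mat$bins, curve = curve, model = model),
            class = "RestraintSet")
}

#' @export
print.RestraintSet <- function(x, ...) {
  cat(sprintf("RestraintSet: %d beads, %d pairwise restraints, mean d_eq %.3f um\n",
              x$bins$n_bins, length(x$i), mean(x$d_eq)))
  invisible(x)
}
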