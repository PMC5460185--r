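# Small in-code fixtures shared across test files.

# Contact matrix whose decay curve is strictly decreasing: C = a * sep^(-g)
power_law_matrix <- function(n = 12, bin_size = 5e4, a = 100, g = 1,
                             chrom = "chrF") {
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  C <- a * ifelse(sep == 0, 0, sep^(-g))
  contact_matrix(C, bin_table(chrom, bin_size, n))
}

# Minimal hand-built restraint set over an explicit geometry
toy_restraints <- function(i, j, target, d_eq, bins,
                           model = scaling_model()) {
  structure(list(i = as.integer(i), j = as.integer(j), target = target,
                 weight = 1 / target^2, d_eq = d_eq, bins = bins,
                 curve = NULL, model = model),
            class = "RestraintSet")
}

rand_conformation <- function(n, bins = bin_table("chrF", 5e4, n), seed = 1,
                              scale = 1) {
  set.seed(seed)
  conformation(matrix(rnorm(3 * n, sd = scale), n, 3), bins, seed = seed)
}

# rigid motion: random proper rotation + translation
rigid_motion <- function(coords, seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(coords %*% R, 2, rnorm(3), `+`)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
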