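test_that("generators are seed-deterministic", {
  spec <- synthetic_spec(n_bins = 60, block_bins = 30)
  expect_identical(make_structure(spec, seed = 1)$coords,
                   make_structure(spec, seed = 1)$coords)
  conf <- make_structure(spec, seed = 1)
  expect_identical(structure_to_hic(conf, spec, seed = 2)$C,
                   structure_to_hic(conf, spec, seed = 2)$C)
  expect_identical(make_plaid_matrix(spec, seed = 3)$matrix$C,
                   make_plaid_matrix(spec, seed = 3)$matrix$C)
  expect_identical(make_typed_segments(spec, 6, seed = 4)$matrix$C,
                   make_typed_segments(spec, 6, seed = 4)$matrix$C)
  expect_false(identical(make_plaid_matrix(spec, seed = 3)$matrix$C,
                         make_plaid_matrix(spec, seed = 5)$matrix$C))
})

test_that("structures follow the scaling law in the mean", {
  spec <- synthetic_spec(n_bins = 400, block_bins = 400, radial_bias = 0)
  conf <- make_structure(spec, seed = 2)
  D <- as.matrix(stats::dist(conf$coords))
  bond <- expected_distance(spec$bin_size, spec$model)
  for (k in c(1, 8, 27, 64)) {
    sepd <- D[cbind(seq_len(400 - k), seq_len(400 - k) + k)]
    expect_lt(abs(mean(sepd) / expected_distance(k * spec$bin_size, spec$model) - 1),
              0.2)
  }
  # mean bonded distance: lattice bond inflated by the jitter
  # (|N(bond e1, 2 jitter^2 bond^2 I3)| has mean ~ bond sqrt(1 + 6 jitter^2))
  bonds <- D[cbind(1:399, 2:400)]
  expect_lt(abs(mean(bonds) / (bond * sqrt(1 + 6 * 0.2^2)) - 1), 0.05)
  expect_true(all(bonds < 5 * bond))
})

test_that("single-compartment structures are unaffected by the radial bias", {
  one <- synthetic_spec(n_bins = 80, block_bins = 80, radial_bias = 0.3)
  zero <- synthetic_spec(n_bins = 80, block_bins = 80, radial_bias = 0)
  expect_identical(make_structure(one, seed = 5)$coords,
                   make_structure(zero, seed = 5)$coords)
})

test_that("compartment-A beads sit closer to the centre than B beads", {
  spec <- synthetic_spec(n_bins = 200, block_bins = 50)
  conf <- make_structure(spec, seed = 6)
  lab <- attr(conf, "compartment")
  r <- sqrt(rowSums(conf$coords^2))
  expect_lt(mean(r[lab == "A"]), mean(r[lab == "B"]))
})

test_that("forward simulation is Poisson around a depth-linear expectation", {
  spec20 <- synthetic_spec(n_bins = 50, block_bins = 50, depth = 20)
  spec40 <- synthetic_spec(n_bins = 50, block_bins = 50, depth = 40)
  conf <- make_structure(spec20, seed = 7)
  e20 <- structure_to_hic(conf, spec20, expected_only = TRUE)$C
  e40 <- structure_to_hic(conf, spec40, expected_only = TRUE)$C
  expect_equal(e40, 2 * e20)

  obs <- structure_to_hic(conf, spec20, seed = 8)$C
  expect_true(all(obs == round(obs)))
  expect_true(all(obs >= 0))
  # observed totals near the expected total (Poisson concentration)
  tot <- sum(e20[upper.tri(e20)])
  expect_lt(abs(sum(obs[upper.tri(obs)]) / tot - 1), 0.05)
})

test_that("the forward/inverse maps round-trip distances", {
  spec <- synthetic_spec(n_bins = 100, block_bins = 100, radial_bias = 0)
  conf <- make_structure(spec, seed = 9)
  model <- spec$model
  curve <- analytic_decay_curve(model, 10^seq(log10(5e3), log10(1e8),
                                              length.out = 300),
                                depth = spec$depth, gamma = spec$gamma)
  E <- structure_to_hic(conf, spec, expected_only = TRUE)
  D <- as.matrix(stats::dist(conf$coords))
  n <- nrow(D)
  l_sep <- abs(outer(seq_len(n), seq_len(n), `-`)) * spec$bin_size
  ut <- upper.tri(D)
  # pairs safely inside the proximity-modulation clamp, where the forward
  # kernel is a pure function of distance (gamma = 1)
  ratio <- D / expected_distance(pmax(l_sep, 1), model)
  ok <- ut & ratio > 0.5 & ratio < 2
  rec <- contact_to_distance(E$C[ok], curve, model)
  expect_lt(max(abs(rec / D[ok] - 1)), 0.01)
})

test_that("plaid O/E block structure reflects the planted enrichment", {
  spec <- synthetic_spec(n_bins = 200, block_bins = 50, alpha = 2)
  sim <- make_plaid_matrix(spec, seed = 10)
  oe <- observed_over_expected(sim$expected)
  same <- outer(sim$profile$label, sim$profile$label, `==`)
  sep <- abs(row(oe) - col(oe))
  # per separation, within/cross O/E ratio is exactly alpha^2 in expectation
  for (k in c(1, 5, 20, 60)) {
    ratio <- mean(oe[same & sep == k]) / mean(oe[!same & sep == k])
    expect_equal(ratio, spec$alpha^2, tolerance = 1e-10)
  }
})

test_that("alpha = 1 yields no recoverable compartment signal", {
  spec <- synthetic_spec(n_bins = 200, block_bins = 50, alpha = 1)
  sim <- make_plaid_matrix(spec, seed = 11)
  corr <- correlation_matrix(observed_over_expected(sim$matrix))
  orient <- make_correlated_track(sim$profile, effect = 1, noise_sd = 0, seed = 12)
  prof <- suppressWarnings(call_compartments(corr, orient, sim$matrix$bins))
  acc <- mean(prof$label == sim$profile$label)
  expect_gt(acc, 0.25)
  expect_lt(acc, 0.75)
})

test_that("noise-free type-B segments have exactly zero contact variance", {
  spec <- synthetic_spec()
  sim <- make_typed_segments(spec, n_segments = 8, seed = 13)
  eps <- 1e-4
  f <- segment_features(sim$expected, sim$segments, eps = eps)
  bidx <- which(sim$segments$label == "B")
  expect_true(all(abs(f[bidx, ] - log(eps)) < 1e-10, na.rm = TRUE))
})

test_that("k-means seeding recovers planted types at the default separation", {
  spec <- synthetic_spec()
  sim <- make_typed_segments(spec, n_segments = 60, seed = 14)
  f <- segment_features(sim$matrix, sim$segments)
  lens <- sim$segments$end - sim$segments$start
  lab <- seed_labels_kmeans(f, lens, seed = 15)
  long <- attr(lab, "long")
  expect_gte(mean(lab[long] == sim$segments$label[long]), 0.97)
})

test_that("correlated tracks have the stated point-biserial correlation", {
  spec <- synthetic_spec(n_bins = 400, block_bins = 50)
  prof <- make_plaid_matrix(spec, seed = 16)$profile
  two <- make_correlated_track(prof, effect = 1, noise_sd = 0, seed = 17)
  expect_setequal(unique(two$values), c(-1, 1))

  set.seed(18)
  noisy <- make_correlated_track(prof, effect = 1, noise_sd = 1, seed = 18)
  truth <- ifelse(prof$label == "A", 1, -1)
  # analytic point-biserial: r = effect / sqrt(effect^2 + sd^2)
  expect_lt(abs(masked_pearson(noisy$values, truth) - 1 / sqrt(2)), 0.08)

  null <- make_correlated_track(prof, effect = 0, noise_sd = 1, seed = 19)
  expect_lt(abs(masked_pearson(null$values, truth)), 3 / sqrt(400))
})
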