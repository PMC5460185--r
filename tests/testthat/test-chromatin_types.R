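test_that("variance features match hand-computed values", {
  bins <- bin_table("c", 1e4, 6)
  C <- matrix(5, 6, 6)  # uniform contacts: zero variance everywhere
  mat <- contact_matrix(C, bins)
  eps <- 1e-3
  vf <- variance_features(mat, list(start = 0, end = 6e4),
                          distance_bins = c(2e4, 3e4, 5e4), eps = eps)
  expect_equal(vf$values, rep(log(eps), 2))

  # two entries {1, 3} at separation 2 -> population variance 1
  C2 <- matrix(0, 4, 4)
  C2[1, 3] <- C2[3, 1] <- 1
  C2[2, 4] <- C2[4, 2] <- 3
  m2 <- contact_matrix(C2, bin_table("c", 1e4, 4))
  vf2 <- variance_features(m2, list(start = 0, end = 4e4),
                           distance_bins = c(2e4, 3e4), eps = eps)
  expect_equal(vf2$values, log(eps + 1))
  expect_equal(vf2$n_entries, 2L)

  expect_error(variance_features(m2, list(start = 0, end = 1e4)), "2 bins")
})

test_that("feature extraction is scale-equivariant in the log", {
  spec <- synthetic_spec()
  sim <- make_typed_segments(spec, n_segments = 6, seed = 2)
  eps1 <- 1e-8 * mean(sim$matrix$C)^2
  f1 <- segment_features(sim$matrix, sim$segments, eps = eps1)
  scaled <- contact_matrix(10 * sim$matrix$C, sim$matrix$bins)
  f2 <- segment_features(scaled, sim$segments, eps = 100 * eps1)
  expect_equal(f2, f1 + log(100), tolerance = 1e-10)
})

test_that("type-A segments carry larger variance features than type-B", {
  spec <- synthetic_spec()
  sim <- make_typed_segments(spec, n_segments = 30, seed = 3)
  f <- segment_features(sim$matrix, sim$segments)
  a <- sim$segments$label == "A"
  frac_bigger <- mean(colMeans(f[a, , drop = FALSE], na.rm = TRUE) >
                      colMeans(f[!a, , drop = FALSE], na.rm = TRUE))
  expect_gte(frac_bigger, 0.8)
})

test_that("k-means seeding splits planted clouds and is deterministic", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40 * 4, mean = 10, sd = 0.5), 40, 4),
             matrix(rnorm(40 * 4, mean = 0, sd = 0.5), 40, 4))
  lens <- rep(6e5, 80)
  lab <- seed_labels_kmeans(X, lens, seed = 5)
  expect_equal(lab[1:40], rep("A", 40))  # higher-mean cloud is type A
  expect_equal(lab[41:80], rep("B", 40))
  expect_identical(lab, seed_labels_kmeans(X, lens, seed = 5))

  # duplicated rows get identical labels
  Xdup <- rbind(X, X[1, , drop = FALSE])
  labd <- seed_labels_kmeans(Xdup, c(lens, 6e5), seed = 5)
  expect_equal(labd[81], labd[1])

  # short segments are excluded; fewer than 2 long ones is an error
  expect_error(seed_labels_kmeans(X, rep(1e5, 80)), ">= 2 segments")
  mixed <- seed_labels_kmeans(X, c(rep(6e5, 50), rep(1e5, 30)), seed = 5)
  expect_true(all(is.na(mixed[51:80])))
})

test_that("LDA separates planted classes and matches MASS on shared data", {
  set.seed(6)
  X <- rbind(matrix(rnorm(60 * 3, mean = 3), 60, 3),
             matrix(rnorm(60 * 3, mean = 0), 60, 3))
  y <- rep(c("A", "B"), each = 60)
  m <- train_lda(X, y, seed = 7)
  expect_equal(m$test_error, 0)
  expect_lt(m$cv_loss, 0.05)
  m2 <- train_lda(X, y, seed = 7)
  expect_identical(m$fit$w, m2$fit$w)
  expect_identical(m$cv_loss, m2$cv_loss)

  # predictions agree with the reference LDA implementation
  fit <- MASS::lda(X, grouping = y)
  ref <- as.character(stats::predict(fit, X)$class)
  segs <- segment_list("c", seq(0, by = 1e6, length.out = 120),
                       seq(4e5, by = 1e6, length.out = 120), "s")
  mine <- classify_segments(m, X, segs)$label
  expect_equal(mine, ref)

  expect_error(train_lda(X, rep("A", 120), seed = 1), "both classes")
})

test_that("permuted labels give chance-level cross-validation loss", {
  set.seed(8)
  X <- rbind(matrix(rnorm(100 * 3, mean = 3), 100, 3),
             matrix(rnorm(100 * 3, mean = 0), 100, 3))
  y <- sample(rep(c("A", "B"), each = 100))  # labels shuffled off the signal
  m <- train_lda(X, y, seed = 9)
  expect_gt(m$cv_loss, 0.3)
  expect_lt(m$cv_loss, 0.7)
})

test_that("classification respects the minimum-length rule and the decision rule", {
  set.seed(10)
  X <- rbind(matrix(rnorm(30 * 3, mean = 3), 30, 3),
             matrix(rnorm(30 * 3, mean = 0), 30, 3))
  y <- rep(c("A", "B"), each = 30)
  m <- train_lda(X, y, seed = 11)
  starts <- seq(0, by = 1e6, length.out = 60)
  segs <- segment_list("c", starts, starts + c(2.5e5, rep(6e5, 59)), "s")
  out <- classify_segments(m, X, segs)
  expect_equal(out$label[1], "unassigned")  # 250 kb segment
  # decision-rule oracle: sign of w . x_std - b
  Xs <- scale(X[, m$feature_cols, drop = FALSE], m$center, m$scale)
  manual <- ifelse(as.vector(Xs %*% m$fit$w) - m$fit$b > 0,
                   m$fit$classes[1], m$fit$classes[2])
  expect_equal(out$label[-1], manual[-1])
  expect_error(classify_segments(m, X[, 1:2], segs), "feature length")
})

test_that("type composition is length-weighted and conserves totals", {
  types <- segment_list("c", c(0, 1000, 2000), c(800, 1600, 2500),
                        c("A", "B", "A"))
  ref <- segment_list("c", c(0, 1200), c(1200, 2600), c("compA", "compB"))
  comp <- type_composition(types, ref)
  expect_equal(rowSums(comp$lengths)[["A"]], 800 + 500)
  expect_equal(rowSums(comp$lengths)[["B"]], 600)
  # per-bp oracle
  for (ty in c("A", "B")) for (rc in c("compA", "compB")) {
    bp <- 0
    for (r in which(types$label == ty)) {
      for (p in seq(types$start[r], types$end[r] - 1)) {
        hit <- ref$label[ref$start <= p & p < ref$end]
        if (length(hit) && hit == rc) bp <- bp + 1
      }
    }
    got <- if (rc %in% colnames(comp$lengths)) comp$lengths[ty, rc] else 0
    expect_equal(got, bp)
  }

  # all-A-inside-A has row fraction 1
  t2 <- segment_list("c", 0, 1000, "A")
  r2 <- segment_list("c", 0, 1200, "compA")
  expect_equal(type_composition(t2, r2)$row_fractions["A", "compA"], 1)
})
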