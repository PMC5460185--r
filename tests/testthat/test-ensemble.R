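test_that("satisfaction counts distances inside the inclusive ratio band", {
  bins <- bin_table("c", 5e4, 3)
  conf <- conformation(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0.4, 0)), bins)
  # distances: d(1,2) = 1, d(1,3) = 0.4
  rs <- toy_restraints(c(1, 1), c(2, 3), target = c(1, 1), d_eq = c(1, 1), bins)
  s <- satisfaction(conf, rs)
  expect_equal(s$satisfaction_fraction, 0.5)  # one at 1x, one at 0.4x

  exact <- conformation(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), bins)
  rs2 <- toy_restraints(c(1, 1), c(2, 3), target = c(1, 1), d_eq = c(1, 1), bins)
  expect_equal(satisfaction(exact, rs2)$satisfaction_fraction, 1)
  # exactly 2x the target still counts (inclusive upper bound)
  doubled <- conformation(2 * exact$coords, bins)
  expect_equal(satisfaction(doubled, rs2)$satisfaction_fraction, 1)
  # and 0.5x exactly (inclusive lower bound)
  halved <- conformation(0.5 * exact$coords, bins)
  expect_equal(satisfaction(halved, rs2)$satisfaction_fraction, 1)

  expect_error(satisfaction(conf, toy_restraints(integer(0), integer(0),
                                                 numeric(0), c(1, 1), bins)),
               "empty restraint")
})

test_that("satisfaction is invariant to rigid motions", {
  set.seed(8)
  bins <- bin_table("c", 5e4, 15)
  conf <- rand_conformation(15, bins, seed = 8)
  idx <- which(upper.tri(diag(15)), arr.ind = TRUE)
  rs <- toy_restraints(idx[, 1], idx[, 2],
                       target = stats::runif(nrow(idx), 0.5, 2),
                       d_eq = rep(1, 14), bins)
  s0 <- satisfaction(conf, rs)$satisfaction_fraction
  moved <- conformation(rigid_motion(conf$coords, seed = 9), bins)
  expect_equal(satisfaction(moved, rs)$satisfaction_fraction, s0)
})

test_that("inverse mapping is exact at knots and inverts the forward map", {
  model <- scaling_model()
  l <- 10^seq(log10(5e3), log10(5e7), length.out = 150)
  curve <- analytic_decay_curve(model, l)
  d_knots <- expected_distance(l, model)

  # conformation with one pairwise distance at a knot
  bins2 <- bin_table("c", 5e4, 2)
  conf <- conformation(rbind(c(0, 0, 0), c(d_knots[40], 0, 0)), bins2)
  mm <- inverse_map(conf, curve, model)
  expect_equal(mm$C[1, 2], curve$C[40], tolerance = 1e-12)
  expect_equal(diag(mm$C), c(0, 0))

  # round trip: contacts -> distances -> contacts on a toy geometry
  conf10 <- rand_conformation(10, bin_table("c", 5e4, 10), seed = 2, scale = 1)
  M <- inverse_map(conf10, curve, model)
  D <- as.matrix(stats::dist(conf10$coords))
  ut <- upper.tri(D)
  inside <- ut & D > min(d_knots) & D < max(d_knots)
  expect_equal(contact_to_distance(M$C[inside], curve, model), D[inside],
               tolerance = 1e-8)

  # averaging two identical models changes nothing
  ens2 <- ensemble(list(conf10, conf10))
  expect_equal(inverse_map(ens2, curve, model)$C, M$C)
})

test_that("inverse_map output is symmetric, non-negative and monotone", {
  model <- scaling_model()
  curve <- analytic_decay_curve(model, 10^seq(4, 7.5, length.out = 80))
  conf <- rand_conformation(12, bin_table("c", 5e4, 12), seed = 3)
  M <- inverse_map(conf, curve, model)
  expect_identical(M$C, t(M$C))
  expect_true(all(M$C >= 0))
  shrunk <- conformation(conf$coords * 0.9, conf$bins)
  M2 <- inverse_map(shrunk, curve, model)
  expect_true(all(M2$C >= M$C - 1e-12))
})

test_that("rmsd is zero on self and rigid copies, and matches a grid oracle", {
  a <- rand_conformation(8, seed = 4)
  expect_equal(rmsd(a, a), 0)
  b <- conformation(rigid_motion(a$coords, seed = 5), a$bins)
  expect_lt(rmsd(a, b), 1e-10)

  # mirror image: plain rmsd sees a difference, reflection-aware does not
  mir <- conformation(a$coords %*% diag(c(-1, 1, 1)), a$bins)
  expect_lt(rmsd(a, mir, allow_reflection = TRUE), 1e-10)
  expect_gt(rmsd(a, mir, allow_reflection = FALSE), 0.1)

  # brute-force oracle: dense rotation grid on two 3-point sets
  bins3 <- bin_table("c", 5e4, 3)
  p <- conformation(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0)), bins3)
  q <- conformation(rbind(c(0.1, 0, 0), c(1.2, 0.3, 0), c(-0.2, 1.7, 0.4)), bins3)
  r_pkg <- rmsd(p, q)
  ang <- seq(0, 2 * pi, length.out = 40)
  best <- Inf
  pc <- sweep(p$coords, 2, colMeans(p$coords))
  qc <- sweep(q$coords, 2, colMeans(q$coords))
  for (a1 in ang) for (a2 in seq(0, pi, length.out = 20)) for (a3 in ang) {
    R1 <- rbind(c(cos(a1), -sin(a1), 0), c(sin(a1), cos(a1), 0), c(0, 0, 1))
    R2 <- rbind(c(1, 0, 0), c(0, cos(a2), -sin(a2)), c(0, sin(a2), cos(a2)))
    R3 <- rbind(c(cos(a3), -sin(a3), 0), c(sin(a3), cos(a3), 0), c(0, 0, 1))
    v <- sqrt(mean(rowSums((qc %*% (R1 %*% R2 %*% R3) - pc)^2)))
    if (v < best) best <- v
  }
  expect_lte(r_pkg, best + 1e-9)      # optimal beats any grid rotation
  expect_lt(abs(r_pkg - best), 0.05)  # and the grid gets close
  expect_error(rmsd(a, rand_conformation(5, seed = 1)), "differ")
})

test_that("rmsd behaves as a pseudo-metric on sampled triples", {
  confs <- lapply(1:4, function(s) rand_conformation(10, seed = s))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(rmsd(confs[[i]], confs[[j]]), rmsd(confs[[j]], confs[[i]]),
                 tolerance = 1e-10)
  }
  for (i in 1:2) for (j in 3:4) for (k in 1:4) {
    expect_lte(rmsd(confs[[i]], confs[[j]]),
               rmsd(confs[[i]], confs[[k]]) + rmsd(confs[[k]], confs[[j]]) + 1e-9)
  }
})

test_that("ensemble clustering separates planted families", {
  base1 <- rand_conformation(12, seed = 10, scale = 1)
  base2 <- rand_conformation(12, seed = 20, scale = 1)
  perturb <- function(base, s) {
    set.seed(s)
    conformation(base$coords + matrix(rnorm(36, sd = 0.02), 12, 3), base$bins)
  }
  ens <- ensemble(c(lapply(1:4, function(s) perturb(base1, s)),
                    lapply(5:8, function(s) perturb(base2, s))))
  cl <- cluster_ensemble(ens, n_clusters = 2)
  expect_equal(length(unique(cl$labels[1:4])), 1L)
  expect_equal(length(unique(cl$labels[5:8])), 1L)
  expect_false(cl$labels[1] == cl$labels[5])
  # representative minimizes mean within-cluster RMSD
  main <- cl$labels[cl$representative]
  members <- which(cl$labels == main)
  means <- vapply(members, function(i) mean(cl$rmsd[i, setdiff(members, i)]),
                  numeric(1))
  expect_equal(cl$representative, members[which.min(means)])

  same <- ensemble(lapply(1:3, function(i) base1))
  cl0 <- cluster_ensemble(same, n_clusters = 2)
  expect_true(all(cl0$rmsd < 1e-10))
  expect_error(cluster_ensemble(same, n_clusters = 5), "exceeds")
})

test_that("local density equals brute force", {
  bins2 <- bin_table("c", 5e4, 2)
  far <- conformation(rbind(c(0, 0, 0), c(5, 0, 0)), bins2)
  expect_equal(local_density(far, radius = 1)$values, c(0, 0))

  bins3 <- bin_table("c", 5e4, 3)
  tri <- conformation(0.3 * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                      bins3)
  expect_equal(local_density(tri, radius = 1)$values, c(2, 2, 2))

  cloud <- rand_conformation(100, bin_table("c", 5e4, 100), seed = 6)
  r <- 1.2
  dens <- local_density(cloud, radius = r)$values
  brute <- integer(100)
  for (i in 1:100) for (j in 1:100) {
    if (i != j && sqrt(sum((cloud$coords[i, ] - cloud$coords[j, ])^2)) <= r)
      brute[i] <- brute[i] + 1L
  }
  expect_equal(dens, brute)
  expect_error(local_density(cloud, radius = -1), "> 0")
})
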