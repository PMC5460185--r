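#' @useDynLib hic3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Optimizer parameters
#'
#' Controls the velocity-assisted adaptive gradient descent used to satisfy
#' distance restraints. Length scales that default to `NULL` are resolved at
#' run time against the mean bonded equilibrium distance `m = mean(d_eq)`:
#' `step_scale = 0.05 m` (the displacement of the most-forced bead per
#' step) and `max_disp = 0.5 m` (hard per-step displacement cap).
#'
#' @param n_steps Optimization steps per model (default 80000).
#' @param resample_every Steps between velocity resamplings (default 100).
#' @param step_scale Adaptive-timestep scale in micrometres; `dt` is set to
#'   `step_scale / max|F|` each step.
#' @param temp_scale Velocity temperature: resampled velocities are sized so
#'   one resample epoch drifts each bead by about `temp_scale * mean(d_eq)`
#'   micrometres (annealed quadratically to zero when `anneal` is `TRUE`).
#' @param max_disp Hard cap on any bead's per-step displacement (um).
#' @param bond_scale Bond stiffness scale; `k_b = bond_scale / d_eq^2`.
#' @param restraint_scale Global multiplier on restraint weights
#'   (`k1 = k2 = restraint_scale * w`, with `w = 1/dbar^2` from the
#'   restraint set).
#' @param anneal Linearly anneal the velocity temperature to zero.
#' @param checkpoint_every Steps between recorded energy/satisfaction
#'   checkpoints.
#' @return An `OptimizerParams` list.
#' @export
optimizer_params <- function(n_steps = 80000L, resample_every = 100L,
                             step_scale = NULL, temp_scale = 1,
                             max_disp = NULL, bond_scale = 5,
                             restraint_scale = 1, anneal = TRUE,
                             checkpoint_every = 1000L) {
  stopifnot(n_steps >= 1, resample_every >= 1, temp_scale >= 0,
            bond_scale > 0, restraint_scale > 0, checkpoint_every >= 1)
  structure(list(n_steps = as.integer(n_steps),
                 resample_every = as.integer(resample_every),
                 step_scale = step_scale, temp_scale = temp_scale,
                 max_disp = max_disp, bond_scale = bond_scale,
                 restraint_scale = restraint_scale, anneal = anneal,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "OptimizerParams")
}

resolve_params <- function(params, restraints) {
  m <- mean(restraints$d_eq)
  if (is.null(params$step_scale)) params$step_scale <- 0.05 * m
  if (is.null(params$max_disp)) params$max_disp <- 0.5 * m
  params
}

#' Harmonic bond energy between consecutive beads
#'
#' `E = 0.5 k_b (d - d_eq)^2`, minimum 0 at `d = d_eq`; keeps the polymer
#' chain continuous.
#'
#' @param d Distance(s), >= 0.
#' @param d_eq Equilibrium distance(s), > 0.
#' @param k_b Stiffness, > 0.
#' @return Energy value(s).
#' @export
bond_energy <- function(d, d_eq, k_b = 1) {
  stopifnot(all(d >= 0), all(d_eq > 0), all(k_b > 0))
  0.5 * k_b * (d - d_eq)^2
}

#' Two-branch restraint energy
#'
#' Upper branch `k1 (d - dbar)^2` for `d >= dbar`; lower branch
#' `k2 (d - dbar log(d/dbar) - dbar)` for `0 < d < dbar`. Both branches are
#' zero with zero slope at `d = dbar`; the lower branch grows without bound
#' as `d -> 0`, acting as a soft excluded-volume wall that pushes beads back
#' out toward their target distance. Distances below `0.01 dbar` are clamped
#' so the energy and gradient stay finite.
#'
#' @param d Distance(s), >= 0.
#' @param dbar Target distance(s), > 0.
#' @param k1,k2 Stiffnesses of the two branches.
#' @return Energy value(s), >= 0.
#' @export
restraint_energy <- function(d, dbar, k1 = 1, k2 = 1) {
  stopifnot(all(d >= 0), all(dbar > 0))
  upper <- d >= dbar
  dcl <- pmax(d, 0.01 * dbar)
  ifelse(upper, k1 * (d - dbar)^2,
         k2 * (dcl - dbar * log(dcl / dbar) - dbar))
}

## Stiffness vectors implied by a restraint set + params
model_stiffness <- function(restraints, params) {
  list(w = params$restraint_scale * restraints$weight,
       kb = params$bond_scale / restraints$d_eq^2)
}

#' Total potential energy of a conformation (R reference implementation)
#'
#' Sum of [bond_energy()] over consecutive beads and [restraint_energy()]
#' over the restraint set, with the stiffness schedule implied by `params`.
#' Kept in R, independent of the compiled gradient path, so the two can be
#' cross-checked by finite differences.
#'
#' @param conf A `Conformation`.
#' @param restraints A `RestraintSet`.
#' @param params [optimizer_params()].
#' @return Scalar energy.
#' @export
total_energy <- function(conf, restraints, params = optimizer_params()) {
  params <- resolve_params(params, restraints)
  st <- model_stiffness(restraints, params)
  xyz <- conf$coords
  n <- nrow(xyz)
  db <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  e <- sum(bond_energy(db, restraints$d_eq, st$kb))
  if (length(restraints$i)) {
    dr <- sqrt(rowSums((xyz[restraints$i, , drop = FALSE] -
                        xyz[restraints$j, , drop = FALSE])^2))
    e <- e + sum(restraint_energy(dr, restraints$target, st$w, st$w))
  }
  e
}

#' Analytic gradient of the total potential
#'
#' @param conf A `Conformation`.
#' @param restraints A `RestraintSet`.
#' @param params [optimizer_params()].
#' @return `n x 3` matrix of energy gradients (forces are the negative).
#' @export
total_gradient <- function(conf, restraints, params = optimizer_params()) {
  params <- resolve_params(params, restraints)
  st <- model_stiffness(restraints, params)
  res <- .energy_gradient_cpp(conf$coords, restraints$i - 1L, restraints$j - 1L,
                              restraints$target, st$w, restraints$d_eq, st$kb)
  g <- res$gradient
  if (!all(is.finite(g))) {
    bad <- which(!is.finite(rowSums(g)))[1]
    stop(sprintf("non-finite force on bead %d", bad))
  }
  g
}

#' Adaptive timestep from the current forces
#'
#' `dt = step_scale / max|F_i|`, clipped to `[dt_min, dt_max]`; all-zero
#' forces give `dt_max`. This bounds the largest per-step displacement
#' contributed by the forces to `step_scale`.
#'
#' @param forces `n x 3` matrix (or vector of norms) of per-bead forces.
#' @param step_scale Displacement scale (um).
#' @param dt_min,dt_max Clipping bounds.
#' @return Scalar timestep.
#' @export
adaptive_step <- function(forces, step_scale = 1, dt_min = 0, dt_max = Inf) {
  fmax <- if (is.matrix(forces)) sqrt(max(rowSums(forces^2))) else max(abs(forces))
  if (fmax <= 0) return(dt_max)
  min(max(step_scale / fmax, dt_min), dt_max)
}

#' Random-coil initial structure
#'
#' Gaussian random walk with per-bond step lengths equal to the bonded
#' equilibrium distances, confined to a sphere of radius
#' `expected_distance(chromosome length)` centred at the origin.
#'
#' @param restraints A `RestraintSet` (supplies `d_eq`, bins and model).
#' @param seed Optional seed (`set.seed` is called when non-`NULL`).
#' @return A `Conformation`.
#' @export
random_coil <- function(restraints, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- restraints$bins
  n <- b$n_bins
  rconf <- expected_distance(n * b$bin_size, restraints$model)
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    step <- restraints$d_eq[i - 1]
    for (try in 1:100) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- xyz[i - 1, ] + step * u
      if (sqrt(sum(cand^2)) <= rconf) break
      ## keep the bond length, bounce back toward the origin
      if (try == 100) cand <- xyz[i - 1, ] - step * xyz[i - 1, ] / sqrt(sum(xyz[i - 1, ]^2))
    }
    xyz[i, ] <- cand
  }
  conformation(sweep(xyz, 2, colMeans(xyz)), b,
               seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Optimize one conformation against a restraint set
#'
#' Velocity-assisted gradient descent: positions move along the forces with
#' an adaptive timestep inversely proportional to the maximum force, and
#' velocities are resampled from a zero-mean Gaussian every
#' `resample_every` steps to help escape local traps. Runs for
#' `params$n_steps` steps and records per-checkpoint total restraint energy
#' and satisfaction fraction.
#'
#' @param initial Starting `Conformation`, or `NULL` for a seeded
#'   [random_coil()].
#' @param restraints A `RestraintSet`.
#' @param params [optimizer_params()].
#' @param seed RNG seed; governs the initial coil (when `initial` is
#'   `NULL`) and all velocity resampling.
#' @return A `Conformation` with attribute `trajectory`, a data frame of
#'   checkpoints (`step`, `energy`, `satisfaction`).
#' @export
optimize_conformation <- function(initial = NULL, restraints,
                                  params = optimizer_params(), seed = 1L) {
  params <- resolve_params(params, restraints)
  set.seed(seed)
  if (is.null(initial)) initial <- random_coil(restraints)
  if (initial$bins$n_bins != restraints$bins$n_bins)
    stop("restraints inconsistent with conformation size")
  st <- model_stiffness(restraints, params)
  ## stability cap on dt: inverse of the largest per-bead curvature bound
  n <- restraints$bins$n_bins
  kappa <- numeric(n)
  if (length(restraints$i)) {
    s <- rowsum(c(2 * st$w, 2 * st$w), c(restraints$i, restraints$j))
    kappa[as.integer(rownames(s))] <- kappa[as.integer(rownames(s))] + s[, 1]
  }
  bk <- st$kb
  kappa[seq_len(n - 1)] <- kappa[seq_len(n - 1)] + bk
  kappa[2:n] <- kappa[2:n] + bk
  dt_max <- 1 / max(kappa)
  res <- .optimize_cpp(initial$coords, restraints$i - 1L, restraints$j - 1L,
                       restraints$target, st$w, restraints$d_eq, st$kb,
                       params$n_steps, params$resample_every, params$step_scale,
                       dt_max, params$max_disp,
                       params$temp_scale * mean(restraints$d_eq), params$anneal,
                       params$checkpoint_every, 0.5, 2.0)
  traj <- data.frame(step = res$checkpoint_step, energy = res$checkpoint_energy,
                     satisfaction = res$checkpoint_satisfaction)
  if (isTRUE(res$diverged)) {
    stop(sprintf(
      "optimization diverged (energy held above 10x initial): initial %.4g, last %.4g at step %d",
      traj$energy[1], traj$energy[nrow(traj)], traj$step[nrow(traj)]))
  }
  out <- conformation(res$coords, restraints$bins, seed = seed)
  attr(out, "trajectory") <- traj
  if (floor(0.95 * params$n_steps) >= 1) attr(out, "coords_95") <- res$coords_95
  out
}

#' Generate an ensemble of optimized models
#'
#' Runs `n_models` independent optimizations from seeded random coils,
#' model `i` using seed `base_seed + i - 1`. Seeding is per model, so
#' results do not depend on execution order. A model whose optimization
#' diverges is dropped with a warning; more than 20% failures is an error.
#'
#' @param restraints A `RestraintSet`.
#' @param params [optimizer_params()].
#' @param n_models Number of models (>= 1); the full-chromosome analyses of
#'   the reference workflow use 300.
#' @param base_seed Seed for model 1.
#' @return An `Ensemble` of optimized `Conformation`s.
#' @export
generate_ensemble <- function(restraints, params = optimizer_params(),
                              n_models = 300L, base_seed = 1L) {
  stopifnot(n_models >= 1)
  models <- vector("list", n_models)
  failed <- integer(0)
  for (i in seq_len(n_models)) {
    m <- tryCatch(optimize_conformation(NULL, restraints, params,
                                        seed = base_seed + i - 1L),
                  error = function(e) e)
    if (inherits(m, "error")) {
      warning(sprintf("model %d failed: %s", i, conditionMessage(m)))
      failed <- c(failed, i)
    } else models[[i]] <- m
  }
  if (length(failed) > 0.2 * n_models)
    stop(sprintf("%d of %d models diverged", length(failed), n_models))
  ensemble(Filter(Negate(is.null), models))
}
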