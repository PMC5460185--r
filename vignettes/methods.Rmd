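---
title: "Restraint-based 3D chromatin modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint-based 3D chromatin modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`hic3d` reconstructs coarse-grained 3D conformations of a chromosome from a
binned Hi-C contact matrix and analyzes the resulting ensembles. A chromosome
is a string of beads, one per fixed-size genomic bin (50 kb for whole
chromosomes, 10 kb for domain-scale work). The pipeline has two stages.

## Contacts to distance restraints

The spatial distance between two loci separated by `l` bp is assumed to
follow the space-filling (fractal-globule) scaling

$$d(l) = 2R\,(l/L)^{1/3},$$

with `R` the nuclear radius (default 10 um) and `L` the total genomic length
(default 6 Gb). The empirical contact decay curve `C(l)` — the mean contact
at each genomic separation — pairs each observed mean contact with the
scaling-law distance at that separation; mapping an individual contact
frequency to a restraint distance is then linear interpolation in log-log
space between these knots (`contact_to_distance()`). The same table inverted
gives the modeled-Hi-C regeneration map (`distance_to_contact()`,
`inverse_map()`).

Practical details that matter:

* **Curve support.** One knot per diagonal up to the 2-Mb cutoff; log-spaced
  pooled knots (10 per decade) beyond it, where counts are sparse.
* **Monotonicity.** Real decay curves wiggle; the curve is made
  non-increasing in log-log space by pool-adjacent-violators before any
  interpolation, and flat runs are collapsed to single knots so the map is
  single-valued.
* **Long-range smoothing.** Contacts at separations above 2 Mb are replaced
  by the mean of their aligned 200 kb x 200 kb block before conversion, the
  standard guard against the low signal/noise of distal Hi-C counts. The
  operation is idempotent and leaves near-diagonal entries untouched.
* **Extrapolation.** Outside the observed contact range the map extrapolates
  with the *global* log-log slope of the curve and clamps distances to
  `[d(l_min), 2R]`. We first used the edge-segment slope; after isotonic
  pooling the long-range end of a noisy curve is nearly flat, and a flat
  edge slope catapults slightly-out-of-range contacts to the 2R clamp
  (12% of all targets in one 500-bead experiment). The global slope is
  robust and changes nothing inside the observed range.
* **Weights.** The reference method states only that shorter restraints have
  higher priority. We use `w = 1/d^2` on the target distance, which makes
  the harmonic violation term dimensionless — every restraint measures
  *relative* violation, so force scales are comparable across distance
  decades.
* **Bonds.** Consecutive beads get their equilibrium distance from the same
  map applied to the first off-diagonal; a zero-contact consecutive pair
  falls back to the scaling-law distance at one bin (chain continuity must
  never break).

## Optimization

Each model starts from a random coil (Gaussian walk with the bonded step
length, confined to a sphere of radius `d(chromosome length)`) and descends
the potential

$$E = \sum_i \tfrac12 k_b (d_{i,i+1} - d_{eq,i})^2 +
      \sum_{ij} E_{restraint}(d_{ij}; \bar d_{ij}),$$

where the restraint term is `k1 (d - dbar)^2` above the target and
`k2 (d - dbar log(d/dbar) - dbar)` below it. The lower branch is the printed
two-branch form with its sign corrected: as printed, the sub-target branch
has a gradient that *attracts* beads to `d = 0`; the corrected form is zero
with zero slope at the target and diverges as `d -> 0`, i.e. a soft
excluded-volume wall. `k1 = k2 = w` per restraint, with global multipliers
in `optimizer_params()`.

The dynamics are an optimization heuristic, not physical MD, and three
details were found to be load-bearing:

1. **Adaptive timestep with a curvature cap.** `dt = step_scale / max|F|`
   alone means the most-forced bead always moves a constant `step_scale` —
   the system jitters forever instead of converging. `dt` is additionally
   capped at the inverse of the largest per-bead stiffness sum (a Lipschitz
   bound on the Hessian of the pair terms), so displacements become
   force-proportional near a minimum and an exactly satisfied conformation
   is a fixed point to machine precision.
2. **Bounded velocity kicks.** Velocities are resampled every 100 steps from
   a zero-mean Gaussian. Scaling them by the rms force alone creates a
   feedback loop (noise raises forces, which raises the noise) that we
   observed diverging on long runs; scaling them by geometry alone jiggles
   even a perfectly satisfied structure. The implemented size is the
   *minimum* of the two: per-epoch drift of about
   `temp_scale x mean(d_eq)`, never beyond the rms force scale.
3. **Annealing.** The kick amplitude is annealed quadratically to zero over
   the run, so the final 5% of a default-length trajectory moves the
   structure by far less than 1% of its radius of gyration.

Per-model seeds are `base_seed + i - 1`; every stochastic element (coil,
kicks) derives from that one seed, so ensembles are bitwise reproducible and
order-independent. The compiled core evaluates roughly 10^8 pair gradients
per second per core; a 500-bead, 125k-restraint model takes ~25 s for
20,000 steps.

## Downstream analyses

* **Satisfaction** — fraction of (model, pair) distances within 0.5-2x
  (inclusive) of their restraint distance; the reference analysis reports
  86.4% on real chromosome-1 data.
* **Compartments** — observed/expected normalization per diagonal, Pearson
  correlation of O/E rows, then a 2-way spectral split: leading eigenvector
  of the column-centered (re-symmetrized) correlation matrix, 2-means on its
  entries. The eigenvector sign is arbitrary, so A/B orientation always
  comes from a user-supplied track (CpG density or GC content recommended);
  flipping the track flips the labels exactly.
* **Degree of compartmentalization** — per bin, the natural-log ratio of
  mean O/E contact with A bins to mean O/E contact with B bins (self
  excluded), with a pseudocount of `1e-6 x mean(O/E)` so bins with no
  contacts to one class stay finite. Scale-invariant by construction; the
  log base only rescales and never changes signs or correlations.
* **RMSD clustering** — Kabsch superposition; reflections are allowed by
  default in clustering because Hi-C cannot distinguish mirror images.
  Average-linkage clustering of the RMSD matrix; the representative is the
  member of the largest cluster minimizing mean RMSD to its cluster mates.
* **Chromatin types** — per-segment features are `log(eps + population
  variance)` of intra-segment contacts in log-spaced distance bins
  (4/decade, from 2 bins to 300 kb — the minimum classifiable length, so
  every classified segment has a complete feature vector; the grid is
  recorded in the model so training and application always agree).
  `eps = 1e-8 x (mean contact)^2` keeps exactly-uniform blocks finite and
  makes features scale-equivariant. Labels are seeded by 2-means on
  segments >= 500 kb (the higher-variance set is type A — localized
  interaction domains), then a two-class LDA (class means + pooled
  covariance, shrunk toward its diagonal when ill-conditioned) is trained on
  an 80/20 split with 5-fold CV. Segments under 300 kb stay unassigned.

# The synthetic world

The generator exists so that every stage is testable without external data.
Its defaults are the stated conditions of the reference analysis where there
are any, and a priori realism choices elsewhere; none were revisited after
seeing test outcomes (parameter *redesigns* forced by internal
inconsistencies are documented below).

* **Ground-truth structure** (`make_structure()`): beads along a 3D Hilbert
  space-filling curve with lattice step `d(bin_size)` and 20% Gaussian
  jitter. We tried two more obvious constructions first and rejected both
  for cause: a fixed-bond confined random walk saturates pairwise distances
  beyond ~20 beads (violating the `l^(1/3)` premise the restraint conversion
  rests on — its decay curve is non-monotone and its restraints mutually
  inconsistent), and fractional Brownian motion with Hurst 1/3 has the right
  scaling only in expectation — single realizations drift ±30% at large
  scales, which again poisons the mean decay curve. The Hilbert curve is the
  standard fractal-globule surrogate and satisfies the scaling *per
  realization at every scale*. Compartments are planted by scaling radial
  positions of A beads inward and B beads outward (`radial_bias = 0.3`);
  single-compartment layouts get no modulation and are bitwise identical
  regardless of the bias setting.
* **Forward Hi-C** (`structure_to_hic()`): expected contact = power-law
  decay in genomic separation (`gamma = 1`, the observed megabase-scale
  Hi-C decay; `depth = 20` expected counts at 1 Mb) times a proximity
  modulation `(d/d(l))^-3` clamped to `[1/10, 10]` (`proximity_cap`), then
  Poisson counts. For `gamma = 1` the unclamped kernel is exactly the
  inverse of the contact-to-distance map. The clamp encodes that population
  Hi-C shows *bounded* O/E enrichment: an unbounded single-structure kernel
  lets a handful of spatially close distal pairs carry thousands of counts
  and dominate (flatten) the mean decay curve, which no real decay curve
  does.
* **Plaid matrices** (`make_plaid_matrix()`): decay times `alpha` for
  same-compartment and `1/alpha` for cross-compartment pairs (`alpha = 2`),
  Poisson noise; `alpha = 1` is the null world.
* **Typed domains** (`make_typed_segments()`): type A domains carry 2-4
  diagonal squares (3x enriched) with nested half-size inner squares (2x
  more); type B domains contact uniformly at their half-length decay level.
  Lengths are drawn around 588 kb (A) and 744 kb (B) — the two types' mean
  lengths in the reference analysis — with a 500-kb floor so the default
  cohort is entirely trainable.
* **Feature tracks** (`make_correlated_track()`): `±effect` by compartment
  plus Gaussian noise; the point-biserial correlation
  `effect/sqrt(effect^2 + sd^2)` is the analytic check.

What a green test does *not* establish: the generator has no loop anchors,
no trans contacts, no coverage biases (no ICE/KR balancing is performed or
needed), Poisson rather than overdispersed counts, and exact block
compartments. Numbers obtained on it say the pipeline is self-consistent at
the stated signal strengths, not that real data would reach the same values.

# Numerical choices and degenerate inputs

* Asymmetric matrices are symmetrized by averaging with a warning; negative
  entries and non-square matrices are rejected.
* All-zero off-diagonals make the decay curve (and hence restraints)
  undefined — an error, not a guess.
* Distances below 1% of a restraint target are clamped in the energy and
  gradient (finite wall height, finite force).
* `rmsd()` computes the superposed RMSD by applying the optimal rotation
  explicitly; the singular-value shortcut loses ~1e-8 to cancellation and
  broke the `rmsd(a, a) == 0` contract.
* Ties in k-means and hierarchical clustering follow the seeded defaults of
  `stats::kmeans` (10 restarts) and `stats::hclust` (average linkage).
* The spectral split warns when the leading eigenvalue of the centered
  correlation matrix is below 5% of the number of usable bins — a matrix
  with one block has no meaningful two-way split.
* Orientation tracks whose class means tie exactly raise an error telling
  the user to choose labels explicitly; silent sign choices are how A/B
  labels get flipped in pipelines.

# Known limitations

* Intra-chromosomal only; no trans restraints, no balancing, no read-level
  processing.
* The optimizer is a heuristic: it finds well-satisfying conformations, not
  thermodynamic samples, and satisfaction-band statistics are its only
  convergence claim.
* The 2-class spectral split does not call sub-compartments; TADs are
  accepted as external input, never called.
* Knot invariants and loop-reproduction checks are out of scope.
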