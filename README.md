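# multibodyr

Multi-body refinement and rigid-body motion analysis for cryo-EM
single-particle data, in R.

Macromolecular complexes are often flexible: a consensus
single-particle refinement, which assumes one rigid structure, blurs
the moving parts. `multibodyr` models the complex as a user-defined
set of `B` rigid bodies, delimited by soft masks, that keep their
internal structure but reorient independently in every particle
image. It is aimed at method developers and students who want a
compact, fully inspectable implementation of this class of algorithm
that runs on synthetic data with known ground truth on a desktop.

## The model

In Fourier space the i-th particle image is

```
X_i = CTF_i ( Σ_b  P_φb V_b ) + N_i ,      b = 1…B
```

with `V_b` the 3D transform of body `b`, `P_φ` the central-slice
projection operator at pose `φ` (three ZYZ Euler angles plus an
in-plane translation), and `N_i` frequency-dependent complex Gaussian
noise with per-shell variance `σ²(k)`. Poses are *residuals* on top of
the particle's consensus pose, with Gaussian priors of user-set widths
(`σ_angles`, `σ_offset`); searches cover ±3σ.

Each expectation-maximization iteration, per body and particle:

1. subtracts the CTF-modulated projections of the *other* bodies at
   their previous-iteration poses (only the non-overlapping parts of
   their masks, in STAR-file order);
2. evaluates the Gaussian likelihood of the subtracted image over a
   pose grid and forms posterior weights `Γ`;
3. records the maximum-posterior pose and accumulates
   `Γ·CTF·S/σ²` and `Γ·CTF²/σ²` into per-half-set reconstruction
   accumulators (gold-standard half-sets never mix).

Bodies are then rebuilt by the Wiener division `num/(den + 1/τ²_b)`,
where the per-shell signal power `τ²_b = FSC/(1−FSC) ×` reconstruction
power comes from the solvent-corrected half-set FSC. Sampling is
refined coarse-to-fine; convergence requires flat resolutions, a
refined sampling floor, and small pose changes.

After convergence, a principal-component analysis over six variables
per body (three Euler angles and the 3D lift of the in-plane shift,
each column weighted by how much the body map changes per unit move)
yields eigen-motions: map series along a component, amplitude-based
particle subsets, and re-centred subtracted particle stacks for
focused downstream refinement.

## Worked example

Simulate a three-body complex with a continuous rocking of body 2
(±9°), refine, and analyse the motion:

```r
library(multibodyr)

phantom <- make_phantom(48)                       # D = 48, 3.0 A/px
motion  <- motion_model("continuous", axes = list("2" = c(0, 1, 0, 0, 0)),
                        magnitude = 9)
sim <- simulate_particles(phantom, N = 300, motion, snr = 0.1, seed = 7)

bodies <- data.frame(body_index = 1:3, mask_path = NA,
                     rotate_relative_to = c(2L, 1L, 1L),
                     sigma_angles = c(1, 3, 3), sigma_offset = 0,
                     reference_path = NA)
class(bodies) <- c("mb_bodies", "data.frame")

state <- multibody_refine(phantom$map, sim$particles, bodies, sim$images,
                          masks = phantom$masks,
                          options = list(seed = 1, max_iter = 5),
                          verbose = TRUE)

pca <- flex_pca(state)
print(pca)

# how well were body 2's rotations recovered?
err <- sapply(seq_len(state$N), function(i) {
  tp <- sim$truth$body_poses[[2]][i, ]; ep <- state$body_poses[[2]][i, ]
  acos(pmin(1, (sum(diag(t(euler_to_matrix(tp$rot, tp$tilt, tp$psi)) %*%
                 euler_to_matrix(ep$rot, ep$tilt, ep$psi))) - 1) / 2)) * 180 / pi
})
cat(sprintf("median rotation error %.2f deg; within one 1.8-deg step: %.0f%%\n",
            median(err), 100 * mean(err <= 1.8)))
```

```
iter  1 | res (A): 19.15 6.00 7.96 | pose change (deg): 0.00 4.02 1.80 | step: 1.80 1.80 1.80
iter  2 | res (A): 18.69 6.00 8.60 | pose change (deg): 0.00 0.00 1.80 | step: 0.90 0.90 0.90
iter  3 | res (A): 18.11 6.00 8.63 | pose change (deg): 0.00 0.90 0.90 | step: 0.45 0.45 0.45
iter  4 | res (A): 17.88 6.00 8.63 | pose change (deg): 0.00 0.45 0.45 | step: 0.45 0.45 0.45
iter  5 | res (A): 17.81 6.00 8.62 | pose change (deg): 0.00 0.00 0.00 | step: 0.45 0.45 0.45
<mb_pca> 18 features, 300 particles
explained variance: 89.0% 4.6% 3.3% 1.7% 1.3% 0.0%
median rotation error 0.93 deg; within one 1.8-deg step: 86%
```

The first principal component carries 89% of the pose variance — it is
the rocking motion that was simulated. The per-iteration log shows the
moving body (second column) held at the resolution of the phantom's
signal band while the median pose update shrinks to zero as sampling
is refined from 1.8° to 0.45°; at the full study size (N = 1000,
as run by the acceptance script) the fraction of particles recovered
within one step rises above nine in ten. `eigen_map_series()`
renders the motion as a series of combined maps,
`select_subset()` writes particle subsets by eigenvector amplitude,
and `write_subtracted_particles()` exports re-centred subtracted
stacks. `run_simulate()` / `run_refine()` / `run_flexanalyse_files()`
provide the same pipeline over STAR/MRC files
(see `inst/cli/multibody.R` for a shell entry point).

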