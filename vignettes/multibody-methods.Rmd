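---
title: "Multi-body refinement: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-body refinement: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A cryo-EM data set of a flexible complex is modelled as `B` rigid
bodies that are identical across particles but reorient independently
in every particle. In Fourier space the i-th particle image is

    X_i = CTF_i * sum_b P_{phi_b} V_b + N_i

where `V_b` is the 3D transform of body `b`, `P_phi` extracts the
central section at pose `phi` (three ZYZ Euler angles and a 2D
in-plane translation, realized as a phase ramp), `CTF_i` is the
particle's contrast transfer function, and `N_i` is zero-mean complex
Gaussian noise with a per-shell variance `sigma^2(k)`. Each body's
Fourier components are treated as zero-mean Gaussian with per-shell
signal power `tau_b^2(k)`, which acts as a Wiener prior in the
reconstruction step.

Each body pose is parameterized as a *residual* relative to the
particle's consensus pose: the body volume is stored with its mask's
centre of mass at the box centre, the effective projection rotation is
`R_consensus %*% R_residual`, and the effective in-plane shift is the
consensus offset plus the residual offset plus the in-plane component
of the rotated centre-of-mass vector. A zero residual therefore
reproduces the consensus projection exactly (`compose_projection_pose`).

## The algorithm

Each iteration performs, per body and particle:

1. **Partial signal subtraction.** The CTF-modulated projections of
   all *other* bodies, at their most likely poses from the previous
   iteration, are subtracted from the particle transform. With
   overlapping masks only the non-overlapping parts are subtracted:
   body masks are decomposed in file order (`decompose_overlaps`), the
   target body having the highest precedence, so the union of the
   masks is tiled without double counting. With `B` mutually
   overlapping bodies this requires `B^2` stored transforms, with
   disjoint bodies only `B`.
2. **Pose posterior.** The Gaussian image likelihood is evaluated over
   a grid of candidate residual poses and combined with a Gaussian
   pose prior centred on the consensus (zero residual), truncated at
   three standard deviations. Posterior weights are normalized with
   the log-sum-exp guard.
3. **Best pose and reconstruction.** The maximum-posterior grid pose
   becomes the particle's stored pose for the next iteration's
   subtraction, while the full posterior weights drive the
   reconstruction: every retained pose inserts `Gamma * CTF * S /
   sigma^2` into the numerator and `Gamma * CTF^2 / sigma^2` into the
   denominator of the body's half-set accumulator (the adjoint of
   slice extraction).

After the particle sweep each body is reconstructed per half-set by
the Wiener division `num / (den + 1/tau_b^2)`, re-masked, and its
`tau_b^2` is re-estimated as `FSC/(1-FSC)` times the power of the
combined reconstruction, from the solvent-corrected half-set FSC
(phase-randomization correction for mask-induced correlation). The
noise curves are re-estimated per half-set from the residuals of the
full model at the current best poses.

Particles are split once into two half-sets that never mix in
reconstructions; alignment of a particle always uses references from
its own half-set (gold standard). Because the noise model is also kept
per half-set, permuting particles within one half-set leaves the other
half-set's reconstructions unchanged within an iteration (the
`tau^2` update couples the halves across iterations, as the half-set
FSC necessarily involves both).

## Sampling and convergence

The rotational search covers a regular grid over the three Euler
angles in `[-3 sigma, +3 sigma]` (for the 10-degree priors used on
real data this is the -30..+30 degree window), translations likewise.
The initial exhaustive grid uses the configured steps (defaults 1.8
degrees / 0.25 pixels). When a body's resolution stops improving by at
least one shell, its steps are halved; refined sampling searches a
*local* displacement grid (span `local_span`, default 4 steps) around
each particle's current pose rather than re-enumerating the global
grid — an exhaustive global enumeration at sub-degree sampling would
be computationally prohibitive and is what coarse-to-fine local
searches replace in practice. Convergence is declared when every body
has reached the sampling floor (`min_angular_step`, default 0.45
degrees), resolutions are flat, and the 90th percentile of per-particle
pose changes is below the current step.

An angular-accuracy estimate (the perturbation angle at which the
signal-weighted projection self-correlation of a body drops by one
natural-log unit, averaged over views and weighted by the mean CTF^2)
is reported each iteration. Freezing a body's poses once the sampling
is finer than this estimate is available (`freeze_on_accuracy`), but
is off by default: the one-nat stand-in systematically overestimates
the accuracy angle on desk-scale problems and would stop the
refinement one to two halvings early. Bodies with zero prior widths
are always kept fixed, which lets very small bodies contribute to the
subtraction without being aligned.

## Tunable parameters

| parameter | unit | default | role |
|---|---|---|---|
| `angular_step` | degrees | 1.8 | initial rotational sampling |
| `trans_step` | pixels | 0.25 | initial translational sampling |
| `min_angular_step` | degrees | 0.45 | sampling floor (two halvings) |
| `sigma_angles`, `sigma_offset` | deg / px | per body | prior widths; 0 = fixed body |
| `tau2_fudge` | — | 4 | multiplier on the FSC-derived signal power; counteracts over-regularization of small, noisy desk-scale reconstructions (the estimator itself is a standard stand-in and explicitly tunable) |
| `gamma_prune` | — | 1e-6 | drop poses below this fraction of the posterior maximum |
| `gamma_mass` / `max_insert_poses` | — | 0.999 / 128 | additionally keep only the top poses covering this posterior mass (renormalized); bounds reconstruction cost with a negligible effect on the marginal |
| `align_rmax` | shells | D/2-2 | resolution limit of the likelihood |
| `fsc_threshold` | — | 0.143 | resolution criterion |
| `pad` | — | 1 | optional zero-padding of Fourier volumes |

## Numerical choices

* Fourier transforms use a centred convention with the phase origin at
  voxel `D/2` (0-based) on every axis; volumes must have even `D`.
* Slice extraction and insertion use trilinear interpolation without a
  gridding-correction deconvolution. At desk-scale box sizes the
  interpolation error is a few percent and identical on the simulation
  and refinement paths; a padding factor is available.
* Likelihoods exclude the DC term; shells with zero weight are
  skipped. Noise variances are floored at a small fraction of the
  measured power so that noiseless (synthetic) data cannot produce
  divisions by zero.
* Posterior ties are broken toward the prior centre, then grid order.
* The soft-edge profile of masks is a raised cosine of the exact
  Euclidean distance transform; the multiplicative complement rule for
  overlapping soft masks reduces to the stated non-overlap rule for
  binary masks, and partial masks are not renormalized.
* The tilt-90 storage convention for residual rotations (so stored
  angles sit at rot 0, tilt 90, psi 0 for a zero residual, rotating
  about a vector orthogonal to the COM-to-COM axis) is applied only at
  serialization; internal computations use rotation matrices. The
  orthogonal vector is chosen deterministically: orthogonal to the COM
  axis and the laboratory z axis where possible, else the x axis —
  this affects only the serialized representation, not the geometry.
* Solvent-corrected FSC randomizes phases from the first shell where
  the unmasked FSC drops below 0.8 and applies the
  `(FSC - FSC_rand)/(1 - FSC_rand)` correction one shell beyond it;
  the randomized reference is averaged over three draws to damp its
  sampling noise in sparsely populated shells.

## The synthetic generator

`make_phantom()` renders three bodies from Gaussian-blob blueprints: a
large smooth body and two smaller bodies whose many narrow blobs
(widths below a voxel pair) are spread through thick shells away from
their centres of mass. This mimics two properties of real particles
that matter for the method: protein-like high-frequency texture, and
mass distributed at a lever arm from the rotation centre — without
both, degree-scale rigid-body rotations are not detectable in single
noisy projections at realistic signal-to-noise (the per-pose
information is, to leading order, the sum over Fourier pixels of
`SSNR(k)` times the squared relative change of the body transform
under the rotation, which grows as `k^2 r^2`). Bodies are band-limited
below Nyquist, as real maps are.

`simulate_particles()` draws uniform consensus rotations, small random
in-plane shifts, and residual body poses from a configurable motion
model: `continuous` one-axis rocking (amplitude uniform in
`[-magnitude, magnitude]` along a fixed direction in pose space;
the default scenario rocks body 2 about its tilt axis by up to 9
degrees) or a `two_state` mixture (default offsets -6/+2 degrees,
weights 0.1/0.9, within-state spread 1 degree). Noise is added in
Fourier space per shell with Hermitian symmetry. The noise level is
set so that every Fourier pixel in the shells of interest carries the
requested SNR (default 0.1); beyond `snr_band` (by default about four
fifths of the Nyquist shell) the per-shell SNR decays exponentially,
emulating the falling spectral signal-to-noise of real micrographs. CTFs come from three defocus groups (1.0/1.5/2.0 um).

What the generator does **not** emulate: per-particle defocus spread,
detector envelopes, beam-induced motion, structural noise from
solvent, consensus-alignment errors (optional jitter is off by
default), and interface rearrangement between bodies. Passing tests on
this generator therefore demonstrate the correctness and statistical
behaviour of the estimator under the stated model, not performance on
real micrographs.

Study sizes used by the acceptance checks: the rocking study runs
D = 48, N = 1000, B = 3 with priors (1, 3, 3) degrees — the tight
prior on the stable large body reflects the practitioner's knowledge
that it does not move, and the 3-degree priors make the `+/-3 sigma`
search window coincide with the `+/-9` degree simulated motion. The
two-state study uses N = 500 and stops at 0.9-degree sampling, which
is ample for an 8-degree state separation. The fixed-point check uses
a D = 32 instance with disjoint binary masks and on-grid true poses,
where the model is exactly self-consistent.

## Motion analysis

The PCA operates on six variables per body: the three residual Euler
angles and the 3D lift of the in-plane translation (the shift vector
rotated into the reconstruction frame by the inverse consensus
rotation; its along-projection component is zero by construction).
Columns are multiplied by per-column scales equal to the summed
squared voxel change of the body map under a one-degree rotation about
the corresponding axis or a one-pixel shift — features that move more
density weigh more. The paper-facing phrasing of this normalization is
ambiguous between multiplying and dividing; multiplication is the
default and `mode = "divide"` is available. Eigen-motion map series
split the amplitudes into equi-populated bins (median amplitude as the
bin centre), map each centre back through the eigenvector and the
scales to per-body poses, and sum the rigidly repositioned bodies.
The PCA uses the stored maximum-posterior poses, matching what the
refinement serializes.

## Known limitations

* Exhaustive+local grid posteriors, no adaptive oversampling; very
  wide priors (sigma >= 10 degrees) make the initial exhaustive grid
  expensive.
* One noise curve per half-set, not per optics group or particle.
* No gridding correction, anisotropic magnification, Ewald curvature
  or point-group symmetry.
* The angular-accuracy estimate is a simplified stand-in; the freeze
  rule driven by it is therefore opt-in.
* Subtraction uses point-estimate poses of the other bodies (as the
  update equations prescribe); with strongly multimodal pose
  posteriors this is a known approximation.
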