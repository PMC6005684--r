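# Synthetic multi-body data with known ground truth: Gaussian-blob
# phantoms, per-body soft masks, configurable motion models, CTF
# modulation and frequency-dependent Fourier-space noise.

#' Default three-body phantom blueprints
#'
#' Gaussian-blob blueprints for a three-body complex loosely shaped
#' like a large subunit, a smaller subunit and a peripheral "head":
#' one dominant body and two progressively smaller ones with distinct
#' centres of mass. Each body is a cloud of many narrow blobs (widths
#' below the voxel pair scale) spread through a thick spherical shell,
#' giving the bodies protein-like high-frequency texture with mass
#' distributed away from the centre of mass — the regime in which
#' small rigid-body rotations are detectable in projections. Blob
#' positions are drawn once from a fixed internal seed, so the default
#' phantom is a constant of the package. Coordinates are in voxels
#' relative to the box centre and scale with `D`.
#'
#' @param D Box size in voxels.
#' @param nblob Blobs per body.
#' @param centres B x 3 matrix of body centres (voxels, at D = 48).
#' @param rmin,rmax Inner/outer shell radii per body (voxels, at D = 48).
#' @param sig Range of blob widths (voxels, at D = 48).
#' @param amp Per-body amplitude multipliers (smaller bodies are made
#'   denser so each body carries comparable per-pixel signal).
#' @return List of per-body data.frames with columns x, y, z, sigma, amp.
#' @export
three_body_blueprints <- function(D = 48L, nblob = c(10L, 42L, 34L),
                                  centres = rbind(c(-10, -2, 0),
                                                  c(9.5, -7.5, 0),
                                                  c(8, 9.5, 0)),
                                  rmin = c(0, 8.5, 6),
                                  rmax = c(8.5, 9.8, 8.3),
                                  sig = rbind(c(2.0, 2.8),
                                              c(0.55, 0.75),
                                              c(0.9, 1.2)),
                                  amp = c(0.8, 1.5, 0.85)) {
  s <- D / 48
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(20180601L)
  lapply(seq_along(nblob), function(b) {
    n <- nblob[b]
    pts <- matrix(NA_real_, n, 3)
    got <- 0L
    while (got < n) {
      p <- runif(3, -rmax[b], rmax[b])
      r <- sqrt(sum(p^2))
      if (r <= rmax[b] && r >= rmin[b]) {
        got <- got + 1L
        pts[got, ] <- p + centres[b, ]
      }
    }
    data.frame(x = pts[, 1] * s, y = pts[, 2] * s, z = pts[, 3] * s,
               sigma = runif(n, sig[b, 1], sig[b, 2]) * s,
               amp = amp[b] * runif(n, 0.7, 1.3))
  })
}

#' Build a multi-body phantom
#'
#' Renders per-body volumes from Gaussian-blob blueprints, derives a
#' binary-then-softened mask per body, and sums the bodies into the
#' combined consensus-like map. Bodies may overlap (their masks
#' exercise the non-overlap decomposition).
#'
#' @param D Even box size in voxels.
#' @param blueprints List of per-body blob data.frames (columns x, y,
#'   z, sigma, amp); default [three_body_blueprints()].
#' @param voxel_size Angstrom per pixel.
#' @param mask_threshold Fraction of the body maximum used to binarize.
#' @param mask_extend,mask_soft_edge Soft-mask parameters in voxels.
#' @return Object of class `mb_phantom`: list with `bodies` (list of
#'   `mb_volume`s), `masks` (list of soft `mb_volume`s), `map`
#'   (combined `mb_volume`), `coms` (B x 3 matrix) and `voxel_size`.
#' @export
make_phantom <- function(D = 48L, blueprints = three_body_blueprints(D),
                         voxel_size = 3.0, mask_threshold = 0.1,
                         mask_extend = 1.5, mask_soft_edge = 1.5,
                         bandlimit_shell = D %/% 2L - 3L,
                         bandlimit_edge = 2.5) {
  if (D %% 2L != 0L) stop("validation error: D must be even")
  if (!length(blueprints)) stop("validation error: no bodies")
  h <- D %/% 2L
  x <- seq_len(D) - 1 - h
  bodies <- vector("list", length(blueprints))
  masks <- vector("list", length(blueprints))
  for (b in seq_along(blueprints)) {
    bp <- blueprints[[b]]
    if (!nrow(bp)) stop("validation error: empty body blueprint")
    v <- array(0, c(D, D, D))
    for (j in seq_len(nrow(bp))) {
      gx <- exp(-(x - bp$x[j])^2 / (2 * bp$sigma[j]^2))
      gy <- exp(-(x - bp$y[j])^2 / (2 * bp$sigma[j]^2))
      gz <- exp(-(x - bp$z[j])^2 / (2 * bp$sigma[j]^2))
      v <- v + bp$amp[j] * outer(outer(gx, gy), gz)
    }
    # band-limit the rendered body: real maps carry no signal at the
    # sampling limit, and a defined band edge keeps projections free of
    # interpolation aliasing
    if (!is.null(bandlimit_shell) && bandlimit_shell < h) {
      res_A <- D * voxel_size / bandlimit_shell
      v <- lowpass_volume(v, voxel_size, res_A, edge_width = bandlimit_edge)
    }
    bodies[[b]] <- mb_volume(v, voxel_size)
    binary <- array(as.numeric(v > mask_threshold * max(v)), c(D, D, D))
    masks[[b]] <- make_soft_mask(mb_volume(binary, voxel_size),
                                 mask_extend, mask_soft_edge)
  }
  map <- Reduce(`+`, lapply(bodies, function(v) v$data))
  coms <- t(vapply(masks, centre_of_mass, numeric(3)))
  structure(list(bodies = bodies, masks = masks,
                 map = mb_volume(map, voxel_size), coms = coms,
                 voxel_size = voxel_size, D = D),
            class = "mb_phantom")
}

#' Define a rigid-body motion model
#'
#' `continuous` draws a scalar amplitude per particle uniformly in
#' `[-magnitude, magnitude]` and applies it along a fixed direction in
#' pose space (a one-axis rocking); `two_state` draws the amplitude
#' from a two-component mixture with Gaussian within-state spread.
#'
#' @param kind `"continuous"` or `"two_state"`.
#' @param axes Named list mapping body index (as character or integer)
#'   to a length-5 direction `c(rot, tilt, psi, dx, dy)` (degrees /
#'   pixels per unit amplitude); bodies not listed do not move.
#' @param magnitude Amplitude bound for `continuous` (so body poses
#'   reach `magnitude * axis`).
#' @param state_offsets Length-2 amplitudes of the two states.
#' @param weights Length-2 mixture weights (sum to 1).
#' @param spread Within-state standard deviation of the amplitude.
#' @return Object of class `mb_motion`.
#' @export
motion_model <- function(kind = c("continuous", "two_state"),
                         axes = list("2" = c(0, 1, 0, 0, 0)),
                         magnitude = 9,
                         state_offsets = c(-6, 2), weights = c(0.1, 0.9),
                         spread = 1) {
  kind <- match.arg(kind)
  if (abs(sum(weights) - 1) > 1e-9) stop("validation error: mixture weights must sum to 1")
  if (spread < 0) stop("validation error: spread must be >= 0")
  axes <- setNames(lapply(axes, as.numeric), as.character(names(axes)))
  structure(list(kind = kind, axes = axes, magnitude = magnitude,
                 state_offsets = state_offsets, weights = weights,
                 spread = spread),
            class = "mb_motion")
}

# amplitude draw + state labels for N particles
draw_motion_amplitudes <- function(motion, N) {
  if (motion$kind == "continuous") {
    list(amplitude = runif(N, -motion$magnitude, motion$magnitude),
         state = rep(NA_integer_, N))
  } else {
    state <- 1L + (runif(N) > motion$weights[1])
    list(amplitude = motion$state_offsets[state] + rnorm(N, 0, motion$spread),
         state = state)
  }
}

# unit direction of the motion in the 6B-dimensional feature space
# (angles as-is; in-plane shifts lifted with the identity consensus)
motion_feature_direction <- function(motion, B) {
  dir <- numeric(6 * B)
  for (nm in names(motion$axes)) {
    b <- as.integer(nm)
    ax <- motion$axes[[nm]]
    dir[(b - 1) * 6 + 1:3] <- ax[1:3]
    dir[(b - 1) * 6 + 4:5] <- ax[4:5]
  }
  dir / sqrt(sum(dir^2))
}

#' Simulate a particle stack from a phantom
#'
#' Per particle: draw a uniform consensus rotation and a small random
#' in-plane shift, draw residual body poses from the motion model,
#' synthesize `CTF * sum_b P_phi V_b` by central-slice extraction of
#' the COM-centred bodies, and add Hermitian complex Gaussian noise
#' with the requested per-shell variance. The noise level can be given
#' directly (`sigma2`) or via a target signal-to-noise ratio per
#' Fourier pixel (`snr`), measured on the noiseless images over shells
#' `2..D/3`.
#'
#' @param phantom An `mb_phantom`.
#' @param N Number of particles.
#' @param motion An `mb_motion` (or `NULL` for no motion).
#' @param snr Target per-pixel SNR in the shells of interest; ignored
#'   when `sigma2` is given.
#' @param snr_band Last shell at which the target SNR is held; beyond
#'   it the per-shell SNR decays exponentially (`snr_decay` per shell),
#'   emulating the falling spectral signal-to-noise of real data.
#'   `NULL` holds the target SNR at every shell.
#' @param snr_decay Log-SNR decay rate per shell beyond `snr_band`.
#' @param sigma2 Per-shell noise variance (scalar or length D/2 + 1).
#' @param defocus Vector of defocus values (angstrom) cycled over
#'   particles as defocus groups.
#' @param shift_range Consensus in-plane shifts drawn uniformly in
#'   `[-shift_range, shift_range]` pixels.
#' @param voltage,cs,amplitude_contrast CTF parameters.
#' @param seed Integer seed; the full output is reproducible from it.
#' @return Object of class `mb_simulation`: list with `images` (real
#'   D x D x N array), `particles` (`mb_particles` with consensus poses
#'   and identity body poses), `truth` (list: `body_poses`, `state`,
#'   `amplitude`, `sigma2`, `snr`), and `phantom`.
#' @export
simulate_particles <- function(phantom, N, motion = motion_model(),
                               snr = 0.1,
                               snr_band = max(4L, round(0.83 * (dim(phantom$map$data)[1] %/% 2L))),
                               snr_decay = 1.7, sigma2 = NULL,
                               defocus = c(10000, 15000, 20000),
                               shift_range = 1,
                               voltage = 300, cs = 2.7, amplitude_contrast = 0.1,
                               seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  D <- phantom$D
  B <- length(phantom$bodies)
  h <- D %/% 2L
  rmax <- h - 2L
  voxel <- phantom$voxel_size

  # COM-centred Fourier volumes of the bodies
  volF <- vector("list", B)
  for (b in seq_len(B)) {
    com <- phantom$coms[b, ]
    volF[[b]] <- structure(
      list(F = fourier_shift_volume(ft3c(phantom$bodies[[b]]$data), -com),
           D = D, voxel_size = voxel), class = "mb_fvolume")
  }

  rots <- random_rotations(N)
  amps <- draw_motion_amplitudes(motion %||% motion_model(magnitude = 0), N)
  body_poses <- replicate(B, empty_pose_table(N), simplify = FALSE)
  if (!is.null(motion)) {
    for (nm in names(motion$axes)) {
      b <- as.integer(nm)
      ax <- motion$axes[[nm]]
      body_poses[[b]]$rot <- amps$amplitude * ax[1]
      body_poses[[b]]$tilt <- amps$amplitude * ax[2]
      body_poses[[b]]$psi <- amps$amplitude * ax[3]
      body_poses[[b]]$dx <- amps$amplitude * ax[4]
      body_poses[[b]]$dy <- amps$amplitude * ax[5]
    }
  }

  meta <- data.frame(
    image_index = seq_len(N), stack_path = "simulated.mrcs",
    rot = numeric(N), tilt = numeric(N), psi = numeric(N),
    dx = runif(N, -shift_range, shift_range),
    dy = runif(N, -shift_range, shift_range),
    defocus_u = rep(defocus, length.out = N),
    defocus_v = rep(defocus, length.out = N),
    astig_angle = 0, voltage = voltage, cs = cs,
    amplitude_contrast = amplitude_contrast,
    half_set = rep(1L, N), stringsAsFactors = FALSE)
  for (i in seq_len(N)) {
    eul <- matrix_to_euler(rots[[i]])
    meta$rot[i] <- eul[1]; meta$tilt[i] <- eul[2]; meta$psi[i] <- eul[3]
  }
  meta$half_set <- halfset_split(N, seed + 1L)

  ctf_cache <- list()
  Xclean <- array(0i, c(D, D, N))
  for (i in seq_len(N)) {
    key <- sprintf("%.1f", meta$defocus_u[i])
    if (is.null(ctf_cache[[key]]))
      ctf_cache[[key]] <- evaluate_ctf(list(defocus_u = meta$defocus_u[i],
                                            defocus_v = meta$defocus_v[i],
                                            astig_angle = 0, voltage = voltage,
                                            cs = cs,
                                            amplitude_contrast = amplitude_contrast),
                                       D, voxel)
    ctf <- ctf_cache[[key]]
    Xi <- matrix(0i, D, D)
    for (b in seq_len(B)) {
      pose <- compose_projection_pose(meta[i, ], body_poses[[b]][i, ],
                                      phantom$coms[b, ])
      Xi <- Xi + extract_slice(volF[[b]], pose, rmax)
    }
    Xclean[, , i] <- Xi * ctf
  }

  nshell <- h + 1L
  if (is.null(sigma2)) {
    # per-shell noise variance set so that every Fourier pixel in the
    # shells of interest carries the requested SNR: sigma2(shell) =
    # mean signal power(shell) / (2 snr), lightly smoothed, and held
    # flat once the signal power falls below 1% of its mid-band level
    # (beyond the phantom's bandwidth).
    pw <- rep(0, nshell); cn <- rep(0, nshell)
    sh2 <- shell_index_2d(D); keep <- sh2 <= h
    shv <- sh2[keep]
    nprobe <- min(N, 200L)
    for (i in seq_len(nprobe)) {
      pw <- pw + shell_sum_vec(Mod(Xclean[, , i][keep])^2, shv, h)
      cn <- cn + shell_sum_vec(rep(1, sum(keep)), shv, h)
    }
    mean_power <- pw / pmax(cn, 1)
    sm <- mean_power
    for (s in 2:(nshell - 1L))
      sm[s] <- mean(mean_power[max(2, s - 1):min(nshell, s + 1)])
    ref_level <- mean(sm[3:min(9, nshell)])
    cutoff <- which(sm < 1e-4 * ref_level & seq_len(nshell) > 3L)
    if (length(cutoff)) sm[min(cutoff):nshell] <- sm[min(cutoff) - 1L]
    snr_curve <- rep(snr, nshell)
    if (!is.null(snr_band)) {
      sh <- seq_len(nshell) - 1L
      snr_curve <- snr * pmin(1, exp(-snr_decay * (sh - snr_band)))
    }
    sigma2_curve <- sm / (2 * snr_curve)
  } else {
    sigma2_curve <- if (length(sigma2) == 1L) rep(sigma2, nshell) else sigma2
  }

  images <- array(0, c(D, D, N))
  sqrt_curve <- sqrt(pmax(sigma2_curve, 0))
  noise_scale_img <- apply_shell_curve_2d_factory(D, sqrt_curve / sqrt(D * D / 2))
  for (i in seq_len(N)) {
    Xi <- Xclean[, , i]
    if (any(sigma2_curve > 0)) {
      Nf <- ft2c(matrix(rnorm(D * D), D, D)) * noise_scale_img
      Xi <- Xi + Nf
    }
    images[, , i] <- ift2c(Xi)
  }

  particles <- structure(list(
    meta = meta,
    body_poses = replicate(B, empty_pose_table(N), simplify = FALSE),
    pca_amplitudes = NULL), class = "mb_particles")
  truth <- list(body_poses = body_poses, state = amps$state,
                amplitude = amps$amplitude, sigma2 = sigma2_curve,
                snr = snr, motion = motion)
  structure(list(images = images, particles = particles, truth = truth,
                 phantom = phantom, seed = seed),
            class = "mb_simulation")
}

# precompute the 2D per-pixel factor for a per-shell curve
apply_shell_curve_2d_factory <- function(D, curve) {
  sh <- shell_index_2d(D)
  vals <- c(curve, rep(0, max(0, max(sh) + 1L - length(curve))))
  matrix(vals[sh + 1L], D, D)
}

#' Write a simulation to disk
#'
#' Writes the MRCS particle stack, the consensus-pose particle STAR
#' file, the phantom map and per-body masks, a body-definition STAR
#' file, and a ground-truth STAR sidecar with the true residual poses.
#'
#' @param sim An `mb_simulation`.
#' @param dir Output directory.
#' @param sigma_angles,sigma_offset Prior widths written to the body
#'   STAR file.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, sigma_angles = 3, sigma_offset = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  voxel <- sim$phantom$voxel_size
  B <- length(sim$phantom$bodies)
  write_mrcs(sim$images, file.path(dir, "simulated.mrcs"), voxel)
  write_mrc(sim$phantom$map, file.path(dir, "consensus.mrc"))
  for (b in seq_len(B))
    write_mrc(sim$phantom$masks[[b]], file.path(dir, sprintf("mask_body%d.mrc", b)))
  bodies <- data.frame(
    body_index = seq_len(B),
    mask_path = file.path(dir, sprintf("mask_body%d.mrc", seq_len(B))),
    rotate_relative_to = c(2L, rep(1L, B - 1L))[seq_len(B)],
    sigma_angles = sigma_angles, sigma_offset = sigma_offset,
    reference_path = NA_character_, stringsAsFactors = FALSE)
  bodies$fixed <- bodies$sigma_angles == 0 & bodies$sigma_offset == 0
  class(bodies) <- c("mb_bodies", "data.frame")
  write_body_star(bodies, file.path(dir, "bodies.star"))
  parts <- sim$particles
  parts$meta$stack_path <- file.path(dir, "simulated.mrcs")
  write_particles_star(parts, file.path(dir, "particles.star"))
  gt <- structure(list(meta = parts$meta, body_poses = sim$truth$body_poses,
                       pca_amplitudes = NULL), class = "mb_particles")
  write_particles_star(gt, file.path(dir, "ground_truth.star"))
  invisible(dir)
}
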