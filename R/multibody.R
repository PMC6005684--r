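# The multi-body expectation-maximization refinement: on-the-fly
# partial signal subtraction, pose-grid posteriors, posterior-weighted
# gold-standard half-set reconstruction, tau^2 regularization from the
# solvent-corrected half-set FSC, and sampling/convergence control.

default_refine_options <- function() {
  list(
    angular_step = 1.8,        # degrees, initial rotational sampling
    trans_step = 0.25,         # pixels, initial translational sampling
    max_iter = 25L,
    min_angular_step = 0.45,   # halving floor
    gamma_prune = 1e-6,        # drop grid poses below this fraction of max(gamma)
    local_span = 4L,           # half-width (in steps) of the refined local search
    gamma_mass = 0.999,        # keep top poses covering this posterior mass
    max_insert_poses = 128L,   # hard cap on inserted poses per particle/body
    align_rmax = NULL,         # alignment resolution limit (shells); NULL = D/2 - 3
    freeze_sigma2 = FALSE,     # keep the initial noise curve fixed
    freeze_on_accuracy = FALSE, # freeze poses once sampling outruns accuracy
    fsc_cap = 0.999,
    tau2_fudge = 4,            # multiplier on the FSC-derived signal power
    fsc_threshold = 0.143,
    solvent_correct = TRUE,
    pad = 1L,
    reference_lowpass = NULL,  # angstrom; low-pass applied to body references
    seed = 1L
  )
}

sigma2_floor <- function(sigma2, power_scale) {
  pmax(sigma2, 1e-8 * power_scale, 1e-30)
}

#' Initialize a multi-body refinement state
#'
#' Builds the initial body models from the consensus map (or per-body
#' reference maps), computes the ordered non-overlap decomposition of
#' the body masks, estimates the per-shell noise variance from
#' particle-minus-consensus-projection residuals, and sets up the
#' half-set split, priors and sampling steps.
#'
#' @param consensus_map `mb_volume` from the consensus refinement.
#' @param particles `mb_particles` with consensus poses and CTF
#'   parameters (body poses, when present, seed the residual poses).
#' @param bodies `mb_bodies` (see [read_body_star()]).
#' @param images Particle images: real D x D x N array, or complex
#'   array of their centred 2D Fourier transforms.
#' @param masks Optional list of soft masks (`mb_volume`s) in body
#'   order; defaults to reading `bodies$mask_path`.
#' @param references Optional list of per-body initial reference
#'   volumes (overrides the masked consensus; `NULL` entries fall back).
#' @param options List of tunables; see `multibodyr:::default_refine_options`.
#' @return An object of class `mb_state` (a list).
#' @export
initialize_state <- function(consensus_map, particles, bodies, images,
                             masks = NULL, references = NULL, options = list()) {
  opt <- utils::modifyList(default_refine_options(), options)
  cons <- as_mb_volume(consensus_map)
  D <- dim(cons$data)[1]
  B <- nrow(bodies)
  if (is.null(masks)) masks <- lapply(bodies$mask_path, read_mrc)
  masks <- lapply(masks, function(m) as_mb_volume(m)$data)
  if (!all(vapply(masks, function(m) all(dim(m) == dim(cons$data)), logical(1))))
    stop("validation error: mask/map grid mismatch")
  validate_bodies(bodies)
  coms <- t(vapply(masks, centre_of_mass, numeric(3)))
  bodies$com_x <- coms[, 1]; bodies$com_y <- coms[, 2]; bodies$com_z <- coms[, 3]
  bodies$fixed <- bodies$sigma_angles == 0 & bodies$sigma_offset == 0
  decomp <- decompose_overlaps(masks)

  # centred masks and initial body volumes (COM-centred)
  masks_centred <- vector("list", B)
  volF <- vector("list", B)          # per body: list(half = list(F1, F2))
  for (b in seq_len(B)) {
    com <- coms[b, ]
    masks_centred[[b]] <- pmin(pmax(
      array(cpp_resample_rigid(as.numeric(masks[[b]]), D, as.numeric(diag(3)),
                               c(0, 0, 0), -com), c(D, D, D)), 0), 1)
    if (!is.null(references) && !is.null(references[[b]])) {
      ref <- as_mb_volume(references[[b]])$data
      if (!is.null(opt$reference_lowpass))
        ref <- lowpass_volume(ref, cons$voxel_size, opt$reference_lowpass)
      v_insitu <- ref * masks[[b]]
    } else if (!is.na(bodies$reference_path[b]) && is.null(references)) {
      ref <- read_mrc(bodies$reference_path[b])$data
      if (!is.null(opt$reference_lowpass))
        ref <- lowpass_volume(ref, cons$voxel_size, opt$reference_lowpass)
      v_insitu <- ref * masks[[b]]
    } else {
      v_insitu <- cons$data * masks[[b]]
    }
    Fb <- fourier_shift_volume(ft3c(v_insitu), -com)
    volF[[b]] <- list(Fb, Fb)
  }

  # particle transforms and CTFs
  N <- nrow(particles$meta)
  if (is.complex(images)) {
    X <- images
  } else {
    X <- array(0i, c(D, D, N))
    for (i in seq_len(N)) X[, , i] <- ft2c(images[, , i])
  }
  meta <- particles$meta
  ctfs <- array(0, c(D, D, N))
  for (i in seq_len(N)) {
    ctfs[, , i] <- evaluate_ctf(list(defocus_u = meta$defocus_u[i],
                                     defocus_v = meta$defocus_v[i],
                                     astig_angle = meta$astig_angle[i],
                                     voltage = meta$voltage[i], cs = meta$cs[i],
                                     amplitude_contrast = meta$amplitude_contrast[i]),
                                D, cons$voxel_size)
  }

  body_poses <- particles$body_poses
  if (length(body_poses) == 0L)
    body_poses <- replicate(B, empty_pose_table(N), simplify = FALSE)
  if (length(body_poses) != B)
    stop("validation error: particle body poses do not match the body count")

  state <- list(
    D = D, B = B, N = N, voxel_size = cons$voxel_size,
    bodies = bodies, masks = masks, masks_centred = masks_centred,
    decomp = decomp, consensusF = ft3c(cons$data),
    X = X, ctfs = ctfs, meta = meta,
    body_poses = body_poses, prev_poses = body_poses,
    volF = volF, partialF = NULL,
    sigma2 = NULL, tau2 = vector("list", B),
    angular_step = rep(opt$angular_step, B),
    trans_step = rep(opt$trans_step, B),
    frozen = bodies$fixed, converged = FALSE,
    res_shell = rep(NA_real_, B), res_history = list(),
    pose_change = rep(NA_real_, B), iteration = 0L,
    options = opt, log = list()
  )

  # noise curve per half-set from consensus-model residuals
  state$sigma2 <- estimate_sigma2_consensus(state)
  # initial tau^2 from the power of the masked consensus bodies
  for (b in seq_len(B))
    state$tau2[[b]] <- pmax(shell_power(volF[[b]][[1]]), 0)
  state$partialF <- update_partial_volumes(state)
  # alignment resolution limit (shells); all shells with signal by default
  if (is.null(opt$align_rmax)) state$align_rmax <- D %/% 2L - 2L
  else state$align_rmax <- as.integer(opt$align_rmax)
  # mean CTF^2 per shell (for the angular-accuracy estimate)
  sh2 <- shell_index_2d(D)
  keep2 <- sh2 <= D %/% 2L
  c2 <- rep(0, D %/% 2L + 1L)
  for (i in seq_len(N))
    c2 <- c2 + shell_sum_vec(ctfs[, , i][keep2]^2, sh2[keep2], D %/% 2L)
  cnt2 <- shell_sum_vec(rep(1, sum(keep2)), sh2[keep2], D %/% 2L) * N
  state$mean_ctf2 <- c2 / pmax(cnt2, 1)
  class(state) <- "mb_state"
  state
}

# per-half per-shell noise variance (of real and imaginary parts) from
# residuals against the consensus model at the consensus poses
estimate_sigma2_consensus <- function(state) {
  D <- state$D
  nmax <- D %/% 2L
  rmax <- D %/% 2L - 2L
  shells2 <- shell_index_2d(D)
  fconsv <- structure(list(F = state$consensusF, D = D,
                           voxel_size = state$voxel_size), class = "mb_fvolume")
  sums <- list(`1` = rep(0, nmax + 1L), `2` = rep(0, nmax + 1L))
  cnts <- list(`1` = rep(0, nmax + 1L), `2` = rep(0, nmax + 1L))
  keep <- shells2 <= nmax
  sh <- shells2[keep]
  for (i in seq_len(state$N)) {
    pose <- compose_projection_pose(state$meta[i, ], list(rot = 0, tilt = 0, psi = 0,
                                                          dx = 0, dy = 0), c(0, 0, 0))
    proj <- extract_slice(fconsv, pose, rmax) * state$ctfs[, , i]
    resid <- state$X[, , i] - proj
    h <- as.character(state$meta$half_set[i])
    sums[[h]] <- sums[[h]] + shell_sum_vec(Mod(resid[keep])^2 / 2, sh, nmax)
    cnts[[h]] <- cnts[[h]] + shell_sum_vec(rep(1, sum(keep)), sh, nmax)
  }
  s1 <- sums[["1"]] / pmax(cnts[["1"]], 1)
  s2 <- sums[["2"]] / pmax(cnts[["2"]], 1)
  scale <- mean(c(s1[2:min(8, nmax)], s2[2:min(8, nmax)]), na.rm = TRUE)
  list(sigma2_floor(s1, scale), sigma2_floor(s2, scale))
}

shell_sum_vec <- function(x, sh, nmax) {
  s <- rowsum(as.numeric(x), sh)
  out <- rep(0, nmax + 1L)
  out[as.integer(rownames(s)) + 1L] <- s
  out
}

# Fourier volumes of the non-overlapping parts of every other body,
# COM-centred on the source body, per half-set: partialF[[b]][[bp]][[half]]
update_partial_volumes <- function(state) {
  B <- state$B
  D <- state$D
  out <- vector("list", B)
  # real in-situ volumes per body/half from the current COM-centred transforms
  insitu <- vector("list", B)
  for (bp in seq_len(B)) {
    com <- as.numeric(state$bodies[bp, c("com_x", "com_y", "com_z")])
    insitu[[bp]] <- lapply(1:2, function(h)
      ift3c(fourier_shift_volume(state$volF[[bp]][[h]], com)))
  }
  for (b in seq_len(B)) {
    out[[b]] <- vector("list", B)
    for (bp in seq_len(B)) {
      if (bp == b) next
      pm <- state$decomp$partial[[b]][[bp]]
      com <- as.numeric(state$bodies[bp, c("com_x", "com_y", "com_z")])
      src <- state$masks[[bp]]
      identical_mask <- max(abs(pm - src)) <= 1e-12
      out[[b]][[bp]] <- lapply(1:2, function(h) {
        v <- if (identical_mask) insitu[[bp]][[h]] else {
          # reweight the stored (already mask-weighted) density to the partial mask
          w <- ifelse(src > 1e-6, pm / pmax(src, 1e-6), 0)
          insitu[[bp]][[h]] * w
        }
        fourier_shift_volume(ft3c(v), -com)
      })
    }
  }
  out
}

#' Partial signal subtraction for one particle and one target body
#'
#' Subtracts from the particle's Fourier transform the CTF-modulated
#' projections of the non-overlapping parts of all other bodies at
#' their most likely poses from the previous iteration (identity
#' residuals before the first iteration).
#'
#' @param state An `mb_state`.
#' @param i Particle index.
#' @param b Target body index.
#' @param poses Optional list of per-body pose tables to subtract at;
#'   defaults to the previous-iteration poses in the state.
#' @return Complex D x D matrix: the subtracted image transform.
#' @export
subtract_signal <- function(state, i, b, poses = NULL) {
  if (is.null(poses)) poses <- state$prev_poses
  D <- state$D
  rmax <- D %/% 2L - 2L
  S <- state$X[, , i]
  half <- state$meta$half_set[i]
  cons <- state$meta[i, ]
  for (bp in seq_len(state$B)) {
    if (bp == b) next
    com <- as.numeric(state$bodies[bp, c("com_x", "com_y", "com_z")])
    pose <- compose_projection_pose(cons, poses[[bp]][i, ], com)
    fv <- structure(list(F = state$partialF[[b]][[bp]][[half]], D = D,
                         voxel_size = state$voxel_size), class = "mb_fvolume")
    S <- S - extract_slice(fv, pose, rmax) * state$ctfs[, , i]
  }
  S
}

#' Image log-likelihood given a reference projection
#'
#' `-0.5 * sum_k |S(k) - proj(k)|^2 / sigma2(shell)`, the Gaussian
#' log-likelihood up to a pose-independent constant. Shells with zero
#' or missing variance are excluded (the DC term is never used).
#'
#' @param S Complex image transform (subtracted particle).
#' @param proj Complex reference projection transform (CTF applied).
#' @param sigma2 Per-shell noise variance, length D/2 + 1.
#' @param rmax Resolution limit in shells.
#' @return Scalar log-likelihood.
#' @export
log_likelihood_image <- function(S, proj, sigma2, rmax = NULL) {
  D <- dim(S)[1]
  if (is.null(rmax)) rmax <- D %/% 2L - 2L
  if (any(sigma2[2:(rmax + 1)] <= 0))
    stop("validation error: zero noise variance in a populated shell")
  sh <- shell_index_2d(D)
  w <- rep(0, max(sh) + 1L)
  idx <- 2:(rmax + 1L)
  w[idx] <- 1 / sigma2[idx]
  keep <- sh >= 1L & sh <= rmax
  -0.5 * sum(w[sh[keep] + 1L] * Mod(S[keep] - proj[keep])^2)
}

#' Posterior weights over a pose grid
#'
#' Normalizes `exp(loglik + logprior)` over the grid with the
#' log-sum-exp guard.
#'
#' @param loglik Vector of per-pose log-likelihoods.
#' @param log_prior Vector of per-pose log prior densities.
#' @return List with `gamma` (weights summing to one) and
#'   `log_posterior` (unnormalized).
#' @export
compute_posterior <- function(loglik, log_prior = 0) {
  lp <- loglik + log_prior
  if (all(!is.finite(lp))) stop("validation error: no pose has finite posterior")
  m <- max(lp[is.finite(lp)])
  g <- exp(lp - m)
  g[!is.finite(g)] <- 0
  list(gamma = g / sum(g), log_posterior = lp)
}

#' Most likely pose of a posterior grid
#'
#' The grid pose of maximal posterior weight; ties are broken by the
#' largest prior density (smallest distance from the grid centre), then
#' by grid order.
#'
#' @param gamma Posterior weights.
#' @param grid An `mb_pose_grid`.
#' @return One-row data.frame: the selected grid pose.
#' @export
best_pose <- function(gamma, grid) {
  m <- max(gamma)
  cand <- which(gamma >= m * (1 - 1e-12))
  if (length(cand) > 1L) {
    lp <- grid$log_prior[cand]
    cand <- cand[lp >= max(lp) - 1e-12]
  }
  grid[cand[1L], c("rot", "tilt", "psi", "dx", "dy")]
}

# effective rotation matrices for all grid rotations under one consensus
# rotation: rotmats is nr x 9 (column-major 3x3 per row); returns the
# same layout for Rc %*% R_r
compose_rotmats_mat <- function(Rc, rotmats) {
  nr <- nrow(rotmats)
  Gf <- matrix(t(rotmats), 3L, 3L * nr)             # stacked columns
  Re <- Rc %*% Gf
  arr <- array(Re, c(3L, 3L, nr))
  matrix(aperm(arr, c(3L, 1L, 2L)), nr, 9L)
}

#' One expectation-maximization iteration
#'
#' For every non-fixed, non-frozen body and every particle: subtract
#' the other bodies at their previous-iteration poses, evaluate the
#' pose-grid posterior, record the most likely pose, and accumulate the
#' posterior-weighted half-set reconstructions. Then, per body: divide
#' out the accumulators with the `1/tau^2` regularizer, re-mask,
#' update `tau^2` from the solvent-corrected half-set FSC, re-estimate
#' the noise curves, and update the partial-subtraction volumes.
#'
#' @param state An `mb_state`.
#' @return The updated `mb_state`.
#' @export
run_iteration <- function(state) {
  D <- state$D
  B <- state$B
  N <- state$N
  opt <- state$options
  rmax_rec <- D %/% 2L - 2L
  nmax <- D %/% 2L
  rmax_align <- min(state$align_rmax, rmax_rec)
  shells2 <- shell_index_2d(D)
  keep2 <- shells2 <= nmax
  sh2 <- shells2[keep2]

  new_poses <- state$body_poses
  accs <- lapply(seq_len(B), function(b) list(slice_accumulator(D), slice_accumulator(D)))
  pose_change_rot <- matrix(0, N, B)
  resid_sums <- list(rep(0, nmax + 1L), rep(0, nmax + 1L))
  resid_cnts <- list(rep(0, nmax + 1L), rep(0, nmax + 1L))

  for (b in seq_len(B)) {
    fixed_b <- state$frozen[b] || state$bodies$fixed[b]
    prior <- pose_prior(state$bodies$sigma_angles[b], state$bodies$sigma_offset[b])
    # coarse sampling: one exhaustive global grid; refined sampling:
    # a fine local displacement grid around each particle's current pose
    local_b <- state$angular_step[b] < opt$angular_step - 1e-9
    if (!local_b) {
      grid <- build_pose_grid(prior, state$angular_step[b], state$trans_step[b])
      gf <- grid_factorise(grid)
      lp_ang0 <- if (prior$sigma_angles > 0)
        -(gf$angles$rot^2 + gf$angles$tilt^2 + gf$angles$psi^2) /
          (2 * prior$sigma_angles^2) else rep(0, gf$nr)
      lp_off0 <- if (prior$sigma_offset > 0)
        -(gf$shifts[, 1]^2 + gf$shifts[, 2]^2) / (2 * prior$sigma_offset^2)
        else rep(0, gf$nt)
    } else {
      base <- local_grid_base(prior, state$angular_step[b], state$trans_step[b],
                              span = opt$local_span)
      gf <- grid_factorise(base)
    }
    com <- as.numeric(state$bodies[b, c("com_x", "com_y", "com_z")])
    wrec <- lapply(state$sigma2, function(s) {
      w <- 1 / s; w[!is.finite(w)] <- 0; w
    })
    walign <- lapply(wrec, function(w) {
      w2 <- w; w2[1] <- 0
      if (rmax_align + 2L <= length(w2)) w2[(rmax_align + 2L):length(w2)] <- 0
      w2
    })
    for (i in seq_len(N)) {
      half <- state$meta$half_set[i]
      ctf <- state$ctfs[, , i]
      S <- subtract_signal(state, i, b)
      cons <- state$meta[i, ]
      Rc <- euler_to_matrix(cons$rot, cons$tilt, cons$psi)
      pc <- Rc %*% com
      base_shift <- c(cons$dx + pc[1], cons$dy + pc[2])
      if (fixed_b) {
        bp_row <- state$body_poses[[b]][i, ]
        eff <- compose_projection_pose(cons, bp_row, com)
        insert_slice(accs[[b]][[half]],
                     S, eff, ctf, wrec[[half]], gamma = 1, rmax = rmax_rec)
        best <- as.numeric(bp_row[c("rot", "tilt", "psi", "dx", "dy")])
      } else {
        if (local_b) {
          ctr <- as.numeric(state$prev_poses[[b]][i, c("rot", "tilt", "psi",
                                                       "dx", "dy")])
          angs <- cbind(gf$angles$rot + ctr[1], gf$angles$tilt + ctr[2],
                        gf$angles$psi + ctr[3])
          offs <- cbind(gf$shifts[, 1] + ctr[4], gf$shifts[, 2] + ctr[5])
          rotm_res <- euler_to_matrix_batch(angs[, 1], angs[, 2], angs[, 3])
          lp_ang <- if (prior$sigma_angles > 0) {
            v <- -(angs[, 1]^2 + angs[, 2]^2 + angs[, 3]^2) /
              (2 * prior$sigma_angles^2)
            v[pmax(abs(angs[, 1]), abs(angs[, 2]), abs(angs[, 3])) >
                3 * prior$sigma_angles + 1e-9] <- -Inf
            v
          } else rep(0, gf$nr)
          lp_off <- if (prior$sigma_offset > 0) {
            v <- -(offs[, 1]^2 + offs[, 2]^2) / (2 * prior$sigma_offset^2)
            v[pmax(abs(offs[, 1]), abs(offs[, 2])) >
                3 * prior$sigma_offset + 1e-9] <- -Inf
            v
          } else rep(0, gf$nt)
        } else {
          angs <- as.matrix(gf$angles)
          offs <- gf$shifts
          rotm_res <- gf$rotmats
          lp_ang <- lp_ang0
          lp_off <- lp_off0
        }
        rotm <- compose_rotmats_mat(Rc, rotm_res)
        shifts <- cbind(offs[, 1] + base_shift[1], offs[, 2] + base_shift[2])
        ll <- cpp_pose_loglik(state$volF[[b]][[half]], D, rotm, shifts,
                              as.complex(S), as.numeric(ctf),
                              as.numeric(walign[[half]]), as.integer(rmax_align))
        lp_vec <- rep(lp_off, each = gf$nr) + rep(lp_ang, gf$nt)
        post <- compute_posterior(as.numeric(ll), lp_vec)
        gam <- post$gamma
        # argmax with tie-breaks: largest prior, then grid order
        cand <- which(gam >= max(gam) * (1 - 1e-12))
        if (length(cand) > 1L) {
          lpc <- lp_vec[cand]
          cand <- cand[lpc >= max(lpc) - 1e-12]
        }
        bi <- cand[1L]
        ri <- (bi - 1L) %% gf$nr + 1L
        ti <- (bi - 1L) %/% gf$nr + 1L
        best <- c(angs[ri, ], offs[ti, ])
        # pruned, renormalized insertion set
        ord <- order(gam, decreasing = TRUE)
        keepn <- min(length(ord),
                     max(1L, which(cumsum(gam[ord]) >= opt$gamma_mass)[1]),
                     opt$max_insert_poses)
        sel <- ord[seq_len(keepn)]
        sel <- sel[gam[sel] >= opt$gamma_prune * gam[sel[1]]]
        gsel <- gam[sel] / sum(gam[sel])
        for (j in seq_along(sel)) {
          rj <- (sel[j] - 1L) %% gf$nr + 1L
          tj <- (sel[j] - 1L) %/% gf$nr + 1L
          eff <- list(R = matrix(rotm[rj, ], 3, 3),
                      shift = c(shifts[tj, 1], shifts[tj, 2]))
          insert_slice(accs[[b]][[half]], S, eff, ctf, wrec[[half]],
                       gamma = gsel[j], rmax = rmax_rec)
        }
      }
      R_old <- euler_to_matrix(state$body_poses[[b]]$rot[i],
                               state$body_poses[[b]]$tilt[i],
                               state$body_poses[[b]]$psi[i])
      R_new <- euler_to_matrix(best[1], best[2], best[3])
      pose_change_rot[i, b] <- rotation_distance(R_old, R_new)
      new_poses[[b]][i, ] <- best

      if (b == 1L && !opt$freeze_sigma2) {
        eff <- compose_projection_pose(cons, list(rot = best[1], tilt = best[2],
                                                  psi = best[3], dx = best[4],
                                                  dy = best[5]), com)
        fv <- structure(list(F = state$volF[[b]][[half]], D = D,
                             voxel_size = state$voxel_size), class = "mb_fvolume")
        resid <- S - extract_slice(fv, eff, rmax_rec) * ctf
        resid_sums[[half]] <- resid_sums[[half]] +
          shell_sum_vec(Mod(resid[keep2])^2 / 2, sh2, nmax)
        resid_cnts[[half]] <- resid_cnts[[half]] +
          shell_sum_vec(rep(1, sum(keep2)), sh2, nmax)
      }
    }
  }

  # maximization: divide, re-mask, update tau^2 and resolutions
  res_shell_new <- state$res_shell
  fsc_list <- vector("list", B)
  for (b in seq_len(B)) {
    halves_real <- vector("list", 2)
    for (h in 1:2) {
      vol <- reconstruct_from_accumulator(accs[[b]][[h]], state$tau2[[b]],
                                          state$voxel_size)
      halves_real[[h]] <- vol$data
    }
    mask_c <- state$masks_centred[[b]]
    if (opt$solvent_correct) {
      fsc <- solvent_correct_fsc(mb_volume(halves_real[[1]], state$voxel_size),
                                 mb_volume(halves_real[[2]], state$voxel_size),
                                 mask_c, seed = opt$seed + 1000L * b)
    } else {
      fsc <- compute_fsc(mb_volume(halves_real[[1]] * mask_c, state$voxel_size),
                         mb_volume(halves_real[[2]] * mask_c, state$voxel_size))
    }
    fsc_list[[b]] <- fsc
    res <- resolution_at_threshold(fsc, opt$fsc_threshold, D, state$voxel_size)
    res_shell_new[b] <- attr(res, "shell")
    # combined reconstruction for tau^2 power
    comb <- slice_accumulator(D)
    comb$numre <- accs[[b]][[1]]$numre + accs[[b]][[2]]$numre
    comb$numim <- accs[[b]][[1]]$numim + accs[[b]][[2]]$numim
    comb$den <- accs[[b]][[1]]$den + accs[[b]][[2]]$den
    comb_vol <- reconstruct_from_accumulator(comb, state$tau2[[b]], state$voxel_size)
    combF <- ft3c(comb_vol$data * mask_c)
    state$tau2[[b]] <- opt$tau2_fudge *
      estimate_tau2(fsc, pmax(shell_power(combF), 0), opt$fsc_cap)
    for (h in 1:2)
      state$volF[[b]][[h]] <- ft3c(halves_real[[h]] * mask_c)
    state$combinedF <- state$combinedF %||% vector("list", B)
    state$combinedF[[b]] <- combF
  }

  if (!opt$freeze_sigma2 && sum(resid_cnts[[1]]) > 0) {
    s1 <- resid_sums[[1]] / pmax(resid_cnts[[1]], 1)
    s2 <- resid_sums[[2]] / pmax(resid_cnts[[2]], 1)
    scale <- mean(c(s1[2:min(8, nmax)], s2[2:min(8, nmax)]), na.rm = TRUE)
    state$sigma2 <- list(sigma2_floor(s1, scale), sigma2_floor(s2, scale))
  }

  state$prev_poses <- new_poses
  state$body_poses <- new_poses
  state$partialF <- update_partial_volumes(state)
  state$pose_change <- apply(pose_change_rot, 2, median)
  state$pose_change_q90 <- apply(pose_change_rot, 2, quantile, probs = 0.9)
  state$iteration <- state$iteration + 1L
  state$res_history[[state$iteration]] <- res_shell_new
  state$fsc <- fsc_list
  old_res <- state$res_shell
  state$res_shell <- res_shell_new
  state$log[[state$iteration]] <- list(
    iteration = state$iteration,
    res_shell = res_shell_new,
    resolution_A = D * state$voxel_size / pmax(res_shell_new, 1e-6),
    pose_change_deg = state$pose_change,
    angular_step = state$angular_step,
    trans_step = state$trans_step,
    frozen = state$frozen)
  state <- check_convergence_and_sampling(state, old_res)
  state
}

#' Update sampling steps, freeze bodies and test convergence
#'
#' A body's poses are frozen once the angular sampling is finer than
#' the estimated accuracy of its rotations. When a body's resolution
#' has not improved by at least one shell over the previous iteration,
#' its sampling steps are halved (down to the configured floor). The
#' refinement converges once resolutions no longer increase, pose
#' changes are small relative to the sampling, and the sampling is
#' finer than the angular accuracy for every body.
#'
#' @param state An `mb_state` (after at least one iteration).
#' @param old_res Per-body resolution shells of the previous iteration
#'   (internal; defaults to the stored history).
#' @return The updated `mb_state`.
#' @export
check_convergence_and_sampling <- function(state, old_res = NULL) {
  if (is.null(old_res)) {
    nh <- length(state$res_history)
    old_res <- if (nh >= 2L) state$res_history[[nh - 1L]] else rep(NA_real_, state$B)
  }
  opt <- state$options
  B <- state$B
  acc <- state$angular_accuracy %||% rep(NA_real_, B)
  stalled <- rep(FALSE, B)
  for (b in seq_len(B)) {
    if (state$bodies$fixed[b]) next
    acc[b] <- estimate_angular_accuracy(state, b)
    if (opt$freeze_on_accuracy && !state$frozen[b] &&
        state$angular_step[b] < acc[b]) state$frozen[b] <- TRUE
    improved <- !is.na(old_res[b]) && state$res_shell[b] >= old_res[b] + 1
    stalled[b] <- !is.na(old_res[b]) && !improved
    if (stalled[b] && !state$frozen[b] &&
        state$angular_step[b] / 2 >= opt$min_angular_step) {
      state$angular_step[b] <- state$angular_step[b] / 2
      state$trans_step[b] <- state$trans_step[b] / 2
    }
  }
  state$angular_accuracy <- acc
  sampling_fine <- all(state$bodies$fixed | state$frozen |
                         state$angular_step <= pmax(acc, opt$min_angular_step + 1e-9))
  fully_refined <- all(state$bodies$fixed | state$frozen |
                         state$angular_step <= opt$min_angular_step + 1e-9)
  chg <- state$pose_change_q90 %||% state$pose_change
  changes_small <- all(is.na(chg) | chg <= state$angular_step)
  res_flat <- length(state$res_history) >= 2L && all(stalled | state$bodies$fixed)
  state$converged <- isTRUE(sampling_fine && fully_refined &&
                              changes_small && res_flat)
  state
}

# Rotation angle (degrees) at which the signal-weighted projection
# self-correlation of the body drops by one natural-log unit of
# likelihood, averaged over a fixed set of view directions.
estimate_angular_accuracy <- function(state, b, n_views = 6L) {
  D <- state$D
  rmax <- min(state$align_rmax, D %/% 2L - 2L)
  w <- state$mean_ctf2 / ((state$sigma2[[1]] + state$sigma2[[2]]) / 2)
  w[1] <- 0
  if (rmax + 2L <= length(w)) w[(rmax + 2L):length(w)] <- 0
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(state$options$seed + 77L)
  views <- random_rotations(n_views)
  alphas <- c(0.25, 0.5, 1, 2, 4, 8, 16)
  drops <- matrix(0, n_views, length(alphas))
  ones <- matrix(1, D, D)
  for (v in seq_len(n_views)) {
    Rc <- views[[v]]
    fv <- structure(list(F = state$volF[[b]][[1]], D = D,
                         voxel_size = state$voxel_size), class = "mb_fvolume")
    ref <- extract_slice(fv, list(R = Rc, shift = c(0, 0)), rmax)
    for (a in seq_along(alphas)) {
      Rd <- Rc %*% euler_to_matrix(0, alphas[a], 0)
      pert <- extract_slice(fv, list(R = Rd, shift = c(0, 0)), rmax)
      drops[v, a] <- -log_likelihood_image(ref, pert, 1 / pmax(w, 1e-300), rmax)
    }
  }
  md <- colMeans(drops)
  if (all(md < 1)) return(Inf)
  a1 <- which(md >= 1)[1]
  if (a1 == 1L) return(alphas[1])
  # log-linear interpolation between bracketing perturbation angles
  x0 <- log(alphas[a1 - 1]); x1 <- log(alphas[a1])
  y0 <- md[a1 - 1]; y1 <- md[a1]
  exp(x0 + (1 - y0) / (y1 - y0) * (x1 - x0))
}

# deterministic-once-seeded uniform random rotation matrices
random_rotations <- function(n) {
  lapply(seq_len(n), function(i) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  })
}

#' Reconstruct one body from explicit posteriors
#'
#' Posterior-weighted direct Fourier reconstruction of one body from a
#' set of particles of a single half-set, with the per-shell `1/tau^2`
#' Wiener term in the denominator.
#'
#' @param state An `mb_state`.
#' @param particle_idx Indices of the particles to use (one half-set).
#' @param b Body index.
#' @param posteriors List (one per particle) of lists with `grid` (an
#'   `mb_pose_grid`) and `gamma` (weights); `NULL` entries use a point
#'   posterior at the particle's current pose.
#' @param tau2 Per-shell regularizer (default: the state's curve for
#'   `b`; `NULL` for unregularized).
#' @return An `mb_volume` (COM-centred body reconstruction).
#' @export
reconstruct_body <- function(state, particle_idx, b, posteriors = NULL,
                             tau2 = state$tau2[[b]]) {
  if (!length(particle_idx)) stop("validation error: empty particle set")
  D <- state$D
  rmax <- D %/% 2L - 2L
  acc <- slice_accumulator(D)
  com <- as.numeric(state$bodies[b, c("com_x", "com_y", "com_z")])
  for (j in seq_along(particle_idx)) {
    i <- particle_idx[j]
    half <- state$meta$half_set[i]
    w <- 1 / state$sigma2[[half]]
    w[!is.finite(w)] <- 0
    S <- subtract_signal(state, i, b)
    ctf <- state$ctfs[, , i]
    cons <- state$meta[i, ]
    post <- if (!is.null(posteriors)) posteriors[[j]] else NULL
    if (is.null(post)) {
      eff <- compose_projection_pose(cons, state$body_poses[[b]][i, ], com)
      insert_slice(acc, S, eff, ctf, w, gamma = 1, rmax = rmax)
    } else {
      gam <- post$gamma / sum(post$gamma)
      for (k in seq_along(gam)) {
        if (gam[k] <= 0) next
        eff <- compose_projection_pose(cons, post$grid[k, ], com)
        insert_slice(acc, S, eff, ctf, w, gamma = gam[k], rmax = rmax)
      }
    }
  }
  reconstruct_from_accumulator(acc, tau2, state$voxel_size)
}

#' Run a full multi-body refinement
#'
#' Drives [initialize_state()] and [run_iteration()] until convergence
#' or `max_iter`, optionally writing per-iteration half-maps, a data
#' STAR file and a text log to an output directory.
#'
#' @inheritParams initialize_state
#' @param out Optional output directory.
#' @param verbose Print per-iteration resolutions and pose changes.
#' @return The final `mb_state`.
#' @export
multibody_refine <- function(consensus_map, particles, bodies, images,
                             masks = NULL, references = NULL, options = list(),
                             out = NULL, verbose = FALSE) {
  state <- initialize_state(consensus_map, particles, bodies, images,
                            masks = masks, references = references,
                            options = options)
  for (it in seq_len(state$options$max_iter)) {
    state <- run_iteration(state)
    if (verbose) {
      cat(sprintf("iter %2d | res (A): %s | pose change (deg): %s | step: %s\n",
                  state$iteration,
                  paste(sprintf("%.2f", state$log[[state$iteration]]$resolution_A),
                        collapse = " "),
                  paste(sprintf("%.2f", state$pose_change), collapse = " "),
                  paste(sprintf("%.2f", state$angular_step), collapse = " ")))
    }
    if (!is.null(out)) write_iteration_outputs(state, out)
    if (state$converged) break
  }
  state
}

write_iteration_outputs <- function(state, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  it <- state$iteration
  for (b in seq_len(state$B)) {
    for (h in 1:2) {
      vol <- mb_volume(ift3c(state$volF[[b]][[h]]), state$voxel_size)
      write_mrc(vol, file.path(out, sprintf("run_it%03d_body%03d_half%d.mrc",
                                            it, b, h)))
    }
  }
  parts <- structure(list(meta = state$meta, body_poses = state$body_poses,
                          pca_amplitudes = NULL), class = "mb_particles")
  write_particles_star(parts, file.path(out, sprintf("run_it%03d_data.star", it)),
                       bodies = state$bodies)
  log_line <- state$log[[it]]
  cat(sprintf("iter %d res_A %s pose_change_deg %s ang_step %s frozen %s\n", it,
              paste(sprintf("%.3f", log_line$resolution_A), collapse = ","),
              paste(sprintf("%.3f", log_line$pose_change_deg), collapse = ","),
              paste(sprintf("%.3f", log_line$angular_step), collapse = ","),
              paste(log_line$frozen, collapse = ",")),
      file = file.path(out, "run_log.txt"), append = TRUE)
  invisible(out)
}

#' Consensus (single-body) reconstruction of the same particles
#'
#' Reconstructs the whole complex from the particle images at their
#' consensus poses only (a delta posterior at the consensus pose), per
#' half-set — the no-motion baseline against which per-body
#' improvements are measured.
#'
#' @param state An `mb_state`.
#' @return List with `half1`, `half2` (`mb_volume`s, box-centred) and
#'   `combined`.
#' @export
reconstruct_consensus_baseline <- function(state) {
  D <- state$D
  rmax <- D %/% 2L - 2L
  accs <- list(slice_accumulator(D), slice_accumulator(D))
  zero <- list(rot = 0, tilt = 0, psi = 0, dx = 0, dy = 0)
  for (i in seq_len(state$N)) {
    half <- state$meta$half_set[i]
    w <- 1 / state$sigma2[[half]]
    w[!is.finite(w)] <- 0
    eff <- compose_projection_pose(state$meta[i, ], zero, c(0, 0, 0))
    insert_slice(accs[[half]], state$X[, , i], eff, state$ctfs[, , i], w,
                 gamma = 1, rmax = rmax)
  }
  tau2 <- pmax(shell_power(state$consensusF), 0)
  halves <- lapply(accs, reconstruct_from_accumulator, tau2 = tau2,
                   voxel_size = state$voxel_size)
  comb <- slice_accumulator(D)
  comb$numre <- accs[[1]]$numre + accs[[2]]$numre
  comb$numim <- accs[[1]]$numim + accs[[2]]$numim
  comb$den <- accs[[1]]$den + accs[[2]]$den
  list(half1 = halves[[1]], half2 = halves[[2]],
       combined = reconstruct_from_accumulator(comb, tau2, state$voxel_size))
}
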