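# A tiny self-consistent refinement instance shared by several tests:
# disjoint binary masks and phantom bodies truncated to their masks, so
# mask x consensus reproduces each body exactly.
fixture_env <- new.env()

fixed_point_setup <- function(N = 12, noiseless = TRUE, seed = 21) {
  key <- paste0("fp_", N, "_", noiseless, "_", seed)
  if (!is.null(fixture_env[[key]])) return(fixture_env[[key]])
  D <- 32L
  phantom <- make_phantom(D, mask_extend = 0, mask_soft_edge = 0,
                          mask_threshold = 0.15)
  # binarize masks and truncate bodies so the model is exactly consistent
  masks <- lapply(phantom$masks, function(m) {
    mb_volume(array(as.numeric(m$data > 0.5), dim(m$data)), m$voxel_size)
  })
  overlap <- Reduce(`+`, lapply(masks, function(m) m$data))
  for (b in seq_along(masks)) {
    m <- masks[[b]]$data
    m[overlap > 1] <- 0                      # enforce disjoint supports
    masks[[b]] <- mb_volume(m, phantom$voxel_size)
  }
  for (b in seq_along(phantom$bodies)) {
    phantom$bodies[[b]] <- mb_volume(phantom$bodies[[b]]$data * masks[[b]]$data,
                                     phantom$voxel_size)
  }
  phantom$map <- mb_volume(Reduce(`+`, lapply(phantom$bodies, `[[`, "data")),
                           phantom$voxel_size)
  phantom$coms <- t(vapply(masks, centre_of_mass, numeric(3)))
  # two-state amplitudes with zero spread put every true pose on the grid
  mm <- motion_model("two_state", axes = list("2" = c(0, 1, 0, 0, 0)),
                     state_offsets = c(-3.6, 1.8), weights = c(0.5, 0.5),
                     spread = 0)
  sim <- simulate_particles(phantom, N, mm,
                            sigma2 = if (noiseless) 0 else NULL,
                            snr = 0.1, shift_range = 0, seed = seed)
  parts <- sim$particles
  parts$body_poses <- sim$truth$body_poses
  st <- initialize_state(phantom$map, parts, tiny_bodies(sigma_angles = c(3, 3, 3)),
                         sim$images, masks = masks,
                         options = list(seed = 1))
  out <- list(state = st, sim = sim, phantom = phantom, masks = masks)
  fixture_env[[key]] <- out
  out
}

test_that("with a single body nothing is subtracted", {
  fx <- fixed_point_setup()
  st <- fx$state
  st$B <- 1L
  st$bodies <- st$bodies[1, ]
  st$body_poses <- st$body_poses[1]
  st$prev_poses <- st$prev_poses[1]
  S <- subtract_signal(st, 3, 1)
  expect_equal(S, st$X[, , 3])
})

test_that("subtraction of self-consistent noiseless data leaves one body's projection", {
  fx <- fixed_point_setup()
  st <- fx$state
  for (i in c(1, 4)) for (b in 1:3) {
    S <- subtract_signal(st, i, b)
    com <- as.numeric(st$bodies[b, c("com_x", "com_y", "com_z")])
    eff <- compose_projection_pose(st$meta[i, ], st$body_poses[[b]][i, ], com)
    fv <- structure(list(F = st$volF[[b]][[st$meta$half_set[i]]], D = st$D,
                         voxel_size = st$voxel_size), class = "mb_fvolume")
    pred <- extract_slice(fv, eff, st$D / 2 - 2) * st$ctfs[, , i]
    expect_lt(sqrt(sum(Mod(S - pred)^2) / sum(Mod(st$X[, , i])^2)), 1e-8)
  }
})

test_that("subtracting another body at a wrong pose leaves more residual power", {
  fx <- fixed_point_setup()
  st <- fx$state
  i <- 2
  good <- subtract_signal(st, i, 1)
  wrong_poses <- st$prev_poses
  wrong_poses[[2]][i, "tilt"] <- wrong_poses[[2]][i, "tilt"] + 7.2
  bad <- subtract_signal(st, i, 1, poses = wrong_poses)
  com <- as.numeric(st$bodies[1, c("com_x", "com_y", "com_z")])
  eff <- compose_projection_pose(st$meta[i, ], st$body_poses[[1]][i, ], com)
  fv <- structure(list(F = st$volF[[1]][[st$meta$half_set[i]]], D = st$D,
                       voxel_size = st$voxel_size), class = "mb_fvolume")
  pred <- extract_slice(fv, eff, st$D / 2 - 2) * st$ctfs[, , i]
  expect_gt(sum(Mod(bad - pred)^2), sum(Mod(good - pred)^2))
})

test_that("image log-likelihood equals a direct pixel sum on a 16x16 instance", {
  D <- 16
  set.seed(22)
  S <- matrix(complex(real = rnorm(D^2), imaginary = rnorm(D^2)), D, D)
  P <- matrix(complex(real = rnorm(D^2), imaginary = rnorm(D^2)), D, D)
  sigma2 <- runif(D / 2 + 1, 0.5, 2)
  rmax <- D / 2 - 2
  ll <- log_likelihood_image(S, P, sigma2, rmax)
  sh <- ns$shell_index_2d(D)
  ref <- 0
  for (ix in 1:D) for (iy in 1:D) {
    s <- sh[ix, iy]
    if (s >= 1 && s <= rmax)
      ref <- ref - 0.5 * Mod(S[ix, iy] - P[ix, iy])^2 / sigma2[s + 1]
  }
  expect_equal(ll, ref, tolerance = 1e-12)
  expect_equal(log_likelihood_image(S, S, sigma2, rmax), 0)
  # doubling sigma2 halves all pairwise differences
  ll2 <- log_likelihood_image(S, P, 2 * sigma2, rmax)
  expect_equal(ll2, ll / 2, tolerance = 1e-12)
  bad <- sigma2; bad[3] <- 0
  expect_error(log_likelihood_image(S, P, bad, rmax), "zero noise")
})

test_that("the compiled pose likelihood matches the reference implementation", {
  fx <- fixed_point_setup()
  st <- fx$state
  i <- 1; b <- 2
  half <- st$meta$half_set[i]
  S <- subtract_signal(st, i, b)
  com <- as.numeric(st$bodies[b, c("com_x", "com_y", "com_z")])
  rmax <- 10L
  w <- 1 / st$sigma2[[half]]
  w[1] <- 0; w[(rmax + 2):length(w)] <- 0
  poses <- expand.grid(rot = c(-1.8, 0, 1.8), tilt = c(-1.8, 0), psi = 0,
                       dx = c(0, 0.5), dy = 0)
  fv <- structure(list(F = st$volF[[b]][[half]], D = st$D,
                       voxel_size = st$voxel_size), class = "mb_fvolume")
  for (j in seq_len(nrow(poses))) {
    eff <- compose_projection_pose(st$meta[i, ], poses[j, ], com)
    proj <- extract_slice(fv, eff, rmax) * st$ctfs[, , i]
    ref <- log_likelihood_image(S, proj, 1 / pmax(w, 1e-300), rmax)
    rotm <- matrix(as.numeric(eff$R), 1, 9)
    got <- ns$cpp_pose_loglik(st$volF[[b]][[half]], st$D, rotm,
                              matrix(eff$shift, 1, 2), as.complex(S),
                              as.numeric(st$ctfs[, , i]), as.numeric(w),
                              rmax)
    expect_equal(as.numeric(got), ref, tolerance = 1e-6)
  }
})

test_that("posteriors normalize exactly and match naive normalization", {
  expect_equal(compute_posterior(0, 0)$gamma, 1)
  two <- compute_posterior(c(1, 1), c(0, 0))
  expect_equal(two$gamma, c(0.5, 0.5))
  set.seed(23)
  for (r in 1:10) {
    ll <- rnorm(200, sd = 5)
    lp <- rnorm(200)
    g <- compute_posterior(ll, lp)$gamma
    expect_equal(sum(g), 1, tolerance = 1e-12)
    naive <- exp(ll + lp) / sum(exp(ll + lp))
    expect_equal(g, naive, tolerance = 1e-9)
  }
  expect_error(compute_posterior(c(-Inf, -Inf), c(0, 0)), "finite")
})

test_that("best_pose takes the argmax with centre-preferring tie-breaks", {
  grid <- build_pose_grid(pose_prior(3, 0), 1.8, 0.25)
  g <- rep(0, nrow(grid)); g[17] <- 1
  expect_equal(as.numeric(best_pose(g, grid)[1, 1:5]),
               as.numeric(grid[17, 1:5]))
  uniform <- rep(1 / nrow(grid), nrow(grid))
  expect_equal(as.numeric(best_pose(uniform, grid)[1, 1:5]), rep(0, 5))
  set.seed(24)
  gr <- runif(nrow(grid))
  expect_equal(as.numeric(best_pose(gr, grid)[1, 1:5]),
               as.numeric(grid[which.max(gr), 1:5]))
})

test_that("posterior-weighted reconstruction recovers a body from noiseless data", {
  fx <- fixed_point_setup(N = 64)
  st <- fx$state
  b <- 2
  # tau -> infinity: no regularization; exact poses as point posteriors
  vol <- reconstruct_body(st, seq_len(st$N), b, tau2 = NULL)
  com <- as.numeric(st$bodies[b, c("com_x", "com_y", "com_z")])
  truth <- ns$ift3c(ns$fourier_shift_volume(
    ns$ft3c(fx$phantom$bodies[[b]]$data), -com))
  # agreement within the phantom's signal band: correlation of the
  # band-limited maps and per-shell FSC against the ground truth
  lp_rec <- ns$lowpass_volume(vol$data, st$voxel_size, 4 * st$voxel_size)
  lp_tru <- ns$lowpass_volume(truth, st$voxel_size, 4 * st$voxel_size)
  expect_gt(cor(as.numeric(lp_rec), as.numeric(lp_tru)), 0.99)
  fsc_truth <- compute_fsc(vol, mb_volume(truth, st$voxel_size))
  expect_gt(min(fsc_truth$fsc[2:13]), 0.95)
  # tau -> 0 annihilates the map
  vol0 <- reconstruct_body(st, seq_len(st$N), b,
                           tau2 = rep(1e-30, st$D / 2 + 1))
  expect_lt(max(abs(vol0$data)), 1e-6 * max(abs(vol$data)))
})

test_that("scaling unnormalized posterior weights leaves the map unchanged", {
  fx <- fixed_point_setup()
  st <- fx$state
  grid <- build_pose_grid(pose_prior(3, 0), 3.6, 0.25)[1:20, ]
  set.seed(25)
  gam <- runif(20)
  posts <- lapply(seq_len(4), function(j) list(grid = grid, gamma = gam))
  v1 <- reconstruct_body(st, 1:4, 1, posteriors = posts)
  posts2 <- lapply(posts, function(p) { p$gamma <- p$gamma / 2; p })
  v2 <- reconstruct_body(st, 1:4, 1, posteriors = posts2)
  expect_equal(v1$data, v2$data, tolerance = 1e-10)
})

test_that("one iteration on self-consistent data is a fixed point and fixed bodies never move", {
  fx <- fixed_point_setup(N = 16)
  st <- fx$state
  st$bodies$sigma_angles[3] <- 0
  st$bodies$sigma_offset[3] <- 0
  st$bodies$fixed[3] <- TRUE
  before <- st$body_poses
  st2 <- run_iteration(st)
  for (b in 1:2) {
    drift <- max(vapply(seq_len(st$N), function(i)
      pose_geodesic(st2$body_poses[[b]][i, ], before[[b]][i, ]), numeric(1)))
    expect_equal(drift, 0)
  }
  expect_identical(st2$body_poses[[3]], before[[3]])
})

test_that("one iteration reduces the total subtracted residual power", {
  fx <- fixed_point_setup(N = 24, noiseless = FALSE, seed = 31)
  st <- fx$state
  # start from identity residuals (the truth carries real motion)
  for (b in 1:3) {
    st$body_poses[[b]][] <- 0
    st$prev_poses[[b]][] <- 0
  }
  resid_power <- function(state, b) {
    tot <- 0
    for (i in seq_len(state$N)) {
      S <- subtract_signal(state, i, b)
      com <- as.numeric(state$bodies[b, c("com_x", "com_y", "com_z")])
      eff <- compose_projection_pose(state$meta[i, ], state$body_poses[[b]][i, ], com)
      fv <- structure(list(F = state$volF[[b]][[state$meta$half_set[i]]],
                           D = state$D, voxel_size = state$voxel_size),
                      class = "mb_fvolume")
      pred <- extract_slice(fv, eff, state$D / 2 - 2) * state$ctfs[, , i]
      tot <- tot + sum(Mod(S - pred)^2)
    }
    tot
  }
  before <- resid_power(st, 2)
  st2 <- run_iteration(st)
  # compare at the same model to isolate the pose update
  st2$volF <- st$volF
  st2$partialF <- st$partialF
  after <- resid_power(st2, 2)
  expect_lt(after, before)
})

test_that("half-sets stay independent within an iteration", {
  fx <- fixed_point_setup(N = 16, noiseless = FALSE, seed = 33)
  st <- fx$state
  idx1 <- which(st$meta$half_set == 1L)
  perm <- sample(idx1)
  st_perm <- st
  st_perm$meta[idx1, ] <- st$meta[perm, ]
  st_perm$X[, , idx1] <- st$X[, , perm]
  st_perm$ctfs[, , idx1] <- st$ctfs[, , perm]
  for (b in 1:3) {
    st_perm$body_poses[[b]][idx1, ] <- st$body_poses[[b]][perm, ]
    st_perm$prev_poses[[b]][idx1, ] <- st$prev_poses[[b]][perm, ]
  }
  a <- run_iteration(st)
  b <- run_iteration(st_perm)
  for (bb in 1:3) {
    h2a <- ns$ift3c(a$volF[[bb]][[2]])
    h2b <- ns$ift3c(b$volF[[bb]][[2]])
    expect_equal(h2a, h2b, tolerance = 1e-8)
  }
})

test_that("noise variance is recovered from residuals of a known simulation", {
  phantom <- tiny_phantom()
  sim <- simulate_particles(phantom, 200, NULL, snr = 0.1, seed = 41)
  st <- initialize_state(phantom$map, sim$particles, tiny_bodies(),
                         sim$images, masks = phantom$masks,
                         options = list(seed = 1))
  truth <- sim$truth$sigma2
  for (h in 1:2) {
    est <- st$sigma2[[h]]
    mid <- 3:12
    expect_true(all(abs(est[mid] / truth[mid] - 1) < 0.2))
  }
})

test_that("convergence and sampling control follow the scripted rules", {
  fx <- fixed_point_setup(N = 16, noiseless = FALSE, seed = 35)
  st <- run_iteration(fx$state)
  # resolution strictly improving: steps unchanged, not converged
  st_imp <- st
  st_imp$res_history <- list(st$res_shell - 3, st$res_shell)
  st_imp$angular_accuracy <- rep(0.1, 3)
  st_imp$pose_change <- rep(10, 3)
  st_imp <- check_convergence_and_sampling(st_imp, old_res = st$res_shell - 3)
  expect_false(st_imp$converged)
  expect_equal(st_imp$angular_step, rep(fx$state$options$angular_step, 3))
  # stalled resolution halves the sampling steps
  st_stall <- st
  st_stall <- check_convergence_and_sampling(st_stall, old_res = st$res_shell)
  expect_equal(st_stall$angular_step, rep(fx$state$options$angular_step / 2, 3))
  # flat resolutions, fine sampling and small changes declare convergence
  st_done <- st
  st_done$angular_step <- rep(st$options$min_angular_step, 3)
  st_done$trans_step <- rep(st$options$min_angular_step / 4, 3)
  st_done$pose_change <- rep(0, 3)
  st_done$pose_change_q90 <- rep(0, 3)
  st_done$res_history <- list(st$res_shell, st$res_shell)
  st_done <- check_convergence_and_sampling(st_done, old_res = st$res_shell)
  expect_true(st_done$converged)
})
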