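make_particles <- function(meta, body_poses) {
  structure(list(meta = meta, body_poses = body_poses, pca_amplitudes = NULL),
            class = "mb_particles")
}

test_that("in-plane shifts lift into the reconstruction frame", {
  meta <- data.frame(rot = 0, tilt = 0, psi = 0, dx = 0, dy = 0)
  poses <- list(data.frame(rot = 1, tilt = 2, psi = 3, dx = 1.5, dy = -0.5))
  f <- poses_to_features(make_particles(meta, poses))
  expect_equal(dim(f), c(1L, 6L))
  expect_equal(as.numeric(f[1, ]), c(1, 2, 3, 1.5, -0.5, 0))
  # zero shift lifts to zero whatever the consensus rotation
  meta2 <- data.frame(rot = 40, tilt = 60, psi = -10, dx = 0, dy = 0)
  poses2 <- list(data.frame(rot = 0, tilt = 0, psi = 0, dx = 0, dy = 0))
  f2 <- poses_to_features(make_particles(meta2, poses2))
  expect_equal(as.numeric(f2[1, 4:6]), c(0, 0, 0))
  # a 90-degree tilt sends the in-plane x shift along the -z axis
  meta3 <- data.frame(rot = 0, tilt = 90, psi = 0, dx = 1, dy = 0)
  poses3 <- list(data.frame(rot = 0, tilt = 0, psi = 0, dx = 1, dy = 0))
  f3 <- poses_to_features(make_particles(meta3, poses3))
  Rc <- euler_to_matrix(0, 90, 0)
  expect_equal(as.numeric(f3[1, 4:6]), as.numeric(t(Rc) %*% c(1, 0, 0)),
               tolerance = 1e-12)
})

test_that("normalization scales reflect map sensitivity to unit moves", {
  D <- 24
  x <- seq_len(D) - 1 - D / 2
  r2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
  sphere <- exp(-r2 / 18)
  blobby <- array(0, c(D, D, D))
  set.seed(51)
  for (j in 1:8) {
    c3 <- runif(3, -6, 6)
    blobby <- blobby + exp(-(outer(outer((x - c3[1])^2, (x - c3[2])^2, "+"),
                                   (x - c3[3])^2, "+")) / 3)
  }
  f <- matrix(rnorm(20 * 12), 20, 12)
  nf <- normalize_features(f, list(sphere, blobby))
  # a spherically symmetric body is insensitive to rotations
  expect_lt(max(nf$scales[1:3]), 1e-3 * max(nf$scales))
  expect_gt(min(nf$scales[7:9]), 1e-3 * max(nf$scales))
  # duplicated bodies give identical scales
  nf2 <- normalize_features(cbind(f, f[, 1:6]),
                            list(blobby, blobby, sphere))
  expect_equal(nf2$scales[1:6], nf2$scales[7:12])
  # brute-force check of one rotational and one translational scale
  R1 <- euler_to_matrix(0, 1, 0)
  vr <- array(ns$cpp_resample_rigid(as.numeric(blobby), D, as.numeric(R1),
                                    c(0, 0, 0), c(0, 0, 0)), c(D, D, D))
  expect_equal(nf$scales[8], sum((blobby - vr)^2), tolerance = 1e-10)
  vs <- array(ns$cpp_resample_rigid(as.numeric(blobby), D, as.numeric(diag(3)),
                                    c(0, 0, 0), c(0, 0, 1)), c(D, D, D))
  expect_equal(nf$scales[12], sum((blobby - vs)^2), tolerance = 1e-10)
  # multiply mode scales the columns by the map-change weight
  expect_equal(nf$features[, 8], f[, 8] * nf$scales[8])
})

test_that("PCA recovers dominant directions and partitions variance", {
  set.seed(52)
  X <- matrix(0, 200, 12)
  X[, 5] <- rnorm(200, sd = 3)
  pca <- pca_fit(X)
  expect_equal(abs(pca$eigenvectors[5, 1]), 1, tolerance = 1e-9)
  expect_equal(pca$explained[1], 1, tolerance = 1e-12)
  expect_equal(sum(pca$explained), 1, tolerance = 1e-12)
  # isotropic features have a flat spectrum within sampling error
  Y <- matrix(rnorm(10000 * 6), 10000, 6)
  pca2 <- pca_fit(Y)
  expect_lt(pca2$eigenvalues[1] / pca2$eigenvalues[6], 1.15)
  expect_equal(sum(pca2$explained), 1, tolerance = 1e-12)
  # amplitudes are projections of the centred features
  expect_equal(pca2$amplitudes,
               sweep(Y, 2, colMeans(Y)) %*% pca2$eigenvectors,
               tolerance = 1e-10)
})

test_that("eigen map series uses equi-populated bins and honours M", {
  phantom <- tiny_phantom()
  set.seed(53)
  N <- 100
  meta <- data.frame(rot = runif(N, -180, 180), tilt = runif(N, 0, 180),
                     psi = runif(N, -180, 180), dx = 0, dy = 0)
  amp <- runif(N, -6, 6)
  poses <- list(ns$empty_pose_table(N),
                data.frame(rot = 0, tilt = amp, psi = 0, dx = 0, dy = 0),
                ns$empty_pose_table(N))
  parts <- make_particles(meta, poses)
  feats <- poses_to_features(parts)
  vols_centred <- lapply(1:3, function(b) {
    com <- phantom$coms[b, ]
    ns$ift3c(ns$fourier_shift_volume(ns$ft3c(phantom$bodies[[b]]$data), -com))
  })
  nf <- normalize_features(feats, vols_centred)
  pca <- pca_fit(nf$features, nf$scales, nf$mode)
  series <- eigen_map_series(pca, 1, lapply(phantom$bodies, `[[`, "data"),
                             phantom$coms, M = 10, voxel_size = 3)
  expect_equal(length(series$maps), 10L)
  expect_equal(series$counts, rep(10L, 10))
  expect_true(all(diff(series$bin_amplitudes) > 0) ||
                all(diff(series$bin_amplitudes) < 0))
  expect_error(eigen_map_series(pca, 1, lapply(phantom$bodies, `[[`, "data"),
                                phantom$coms, M = 101), "more bins")
  # amplitude round trip: un-normalize a bin centre, re-featurize, project
  a <- series$bin_amplitudes[3]
  fvec <- pca$mean + a * pca$eigenvectors[, 1]
  a_back <- sum((fvec - pca$mean) * pca$eigenvectors[, 1])
  expect_equal(a_back, a, tolerance = 1e-8)
})

test_that("all-zero amplitudes reproduce the unmoved combined map", {
  phantom <- tiny_phantom()
  N <- 20
  meta <- data.frame(rot = 0, tilt = 0, psi = 0, dx = 0, dy = 0)[rep(1, N), ]
  poses <- replicate(3, ns$empty_pose_table(N), simplify = FALSE)
  parts <- make_particles(meta, poses)
  feats <- poses_to_features(parts)
  nf <- normalize_features(feats, lapply(phantom$bodies, `[[`, "data"))
  pca <- pca_fit(nf$features, nf$scales, nf$mode)
  series <- eigen_map_series(pca, 1, lapply(phantom$bodies, `[[`, "data"),
                             phantom$coms, M = 4, voxel_size = 3)
  for (m in 2:4)
    expect_equal(series$maps[[m]]$data, series$maps[[1]]$data, tolerance = 1e-9)
  interior <- phantom$map$data[4:29, 4:29, 4:29]
  expect_equal(series$maps[[1]]$data[4:29, 4:29, 4:29], interior,
               tolerance = 0.05 * max(abs(interior)))
})

test_that("amplitude subsets partition the data and serialize", {
  set.seed(54)
  N <- 60
  meta <- data.frame(image_index = 1:N, stack_path = "s.mrcs",
                     rot = 0, tilt = 0, psi = 0, dx = 0, dy = 0,
                     defocus_u = 15000, defocus_v = 15000, astig_angle = 0,
                     voltage = 300, cs = 2.7, amplitude_contrast = 0.1,
                     half_set = rep(1:2, length.out = N))
  poses <- list(data.frame(rot = 0, tilt = rnorm(N), psi = 0, dx = 0, dy = 0))
  parts <- make_particles(meta, poses)
  pca <- pca_fit(poses_to_features(parts))
  all_idx <- select_subset(parts, pca, 1)
  expect_equal(sort(all_idx), 1:N)
  lo <- select_subset(parts, pca, 1, amax = 0)
  hi <- select_subset(parts, pca, 1, amin = 0)
  expect_equal(sort(c(lo, hi)), 1:N)
  p <- withr::local_tempfile(fileext = ".star")
  select_subset(parts, pca, 1, amin = 0, path = p)
  back <- read_particles_star(p)
  expect_equal(nrow(back$meta), length(hi))
  expect_warning(select_subset(parts, pca, 1, amin = 1e9), "empty")
})

test_that("subtracted particle export centres the kept body", {
  skip_if_not_installed("withr")
  # noiseless self-consistent instance: output should equal the kept
  # body's CTF-modulated projection, re-centred
  D <- 32
  phantom <- make_phantom(D, mask_extend = 0, mask_soft_edge = 0,
                          mask_threshold = 0.15)
  masks <- lapply(phantom$masks, function(m)
    mb_volume(array(as.numeric(m$data > 0.5), dim(m$data)), m$voxel_size))
  overlap <- Reduce(`+`, lapply(masks, function(m) m$data))
  for (b in 1:3) {
    m <- masks[[b]]$data; m[overlap > 1] <- 0
    masks[[b]] <- mb_volume(m, phantom$voxel_size)
    phantom$bodies[[b]] <- mb_volume(phantom$bodies[[b]]$data * m,
                                     phantom$voxel_size)
  }
  phantom$map <- mb_volume(Reduce(`+`, lapply(phantom$bodies, `[[`, "data")),
                           phantom$voxel_size)
  phantom$coms <- t(vapply(masks, centre_of_mass, numeric(3)))
  sim <- simulate_particles(phantom, 6, NULL, sigma2 = 0, seed = 55)
  st <- initialize_state(phantom$map, sim$particles, tiny_bodies(),
                         sim$images, masks = masks, options = list(seed = 1))
  stack <- withr::local_tempfile(fileext = ".mrcs")
  star <- withr::local_tempfile(fileext = ".star")
  out <- write_subtracted_particles(st, 2, stack, star)
  imgs <- read_mrcs(stack)
  expect_equal(dim(imgs$data), c(D, D, 6L))
  com <- phantom$coms[2, ]
  for (i in c(1, 4)) {
    eff <- compose_projection_pose(st$meta[i, ],
                                   list(rot = 0, tilt = 0, psi = 0, dx = 0, dy = 0),
                                   com)
    # the recorded shift is the projected COM displacement plus offsets
    expect_equal(out$shifts[i, ], eff$shift, tolerance = 1e-10)
    fv <- structure(list(F = st$volF[[2]][[st$meta$half_set[i]]], D = D,
                         voxel_size = 3), class = "mb_fvolume")
    pred <- ns$ift2c(extract_slice(fv, list(R = eff$R, shift = c(0, 0)),
                                   D / 2 - 2) * st$ctfs[, , i])
    expect_lt(sqrt(sum((imgs$data[, , i] - pred)^2) / sum(pred^2)), 0.02)
  }
  back <- read_particles_star(star)
  expect_true(all(back$meta$dx == 0))
  expect_equal(length(back$body_poses), 0L)
})

test_that("bimodal amplitude histograms expose a valley", {
  set.seed(56)
  amps <- c(rnorm(100, -6, 1), rnorm(900, 2, 1))
  v <- amplitude_valley(amps)
  expect_true(v$threshold > -6 && v$threshold < 2)
  expect_gt(v$depth, 0.2)
  flat <- amplitude_valley(rnorm(500))
  expect_true(is.na(flat$threshold) || flat$depth < 0.5)
})
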