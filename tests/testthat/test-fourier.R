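test_that("CTF evaluation matches the phase-contrast model", {
  D <- 32; voxel <- 1.5
  p <- list(defocus_u = 15000, defocus_v = 15000, astig_angle = 0,
            voltage = 300, cs = 2.7, amplitude_contrast = 0.1)
  ctf <- evaluate_ctf(p, D, voxel)
  expect_equal(ctf[D / 2 + 1, D / 2 + 1], -0.1)          # zero frequency: -A
  p1 <- p; p1$amplitude_contrast <- 1
  ctf1 <- evaluate_ctf(p1, D, voxel)
  expect_equal(ctf1[D / 2 + 1, D / 2 + 1], -1)           # A = 1: pure cosine
  # hand evaluation of chi at three frequencies along the x axis
  lambda <- 12.2643247 / sqrt(300000 * (1 + 300000 * 0.978466e-6))
  for (kpx in c(3, 7, 12)) {
    k <- kpx / (D * voxel)
    chi <- pi * lambda * 15000 * k^2 - pi / 2 * 2.7e7 * lambda^3 * k^4
    expect_equal(ctf[D / 2 + 1 + kpx, D / 2 + 1],
                 -(sqrt(1 - 0.01) * sin(chi) + 0.1 * cos(chi)),
                 tolerance = 1e-10)
  }
  # astigmatism: defocus varies with the azimuth
  p2 <- p; p2$defocus_u <- 18000; p2$defocus_v <- 12000
  ctf2 <- evaluate_ctf(p2, D, voxel)
  expect_false(isTRUE(all.equal(ctf2[D / 2 + 1 + 8, D / 2 + 1],
                                ctf2[D / 2 + 1, D / 2 + 1 + 8])))
})

test_that("slice extraction reproduces closed-form Gaussian transforms", {
  D <- 32; s <- 2
  x <- seq_len(D) - 1 - D / 2
  g <- exp(-outer(outer(x^2, x^2, "+"), x^2, "+") / (2 * s^2))
  fv <- fourier_volume(mb_volume(g, 1))
  k <- ns$freq_index(D)
  k2 <- outer(k^2, k^2, "+") / D^2
  pred <- (sqrt(2 * pi) * s)^3 * exp(-2 * pi^2 * s^2 * k2)
  sh <- ns$shell_index_2d(D)
  msk <- sh <= D / 2 - 2
  set.seed(5)
  for (t in 1:10) {
    R <- random_rotation()
    sl <- extract_slice(fv, list(R = R, shift = c(0, 0)))
    expect_lt(max(abs(Re(sl[msk]) - pred[msk])) / max(pred), 0.05)
    expect_lt(max(abs(Im(sl[msk]))) / max(pred), 0.05)
  }
  # identity pose: exactly the central section
  sl0 <- extract_slice(fv, list(rot = 0, tilt = 0, psi = 0, dx = 0, dy = 0))
  expect_equal(Re(sl0[msk]), pred[msk], tolerance = 2e-4)
})

test_that("a centred delta has flat slices for every pose", {
  D <- 32
  v <- array(0, c(D, D, D)); v[D / 2 + 1, D / 2 + 1, D / 2 + 1] <- 1
  fv <- fourier_volume(mb_volume(v, 1))
  sh <- ns$shell_index_2d(D)
  msk <- sh <= D / 2 - 2
  set.seed(6)
  for (t in 1:5) {
    sl <- extract_slice(fv, list(R = random_rotation(), shift = c(0, 0)))
    expect_lt(max(Mod(sl[msk] - 1)), 1e-8)
  }
})

test_that("insertion is the adjoint of extraction", {
  D <- 32
  set.seed(7)
  fv <- fourier_volume(mb_volume(array(rnorm(D^3), c(D, D, D)), 1))
  for (t in 1:4) {
    R <- random_rotation()
    shift <- runif(2, -2, 2)
    I <- matrix(complex(real = rnorm(D^2), imaginary = rnorm(D^2)), D, D)
    sl <- extract_slice(fv, list(R = R, shift = shift))
    lhs <- sum(Re(sl * Conj(I)))
    acc <- slice_accumulator(D)
    insert_slice(acc, I, list(R = R, shift = shift))
    rhs <- sum(Re(fv$F * Conj(acc$numre + 1i * acc$numim)))
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("insertion is linear and ignores zero weights", {
  D <- 16
  img <- matrix(complex(real = rnorm(D^2), imaginary = rnorm(D^2)), D, D)
  pose <- list(R = random_rotation(), shift = c(0.5, -0.25))
  a1 <- slice_accumulator(D)
  insert_slice(a1, img, pose, gamma = 0)
  expect_true(all(a1$numre == 0) && all(a1$den == 0))
  insert_slice(a1, img, pose, gamma = 1)
  a2 <- slice_accumulator(D)
  insert_slice(a2, img, pose, gamma = 1)
  insert_slice(a2, img, pose, gamma = 1)
  expect_equal(a2$numre, 2 * a1$numre)
  expect_equal(a2$numim, 2 * a1$numim)
  expect_equal(a2$den, 2 * a1$den)
})

test_that("Fourier phase shifts equal circular shifts for integer offsets", {
  D <- 32
  set.seed(8)
  img <- matrix(rnorm(D^2), D, D)
  Fi <- ns$ft2c(img)
  k <- ns$freq_index(D)
  ph <- outer(exp(-2i * pi * k * 3 / D), exp(-2i * pi * k * (-2) / D))
  shifted <- ns$ift2c(Fi * ph)
  expect_equal(shifted, img[c((D - 2):D, 1:(D - 3)), c(3:D, 1:2)],
               tolerance = 1e-12)
})

test_that("FSC behaves on identical, negated and independent maps", {
  D <- 32
  set.seed(9)
  v <- array(rnorm(D^3), c(D, D, D))
  f_self <- compute_fsc(mb_volume(v), mb_volume(v))
  expect_true(all(abs(f_self$fsc[f_self$n > 0] - 1) < 1e-10))
  f_neg <- compute_fsc(mb_volume(v), mb_volume(-v))
  expect_true(all(abs(f_neg$fsc[f_neg$n > 0] + 1) < 1e-10))
  w1 <- array(rnorm(D^3), c(D, D, D))
  w2 <- array(rnorm(D^3), c(D, D, D))
  f_noise <- compute_fsc(mb_volume(w1), mb_volume(w2))
  ok <- f_noise$n > 0 & f_noise$shell > 0
  expect_true(all(abs(f_noise$fsc[ok]) <= 3 / sqrt(f_noise$n[ok])))
  expect_error(compute_fsc(mb_volume(v), array(0, c(16, 16, 16))), "mismatch")
})

test_that("solvent-corrected FSC removes mask-induced correlation", {
  D <- 32
  set.seed(10)
  # common band-limited signal plus independent noise: beyond the
  # signal band the true half-map correlation is zero, but a sharp
  # tight mask convolves the in-band correlation outward
  x <- seq_len(D) - 1 - D / 2
  blob <- 40 * exp(-outer(outer(x^2, x^2, "+"), x^2, "+") / 18)
  sig <- ns$lowpass_volume(blob * array(1 + 0.5 * rnorm(D^3), c(D, D, D)),
                           1, D / 6)     # band ends near shell 6
  n1 <- sig + array(rnorm(D^3), c(D, D, D))
  n2 <- sig + array(rnorm(D^3), c(D, D, D))
  tight <- array(0, c(D, D, D))
  tight[13:21, 13:21, 13:21] <- 1
  plain <- compute_fsc(mb_volume(n1), mb_volume(n2))
  masked <- compute_fsc(mb_volume(n1 * tight), mb_volume(n2 * tight))
  corrected <- solvent_correct_fsc(mb_volume(n1), mb_volume(n2), tight,
                                   randomize_from_shell = 8)
  beyond <- 11:15
  # the unmasked oracle is near zero beyond the band, the masked FSC is
  # inflated there, and the correction removes most of the inflation
  expect_lt(mean(plain$fsc[beyond + 1]), 0.1)
  expect_gt(mean(masked$fsc[beyond + 1]), 0.2)
  expect_lt(mean(corrected$fsc[beyond + 1]),
            0.5 * mean(corrected$fsc_masked[beyond + 1]))
  # identical half-maps stay at 1 under any mask
  same <- solvent_correct_fsc(mb_volume(n1), mb_volume(n1), tight, 4)
  expect_true(all(abs(same$fsc[same$n > 0] - 1) < 1e-6))
  # an all-ones mask reproduces the plain FSC below the randomization shell
  ones <- solvent_correct_fsc(mb_volume(n1), mb_volume(n2),
                              array(1, c(D, D, D)), randomize_from_shell = 10)
  expect_equal(ones$fsc[1:10], plain$fsc[1:10], tolerance = 1e-10)
})

test_that("tau2 follows FSC/(1-FSC) times the reconstruction power", {
  power <- c(0, 10, 20, 30, 40)
  expect_equal(estimate_tau2(c(1, 0, 0.5, -0.2, 0.9), power)[2], 0)
  expect_equal(estimate_tau2(c(1, 0, 0.5, -0.2, 0.9), power)[3], 20)
  expect_equal(estimate_tau2(c(1, 0, 0.5, -0.2, 0.9), power)[4], 0)
  expect_equal(estimate_tau2(c(1, 0, 0.5, -0.2, 0.9), power)[5],
               0.9 / 0.1 * 40)
  # the cap keeps perfect shells finite
  expect_true(is.finite(estimate_tau2(1, 100, fsc_cap = 0.999)))
})

test_that("resolution crossing interpolates between shells", {
  fsc <- data.frame(shell = 0:16, n = c(1, rep(10, 16)),
                    freq = (0:16) / 32, fsc = rep(1, 17))
  res <- resolution_at_threshold(fsc, 0.143, D = 32, voxel_size = 2)
  expect_true(attr(res, "flagged"))
  expect_equal(as.numeric(res), 32 * 2 / 16)
  # a linear drop from 1 at shell 8 to 0 at shell 9 crosses 0.5 halfway
  fsc$fsc <- c(rep(1, 9), rep(0, 8))
  res2 <- resolution_at_threshold(fsc, 0.5, D = 32, voxel_size = 2)
  expect_equal(attr(res2, "shell"), 8.5, tolerance = 1e-10)
  expect_equal(as.numeric(res2), 64 / 8.5, tolerance = 1e-10)
  # hand interpolation on a synthetic curve
  fsc$fsc <- exp(-(0:16) / 4)
  k <- min(which(fsc$fsc < 0.143)) - 1L
  frac <- (fsc$fsc[k] - 0.143) / (fsc$fsc[k] - fsc$fsc[k + 1])
  res3 <- resolution_at_threshold(fsc, 0.143, D = 32, voxel_size = 2)
  expect_equal(attr(res3, "shell"), k - 1 + frac, tolerance = 1e-10)
})

test_that("operations on transforms of real inputs stay Hermitian", {
  D <- 16
  set.seed(11)
  fv <- fourier_volume(mb_volume(array(rnorm(D^3), c(D, D, D)), 1))
  sl <- extract_slice(fv, list(R = random_rotation(), shift = c(1.2, -0.4)))
  rev_idx <- c(1L, seq(D, 2L))
  herm_err <- Mod(sl - Conj(sl[rev_idx, rev_idx]))
  sh <- ns$shell_index_2d(D)
  expect_lt(max(herm_err[sh <= D / 2 - 2 & sh >= 1]), 1e-9)
  # real image after inverse transform of an extracted slice
  img <- ns$ift2c(sl)
  expect_true(is.numeric(img))
})
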