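# Fourier-space machinery: CTF evaluation, central-slice extraction and
# insertion, FSC computation with solvent correction, and signal-power
# (tau^2) estimation.

#' Fourier transform of a real volume
#'
#' Centred-grid 3D transform (zero frequency at 1-based index D/2 + 1)
#' with phases taken about the box centre, optionally zero-padded by an
#' integer factor before transforming.
#'
#' @param volume An `mb_volume` or cubic 3D array.
#' @param pad Integer padding factor (default 1: no padding).
#' @return Object of class `mb_fvolume`: list with complex array `F`,
#'   box size `D`, `voxel_size` and `pad`.
#' @export
fourier_volume <- function(volume, pad = 1L) {
  vol <- as_mb_volume(volume)
  v <- vol$data
  D0 <- dim(v)[1]
  if (pad > 1L) {
    D <- D0 * pad
    big <- array(0, c(D, D, D))
    off <- (D - D0) %/% 2L
    big[off + seq_len(D0), off + seq_len(D0), off + seq_len(D0)] <- v
    v <- big
  }
  structure(list(F = ft3c(v), D = dim(v)[1], voxel_size = vol$voxel_size,
                 pad = pad, D0 = D0),
            class = "mb_fvolume")
}

as_pose <- function(pose) {
  if (!is.null(pose$R)) return(pose)
  list(R = euler_to_matrix(pose$rot %||% 0, pose$tilt %||% 0, pose$psi %||% 0),
       shift = c(pose$dx %||% 0, pose$dy %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a central slice from a Fourier volume
#'
#' Interpolates the central section perpendicular to the pose's
#' projection direction (trilinear interpolation) and applies the phase
#' shift of the pose's in-plane translation; by the projection-slice
#' theorem this is the transform of the posed projection.
#'
#' @param fvolume An `mb_fvolume`.
#' @param pose Either a list with rot/tilt/psi/dx/dy or a composed pose
#'   with `R` and `shift` (see [compose_projection_pose()]).
#' @param rmax Maximum frequency shell; default D/2 - 2.
#' @return Complex D x D matrix (zero outside the `rmax` disc).
#' @export
extract_slice <- function(fvolume, pose, rmax = NULL) {
  Dvol <- fvolume$D
  pad <- fvolume$pad %||% 1L
  Dout <- fvolume$D0 %||% Dvol
  if (is.null(rmax)) rmax <- Dout %/% 2L - 2L
  rmax <- min(rmax, floor((Dvol %/% 2L - 2L) / pad), Dout %/% 2L - 2L)
  p <- as_pose(pose)
  cpp_extract_slice(fvolume$F, Dvol, as.numeric(p$R), p$shift[1], p$shift[2],
                    as.integer(rmax), as.integer(Dout), as.numeric(pad))
}

#' Create a slice-insertion accumulator
#'
#' Holds the running numerator (complex, split into real and imaginary
#' parts) and denominator of a direct Fourier reconstruction.
#'
#' @param D Box size.
#' @return An environment of class `mb_accumulator` with fields
#'   `numre`, `numim`, `den` (D^3 arrays) and `D`.
#' @export
slice_accumulator <- function(D) {
  acc <- new.env(parent = emptyenv())
  acc$numre <- array(0, c(D, D, D))
  acc$numim <- array(0, c(D, D, D))
  acc$den <- array(0, c(D, D, D))
  acc$D <- as.integer(D)
  class(acc) <- "mb_accumulator"
  acc
}

#' Insert a weighted image slice into an accumulator
#'
#' Adjoint of [extract_slice()]: spreads `gamma * w * CTF * image`
#' (numerator) and `gamma * w * CTF^2` (denominator) trilinearly onto
#' the 3D grid at the pose's slice position, after removing the pose's
#' phase shift. `w` is the per-shell weight (typically `1/sigma^2`).
#'
#' @param acc An `mb_accumulator` (modified in place).
#' @param image Complex D x D matrix (Fourier transform of the image).
#' @param pose Pose as in [extract_slice()].
#' @param ctf Real D x D CTF matrix (use `matrix(1, D, D)` for none).
#' @param wshell Per-shell weights, length D/2 + 1.
#' @param gamma Posterior weight of this pose.
#' @param rmax Maximum frequency shell; default D/2 - 2.
#' @return `acc`, invisibly.
#' @export
insert_slice <- function(acc, image, pose, ctf = NULL, wshell = NULL,
                         gamma = 1, rmax = NULL) {
  D <- acc$D
  if (!all(dim(image) == c(D, D))) stop("validation error: image/accumulator shape mismatch")
  if (is.null(ctf)) ctf <- matrix(1, D, D)
  if (!all(dim(ctf) == c(D, D))) stop("validation error: ctf shape mismatch")
  if (is.null(wshell)) wshell <- rep(1, D %/% 2L + 1L)
  if (is.null(rmax)) rmax <- D %/% 2L - 2L
  rmax <- min(rmax, D %/% 2L - 2L)
  p <- as_pose(pose)
  cpp_insert_slice(acc$numre, acc$numim, acc$den, D, as.numeric(p$R),
                   p$shift[1], p$shift[2], as.complex(image), as.numeric(ctf),
                   as.numeric(wshell), gamma, as.integer(rmax))
  invisible(acc)
}

#' Finish a reconstruction from an accumulator
#'
#' Per-voxel Wiener-style division `num / (den + 1/tau2(shell))` and
#' inverse transform to real space.
#'
#' @param acc An `mb_accumulator`.
#' @param tau2 Per-shell signal power (length D/2 + 1) or `NULL` for an
#'   unregularized division (`den` floored at a small epsilon).
#' @param voxel_size Angstrom per pixel of the output volume.
#' @return An `mb_volume`.
#' @export
reconstruct_from_accumulator <- function(acc, tau2 = NULL, voxel_size = 1) {
  D <- acc$D
  num <- acc$numre + 1i * acc$numim
  den <- acc$den
  if (is.null(tau2)) {
    den <- pmax(den, 1e-12 * max(den, 1e-300))
  } else {
    inv_tau2 <- ifelse(tau2 > 0, 1 / tau2, Inf)
    shells <- shell_index_3d(D)
    vals <- c(inv_tau2, rep(Inf, max(0, max(shells) + 1L - length(inv_tau2))))
    den <- den + array(vals[shells + 1L], dim(den))
  }
  F <- ifelse(is.finite(den) & den > 0, num / den, 0 + 0i)
  dim(F) <- c(D, D, D)
  mb_volume(ift3c(F), voxel_size)
}

#' Evaluate a contrast transfer function
#'
#' Standard phase-contrast CTF
#' `-(sqrt(1 - A^2) sin(chi) + A cos(chi))` with astigmatic defocus in
#' the phase function `chi` and an optional Gaussian B-factor envelope.
#'
#' @param ctf_params List with `defocus_u`, `defocus_v` (angstrom,
#'   positive underfocus), `astig_angle` (degrees), `voltage` (kV),
#'   `cs` (mm), `amplitude_contrast` (fraction), optional `bfactor`
#'   (angstrom^2).
#' @param D Box size in pixels.
#' @param voxel_size Angstrom per pixel.
#' @return Real D x D matrix over the centred frequency grid.
#' @export
evaluate_ctf <- function(ctf_params, D, voxel_size) {
  p <- ctf_params
  A <- p$amplitude_contrast %||% 0.1
  if (A < 0 || A > 1) stop("validation error: amplitude contrast must be in [0, 1]")
  V <- (p$voltage %||% 300) * 1000
  lambda <- 12.2643247 / sqrt(V * (1 + V * 0.978466e-6))
  cs <- (p$cs %||% 2.7) * 1e7
  kk <- freq_index(D) / (D * voxel_size)
  kx <- matrix(kk, D, D)
  ky <- matrix(kk, D, D, byrow = TRUE)
  k2 <- kx^2 + ky^2
  theta <- atan2(ky, kx)
  defocus <- (p$defocus_u + p$defocus_v) / 2 +
    (p$defocus_u - p$defocus_v) / 2 * cos(2 * (theta - deg2rad(p$astig_angle %||% 0)))
  chi <- pi * lambda * defocus * k2 - pi / 2 * cs * lambda^3 * k2^2
  ctf <- -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))
  if (!is.null(p$bfactor) && p$bfactor != 0) ctf <- ctf * exp(-p$bfactor * k2 / 4)
  ctf
}

#' Fourier shell correlation between two volumes
#'
#' @param half1,half2 `mb_volume`s or 3D arrays of the same shape.
#' @return Data.frame with `shell`, `n` (Fourier voxels per shell),
#'   `freq` (1/angstrom) and `fsc`, for shells 0..D/2.
#' @export
compute_fsc <- function(half1, half2) {
  v1 <- as_mb_volume(half1)
  v2 <- as_mb_volume(half2)
  if (!all(dim(v1$data) == dim(v2$data)))
    stop("validation error: half-map shape mismatch")
  D <- dim(v1$data)[1]
  F1 <- ft3c(v1$data)
  F2 <- ft3c(v2$data)
  shells <- shell_index_3d(D)
  nmax <- D %/% 2L
  keep <- shells <= nmax
  sh <- shells[keep]
  num <- rowsum(Re(F1[keep] * Conj(F2[keep])), sh)
  d1 <- rowsum(Mod(F1[keep])^2, sh)
  d2 <- rowsum(Mod(F2[keep])^2, sh)
  n <- rowsum(rep(1, length(sh)), sh)
  fsc <- rep(NA_real_, nmax + 1L)
  cnt <- rep(0, nmax + 1L)
  idx <- as.integer(rownames(num)) + 1L
  denom <- sqrt(d1 * d2)
  fsc[idx] <- ifelse(denom > 0, num / denom, NA_real_)
  cnt[idx] <- n
  data.frame(shell = 0:nmax, n = cnt,
             freq = (0:nmax) / (D * v1$voxel_size), fsc = fsc)
}

# Hermitian-symmetric phase randomization of a Fourier volume beyond a shell
randomize_phases <- function(F, from_shell) {
  D <- dim(F)[1]
  theta <- array(runif(length(F), -pi, pi), dim(F))
  rev_idx <- c(1L, seq(D, 2L))   # k -> -k (the k = -D/2 plane maps to itself)
  k <- freq_index(D)
  kx <- array(k, c(D, D, D))
  ky <- array(rep(k, each = D), c(D, D, D))
  kz <- array(rep(k, each = D * D), c(D, D, D))
  upper <- (kz > 0) | (kz == 0 & ky > 0) | (kz == 0 & ky == 0 & kx > 0)
  th_rev <- theta[rev_idx, rev_idx, rev_idx]
  theta[!upper] <- -th_rev[!upper]            # antisymmetric: theta(-k) = -theta(k)
  theta[kx == 0 & ky == 0 & kz == 0] <- 0
  theta[kx == -D / 2 | ky == -D / 2 | kz == -D / 2] <- 0   # self-conjugate planes
  shells <- shell_index_3d(D)
  theta[shells < from_shell] <- 0
  F * exp(1i * theta)
}

#' Mask-corrected (solvent-corrected) FSC
#'
#' FSC of the masked half-maps, corrected for the correlation inflation
#' introduced by the mask via phase randomization: beyond the
#' randomization shell the corrected value is
#' `(FSC_masked - FSC_rand) / (1 - FSC_rand)` where `FSC_rand` is the
#' masked FSC of the phase-randomized half-maps; below it the masked
#' FSC is reported unchanged.
#'
#' @param half1,half2 Unmasked half-maps (`mb_volume`s or arrays).
#' @param mask A soft mask on the same grid.
#' @param randomize_from_shell Shell index where phase randomization
#'   starts; default: first shell where the unmasked FSC drops below
#'   0.8.
#' @param seed Seed for the random phases (local RNG use).
#' @return Data.frame as [compute_fsc()], plus column `fsc_masked`.
#' @export
solvent_correct_fsc <- function(half1, half2, mask, randomize_from_shell = NULL,
                                seed = 123L) {
  v1 <- as_mb_volume(half1); v2 <- as_mb_volume(half2)
  m <- as_mb_volume(mask)$data
  if (!all(dim(v1$data) == dim(m)))
    stop("validation error: mask/map shape mismatch")
  if (sum(abs(v1$data * m)) == 0 || sum(abs(v2$data * m)) == 0)
    stop("validation error: masked half-map is all zero")
  D <- dim(m)[1]
  fsc_masked <- compute_fsc(mb_volume(v1$data * m, v1$voxel_size),
                            mb_volume(v2$data * m, v2$voxel_size))
  if (is.null(randomize_from_shell)) {
    fsc_plain <- compute_fsc(v1, v2)
    below <- which(!is.na(fsc_plain$fsc) & fsc_plain$fsc < 0.8 & fsc_plain$shell > 0)
    randomize_from_shell <- if (length(below)) min(below) - 1L else D %/% 2L
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # average the randomized reference over a few draws to damp its own
  # sampling noise in the sparsely populated shells
  F1 <- ft3c(v1$data); F2 <- ft3c(v2$data)
  rand_curves <- lapply(1:3, function(r) {
    r1 <- ift3c(randomize_phases(F1, randomize_from_shell)) * m
    r2 <- ift3c(randomize_phases(F2, randomize_from_shell)) * m
    compute_fsc(mb_volume(r1, v1$voxel_size), mb_volume(r2, v2$voxel_size))$fsc
  })
  fsc_rand <- fsc_masked
  fsc_rand$fsc <- rowMeans(do.call(cbind, rand_curves), na.rm = TRUE)
  out <- fsc_masked
  out$fsc_masked <- fsc_masked$fsc
  corr <- out$fsc
  sel <- out$shell >= randomize_from_shell + 1L & !is.na(out$fsc) & !is.na(fsc_rand$fsc)
  fr <- fsc_rand$fsc[sel]
  fr <- pmin(fr, 0.999)
  corr[sel] <- (out$fsc[sel] - fr) / (1 - fr)
  out$fsc <- corr
  attr(out, "randomize_from_shell") <- randomize_from_shell
  out
}

#' Estimate per-shell signal power from an FSC curve
#'
#' `tau2 = FSC / (1 - FSC) * reconstruction_power`, with the FSC
#' clipped to `[0, fsc_cap]`; shells with FSC <= 0 get zero power.
#'
#' @param fsc_corrected Per-shell FSC values (vector, or data.frame
#'   with an `fsc` column).
#' @param reconstruction_power Per-shell power of the current combined
#'   reconstruction (same length).
#' @param fsc_cap Upper clip for the FSC before the ratio.
#' @return Numeric vector of per-shell tau^2 values.
#' @export
estimate_tau2 <- function(fsc_corrected, reconstruction_power, fsc_cap = 0.999) {
  fsc <- if (is.data.frame(fsc_corrected)) fsc_corrected$fsc else fsc_corrected
  fsc[is.na(fsc)] <- 0
  fsc <- pmax(0, pmin(fsc, fsc_cap))
  tau2 <- fsc / (1 - fsc) * reconstruction_power
  tau2[!is.finite(tau2) | tau2 < 0] <- 0
  tau2
}

#' Resolution at an FSC threshold
#'
#' Reciprocal spatial frequency of the first crossing below the
#' threshold, with linear interpolation between shells. When the curve
#' never drops below the threshold the Nyquist resolution is returned
#' with attribute `flagged = TRUE`.
#'
#' @param fsc Data.frame from [compute_fsc()] (needs `shell` and `fsc`),
#'   or a numeric per-shell vector.
#' @param threshold FSC threshold (default 0.143, the gold-standard
#'   half-set convention).
#' @param D Box size (only needed when `fsc` is a plain vector).
#' @param voxel_size Angstrom per pixel (idem).
#' @return Resolution in angstrom, with attributes `shell` (fractional
#'   crossing shell) and `flagged`.
#' @export
resolution_at_threshold <- function(fsc, threshold = 0.143, D = NULL,
                                    voxel_size = NULL) {
  if (is.data.frame(fsc)) {
    vals <- fsc$fsc
    if (is.null(D)) D <- 2L * max(fsc$shell)
    if (is.null(voxel_size))
      voxel_size <- if (max(fsc$freq) > 0) max(fsc$shell) / (D * max(fsc$freq)) else 1
  } else vals <- fsc
  vals[is.na(vals)] <- 1
  nmax <- length(vals) - 1L
  below <- which(vals < threshold & seq_along(vals) > 1L)
  if (!length(below)) {
    res <- D * voxel_size / nmax
    attr(res, "shell") <- nmax
    attr(res, "flagged") <- TRUE
    return(res)
  }
  k <- min(below) - 1L          # 0-based shell of first crossing
  f0 <- vals[k]; f1 <- vals[k + 1L]
  frac <- if (f0 > f1) (f0 - threshold) / (f0 - f1) else 0
  kc <- (k - 1L) + frac
  kc <- max(kc, 1e-6)
  res <- D * voxel_size / kc
  attr(res, "shell") <- kc
  attr(res, "flagged") <- FALSE
  res
}

#' Export a per-shell curve as two-column text
#'
#' @param curve Numeric per-shell vector (shells 0..D/2).
#' @param path Output path.
#' @param D Box size.
#' @param voxel_size Angstrom per pixel.
#' @return `path`, invisibly.
#' @export
write_shell_curve <- function(curve, path, D, voxel_size) {
  df <- data.frame(freq = (seq_along(curve) - 1) / (D * voxel_size),
                   value = curve)
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
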