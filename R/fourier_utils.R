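# Centred FFT helpers. Throughout the package a transform of a D-box
# uses the centred convention V(k) = sum_x v(x) exp(-2*pi*i*k.(x-c)/D)
# with c = D/2 (0-based) on every axis, so that the zero frequency sits
# at 1-based array index D/2 + 1 and phases are taken about the box
# centre. D must be even.

fftshift1 <- function(n) {
  h <- n %/% 2
  c((h + 1):n, 1:h)
}

fftshift2 <- function(m) {
  ix <- fftshift1(nrow(m))
  m[ix, ix, drop = FALSE]
}

fftshift3 <- function(a) {
  ix <- fftshift1(dim(a)[1])
  a[ix, ix, ix, drop = FALSE]
}

ft2c <- function(img) fftshift2(stats::fft(fftshift2(img)))

ift2c <- function(F) {
  v <- fftshift2(stats::fft(fftshift2(F), inverse = TRUE)) / length(F)
  Re(v)
}

ft3c <- function(vol) fftshift3(stats::fft(fftshift3(vol)))

ift3c <- function(F) {
  v <- fftshift3(stats::fft(fftshift3(F), inverse = TRUE)) / length(F)
  Re(v)
}

# centred frequency values for a box side D: -D/2 .. D/2-1
freq_index <- function(D) seq_len(D) - 1L - D %/% 2L

# integer shell index (rounded radius) for a 2D grid
shell_index_2d <- function(D) {
  k <- freq_index(D)
  kx <- matrix(k, D, D)
  ky <- matrix(k, D, D, byrow = TRUE)
  round(sqrt(kx^2 + ky^2))
}

shell_index_3d <- function(D) {
  k <- freq_index(D)
  kx <- array(k, c(D, D, D))
  ky <- array(rep(k, each = D), c(D, D, D))
  kz <- array(rep(k, each = D * D), c(D, D, D))
  round(sqrt(kx^2 + ky^2 + kz^2))
}

# mean of x over integer shells 0..D/2; x and shells same shape
shell_mean <- function(x, shells, D) {
  nmax <- D %/% 2L
  keep <- shells <= nmax
  s <- rowsum(as.numeric(x[keep]), shells[keep])
  n <- rowsum(rep(1, sum(keep)), shells[keep])
  out <- rep(NA_real_, nmax + 1L)
  out[as.integer(rownames(s)) + 1L] <- s / n
  out
}

# per-shell power (mean squared modulus) of a complex Fourier array
shell_power <- function(F) {
  D <- dim(F)[1]
  shells <- if (length(dim(F)) == 3L) shell_index_3d(D) else shell_index_2d(D)
  shell_mean(Mod(F)^2, shells, D)
}

# apply a per-shell curve multiplicatively to a Fourier array
apply_shell_curve <- function(F, curve) {
  D <- dim(F)[1]
  shells <- if (length(dim(F)) == 3L) shell_index_3d(D) else shell_index_2d(D)
  vals <- c(curve, rep(0, max(0, max(shells) + 1L - length(curve))))
  F * array(vals[shells + 1L], dim(F))
}

# Fourier-space phase ramp shifting a 3D volume by t (voxels)
fourier_shift_volume <- function(F, t) {
  D <- dim(F)[1]
  k <- freq_index(D)
  px <- exp(-2i * pi * k * t[1] / D)
  py <- exp(-2i * pi * k * t[2] / D)
  pz <- exp(-2i * pi * k * t[3] / D)
  F * outer(outer(px, py), pz)
}

# low-pass filter a real volume at `resolution` (angstrom), raised-cosine
# edge of `edge_width` shells
lowpass_volume <- function(vol, voxel_size, resolution, edge_width = 2) {
  D <- dim(vol)[1]
  cutoff <- D * voxel_size / resolution
  sh <- 0:(D %/% 2)
  f <- ifelse(sh <= cutoff, 1,
              ifelse(sh >= cutoff + edge_width, 0,
                     0.5 * (1 + cos(pi * (sh - cutoff) / edge_width))))
  ift3c(apply_shell_curve(ft3c(vol), f))
}
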