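# Euler-angle conventions, residual-rotation frames, pose priors and
# pose-grid construction.
#
# Rotations use the ZYZ convention R = Rz(psi) %*% Ry(tilt) %*% Rz(rot),
# angles in degrees. A pose is (rot, tilt, psi, dx, dy): three Euler
# angles plus an in-plane translation in pixels. A positive (dx, dy)
# means the reference projection is shifted by (+dx, +dy) before
# comparison with the particle image.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_z <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Euler angles to rotation matrix (ZYZ)
#'
#' @param rot,tilt,psi Euler angles in degrees;
#'   `R = Rz(psi) Ry(tilt) Rz(rot)`.
#' @return A 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  rot_z(psi) %*% rot_y(tilt) %*% rot_z(rot)
}

#' Rotation matrix to Euler angles (ZYZ)
#'
#' Returns the canonical triplet with tilt in \[0, 180\] degrees. At the
#' gimbal singularities (tilt 0 or 180) `rot` is set to 0 and the full
#' in-plane rotation is carried by `psi`.
#'
#' @param R A 3x3 rotation matrix.
#' @return Numeric vector `c(rot, tilt, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  tilt <- rad2deg(acos(max(-1, min(1, R[3, 3]))))
  if (abs(R[3, 3]) > 1 - 1e-12) {
    rot <- 0
    psi <- rad2deg(atan2(R[2, 1], R[1, 1]))
    if (R[3, 3] < 0) psi <- rad2deg(atan2(-R[2, 1], -R[1, 1]))
  } else {
    rot <- rad2deg(atan2(R[3, 2], -R[3, 1]))
    psi <- rad2deg(atan2(R[2, 3], R[1, 3]))
  }
  c(rot = rot, tilt = tilt, psi = psi)
}

# geodesic angle (degrees) between two rotation matrices
rotation_distance <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  rad2deg(acos(max(-1, min(1, (tr - 1) / 2))))
}

#' Reference frame for stored residual rotations
#'
#' Residual body rotations are serialized around (rot 0, tilt 90,
#' psi 0), i.e. as rotations about a vector orthogonal to the axis
#' joining the body's centre-of-mass to its rotation-reference body's
#' centre-of-mass, so the stored tilt never sits at the Euler gimbal.
#' This function returns the fixed frame rotation `F` used by that
#' convention: a stored matrix `Rs` relates to the internal residual
#' rotation `R` by `Rs = Ry(90) t(F) R F`, so a zero residual maps to
#' exactly (0, 90, 0). The orthogonal direction is chosen
#' deterministically: orthogonal to both the centre-of-mass axis and
#' the lab z axis when possible, else the lab x axis.
#'
#' @param body_com,reference_com Centre-of-mass 3-vectors (voxels,
#'   relative to the box centre).
#' @return A 3x3 rotation matrix with columns (a, b, u) where `u` is the
#'   unit COM-to-COM direction.
#' @export
residual_frame <- function(body_com, reference_com) {
  u <- reference_com - body_com
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("validation error: coincident centres of mass")
  u <- u / nu
  zax <- c(0, 0, 1)
  a <- c(u[2] * zax[3] - u[3] * zax[2],
         u[3] * zax[1] - u[1] * zax[3],
         u[1] * zax[2] - u[2] * zax[1])
  if (sqrt(sum(a^2)) < 1e-6) a <- c(u[2] * 0 - u[3] * 0, u[3] * 1 - u[1] * 0,
                                    u[1] * 0 - u[2] * 1)  # u x x-axis
  a <- a / sqrt(sum(a^2))
  b <- c(u[2] * a[3] - u[3] * a[2],
         u[3] * a[1] - u[1] * a[3],
         u[1] * a[2] - u[2] * a[1])
  unname(cbind(a, b, u))
}

#' Compose consensus and residual poses into a projection pose
#'
#' Every body is reconstructed with its centre-of-mass at the box
#' centre and rotated about that centre. Projecting the COM-centred
#' body with the composed pose reproduces the body rotated in situ by
#' the residual and projected with the consensus pose: the effective
#' rotation is `R_cons R_res` and the effective in-plane shift is the
#' consensus offset plus the residual offset plus the projected
#' centre-of-mass displacement `(R_cons com)[1:2]`.
#'
#' @param consensus_pose,residual_pose Lists or one-row data.frames
#'   with fields rot, tilt, psi (degrees), dx, dy (pixels).
#' @param body_com Body centre-of-mass (voxels, relative to box centre).
#' @return List with `R` (3x3 effective rotation) and `shift`
#'   (length-2 effective in-plane translation, pixels).
#' @export
compose_projection_pose <- function(consensus_pose, residual_pose,
                                    body_com = c(0, 0, 0)) {
  Rc <- euler_to_matrix(consensus_pose$rot, consensus_pose$tilt, consensus_pose$psi)
  Rm <- euler_to_matrix(residual_pose$rot, residual_pose$tilt, residual_pose$psi)
  pc <- Rc %*% body_com
  list(R = Rc %*% Rm,
       shift = c(consensus_pose$dx + residual_pose$dx + pc[1],
                 consensus_pose$dy + residual_pose$dy + pc[2]))
}

#' Gaussian pose prior
#'
#' @param sigma_angles Std of the rotational prior, degrees (0 = fixed).
#' @param sigma_offset Std of the translational prior, pixels (0 = fixed).
#' @return An object of class `mb_prior`.
#' @export
pose_prior <- function(sigma_angles, sigma_offset) {
  if (sigma_angles < 0 || sigma_offset < 0)
    stop("validation error: prior standard deviations must be >= 0")
  structure(list(sigma_angles = sigma_angles, sigma_offset = sigma_offset),
            class = "mb_prior")
}

#' Log prior density of a residual pose
#'
#' Sum of independent Gaussian log-densities over the three Euler
#' angles and two translations, up to an additive constant; `-Inf`
#' outside the +/-3 sigma search range (and away from the centre when a
#' sigma is zero).
#'
#' @param residual_pose List/row with rot, tilt, psi, dx, dy.
#' @param prior An `mb_prior`.
#' @return Scalar log-density (unnormalized).
#' @export
prior_log_density <- function(residual_pose, prior) {
  ang <- c(residual_pose$rot, residual_pose$tilt, residual_pose$psi)
  off <- c(residual_pose$dx, residual_pose$dy)
  lp <- 0
  tol <- 1e-9
  if (prior$sigma_angles == 0) {
    if (any(abs(ang) > tol)) return(-Inf)
  } else {
    if (any(abs(ang) > 3 * prior$sigma_angles + tol)) return(-Inf)
    lp <- lp - sum(ang^2) / (2 * prior$sigma_angles^2)
  }
  if (prior$sigma_offset == 0) {
    if (any(abs(off) > tol)) return(-Inf)
  } else {
    if (any(abs(off) > 3 * prior$sigma_offset + tol)) return(-Inf)
    lp <- lp - sum(off^2) / (2 * prior$sigma_offset^2)
  }
  lp
}

grid_axis <- function(sigma, step) {
  if (sigma == 0) return(0)
  if (step <= 0) stop("validation error: grid step must be > 0")
  k <- floor(3 * sigma / step + 1e-9)
  step * (-k:k)
}

#' Build a residual pose grid
#'
#' Regular grid over the three Euler angles in `[-3 sigma_angles,
#' +3 sigma_angles]` and the two in-plane translations in
#' `[-3 sigma_offset, +3 sigma_offset]`, symmetric about and always
#' containing zero (the consensus pose). A zero sigma collapses the
#' corresponding axes to the centre.
#'
#' @param prior An `mb_prior`.
#' @param angular_step Angular sampling, degrees.
#' @param trans_step Translational sampling, pixels.
#' @return An object of class `mb_pose_grid`: data.frame with columns
#'   rot, tilt, psi, dx, dy, log_prior.
#' @export
build_pose_grid <- function(prior, angular_step, trans_step) {
  ang <- grid_axis(prior$sigma_angles, angular_step)
  off <- grid_axis(prior$sigma_offset, trans_step)
  g <- expand.grid(rot = ang, tilt = ang, psi = ang, dx = off, dy = off,
                   KEEP.OUT.ATTRS = FALSE)
  lp <- numeric(nrow(g))
  if (prior$sigma_angles > 0)
    lp <- lp - (g$rot^2 + g$tilt^2 + g$psi^2) / (2 * prior$sigma_angles^2)
  if (prior$sigma_offset > 0)
    lp <- lp - (g$dx^2 + g$dy^2) / (2 * prior$sigma_offset^2)
  g$log_prior <- lp
  attr(g, "angular_step") <- angular_step
  attr(g, "trans_step") <- trans_step
  attr(g, "n_rot") <- length(ang)^3
  attr(g, "n_trans") <- length(off)^2
  class(g) <- c("mb_pose_grid", "data.frame")
  g
}

# vectorized ZYZ Euler-to-matrix: returns an n x 9 matrix of
# column-major 3x3 rotation matrices
euler_to_matrix_batch <- function(rot, tilt, psi) {
  cr <- cos(deg2rad(rot)); sr <- sin(deg2rad(rot))
  ct <- cos(deg2rad(tilt)); st <- sin(deg2rad(tilt))
  cp <- cos(deg2rad(psi)); sp <- sin(deg2rad(psi))
  cbind(cp * ct * cr - sp * sr,
        sp * ct * cr + cp * sr,
        -st * cr,
        -cp * ct * sr - sp * cr,
        -sp * ct * sr + cp * cr,
        st * sr,
        cp * st,
        sp * st,
        ct)
}

# unique rotation triplets and shift pairs of a grid, plus the mapping
# grid row -> (rotation index, shift index); the grid from expand.grid
# orders rotations fastest, so rows factorise exactly
grid_factorise <- function(grid) {
  ang <- unique(grid[c("rot", "tilt", "psi")])
  off <- unique(grid[c("dx", "dy")])
  nr <- nrow(ang)
  nt <- nrow(off)
  stopifnot(nr * nt == nrow(grid))
  rotmats <- euler_to_matrix_batch(ang$rot, ang$tilt, ang$psi)
  list(angles = ang, shifts = as.matrix(off), rotmats = rotmats, nr = nr, nt = nt)
}

# local fine grid: symmetric displacement grid of +/- span steps around
# zero; per-particle centre offsets are added by the caller
local_grid_base <- function(prior, angular_step, trans_step, span = 3L) {
  ang <- if (prior$sigma_angles > 0) angular_step * (-span:span) else 0
  off <- if (prior$sigma_offset > 0) trans_step * (-span:span) else 0
  expand.grid(rot = ang, tilt = ang, psi = ang, dx = off, dy = off,
              KEEP.OUT.ATTRS = FALSE)
}

# shift a displacement grid to a particle's current pose and evaluate
# the (truncated Gaussian) prior there
local_grid_at <- function(base, centre, prior) {
  g <- base
  g$rot <- g$rot + centre$rot
  g$tilt <- g$tilt + centre$tilt
  g$psi <- g$psi + centre$psi
  g$dx <- g$dx + centre$dx
  g$dy <- g$dy + centre$dy
  lp <- numeric(nrow(g))
  if (prior$sigma_angles > 0) {
    lp <- lp - (g$rot^2 + g$tilt^2 + g$psi^2) / (2 * prior$sigma_angles^2)
    out <- pmax(abs(g$rot), abs(g$tilt), abs(g$psi)) > 3 * prior$sigma_angles + 1e-9
    lp[out] <- -Inf
  }
  if (prior$sigma_offset > 0) {
    lp <- lp - (g$dx^2 + g$dy^2) / (2 * prior$sigma_offset^2)
    out <- pmax(abs(g$dx), abs(g$dy)) > 3 * prior$sigma_offset + 1e-9
    lp[out] <- -Inf
  }
  g$log_prior <- lp
  class(g) <- c("mb_pose_grid", "data.frame")
  g
}
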