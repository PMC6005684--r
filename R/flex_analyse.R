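# Post-refinement motion analysis: PCA on per-body poses, eigen-motion
# map series, amplitude-based particle subsets, and export of
# re-centred subtracted particle images.

#' Convert per-body poses to PCA features
#'
#' Six variables per body: the three residual Euler angles (degrees)
#' and the three-dimensional lift of the in-plane translation — the
#' shift vector `(dx, dy, 0)` rotated into the reconstruction frame by
#' the inverse consensus rotation (its component along the projection
#' direction is zero by construction), in pixels.
#'
#' @param particles An `mb_particles` (or an `mb_state`) carrying
#'   consensus poses and per-body residual poses.
#' @return N x 6B numeric matrix, columns named
#'   `body<b>.<rot|tilt|psi|tx|ty|tz>`.
#' @export
poses_to_features <- function(particles) {
  meta <- particles$meta
  body_poses <- particles$body_poses
  if (!length(body_poses)) stop("validation error: no body poses")
  N <- nrow(meta)
  B <- length(body_poses)
  feats <- matrix(0, N, 6 * B)
  cn <- character(6 * B)
  for (b in seq_len(B)) {
    if (nrow(body_poses[[b]]) != N) stop("validation error: missing body poses")
    cn[(b - 1) * 6 + 1:6] <- paste0("body", b, ".", c("rot", "tilt", "psi",
                                                      "tx", "ty", "tz"))
  }
  for (i in seq_len(N)) {
    Rc <- euler_to_matrix(meta$rot[i], meta$tilt[i], meta$psi[i])
    for (b in seq_len(B)) {
      p <- body_poses[[b]][i, ]
      t3 <- t(Rc) %*% c(p$dx, p$dy, 0)
      feats[i, (b - 1) * 6 + 1:6] <- c(p$rot, p$tilt, p$psi, t3)
    }
  }
  colnames(feats) <- cn
  feats
}

#' Per-column normalization scales from map sensitivity
#'
#' Each angular column of body `b` is scaled by the sum of squared
#' voxel differences between the body map and the same map rotated one
#' degree about the corresponding residual-rotation axis; each
#' translational column by the same quantity for a one-pixel shift
#' along the corresponding Cartesian axis. Columns are multiplied by
#' their scale, so a unit of any normalized feature represents a
#' comparable amount of map change.
#'
#' @param features N x 6B matrix from [poses_to_features()].
#' @param body_volumes List of COM-centred body volumes
#'   (`mb_volume`s or arrays).
#' @param mode `"multiply"` (default) or `"divide"`.
#' @return List with `features` (normalized matrix) and `scales`
#'   (length 6B).
#' @export
normalize_features <- function(features, body_volumes, mode = c("multiply", "divide")) {
  mode <- match.arg(mode)
  B <- length(body_volumes)
  if (ncol(features) != 6 * B)
    stop("validation error: feature/body count mismatch")
  scales <- numeric(6 * B)
  probes_ang <- list(euler_to_matrix(1, 0, 0), euler_to_matrix(0, 1, 0),
                     euler_to_matrix(0, 0, 1))
  for (b in seq_len(B)) {
    v <- as_mb_volume(body_volumes[[b]])$data
    if (sum(abs(v)) == 0) stop("validation error: zero body map")
    D <- dim(v)[1]
    for (a in 1:3) {
      vr <- cpp_resample_rigid(as.numeric(v), D, as.numeric(probes_ang[[a]]),
                               c(0, 0, 0), c(0, 0, 0))
      scales[(b - 1) * 6 + a] <- sum((v - vr)^2)
    }
    for (a in 1:3) {
      sh <- c(0, 0, 0); sh[a] <- 1
      vs <- cpp_resample_rigid(as.numeric(v), D, as.numeric(diag(3)),
                               c(0, 0, 0), sh)
      scales[(b - 1) * 6 + 3 + a] <- sum((v - vs)^2)
    }
  }
  f <- if (mode == "multiply") sweep(features, 2, scales, `*`)
       else sweep(features, 2, ifelse(scales > 0, scales, 1), `/`)
  list(features = f, scales = scales, mode = mode)
}

#' Principal component analysis of normalized pose features
#'
#' Eigendecomposition of the covariance of the mean-centred normalized
#' features; amplitudes are the projections of the centred features on
#' the eigenvectors.
#'
#' @param normalized_features N x 6B matrix (see [normalize_features()]).
#' @param scales Optional normalization scales to carry along.
#' @param mode Normalization mode used (`"multiply"` or `"divide"`).
#' @return Object of class `mb_pca`: list with `mean`, `eigenvalues`
#'   (descending), `eigenvectors` (columns), `amplitudes` (N x K),
#'   `explained` (fractions summing to 1), `scales`, `mode`.
#' @export
pca_fit <- function(normalized_features, scales = NULL, mode = "multiply") {
  X <- as.matrix(normalized_features)
  if (nrow(X) <= ncol(X))
    warning("fewer particles than features; trailing eigenvalues are zero")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  structure(list(mean = mu, eigenvalues = ev, eigenvectors = eg$vectors,
                 amplitudes = Xc %*% eg$vectors,
                 explained = if (sum(ev) > 0) ev / sum(ev) else ev,
                 scales = scales, mode = mode),
            class = "mb_pca")
}

#' @export
print.mb_pca <- function(x, ...) {
  cat(sprintf("<mb_pca> %d features, %d particles\n",
              length(x$mean), nrow(x$amplitudes)))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 6)), collapse = " "),
      "\n")
  invisible(x)
}

#' Fit the motion PCA for a refined state
#'
#' Convenience wrapper: features from the refined poses, normalization
#' against the current body reconstructions, PCA fit.
#'
#' @param state An `mb_state` after refinement.
#' @param mode Normalization mode.
#' @return An `mb_pca`.
#' @export
flex_pca <- function(state, mode = "multiply") {
  feats <- poses_to_features(list(meta = state$meta, body_poses = state$body_poses))
  vols <- lapply(seq_len(state$B), function(b) ift3c(state$volF[[b]][[1]] / 2 +
                                                       state$volF[[b]][[2]] / 2))
  nf <- normalize_features(feats, vols, mode)
  pca_fit(nf$features, nf$scales, nf$mode)
}

# map a feature direction into normalized feature space
normalize_direction <- function(direction, scales, mode = "multiply") {
  d <- if (mode == "multiply") direction * scales else direction / ifelse(scales > 0, scales, 1)
  d / sqrt(sum(d^2))
}

# un-normalize a normalized feature vector back to raw pose units
unnormalize_features <- function(f, scales, mode = "multiply") {
  if (mode == "multiply") f / ifelse(scales > 0, scales, 1) else f * scales
}

#' Eigen-motion map series
#'
#' Splits the amplitudes along one principal component into `M`
#' equi-populated bins; for each bin, maps the bin's median amplitude
#' back to per-body poses and generates a combined map by rigidly
#' repositioning every body (rotation about its centre of mass plus
#' the lifted translation, in situ) and summing.
#'
#' @param pca An `mb_pca` with `scales` set.
#' @param component Eigenvector index.
#' @param body_volumes List of in-situ body volumes (`mb_volume`s).
#' @param coms B x 3 matrix of body centres of mass (voxels, from box
#'   centre).
#' @param M Number of maps (default 10).
#' @param voxel_size Angstrom per pixel of the outputs.
#' @return Object of class `mb_map_series`: list with `maps` (list of
#'   M `mb_volume`s), `bin_amplitudes`, `bin_edges` and `counts`.
#' @export
eigen_map_series <- function(pca, component, body_volumes, coms, M = 10L,
                             voxel_size = 1) {
  amps <- pca$amplitudes[, component]
  N <- length(amps)
  if (M < 2L) stop("validation error: M must be >= 2")
  if (M > N) stop("validation error: more bins than particles")
  B <- length(body_volumes)
  ord <- order(amps)
  bin_of <- integer(N)
  bin_of[ord] <- ceiling(seq_len(N) / (N / M))
  bin_of[bin_of > M] <- M
  centres <- vapply(seq_len(M), function(m) median(amps[bin_of == m]), numeric(1))
  edges <- vapply(seq_len(M - 1L),
                  function(m) mean(c(max(amps[bin_of == m]), min(amps[bin_of == m + 1L]))),
                  numeric(1))
  maps <- vector("list", M)
  for (m in seq_len(M)) {
    f <- pca$mean + centres[m] * pca$eigenvectors[, component]
    raw <- unnormalize_features(f, pca$scales, pca$mode)
    comb <- NULL
    for (b in seq_len(B)) {
      v <- as_mb_volume(body_volumes[[b]])$data
      D <- dim(v)[1]
      fb <- raw[(b - 1) * 6 + 1:6]
      R <- euler_to_matrix(fb[1], fb[2], fb[3])
      out <- array(cpp_resample_rigid(as.numeric(v), D, as.numeric(R),
                                      coms[b, ], fb[4:6]), c(D, D, D))
      comb <- if (is.null(comb)) out else comb + out
    }
    maps[[m]] <- mb_volume(comb, voxel_size)
  }
  structure(list(maps = maps, bin_amplitudes = centres, bin_edges = edges,
                 counts = tabulate(bin_of, M), component = component),
            class = "mb_map_series")
}

#' Select a particle subset by eigenvector amplitude
#'
#' @param particles An `mb_particles`.
#' @param pca An `mb_pca` fitted on the same particles.
#' @param component Eigenvector index.
#' @param amin,amax Amplitude range; particles with
#'   `amin <= a < amax` are kept.
#' @param path Optional output STAR path.
#' @return Indices of the selected particles (invisibly, the STAR is
#'   written when `path` is given); a warning is raised for an empty
#'   selection.
#' @export
select_subset <- function(particles, pca, component, amin = -Inf, amax = Inf,
                          path = NULL) {
  a <- pca$amplitudes[, component]
  sel <- which(a >= amin & a < amax)
  if (!length(sel)) warning("empty selection")
  if (!is.null(path)) {
    sub <- particles
    sub$meta <- particles$meta[sel, , drop = FALSE]
    sub$body_poses <- lapply(particles$body_poses,
                             function(p) p[sel, , drop = FALSE])
    if (!is.null(particles$pca_amplitudes))
      sub$pca_amplitudes <- particles$pca_amplitudes[sel, , drop = FALSE]
    write_particles_star(sub, path)
  }
  invisible(sel)
}

#' Valley of a bimodal amplitude histogram
#'
#' Kernel-density location of the deepest minimum between the two
#' strongest modes, with the depth relative to the smaller mode.
#'
#' @param amplitudes Numeric vector.
#' @return List with `threshold`, `valley_density`, `peak_densities`
#'   and `depth` (1 - valley/smaller peak).
#' @export
amplitude_valley <- function(amplitudes) {
  d <- density(amplitudes, n = 512)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  locmax <- locmax[y[locmax] >= 0.05 * max(y)]
  if (length(locmax) < 2L)
    return(list(threshold = NA_real_, valley_density = NA_real_,
                peak_densities = y[locmax], depth = 0))
  # pick the pair of modes with the deepest relative valley between them
  best <- list(depth = -Inf)
  for (a in seq_len(length(locmax) - 1L)) for (b in (a + 1L):length(locmax)) {
    lo <- locmax[a]; hi <- locmax[b]
    vi <- lo + which.min(y[lo:hi]) - 1L
    depth <- 1 - y[vi] / min(y[c(lo, hi)])
    if (depth > best$depth)
      best <- list(threshold = d$x[vi], valley_density = y[vi],
                   peak_densities = y[c(lo, hi)], depth = depth)
  }
  best
}

#' Write re-centred subtracted particle images
#'
#' For every particle, subtracts the non-overlapping parts of all
#' bodies except `keep_body` at their refined poses, then re-centres
#' the image on the projected centre-of-mass of the kept body (a
#' Fourier phase shift), so downstream focused refinements see the
#' kept body at the box centre with zero offsets.
#'
#' @param state An `mb_state` after refinement.
#' @param keep_body Body index to keep.
#' @param stack_path Output MRCS path.
#' @param star_path Output STAR path.
#' @return Invisible list with the applied per-particle shifts.
#' @export
write_subtracted_particles <- function(state, keep_body, stack_path, star_path) {
  if (keep_body < 1L || keep_body > state$B)
    stop("validation error: keep_body out of range")
  D <- state$D
  N <- state$N
  com <- as.numeric(state$bodies[keep_body, c("com_x", "com_y", "com_z")])
  images <- array(0, c(D, D, N))
  k <- freq_index(D)
  newmeta <- state$meta
  shifts <- matrix(0, N, 2)
  for (i in seq_len(N)) {
    S <- subtract_signal(state, i, keep_body)
    cons <- state$meta[i, ]
    eff <- compose_projection_pose(cons, state$body_poses[[keep_body]][i, ], com)
    t <- eff$shift
    shifts[i, ] <- t
    phase <- outer(exp(2i * pi * k * t[1] / D), exp(2i * pi * k * t[2] / D))
    images[, , i] <- ift2c(S * phase)
    eul <- matrix_to_euler(eff$R)
    newmeta$rot[i] <- eul[1]; newmeta$tilt[i] <- eul[2]; newmeta$psi[i] <- eul[3]
    newmeta$dx[i] <- 0; newmeta$dy[i] <- 0
    newmeta$image_index[i] <- i
    newmeta$stack_path[i] <- basename(stack_path)
  }
  write_mrcs(images, stack_path, state$voxel_size)
  parts <- structure(list(meta = newmeta, body_poses = list(),
                          pca_amplitudes = NULL), class = "mb_particles")
  write_particles_star(parts, star_path)
  invisible(list(shifts = shifts))
}
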