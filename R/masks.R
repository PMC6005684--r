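# Soft-mask construction, centre-of-mass, and the ordered non-overlap
# decomposition used for partial signal subtraction.

#' Build a soft mask from a binary mask
#'
#' Dilates the support by `extend_px` voxels and adds a raised-cosine
#' falloff of width `soft_edge_px` voxels of Euclidean distance beyond
#' the dilated support, so values drop smoothly from 1 to 0.
#'
#' @param binary_mask Cubic 3D array in \{0, 1\} (an `mb_volume` or a
#'   plain array).
#' @param extend_px Dilation radius in voxels (>= 0).
#' @param soft_edge_px Soft-edge width in voxels (>= 0).
#' @return An `mb_volume` whose data lie in \[0, 1\].
#' @export
make_soft_mask <- function(binary_mask, extend_px = 0, soft_edge_px = 0) {
  vol <- as_mb_volume(binary_mask)
  m <- vol$data
  if (extend_px < 0 || soft_edge_px < 0)
    stop("validation error: extend_px and soft_edge_px must be >= 0")
  if (!any(m > 0.5)) stop("validation error: empty input mask")
  d <- cpp_edt(as.numeric(m), dim(m))
  out <- array(0, dim(m))
  out[d <= extend_px] <- 1
  if (soft_edge_px > 0) {
    edge <- d > extend_px & d < extend_px + soft_edge_px
    out[edge] <- 0.5 * (1 + cos(pi * (d[edge] - extend_px) / soft_edge_px))
  }
  mb_volume(out, vol$voxel_size)
}

#' Centre of mass of a mask or map
#'
#' Intensity-weighted mean coordinate, in voxels relative to the box
#' centre (the voxel at 0-based index D/2 on each axis).
#'
#' @param mask An `mb_volume` or 3D array with non-negative weights.
#' @return Numeric 3-vector.
#' @export
centre_of_mass <- function(mask) {
  m <- as_mb_volume(mask)$data
  tot <- sum(m)
  if (tot <= 0) stop("validation error: all-zero mask")
  D <- dim(m)[1]
  x <- seq_len(D) - 1 - D %/% 2
  cx <- sum(rowSums(m, dims = 1) * x)
  cy <- sum(apply(m, 2, sum) * x)
  cz <- sum(apply(m, 3, sum) * x)
  c(cx, cy, cz) / tot
}

#' Ordered non-overlap decomposition of body masks
#'
#' For the subtraction targeting body `b`, the partial mask of every
#' other body `bp` is its mask multiplied by the complements
#' `prod(1 - m_k)` over all bodies `k` of higher subtraction precedence
#' with respect to `b` (bodies earlier in the STAR file are subtracted
#' first, and the target body itself always has the highest
#' precedence), so only non-overlapping parts of the other bodies are
#' ever subtracted. For binary masks this tiles the union of all masks
#' without double counting.
#'
#' @param masks List of same-grid masks (`mb_volume`s or arrays), in
#'   body (file) order.
#' @return Object of class `mb_mask_decomposition`: list with
#'   `partial[[b]][[bp]]` (the partial mask of body `bp` used when
#'   subtracting for body `b`; `NULL` for `bp == b`) and
#'   `n_stored_transforms`, the number of distinct 3D transforms a
#'   refinement must hold (full bodies plus partials differing from
#'   their source mask).
#' @export
decompose_overlaps <- function(masks) {
  B <- length(masks)
  if (B < 1L) stop("validation error: need at least one mask")
  arrs <- lapply(masks, function(m) as_mb_volume(m)$data)
  dims <- vapply(arrs, function(a) dim(a)[1], numeric(1))
  if (length(unique(dims)) != 1L)
    stop("validation error: masks must share one grid")
  partial <- vector("list", B)
  n_distinct <- B
  for (b in seq_len(B)) {
    partial[[b]] <- vector("list", B)
    # subtraction order for target b: b first, then the others in file order
    order_b <- c(b, setdiff(seq_len(B), b))
    comp <- 1 - arrs[[b]]
    for (bp in order_b[-1]) {
      pm <- arrs[[bp]] * comp
      partial[[b]][[bp]] <- pm
      if (max(abs(pm - arrs[[bp]])) > 1e-12) n_distinct <- n_distinct + 1L
      comp <- comp * (1 - arrs[[bp]])
    }
  }
  structure(list(partial = partial, n_stored_transforms = n_distinct),
            class = "mb_mask_decomposition")
}
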