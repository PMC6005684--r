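# Shared fixtures: everything is generated in code at test time.

ns <- asNamespace("multibodyr")

# a small, fast phantom for unit tests
tiny_phantom <- function(D = 32L) {
  make_phantom(D)
}

# body-definition table matching the default three-body phantom
tiny_bodies <- function(sigma_angles = c(1, 3, 3), sigma_offset = 0) {
  bodies <- data.frame(
    body_index = 1:3, mask_path = NA_character_,
    rotate_relative_to = c(2L, 1L, 1L),
    sigma_angles = sigma_angles, sigma_offset = sigma_offset,
    reference_path = NA_character_, stringsAsFactors = FALSE)
  bodies$fixed <- bodies$sigma_angles == 0 & bodies$sigma_offset == 0
  class(bodies) <- c("mb_bodies", "data.frame")
  bodies
}

# geodesic angle between pose rows (degrees)
pose_geodesic <- function(p1, p2) {
  ns$rotation_distance(euler_to_matrix(p1$rot, p1$tilt, p1$psi),
                       euler_to_matrix(p2$rot, p2$tilt, p2$psi))
}

random_rotation <- function() ns$random_rotations(1)[[1]]

write_example_body_star <- function(path,
                                    sigma_angles = c(10, 10, 10),
                                    rotate_relative_to = c(2, 1, 2),
                                    extra_col = FALSE,
                                    permute_cols = FALSE) {
  cols <- c("rlnBodyMaskName", "rlnBodyRotateRelativeTo",
            "rlnBodySigmaAngles", "rlnBodySigmaOffset")
  vals <- cbind(sprintf("mask_body%d.mrc", 1:3), rotate_relative_to,
                sigma_angles, c(2, 2, 2))
  if (extra_col) {
    cols <- c(cols, "rlnBodyReferenceName")
    vals <- cbind(vals, sprintf("ref_body%d.mrc", 1:3))
  }
  ord <- if (permute_cols) rev(seq_along(cols)) else seq_along(cols)
  lines <- c("data_bodies", "", "loop_",
             sprintf("_%s #%d", cols[ord], seq_along(cols)),
             apply(vals[, ord, drop = FALSE], 1, paste, collapse = "  "))
  writeLines(lines, path)
  path
}
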