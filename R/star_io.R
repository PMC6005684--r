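# STAR 1.0 metadata I/O: named data_ blocks containing loop_ tables.

#' Read a STAR file
#'
#' Parses every `data_` block containing a `loop_` table into a
#' data.frame; numeric columns are converted automatically.
#'
#' @param path Path to a STAR file.
#' @return Named list of data.frames, one per `data_` block, in file order.
#' @export
read_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!startsWith(lines[i], "data_")) { i <- i + 1L; next }
    block <- sub("^data_", "", lines[i])
    i <- i + 1L
    while (i <= n && lines[i] != "loop_") {
      if (startsWith(lines[i], "data_")) break
      i <- i + 1L
    }
    if (i > n || lines[i] != "loop_") next
    i <- i + 1L
    cols <- character(0)
    while (i <= n && startsWith(lines[i], "_")) {
      cols <- c(cols, sub("\\s.*$", "", sub("^_", "", lines[i])))
      i <- i + 1L
    }
    rows <- list()
    while (i <= n && nzchar(lines[i]) && !startsWith(lines[i], "data_")) {
      fields <- strsplit(lines[i], "[ \t]+")[[1]]
      if (length(fields) != length(cols))
        stop("STAR format error in block 'data_", block, "': row with ",
             length(fields), " fields, expected ", length(cols))
      rows[[length(rows) + 1L]] <- fields
      i <- i + 1L
    }
    if (length(rows)) {
      m <- do.call(rbind, rows)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
    } else {
      df <- as.data.frame(matrix(character(0), 0, length(cols)),
                          stringsAsFactors = FALSE)
    }
    names(df) <- cols
    for (j in seq_along(df)) {
      v <- df[[j]]
      suppressWarnings(num <- as.numeric(v))
      if (length(v) && !anyNA(num)) df[[j]] <- num
    }
    out[[block]] <- df
  }
  out
}

#' Write a STAR file
#'
#' @param tables Named list of data.frames; names become `data_` block names.
#' @param path Output path.
#' @param digits Decimal places for numeric columns.
#' @return `path`, invisibly.
#' @export
write_star <- function(tables, path, digits = 6L) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("# written by multibodyr", con)
  for (block in names(tables)) {
    df <- tables[[block]]
    writeLines(c("", paste0("data_", block), "", "loop_"), con)
    writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
    if (nrow(df)) {
      cols <- lapply(df, function(v) {
        if (is.numeric(v)) formatC(v, digits = digits, format = "f") else as.character(v)
      })
      writeLines(do.call(paste, c(cols, sep = "  ")), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

body_star_required <- c("rlnBodyMaskName", "rlnBodyRotateRelativeTo",
                        "rlnBodySigmaAngles", "rlnBodySigmaOffset")

#' Read a body-definition STAR file
#'
#' One row per rigid body, in file order (the order fixes the
#' subtraction precedence: earlier bodies are subtracted first).
#' Mandatory columns: `rlnBodyMaskName`, `rlnBodyRotateRelativeTo`,
#' `rlnBodySigmaAngles` (degrees), `rlnBodySigmaOffset` (pixels);
#' optional `rlnBodyReferenceName` points to an initial reference map.
#' A body with both prior widths zero is flagged as fixed.
#'
#' @param path Path to the body STAR file.
#' @return A data.frame of class `mb_bodies` with columns `body_index`,
#'   `mask_path`, `rotate_relative_to`, `sigma_angles`, `sigma_offset`,
#'   `reference_path` (`NA` when absent) and `fixed`.
#' @export
read_body_star <- function(path) {
  tabs <- read_star(path)
  if (!length(tabs)) stop("STAR format error: no data block in ", path)
  df <- tabs[[1]]
  missing_cols <- setdiff(body_star_required, names(df))
  if (length(missing_cols))
    stop("STAR format error: missing mandatory column ", missing_cols[1])
  bodies <- data.frame(
    body_index = seq_len(nrow(df)),
    mask_path = as.character(df$rlnBodyMaskName),
    rotate_relative_to = as.integer(df$rlnBodyRotateRelativeTo),
    sigma_angles = as.numeric(df$rlnBodySigmaAngles),
    sigma_offset = as.numeric(df$rlnBodySigmaOffset),
    reference_path = if ("rlnBodyReferenceName" %in% names(df))
      as.character(df$rlnBodyReferenceName) else NA_character_,
    stringsAsFactors = FALSE
  )
  bodies$reference_path[bodies$reference_path %in% c("", "None", "\"\"")] <- NA_character_
  validate_bodies(bodies)
  bodies$fixed <- bodies$sigma_angles == 0 & bodies$sigma_offset == 0
  class(bodies) <- c("mb_bodies", "data.frame")
  bodies
}

validate_bodies <- function(bodies) {
  B <- nrow(bodies)
  if (any(bodies$sigma_angles < 0) || any(bodies$sigma_offset < 0))
    stop("validation error: prior standard deviations must be >= 0")
  if (any(bodies$rotate_relative_to < 1 | bodies$rotate_relative_to > B))
    stop("validation error: rlnBodyRotateRelativeTo refers to a nonexistent body")
  if (any(bodies$rotate_relative_to == bodies$body_index))
    stop("validation error: a body cannot rotate relative to itself")
  invisible(bodies)
}

#' Write a body-definition STAR file
#'
#' @param bodies An `mb_bodies` data.frame (see [read_body_star()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_body_star <- function(bodies, path) {
  df <- data.frame(
    rlnBodyMaskName = bodies$mask_path,
    rlnBodyRotateRelativeTo = bodies$rotate_relative_to,
    rlnBodySigmaAngles = bodies$sigma_angles,
    rlnBodySigmaOffset = bodies$sigma_offset,
    stringsAsFactors = FALSE
  )
  if (!all(is.na(bodies$reference_path))) {
    df$rlnBodyReferenceName <- ifelse(is.na(bodies$reference_path), "None",
                                      bodies$reference_path)
  }
  write_star(list(bodies = df), path)
}

particle_main_cols <- c("rlnImageName", "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
                        "rlnOriginX", "rlnOriginY", "rlnDefocusU", "rlnDefocusV",
                        "rlnDefocusAngle", "rlnVoltage", "rlnSphericalAberration",
                        "rlnAmplitudeContrast", "rlnRandomSubset")

empty_pose_table <- function(n) {
  data.frame(rot = numeric(n), tilt = numeric(n), psi = numeric(n),
             dx = numeric(n), dy = numeric(n))
}

#' Read a particle STAR file
#'
#' Reads the main particle table (consensus poses + CTF parameters) and,
#' when present, the per-body tables `data_images_body_b` holding the
#' residual body poses in the tilt-90 storage convention. When no body
#' tables are present, residual poses are initialized to the identity.
#' A missing `rlnRandomSubset` column triggers a seeded random split
#' into two equal half-sets.
#'
#' @param path Path to the particle STAR file.
#' @param n_bodies Number of bodies to initialize identity residual
#'   poses for when no body tables are present (default 0: none).
#' @param bodies Optional `mb_bodies` with per-body centre-of-mass
#'   columns `com_x`, `com_y`, `com_z`; required to decode stored
#'   tilt-90 residual angles back to internal residual poses when body
#'   tables are present.
#' @param halfset_seed Seed for the half-set split when the file does
#'   not record one.
#' @return An object of class `mb_particles`: list with `meta` (main
#'   table as a data.frame with internal column names), `body_poses`
#'   (list of per-body pose data.frames with columns rot, tilt, psi in
#'   degrees and dx, dy in pixels) and `pca_amplitudes` (matrix or NULL).
#' @export
read_particles_star <- function(path, n_bodies = 0L, bodies = NULL,
                                halfset_seed = 1L) {
  tabs <- read_star(path)
  main_name <- intersect(c("images", "particles"), names(tabs))
  if (!length(main_name))
    stop("STAR format error: no data_images or data_particles block in ", path)
  df <- tabs[[main_name[1]]]
  need <- c("rlnImageName", "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
            "rlnOriginX", "rlnOriginY")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("STAR format error: missing mandatory column ", missing_cols[1])
  n <- nrow(df)
  img <- strsplit(as.character(df$rlnImageName), "@", fixed = TRUE)
  slice <- vapply(img, function(x) if (length(x) == 2L) as.integer(x[1]) else NA_integer_,
                  integer(1))
  stack <- vapply(img, function(x) x[length(x)], character(1))
  getn <- function(col, default) if (col %in% names(df)) as.numeric(df[[col]]) else
    rep(default, n)
  meta <- data.frame(
    image_index = slice, stack_path = stack,
    rot = as.numeric(df$rlnAngleRot), tilt = as.numeric(df$rlnAngleTilt),
    psi = as.numeric(df$rlnAnglePsi),
    dx = as.numeric(df$rlnOriginX), dy = as.numeric(df$rlnOriginY),
    defocus_u = getn("rlnDefocusU", 15000), defocus_v = getn("rlnDefocusV", 15000),
    astig_angle = getn("rlnDefocusAngle", 0), voltage = getn("rlnVoltage", 300),
    cs = getn("rlnSphericalAberration", 2.7),
    amplitude_contrast = getn("rlnAmplitudeContrast", 0.1),
    stringsAsFactors = FALSE
  )
  if ("rlnRandomSubset" %in% names(df)) {
    meta$half_set <- as.integer(df$rlnRandomSubset)
  } else {
    meta$half_set <- halfset_split(n, halfset_seed)
  }
  body_names <- grep("^images_body_[0-9]+$", names(tabs), value = TRUE)
  if (length(body_names)) {
    idx <- as.integer(sub("^images_body_", "", body_names))
    body_names <- body_names[order(idx)]
    B <- length(body_names)
    body_poses <- vector("list", B)
    for (b in seq_len(B)) {
      bt <- tabs[[body_names[b]]]
      if (nrow(bt) != n)
        stop("consistency error: body table ", body_names[b], " has ", nrow(bt),
             " rows but the main table has ", n)
      stored <- data.frame(rot = as.numeric(bt$rlnAngleRot),
                           tilt = as.numeric(bt$rlnAngleTilt),
                           psi = as.numeric(bt$rlnAnglePsi),
                           dx = as.numeric(bt$rlnOriginX),
                           dy = as.numeric(bt$rlnOriginY))
      if (!is.null(bodies)) {
        Fb <- body_frame(bodies, b)
        body_poses[[b]] <- decode_stored_poses(stored, Fb)
      } else {
        body_poses[[b]] <- stored
      }
    }
  } else {
    B <- n_bodies
    body_poses <- replicate(B, empty_pose_table(n), simplify = FALSE)
  }
  pca <- NULL
  pc_cols <- grep("^rlnPcaAmplitude", names(df), value = TRUE)
  if (length(pc_cols)) pca <- as.matrix(df[pc_cols])
  structure(list(meta = meta, body_poses = body_poses, pca_amplitudes = pca),
            class = "mb_particles")
}

halfset_split <- function(n, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  half <- rep(1L, n)
  half[sample.int(n, n %/% 2L)] <- 2L
  half
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a particle STAR file
#'
#' Emits the main particle table plus one `data_images_body_b` table per
#' body, with the residual rotations serialized in the tilt-90
#' convention (a zero residual is stored as rot 0, tilt 90, psi 0) when
#' body centre-of-mass geometry is supplied.
#'
#' @param particles An `mb_particles` object.
#' @param path Output path.
#' @param bodies Optional `mb_bodies` with `com_x`, `com_y`, `com_z`
#'   columns; when given, residual rotations are stored in the tilt-90
#'   convention, otherwise as raw residual Euler angles.
#' @return `path`, invisibly.
#' @export
write_particles_star <- function(particles, path, bodies = NULL) {
  meta <- particles$meta
  n <- nrow(meta)
  B <- length(particles$body_poses)
  if (B > 1L) {
    nb <- vapply(particles$body_poses, nrow, integer(1))
    if (length(unique(nb)) != 1L || (n > 0 && any(nb != n)))
      stop("validation error: heterogeneous body pose counts")
  }
  main <- data.frame(
    rlnImageName = sprintf("%06d@%s", meta$image_index, meta$stack_path),
    rlnAngleRot = meta$rot, rlnAngleTilt = meta$tilt, rlnAnglePsi = meta$psi,
    rlnOriginX = meta$dx, rlnOriginY = meta$dy,
    rlnDefocusU = meta$defocus_u, rlnDefocusV = meta$defocus_v,
    rlnDefocusAngle = meta$astig_angle, rlnVoltage = meta$voltage,
    rlnSphericalAberration = meta$cs,
    rlnAmplitudeContrast = meta$amplitude_contrast,
    rlnRandomSubset = meta$half_set,
    stringsAsFactors = FALSE
  )
  if (!is.null(particles$pca_amplitudes)) {
    amp <- particles$pca_amplitudes
    for (j in seq_len(ncol(amp)))
      main[[sprintf("rlnPcaAmplitude%d", j)]] <- amp[, j]
  }
  tabs <- list(images = main)
  for (b in seq_len(B)) {
    poses <- particles$body_poses[[b]]
    if (!is.null(bodies)) {
      Fb <- body_frame(bodies, b)
      stored <- encode_stored_poses(poses, Fb)
    } else {
      stored <- poses
    }
    tabs[[sprintf("images_body_%d", b)]] <- data.frame(
      rlnAngleRot = stored$rot, rlnAngleTilt = stored$tilt,
      rlnAnglePsi = stored$psi, rlnOriginX = stored$dx, rlnOriginY = stored$dy)
  }
  write_star(tabs, path)
}

# reference frame for the stored tilt-90 residual convention of body b
body_frame <- function(bodies, b) {
  if (!all(c("com_x", "com_y", "com_z") %in% names(bodies)))
    stop("bodies must carry com_x/com_y/com_z to en/decode stored residual angles")
  ref <- bodies$rotate_relative_to[b]
  residual_frame(c(bodies$com_x[b], bodies$com_y[b], bodies$com_z[b]),
                 c(bodies$com_x[ref], bodies$com_y[ref], bodies$com_z[ref]))
}

encode_stored_poses <- function(poses, Fb) {
  Ry90 <- euler_to_matrix(0, 90, 0)
  out <- poses
  for (i in seq_len(nrow(poses))) {
    R <- euler_to_matrix(poses$rot[i], poses$tilt[i], poses$psi[i])
    eul <- matrix_to_euler(Ry90 %*% t(Fb) %*% R %*% Fb)
    out$rot[i] <- eul[1]; out$tilt[i] <- eul[2]; out$psi[i] <- eul[3]
  }
  out
}

decode_stored_poses <- function(stored, Fb) {
  Ry90 <- euler_to_matrix(0, 90, 0)
  out <- stored
  for (i in seq_len(nrow(stored))) {
    Rs <- euler_to_matrix(stored$rot[i], stored$tilt[i], stored$psi[i])
    R <- Fb %*% t(Ry90) %*% Rs %*% t(Fb)
    eul <- matrix_to_euler(R)
    out$rot[i] <- eul[1]; out$tilt[i] <- eul[2]; out$psi[i] <- eul[3]
  }
  out
}

#' @export
print.mb_particles <- function(x, ...) {
  cat(sprintf("<mb_particles> %d particles, %d bodies\n",
              nrow(x$meta), length(x$body_poses)))
  invisible(x)
}
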