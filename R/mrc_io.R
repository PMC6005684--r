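# MRC2014 I/O, mode 2 (32-bit float) only, little-endian, x fastest.

mrc_read_header <- function(con) {
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
       mx = ints[8], my = ints[9], mz = ints[10], cella = cella,
       nsymbt = nsymbt)
}

mrc_write_header <- function(con, nx, ny, nz, mx, my, mz, voxel_size) {
  writeBin(as.integer(c(nx, ny, nz, 2L, 0L, 0L, 0L, mx, my, mz)),
           con, size = 4, endian = "little")
  writeBin(as.numeric(c(mx, my, mz) * voxel_size), con, size = 4, endian = "little")
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")   # dmin dmax dmean
  writeBin(as.integer(c(1L, 0L)), con, size = 4, endian = "little")    # ispg nsymbt
  writeBin(raw(8), con)                                                # extra 25-26
  writeBin(charToRaw("MRCO"), con)                                     # exttyp
  writeBin(20140L, con, size = 4, endian = "little")                   # nversion
  writeBin(raw(4 * 21), con)                                           # extra 29-49
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")   # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                     # machst LE
  writeBin(as.numeric(-1), con, size = 4, endian = "little")           # rms
  writeBin(0L, con, size = 4, endian = "little")                       # nlabl
  writeBin(raw(800), con)                                              # labels
}

#' Read a cubic MRC map
#'
#' Reads an MRC2014 mode-2 (32-bit float) map. Only cubic maps with an
#' even side length are accepted; the voxel size is taken from the cell
#' dimensions in the header.
#'
#' @param path Path to an `.mrc` file.
#' @return An object of class `mb_volume`: a list with `data` (a cubic
#'   3D array) and `voxel_size` (angstrom per pixel).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- mrc_read_header(con)
  if (hd$mode != 2L)
    stop("MRC format error: only mode 2 (32-bit float) is supported, got mode ", hd$mode)
  if (hd$nx != hd$ny || hd$ny != hd$nz || hd$nz < 2L)
    stop("MRC format error: expected a cubic 3D map, got ",
         hd$nx, " x ", hd$ny, " x ", hd$nz)
  n <- hd$nx * hd$ny * hd$nz
  dat <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(dat) != n) stop("MRC format error: truncated data block")
  voxel <- if (hd$mx > 0 && hd$cella[1] > 0) hd$cella[1] / hd$mx else 1
  mb_volume(array(dat, c(hd$nx, hd$ny, hd$nz)), voxel)
}

#' Write a cubic MRC map
#'
#' @param volume An `mb_volume` (or a plain cubic 3D array, in which
#'   case `voxel_size` must be given).
#' @param path Output path.
#' @param voxel_size Angstrom per pixel; defaults to the volume's own.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(volume, path, voxel_size = NULL) {
  if (is.array(volume) && is.null(voxel_size)) voxel_size <- 1
  vol <- as_mb_volume(volume, voxel_size)
  D <- dim(vol$data)[1]
  con <- file(path, "wb")
  on.exit(close(con))
  mrc_write_header(con, D, D, D, D, D, D, vol$voxel_size)
  writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRCS particle image stack
#'
#' @param path Path to an `.mrcs` stack (mode 2).
#' @return A list with `data` (array of size D x D x N) and `voxel_size`.
#' @export
read_mrcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- mrc_read_header(con)
  if (hd$mode != 2L)
    stop("MRC format error: only mode 2 (32-bit float) is supported")
  if (hd$nx != hd$ny)
    stop("MRC format error: particle images must be square")
  n <- hd$nx * hd$ny * hd$nz
  dat <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  voxel <- if (hd$mx > 0 && hd$cella[1] > 0) hd$cella[1] / hd$mx else 1
  list(data = array(dat, c(hd$nx, hd$ny, hd$nz)), voxel_size = voxel)
}

#' Write an MRCS particle image stack
#'
#' @param images Array of size D x D x N.
#' @param path Output path.
#' @param voxel_size Angstrom per pixel.
#' @return `path`, invisibly.
#' @export
write_mrcs <- function(images, path, voxel_size = 1) {
  d <- dim(images)
  if (length(d) == 2L) { images <- array(images, c(d, 1L)); d <- dim(images) }
  con <- file(path, "wb")
  on.exit(close(con))
  mrc_write_header(con, d[1], d[2], d[3], d[1], d[2], 1L, voxel_size)
  writeBin(as.numeric(images), con, size = 4, endian = "little")
  invisible(path)
}

#' Construct a volume object
#'
#' @param data Cubic 3D array with an even side length.
#' @param voxel_size Angstrom per pixel.
#' @return An object of class `mb_volume`.
#' @export
mb_volume <- function(data, voxel_size = 1) {
  d <- dim(data)
  if (length(d) != 3L || d[1] != d[2] || d[2] != d[3])
    stop("volume must be a cubic 3D array")
  if (d[1] %% 2L != 0L) stop("volume side length must be even")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  structure(list(data = data, voxel_size = voxel_size), class = "mb_volume")
}

as_mb_volume <- function(x, voxel_size = NULL) {
  if (inherits(x, "mb_volume")) {
    if (!is.null(voxel_size)) x$voxel_size <- voxel_size
    return(x)
  }
  mb_volume(x, if (is.null(voxel_size)) 1 else voxel_size)
}

#' @export
print.mb_volume <- function(x, ...) {
  cat(sprintf("<mb_volume> %d^3 voxels, %.3f A/px, range [%.3g, %.3g]\n",
              dim(x$data)[1], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}
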