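#' Read an MRC image or volume
#'
#' Minimal reader for MRC/MRCS files in mode 2 (32-bit float), the
#' interchange format of cryo-EM image processing. The pixel/voxel size is
#' taken from the header cell dimensions; anisotropic cells are rejected.
#'
#' @param path path to an `.mrc`/`.mrcs` file.
#' @return a [mem_image()] (nz = 1), a [mem_volume()] (nz > 1), or a list of
#'   [mem_image()] for a multi-frame stack written by [write_mrc_stack()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  if (!all(is.finite(c(nx, ny, nz))) || nx <= 0 || ny <= 0 || nz <= 0)
    stop("corrupt MRC header: bad dimensions field (nx/ny/nz)")
  if (mode != 2)
    stop(sprintf("unsupported MRC mode %d (field 'mode'; only mode 2 float32 is supported)",
                 mode))
  mxyz <- hdr_int[8:10]                 # words 8-10: mx, my, mz
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  px <- cella[1] / mxyz[1]
  py <- cella[2] / mxyz[2]
  if (abs(px - py) > 1e-4 * px)
    stop("anisotropic cell in MRC header (cella): unsupported")
  seek(con, 1024 + nsymbt)
  n_total <- as.numeric(nx) * ny * nz
  data <- readBin(con, "numeric", n = n_total, size = 4, endian = "little")
  if (length(data) != n_total)
    stop(sprintf("truncated MRC data section: expected %d values, read %d",
                 n_total, length(data)))
  is_stack <- grepl("\\.mrcs$", path, ignore.case = TRUE)
  if (nz == 1) {
    mem_image(frame_to_matrix(data, nx, ny), px)
  } else if (is_stack) {
    lapply(seq_len(nz), function(k) {
      off <- (k - 1) * nx * ny
      mem_image(frame_to_matrix(data[off + seq_len(nx * ny)], nx, ny), px)
    })
  } else {
    pz <- cella[3] / mxyz[3]
    if (abs(px - pz) > 1e-4 * px)
      stop("anisotropic cell in MRC header (cella): unsupported")
    arr <- array(data, c(nx, ny, nz))
    mem_volume(arr, px)
  }
}

# MRC stores rows fastest along x with the origin at the bottom-left;
# convert to the raster convention (row 1 = top).
frame_to_matrix <- function(vals, nx, ny) {
  m <- matrix(vals, nx, ny)          # [ix, iy], iy from bottom
  t(m)[rev(seq_len(ny)), , drop = FALSE]
}

matrix_to_frame <- function(m) {
  ny <- nrow(m)
  as.vector(t(m[rev(seq_len(ny)), , drop = FALSE]))
}

mrc_header <- function(nx, ny, nz, pixel_size, dmin, dmax, dmean) {
  con <- raw(0)
  buf <- rawConnection(con, "wb")
  wi <- function(x) writeBin(as.integer(x), buf, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), buf, size = 4, endian = "little")
  wi(c(nx, ny, nz, 2L, 0L, 0L, 0L))                 # dims, mode 2, nstart
  wi(c(nx, ny, nz))                                 # mx, my, mz
  wf(c(nx, ny, nz) * pixel_size)                    # cella
  wf(c(90, 90, 90))                                 # cellb
  wi(c(1L, 2L, 3L))                                 # mapc, mapr, maps
  wf(c(dmin, dmax, dmean))
  wi(c(1L, 0L))                                     # ispg, nsymbt
  wi(rep(0L, 25))                                   # extra
  wi(c(0L, 0L, 0L))                                 # origin
  writeChar("MAP ", buf, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), buf)  # little-endian stamp
  wf(0)                                             # rms (not tracked)
  wi(0L)                                            # nlabl
  writeBin(raw(800), buf)                           # labels
  out <- rawConnectionValue(buf)
  close(buf)
  out
}

#' Write an image or volume as MRC (mode 2, float32)
#'
#' @param x a [mem_image()] or [mem_volume()].
#' @param path output path.
#' @param em_dark if TRUE, the sign of the data is inverted on output to
#'   mimic raw cryo-EM contrast (protein/membrane dark).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, em_dark = FALSE) {
  if (inherits(x, "mem_image")) {
    data <- matrix_to_frame(x$data)
    dims <- c(ncol(x$data), nrow(x$data), 1L)
    ps <- x$pixel_size
  } else if (inherits(x, "mem_volume")) {
    data <- as.vector(x$data)
    dims <- dim(x$data)
    ps <- x$voxel_size
  } else stop("x must be a mem_image or mem_volume")
  if (em_dark) data <- -data
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(mrc_header(dims[1], dims[2], dims[3], ps,
                      min(data), max(data), mean(data)), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a multi-frame MRCS stack
#'
#' @param images list of [mem_image()]s of identical shape and pixel size.
#' @param path output path (conventionally `.mrcs`).
#' @return `path`, invisibly.
#' @export
write_mrc_stack <- function(images, path) {
  stopifnot(length(images) > 0,
            all(vapply(images, inherits, TRUE, "mem_image")))
  d1 <- dim(images[[1]]$data)
  ps <- images[[1]]$pixel_size
  for (im in images)
    if (!all(dim(im$data) == d1) || im$pixel_size != ps)
      stop("all stack frames must share shape and pixel size")
  data <- unlist(lapply(images, function(im) matrix_to_frame(im$data)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(mrc_header(d1[2], d1[1], length(images), ps,
                      min(data), max(data), mean(data)), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}
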