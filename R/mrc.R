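# Minimal MRC2014 container support: mode 2 (32-bit float) volumes and image
# stacks, voxel size carried in the cella fields. Little-endian files only,
# which covers maps distributed by the EMDB.

mrc_read_header <- function(con) {
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  maps <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 4 * 52)  # skip extra words, jump to MAP stamp
  stamp <- readBin(con, "raw", n = 4)
  seek(con, 1024 + max(0, nsymbt))
  if (any(is.na(ints[1:4])) || any(ints[1:3] <= 0) ||
      any(ints[1:3] > 100000) || !(ints[4] %in% c(0L, 1L, 2L, 6L)))
    stop("corrupt or truncated MRC header")
  list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
       mx = ints[8], my = ints[9], mz = ints[10], cella = cella,
       ispg = ispg, stamp = rawToChar(stamp[1:3]))
}

mrc_read_data <- function(con, h) {
  n <- as.numeric(h$nx) * h$ny * h$nz
  vals <- switch(as.character(h$mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                             endian = "little")),
    stop(sprintf("unsupported MRC mode %d", h$mode)))
  if (length(vals) < n) stop("MRC data block shorter than header promises")
  vals
}

mrc_write <- function(path, data3d, voxel_size, ispg) {
  d <- dim(data3d)
  con <- file(path, "wb")
  on.exit(close(con))
  ints <- integer(10)
  ints[1:3] <- d
  ints[4] <- 2L                     # mode 2: float32
  ints[8:10] <- d
  writeBin(ints, con, size = 4, endian = "little")
  writeBin(as.numeric(d * voxel_size), con, size = 4, endian = "little")
  writeBin(c(90, 90, 90), con, size = 4, endian = "little")
  writeBin(1:3, con, size = 4, endian = "little")
  writeBin(c(min(data3d), max(data3d), mean(data3d)), con, size = 4,
           endian = "little")
  writeBin(c(as.integer(ispg), 0L), con, size = 4, endian = "little")
  writeBin(raw(4 * 25), con)        # extra space incl. exttyp/nversion
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")  # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)        # little-endian stamp
  writeBin(as.numeric(sd(data3d)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")           # nlabl
  writeBin(raw(800), con)
  writeBin(as.vector(data3d), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a cubic density map from an MRC file
#'
#' @param path path to an MRC 3D map (mode 0, 1, 2 or 6; little-endian).
#' @return A [new_volume()] with the voxel size taken from the header cell
#'   dimensions.
#' @export
read_mrc_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  h <- mrc_read_header(con)
  if (h$nx != h$ny || h$ny != h$nz)
    stop(sprintf("not a cubic 3D map (%dx%dx%d); 2D images and non-cubic maps are unsupported",
                 h$nx, h$ny, h$nz))
  vals <- mrc_read_data(con, h)
  vox <- if (h$mx > 0 && h$cella[1] > 0) h$cella[1] / h$mx else 1
  new_volume(array(vals, dim = c(h$nx, h$ny, h$nz)), vox)
}

#' Write a volume to an MRC file
#'
#' Mode 2 (32-bit float), spacegroup 1, voxel size stored in the cell fields.
#' A write/read round trip reproduces the grid at float32 precision.
#'
#' @param volume a `cryo_volume`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc_volume <- function(volume, path) {
  stopifnot(inherits(volume, "cryo_volume"))
  mrc_write(path, volume$grid, volume$voxel_size, ispg = 1L)
  invisible(path)
}

#' Read a particle stack from MRC plus CSV sidecar
#'
#' Reads an MRC image stack (`nz` = number of images) and, when present, the
#' sidecar `<path>.csv` holding `image_index, label_true, rot_deg, tilt_deg,
#' psi_deg, source_id` (ZYZ Euler angles, degrees; labels 0-based).
#'
#' @param path path to the MRC stack.
#' @return A `cryo_stack` object (see [build_heterogeneous_stack()]).
#' @export
read_particle_stack <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  con <- file(path, "rb")
  h <- mrc_read_header(con)
  if (h$nx != h$ny) stop("stack images must be square")
  vals <- mrc_read_data(con, h)
  close(con)
  images <- array(vals, dim = c(h$nx, h$ny, h$nz))
  vox <- if (h$mx > 0 && h$cella[1] > 0) h$cella[1] / h$mx else 1
  labels <- NULL; orientations <- NULL; source_ids <- NULL
  sidecar <- paste0(path, ".csv")
  if (file.exists(sidecar)) {
    meta <- read.csv(sidecar)
    ord <- order(meta$image_index)
    meta <- meta[ord, , drop = FALSE]
    if (nrow(meta) != h$nz) stop("sidecar row count does not match stack")
    if (!is.null(meta$label_true)) labels <- as.integer(meta$label_true)
    if (!is.null(meta$rot_deg))
      orientations <- lapply(seq_len(nrow(meta)), function(i)
        euler_to_matrix(meta$rot_deg[i], meta$tilt_deg[i], meta$psi_deg[i]))
    if (!is.null(meta$source_id)) source_ids <- meta$source_id
  }
  new_particle_stack(images, pixel_size = vox, labels_true = labels,
                     orientations = orientations, source_ids = source_ids)
}

#' Write a particle stack to MRC plus CSV sidecar
#'
#' @param stack a `cryo_stack`.
#' @param path output MRC path; metadata goes to `<path>.csv`.
#' @return `path`, invisibly.
#' @export
write_particle_stack <- function(stack, path) {
  stopifnot(inherits(stack, "cryo_stack"))
  mrc_write(path, stack$images, stack$pixel_size, ispg = 0L)
  n <- dim(stack$images)[3]
  meta <- data.frame(image_index = seq_len(n) - 1L)
  if (!is.null(stack$labels_true)) meta$label_true <- stack$labels_true
  if (!is.null(stack$orientations)) {
    ang <- t(vapply(stack$orientations, matrix_to_euler, numeric(3)))
    meta$rot_deg <- ang[, 1]; meta$tilt_deg <- ang[, 2]; meta$psi_deg <- ang[, 3]
  }
  if (!is.null(stack$source_ids)) meta$source_id <- stack$source_ids
  write.csv(meta, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
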