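#' Construct a particle stack
#'
#' Container for N square projection images with optional ground-truth class
#' labels (0-based integers), orientations and source identifiers.
#'
#' @param images numeric array `H x W x N` with `H == W`.
#' @param pixel_size Angstroms per pixel.
#' @param labels_true optional integer vector of length N, values in
#'   `[0, K)`.
#' @param orientations optional list of N rotation matrices.
#' @param source_ids optional character/integer vector of length N.
#' @return An object of class `cryo_stack`.
#' @export
new_particle_stack <- function(images, pixel_size = 1, labels_true = NULL,
                               orientations = NULL, source_ids = NULL) {
  d <- dim(images)
  if (length(d) != 3 || d[1] != d[2]) stop("images must be an H x W x N array with H == W")
  n <- d[3]
  if (n < 1) stop("stack must contain at least one image")
  if (!is.null(labels_true) && length(labels_true) != n)
    stop("labels_true length must equal the number of images")
  if (!is.null(orientations) && length(orientations) != n)
    stop("orientations length must equal the number of images")
  structure(list(images = images, pixel_size = as.numeric(pixel_size),
                 labels_true = labels_true, orientations = orientations,
                 source_ids = source_ids), class = "cryo_stack")
}

#' @export
print.cryo_stack <- function(x, ...) {
  d <- dim(x$images)
  k <- if (is.null(x$labels_true)) "none" else
    as.character(length(unique(x$labels_true)))
  cat(sprintf("<cryo_stack> %d images of %dx%d px (%.3f A/px), classes: %s\n",
              d[3], d[1], d[2], x$pixel_size, k))
  invisible(x)
}

#' Project a volume along a viewing direction
#'
#' Computes the noise-free projection image: the volume is rotated by the
#' transpose of `orientation` using trilinear interpolation and summed along
#' the z axis (a real-space line integral with unit step). The viewing
#' direction in the volume frame is the third row of the rotation matrix.
#'
#' @param volume a `cryo_volume`.
#' @param orientation 3x3 rotation matrix.
#' @param out_size output image side length, at most the volume dimension.
#' @return `out_size x out_size` numeric matrix.
#' @export
project_volume <- function(volume, orientation, out_size = dim(volume$grid)[1]) {
  stopifnot(inherits(volume, "cryo_volume"))
  D <- dim(volume$grid)[1]
  if (out_size > D) stop("out_size must not exceed the volume dimension")
  if (!is_rotation_matrix(orientation, tol = 1e-8))
    stop("orientation must be a proper rotation matrix")
  .project_volume_cpp(as.numeric(volume$grid), D, orientation,
                      as.integer(out_size))
}

#' Add Gaussian white noise at a fixed SNR
#'
#' The SNR is the variance ratio var(signal)/var(noise), so the added noise
#' is i.i.d. zero-mean Gaussian with variance `var(image)/snr`, computed for
#' this image.
#'
#' @param image numeric matrix (the clean projection).
#' @param snr positive signal-to-noise ratio (cryo-EM data is around 0.1).
#' @return The noisy image; uses the current RNG stream.
#' @export
add_noise_snr <- function(image, snr) {
  if (snr <= 0) stop("snr must be positive")
  v <- var(as.vector(image))
  if (v == 0) stop("image has zero variance; SNR-scaled noise is undefined")
  image + array(rnorm(length(image), sd = sqrt(v / snr)), dim = dim(image))
}

#' Estimate the SNR of a noisy image given its clean counterpart
#'
#' Returns `var(clean) / var(noisy - clean)`, the empirical variance-ratio
#' SNR. Identical images give `Inf` (zero noise energy).
#'
#' @param clean,noisy numeric matrices of the same shape.
#' @return Scalar SNR estimate.
#' @export
estimate_snr <- function(clean, noisy) {
  if (!identical(dim(clean), dim(noisy))) stop("images must have the same shape")
  vn <- var(as.vector(noisy - clean))
  vs <- var(as.vector(clean))
  if (vn == 0) return(Inf)
  vs / vn
}

#' Simulation configuration
#'
#' Bundles the study conditions for generating a heterogeneous stack:
#' number of structures K, projections per structure, SNR, rendered image
#' size and seed. The defaults mirror the standard synthetic protocol:
#' 500 projections per map at SNR 0.1.
#'
#' @param num_classes K >= 2 structures.
#' @param images_per_class projections generated per structure.
#' @param snr positive variance-ratio signal-to-noise ratio.
#' @param image_size rendered projection side length; `NULL` means the
#'   volume dimension.
#' @param seed integer seed controlling orientations and noise.
#' @return A list of class `cryo_simconfig`.
#' @export
simulation_config <- function(num_classes = 3, images_per_class = 500,
                              snr = 0.1, image_size = NULL, seed = 1) {
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (images_per_class < 1) stop("images_per_class must be >= 1")
  if (snr <= 0) stop("snr must be positive")
  structure(list(num_classes = as.integer(num_classes),
                 images_per_class = as.integer(images_per_class),
                 snr = snr, image_size = image_size,
                 seed = as.integer(seed)), class = "cryo_simconfig")
}

#' Build a heterogeneous particle stack from several volumes
#'
#' For each of the K volumes, draws `images_per_class` uniform orientations,
#' projects, and adds Gaussian white noise at the configured SNR (noise
#' variance set per image from that image's clean variance). Ground-truth
#' labels (0-based, in volume order), orientations and source indices are
#' recorded. Deterministic given `cfg$seed`.
#'
#' @param volumes list of `cryo_volume`, all of the same dimension and voxel
#'   size; length must equal `cfg$num_classes`.
#' @param cfg a [simulation_config()].
#' @return A `cryo_stack` of `K * images_per_class` images.
#' @export
build_heterogeneous_stack <- function(volumes, cfg) {
  stopifnot(inherits(cfg, "cryo_simconfig"))
  K <- cfg$num_classes
  if (length(volumes) != K) stop("need exactly num_classes volumes")
  dims <- vapply(volumes, function(v) dim(v$grid)[1], integer(1))
  vox <- vapply(volumes, function(v) v$voxel_size, numeric(1))
  if (length(unique(dims)) != 1 || length(unique(vox)) != 1)
    stop("all volumes must share dimension and voxel size")
  D <- dims[1]
  P <- if (is.null(cfg$image_size)) D else as.integer(cfg$image_size)
  m <- cfg$images_per_class
  N <- K * m
  images <- array(0, dim = c(P, P, N))
  orientations <- vector("list", N)
  labels <- integer(N)
  with_seed(cfg$seed, {
    idx <- 0L
    for (k in seq_len(K)) {
      ors <- sample_orientations_uniform(
        m, seed = derive_seed(cfg$seed, paste0("so3-", k)))
      for (i in seq_len(m)) {
        idx <- idx + 1L
        clean <- project_volume(volumes[[k]], ors[[i]], P)
        images[, , idx] <- add_noise_snr(clean, cfg$snr)
        orientations[[idx]] <- ors[[i]]
        labels[idx] <- k - 1L
      }
    }
  })
  new_particle_stack(images, pixel_size = vox[1], labels_true = labels,
                     orientations = orientations,
                     source_ids = labels)
}
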