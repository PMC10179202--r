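# Direct-Fourier reconstruction via the central-slice theorem, and Fourier
# shell correlation. The reconstructor is deliberately simple: it serves to
# compare reconstructions between classified subsets, not to compete with
# production refinement packages.

# centred 2D DFT: origin of both space and frequency at index n/2 (0-based)
centered_fft2 <- function(img) fftshift2(fft(ifftshift2(img)))

#' Reconstruct a volume from projections by direct Fourier inversion
#'
#' Each image's centred 2D DFT is inserted as a central slice of the 3D
#' Fourier transform, oriented by the image's rotation, with trilinear
#' gridding and overlap weighting; the accumulated transform is averaged and
#' inverted. Uses the stack's recorded (ground-truth) orientations.
#'
#' @param stack a `cryo_stack` with orientations.
#' @param subset indices of the images to use (default: all).
#' @param size output volume dimension; images are Fourier-cropped to this
#'   size first (default: image size).
#' @return A `cryo_volume` of dimension `size`.
#' @export
backproject_reconstruct <- function(stack, subset = NULL, size = NULL) {
  stopifnot(inherits(stack, "cryo_stack"))
  n_all <- dim(stack$images)[3]
  if (is.null(subset)) subset <- seq_len(n_all)
  if (length(subset) == 0) stop("subset is empty")
  if (is.null(stack$orientations) ||
      any(vapply(stack$orientations[subset], is.null, logical(1))))
    stop("orientations are required for reconstruction")
  P <- if (is.null(size)) dim(stack$images)[1] else as.integer(size)
  acc <- array(complex(real = 0), dim = c(P, P, P))
  wt <- array(0, dim = c(P, P, P))
  chunk <- 128L
  for (s in seq(1, length(subset), by = chunk)) {
    idx <- subset[s:min(s + chunk - 1, length(subset))]
    fstack <- array(complex(real = 0), dim = c(P, P, length(idx)))
    rots <- array(0, dim = c(3, 3, length(idx)))
    for (m in seq_along(idx)) {
      img <- stack$images[, , idx[m]]
      if (nrow(img) != P) img <- downsample_image(img, P)
      fstack[, , m] <- centered_fft2(img)
      rots[, , m] <- stack$orientations[[idx[m]]]
    }
    part <- .insert_slices_cpp(fstack, dim(fstack), as.numeric(rots))
    acc <- acc + part$acc
    wt <- wt + part$wt
  }
  F3 <- array(complex(real = 0), dim = dim(acc))
  nz <- wt > 1e-8
  F3[nz] <- acc[nz] / wt[nz]
  vol <- Re(fftshift3(fft(ifftshift3(F3), inverse = TRUE))) / (P^3)
  # scale: a projection integrates D voxels per ray at the original size
  new_volume(vol, voxel_size = stack$pixel_size * dim(stack$images)[1] / P)
}

#' Fourier shell correlation between two volumes
#'
#' The normalised cross-correlation of the two 3D Fourier transforms over
#' concentric shells of width one Fourier voxel:
#' `FSC(s) = Re(sum F_a conj(F_b)) / sqrt(sum |F_a|^2 sum |F_b|^2)`,
#' with voxels binned to shells by rounding the radial frequency magnitude.
#'
#' @param a,b `cryo_volume` objects of equal dimension and voxel size.
#' @return A data frame of class `cryo_fsc`: `shell` (0..D/2), `freq`
#'   (cycles/voxel), `freq_invA` (1/Angstrom) and `fsc`.
#' @export
fsc_curve <- function(a, b) {
  stopifnot(inherits(a, "cryo_volume"), inherits(b, "cryo_volume"))
  if (!identical(dim(a$grid), dim(b$grid))) stop("volume dimensions differ")
  D <- dim(a$grid)[1]
  Fa <- fft(a$grid)
  Fb <- fft(b$grid)
  f1 <- c(0:(D %/% 2), -((D - D %/% 2 - 1):1))  # unshifted frequency index
  r <- sqrt(outer(outer(f1^2, f1^2, `+`), f1^2, `+`))
  shell <- pmin(as.integer(round(r)), D)
  num <- Re(Fa * Conj(Fb))
  d1 <- Mod(Fa)^2
  d2 <- Mod(Fb)^2
  smax <- D %/% 2
  keep <- shell <= smax
  sn <- rowsum(num[keep], shell[keep])
  s1 <- rowsum(d1[keep], shell[keep])
  s2 <- rowsum(d2[keep], shell[keep])
  denom <- sqrt(s1 * s2)
  fsc <- ifelse(denom > 0, sn / denom, 0)
  out <- data.frame(shell = as.integer(rownames(sn)),
                    freq = as.integer(rownames(sn)) / D,
                    freq_invA = as.integer(rownames(sn)) / (D * a$voxel_size),
                    fsc = as.numeric(fsc))
  class(out) <- c("cryo_fsc", "data.frame")
  out
}

#' Resolution at an FSC threshold
#'
#' First spatial frequency at which the FSC curve drops below `threshold`,
#' linearly interpolated between shells and converted to Angstroms. A curve
#' that never crosses reports the Nyquist resolution `2 * voxel_size`.
#'
#' @param curve a `cryo_fsc` data frame.
#' @param threshold value in (0, 1), e.g. 0.143 or 0.5.
#' @param voxel_size Angstroms per voxel.
#' @return Resolution in Angstroms.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.5, voxel_size = 1) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  f <- curve$freq
  y <- curve$fsc
  below <- which(y < threshold)
  below <- below[below > 1]
  if (length(below) == 0) return(2 * voxel_size)
  i <- below[1]
  f_cross <- f[i - 1] + (y[i - 1] - threshold) / (y[i - 1] - y[i]) *
    (f[i] - f[i - 1])
  voxel_size / f_cross
}

#' Area under an FSC curve
#'
#' Trapezoidal integral of FSC over spatial frequency; a scalar summary used
#' to compare reconstruction fidelity between subsets (more and better
#' images give larger area).
#'
#' @param curve a `cryo_fsc` data frame.
#' @return Scalar.
#' @export
fsc_auc <- function(curve) {
  f <- curve$freq
  y <- curve$fsc
  sum(diff(f) * (head(y, -1) + y[-1]) / 2)
}

#' Write an FSC curve to CSV
#'
#' @param curve a `cryo_fsc`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fsc_csv <- function(curve, path) {
  write.csv(data.frame(shell_radius_cycles_per_voxel = curve$freq,
                       resolution_angstrom = ifelse(curve$freq > 0,
                                                    1 / curve$freq_invA, Inf),
                       fsc = curve$fsc),
            path, row.names = FALSE)
  invisible(path)
}
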