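#' Construct a cubic density volume
#'
#' A volume is the package's container for a 3D electron density map: a cubic
#' grid of real values plus the physical voxel size.
#'
#' @param grid numeric 3D array with equal extents in all three dimensions.
#' @param voxel_size positive scalar, Angstroms per voxel edge.
#' @return An object of class `cryo_volume` with elements `grid` and
#'   `voxel_size`.
#' @export
new_volume <- function(grid, voxel_size = 1) {
  d <- dim(grid)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("volume grid must be a cubic 3D array")
  if (!all(is.finite(grid))) stop("volume grid contains non-finite values")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a positive scalar")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size)),
            class = "cryo_volume")
}

#' @export
print.cryo_volume <- function(x, ...) {
  d <- dim(x$grid)[1]
  cat(sprintf("<cryo_volume> %d^3 voxels, %.3f A/voxel, density range [%.3g, %.3g]\n",
              d, x$voxel_size, min(x$grid), max(x$grid)))
  invisible(x)
}

#' Generate a phantom density volume
#'
#' Builds a synthetic cubic density map as a sum of anisotropic, axis-aligned
#' 3D Gaussian blobs. Blob centres, widths and amplitudes are a deterministic
#' function of `(class_index, seed)`, so distinct class indices give distinct
#' structures and the same pair always reproduces the same map. These
#' phantoms stand in for deposited density maps in simulations and tests; a
#' phantom is labelled synthetic by construction and carries no relation to
#' any deposited structure.
#'
#' Each class places its blobs around a class-characteristic shell radius
#' and uses a class-characteristic blob width (both spaced by a golden-ratio
#' sequence over class indices and scaled by `separation`), so different
#' classes differ in their rotationally stable radial mass profile -- the
#' kind of gross size/compactness difference that also distinguishes real
#' macromolecular complexes in projection -- while orientation only moves
#' mass around within that profile.
#'
#' @param class_index integer identifying the structure (distinct indices
#'   yield distinct blob configurations).
#' @param size grid dimension D (D >= 32).
#' @param num_blobs baseline number of Gaussian blobs; the realised count is
#'   modulated by the class granularity signature (0 gives the zero
#'   volume).
#' @param separation positive scalar scaling how strongly the shell radius
#'   and blob width differ between class indices; larger values make classes
#'   easier to tell apart in projection.
#' @param seed integer seed.
#' @param voxel_size Angstroms per voxel.
#' @return A [new_volume()] object.
#' @export
#' @examples
#' v <- make_phantom_volume(0, 64, num_blobs = 4, seed = 1)
#' dim(v$grid)
make_phantom_volume <- function(class_index, size, num_blobs = 8,
                                separation = 1, seed = 1, voxel_size = 1) {
  if (size < 32) stop("size must be >= 32")
  if (num_blobs < 0) stop("num_blobs must be >= 0")
  grid <- array(0, dim = c(size, size, size))
  if (num_blobs > 0) {
    ci <- as.integer(class_index)
    # two-dimensional class signature, spread over class indices by
    # low-discrepancy (golden-ratio) sequences and scaled by `separation`:
    #   u1 -- overall object scale (shell radius and blob width together)
    #   u2 -- granularity (how many blobs the mass is split into)
    # both are stable under the projection direction, so classes stay
    # distinguishable across uniformly distributed orientations
    u1 <- (ci * 0.6180339887) %% 1
    u2 <- (ci * 0.7548776662) %% 1
    oscale <- 0.35 + separation * 1.3 * u1
    shell <- size / 6 * oscale
    wscale <- size * 0.06 * oscale
    nb <- max(6, round(num_blobs * (0.4 + separation * 1.2 * u2)))
    pars <- with_seed(seed * 1009L + ci * 131L + 17L, {
      dirs <- matrix(rnorm(3 * nb), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      list(dirs = dirs, radii = shell * runif(nb, 0.85, 1.15),
           sigmas = matrix(wscale * runif(3 * nb, 0.8, 1.25), ncol = 3),
           amps = runif(nb, 0.8, 1.2))
    })
    num_blobs <- nb
    ctr <- size / 2            # matches the projection/FFT centre convention
    ax <- seq_len(size) - 1
    for (b in seq_len(num_blobs)) {
      cen <- ctr + pars$dirs[b, ] * pars$radii[b]
      sig <- pars$sigmas[b, ]
      gx <- exp(-(ax - cen[1])^2 / (2 * sig[1]^2))
      gy <- exp(-(ax - cen[2])^2 / (2 * sig[2]^2))
      gz <- exp(-(ax - cen[3])^2 / (2 * sig[3]^2))
      grid <- grid + pars$amps[b] * (gx %o% gy %o% gz)
    }
  }
  new_volume(grid, voxel_size)
}

#' Normalised cross-correlation between two volumes
#'
#' Pearson correlation of the two density grids, used e.g. to check that two
#' phantom classes are structurally distinct.
#'
#' @param a,b `cryo_volume` objects of equal dimension.
#' @return Scalar in `[-1, 1]`.
#' @export
volume_ncc <- function(a, b) {
  stopifnot(inherits(a, "cryo_volume"), inherits(b, "cryo_volume"))
  if (!identical(dim(a$grid), dim(b$grid))) stop("volume dimensions differ")
  cor(as.vector(a$grid), as.vector(b$grid))
}
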