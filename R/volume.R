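#' 3D image volume with world-space geometry
#'
#' A `volume3d` is the basic carrier for all volumetric data in the package:
#' PET frames, T2*-weighted MRI, binary masks, bias fields and integer atlas
#' label volumes. It bundles a numeric 3D array with a 4x4 voxel-to-world
#' affine (NIfTI convention: 0-based voxel indices, RAS world coordinates in
#' millimetres) and an optional unit string.
#'
#' @param data numeric 3D array of voxel values.
#' @param affine 4x4 voxel-to-world matrix. If `NULL`, one is built from
#'   `voxel_size` with the world origin at the grid centre.
#' @param voxel_size length-3 voxel edge lengths in mm (used only when
#'   `affine` is `NULL`).
#' @param units optional unit string (e.g. `"MBq/cm3"`), kept as metadata.
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(0, c(8, 8, 8)), voxel_size = c(0.2, 0.2, 0.2))
#' vox_size(v)
#' @export
volume3d <- function(data, affine = NULL, voxel_size = c(1, 1, 1), units = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (is.null(affine)) {
    voxel_size <- rep_len(as.numeric(voxel_size), 3L)
    affine <- diag(c(voxel_size, 1))
    # centre of the grid sits at world (0,0,0)
    affine[1:3, 4] <- -voxel_size * (dim(data) - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  structure(list(data = data, affine = affine, units = units),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, voxel size %s mm%s\n",
              d[1], d[2], d[3],
              paste(signif(vox_size(x), 4), collapse = " x "),
              if (is.null(x$units)) "" else paste0(", units: ", x$units)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Voxel edge lengths of a volume, in mm
#' @param vol a [volume3d()].
#' @return numeric length-3 vector.
#' @export
vox_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Convert voxel indices to world coordinates
#'
#' Indices are 1-based (R convention); the stored affine maps 0-based indices,
#' so the conversion subtracts 1 before applying it.
#'
#' @param vol a [volume3d()].
#' @param idx n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- rbind3(idx)
  t(vol$affine[1:3, 1:3] %*% t(idx - 1) + vol$affine[1:3, 4])
}

#' Convert world coordinates to (fractional, 1-based) voxel indices
#' @param vol a [volume3d()].
#' @param pts n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @return n x 3 matrix of fractional 1-based voxel indices.
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- rbind3(pts)
  inv <- solve(vol$affine)
  t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4]) + 1
}

# coerce a length-3 vector or n x 3 matrix to n x 3 matrix
rbind3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  as.matrix(x)
}

# world coordinates of every voxel centre, as an (n_voxels x 3) matrix in
# array (column-major) order
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  idx <- cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
               rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               rep(seq_len(d[3]), each = d[1] * d[2]))
  voxel_to_world(vol, idx)
}

#' Resample a volume onto a reference grid under a world-space transform
#'
#' Maps each reference voxel centre back through the inverse of `transform`
#' into the source volume's frame and interpolates. Used to bring the
#' co-registered MRI (and its label maps) onto the atlas/PET grid.
#'
#' @param volume source [volume3d()].
#' @param transform a [rigid_transform()] or [affine_transform()] mapping the
#'   source volume's world frame to the reference's world frame.
#' @param reference [volume3d()] whose grid defines the output.
#' @param interpolation `"trilinear"` for intensity images, `"nearest"` for
#'   label and mask volumes (the output label set is then a subset of the
#'   input's).
#' @return A [volume3d()] on the reference grid; voxels mapping outside the
#'   source field of view are set to 0.
#' @export
resample <- function(volume, transform, reference,
                     interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  inv <- invert_transform(transform)
  w_ref <- grid_world_coords(reference)
  w_src <- apply_transform(inv, w_ref)
  vox <- world_to_voxel(volume, w_src)
  out <- interp3(volume$data, vox, interpolation)
  volume3d(array(out, dim(reference$data)), affine = reference$affine,
           units = volume$units)
}

# vectorised 3D interpolation at fractional 1-based voxel coordinates
interp3 <- function(arr, vox, interpolation) {
  d <- dim(arr)
  n <- nrow(vox)
  out <- numeric(n)
  if (interpolation == "nearest") {
    i <- round(vox[, 1]); j <- round(vox[, 2]); k <- round(vox[, 3])
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out[ok] <- arr[cbind(i[ok], j[ok], k[ok])]
    return(out)
  }
  eps <- 1e-9
  ok <- vox[, 1] >= 1 - eps & vox[, 1] <= d[1] + eps &
    vox[, 2] >= 1 - eps & vox[, 2] <= d[2] + eps &
    vox[, 3] >= 1 - eps & vox[, 3] <= d[3] + eps
  # clamp so points on the upper face interpolate within the last cell
  i0 <- pmin(pmax(floor(vox[, 1]), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(vox[, 2]), 1), d[2] - 1)
  k0 <- pmin(pmax(floor(vox[, 3]), 1), d[3] - 1)
  fx <- vox[, 1] - i0; fy <- vox[, 2] - j0; fz <- vox[, 3] - k0
  if (any(ok)) {
    i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
    fx <- pmin(pmax(fx[ok], 0), 1); fy <- pmin(pmax(fy[ok], 0), 1)
    fz <- pmin(pmax(fz[ok], 0), 1)
    g <- function(di, dj, dk) arr[cbind(i0 + di, j0 + dj, k0 + dk)]
    out[ok] <-
      g(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
      g(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
      g(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
      g(1, 1, 0) * fx       * fy       * (1 - fz) +
      g(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
      g(1, 0, 1) * fx       * (1 - fy) * fz +
      g(0, 1, 1) * (1 - fx) * fy       * fz +
      g(1, 1, 1) * fx       * fy       * fz
  }
  out
}

#' Separable 3D Gaussian blur
#'
#' Emulates the scanner point-spread function on phantom PET frames. The blur
#' is applied as one banded-matrix multiplication per axis with a kernel
#' truncated at 4 sigma; boundaries behave as zero padding (signal leaks out
#' of the field of view, as in a real reconstruction).
#'
#' @param arr 3D numeric array.
#' @param sigma_vox Gaussian sigma per axis, in voxels (scalar or length 3).
#'   Values below 1e-6 leave that axis untouched.
#' @return blurred array of the same dimensions.
#' @export
gauss_blur3 <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-6) next
    n <- d[ax]
    r <- ceiling(4 * s)
    ker <- dnorm(seq(-r, r), sd = s)
    ker <- ker / sum(ker)
    K <- matrix(0, n, n)
    for (o in seq(-r, r)) {
      j <- seq_len(n) + o
      keep <- j >= 1 & j <= n
      K[cbind(which(keep), j[keep])] <- ker[o + r + 1]
    }
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- K %*% matrix(a, nrow = n)
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti} preserving the voxel-to-world affine.
#'
#' @param vol a [volume3d()] (for writing).
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_volume()` returns a [volume3d()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  volume3d(array(as.numeric(img), dim(img)),
           affine = matrix(as.numeric(aff), 4, 4))
}
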