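#' Rigid and affine world-space transforms
#'
#' Transforms map world coordinates (mm) of one modality frame into another:
#' rigid for MRI-to-PET co-registration, affine for normalisation of an
#' animal's frame to atlas space. A rigid transform stores a proper rotation
#' (orthonormal, det = +1) and a translation; an affine transform any
#' invertible 3x3 matrix plus translation.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector, mm.
#' @return an object of class `rigid_transform` (also `spatial_transform`).
#' @examples
#' t <- rigid_transform(rot_z(pi / 6), c(1, 2, 3))
#' apply_transform(t, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("`rotation` must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("`rotation` is not orthonormal")
  if (det(rotation) < 0)
    stop("`rotation` has determinant -1 (reflection, not a rotation)")
  structure(list(matrix = rotation, translation = as.numeric(translation)),
            class = c("rigid_transform", "spatial_transform"))
}

#' @param matrix 3x3 invertible matrix (affine case).
#' @rdname rigid_transform
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(3L, 3L)))
    stop("`matrix` must be 3x3")
  if (abs(det(matrix)) < 1e-12)
    stop("`matrix` is singular")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = c("affine_transform", "spatial_transform"))
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' Rotation about the z axis
#' @param theta angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

#' Apply a transform to points
#' @param transform a `spatial_transform`.
#' @param pts n x 3 matrix or length-3 vector of world coordinates (mm), or a
#'   [landmark_set()].
#' @return transformed points in the same form.
#' @export
apply_transform <- function(transform, pts) {
  if (inherits(pts, "landmark_set")) {
    xyz <- apply_transform(transform, as.matrix(pts[, c("x", "y", "z")]))
    return(landmark_set(pts$name, xyz))
  }
  vec <- is.null(dim(pts))
  pts <- rbind3(pts)
  out <- t(transform$matrix %*% t(pts) + transform$translation)
  if (vec) drop(out) else out
}

#' Compose two transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a` (i.e. the function
#' composition a o b). Rigidity is preserved when both inputs are rigid.
#'
#' @param a,b `spatial_transform` objects.
#' @return the composed transform.
#' @export
compose_transforms <- function(a, b) {
  m <- a$matrix %*% b$matrix
  t <- a$matrix %*% b$translation + a$translation
  if (inherits(a, "rigid_transform") && inherits(b, "rigid_transform"))
    rigid_transform(m, t)
  else
    affine_transform(m, t)
}

#' Invert a transform
#' @param transform a `spatial_transform`.
#' @return the inverse transform (same class).
#' @export
invert_transform <- function(transform) {
  minv <- solve(transform$matrix)
  tinv <- -minv %*% transform$translation
  if (inherits(transform, "rigid_transform"))
    rigid_transform(t(transform$matrix), drop(tinv))
  else
    affine_transform(minv, drop(tinv))
}

#' 4x4 homogeneous matrix form of a transform
#' @param transform a `spatial_transform`.
#' @return 4x4 matrix.
#' @export
as_matrix4 <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$matrix
  m[1:3, 4] <- transform$translation
  m
}

#' Build a transform from a 4x4 homogeneous matrix
#' @param m 4x4 matrix with last row (0,0,0,1).
#' @return a `rigid_transform` when the linear part is a proper rotation,
#'   otherwise an `affine_transform`.
#' @export
transform_from_matrix4 <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4, 4)))
  lin <- m[1:3, 1:3]
  tr <- m[1:3, 4]
  rigid <- max(abs(crossprod(lin) - diag(3))) < 1e-6 && det(lin) > 0
  if (rigid) rigid_transform(lin, tr) else affine_transform(lin, tr)
}

#' Serialise a transform to / from JSON
#'
#' Transforms are stored as the 4x4 homogeneous matrix in row-major order,
#' a portable interchange form.
#'
#' @param transform a `spatial_transform`.
#' @param path JSON file path.
#' @return `read_transform_json()` returns the transform; the writer returns
#'   `path` invisibly.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(matrix4_row_major = as.vector(t(as_matrix4(transform))),
         type = class(transform)[1]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(obj$matrix4_row_major, 4, 4, byrow = TRUE)
  transform_from_matrix4(m)
}

#' Named fiducial landmark set
#'
#' The six skull-fixed fiducials used for co-registration (left/right eyes,
#' mandibular condyles, cochleae), as a data frame with columns `name`, `x`,
#' `y`, `z` (world mm).
#'
#' @param name character vector of unique landmark names.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return a `landmark_set` (a data frame).
#' @export
landmark_set <- function(name, xyz) {
  xyz <- rbind3(xyz)
  dimnames(xyz) <- NULL
  if (anyDuplicated(name)) stop("landmark names must be unique")
  if (length(name) != nrow(xyz)) stop("one name per point required")
  structure(data.frame(name = as.character(name), x = xyz[, 1], y = xyz[, 2],
                       z = xyz[, 3], stringsAsFactors = FALSE),
            class = c("landmark_set", "data.frame"))
}

#' Read / write a landmark set as CSV (columns name, x, y, z; mm)
#' @param lms a [landmark_set()] (for writing).
#' @param path CSV path.
#' @return `read_landmarks()` returns a [landmark_set()].
#' @export
write_landmarks <- function(lms, path) {
  utils::write.csv(as.data.frame(lms), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  landmark_set(d$name, as.matrix(d[, c("x", "y", "z")]))
}
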