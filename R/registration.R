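#' Least-squares rigid fit between two landmark sets
#'
#' Closed-form solution (centroid alignment followed by SVD of the
#' cross-covariance, with a reflection guard) of the rigid transform
#' minimising the root-mean-square distance between paired fiducials — the
#' standard Kabsch/Procrustes estimator. Used to co-register the MRI frame to
#' the PET/CT frame from the six skull fiducials.
#'
#' @param src,dst [landmark_set()]s with identical point names. `dst` is the
#'   target frame: the returned transform maps `src` world coordinates onto
#'   `dst` world coordinates.
#' @return list with elements `transform` (a [rigid_transform()]) and
#'   `rms_mm`, the post-fit root-mean-square residual distance.
#' @examples
#' lm <- landmark_set(letters[1:4],
#'                    rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(0, 0, 6)))
#' fit <- estimate_rigid(lm, apply_transform(rigid_transform(rot_z(0.2),
#'                                                           c(1, 2, 3)), lm))
#' fit$rms_mm
#' @export
estimate_rigid <- function(src, dst) {
  p <- matched_points(src, dst)
  X <- p$src; Y <- p$dst
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  if (qr(Xc)$rank < 2)
    stop("degenerate landmark geometry: points are collinear or coincident")
  H <- crossprod(Xc, Yc)              # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))      # reflection guard
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cy - drop(R %*% cx)
  fit <- rigid_transform(R, tr)
  res <- apply_transform(fit, X) - Y
  list(transform = fit, rms_mm = sqrt(mean(rowSums(res^2))))
}

#' Least-squares affine fit between two landmark sets
#'
#' Ordinary least-squares 12-parameter fit, used as the spatial-normalisation
#' step mapping an animal's frame to atlas space. Exact (zero residual) when
#' `dst` is an affine image of `src`.
#'
#' @inheritParams estimate_rigid
#' @return list with `transform` (an [affine_transform()]) and `rms_mm`.
#' @export
estimate_affine <- function(src, dst) {
  p <- matched_points(src, dst)
  X <- p$src; Y <- p$dst
  if (nrow(X) < 4)
    stop("affine fit needs at least 4 landmarks")
  D <- cbind(1, X)
  if (qr(D)$rank < 4)
    stop("degenerate landmark geometry: points are coplanar")
  B <- qr.solve(D, Y)                 # 4x3: row 1 translation, rows 2-4 linear
  fit <- affine_transform(t(B[-1, , drop = FALSE]), B[1, ])
  res <- apply_transform(fit, X) - Y
  list(transform = fit, rms_mm = sqrt(mean(rowSums(res^2))))
}

# align two landmark sets by name, erroring on mismatch
matched_points <- function(src, dst) {
  if (!inherits(src, "landmark_set") || !inherits(dst, "landmark_set"))
    stop("`src` and `dst` must be landmark_set objects")
  if (!setequal(src$name, dst$name))
    stop("landmark names differ between the two sets: ",
         paste(union(setdiff(src$name, dst$name), setdiff(dst$name, src$name)),
               collapse = ", "))
  i <- match(src$name, dst$name)
  list(src = unname(as.matrix(src[, c("x", "y", "z")])),
       dst = unname(as.matrix(dst[i, c("x", "y", "z")])))
}

#' Angle of a rotation, in degrees
#'
#' Geodesic distance of a rotation matrix from the identity; used to report
#' registration recovery error.
#'
#' @param rotation 3x3 rotation matrix (or a [rigid_transform()]).
#' @return angle in degrees, in `[0, 180]`.
#' @export
rotation_angle_deg <- function(rotation) {
  if (inherits(rotation, "spatial_transform")) rotation <- rotation$matrix
  ct <- (sum(diag(rotation)) - 1) / 2
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}
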