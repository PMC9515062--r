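#' Horn's closed-form absolute orientation
#'
#' Least-squares rigid transform between matched point sets by the
#' unit-quaternion method: the optimal rotation is the eigenvector of the
#' largest eigenvalue of the 4x4 matrix built from the cross-covariance of
#' the centered point sets, the translation follows from the centroids. No
#' scaling and no reflection are estimated. The fiducial registration
#' error (FRE) is the RMS of the per-point residuals.
#'
#' @param source n x 3 matrix of points (n >= 3, not collinear), mm.
#' @param target n x 3 matrix of matched points, mm.
#' @return A list with elements `transform` (a [rigid_transform()] mapping
#'   source to target), `fre` (mm) and `residuals` (per-point residual
#'   norms, mm).
#' @examples
#' s <- matrix(rnorm(24), 8)
#' tf <- rigid_transform(rotation_about_axis("z", 40), c(5, -2, 1))
#' horn_absolute_orientation(s, transform_points(tf, s))$fre
#' @export
horn_absolute_orientation <- function(source, target) {
  s <- as.matrix(source); t_ <- as.matrix(target)
  if (!identical(dim(s), dim(t_)) || ncol(s) != 3L)
    stop("source and target must be matched n x 3 point sets")
  n <- nrow(s)
  if (n < 3L) stop("at least 3 point pairs are required")
  sc <- colMeans(s); tc <- colMeans(t_)
  s0 <- sweep(s, 2L, sc); t0 <- sweep(t_, 2L, tc)
  sv <- svd(s0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12))
    stop("degenerate source points: collinear configurations do not determine a rotation")
  h <- crossprod(s0, t0)  # H[i, j] = sum_k s0[k, i] * t0[k, j]
  sxx <- h[1, 1]; sxy <- h[1, 2]; sxz <- h[1, 3]
  syx <- h[2, 1]; syy <- h[2, 2]; syz <- h[2, 3]
  szx <- h[3, 1]; szy <- h[3, 2]; szz <- h[3, 3]
  nmat <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz), 4L, 4L)
  q <- eigen(nmat, symmetric = TRUE)$vectors[, 1]
  r <- quaternion_to_rotation(q)
  tf <- rigid_transform(r, tc - drop(r %*% sc))
  res <- sqrt(rowSums((transform_points(tf, s) - t_)^2))
  list(transform = tf, fre = sqrt(mean(res^2)), residuals = res)
}
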