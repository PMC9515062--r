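#' Rigid transforms
#'
#' A rigid transform is a proper rotation plus a translation in millimetres,
#' mapping points as `p' = R p + t`. It is the currency of the package: the
#' marker-to-image pose estimated by [localize_marker()], the ground-truth
#' station poses of a [phantom_spec()], and the links of a CT-to-ultrasound
#' transform chain are all `rigid_transform` objects.
#'
#' @param rotation 3x3 proper orthonormal matrix (`det = +1`).
#' @param translation numeric length-3 vector, millimetres.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' tf <- rigid_transform(rotation_about_axis("z", 90), c(10, 0, 0))
#' transform_points(tf, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal (|R'R - I| > 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix is not proper (det != +1); reflections are not rigid transforms")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param x object to test or convert.
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (mm)\n")
  m <- cbind(x$rotation, x$translation)
  dimnames(m) <- list(c("x", "y", "z"), c("r1", "r2", "r3", "t"))
  print(round(m, 6))
  invisible(x)
}

#' @describeIn rigid_transform homogeneous 4x4 matrix representation.
#' @param ... unused.
#' @export
as.matrix.rigid_transform <- function(x, ...) {
  rbind(cbind(x$rotation, x$translation), c(0, 0, 0, 1))
}

#' Build a rigid transform from a homogeneous 4x4 matrix
#'
#' @param m 4x4 matrix with last row (0, 0, 0, 1).
#' @return A [rigid_transform()].
#' @export
rigid_transform_from_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(identical(dim(m), c(4L, 4L)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row of a homogeneous rigid matrix must be (0, 0, 0, 1)")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points numeric length-3 vector or n x 3 matrix of points (mm).
#' @return Points in the target frame, same shape as the input.
#' @export
transform_points <- function(transform, points) {
  stopifnot(is_rigid_transform(transform))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), 1L) else as.matrix(points)
  stopifnot(ncol(p) == 3L)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, "+")
  if (vec) drop(out) else out
}

#' Compose and invert rigid transforms
#'
#' `compose(a, b)` returns the transform whose action is `a(b(p))`;
#' `invert(a)` returns the inverse so that `compose(invert(a), a)` is the
#' identity.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose <- function(a, b) {
  stopifnot(is_rigid_transform(a), is_rigid_transform(b))
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose
#' @export
invert <- function(a) {
  stopifnot(is_rigid_transform(a))
  rt <- t(a$rotation)
  rigid_transform(rt, drop(-rt %*% a$translation))
}

#' Compose a named chain of rigid transforms
#'
#' Convenience for multi-frame setups such as the CT-to-ultrasound chain,
#' where the overall transform is assembled from the marker-to-CT pose
#' (inverted), the sensor-holder-to-marker offset, and the tracking and
#' ultrasound calibration transforms. Transforms are listed in application
#' order: the first element is applied first, i.e. the result acts as
#' `T_n(...T_2(T_1(p))...)`.
#'
#' @param transforms list of [rigid_transform()] objects, in application
#'   order. Names, if present, are used in error messages.
#' @param invert logical vector (recycled) flagging elements to invert
#'   before composition.
#' @return The composed [rigid_transform()].
#' @examples
#' a <- rigid_transform(rotation_about_axis("x", 30), c(1, 2, 3))
#' compose_chain(list(a, a), invert = c(FALSE, TRUE))  # identity
#' @export
compose_chain <- function(transforms, invert = FALSE) {
  stopifnot(is.list(transforms), length(transforms) >= 1L)
  invert <- rep_len(as.logical(invert), length(transforms))
  for (i in seq_along(transforms)) {
    if (!is_rigid_transform(transforms[[i]])) {
      nm <- names(transforms)[i]
      stop("chain element ", if (!is.null(nm) && nzchar(nm)) nm else i,
           " is not a rigid_transform")
    }
  }
  out <- rigid_transform()
  for (i in seq_along(transforms)) {
    ti <- if (invert[i]) invert(transforms[[i]]) else transforms[[i]]
    out <- compose(ti, out)  # applied after everything before it
  }
  out
}

#' Elementary rotations and Euler angles
#'
#' Rotations are parameterized as intrinsic Z-Y-X Euler angles in degrees:
#' `R = Rz(a) Ry(b) Rx(c)`. This is the convention used for the rotational
#' clipping-precision statistic; it is configurable only in the sense that
#' all functions work on rotation matrices, so any other convention can be
#' layered on top.
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle_deg rotation angle in degrees.
#' @return `rotation_about_axis()` and `euler_to_rotation()` return a 3x3
#'   rotation matrix; `to_euler_angles()` returns a length-3 numeric vector
#'   `c(z, y, x)` in degrees with attribute `gimbal_lock` set to `TRUE` when
#'   the middle angle is within ~1e-7 degrees of +/-90 (where the first and
#'   last angles are not separable).
#' @examples
#' to_euler_angles(rigid_transform(rotation_about_axis("z", 90)))
#' @export
rotation_about_axis <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L),
    y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3L),
    z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L))
}

#' @rdname rotation_about_axis
#' @param angles_deg length-3 vector `c(z, y, x)` of intrinsic Z-Y-X angles,
#'   degrees.
#' @export
euler_to_rotation <- function(angles_deg) {
  stopifnot(length(angles_deg) == 3L)
  rotation_about_axis("z", angles_deg[1]) %*%
    rotation_about_axis("y", angles_deg[2]) %*%
    rotation_about_axis("x", angles_deg[3])
}

#' @rdname rotation_about_axis
#' @param transform a [rigid_transform()] (or 3x3 rotation matrix).
#' @export
to_euler_angles <- function(transform) {
  r <- if (is_rigid_transform(transform)) transform$rotation else unname(as.matrix(transform))
  stopifnot(identical(dim(r), c(3L, 3L)))
  sy <- -r[3, 1]
  gimbal <- abs(abs(sy) - 1) < 1e-14
  b <- asin(max(-1, min(1, sy)))
  if (gimbal) {
    # a and c degenerate; report their combination in a, zero in c
    a <- atan2(-r[1, 2], r[2, 2])
    c <- 0
    warning("Euler extraction near gimbal lock (|pitch| ~ 90 degrees); ",
            "first and last angles are not separable")
  } else {
    a <- atan2(r[2, 1], r[1, 1])
    c <- atan2(r[3, 2], r[3, 3])
  }
  out <- c(a, b, c) * 180 / pi
  names(out) <- c("z", "y", "x")
  attr(out, "gimbal_lock") <- gimbal
  out
}

#' Random rigid transform
#'
#' Rotation drawn uniformly on SO(3) (normalized Gaussian quaternion),
#' translation uniform in a cube. Used by the simulation tests and the
#' synthetic phantom study; always seeded explicitly.
#'
#' @param translation_range half-width of the uniform translation cube (mm).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(translation_range = 50, seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  rigid_transform(quaternion_to_rotation(q),
                  stats::runif(3, -translation_range, translation_range))
}

# unit quaternion (w, x, y, z) -> rotation matrix
quaternion_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y + w * z),   2 * (x * z - w * y),
    2 * (x * y - w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z + w * x),
    2 * (x * z + w * y),   2 * (y * z - w * x),   w^2 - x^2 - y^2 + z^2), 3L)
}

# angle (degrees) between two rotations
rotation_angle_between <- function(r1, r2) {
  tr <- sum(diag(crossprod(r1, r2)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}
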