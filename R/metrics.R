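#' Point prediction error (PPE)
#'
#' Reference-free localization-quality measure of the six-station phantom
#' assessment. The six marker-to-image transforms `T_1..T_6` are applied to
#' a virtual target defined in the marker frame, and the PPE is the RMS
#' deviation of the six transformed points about their mean (the
#' approximated symmetry point):
#' \deqn{PPE = \sqrt{\frac{1}{6}\sum_{i=1}^{6} \|p_i - \bar p\|^2}.}
#' With ideal, point-symmetric station poses every transformed target
#' coincides with the symmetry point and the PPE is zero; localization
#' errors spread the six points apart.
#'
#' The divisor 6 is part of the definition; [point_dispersion_rms()] is the
#' generalized-n variant.
#'
#' @param transforms list of exactly six [rigid_transform()] objects
#'   (marker to image).
#' @param target length-3 virtual target, mm, marker coordinate system.
#' @return PPE in mm.
#' @examples
#' ts <- lapply(1:6, function(i) rigid_transform())
#' point_prediction_error(ts, c(0, 0, 100))  # identical poses: 0
#' @export
point_prediction_error <- function(transforms, target) {
  if (length(transforms) != 6L)
    stop("the point prediction error is defined over exactly 6 station poses; ",
         "use point_dispersion_rms() for other counts")
  point_dispersion_rms(transforms, target)
}

#' @rdname point_prediction_error
#' @export
point_dispersion_rms <- function(transforms, target) {
  stopifnot(is.list(transforms), length(transforms) >= 2L,
            length(target) == 3L, all(is.finite(target)))
  p <- t(vapply(transforms, function(tf) transform_points(tf, target), numeric(3)))
  pbar <- colMeans(p)
  sqrt(mean(rowSums(sweep(p, 2L, pbar)^2)))
}

#' Repeatability error
#'
#' The PPE statistic applied to six repeat localizations of one fixed
#' marker pose (six successive scans with the marker permanently attached):
#' it isolates the scan-to-scan localization jitter from the station
#' geometry.
#'
#' @inheritParams point_prediction_error
#' @param target virtual target, mm, marker frame; defaults to the marker
#'   origin.
#' @return Repeatability error in mm.
#' @export
repeatability_error <- function(transforms, target = c(0, 0, 0)) {
  point_prediction_error(transforms, target)
}

#' Clipping precision
#'
#' Dispersion statistics of repeated clip-on events of the sensor holder,
#' measured against a reference sensor. `clipping_translation_precision()`
#' is the mean absolute deviation of the scalar reference-to-holder
#' distances about their mean,
#' \deqn{\epsilon_{trans} = \frac{1}{n}\sum_i |l_i - l_{mean}|,}
#' implemented literally on the scalar distances; being scalar it is blind
#' to tangential shifts, so the clearly named vector alternative
#' [clipping_translation_precision_vector()] (mean norm of the 3-vector
#' deviations about the mean position) is provided separately.
#' `clipping_rotation_precision()` averages the L2 norms of the Euler-angle
#' vectors about their component-wise mean,
#' \deqn{\epsilon_{rot} = \frac{1}{n}\sum_i \|\theta_i - \theta_{mean}\|_2.}
#' Euler vectors are unwrapped relative to the first sample before
#' averaging (component-wise means are ill-defined across the +/-180
#' degree cut); if any component still spans more than 180 degrees after
#' unwrapping, an error asks for manual unwrapping.
#'
#' @param distances numeric vector (n >= 2) of per-sample reference-to-
#'   holder distances `l_i`, mm.
#' @return `epsilon_trans` in mm respectively `epsilon_rot` in degrees.
#' @examples
#' clipping_translation_precision(c(10.0, 10.2, 9.8))  # 0.1333 mm
#' clipping_rotation_precision(rbind(c(1, 0, 0), c(-1, 0, 0)))  # 1 degree
#' @export
clipping_translation_precision <- function(distances) {
  distances <- as.numeric(distances)
  stopifnot(length(distances) >= 2L, all(is.finite(distances)))
  mean(abs(distances - mean(distances)))
}

#' @rdname clipping_translation_precision
#' @param positions n x 3 matrix of sensor-holder positions relative to the
#'   reference sensor, mm.
#' @export
clipping_translation_precision_vector <- function(positions) {
  p <- as.matrix(positions)
  stopifnot(nrow(p) >= 2L, ncol(p) == 3L)
  dev <- sweep(p, 2L, colMeans(p))
  mean(sqrt(rowSums(dev^2)))
}

#' @rdname clipping_translation_precision
#' @param euler_vectors n x 3 matrix of Euler-angle vectors (degrees), one
#'   row per clip-on sample.
#' @param unwrap unwrap angles relative to the first sample before
#'   averaging.
#' @export
clipping_rotation_precision <- function(euler_vectors, unwrap = TRUE) {
  th <- as.matrix(euler_vectors)
  stopifnot(nrow(th) >= 2L, ncol(th) == 3L)
  if (unwrap) th <- sweep_unwrap(th)
  rng <- apply(th, 2L, function(x) diff(range(x)))
  if (any(rng > 180))
    stop("Euler angle wrap-around detected (component range > 180 degrees); ",
         "unwrap the angle series before computing the rotation precision")
  dev <- sweep(th, 2L, colMeans(th))
  mean(sqrt(rowSums(dev^2)))
}

# shift each sample by multiples of 360 degrees onto the branch of the first
sweep_unwrap <- function(th) {
  ref <- th[1L, ]
  th - 360 * round(sweep(th, 2L, ref) / 360)
}

#' Target registration error (TRE)
#'
#' Euclidean distance between each registered target position and its
#' independently marked reference position, with the mean and sample
#' (n - 1) standard deviation over targets.
#'
#' @param registered n x 3 matrix of registered target positions, mm.
#' @param reference n x 3 matrix of reference positions, mm.
#' @return A list with `tre` (per-target distances, mm), `mean` and `sd`.
#' @examples
#' target_registration_error(rbind(c(1, 0, 0), c(0, 2, 0)), matrix(0, 2, 3))
#' @export
target_registration_error <- function(registered, reference) {
  r <- as.matrix(registered); m <- as.matrix(reference)
  if (is.null(dim(registered))) r <- matrix(registered, 1L)
  if (is.null(dim(reference))) m <- matrix(reference, 1L)
  if (!identical(dim(r), dim(m)) || ncol(r) != 3L || nrow(r) < 1L)
    stop("registered and reference must be matched n x 3 point sets, n >= 1")
  tre <- sqrt(rowSums((r - m)^2))
  list(tre = tre, mean = mean(tre),
       sd = if (length(tre) > 1L) stats::sd(tre) else NA_real_)
}
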