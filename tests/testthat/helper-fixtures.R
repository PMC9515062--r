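# shared fixtures and independent oracles, all built in code at test time

geo_ct <- marker_geometry("3_15")

# uniform random rotation matrix under an explicit seed-free draw
rand_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), w^2 - x^2 - y^2 + z^2), 3L)
}

rand_transform <- function(trans = 20) {
  rigid_transform(rand_rotation(), runif(3, -trans, trans))
}

translation_error <- function(fit, pose) {
  sqrt(sum((fit$transform$translation - pose$translation)^2))
}

rotation_error_deg <- function(fit, pose) {
  tr <- sum(diag(crossprod(fit$transform$rotation, pose$rotation)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

# independent numerical least-squares oracle for the absolute-orientation
# problem: axis-angle (Rodrigues) parameterization, multi-start BFGS
rodrigues <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3L)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

horn_oracle <- function(src, tgt, n_starts = 4L) {
  obj <- function(par) {
    r <- rodrigues(par[1:3])
    sum((src %*% t(r) + rep(par[4:6], each = nrow(src)) - tgt)^2)
  }
  t0 <- colMeans(tgt) - colMeans(src)
  starts <- c(list(c(0, 0, 0, t0)),
              lapply(seq_len(n_starts - 1L), function(i) c(runif(3, -pi, pi), t0)))
  best <- NULL
  for (s in starts) {
    o <- optim(s, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-16))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # Gauss-Newton polish on the local small-angle parameterization
  r <- rodrigues(best$par[1:3])
  tr <- best$par[4:6]
  skew <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3L)
  for (it in 1:50) {
    pred <- src %*% t(r) + rep(tr, each = nrow(src))
    res <- as.vector(t(tgt - pred))  # stacked per-point x, y, z
    jac <- do.call(rbind, lapply(seq_len(nrow(src)), function(i)
      cbind(-skew(drop(r %*% src[i, ])), diag(3))))
    upd <- solve(crossprod(jac), crossprod(jac, res))
    r <- rodrigues(upd[1:3]) %*% r
    tr <- tr + upd[4:6]
    if (max(abs(upd)) < 1e-14) break
  }
  # re-orthonormalize accumulated rounding
  sv <- svd(r)
  r <- sv$u %*% t(sv$v)
  list(transform = rigid_transform(r, tr),
       sse = sum((src %*% t(r) + rep(tr, each = nrow(src)) - tgt)^2))
}

# brute-force PPE: explicit loops, no shared code with the implementation
ppe_bruteforce <- function(transforms, target) {
  p <- matrix(0, 6, 3)
  for (i in 1:6) {
    tf <- transforms[[i]]
    p[i, ] <- as.numeric(tf$rotation %*% target) + tf$translation
  }
  pb <- c(mean(p[, 1]), mean(p[, 2]), mean(p[, 3]))
  acc <- 0
  for (i in 1:6)
    acc <- acc + (p[i, 1] - pb[1])^2 + (p[i, 2] - pb[2])^2 + (p[i, 3] - pb[3])^2
  sqrt(acc / 6)
}

# small noiseless CT scene for detection tests
render_test_scene <- function(pose = rigid_transform(), thickness = 1,
                              noise_sd = 0, seed = 1, geometry = geo_ct, ...) {
  render_marker_volume(geometry, pose,
                       render_profile(geometry$modality, noise_sd = noise_sd,
                                      seed = seed),
                       spacing = c(0.98, 0.98, thickness), ...)
}

# synthetic candidate table from world points, with plausible volumes
as_candidates <- function(points, geometry, vol_jitter = 0.1) {
  vf <- expected_feature_volume(geometry)
  n <- nrow(points)
  structure(data.frame(label_id = seq_len(n),
                       x = points[, 1], y = points[, 2], z = points[, 3],
                       voxel_x = 0, voxel_y = 0, voxel_z = 0,
                       voxel_count = 1L,
                       physical_volume = vf * runif(n, 1 - vol_jitter, 1 + vol_jitter),
                       mean_intensity = runif(n, 2000, 3000)),
            class = c("candidate_features", "data.frame"))
}
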