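# Fixtures shared across the suite. Everything is generated in code; no
# binary files ship with the package.

# Small isotropic grid volume with voxel centres at (i + 0.5) * spacing.
grid_volume <- function(n = 32, spacing = 1) {
  aff <- diag(c(rep(spacing, 3), 1))
  aff[1:3, 4] <- spacing / 2
  volume(array(0, rep(n, 3)), aff)
}

# Smooth band-limited image: sum of Gaussian blobs, evaluable analytically
# at arbitrary world points (for constructing exactly transformed copies).
blob_field <- function(points, centers, sigma = 6) {
  v <- 0
  for (i in seq_len(nrow(centers)))
    v <- v + exp(-rowSums(sweep(points, 2, centers[i, ])^2) / (2 * sigma^2))
  v
}

blob_volume <- function(centers, n = 32, spacing = 2, sigma = 6,
                        transform = NULL) {
  g <- grid_volume(n, spacing)
  w <- voxel_to_world(g, tfusplan:::voxel_index_grid(rep(n, 3)))
  if (!is.null(transform)) w <- apply_rigid(transform, w)
  g$data <- array(blob_field(w, centers, sigma), rep(n, 3))
  g
}

# Rotation-angle (deg) and centre-point displacement (mm) between two rigid
# transforms.
rigid_discrepancy <- function(a, b, point = c(32, 32, 32)) {
  dR <- a$rotation %*% t(b$rotation)
  ang <- acos(pmin(1, pmax(-1, (sum(diag(dR)) - 1) / 2))) * 180 / pi
  shift <- sqrt(sum((apply_rigid(a, point) - apply_rigid(b, point))^2))
  c(angle_deg = ang, shift_mm = shift)
}

# Deterministic phantom pair reused by the tractography tests.
straight_phantom <- function(noise = "none", seed = 42L, ...) {
  make_phantom(phantom_spec(shape = "straight", noise = noise, seed = seed,
                            ...))
}

# Polyline length restricted to the arc phantom's angular span. The FA
# stop rule lets tracks run ~one voxel past each flush tube end (tensor
# interpolation keeps FA above threshold in the mixing zone), so the
# curvature-following check compares in-span length against the analytic
# quarter-circle length.
arc_span_length <- function(points, ph) {
  ext <- ph$spec$grid_shape * ph$spec$spacing_mm
  cen <- c(ext[1] / 2 - ph$spec$arc_radius_mm / 2,
           ext[2] / 2 - ph$spec$arc_radius_mm / 2)
  mid <- (points[-1, , drop = FALSE] + points[-nrow(points), , drop = FALSE]) / 2
  ang <- atan2(mid[, 2] - cen[2], mid[, 1] - cen[1])
  seg <- sqrt(rowSums(diff(points)^2))
  sum(seg[ang >= 0 & ang <= pi / 2])
}

random_spd_tensor <- function() {
  lam <- sort(runif(3, 0.1, 2.5) * 1e-3, decreasing = TRUE)
  a <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(a))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q %*% diag(lam) %*% t(q)
}

# Forward Stejskal-Tanner signals for one tensor.
st_signal <- function(D, scheme, s0 = 1000) {
  g <- scheme$bvecs
  b <- scheme$bvals
  s0 * exp(-b * colSums(g * (D %*% g)))
}

tensor_to_vec6 <- function(D) c(D[1,1], D[1,2], D[2,2], D[1,3], D[2,3], D[3,3])
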