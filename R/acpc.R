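#' Rigid transform
#'
#' A proper rigid transform `x' = R x + t` with orthonormal rotation
#' (det +1) and translation in millimetres.
#'
#' @param rotation 3x3 orthonormal matrix.
#' @param translation length-3 numeric vector, mm.
#' @return An object of class `tfus_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "tfus_rigid")
}

#' @export
print.tfus_rigid <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<tfus_rigid> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#' @param t a [rigid_transform()].
#' @param x length-3 vector or n x 3 matrix of world points.
#' @export
apply_rigid <- function(t, x) {
  stopifnot(inherits(t, "tfus_rigid"))
  if (is.matrix(x)) t(t$rotation %*% base::t(x) + t$translation)
  else drop(t$rotation %*% x + t$translation)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @export
invert_rigid <- function(t) {
  Rt <- base::t(t$rotation)
  rigid_transform(Rt, -drop(Rt %*% t$translation))
}

#' Compose rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()] objects.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

# Rotation matrix from ZYX Euler angles (radians).
euler_to_rotation <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# Minimal rotation taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  axis <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to u
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- w - sum(w * u) * u
    axis <- axis / sqrt(sum(axis^2))
    K <- skew(axis)
    return(diag(3) + 2 * K %*% K)
  }
  axis <- axis / s
  K <- skew(axis)
  diag(3) + s * K + (1 - c_) * K %*% K
}

skew <- function(a) matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)

#' AC-PC alignment transform
#'
#' Computes the rigid transform that brings an image into the standardized
#' AC-PC view: after the transform the AC and PC share an axial (z) plane
#' and lie on a line parallel to the anterior (y) axis with AC anterior of
#' PC; the PC maps to the origin. The rotation is the minimal rotation of
#' the AC-PC direction onto +y, so residual roll about the AC-PC axis is
#' zero unless a roll reference volume is supplied, in which case the roll
#' angle is estimated by rigid registration against the (already aligned)
#' reference and composed in.
#'
#' @param lm a [landmark_pair()] in world mm.
#' @param roll_reference optional AC-PC-aligned reference [volume()] used to
#'   estimate residual rotation about the AC-PC axis.
#' @param moving the volume being aligned; required when `roll_reference`
#'   is given.
#' @return A [rigid_transform()].
#' @export
acpc_transform <- function(lm, roll_reference = NULL, moving = NULL) {
  stopifnot(inherits(lm, "tfus_landmarks"))
  d <- sqrt(sum((lm$ac - lm$pc)^2))
  if (d < 5)
    stop("degenerate landmarks: AC-PC distance ", format(d),
         " mm is below 5 mm", call. = FALSE)
  u <- (lm$ac - lm$pc) / d
  R <- rotation_between(u, c(0, 1, 0))
  t0 <- rigid_transform(R, -drop(R %*% lm$pc))
  if (is.null(roll_reference)) return(t0)
  if (is.null(moving))
    stop("roll estimation requires the moving volume", call. = FALSE)
  aligned <- reorient_to_acpc(moving, t0, min(roll_reference$spacing))
  reg <- register_rigid(roll_reference, aligned, n_levels = 3)
  # keep only the roll component (rotation about the AC-PC axis, +y)
  ang <- atan2(reg$transform$rotation[1, 3], reg$transform$rotation[3, 3])
  roll <- rigid_transform(euler_to_rotation(0, ang, 0), c(0, 0, 0))
  compose_rigid(roll, t0)
}

#' Resample a volume into the AC-PC aligned grid
#'
#' Applies an AC-PC (or any rigid) transform and resamples onto an
#' axis-aligned isotropic grid using trilinear interpolation. The output
#' grid covers the transformed bounding box of the input. The same
#' transform can be applied to any volume derived from the input (e.g.
#' tract probability maps) so that all planning outputs share the AC-PC
#' frame.
#'
#' @param v a [volume()] (3D).
#' @param t a [rigid_transform()] mapping input world mm to AC-PC world mm.
#' @param target_spacing isotropic output voxel size, mm.
#' @param fill value for samples outside the input grid (default 0).
#' @return A [volume()] on the new grid.
#' @export
reorient_to_acpc <- function(v, t, target_spacing = 1, fill = 0) {
  stopifnot(is_volume(v), inherits(t, "tfus_rigid"), target_spacing > 0)
  d <- dim(v$data)[1:3]
  corners <- as.matrix(expand.grid(c(-0.5, d[1] - 0.5), c(-0.5, d[2] - 0.5),
                                   c(-0.5, d[3] - 0.5)))
  wc <- apply_rigid(t, voxel_to_world(v, corners))
  lo <- apply(wc, 2, min); hi <- apply(wc, 2, max)
  n <- pmax(2L, as.integer(ceiling((hi - lo) / target_spacing)))
  aff <- diag(c(rep(target_spacing, 3), 1))
  aff[1:3, 4] <- lo + target_spacing / 2
  out <- volume(array(0, n), aff)
  grid_w <- voxel_to_world(out, voxel_index_grid(n))
  src_vox <- world_to_voxel(v, apply_rigid(invert_rigid(t), grid_w))
  vals <- interp_trilinear(v$data, src_vox)
  vals[is.na(vals)] <- fill
  out$data <- array(vals, n)
  out
}

#' Geometric standard target coordinate
#'
#' The stereotactic standard target for VIM thalamotomy, computed in AC-PC
#' space: anterior to the PC by 25% of the AC-PC distance, 1 mm superior to
#' the AC-PC plane, and 14 mm lateral toward the treated side (+14 for
#' left, -14 for right under the package's +x-left convention).
#'
#' @param lm a [landmark_pair()] expressed in AC-PC space (apply
#'   [acpc_transform()] first).
#' @param side treated side, `"left"` or `"right"`.
#' @return An object of class `tfus_std_coord` with elements `point`
#'   (world mm) and `side`.
#' @export
standard_coordinate <- function(lm, side = c("left", "right")) {
  stopifnot(inherits(lm, "tfus_landmarks"))
  side <- match.arg(side)
  d <- sqrt(sum((lm$ac - lm$pc)^2))
  if (d < 5)
    stop("degenerate landmarks: AC-PC distance below 5 mm", call. = FALSE)
  u <- (lm$ac - lm$pc) / d               # anterior direction (PC -> AC)
  lat <- if (side == "left") 14 else -14
  point <- lm$pc + 0.25 * d * u + c(0, 0, 1) + c(lat, 0, 0)
  structure(list(point = point, side = side), class = "tfus_std_coord")
}

#' @export
print.tfus_std_coord <- function(x, ...) {
  cat(sprintf("<standard coordinate> (%g, %g, %g) mm, side %s\n",
              x$point[1], x$point[2], x$point[3], x$side))
  invisible(x)
}

LATERAL_OFFSET_MM <- 14  # lateral offset of the standard target from midline
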