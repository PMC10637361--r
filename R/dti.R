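#' Lanczos-3 supersampling
#'
#' Resamples a volume to an isotropic target voxel size with a separable
#' Lanczos-3 kernel, `L(x) = sinc(x) sinc(x/3)` for `|x| < 3`. Kernel
#' weights are renormalized to sum to one per output sample, so constant
#' images are reproduced exactly. The world extent of the grid is
#' preserved. Supersampling adds no information but permits plain trilinear
#' interpolation at sub-voxel positions during fiber tracking.
#'
#' @param v a [volume()], 3D or 4D (each trailing frame resampled
#'   independently).
#' @param target_spacing isotropic output voxel size in mm (> 0).
#' @return A [volume()] on the finer grid.
#' @export
lanczos3_resample <- function(v, target_spacing) {
  stopifnot(is_volume(v))
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      target_spacing <= 0)
    stop("target_spacing must be a positive scalar (mm)", call. = FALSE)
  d <- dim(v$data)
  d3 <- d[1:3]
  mats <- vector("list", 3)
  n_out <- integer(3)
  for (ax in 1:3) {
    sp_in <- v$spacing[ax]
    n_out[ax] <- max(2L, as.integer(round(d3[ax] * sp_in / target_spacing)))
    # output voxel centre o maps to input voxel coordinate, preserving the
    # [-0.5, n-0.5] field of view
    ratio <- target_spacing / sp_in
    xi <- (seq_len(n_out[ax]) - 1 + 0.5) * ratio - 0.5
    W <- matrix(0, n_out[ax], d3[ax])
    for (o in seq_len(n_out[ax])) {
      ctr <- xi[o]
      j <- seq(floor(ctr) - 2, floor(ctr) + 3)
      w <- lanczos3_kernel(ctr - j)
      j_cl <- pmin(pmax(j, 0), d3[ax] - 1)   # clamp at edges
      for (k in seq_along(j)) W[o, j_cl[k] + 1] <- W[o, j_cl[k] + 1] + w[k]
    }
    W <- W / rowSums(W)
    mats[[ax]] <- W
  }
  frames <- if (length(d) == 4L) d[4] else 1L
  out <- array(0, c(n_out, frames))
  src <- if (length(d) == 4L) v$data else array(v$data, c(d3, 1L))
  for (f in seq_len(frames)) {
    a <- src[, , , f]
    a <- tensor3_apply(a, mats[[1]], 1)
    a <- tensor3_apply(a, mats[[2]], 2)
    a <- tensor3_apply(a, mats[[3]], 3)
    out[, , , f] <- a
  }
  if (length(d) == 3L) out <- array(out, n_out)
  aff <- v$affine
  dirs <- sweep(v$affine[1:3, 1:3], 2, v$spacing, "/")
  aff[1:3, 1:3] <- dirs * target_spacing
  # first output voxel centre in input voxel coordinates
  shift <- (0.5 * target_spacing / v$spacing) - 0.5
  aff[1:3, 4] <- v$affine[1:3, 4] + drop(v$affine[1:3, 1:3] %*% shift)
  volume(out, aff)
}

lanczos3_kernel <- function(x) {
  w <- ifelse(abs(x) < 3,
              ifelse(abs(x) < 1e-12, 1,
                     (sin(pi * x) / (pi * x)) * (sin(pi * x / 3) / (pi * x / 3))),
              0)
  w
}

# Apply matrix W (n_out x n_in) along axis `ax` of 3D array a.
tensor3_apply <- function(a, W, ax) {
  d <- dim(a)
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- W %*% matrix(ap, nrow = d[ax])
  dp <- dim(ap); dp[1] <- nrow(W)
  res <- array(m, dp)
  aperm(res, order(perm))
}

#' Gaussian smoothing in world millimetres
#'
#' Separable Gaussian filtering with the kernel width given in mm (scaled
#' per axis by the voxel spacing); `sigma_mm = 0` is the identity. Kernel
#' truncated at 4 sigma and normalized; edges use renormalized (truncated)
#' kernels.
#'
#' @param v a [volume()], 3D or 4D.
#' @param sigma_mm Gaussian standard deviation in mm (>= 0).
#' @return smoothed [volume()] on the same grid.
#' @export
gaussian_smooth <- function(v, sigma_mm) {
  stopifnot(is_volume(v), sigma_mm >= 0)
  if (sigma_mm == 0) return(v)
  d <- dim(v$data)
  d3 <- d[1:3]
  frames <- if (length(d) == 4L) d[4] else 1L
  src <- if (length(d) == 4L) v$data else array(v$data, c(d3, 1L))
  out <- array(0, c(d3, frames))
  kerns <- lapply(1:3, function(ax) {
    s_vox <- sigma_mm / v$spacing[ax]
    r <- max(1L, ceiling(4 * s_vox))
    k <- stats::dnorm(seq(-r, r), sd = s_vox)
    k / sum(k)
  })
  for (f in seq_len(frames)) {
    a <- src[, , , f]
    for (ax in 1:3) a <- tensor3_apply(a, conv_matrix(kerns[[ax]], dim(a)[ax]), ax)
    out[, , , f] <- a
  }
  if (length(d) == 3L) out <- array(out, d3)
  volume(out, v$affine)
}

# Banded convolution matrix with edge renormalization.
conv_matrix <- function(k, n) {
  r <- (length(k) - 1) / 2
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    W[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  W
}

#' Fit diffusion tensors with the Stejskal-Tanner model
#'
#' Per-voxel log-linear least squares on
#' \deqn{\log(S_k / S_0) = -b_k\, g_k^\top D\, g_k}
#' where `S0` is the mean of the b = 0 frames. Voxels with non-positive
#' `S0` or any non-positive weighted signal are masked out. Negative
#' eigenvalues are clamped to zero for derived metrics (FA, color maps)
#' while the raw tensor is retained.
#'
#' @param dwi 4D [volume()], gradient axis last.
#' @param scheme a [diffusion_scheme()] matching the gradient axis.
#' @param mask optional 3D [volume()] of 0/1 validity flags.
#' @return An object of class `tfus_tensor_field` with `tensors` (4D array,
#'   last axis the 6 unique components in lower-triangular order
#'   dxx, dxy, dyy, dxz, dyz, dzz, units mm^2/s), `s0`, `mask` (logical
#'   array), and the grid `affine`.
#' @export
fit_tensors <- function(dwi, scheme, mask = NULL) {
  stopifnot(is_volume(dwi), inherits(scheme, "tfus_scheme"))
  d <- dim(dwi$data)
  if (length(d) != 4L) stop("dwi must be a 4D volume", call. = FALSE)
  if (d[4] != length(scheme$bvals))
    stop("gradient axis length ", d[4], " does not match scheme length ",
         length(scheme$bvals), call. = FALSE)
  w <- !scheme$is_b0
  if (sum(w) < 6L)
    stop("tensor fit requires at least 6 diffusion-weighted directions",
         call. = FALSE)
  g <- scheme$bvecs[, w, drop = FALSE]
  b <- scheme$bvals[w]
  # design matrix rows: b * (gx^2, 2 gx gy, gy^2, 2 gx gz, 2 gy gz, gz^2)
  B <- cbind(g[1, ]^2, 2 * g[1, ] * g[2, ], g[2, ]^2,
             2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ], g[3, ]^2) * b
  if (qr(B)$rank < 6L)
    stop("gradient directions do not span 3D: design matrix rank ",
         qr(B)$rank, " < 6", call. = FALSE)
  nvox <- prod(d[1:3])
  sig <- matrix(dwi$data, nvox, d[4])
  s0 <- rowMeans(sig[, scheme$is_b0, drop = FALSE])
  sw <- sig[, w, drop = FALSE]
  valid <- s0 > 0 & apply(sw > 0, 1, all)
  if (!is.null(mask)) valid <- valid & (as.vector(mask$data) > 0)
  Y <- matrix(0, nvox, sum(w))
  Y[valid, ] <- -log(sw[valid, , drop = FALSE] / s0[valid])
  coef <- t(qr.solve(B, t(Y)))           # nvox x 6
  coef[!valid, ] <- 0
  structure(list(tensors = array(coef, c(d[1:3], 6L)),
                 s0 = array(s0, d[1:3]),
                 mask = array(valid, d[1:3]),
                 affine = dwi$affine),
            class = "tfus_tensor_field")
}

#' @export
print.tfus_tensor_field <- function(x, ...) {
  d <- dim(x$tensors)
  cat("<tfus_tensor_field>", paste(d[1:3], collapse = " x "),
      "voxels,", sum(x$mask), "masked-in\n")
  invisible(x)
}

# Eigenvalues (descending) of all voxel tensors; n x 3 matrix.
tensor_eigenvalues <- function(tf) {
  tens <- matrix(tf$tensors, ncol = 6)
  t(apply(tens, 1, function(v) {
    m <- matrix(c(v[1], v[2], v[4], v[2], v[3], v[5], v[4], v[5], v[6]), 3, 3)
    sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }))
}

fa_from_eigenvalues <- function(lam) {
  lam <- pmax(lam, 0)
  if (is.null(dim(lam))) lam <- matrix(lam, nrow = 1)
  mu <- rowMeans(lam)
  num <- sqrt(rowSums((lam - mu)^2))
  den <- sqrt(rowSums(lam^2))
  fa <- sqrt(1.5) * num / den
  fa[den == 0] <- 0
  pmin(pmax(fa, 0), 1)
}

#' Fractional anisotropy map
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||` per voxel, with
#' negative eigenvalues clamped to zero; 0 on masked-out voxels.
#'
#' @param tf a [fit_tensors()] result.
#' @return 3D [volume()] of FA in [0, 1].
#' @export
fa_map <- function(tf) {
  stopifnot(inherits(tf, "tfus_tensor_field"))
  d <- dim(tf$tensors)[1:3]
  fa <- fa_map_cpp(tf$tensors)
  fa[!tf$mask] <- 0
  volume(array(fa, d), tf$affine)
}

#' Color-coded principal direction map
#'
#' Standard DTI direction encoding: per voxel the absolute components of
#' the principal eigenvector weighted by FA, giving three channels in
#' [0, 1] (x = red/left-right, y = green/anterior-posterior,
#' z = blue/superior-inferior).
#'
#' @param tf a [fit_tensors()] result.
#' @return 4D [volume()] with 3 trailing channels.
#' @export
color_direction_map <- function(tf) {
  stopifnot(inherits(tf, "tfus_tensor_field"))
  d <- dim(tf$tensors)[1:3]
  rgb <- color_map_cpp(tf$tensors)        # nvox x 3
  rgb[!as.vector(tf$mask), ] <- 0
  volume(array(rgb, c(d, 3L)), tf$affine)
}

#' Persist a tensor field as NIfTI + JSON sidecar
#'
#' Components are written as a 4D NIfTI (6 trailing frames, lower-triangular
#' order) with a JSON sidecar naming the order; S0 and the mask are written
#' alongside.
#'
#' @param tf a [fit_tensors()] result.
#' @param prefix output path prefix (writes `<prefix>_tensor.nii.gz`,
#'   `<prefix>_s0.nii.gz`, `<prefix>_mask.nii.gz`, `<prefix>_tensor.json`).
#' @export
save_tensor_field <- function(tf, prefix) {
  save_volume(volume(tf$tensors, tf$affine), paste0(prefix, "_tensor.nii.gz"))
  save_volume(volume(tf$s0, tf$affine), paste0(prefix, "_s0.nii.gz"))
  save_volume(volume(array(as.numeric(tf$mask), dim(tf$mask)), tf$affine),
              paste0(prefix, "_mask.nii.gz"))
  jsonlite::write_json(
    list(component_order = c("dxx", "dxy", "dyy", "dxz", "dyz", "dzz"),
         units = "mm^2/s"),
    paste0(prefix, "_tensor.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname save_tensor_field
#' @export
load_tensor_field <- function(prefix) {
  tens <- load_volume(paste0(prefix, "_tensor.nii.gz"))
  s0 <- load_volume(paste0(prefix, "_s0.nii.gz"))
  mask <- load_volume(paste0(prefix, "_mask.nii.gz"))
  structure(list(tensors = tens$data, s0 = s0$data,
                 mask = array(mask$data > 0, dim(mask$data)),
                 affine = tens$affine),
            class = "tfus_tensor_field")
}

#' DWI preprocessing chain
#'
#' Supersample (Lanczos-3) to an isotropic grid, Gaussian-smooth, and fit
#' diffusion tensors; the standard preparation ahead of fiber tracking.
#'
#' @param dwi 4D [volume()].
#' @param scheme [diffusion_scheme()].
#' @param target_spacing isotropic spacing for supersampling, mm; `NULL`
#'   skips resampling.
#' @param sigma_mm Gaussian width, mm (0 skips smoothing).
#' @param mask optional mask volume (on the *output* grid).
#' @return A `tfus_tensor_field`.
#' @export
prepare_dti <- function(dwi, scheme, target_spacing = 1, sigma_mm = 1,
                        mask = NULL) {
  if (!is.null(target_spacing)) dwi <- lanczos3_resample(dwi, target_spacing)
  if (sigma_mm > 0) dwi <- gaussian_smooth(dwi, sigma_mm)
  fit_tensors(dwi, scheme, mask = mask)
}
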