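#' Image volume with a voxel-to-world affine
#'
#' A `tfus_volume` couples a 3D (or 4D, gradient axis last) numeric array
#' with a 4x4 affine mapping 0-based voxel indices to world coordinates in
#' millimetres. The world frame follows the package convention: +x toward
#' the patient's left, +y anterior, +z superior, so a lateral-left offset of
#' 14 mm is +14 on x and the right side is -14.
#'
#' @param data numeric array, 3D or 4D.
#' @param affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#' @return An object of class `tfus_volume` with elements `data`, `affine`
#'   and derived `spacing` (per-axis voxel size, mm).
#' @export
volume <- function(data, affine = diag(4)) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L)
    stop("volume data must be a 3D or 4D array, got ", nd, "D", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("affine is singular", call. = FALSE)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive", call. = FALSE)
  structure(list(data = data, affine = affine, spacing = spacing),
            class = "tfus_volume")
}

#' @export
print.tfus_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<tfus_volume> ", paste(d, collapse = " x "),
      sprintf(" | spacing %.3g x %.3g x %.3g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.tfus_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "tfus_volume")

#' Read a NIfTI-1 volume
#'
#' Loads a 3D or 4D NIfTI file (optionally gzipped) without resampling.
#' The affine is taken from the file's sform/qform.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # drop RNifti header attributes
  if (!(length(dim(arr)) %in% c(3L, 4L)))
    stop("expected a 3D or 4D image, got ", length(dim(arr)), "D", call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume(arr, aff)
}

#' Write a volume as NIfTI-1
#'
#' Data are stored as float32/float64 as given; the affine is written as the
#' sform (code 2).
#'
#' @param v a [volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @export
save_volume <- function(v, path) {
  stopifnot(is_volume(v))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  img <- RNifti::asNifti(v$data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Map continuous voxel indices to world millimetres
#'
#' @param v a [volume()].
#' @param index numeric vector of length 3 (0-based, may be fractional) or
#'   an n x 3 matrix.
#' @return world coordinates, same shape as `index`.
#' @export
voxel_to_world <- function(v, index) {
  stopifnot(is_volume(v))
  apply_affine(v$affine, index)
}

#' Map world millimetres to continuous voxel indices
#' @rdname voxel_to_world
#' @param point world coordinates (length-3 vector or n x 3 matrix).
#' @export
world_to_voxel <- function(v, point) {
  stopifnot(is_volume(v))
  apply_affine(solve(v$affine), point)
}

apply_affine <- function(aff, x) {
  if (is.matrix(x)) {
    t(aff[1:3, 1:3] %*% t(x) + aff[1:3, 4])
  } else {
    drop(aff[1:3, 1:3] %*% x + aff[1:3, 4])
  }
}

#' Diffusion gradient scheme
#'
#' Holds b-values (s/mm^2) and unit gradient directions in the FSL bval/bvec
#' dialect. Frames with b = 0 are the non-diffusion-weighted (S0) reference.
#'
#' @param bvals numeric vector of b-values.
#' @param bvecs 3 x n matrix of gradient directions (columns).
#' @return An object of class `tfus_scheme` with `bvals`, `bvecs`, and a
#'   logical `is_b0` flag per frame.
#' @export
diffusion_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L)
    stop("bvecs must have 3 rows (FSL convention)", call. = FALSE)
  if (ncol(bvecs) != length(bvals))
    stop("bval/bvec length mismatch: ", length(bvals), " b-values vs ",
         ncol(bvecs), " gradient columns", call. = FALSE)
  if (!any(bvals == 0))
    stop("scheme has no b = 0 (S0) frame", call. = FALSE)
  wt <- bvals > 0
  norms <- sqrt(colSums(bvecs^2))
  if (any(abs(norms[wt] - 1) > 1e-6))
    stop("diffusion-weighted gradient directions must have unit norm",
         call. = FALSE)
  structure(list(bvals = bvals, bvecs = bvecs, is_b0 = !wt),
            class = "tfus_scheme")
}

#' @export
print.tfus_scheme <- function(x, ...) {
  cat("<tfus_scheme>", sum(!x$is_b0), "weighted frames (b =",
      paste(unique(x$bvals[!x$is_b0]), collapse = ", "),
      "s/mm^2),", sum(x$is_b0), "S0 frames\n")
  invisible(x)
}

#' Read an FSL-style bval/bvec pair
#'
#' @param bval_path whitespace-separated text file with one row of b-values.
#' @param bvec_path whitespace-separated text file with three rows of
#'   gradient components.
#' @return A [diffusion_scheme()].
#' @export
load_scheme <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3L)
    stop("bvec file must have exactly 3 rows, found ", length(rows), call. = FALSE)
  cols <- lapply(rows, function(r) scan(text = r, quiet = TRUE))
  ncols <- lengths(cols)
  if (length(unique(ncols)) != 1L || ncols[1] != length(bvals))
    stop("bval/bvec column counts differ: ", length(bvals), " b-values vs ",
         paste(ncols, collapse = "/"), " gradient columns", call. = FALSE)
  diffusion_scheme(bvals, do.call(rbind, cols))
}

#' Write an FSL-style bval/bvec pair
#' @param scheme a [diffusion_scheme()].
#' @param bval_path,bvec_path output paths.
#' @export
save_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' AC/PC landmark pair
#'
#' @param ac,pc world-mm positions of the anterior and posterior commissure.
#' @return An object of class `tfus_landmarks`.
#' @export
landmark_pair <- function(ac, pc) {
  ac <- as.numeric(ac); pc <- as.numeric(pc)
  stopifnot(length(ac) == 3L, length(pc) == 3L)
  if (sqrt(sum((ac - pc)^2)) <= 0)
    stop("AC and PC must be distinct points", call. = FALSE)
  structure(list(ac = ac, pc = pc), class = "tfus_landmarks")
}

#' Read AC/PC landmarks from JSON
#'
#' Expects `{"ac": [x,y,z], "pc": [x,y,z]}` in world millimetres.
#' @param path JSON file path.
#' @return A [landmark_pair()].
#' @export
load_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path)
  if (is.null(j$ac) || is.null(j$pc))
    stop("landmark JSON must contain 'ac' and 'pc'", call. = FALSE)
  landmark_pair(j$ac, j$pc)
}

#' @rdname load_landmarks
#' @param lm a [landmark_pair()].
#' @export
save_landmarks <- function(lm, path) {
  jsonlite::write_json(list(ac = lm$ac, pc = lm$pc), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Trilinear interpolation of a 3D array at continuous 0-based voxel
# coordinates (n x 3 matrix). Out-of-bounds samples return NA.
interp_trilinear <- function(arr, vox) {
  d <- dim(arr)
  x <- vox[, 1]; y <- vox[, 2]; z <- vox[, 3]
  ok <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  out <- rep(NA_real_, nrow(vox))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v <- arr[idx(x0,     y0,     z0)]     * (1-fx)*(1-fy)*(1-fz) +
       arr[idx(x0+1,   y0,     z0)]     * fx*(1-fy)*(1-fz) +
       arr[idx(x0,     y0+1,   z0)]     * (1-fx)*fy*(1-fz) +
       arr[idx(x0,     y0,     z0+1)]   * (1-fx)*(1-fy)*fz +
       arr[idx(x0+1,   y0+1,   z0)]     * fx*fy*(1-fz) +
       arr[idx(x0+1,   y0,     z0+1)]   * fx*(1-fy)*fz +
       arr[idx(x0,     y0+1,   z0+1)]   * (1-fx)*fy*fz +
       arr[idx(x0+1,   y0+1,   z0+1)]   * fx*fy*fz
  out[ok] <- v
  out
}

# 0-based integer voxel index grids for a 3D volume, as an n x 3 matrix in
# array order.
voxel_index_grid <- function(d) {
  cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
        rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}
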