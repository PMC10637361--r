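#' Track a single streamline
#'
#' Deterministic streamline tractography: the principal-eigenvector field
#' of the diffusion tensor is integrated bidirectionally from the seed with
#' fixed-step Euler steps. The tensor is interpolated trilinearly
#' component-wise and eigen-decomposed after interpolation. At every
#' position the step size, FA stop threshold, bend-angle limit and length
#' bounds come from [params_at()] on the covering atlas region, so
#' parameters adapt locally along the track. Integration stops on low FA,
#' a sharp bend, leaving the grid, or reaching the maximum length; tracks
#' shorter than the minimum length are rejected.
#'
#' @param tf a [fit_tensors()] tensor field.
#' @param seed world-mm seed point (inside the tensor grid).
#' @param atlas optional integer-label [volume()] for parameter adaptation.
#' @param pm a [region_parameter_map()].
#' @return An object of class `tfus_streamline`: `points` (n x 3 world mm,
#'   seed-centred), `status` (`"accepted"`/`"rejected"`), `reason`,
#'   `length_mm`.
#' @export
track_streamline <- function(tf, seed, atlas = NULL,
                             pm = region_parameter_map()) {
  stopifnot(inherits(tf, "tfus_tensor_field"))
  pt <- param_table(pm)
  d <- dim(tf$tensors)[1:3]
  res <- track_streamline_cpp(
    tf$tensors, as.integer(d), solve(tf$affine), as.numeric(seed),
    if (is.null(atlas)) NULL else as.integer(atlas$data),
    if (is.null(atlas)) NULL else as.integer(dim(atlas$data)[1:3]),
    if (is.null(atlas)) NULL else solve(atlas$affine),
    pt$labels, pt$table)
  structure(list(points = res$points, status = res$status,
                 reason = res$reason,
                 length_mm = res$length_mm %||% 0),
            class = "tfus_streamline")
}

#' @export
print.tfus_streamline <- function(x, ...) {
  cat(sprintf("<streamline> %d points, %.1f mm, %s%s\n", nrow(x$points),
              x$length_mm, x$status,
              if (nzchar(x$reason)) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

# 0-based voxel indices visited by a polyline on the grid of `vol`
# (nearest-voxel containment, no dilation); rows unique-ified.
visited_voxels <- function(vol, points) {
  v <- round(world_to_voxel(vol, points))
  d <- dim(vol$data)[1:3]
  ok <- v[, 1] >= 0 & v[, 1] <= d[1] - 1 &
        v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
        v[, 3] >= 0 & v[, 3] <= d[3] - 1
  unique(v[ok, , drop = FALSE])
}

polyline_hits_mask <- function(mask_vol, points) {
  v <- visited_voxels(mask_vol, points)
  if (nrow(v) == 0) return(FALSE)
  any(mask_vol$data[v[, 1:3, drop = FALSE] + 1] > 0)
}

#' Track a bundle with the minimum-fiber retry loop
#'
#' Repeatedly seeds batches of streamlines inside the seed ROI and keeps
#' those that traverse every include ROI and avoid all exclude ROIs.
#' Seeding rounds repeat until at least `spec$min_fibers` streamlines are
#' accepted or `spec$max_iterations` rounds have run. Seed points are drawn
#' uniformly over seed-ROI voxels with uniform sub-voxel jitter; results
#' are bit-reproducible for a fixed `rng_seed`.
#'
#' @param spec a [bundle_spec()].
#' @param rs a [roi_set()] providing the referenced masks.
#' @param tf a [fit_tensors()] tensor field.
#' @param atlas optional integer-label [volume()].
#' @param pm a [region_parameter_map()].
#' @param rng_seed integer seed for the seeding RNG.
#' @param batch_size seeds drawn per iteration (default 100).
#' @return An object of class `tfus_bundle`: `name`, `streamlines` (list of
#'   accepted `tfus_streamline`), `iterations_used`, `n_seeded`,
#'   `rng_seed`, `reached_min_fibers`.
#' @export
track_bundle <- function(spec, rs, tf, atlas = NULL,
                         pm = region_parameter_map(), rng_seed = 42L,
                         batch_size = 100L) {
  stopifnot(inherits(spec, "tfus_bundle_spec"), inherits(rs, "tfus_roiset"))
  rep_ <- validate_roiset(rs, spec)
  if (any(rep_$fatal))
    stop("ROI set invalid for bundle ", spec$name, ": ",
         paste(rep_$problem[rep_$fatal], "(", rep_$roi[rep_$fatal], ")",
               collapse = "; "), call. = FALSE)
  seed_mask <- rs$masks[[spec$seed_roi]]
  if (is.null(seed_mask) || sum(seed_mask$data > 0) == 0)
    stop("seed ROI '", spec$seed_roi, "' is missing or empty", call. = FALSE)
  seed_vox <- which(seed_mask$data > 0, arr.ind = TRUE) - 1  # 0-based
  includes <- rs$masks[spec$include_rois]
  excludes <- rs$masks[spec$exclude_rois]

  accepted <- list()
  iterations <- 0L
  n_seeded <- 0L
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(rng_seed)
  while (length(accepted) < spec$min_fibers &&
         iterations < spec$max_iterations) {
    iterations <- iterations + 1L
    pick <- sample.int(nrow(seed_vox), batch_size, replace = TRUE)
    jitter <- matrix(stats::runif(3 * batch_size, -0.5, 0.5), ncol = 3)
    seeds <- voxel_to_world(seed_mask,
                            seed_vox[pick, , drop = FALSE] + jitter)
    n_seeded <- n_seeded + batch_size
    for (i in seq_len(batch_size)) {
      sl <- track_streamline(tf, seeds[i, ], atlas, pm)
      if (sl$status != "accepted") next
      if (length(includes) &&
          !all(vapply(includes, polyline_hits_mask, TRUE,
                      points = sl$points))) next
      if (length(excludes) &&
          any(vapply(excludes, polyline_hits_mask, TRUE,
                     points = sl$points))) next
      accepted[[length(accepted) + 1]] <- sl
      if (length(accepted) >= spec$min_fibers) break
    }
  }
  structure(list(name = spec$name, streamlines = accepted,
                 iterations_used = iterations, n_seeded = n_seeded,
                 rng_seed = as.integer(rng_seed),
                 reached_min_fibers = length(accepted) >= spec$min_fibers),
            class = "tfus_bundle")
}

#' @export
print.tfus_bundle <- function(x, ...) {
  cat(sprintf("<bundle %s> %d accepted streamlines in %d iterations%s\n",
              x$name, length(x$streamlines), x$iterations_used,
              if (x$reached_min_fibers) "" else " (minimum fiber count NOT reached)"))
  invisible(x)
}

#' Streamline visitation probability map
#'
#' Counts, per voxel of the template grid, the number of distinct accepted
#' streamlines visiting the voxel (multiple visits by one streamline count
#' once), divides by the total number of accepted streamlines, and rescales
#' so the maximum is 1.
#'
#' @param bundle a [track_bundle()] result with >= 1 accepted streamline.
#' @param grid template [volume()] defining the output grid.
#' @return An object of class `tfus_probmap`: `map` ([volume()] in [0, 1]),
#'   `threshold` (`NA` until thresholded), `bundle_name`, `n_streamlines`.
#' @export
probability_map <- function(bundle, grid) {
  stopifnot(inherits(bundle, "tfus_bundle"), is_volume(grid))
  n <- length(bundle$streamlines)
  if (n == 0) stop("bundle '", bundle$name, "' has no accepted streamlines",
                   call. = FALSE)
  d <- dim(grid$data)[1:3]
  counts <- array(0, d)
  for (sl in bundle$streamlines) {
    v <- visited_voxels(grid, sl$points)
    counts[v + 1] <- counts[v + 1] + 1
  }
  p <- counts / n
  mx <- max(p)
  if (mx > 0) p <- p / mx
  structure(list(map = volume(p, grid$affine), threshold = NA_real_,
                 bundle_name = bundle$name, n_streamlines = n),
            class = "tfus_probmap")
}

#' @export
print.tfus_probmap <- function(x, ...) {
  cat(sprintf("<probability map %s> %d streamlines, %d suprathreshold voxels%s\n",
              x$bundle_name, x$n_streamlines, sum(x$map$data > 0),
              if (is.na(x$threshold)) " (unthresholded)"
              else sprintf(", threshold %.2f", x$threshold)))
  invisible(x)
}

#' Bundle-specific probability-map thresholds
#'
#' Default thresholds on the [0, 1]-scaled maps: the adaptive fiber
#' tracking (AFT) pipeline thresholds CTT/PTT/CST maps at 0.2 and ML maps
#' at 0.5; FSL-derived maps use 0.1 for every bundle. Thresholds are
#' inclusive: a voxel exactly at the threshold is retained.
#'
#' @param p an unthresholded [probability_map()].
#' @param bundle_name one of `"CTT"`, `"PTT"`, `"CST"`, `"ML"`.
#' @param pipeline `"AFT"` (default) or `"FSL"`.
#' @param thresholds optional named override list, e.g.
#'   `list(AFT = c(CTT = 0.2, PTT = 0.2, CST = 0.2, ML = 0.5))`.
#' @return the map with sub-threshold voxels zeroed and `threshold` set.
#' @export
threshold_map <- function(p, bundle_name = p$bundle_name,
                          pipeline = c("AFT", "FSL"), thresholds = NULL) {
  stopifnot(inherits(p, "tfus_probmap"))
  if (!is.na(p$threshold)) stop("map is already thresholded", call. = FALSE)
  pipeline <- match.arg(pipeline)
  defaults <- list(AFT = c(CTT = 0.2, PTT = 0.2, CST = 0.2, ML = 0.5),
                   FSL = c(CTT = 0.1, PTT = 0.1, CST = 0.1, ML = 0.1))
  tab <- defaults
  if (!is.null(thresholds)) tab <- utils::modifyList(defaults, thresholds)
  row <- tab[[pipeline]]
  if (!bundle_name %in% names(row))
    stop("unknown bundle name '", bundle_name, "'", call. = FALSE)
  thr <- unname(row[[bundle_name]])
  m <- p$map$data
  m[m < thr] <- 0
  if (all(m == 0))
    warning("all probability-map voxels fall below the ", pipeline,
            " threshold ", thr, " for ", bundle_name, call. = FALSE)
  p$map$data <- m
  p$threshold <- thr
  p
}

#' Write streamlines as a TrackVis .trk file
#'
#' Minimal TrackVis writer: points are stored in the .trk convention
#' (voxel-size-scaled voxel coordinates of the template grid, a.k.a.
#' "voxmm"), with the grid's dimensions and voxel size in the header.
#'
#' @param bundle a [track_bundle()] result.
#' @param grid template [volume()] supplying dimensions and voxel size.
#' @param path output `.trk` path.
#' @export
save_trk <- function(bundle, grid, path) {
  stopifnot(inherits(bundle, "tfus_bundle"), is_volume(grid))
  con <- file(path, "wb")
  on.exit(close(con))
  wr_char <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }
  d <- dim(grid$data)[1:3]
  wr_char("TRACK", 6)                                   # id_string
  writeBin(as.integer(d), con, size = 2)                # dim, int16
  writeBin(as.numeric(grid$spacing), con, size = 4)     # voxel_size
  writeBin(rep(0, 3), con, size = 4)                    # origin
  writeBin(0L, con, size = 2)                           # n_scalars
  writeBin(raw(200), con)                               # scalar names
  writeBin(0L, con, size = 2)                           # n_properties
  writeBin(raw(200), con)                               # property names
  writeBin(as.numeric(t(grid$affine)), con, size = 4)   # vox_to_ras
  writeBin(raw(444), con)                               # reserved
  wr_char("LPS", 4)                                     # voxel_order
  wr_char("", 4)                                        # pad2
  writeBin(rep(0, 6), con, size = 4)                    # image orientation
  writeBin(raw(2 + 6), con)                             # pad1 + invert flags
  writeBin(length(bundle$streamlines), con, size = 4)   # n_count
  writeBin(2L, con, size = 4)                           # version
  writeBin(1000L, con, size = 4)                        # hdr_size
  for (sl in bundle$streamlines) {
    vox <- world_to_voxel(grid, sl$points)
    voxmm <- sweep(vox + 0.5, 2, grid$spacing, "*")
    writeBin(nrow(voxmm), con, size = 4)
    writeBin(as.numeric(t(voxmm)), con, size = 4)
  }
  invisible(path)
}

#' Read back a TrackVis .trk file written by [save_trk()]
#'
#' @param path `.trk` path.
#' @param grid the template [volume()] used at write time (to restore world
#'   coordinates).
#' @return list with `n_count` and `streamlines` (list of n x 3 world-mm
#'   matrices).
#' @export
load_trk <- function(path, grid) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, "raw", 6)[1:5])
  if (id != "TRACK") stop("not a TrackVis file: ", path, call. = FALSE)
  dims <- readBin(con, "integer", 3, size = 2)
  voxel_size <- readBin(con, "numeric", 3, size = 4)
  seek(con, 988)
  n_count <- readBin(con, "integer", 1, size = 4)
  seek(con, 1000)
  out <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4)
    pts <- matrix(readBin(con, "numeric", 3 * np, size = 4),
                  ncol = 3, byrow = TRUE)
    vox <- sweep(pts, 2, voxel_size, "/") - 0.5
    out[[i]] <- voxel_to_world(grid, vox)
  }
  list(n_count = n_count, streamlines = out, dims = dims,
       voxel_size = voxel_size)
}

#' Save a probability map as NIfTI plus JSON summary
#'
#' @param p a [probability_map()] (thresholded or not).
#' @param prefix output prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @export
save_probmap <- function(p, prefix) {
  save_volume(p$map, paste0(prefix, ".nii.gz"))
  jsonlite::write_json(list(bundle = p$bundle_name,
                            n_streamlines = p$n_streamlines,
                            threshold = if (is.na(p$threshold)) NULL
                                        else p$threshold,
                            suprathreshold_voxels = sum(p$map$data > 0)),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
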