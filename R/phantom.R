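#' Synthetic diffusion gradient scheme
#'
#' Deterministic gradient table emulating the planning protocol: one b = 0
#' frame followed by `n_dirs` unit directions (spherical Fibonacci lattice)
#' at a single shell.
#'
#' @param n_dirs number of diffusion-weighted directions (default 56).
#' @param bval shell b-value in s/mm^2 (default 1200).
#' @param n_b0 number of leading b = 0 frames.
#' @return A [diffusion_scheme()].
#' @export
make_scheme <- function(n_dirs = 56L, bval = 1200, n_b0 = 1L) {
  i <- seq_len(n_dirs) - 0.5
  phi <- acos(1 - 2 * i / n_dirs)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- rbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  diffusion_scheme(c(rep(0, n_b0), rep(bval, n_dirs)),
                   cbind(matrix(0, 3, n_b0), dirs))
}

#' Phantom specification
#'
#' Declares the geometry and signal model of a synthetic planning dataset:
#' a single fiber bundle (straight segment or circular arc) embedded as a
#' tube of anisotropic tensors in an isotropic low-FA background, with
#' seed/include/exclude ROIs on the corridor, a two-region atlas, AC/PC
#' landmarks, a spherical lesion and a treatment log.
#'
#' @param shape `"straight"` or `"arc"`.
#' @param grid_shape 3 integers, voxels (default 64^3).
#' @param spacing_mm isotropic voxel size (default 1).
#' @param radius_mm tube radius (default 4).
#' @param arc_radius_mm radius of the arc centreline (arc shape only,
#'   default 20).
#' @param eigenvalues bundle tensor eigenvalues, mm^2/s (default
#'   `c(1.7, 0.3, 0.3) * 1e-3`).
#' @param background_adc isotropic background diffusivity, mm^2/s.
#' @param s0 non-diffusion-weighted signal level.
#' @param noise `"none"` or `"gaussian"`.
#' @param snr signal-to-noise ratio of the b = 0 signal when noise is
#'   enabled (default 20).
#' @param roi_radius_vox ROI sphere radius in voxels (default 3; 1 gives
#'   the small-nucleus hard mode).
#' @param seed RNG seed controlling noise and the treatment log.
#' @return An object of class `tfus_phantom_spec`.
#' @export
phantom_spec <- function(shape = c("straight", "arc"),
                         grid_shape = c(64L, 64L, 64L), spacing_mm = 1,
                         radius_mm = 4, arc_radius_mm = 20,
                         eigenvalues = c(1.7, 0.3, 0.3) * 1e-3,
                         background_adc = 0.7e-3, s0 = 1000,
                         noise = c("gaussian", "none"), snr = 20,
                         roi_radius_vox = 3, seed = 42L) {
  shape <- match.arg(shape)
  noise <- match.arg(noise)
  if (noise == "gaussian" && snr <= 0) stop("snr must be > 0", call. = FALSE)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L), spacing_mm > 0,
            radius_mm > 0, length(eigenvalues) == 3L,
            all(diff(eigenvalues) <= 0))
  structure(list(shape = shape, grid_shape = as.integer(grid_shape),
                 spacing_mm = spacing_mm, radius_mm = radius_mm,
                 arc_radius_mm = arc_radius_mm, eigenvalues = eigenvalues,
                 background_adc = background_adc, s0 = s0, noise = noise,
                 snr = snr, roi_radius_vox = roi_radius_vox,
                 seed = as.integer(seed)),
            class = "tfus_phantom_spec")
}

# Centreline sample points and tangents (world mm) of the phantom bundle.
phantom_centerline <- function(spec, n = 200) {
  ext <- spec$grid_shape * spec$spacing_mm
  ctr <- ext / 2
  if (spec$shape == "straight") {
    y <- seq(0.125 * ext[2], 0.875 * ext[2], length.out = n)
    pts <- cbind(ctr[1], y, ctr[3])
    tan <- matrix(rep(c(0, 1, 0), n), ncol = 3, byrow = TRUE)
  } else {
    r <- spec$arc_radius_mm
    cen <- c(ctr[1] - r / 2, ctr[2] - r / 2, ctr[3])
    th <- seq(0, pi / 2, length.out = n)
    pts <- cbind(cen[1] + r * cos(th), cen[2] + r * sin(th), cen[3])
    tan <- cbind(-sin(th), cos(th), 0)
  }
  list(points = pts, tangents = tan)
}

# Per-voxel distance to the centreline and tangent of the nearest sample.
# Points whose nearest sample is an endpoint are flagged as beyond the
# tube: the bundle ends flush with the centreline instead of growing
# spherical caps, so tracked lengths match the analytic centreline length.
nearest_centerline <- function(spec, world) {
  cl <- phantom_centerline(spec, n = 400)
  nvox <- nrow(world)
  ncl <- nrow(cl$points)
  # brute-force nearest over centreline samples, blocked to bound memory
  dist <- numeric(nvox); idx <- integer(nvox)
  block <- 20000L
  for (s in seq(1, nvox, block)) {
    e <- min(s + block - 1L, nvox)
    w <- world[s:e, , drop = FALSE]
    d2 <- outer(rowSums(w^2), rep(1, ncl)) -
      2 * w %*% t(cl$points) +
      outer(rep(1, nrow(w)), rowSums(cl$points^2))
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dist[s:e] <- sqrt(pmax(d2[cbind(seq_len(nrow(w)), j)], 0))
  }
  beyond <- idx == 1L | idx == ncl
  list(dist = dist, tangent = cl$tangents[idx, , drop = FALSE],
       beyond = beyond)
}

sphere_mask <- function(grid, center_mm, radius_mm) {
  w <- voxel_to_world(grid, voxel_index_grid(dim(grid$data)[1:3]))
  d <- sqrt(rowSums(sweep(w, 2, center_mm)^2))
  volume(array(as.numeric(d <= radius_mm), dim(grid$data)[1:3]), grid$affine)
}

#' Generate a synthetic planning dataset
#'
#' Builds the full set of inputs a planning run needs: a 4D DWI volume
#' forward-simulated from the ground-truth tensor field
#' (`S = S0 exp(-b g' D g)` plus optional Gaussian noise), the tensor-field
#' truth itself, seed/include/exclude ROI masks on the bundle corridor, a
#' two-region atlas partitioning the corridor, AC/PC landmarks, a T1-like
#' anatomical volume, a spherical lesion near the corridor midpoint, and a
#' treatment log sampled around the standard coordinate with temperatures
#' straddling the 55 degree C therapeutic criterion. Deterministic for a
#' fixed `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param scheme a [diffusion_scheme()]; default [make_scheme()].
#' @param side treated side for the landmark/treatment components.
#' @return list with elements `dwi`, `scheme`, `tensor_truth`, `rois`
#'   ([roi_set()]), `bundle_specs`, `atlas`, `landmarks`, `t1`, `lesion`,
#'   `treatment` (data.frame), `std_coord_acpc`, `centerline`, `spec`.
#' @export
make_phantom <- function(spec, scheme = make_scheme(), side = "left") {
  stopifnot(inherits(spec, "tfus_phantom_spec"))
  d <- spec$grid_shape
  aff <- diag(c(rep(spec$spacing_mm, 3), 1))
  aff[1:3, 4] <- spec$spacing_mm / 2   # voxel centres at (i + 0.5) * spacing
  grid <- volume(array(0, d), aff)
  world <- voxel_to_world(grid, voxel_index_grid(d))
  nc <- nearest_centerline(spec, world)
  inside <- nc$dist <= spec$radius_mm & !nc$beyond
  ext <- d * spec$spacing_mm
  if (spec$shape == "straight") {
    cl <- phantom_centerline(spec, 2)
    if (any(cl$points < 0) || any(cl$points > rep(ext, each = 2)))
      stop("bundle exits the grid", call. = FALSE)
  }

  # ground-truth tensors: anisotropic along the local tangent inside the
  # tube, isotropic background outside
  nvox <- prod(d)
  lam <- spec$eigenvalues
  tens <- matrix(0, nvox, 6)
  iso <- spec$background_adc
  tens[, 1] <- iso; tens[, 3] <- iso; tens[, 6] <- iso
  if (any(inside)) {
    t1v <- nc$tangent[inside, , drop = FALSE]
    # D = (l1 - l23) t t' + l23 I
    l23 <- lam[2]
    dl <- lam[1] - l23
    tens[inside, 1] <- dl * t1v[, 1]^2 + l23
    tens[inside, 2] <- dl * t1v[, 1] * t1v[, 2]
    tens[inside, 3] <- dl * t1v[, 2]^2 + l23
    tens[inside, 4] <- dl * t1v[, 1] * t1v[, 3]
    tens[inside, 5] <- dl * t1v[, 2] * t1v[, 3]
    tens[inside, 6] <- dl * t1v[, 3]^2 + l23
  }
  tensor_truth <- structure(
    list(tensors = array(tens, c(d, 6L)), s0 = array(spec$s0, d),
         mask = array(TRUE, d), affine = aff),
    class = "tfus_tensor_field")

  # forward-simulated DWI
  g <- scheme$bvecs; b <- scheme$bvals
  nfr <- length(b)
  B <- cbind(g[1, ]^2, 2 * g[1, ] * g[2, ], g[2, ]^2,
             2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ], g[3, ]^2) * b
  sig <- spec$s0 * exp(-tens %*% t(B))   # nvox x nfr
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  if (spec$noise == "gaussian")
    sig <- sig + stats::rnorm(length(sig), sd = spec$s0 / spec$snr)
  dwi <- volume(array(sig, c(d, nfr)), aff)

  # ROIs on the corridor: seed at one end, include at the other, a
  # mid-corridor include, an exclude blocking the corridor, and an exclude
  # far off it
  cl <- phantom_centerline(spec, n = 200)
  npts <- nrow(cl$points)
  ends <- list(start = cl$points[10, ], mid = cl$points[npts %/% 2, ],
               end = cl$points[npts - 9, ])
  r_roi <- spec$roi_radius_vox * spec$spacing_mm
  off_point <- c(ext[1] * 0.15, ext[2] * 0.5, ext[3] * 0.15)
  rois <- roi_set(list(
    corridor_start = sphere_mask(grid, ends$start, r_roi),
    corridor_mid = sphere_mask(grid, ends$mid, r_roi),
    corridor_end = sphere_mask(grid, ends$end, r_roi),
    corridor_block = sphere_mask(grid, ends$mid, spec$radius_mm + 1),
    off_corridor = sphere_mask(grid, off_point, r_roi)))

  bundle_specs <- list(
    CTT = bundle_spec("CTT", "corridor_start",
                      include_rois = c("corridor_mid", "corridor_end"),
                      max_iterations = 2500L),
    PTT = bundle_spec("PTT", "corridor_start",
                      include_rois = "corridor_end"),
    CST = bundle_spec("CST", "corridor_start",
                      include_rois = "corridor_end",
                      exclude_rois = "off_corridor"),
    ML = bundle_spec("ML", "corridor_end",
                     include_rois = "corridor_start"))

  # two-region atlas partitioning the corridor along its course
  wy <- world[, 2]
  atlas <- volume(array(as.integer(ifelse(wy < ext[2] / 2, 1L, 2L)), d), aff)

  # AC/PC landmarks on the midline, already axis-aligned
  pc <- c(ext[1] / 2, ext[2] * 0.3, ext[3] / 2)
  ac <- pc + c(0, 24, 0)
  lm <- landmark_pair(ac, pc)

  # T1-like anatomical image: bright tissue ellipsoid + corridor contrast
  cw <- sweep(world, 2, ext / 2)
  r2 <- rowSums(sweep(cw, 2, ext * 0.45, "/")^2)
  t1dat <- 100 + 900 * exp(-r2) + 300 * exp(-(nc$dist / spec$radius_mm)^2)
  t1 <- volume(array(t1dat, d), aff)

  lesion_ctr <- ends$mid + c(2, 0, 1)
  lesion <- sphere_mask(grid, lesion_ctr, 3)

  # treatment log around the AC-PC-space standard coordinate
  lm_acpc <- landmark_pair(c(0, 24, 0), c(0, 0, 0))
  sc <- standard_coordinate(lm_acpc, side)
  k <- 5L
  pts <- sweep(matrix(stats::rnorm(3 * k, sd = 1), ncol = 3), 2, sc$point, "+")
  temps <- c(58, 56.5, 55, 54, 52.5)   # straddle the 55 C criterion
  treatment <- data.frame(patient = "phantom-01",
                          x = pts[, 1], y = pts[, 2], z = pts[, 3],
                          temp_c = temps[seq_len(k)])

  list(dwi = dwi, scheme = scheme, tensor_truth = tensor_truth, rois = rois,
       bundle_specs = bundle_specs, atlas = atlas, landmarks = lm, t1 = t1,
       lesion = lesion, treatment = treatment, std_coord_acpc = sc,
       centerline = cl, spec = spec, side = side)
}

#' Write a phantom dataset to disk
#'
#' Emits every component in the external dialects the pipeline reads
#' (NIfTI, bval/bvec, manifest/landmark JSON, treatment CSV, bundle and
#' parameter YAML/JSON) plus a manifest listing all paths and the
#' ground-truth parameters.
#'
#' @param ph a [make_phantom()] result.
#' @param out_dir output directory (created if needed).
#' @return the manifest as a list (also written to `manifest.json`).
#' @export
write_phantom_dataset <- function(ph, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "rois"), showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  save_volume(ph$t1, p("t1.nii.gz"))
  save_volume(ph$dwi, p("dwi.nii.gz"))
  save_scheme(ph$scheme, p("dwi.bval"), p("dwi.bvec"))
  save_volume(ph$atlas, p("atlas.nii.gz"))
  save_volume(ph$lesion, p("lesion.nii.gz"))
  save_landmarks(ph$landmarks, p("landmarks.json"))
  utils::write.csv(ph$treatment, p("treatment.csv"), row.names = FALSE)
  roi_paths <- list()
  for (nm in names(ph$rois$masks)) {
    rp <- file.path("rois", paste0(nm, ".nii.gz"))
    save_volume(ph$rois$masks[[nm]], p(rp))
    roi_paths[[nm]] <- rp
  }
  # the ROI manifest holds paths relative to its own directory
  jsonlite::write_json(lapply(roi_paths, basename),
                       p("rois", "manifest.json"), auto_unbox = TRUE)
  bundles <- lapply(ph$bundle_specs, function(sp)
    list(name = sp$name, seed_roi = sp$seed_roi,
         include_rois = sp$include_rois, exclude_rois = sp$exclude_rois,
         min_fibers = sp$min_fibers, max_iterations = sp$max_iterations))
  jsonlite::write_json(bundles, p("bundles.json"), auto_unbox = TRUE)
  yaml::write_yaml(region_parameter_map()$defaults, p("params.yaml"))
  manifest <- list(
    files = c(list(t1 = "t1.nii.gz", dwi = "dwi.nii.gz",
                   bval = "dwi.bval", bvec = "dwi.bvec",
                   atlas = "atlas.nii.gz", lesion = "lesion.nii.gz",
                   landmarks = "landmarks.json",
                   treatment = "treatment.csv",
                   roi_manifest = "rois/manifest.json",
                   bundles = "bundles.json", params = "params.yaml"),
              list(rois = roi_paths)),
    truth = list(shape = ph$spec$shape,
                 grid_shape = ph$spec$grid_shape,
                 spacing_mm = ph$spec$spacing_mm,
                 radius_mm = ph$spec$radius_mm,
                 eigenvalues = ph$spec$eigenvalues,
                 background_adc = ph$spec$background_adc,
                 s0 = ph$spec$s0, noise = ph$spec$noise,
                 snr = ph$spec$snr, seed = ph$spec$seed,
                 side = ph$side,
                 std_coord_acpc = ph$std_coord_acpc$point))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read bundle specifications from JSON
#'
#' @param path JSON written by [write_phantom_dataset()] (named list of
#'   bundle definitions).
#' @return named list of [bundle_spec()] objects.
#' @export
load_bundle_specs <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(j, function(sp)
    bundle_spec(sp$name, sp$seed_roi,
                include_rois = unlist(sp$include_rois),
                exclude_rois = unlist(sp$exclude_rois) %||% character(),
                min_fibers = sp$min_fibers,
                max_iterations = sp$max_iterations))
}
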