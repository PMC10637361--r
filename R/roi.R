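#' Bundle specification
#'
#' Defines a named tract by its seed region, the include (waypoint) regions
#' every accepted streamline must traverse, the exclude regions no accepted
#' streamline may touch, and the iteration contract of the tracking loop:
#' seeding is repeated until at least `min_fibers` streamlines are accepted
#' or `max_iterations` seeding rounds have run.
#'
#' @param name bundle name (e.g. `"CTT"`).
#' @param seed_roi name of the seed mask.
#' @param include_rois character vector of include mask names.
#' @param exclude_rois character vector of exclude mask names.
#' @param min_fibers minimum accepted streamlines (>= 1).
#' @param max_iterations seeding-round cap (>= 1).
#' @return An object of class `tfus_bundle_spec`.
#' @export
bundle_spec <- function(name, seed_roi, include_rois = character(),
                        exclude_rois = character(),
                        min_fibers = 100L, max_iterations = 500L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(seed_roi), length(seed_roi) == 1L)
  min_fibers <- as.integer(min_fibers)
  max_iterations <- as.integer(max_iterations)
  if (min_fibers < 1L) stop("min_fibers must be >= 1", call. = FALSE)
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  if (seed_roi %in% exclude_rois)
    stop("seed ROI '", seed_roi, "' cannot also be an exclude ROI",
         call. = FALSE)
  structure(list(name = name, seed_roi = seed_roi,
                 include_rois = as.character(include_rois),
                 exclude_rois = as.character(exclude_rois),
                 min_fibers = min_fibers, max_iterations = max_iterations),
            class = "tfus_bundle_spec")
}

#' @export
print.tfus_bundle_spec <- function(x, ...) {
  cat(sprintf("<bundle %s> seed %s | include: %s | exclude: %s | >=%d fibers, <=%d iterations\n",
              x$name, x$seed_roi,
              paste(x$include_rois, collapse = ", "),
              if (length(x$exclude_rois)) paste(x$exclude_rois, collapse = ", ") else "-",
              x$min_fibers, x$max_iterations))
  invisible(x)
}

opposite_side <- function(side) if (side == "left") "right" else "left"

#' Default bundle definitions for tcMRgFUS planning
#'
#' The four planning bundles with their anatomical seed/include/exclude
#' regions: the cerebellothalamic tract (CTT) and pallidothalamic tract
#' (PTT) as treatment targets, and the corticospinal tract (CST) and medial
#' lemniscus (ML) as no-go bundles. ROI names are prefixed with the
#' resolved laterality (`left_`/`right_`): "ipsilateral" resolves to the
#' treated side, "contralateral" to the opposite side (the CTT decussates,
#' so its cerebellar regions lie contralateral to its cortical seed).
#' The CTT allows up to 2500 seeding rounds because streamlines must thread
#' both the small red nucleus and the thalamus; all other bundles cap at
#' 500. Every bundle requires at least 100 accepted fibers.
#'
#' @param side treated side, `"left"` or `"right"`.
#' @return named list of four [bundle_spec()] objects (CTT, PTT, CST, ML).
#' @export
default_bundle_specs <- function(side = c("left", "right")) {
  side <- match.arg(side)
  ipsi <- side
  contra <- opposite_side(side)
  rn <- function(lat, nm) paste0(lat, "_", nm)
  list(
    CTT = bundle_spec(
      "CTT",
      seed_roi = rn(ipsi, "precentral_gyrus"),
      include_rois = c(rn(contra, "dentate_nucleus"),
                       rn(contra, "superior_cerebellar_peduncle"),
                       rn(ipsi, "red_nucleus"),
                       rn(ipsi, "thalamus")),
      max_iterations = 2500L),
    PTT = bundle_spec(
      "PTT",
      seed_roi = rn(ipsi, "globus_pallidus_interna"),
      include_rois = rn(ipsi, "frontal_thalamus")),
    CST = bundle_spec(
      "CST",
      seed_roi = rn(ipsi, "precentral_gyrus"),
      include_rois = c(rn(ipsi, "cerebral_peduncle"),
                       rn(ipsi, "posterior_limb_internal_capsule")),
      exclude_rois = rn(ipsi, "thalamus")),
    ML = bundle_spec(
      "ML",
      seed_roi = rn(ipsi, "midbrain_medial_lemniscus"),
      include_rois = c(rn(ipsi, "postcentral_gyrus"),
                       rn(ipsi, "thalamus")))
  )
}

#' Region-adaptive tracking parameter map
#'
#' Tracking parameters with per-atlas-label overrides: at every tracking
#' position the covering atlas label is looked up (nearest voxel, labels
#' are never interpolated) and, if an override exists for that label, its
#' values replace the defaults field-by-field.
#'
#' @param step_mm Euler step length, mm.
#' @param fa_threshold stop when local FA falls below this, in [0, 1).
#' @param max_angle_deg stop when the bend between successive steps exceeds
#'   this, degrees in (0, 90].
#' @param min_length_mm,max_length_mm accepted streamline length range, mm.
#' @param overrides named list keyed by atlas label id (as character), each
#'   a list with any subset of the five parameter fields.
#' @return An object of class `tfus_region_params`.
#' @export
region_parameter_map <- function(step_mm = 1, fa_threshold = 0.15,
                                 max_angle_deg = 45,
                                 min_length_mm = 20, max_length_mm = 200,
                                 overrides = list()) {
  defaults <- list(step_mm = step_mm, fa_threshold = fa_threshold,
                   max_angle_deg = max_angle_deg,
                   min_length_mm = min_length_mm,
                   max_length_mm = max_length_mm)
  validate_params(defaults)
  merged <- lapply(overrides, function(ov) {
    p <- utils::modifyList(defaults, ov[names(ov) %in% names(defaults)])
    validate_params(p)
    p
  })
  if (length(merged) && is.null(names(merged)))
    stop("overrides must be named by atlas label id", call. = FALSE)
  structure(list(defaults = defaults, overrides = merged),
            class = "tfus_region_params")
}

validate_params <- function(p) {
  if (p$step_mm <= 0) stop("step_mm must be > 0", call. = FALSE)
  if (p$fa_threshold < 0 || p$fa_threshold >= 1)
    stop("fa_threshold must be in [0, 1)", call. = FALSE)
  if (p$max_angle_deg <= 0 || p$max_angle_deg > 90)
    stop("max_angle_deg must be in (0, 90]", call. = FALSE)
  if (p$min_length_mm >= p$max_length_mm)
    stop("min_length_mm must be below max_length_mm", call. = FALSE)
  invisible(p)
}

#' Look up tracking parameters at a world position
#'
#' @param pm a [region_parameter_map()].
#' @param atlas integer-label [volume()] or `NULL` (defaults apply
#'   everywhere).
#' @param point world-mm position.
#' @param warn warn when the point falls outside the atlas grid.
#' @return list of the five tracking parameters in force at `point`.
#' @export
params_at <- function(pm, atlas, point, warn = TRUE) {
  stopifnot(inherits(pm, "tfus_region_params"))
  if (is.null(atlas) || length(pm$overrides) == 0L) return(pm$defaults)
  v <- round(world_to_voxel(atlas, as.numeric(point)))
  d <- dim(atlas$data)[1:3]
  if (any(v < 0) || any(v > d - 1)) {
    if (warn) warning("point (", paste(signif(point, 4), collapse = ", "),
                      ") lies outside the atlas grid; using defaults",
                      call. = FALSE)
    return(pm$defaults)
  }
  lab <- atlas$data[v[1] + 1, v[2] + 1, v[3] + 1]
  ov <- pm$overrides[[as.character(lab)]]
  if (is.null(ov)) pm$defaults else ov
}

# Flatten a parameter map into the (1+n_override) x 5 table + label vector
# consumed by the C++ tracker. Row 1 holds the defaults.
param_table <- function(pm) {
  rows <- c(list(pm$defaults), unname(pm$overrides))
  tab <- do.call(rbind, lapply(rows, function(p)
    c(p$step_mm, p$fa_threshold, p$max_angle_deg, p$min_length_mm,
      p$max_length_mm)))
  labels <- suppressWarnings(as.integer(names(pm$overrides)))
  if (anyNA(labels) && length(pm$overrides))
    stop("override names must be integer atlas labels", call. = FALSE)
  list(table = tab, labels = labels)
}

#' Assemble a named set of ROI masks
#'
#' @param masks named list of binary 3D [volume()] objects on a common grid.
#' @return An object of class `tfus_roiset`.
#' @export
roi_set <- function(masks) {
  stopifnot(is.list(masks), length(masks) > 0, !is.null(names(masks)))
  ref <- masks[[1]]
  for (m in masks) {
    stopifnot(is_volume(m))
    if (!all(dim(m$data)[1:3] == dim(ref$data)[1:3]) ||
        max(abs(m$affine - ref$affine)) > 1e-6)
      stop("all ROI masks must share one grid", call. = FALSE)
  }
  structure(list(masks = masks), class = "tfus_roiset")
}

#' @export
print.tfus_roiset <- function(x, ...) {
  cat("<tfus_roiset>", length(x$masks), "masks:",
      paste(names(x$masks), collapse = ", "), "\n")
  invisible(x)
}

#' Validate an ROI set against bundle specifications
#'
#' Checks that every mask referenced by any spec exists, is non-empty, and
#' sits on the common grid. Violations are collected into a report rather
#' than raised; empty seed masks are flagged fatal.
#'
#' @param rs a [roi_set()].
#' @param specs list of [bundle_spec()] objects.
#' @return data.frame report with columns `bundle`, `roi`, `role`,
#'   `problem`, `fatal`; zero rows when the set is complete.
#' @export
validate_roiset <- function(rs, specs) {
  stopifnot(inherits(rs, "tfus_roiset"))
  if (inherits(specs, "tfus_bundle_spec")) specs <- list(specs)
  rows <- list()
  add <- function(bundle, roi, role, problem, fatal) {
    rows[[length(rows) + 1]] <<- data.frame(bundle = bundle, roi = roi,
                                            role = role, problem = problem,
                                            fatal = fatal)
  }
  for (sp in specs) {
    refs <- rbind(data.frame(roi = sp$seed_roi, role = "seed"),
                  if (length(sp$include_rois))
                    data.frame(roi = sp$include_rois, role = "include"),
                  if (length(sp$exclude_rois))
                    data.frame(roi = sp$exclude_rois, role = "exclude"))
    for (i in seq_len(nrow(refs))) {
      nm <- refs$roi[i]; role <- refs$role[i]
      m <- rs$masks[[nm]]
      if (is.null(m)) {
        add(sp$name, nm, role, "missing mask", role == "seed")
      } else if (sum(m$data > 0) == 0) {
        add(sp$name, nm, role, "empty mask", role == "seed")
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(bundle = character(), roi = character(), role = character(),
                  problem = character(), fatal = logical())
}

#' Read an ROI manifest
#'
#' The manifest is a JSON object mapping ROI names to NIfTI paths
#' (relative paths resolved against the manifest's directory).
#'
#' @param path manifest JSON path.
#' @return A [roi_set()].
#' @export
load_roiset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  man <- jsonlite::fromJSON(path)
  base <- dirname(path)
  masks <- lapply(man, function(p) {
    p <- as.character(p)
    if (!file.exists(p)) p <- file.path(base, p)
    load_volume(p)
  })
  roi_set(masks)
}

#' Read a region parameter map from YAML or JSON
#'
#' Top-level keys are the five default parameters plus an optional
#' `overrides` mapping of atlas label ids to partial parameter sets.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [region_parameter_map()].
#' @export
load_parameter_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  do.call(region_parameter_map, cfg[names(cfg) %in%
    c("step_mm", "fa_threshold", "max_angle_deg", "min_length_mm",
      "max_length_mm", "overrides")])
}
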