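#' Planning run configuration
#'
#' Collects all inputs of an automatic planning run. Paths may be absolute
#' or relative to `base_dir`.
#'
#' @param t1 path to the anatomical T1-like NIfTI.
#' @param dwi,bval,bvec DWI NIfTI and FSL-style gradient table paths.
#' @param landmarks AC/PC landmark JSON path.
#' @param rois ROI manifest JSON path.
#' @param bundles bundle-spec JSON path.
#' @param atlas integer-label atlas NIfTI path (optional).
#' @param params region parameter map YAML/JSON path (optional).
#' @param treatment treatment-log CSV path (optional).
#' @param lesion lesion mask NIfTI path (optional).
#' @param side treated side, `"left"` or `"right"`.
#' @param seed RNG seed for all stochastic stages.
#' @param out_dir output directory.
#' @param target_spacing supersampling target, mm.
#' @param smoothing_sigma Gaussian width, mm.
#' @param register logical: rigidly register T1 to the DWI b0 (normalized
#'   gradient fields)?
#' @param batch_size tractography seeds per iteration.
#' @param base_dir directory against which relative paths resolve.
#' @return An object of class `tfus_plan_config`.
#' @export
plan_config <- function(t1, dwi, bval, bvec, landmarks, rois, bundles,
                        atlas = NULL, params = NULL, treatment = NULL,
                        lesion = NULL, side = c("left", "right"),
                        seed = 42L, out_dir = "plan_out",
                        target_spacing = 1, smoothing_sigma = 1,
                        register = FALSE, batch_size = 100L,
                        base_dir = ".") {
  side <- match.arg(side)
  res <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  cfg <- list(t1 = res(t1), dwi = res(dwi), bval = res(bval),
              bvec = res(bvec), landmarks = res(landmarks),
              rois = res(rois), bundles = res(bundles),
              atlas = res(atlas), params = res(params),
              treatment = res(treatment), lesion = res(lesion),
              side = side, seed = as.integer(seed), out_dir = out_dir,
              target_spacing = target_spacing,
              smoothing_sigma = smoothing_sigma, register = register,
              batch_size = as.integer(batch_size))
  required <- c("t1", "dwi", "bval", "bvec", "landmarks", "rois", "bundles")
  for (nm in required)
    if (is.null(cfg[[nm]]) || !file.exists(cfg[[nm]]))
      stop("required input '", nm, "' not found: ",
           cfg[[nm]] %||% "<missing>", call. = FALSE)
  for (nm in c("atlas", "params", "treatment", "lesion"))
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop("optional input '", nm, "' given but not found: ", cfg[[nm]],
           call. = FALSE)
  structure(cfg, class = "tfus_plan_config")
}

#' Read a planning configuration from YAML
#'
#' @param path YAML file whose keys match the [plan_config()] arguments;
#'   relative paths resolve against the YAML's directory.
#' @param ... overrides applied on top of the file.
#' @return A `tfus_plan_config`.
#' @export
load_plan_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(path)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(plan_config, cfg)
}

plan_stages <- c("acpc_alignment", "standard_coordinate", "registration",
                 "dti_preprocessing", "fiber_tracking",
                 "probability_thresholding", "evaluation")

#' Run the automatic planning pipeline
#'
#' Executes the full planning data flow: AC-PC alignment of the T1 and
#' derivation of the standard target coordinate; optional rigid T1-to-DWI
#' registration (normalized gradient fields); DWI preprocessing
#' (Lanczos-3 supersampling, Gaussian smoothing, Stejskal-Tanner tensor
#' fit); atlas-adaptive tracking of each configured bundle with
#' seed/include/exclude filtering and the minimum-fiber retry loop;
#' probability-map scaling and bundle-specific thresholding (maps are also
#' reoriented into AC-PC space, like every derived output); and, when a
#' treatment log or lesion mask is supplied, the distance evaluation
#' report. All outputs are written under `config$out_dir`; the run is
#' deterministic for a fixed `config$seed`.
#'
#' @param config a [plan_config()].
#' @return An object of class `tfus_plan_report`: per-stage status and
#'   timings, the standard coordinate, per-bundle summaries, and output
#'   paths. Fatal stage errors are re-raised with a stage tag.
#' @export
plan <- function(config) {
  stopifnot(inherits(config, "tfus_plan_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), outputs = list(), side = config$side,
                 seed = config$seed)
  t_all <- proc.time()[3]
  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
    report$stages[[name]] <<- list(status = "ok",
                                   seconds = round(proc.time()[3] - t0, 3))
    res
  }

  lm <- run_stage("acpc_alignment-inputs", function()
    load_landmarks(config$landmarks))
  t1 <- run_stage("acpc_alignment", function() load_volume(config$t1))
  acpc <- acpc_transform(lm)
  t1_acpc <- reorient_to_acpc(t1, acpc, config$target_spacing)
  save_volume(t1_acpc, file.path(config$out_dir, "t1_acpc.nii"))

  sc <- run_stage("standard_coordinate", function() {
    lm_acpc <- landmark_pair(apply_rigid(acpc, lm$ac),
                             apply_rigid(acpc, lm$pc))
    standard_coordinate(lm_acpc, config$side)
  })
  jsonlite::write_json(list(point_acpc_mm = sc$point, side = sc$side),
                       file.path(config$out_dir, "standard_coordinate.json"),
                       auto_unbox = TRUE, digits = NA)

  inputs <- run_stage("dti_prep-inputs", function() {
    list(dwi = load_volume(config$dwi),
         scheme = load_scheme(config$bval, config$bvec))
  })

  reg <- NULL
  if (isTRUE(config$register)) {
    reg <- run_stage("registration", function() {
      b0 <- inputs$dwi$data[, , , which(inputs$scheme$is_b0)[1]]
      register_rigid(volume(b0, inputs$dwi$affine), t1, n_levels = 3)
    })
  } else {
    report$stages[["registration"]] <- list(status = "skipped", seconds = 0)
  }

  tf <- run_stage("dti_preprocessing", function()
    prepare_dti(inputs$dwi, inputs$scheme,
                target_spacing = config$target_spacing,
                sigma_mm = config$smoothing_sigma))

  rois <- run_stage("fiber_tracking-inputs", function()
    load_roiset(config$rois))
  specs <- load_bundle_specs(config$bundles)
  atlas <- if (!is.null(config$atlas)) load_volume(config$atlas)
  pm <- if (!is.null(config$params)) load_parameter_map(config$params)
        else region_parameter_map()

  grid <- volume(tf$s0, tf$affine)
  bundles <- run_stage("fiber_tracking", function() {
    out <- list()
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      out[[sp$name]] <- track_bundle(sp, rois, tf, atlas, pm,
                                     rng_seed = config$seed + i,
                                     batch_size = config$batch_size)
    }
    out
  })
  report$bundles <- lapply(bundles, function(b)
    list(accepted = length(b$streamlines),
         iterations_used = b$iterations_used,
         reached_min_fibers = b$reached_min_fibers))

  maps <- run_stage("probability_thresholding", function() {
    out <- list()
    for (nm in names(bundles)) {
      b <- bundles[[nm]]
      trk <- file.path(config$out_dir, paste0(nm, ".trk"))
      save_trk(b, grid, trk)
      report$outputs[[paste0("trk_", nm)]] <<- trk
      if (length(b$streamlines) == 0) next
      p <- threshold_map(probability_map(b, grid), nm, pipeline = "AFT")
      # derived maps get the same AC-PC reorientation as the planning image
      p$map <- reorient_to_acpc(p$map, acpc, config$target_spacing)
      save_probmap(p, file.path(config$out_dir, paste0(nm, "_probmap")))
      report$outputs[[paste0("probmap_", nm)]] <<-
        file.path(config$out_dir, paste0(nm, "_probmap.nii.gz"))
      out[[nm]] <- p
    }
    out
  })

  if (!is.null(config$treatment) || !is.null(config$lesion)) {
    ev <- run_stage("evaluation", function() {
      treatment <- if (!is.null(config$treatment)) {
        recs <- load_treatment_log(config$treatment, sc)
        recs[[1]]
      }
      lesion <- if (!is.null(config$lesion)) {
        les <- load_volume(config$lesion)
        lm_mask <- reorient_to_acpc(les, acpc, config$target_spacing)
        lm_mask$data <- array(as.numeric(lm_mask$data >= 0.5),
                              dim(lm_mask$data))
        lm_mask
      }
      rep_df <- evaluation_report(maps, sc, treatment, lesion)
      out <- list(table = rep_df)
      if (!is.null(treatment)) out$dev_mm <- dev_mm(treatment)
      if (!is.null(treatment)) out$xdev_mm <- xdev_mm(treatment)
      out
    })
    report$evaluation <- ev
    jsonlite::write_json(
      list(per_bundle = ev$table, dev_mm = ev$dev_mm, xdev_mm = ev$xdev_mm),
      file.path(config$out_dir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    report$stages[["evaluation"]] <- list(status = "skipped", seconds = 0)
  }

  report$standard_coordinate <- sc$point
  report$registration <- if (!is.null(reg))
    list(final_distance = reg$final_distance, levels = reg$levels_used)
  report$total_seconds <- round(proc.time()[3] - t_all, 3)
  report$stage_order <- plan_stages
  class(report) <- "tfus_plan_report"
  jsonlite::write_json(plan_report_json(report),
                       file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

plan_report_json <- function(r) {
  list(side = r$side, seed = r$seed,
       standard_coordinate_acpc_mm = r$standard_coordinate,
       stages = r$stages, bundles = r$bundles,
       outputs = r$outputs, total_seconds = r$total_seconds)
}

#' @export
print.tfus_plan_report <- function(x, ...) {
  cat("<tfus_plan_report> side", x$side, "| seed", x$seed, "\n")
  cat(sprintf("  standard coordinate (AC-PC mm): (%.2f, %.2f, %.2f)\n",
              x$standard_coordinate[1], x$standard_coordinate[2],
              x$standard_coordinate[3]))
  for (nm in names(x$stages))
    cat(sprintf("  %-28s %-8s %7.2fs\n", nm, x$stages[[nm]]$status,
                x$stages[[nm]]$seconds))
  for (nm in names(x$bundles))
    cat(sprintf("  bundle %-4s %4d fibers, %d iterations\n", nm,
                x$bundles[[nm]]$accepted, x$bundles[[nm]]$iterations_used))
  cat("  total", x$total_seconds, "s\n")
  invisible(x)
}
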