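# End-to-end pipeline runs on a written-to-disk phantom dataset.

plan_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- straight_phantom()
      dir <- file.path(tempdir(), "plan_ds")
      write_phantom_dataset(ph, dir)
      cache <<- list(ph = ph, dir = dir)
    }
    cache
  }
})

mk_config <- function(dir, out, ...) {
  plan_config(t1 = file.path(dir, "t1.nii.gz"),
              dwi = file.path(dir, "dwi.nii.gz"),
              bval = file.path(dir, "dwi.bval"),
              bvec = file.path(dir, "dwi.bvec"),
              landmarks = file.path(dir, "landmarks.json"),
              rois = file.path(dir, "rois", "manifest.json"),
              bundles = file.path(dir, "bundles.json"),
              atlas = file.path(dir, "atlas.nii.gz"),
              treatment = file.path(dir, "treatment.csv"),
              lesion = file.path(dir, "lesion.nii.gz"),
              side = "left", seed = 42L, out_dir = out, ...)
}

test_that("the full planning pipeline runs end to end on a phantom", {
  fx <- plan_fixture()
  out <- file.path(tempdir(), "plan_run1")
  rep <- plan(mk_config(fx$dir, out))
  expect_s3_class(rep, "tfus_plan_report")
  # declared outputs exist
  expect_true(file.exists(file.path(out, "standard_coordinate.json")))
  expect_true(file.exists(file.path(out, "run_report.json")))
  expect_true(file.exists(file.path(out, "evaluation.json")))
  for (nm in c("CTT", "PTT", "CST", "ML"))
    expect_true(file.exists(file.path(out, paste0(nm, ".trk"))))
  # the phantom landmarks sit 24 mm apart: standard coordinate (14, 6, 1)
  expect_equal(rep$standard_coordinate, c(14, 6, 1), tolerance = 1e-6)
  # stage bookkeeping follows the pipeline order
  expect_equal(rep$stage_order,
               c("acpc_alignment", "standard_coordinate", "registration",
                 "dti_preprocessing", "fiber_tracking",
                 "probability_thresholding", "evaluation"))
  # every bundle reached its fiber minimum on the clear corridor except
  # CST, whose exclude ROI is off-corridor and harmless
  for (nm in names(rep$bundles))
    expect_true(rep$bundles[[nm]]$reached_min_fibers)
  # evaluation carries per-bundle distances and the deviation statistics
  expect_s3_class(rep$evaluation$table, "data.frame")
  expect_equal(nrow(rep$evaluation$table), 4)
  expect_true(is.finite(rep$evaluation$dev_mm))
})

test_that("reruns with the same configuration are byte-identical", {
  fx <- plan_fixture()
  out1 <- file.path(tempdir(), "plan_det1")
  out2 <- file.path(tempdir(), "plan_det2")
  plan(mk_config(fx$dir, out1))
  plan(mk_config(fx$dir, out2))
  f1 <- sort(list.files(out1, recursive = TRUE))
  f2 <- sort(list.files(out2, recursive = TRUE))
  expect_identical(f1, f2)
  f1 <- setdiff(f1, "run_report.json")   # carries wall-clock timings
  for (f in f1) {
    h1 <- unname(tools::md5sum(file.path(out1, f)))
    h2 <- unname(tools::md5sum(file.path(out2, f)))
    expect_identical(h1, h2)
  }
})

test_that("optional inputs only toggle the evaluation stage", {
  fx <- plan_fixture()
  out <- file.path(tempdir(), "plan_noeval")
  cfg <- mk_config(fx$dir, out)
  cfg$treatment <- NULL
  cfg$lesion <- NULL
  rep <- plan(cfg)
  expect_equal(rep$stages$evaluation$status, "skipped")
  expect_false(file.exists(file.path(out, "evaluation.json")))
  expect_null(rep$evaluation)
  for (nm in c("CTT", "PTT", "CST", "ML"))
    expect_true(file.exists(file.path(out, paste0(nm, ".trk"))))
})

test_that("missing inputs fail with a stage-tagged error", {
  fx <- plan_fixture()
  out <- file.path(tempdir(), "plan_fail")
  cfg <- mk_config(fx$dir, out)
  cfg$bvec <- tempfile()  # break it after validation
  expect_error(plan(cfg), "dti_prep-inputs")
})

test_that("plan configs load from YAML with overrides", {
  fx <- plan_fixture()
  y <- file.path(fx$dir, "plan.yaml")
  yaml::write_yaml(list(t1 = "t1.nii.gz", dwi = "dwi.nii.gz",
                        bval = "dwi.bval", bvec = "dwi.bvec",
                        landmarks = "landmarks.json",
                        rois = "rois/manifest.json",
                        bundles = "bundles.json", side = "left"), y)
  cfg <- load_plan_config(y, seed = 99L, out_dir = "X")
  expect_s3_class(cfg, "tfus_plan_config")
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$side, "left")
  expect_error(plan_config(t1 = tempfile(), dwi = "x", bval = "x",
                           bvec = "x", landmarks = "x", rois = "x",
                           bundles = "x"), "not found")
})
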