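test_that("a uniform field yields a straight, step-exact streamline", {
  ph <- straight_phantom()
  sl <- track_streamline(ph$tensor_truth, c(32, 32, 32))
  expect_equal(sl$status, "accepted")
  # straight: x and z constant along the whole polyline
  expect_lt(diff(range(sl$points[, 1])), 1e-9)
  expect_lt(diff(range(sl$points[, 3])), 1e-9)
  # consecutive points exactly one step apart
  steps <- sqrt(rowSums(diff(sl$points)^2))
  expect_lt(max(abs(steps - 1)), 1e-6)
  # bend angles essentially zero
  d <- diff(sl$points)
  cosang <- rowSums(d[-1, ] * d[-nrow(d), ]) /
    (sqrt(rowSums(d[-1, ]^2)) * sqrt(rowSums(d[-nrow(d), ]^2)))
  expect_lt(max(acos(pmin(1, cosang))), 1e-6)
})

test_that("arc tracking reproduces the analytic quarter-circle length", {
  ph <- make_phantom(phantom_spec(shape = "arc", noise = "none"))
  start <- ph$centerline$points[1, ]
  sl <- track_streamline(ph$tensor_truth, start)
  expect_equal(sl$status, "accepted")
  analytic <- pi / 2 * 20   # quarter circle, radius 20 mm
  expect_lt(abs(arc_span_length(sl$points, ph) - analytic) / analytic, 0.05)
  # total tracked length only exceeds the span by the end mixing zones
  expect_lt(sl$length_mm - analytic, 4)
})

test_that("seeds in isotropic tissue or outside the grid are handled", {
  ph <- straight_phantom()
  sl <- track_streamline(ph$tensor_truth, c(5, 5, 5))   # FA = 0 out there
  expect_equal(sl$status, "rejected")
  expect_equal(sl$reason, "low-FA")
  expect_equal(nrow(sl$points), 1L)
  expect_error(track_streamline(ph$tensor_truth, c(500, 0, 0)), "outside")
})

test_that("region overrides adapt parameters along the track", {
  ph <- straight_phantom()
  # halve the step size in the atlas region covering the corridor's lower
  # half (label 1): step lengths must change exactly at the label boundary
  pm <- region_parameter_map(overrides = list(`1` = list(step_mm = 0.5)))
  sl <- track_streamline(ph$tensor_truth, c(32, 30, 32), ph$atlas, pm)
  steps <- sqrt(rowSums(diff(sl$points)^2))
  y_mid <- sl$points[-nrow(sl$points), 2]
  expect_true(all(abs(steps[y_mid < 31] - 0.5) < 1e-6))
  expect_true(all(abs(steps[y_mid > 33] - 1) < 1e-6))
})

test_that("bundle tracking satisfies the min-fiber/max-iteration contract", {
  ph <- straight_phantom()
  b <- track_bundle(ph$bundle_specs$PTT, ph$rois, ph$tensor_truth,
                    ph$atlas, rng_seed = 42L)
  expect_gte(length(b$streamlines), 100)
  expect_lte(b$iterations_used, 5)
  expect_true(b$reached_min_fibers)

  # an exclude ROI blocking the corridor rejects everything
  spec_block <- bundle_spec("blocked", "corridor_start",
                            include_rois = "corridor_end",
                            exclude_rois = "corridor_block",
                            min_fibers = 100L, max_iterations = 5L)
  b2 <- track_bundle(spec_block, ph$rois, ph$tensor_truth, ph$atlas,
                     rng_seed = 42L)
  expect_equal(length(b2$streamlines), 0L)
  expect_equal(b2$iterations_used, 5L)

  # an unreachable include exhausts the iteration budget without error
  spec_unreach <- bundle_spec("unreachable", "corridor_start",
                              include_rois = "off_corridor",
                              min_fibers = 100L, max_iterations = 4L)
  b3 <- track_bundle(spec_unreach, ph$rois, ph$tensor_truth, ph$atlas,
                     rng_seed = 7L, batch_size = 10L)
  expect_equal(length(b3$streamlines), 0L)
  expect_equal(b3$iterations_used, 4L)
  expect_false(b3$reached_min_fibers)

  # empty seed mask raises
  rs <- ph$rois
  rs$masks$corridor_start$data[] <- 0
  expect_error(track_bundle(ph$bundle_specs$PTT, rs, ph$tensor_truth),
               "empty")
})

test_that("bundle tracking is reproducible and monotone in min_fibers", {
  ph <- straight_phantom()
  spec <- ph$bundle_specs$PTT
  b1 <- track_bundle(spec, ph$rois, ph$tensor_truth, rng_seed = 9L)
  b2 <- track_bundle(spec, ph$rois, ph$tensor_truth, rng_seed = 9L)
  expect_identical(lapply(b1$streamlines, `[[`, "points"),
                   lapply(b2$streamlines, `[[`, "points"))
  spec_small <- spec; spec_small$min_fibers <- 10L
  b3 <- track_bundle(spec_small, ph$rois, ph$tensor_truth, rng_seed = 9L)
  expect_lte(b3$iterations_used, b1$iterations_used)
})

test_that("probability maps count distinct streamline visits", {
  grid <- grid_volume(16)
  mk_sl <- function(pts) structure(list(points = pts, status = "accepted",
                                        reason = "", length_mm = 0),
                                   class = "tfus_streamline")
  line_pts <- cbind(8.5, seq(2.5, 13.5, by = 0.5), 8.5)
  ident <- structure(list(name = "X",
                          streamlines = rep(list(mk_sl(line_pts)), 10),
                          iterations_used = 1L, rng_seed = 1L,
                          reached_min_fibers = TRUE),
                     class = "tfus_bundle")
  p <- probability_map(ident, grid)
  vis <- p$map$data[9, , 9]
  expect_true(all(p$map$data %in% c(0, 1)))
  expect_true(all(vis[3:14] == 1))

  # two streamlines sharing half their voxels: shared 1.0, unique 0.5
  a <- cbind(8.5, seq(2.5, 13.5, 0.5), 8.5)
  bpts <- cbind(8.5, seq(2.5, 7.5, 0.5), 8.5)
  two <- structure(list(name = "X", streamlines = list(mk_sl(a), mk_sl(bpts)),
                        iterations_used = 1L, rng_seed = 1L,
                        reached_min_fibers = TRUE),
                   class = "tfus_bundle")
  p2 <- probability_map(two, grid)
  expect_equal(p2$map$data[9, 4, 9], 1)     # shared stretch
  expect_equal(p2$map$data[9, 12, 9], 0.5)  # unique stretch after rescale
  expect_true(all(p2$map$data >= 0 & p2$map$data <= 1))
  empty <- structure(list(name = "X", streamlines = list()),
                     class = "tfus_bundle")
  expect_error(probability_map(empty, grid), "no accepted")
})

test_that("threshold dialect: AFT 0.2/0.5, FSL 0.1, inclusive", {
  grid <- grid_volume(4)
  mk_map <- function(vals) {
    m <- grid
    m$data[seq_along(vals)] <- vals
    structure(list(map = m, threshold = NA_real_, bundle_name = "ML",
                   n_streamlines = 10L), class = "tfus_probmap")
  }
  # AFT ML threshold 0.5: 0.4 dropped, 0.6 kept
  p <- threshold_map(mk_map(c(0.4, 0.6)), "ML", "AFT")
  expect_equal(sort(unique(as.vector(p$map$data))), c(0, 0.6))
  expect_equal(p$threshold, 0.5)
  # AFT CTT/PTT/CST threshold 0.2, inclusive at the boundary
  p2 <- threshold_map(mk_map(c(0.19, 0.2, 0.21)), "CTT", "AFT")
  expect_equal(sum(p2$map$data > 0), 2)
  # FSL: 0.1 retained for every bundle ("at least 0.1")
  p3 <- threshold_map(mk_map(c(0.1, 0.09)), "ML", "FSL")
  expect_equal(sum(p3$map$data > 0), 1)
  expect_equal(p3$threshold, 0.1)
  # all below threshold: zero map with a warning
  expect_warning(p4 <- threshold_map(mk_map(c(0.05, 0.02)), "CST", "AFT"),
                 "below")
  expect_true(all(p4$map$data == 0))
  expect_error(threshold_map(mk_map(0.5), "XYZ", "AFT"), "unknown bundle")
  expect_error(threshold_map(p, "ML", "AFT"), "already thresholded")
})

test_that("thresholded straight-bundle maps form a connected corridor", {
  ph <- straight_phantom()
  b <- track_bundle(ph$bundle_specs$PTT, ph$rois, ph$tensor_truth,
                    rng_seed = 5L)
  grid <- volume(ph$tensor_truth$s0, ph$tensor_truth$affine)
  p <- threshold_map(probability_map(b, grid), "PTT", "AFT")
  vox <- which(p$map$data > 0, arr.ind = TRUE)
  expect_gt(nrow(vox), 0)
  # 6-neighbour flood fill from one suprathreshold voxel reaches all
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  todo <- vox[1, , drop = FALSE]
  seen <- new.env()
  assign(key(todo), TRUE, envir = seen)
  all_keys <- key(vox)
  shifts <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  while (nrow(todo) > 0) {
    cur <- todo[1, , drop = FALSE]
    todo <- todo[-1, , drop = FALSE]
    for (s in 1:6) {
      nb <- cur + shifts[s, , drop = FALSE]
      k <- key(nb)
      if (k %in% all_keys && !exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        todo <- rbind(todo, nb)
      }
    }
  }
  expect_equal(length(ls(seen)), nrow(vox))
  # corridor touches both the seed and the include ROI
  seed_vox <- which(ph$rois$masks$corridor_start$data > 0, arr.ind = TRUE)
  end_vox <- which(ph$rois$masks$corridor_end$data > 0, arr.ind = TRUE)
  expect_true(any(key(seed_vox) %in% all_keys))
  expect_true(any(key(end_vox) %in% all_keys))
})

test_that("TrackVis export round-trips streamline geometry", {
  ph <- straight_phantom()
  spec <- ph$bundle_specs$PTT; spec$min_fibers <- 5L
  b <- track_bundle(spec, ph$rois, ph$tensor_truth, rng_seed = 3L,
                    batch_size = 10L)
  grid <- volume(ph$tensor_truth$s0, ph$tensor_truth$affine)
  f <- tempfile(fileext = ".trk")
  save_trk(b, grid, f)
  trk <- load_trk(f, grid)
  expect_equal(trk$n_count, length(b$streamlines))
  expect_equal(trk$voxel_size, grid$spacing, tolerance = 1e-6)
  for (i in seq_along(b$streamlines))
    expect_equal(trk$streamlines[[i]], b$streamlines[[i]]$points,
                 tolerance = 1e-3, ignore_attr = TRUE)
})
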