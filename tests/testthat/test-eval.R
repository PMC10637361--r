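test_that("temperature filtering keeps therapeutic sonications inclusively", {
  pts <- matrix(seq_len(9), ncol = 3)
  kept <- filter_treatment_points(pts, c(54.9, 55.0, 58.0))
  expect_equal(nrow(kept), 2)
  expect_equal(kept, pts[2:3, , drop = FALSE])
  expect_equal(filter_treatment_points(pts, c(55, 60, 70)), pts)
  expect_error(filter_treatment_points(pts, c(50, 52, 54.9)), "therapeutic")
})

test_that("dev is the mean Euclidean distance to the standard coordinate", {
  sc <- c(14, 6, 1)
  r0 <- treatment_record("p", matrix(sc, 1), sc)
  expect_equal(dev_mm(r0), 0)
  r2 <- treatment_record("p", rbind(sc + c(1, 0, 0), sc + c(0, 3, 0)), sc)
  expect_equal(dev_mm(r2), 2)
  # brute-force oracle on random instances
  set.seed(41)
  for (i in 1:100) {
    k <- sample(1:50, 1)
    pts <- matrix(rnorm(3 * k, sd = 5), ncol = 3)
    scr <- rnorm(3)
    r <- treatment_record("p", pts, scr)
    brute <- 0
    for (j in seq_len(k)) brute <- brute + sqrt(sum((pts[j, ] - scr)^2))
    expect_equal(dev_mm(r), brute / k, tolerance = 1e-12)
  }
  # translation invariance
  r <- treatment_record("p", matrix(rnorm(30), ncol = 3), c(1, 2, 3))
  shift <- c(5, -4, 2)
  rs <- treatment_record("p", sweep(r$points, 2, -shift), r$std_coord + shift)
  expect_equal(dev_mm(r), dev_mm(rs), tolerance = 1e-12)
})

test_that("xdev compares |x| against the 14 mm lateral offset", {
  sc <- c(14, 6, 1)
  expect_equal(xdev_mm(treatment_record("p", matrix(c(14, 0, 0), 1), sc)), 0)
  expect_equal(xdev_mm(treatment_record("p", rbind(c(12, 0, 0), c(16, 0, 0)),
                                        sc)), 2)
  # right-treated patients at x = -14 are on target under the magnitude rule
  expect_equal(xdev_mm(treatment_record("p", matrix(c(-14, 5, 2), 1),
                                        c(-14, 6, 1))), 0)
  set.seed(42)
  for (i in 1:100) {
    k <- sample(1:30, 1)
    pts <- matrix(rnorm(3 * k, sd = 8), ncol = 3)
    r <- treatment_record("p", pts, sc)
    brute <- mean(abs(abs(pts[, 1]) - 14))
    expect_equal(xdev_mm(r), brute, tolerance = 1e-12)
  }
})

test_that("conditional cohort means follow filter-then-average", {
  sc <- c(14, 6, 1)
  mk <- function(d) treatment_record("p", matrix(sc + c(0, d, 0), 1), sc)
  recs <- lapply(c(1, 3, 5), mk)
  all_mean <- conditional_mean_dev(recs)
  expect_equal(all_mean$mean, 3)
  expect_equal(all_mean$M, 3)
  cond <- conditional_mean_dev(recs, "dev", function(d) d >= 2)
  expect_equal(cond$mean, 4)
  expect_equal(cond$M, 2)
  expect_error(conditional_mean_dev(recs, "dev", function(d) d > 100),
               "no patient")
  # oracle on random cohorts
  set.seed(43)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    recs <- lapply(seq_len(n), function(j)
      treatment_record(j, matrix(rnorm(9, sd = 4), ncol = 3), rnorm(3)))
    thr <- runif(1, 0, 8)
    devs <- vapply(recs, dev_mm, 0)
    keep <- devs >= thr
    if (!any(keep)) next
    res <- conditional_mean_dev(recs, "dev", function(d) d >= thr)
    expect_equal(res$mean, mean(devs[keep]), tolerance = 1e-12)
    expect_equal(res$M, sum(keep))
  }
})

test_that("point-to-bundle distance is exact against brute force", {
  grid <- grid_volume(12)
  mk_map <- function(mask) structure(
    list(map = volume(mask, grid$affine), threshold = 0.2,
         bundle_name = "CTT", n_streamlines = 1L), class = "tfus_probmap")
  m <- array(0, rep(12, 3)); m[6, 6, 6] <- 1
  p <- mk_map(m)
  # inside the suprathreshold voxel: 0
  expect_equal(point_to_bundle_distance(c(5.5, 5.5, 5.5), p), 0)
  # single voxel centre at a known offset
  expect_equal(point_to_bundle_distance(c(5.5, 5.5, 8.5), p), 3)
  # random sparse maps against exhaustive minimisation
  set.seed(44)
  for (i in 1:100) {
    m <- array(0, rep(12, 3))
    m[sample(length(m), 20)] <- runif(20)
    pm <- mk_map(m)
    pt <- runif(3, -5, 17)
    centers <- voxel_to_world(pm$map,
                              which(m > 0, arr.ind = TRUE) - 1)
    brute <- sqrt(min(rowSums(sweep(centers, 2, pt)^2)))
    v <- round(world_to_voxel(pm$map, pt))
    inside <- all(v >= 0) && all(v <= 11) && m[v[1]+1, v[2]+1, v[3]+1] > 0
    expect_equal(point_to_bundle_distance(pt, pm),
                 if (inside) 0 else brute, tolerance = 1e-12)
  }
  expect_error(point_to_bundle_distance(c(0, 0, 0),
                                        mk_map(array(0, rep(12, 3)))),
               "no suprathreshold")
})

test_that("lesion centres are world-space voxel centroids", {
  g <- grid_volume(10)
  m1 <- g; m1$data[4, 5, 6] <- 1
  expect_equal(lesion_center(m1), voxel_to_world(g, c(3, 4, 5)))
  m2 <- g; m2$data[2, 5, 5] <- 1; m2$data[8, 5, 5] <- 1
  expect_equal(lesion_center(m2), voxel_to_world(g, c(4, 4, 4)))
  set.seed(45)
  for (i in 1:100) {
    m <- g
    m$data[sample(length(m$data), 30)] <- 1
    vox <- which(m$data > 0, arr.ind = TRUE) - 1
    expect_equal(lesion_center(m), colMeans(voxel_to_world(g, vox)),
                 tolerance = 1e-12)
  }
  expect_error(lesion_center(g), "empty")
})

test_that("Dice overlap matches its formula and symmetry", {
  g <- grid_volume(8)
  a <- g; a$data[1:4, 1, 1] <- 1
  expect_equal(dice(a, a), 1)
  b <- g; b$data[5:8, 2, 1] <- 1
  expect_equal(dice(a, b), 0)
  c_ <- g; c_$data[3:6, 1, 1] <- 1   # |A|=|B|=4, overlap 2
  expect_equal(dice(a, c_), 0.5)
  set.seed(46)
  for (i in 1:100) {
    x <- g; x$data[sample(length(x$data), 40)] <- 1
    y <- g; y$data[sample(length(y$data), 25)] <- 1
    A <- x$data > 0; B <- y$data > 0
    expect_equal(dice(x, y), 2 * sum(A & B) / (sum(A) + sum(B)),
                 tolerance = 1e-12)
    expect_equal(dice(x, y), dice(y, x))
    expect_gte(dice(x, y), 0); expect_lte(dice(x, y), 1)
  }
  expect_error(dice(g, g), "both masks are empty")
})

test_that("treatment logs parse, filter and aggregate per patient", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(patient = c("a", "a", "a", "b"),
                   x = c(14, 13, 20, -14), y = c(6, 6, 6, 7),
                   z = c(1, 1, 1, 1), temp_c = c(57, 55, 54, 58))
  write.csv(df, f, row.names = FALSE)
  recs <- load_treatment_log(f, c(14, 6, 1))
  expect_length(recs, 2)
  expect_equal(nrow(recs[["a"]]$points), 2)   # 54 C sonication dropped
  expect_equal(dev_mm(recs[["a"]]), 0.5)
  rep_ <- evaluation_report(list(), c(14, 6, 1))
  expect_null(rep_)
})
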