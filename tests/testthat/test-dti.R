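test_that("Lanczos-3 kernel and constant preservation behave", {
  k <- tfusplan:::lanczos3_kernel(c(0, 1, 2, -1, -2, 3, 4))
  expect_equal(k[1], 1)
  expect_equal(k[2:5], rep(0, 4), tolerance = 1e-15)
  expect_equal(k[6:7], rep(0, 2))

  v <- grid_volume(16, 2)
  v$data <- array(3.7, rep(16, 3))
  out <- lanczos3_resample(v, 1)
  expect_equal(dim(out$data), rep(32L, 3))
  expect_lt(max(abs(out$data - 3.7)), 1e-9)
  expect_equal(out$spacing, rep(1, 3))
  expect_error(lanczos3_resample(v, -1), "positive")
})

test_that("Lanczos supersampling reproduces a band-limited sinusoid", {
  n <- 32
  v <- grid_volume(n, 2)
  w <- voxel_to_world(v, tfusplan:::voxel_index_grid(rep(n, 3)))
  lambda <- 16  # mm, well below the 4 mm Nyquist limit of the 2 mm grid
  v$data <- array(sin(2 * pi * w[, 2] / lambda), rep(n, 3))
  out <- lanczos3_resample(v, 1)
  wo <- voxel_to_world(out, tfusplan:::voxel_index_grid(dim(out$data)))
  truth <- sin(2 * pi * wo[, 2] / lambda)
  # compare away from the volume border where the kernel is truncated
  interior <- wo[, 2] > 8 & wo[, 2] < 56
  expect_lt(max(abs(out$data[array(interior, dim(out$data))] -
                    truth[interior])), 1e-2)
})

test_that("Gaussian smoothing is mass-preserving and a semigroup", {
  v <- grid_volume(33)
  expect_identical(gaussian_smooth(v, 0), v)
  v$data[17, 17, 17] <- 1
  sm <- gaussian_smooth(v, 2)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  # impulse response matches the sampled Gaussian in the interior
  prof <- sm$data[, 17, 17]
  expect_equal(which.max(prof), 17)
  # two smooths compose like one with sqrt(s1^2 + s2^2)
  s1 <- gaussian_smooth(gaussian_smooth(v, 1.5), 2)
  s2 <- gaussian_smooth(v, sqrt(1.5^2 + 2^2))
  expect_lt(max(abs(s1$data - s2$data)), 1e-3)
})

test_that("noise-free tensors are recovered to numerical precision", {
  sch <- make_scheme(56, 1200)
  set.seed(31)
  n <- 5
  dwi <- volume(array(0, c(n, n, n, length(sch$bvals))))
  truth <- vector("list", n^3)
  idx <- 1
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    D <- random_spd_tensor()
    truth[[idx]] <- D
    dwi$data[i, j, k, ] <- st_signal(D, sch)
    idx <- idx + 1
  }
  tf <- fit_tensors(dwi, sch)
  idx <- 1
  worst <- 0
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    D <- truth[[idx]]
    rel <- max(abs(tf$tensors[i, j, k, ] - tensor_to_vec6(D))) / max(abs(D))
    worst <- max(worst, rel)
    idx <- idx + 1
  }
  expect_lt(worst, 1e-9)
})

test_that("noisy tensor estimates stay within a 5% median eigenvalue error", {
  sch <- make_scheme(56, 1200)
  set.seed(32)
  nvox <- 200
  s0 <- 1000
  lam_true <- c(1.7, 0.3, 0.3) * 1e-3
  D <- diag(lam_true)
  sig <- matrix(rep(st_signal(D, sch, s0), nvox), nrow = nvox, byrow = TRUE)
  sig <- sig + rnorm(length(sig), sd = s0 / 20)   # SNR 20
  dwi <- volume(array(sig, c(nvox, 1, 1, length(sch$bvals))))
  tf <- fit_tensors(dwi, sch)
  lam <- tfusplan:::tensor_eigenvalues(tf)
  err <- abs(sweep(lam, 2, lam_true)) / lam_true[1]
  expect_lt(median(err), 0.05)
})

test_that("tensor fitting validates its design matrix and signals", {
  sch <- make_scheme(56, 1200)
  dwi3 <- volume(array(1, c(4, 4, 4)))
  expect_error(fit_tensors(dwi3, sch), "4D")
  # too few directions
  sch5 <- diffusion_scheme(c(0, rep(1200, 5)),
                           cbind(0, make_scheme(5)$bvecs[, -1]))
  dwi5 <- volume(array(1, c(2, 2, 2, 6)))
  expect_error(fit_tensors(dwi5, sch5), "at least 6")
  # directions that do not span 3D
  gx <- rbind(cos(seq(0, pi, length.out = 8)),
              sin(seq(0, pi, length.out = 8)), 0)
  schp <- diffusion_scheme(c(0, rep(1200, 8)), cbind(0, gx))
  dwip <- volume(array(1, c(2, 2, 2, 9)))
  expect_error(fit_tensors(dwip, schp), "rank")
  # all-zero bvals cannot be fit
  sch0 <- diffusion_scheme(rep(0, 8), matrix(0, 3, 8))
  dwi0 <- volume(array(1, c(2, 2, 2, 8)))
  expect_error(fit_tensors(dwi0, sch0), "at least 6")
  # non-positive signals are masked out, not propagated
  schk <- make_scheme(8)
  dwik <- volume(array(1000, c(2, 2, 2, 9)))
  dwik$data[1, 1, 1, 3] <- -5
  tfk <- fit_tensors(dwik, schk)
  expect_false(tfk$mask[1, 1, 1])
  expect_true(tfk$mask[2, 2, 2])
})

test_that("FA has its closed-form values and rotation invariance", {
  sch <- make_scheme(56, 1200)
  mk <- function(D) {
    dwi <- volume(array(st_signal(D, sch), c(1, 1, 1, length(sch$bvals))))
    fit_tensors(dwi, sch)
  }
  # isotropic tensor: FA 0
  expect_equal(fa_map(mk(diag(rep(1e-3, 3))))$data[1, 1, 1], 0,
               tolerance = 1e-9)
  # prolate tensor 1.7/0.3/0.3: closed-form sqrt(3/2)|l - lbar|/|l|
  lam <- c(1.7, 0.3, 0.3) * 1e-3
  fa_expect <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(fa_expect, 0.7990222, tolerance = 1e-6)
  expect_equal(fa_map(mk(diag(lam)))$data[1, 1, 1], fa_expect,
               tolerance = 1e-3)
  # rotation invariance
  set.seed(33)
  for (i in 1:100) {
    a <- matrix(rnorm(9), 3); q <- qr.Q(qr(a))
    D <- q %*% diag(lam) %*% t(q)
    lam_r <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
                  decreasing = TRUE)
    expect_equal(tfusplan:::fa_from_eigenvalues(lam_r)[1], fa_expect,
                 tolerance = 1e-9)
  }
})

test_that("the color direction map encodes |e1| weighted by FA", {
  sch <- make_scheme(56, 1200)
  D <- diag(c(2.0, 0.05, 0.05) * 1e-3)   # nearly rank-1 along x
  dwi <- volume(array(st_signal(D, sch), c(1, 1, 1, length(sch$bvals))))
  tf <- fit_tensors(dwi, sch)
  rgb <- color_direction_map(tf)
  expect_equal(dim(rgb$data), c(1L, 1L, 1L, 3L))
  fa <- fa_map(tf)$data[1]
  expect_equal(rgb$data[1, 1, 1, ], c(fa, 0, 0), tolerance = 1e-6)
  # isotropic voxel maps to black
  Di <- diag(rep(1e-3, 3))
  dwii <- volume(array(st_signal(Di, sch), c(1, 1, 1, length(sch$bvals))))
  expect_equal(color_direction_map(fit_tensors(dwii, sch))$data[1, 1, 1, ],
               c(0, 0, 0), tolerance = 1e-9)
  expect_true(all(rgb$data >= 0 & rgb$data <= 1))
})

test_that("tensor fields persist losslessly with their sidecar", {
  ph <- straight_phantom()
  tf <- ph$tensor_truth
  pre <- file.path(tempdir(), "tfield")
  save_tensor_field(tf, pre)
  tf2 <- load_tensor_field(pre)
  expect_equal(tf2$tensors, tf$tensors, tolerance = 1e-12)
  expect_equal(tf2$mask, tf$mask)
  side <- jsonlite::fromJSON(paste0(pre, "_tensor.json"))
  expect_equal(side$component_order,
               c("dxx", "dxy", "dyy", "dxz", "dyz", "dzz"))
})
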