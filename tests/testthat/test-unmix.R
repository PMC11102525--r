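test_that("rate grids have the sentinel first and the documented span", {
  g <- build_rate_grid()
  expect_length(g$rates, 12)
  expect_equal(g$rates[1], 1e-4)
  expect_equal(max(g$rates), 0.09)
  expect_false(is.unsorted(g$rates, strictly = TRUE))
  g2 <- build_rate_grid(n = 2)
  expect_equal(g2$rates, c(1e-4, 0.09))
  gaps <- diff(build_rate_grid(n = 7)$rates[-1])
  expect_lt(max(gaps) - min(gaps), 1e-12)
  glog <- build_rate_grid(n = 5, spacing = "log")
  expect_equal(sd(diff(log(glog$rates[-1]))), 0, tolerance = 1e-12)
  expect_error(build_rate_grid(sentinel = 0.5), "sentinel")
  expect_error(rate_grid(c(0.01, 0.005)), "ascending")
})

test_that("noiseless series with an on-grid rate are recovered exactly", {
  t <- 0:224
  g <- round_rate_grid()
  fit <- fit_bleach(bleach_curve(5, 0.03, 2, t), t, g)
  expect_equal(coef(fit), c(a = 5, b = 0.03, c = 2), tolerance = 1e-9)
  expect_gt(fit$confidence, 1 - 1e-9)
  expect_false(fit$flagged_unbleachable)
  # negative-amplitude series: absolute-value manipulation
  fit_neg <- fit_bleach(bleach_curve(-4, 0.05, 10, t), t, g)
  expect_equal(coef(fit_neg)[["a"]], 4, tolerance = 1e-9)
  expect_equal(fit_neg$raw_a, -4, tolerance = 1e-9)
})

test_that("constant series are classified unbleachable, not an error", {
  fit <- fit_bleach(rep(3.3, 50))
  expect_true(fit$flagged_unbleachable)
  expect_equal(coef(fit), c(a = 0, b = 1e-4, c = 3.3))
  expect_equal(fit$confidence, 0)
  expect_error(fit_bleach(c(1, 2)), "3 time points")
  expect_error(fit_bleach(1:5, times = c(0, 1, 1, 2, 3)), "increasing")
})

test_that("rate selection is invariant to affine transforms of the series", {
  t <- 0:100
  g <- round_rate_grid()
  y <- bleach_curve(2, 0.04, 1, t) + stats::rnorm(101, 0, 0.05)
  base <- fit_bleach(y, t, g)
  for (alpha in c(0.5, 3)) for (gamma in c(-2, 7)) {
    tr <- fit_bleach(alpha * y + gamma, t, g)
    expect_equal(coef(tr)[["b"]], coef(base)[["b"]])
    expect_equal(tr$confidence, base$confidence, tolerance = 1e-12)
  }
})

test_that("off-grid rates select one of the two bracketing candidates", {
  t <- 0:224
  g <- round_rate_grid()
  set.seed(5)
  for (b_true in runif(8, 0.012, 0.088)) {
    fit <- fit_bleach(bleach_curve(3, b_true, 0.5, t), t, g)
    lo <- max(g$rates[g$rates <= b_true])
    hi <- min(g$rates[g$rates >= b_true])
    expect_true(coef(fit)[["b"]] %in% c(lo, hi))
  }
})

test_that("amplitude recovery stays accurate under measurement noise", {
  t <- 0:224
  g <- round_rate_grid()
  rel_err <- vapply(1:20, function(s) {
    set.seed(s)
    y <- bleach_curve(5, 0.03, 2, t) + stats::rnorm(225, 0, 0.1)
    abs(coef(fit_bleach(y, t, g))[["a"]] - 5) / 5
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.10)
})

test_that("bleach_fit methods are mutually consistent", {
  t <- 0:150
  y <- bleach_curve(4, 0.02, 1, t) + stats::rnorm(151, 0, 0.05)
  fit <- fit_bleach(y, t, round_rate_grid())
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_equal(unname(predict(fit)), unname(fitted(fit)))
  expect_equal(predict(fit, newdata = list(times = 0)),
               fit$raw_a + coef(fit)[["c"]])
  expect_output(print(fit), "confidence")
  expect_output(print(summary(fit)), "profile")
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(151L, 3L))
  expect_equal(simulate(fit, nsim = 3, seed = 9), sims)
})

test_that("voxelwise unmixing matches per-voxel fits and handles degenerate voxels", {
  set.seed(8)
  arr <- array(0, c(6, 5, 60))
  t <- 0:59
  params <- expand.grid(r = 1:6, cl = 1:5)
  params$a <- runif(30, 0, 4)
  params$a[1:7] <- 0                 # some unbleachable voxels
  params$b <- sample(c(0.02, 0.05, 0.08), 30, replace = TRUE)
  params$c <- runif(30, 0, 2)
  for (i in 1:30)
    arr[params$r[i], params$cl[i], ] <-
      bleach_curve(params$a[i], params$b[i], params$c[i], t) +
      rnorm(60, 0, 0.01)
  g <- round_rate_grid()
  um <- unmix_volume(arr, times = t, grid = g)
  for (i in c(1, 5, 12, 30)) {
    ref <- fit_bleach(arr[params$r[i], params$cl[i], ], t, g)
    expect_equal(um$a[params$r[i], params$cl[i]], coef(ref)[["a"]])
    expect_equal(um$b[params$r[i], params$cl[i]], coef(ref)[["b"]])
    expect_equal(um$c[params$r[i], params$cl[i]], coef(ref)[["c"]])
    expect_equal(um$confidence[params$r[i], params$cl[i]],
                 ref$confidence, tolerance = 1e-12)
  }
  # all-zero input gives all-zero maps
  um0 <- unmix_volume(array(0, c(4, 4, 10)))
  expect_true(all(um0$a == 0) && all(um0$c == 0))
  expect_true(all(um0$flagged_unbleachable))
  expect_error(unmix_volume(array(0, c(4, 4, 2))), "at least 3")
})

test_that("full pipeline recovers a bleachable disk on unbleachable background", {
  ph <- make_phantom("tube", c(64, 64),
                     params = list(a = 1, b = 0.05, c = 0.3, radius_px = 6))
  plan <- scan_plan(32, 8)
  fused <- sliding_fuse(simulate_acquisition(ph, plan, 0.055), plan, 0.055)
  um <- unmix_volume(fused, grid = round_rate_grid())
  truth <- ph$a > 0
  detected <- um$a > 0.2 * max(um$a)
  expect_dice_at_least(detected, truth, 0.9)
  expect_lt(max(um$a[!truth]) / max(um$a), 0.1)
  expect_equal(um$b[33, 33], 0.05)
  # pure-background phantom: tag map identically zero, c recovers the scene
  ph0 <- make_phantom("tube", c(32, 32),
                      params = list(a = 0, b = 0, c = 0.7, radius_px = 5))
  plan0 <- scan_plan(8, 2)
  f0 <- sliding_fuse(simulate_acquisition(ph0, plan0, 0.08), plan0, 0.08)
  um0 <- unmix_volume(f0, grid = round_rate_grid())
  expect_true(all(um0$a == 0))
  expect_equal(um0$c, f0$images[[1]], tolerance = 1e-6)
})

test_that("noise-floor thresholding follows the three-sigma rule", {
  set.seed(21)
  a_map <- matrix(abs(rnorm(256 * 256)), 256, 256)
  roi <- matrix(FALSE, 256, 256); roi[1:64, 1:64] <- TRUE
  nf <- noise_floor_mask(a_map, roi, k = 3)
  expect_equal(nf$threshold, 3 * sd(a_map[roi]))
  # scale equivariance
  nf10 <- noise_floor_mask(10 * a_map, roi, k = 3)
  expect_equal(nf10$threshold, 10 * nf$threshold)
  expect_identical(nf10$mask, nf$mask)
  # zero-noise ROI: threshold collapses to zero, positives survive
  zmap <- matrix(0, 8, 8); zmap[5, 5] <- 1
  zroi <- matrix(FALSE, 8, 8); zroi[1:2, 1:2] <- TRUE
  nfz <- noise_floor_mask(zmap, zroi)
  expect_equal(nfz$threshold, 0)
  expect_identical(nfz$mask, zmap > 0)
  expect_error(noise_floor_mask(zmap, matrix(FALSE, 8, 8)), "empty")
})

test_that("tag-map noise passes the three-sigma floor at the normal tail rate", {
  # a Gaussian a-map thresholded at 3 sd keeps ~0.13% of noise voxels
  set.seed(31)
  a_map <- matrix(rnorm(512 * 512), 512, 512)
  roi <- matrix(FALSE, 512, 512); roi[1:128, ] <- TRUE
  nf <- noise_floor_mask(a_map, roi, k = 3)
  expect_equal(nf$threshold, 3, tolerance = 0.02)
  pass_rate <- mean(a_map >= nf$threshold)
  expect_equal(pass_rate, stats::pnorm(-3), tolerance = 0.25)
})
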