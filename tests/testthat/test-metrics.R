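test_that("BNR measures the bleaching extent against noise in dB", {
  series <- c(100, 60, 30, 0)
  expect_equal(bnr(series, 1), 40)          # 100x dynamic range
  expect_equal(bnr(series + 17, 1), 40)     # offset invariant
  expect_equal(bnr(series * 3, 3), 40)      # joint-scaling invariant
  expect_error(bnr(series, 0), "positive")
  expect_error(bnr(rep(2, 5), 1), "no bleaching")
})

test_that("region power and SNR follow their definitions", {
  expect_equal(region_power(c(3, 4)), 12.5)
  expect_equal(region_power(rep(0, 10)), 0)
  expect_equal(region_power(rep(-2, 7)), 4)
  expect_error(region_power(numeric(0)), "empty")
  img <- matrix(0, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[1:5, ] <- TRUE
  img[roi] <- sqrt(10); img[!roi] <- sqrt(2)
  expect_equal(snr(img, roi), 4)
  img2 <- matrix(1, 10, 10)
  expect_equal(snr(img2, roi), 0)
  expect_error(snr(img, matrix(TRUE, 10, 10)), "non-empty")
})

test_that("power SNR approaches s^2/sigma^2 for strong signal", {
  vals <- vapply(1:50, function(s) {
    set.seed(s)
    img <- matrix(rnorm(40 * 40), 40, 40)
    roi <- matrix(FALSE, 40, 40); roi[15:25, 15:25] <- TRUE
    img[roi] <- img[roi] + 10
    snr(img, roi)
  }, numeric(1))
  expect_equal(mean(vals), 100, tolerance = 0.1)
})

test_that("cosine similarity behaves like a normalised inner product", {
  m <- matrix(rnorm(25), 5, 5)
  expect_equal(cosine_similarity(m, m), 1)
  expect_equal(cosine_similarity(m, -2 * m), -1)
  a <- matrix(c(1, 0, 0, 0), 2, 2)
  b <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_equal(cosine_similarity(a, b), 0)
  expect_equal(cosine_similarity(matrix(c(1, 0), 1, 2),
                                 matrix(c(1, 1), 1, 2)), 1 / sqrt(2))
  expect_error(cosine_similarity(m, matrix(0, 5, 5)), "zero-norm")
  expect_error(cosine_similarity(m, matrix(1, 2, 2)), "differ")
})

test_that("AUC equals the brute-force pairwise ordering oracle", {
  auc_oracle <- function(scores, truth) {
    pos <- scores[truth]; neg <- scores[!truth]
    pairs <- outer(pos, neg, function(p, n)
      (p > n) + 0.5 * (p == n))
    mean(pairs)
  }
  # printed toy case
  r <- roc_auc(c(2, 3, 1, 2.5), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  # perfect separation and exchangeable scores
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  # randomised instances up to 1e4 pairs, with ties
  for (s in 1:5) {
    set.seed(s)
    n <- sample(40:100, 1)
    truth <- runif(n) < 0.4
    truth[1:2] <- c(TRUE, FALSE)
    scores <- round(rnorm(n, mean = truth), 1)
    expect_equal(roc_auc(scores, truth)$auc, auc_oracle(scores, truth))
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC points trace monotone rates from (0,0) to (1,1)", {
  set.seed(2)
  truth <- rep(c(TRUE, FALSE), each = 30)
  scores <- rnorm(60, mean = truth * 1.5)
  r <- roc_auc(scores, truth)
  expect_true(all(diff(r$roc$fpr[order(r$roc$threshold)]) <= 0 + 1e-12))
  expect_equal(range(r$roc$fpr), c(0, 1))
  expect_equal(range(r$roc$tpr), c(0, 1))
})

test_that("metrics are invariant to voxel ordering", {
  set.seed(9)
  img <- matrix(rnorm(100, 1), 10, 10)
  roi <- matrix(runif(100) < 0.3, 10, 10)
  if (!any(roi)) roi[1] <- TRUE
  perm <- sample(100)
  img_p <- matrix(img[perm], 10, 10)
  roi_p <- matrix(roi[perm], 10, 10)
  expect_equal(snr(img, roi), snr(img_p, roi_p))
  expect_equal(roc_auc(img, roi)$auc, roc_auc(img_p, roi_p)$auc)
  expect_equal(region_power(img[roi]), region_power(img_p[roi_p]))
})

test_that("sensitivity gain is the threshold ratio", {
  expect_equal(sensitivity_gain(12, 1), 12)
  expect_equal(sensitivity_gain(0.4, 0.4), 1)
  expect_error(sensitivity_gain(0, 1), "positive")
  expect_error(sensitivity_gain(1, -2), "positive")
})

test_that("unmixing beats background thresholding on a noisy tube phantom", {
  # a dim bleachable tube inside bright unbleachable background: the
  # conventional threshold must clear the background roof, while the
  # tag map only needs to clear its own noise floor
  ph <- make_phantom("tube", c(48, 48),
                     params = list(a = 0.6, b = 0.05, c = 0, radius_px = 5))
  bg <- fluence_map(c(48, 48), surface_intensity = 1.5, mu_eff = 0.4,
                    spacing_mm = 0.075)
  ph$c <- bg * 0.5                      # unbleachable tissue everywhere
  plan <- scan_plan(16, 4)
  stream <- simulate_acquisition(ph, plan, 0.12, noise_sigma = 0.01,
                                 seed = 77)
  um <- unmix_volume(sliding_fuse(stream, plan, 0.12),
                     grid = round_rate_grid())
  roi <- matrix(FALSE, 48, 48); roi[1:10, 39:48] <- TRUE  # corner, no tube
  floor3 <- noise_floor_mask(um$a, roi)$threshold
  roof <- max(um$c)
  gain <- sensitivity_gain(roof, floor3)
  expect_gt(gain, 1)
  # the tube is detectable in the tag map above its noise floor
  truth <- ph$a > 0
  expect_dice_at_least(um$a >= floor3, truth, 0.6)
})
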