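test_that("axis-aligned slab masks select the expected bands", {
  g <- c(33, 33)  # odd grid: no Nyquist ambiguity
  We <- 0.12
  m0 <- slab_indicator(0, We, g)
  fc <- ((seq_len(33) - 1) - 16) / 33
  expect_equal(m0, matrix(rep((abs(fc) <= We) * 1, each = 33), 33, 33))
  m90 <- slab_indicator(90, We, g)
  expect_equal(m90, matrix(rep((abs(fc) <= We) * 1, times = 33), 33, 33))
  expect_error(slab_indicator(0, 0.7, g), "cycles/voxel")
  expect_error(slab_indicator(0, 0, g), "cycles/voxel")
})

test_that("a rotated slab equals the zero-angle slab rotated about the centre", {
  g <- c(65, 65)
  We <- 0.1
  n <- g[1]
  m0 <- slab_indicator(0, We, g)
  ctr <- 33
  freq <- ((seq_len(n) - 1) - 32) / n
  for (th in c(30, 45, -60)) {
    mth <- slab_indicator(th, We, g)
    # nearest-neighbour rotation oracle of the centred zero-angle mask
    rot <- matrix(NA_real_, n, n)   # NA where the source falls off-grid
    rad <- -th * pi / 180
    for (r in seq_len(n)) for (cl in seq_len(n)) {
      y <- r - ctr; x <- cl - ctr
      rs <- round(ctr + y * cos(rad) + x * sin(rad))
      cs <- round(ctr - y * sin(rad) + x * cos(rad))
      if (rs >= 1 && rs <= n && cs >= 1 && cs <= n)
        rot[r, cl] <- m0[rs, cs]
    }
    # nearest-neighbour rotation is ambiguous within a pixel of the slab
    # boundary; away from it the two constructions must agree
    u <- outer(freq * sin(th * pi / 180), freq * cos(th * pi / 180), "+")
    decisive <- abs(abs(u) - We) > 1 / n & !is.na(rot)
    comparable <- !is.na(rot)
    expect_gte(mean(rot[comparable] == mth[comparable]), 0.9)
    expect_gte(mean(rot[decisive] == mth[decisive]), 0.95)
  }
})

test_that("density weights sum to one on the union support and vanish outside", {
  g <- c(32, 32)
  for (angles in list(0, c(0, 90), jump_sequence(8))) {
    H <- density_filter(angles, 0.08, g, centered = FALSE)
    total <- Reduce(`+`, H)
    union <- union_mask_oracle(angles, 0.08, 32)
    expect_equal(total, union)
  }
  # single angle: H is the 0/1 slab itself
  H1 <- density_filter(45, 0.08, g)
  expect_equal(H1[[1]], slab_indicator(45, 0.08, g))
  # DC is shared by all slabs, so weights there are 1/n each
  Hj <- density_filter(jump_sequence(4), 0.08, c(33, 33))
  expect_equal(vapply(Hj, function(h) h[17, 17], numeric(1)),
               rep(0.25, 4), ignore_attr = TRUE)
})

test_that("the acquisition operator is an idempotent band-limiting projection", {
  set.seed(3)
  img <- matrix(rnorm(48 * 48), 48, 48)
  tm <- acquire_tomogram(img, 30, 0.1)
  tm2 <- acquire_tomogram(tm$image, 30, 0.1)
  expect_equal(tm2$image, tm$image, tolerance = 1e-12)
  # constant images pass through unchanged (DC is in every slab)
  flat <- matrix(2.5, 32, 32)
  expect_equal(acquire_tomogram(flat, 57, 0.05)$image, flat)
  # a line source oriented along the slab angle is preserved
  for (th in c(0, 45, 90)) {
    ln <- make_phantom("line", c(64, 64),
                       params = list(orientation_deg = th))$a
    kept <- acquire_tomogram(ln, th, 0.055)$image
    expect_gt(cosine_similarity(kept, ln), 0.98)
  }
})

test_that("fusion equals the independent union-support k-space oracle", {
  set.seed(11)
  img <- matrix(rnorm(64 * 64), 64, 64)
  for (angles in list(jump_sequence(32), jump_sequence(8), c(0, 90))) {
    toms <- lapply(angles, function(th) acquire_tomogram(img, th, 0.055))
    fused <- fuse(toms, 0.055)
    expect_lt(max(abs(fused - kspace_fuse_oracle(img, angles, 0.055))),
              1e-6)
  }
})

test_that("fusion is linear and preserves DC and phase support", {
  set.seed(4)
  x <- matrix(rnorm(32 * 32), 32, 32)
  y <- matrix(rnorm(32 * 32), 32, 32)
  angles <- jump_sequence(8)
  fuse_of <- function(img) fuse(lapply(angles, function(th)
    acquire_tomogram(img, th, 0.07)), 0.07)
  expect_equal(fuse_of(2 * x + 3 * y), 2 * fuse_of(x) + 3 * fuse_of(y),
               tolerance = 1e-10)
  expect_equal(mean(fuse_of(x)), mean(x))
  # spectrum outside the union support is exactly zero
  spec <- stats::fft(fuse_of(x))
  outside <- union_mask_oracle(angles, 0.07, 32) == 0
  expect_lt(max(Mod(spec[outside])), 1e-9)
  # single tomogram fuses to itself
  tm <- acquire_tomogram(x, 12.3, 0.07)
  expect_equal(fuse(list(tm), 0.07), tm$image)
  expect_error(fuse(list(tm, tm), 0.07), "duplicate")
})

test_that("sliding fusion produces the full volume series with window timestamps", {
  ph <- make_phantom("tube", c(32, 32),
                     params = list(a = 0, b = 0, c = 0.5, radius_px = 5))
  plan <- scan_plan(8, 3)
  stream <- simulate_acquisition(ph, plan, 0.08)
  fused <- sliding_fuse(stream, plan, 0.08)
  expect_length(fused$images, fused_volume_count(8, 3))
  expect_equal(fused$timestamps, 0:16)
  # static unbleached phantom: every window fuses to the same image
  ref <- fused$images[[1]]
  for (im in fused$images) expect_equal(im, ref, tolerance = 1e-9)
  # each window must equal a direct fuse of its tomograms
  direct <- fuse(stream[6:13], 0.08)
  expect_equal(fused$images[[6]], direct, tolerance = 1e-10)
  expect_error(sliding_fuse(stream[-1], plan, 0.08), "stream length")
  plan1 <- scan_plan(8, 1)
  expect_length(sliding_fuse(stream[1:8], plan1, 0.08)$images, 1)
})
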