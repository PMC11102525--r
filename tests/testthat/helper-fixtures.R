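# Shared fixtures, all generated in code.

# the 32-angle jumping order as printed for the instrument
printed_jump32 <- c(
  0, 90, 45, -45, 22.5, -67.5, 67.5, -22.5,
  11.25, -78.75, 56.25, -33.75, 33.75, -56.25, 78.75, -11.25,
  5.625, -84.375, 50.625, -39.375, 28.125, -61.875, 73.125, -16.875,
  16.875, -73.125, 61.875, -28.125, 39.375, -50.625, 84.375, -5.625)

# independent union-support k-space oracle: masks built from scratch in
# natural FFT layout, symmetrised the Hermitian way, applied directly
union_mask_oracle <- function(angles_deg, We, n) {
  f <- ifelse(0:(n - 1) <= (n - 1) %/% 2, 0:(n - 1), 0:(n - 1) - n) / n
  mirror <- c(1, if (n > 1) n:2)
  u <- matrix(0, n, n)
  for (th in angles_deg * pi / 180) {
    m <- (abs(outer(f * sin(th), f * cos(th), "+")) <= We) * 1
    u <- u + pmax(m, m[mirror, mirror])
  }
  (u > 0) * 1
}

kspace_fuse_oracle <- function(image, angles_deg, We) {
  n <- nrow(image)
  om <- union_mask_oracle(angles_deg, We, n)
  Re(stats::fft(stats::fft(image) * om, inverse = TRUE)) / length(image)
}

# rate grid whose interior points are round multiples of 0.01
round_rate_grid <- function() rate_grid(c(1e-4, seq(0.01, 0.09, by = 0.01)))

expect_dice_at_least <- function(detected, truth, minimum) {
  dice <- 2 * sum(detected & truth) / (sum(detected) + sum(truth))
  expect_gte(dice, minimum)
}
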