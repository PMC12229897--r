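test_that("dF/F of a constant trace is zero and an isolated peak is (F-F0)/F0", {
  d <- compute_dff(rep(100, 900), frame_rate = 30)
  expect_equal(d$values, rep(0, 900))

  raw <- rep(100, 900); raw[450] <- 200
  d <- compute_dff(raw, frame_rate = 30)
  expect_equal(max(d$values), 1.0)
  expect_equal(which.max(d$values), 450)
})

test_that("moving-window baseline matches the naive per-frame median oracle", {
  set.seed(1)
  raw <- 50 + cumsum(rnorm(400, 0, 0.5))   # slow ramp/drift
  raw <- raw - min(raw) + 10
  fr <- 4                                  # 25 s * 4 Hz = 100-frame window
  d <- compute_dff(raw, frame_rate = fr)
  h <- round(25 * fr) %/% 2
  f0_naive <- vapply(seq_along(raw), function(i)
    median(raw[max(1, i - h):min(length(raw), i + h)]), numeric(1))
  expect_equal(d$f0, f0_naive, tolerance = 1e-12)
  expect_equal(d$values, (raw - f0_naive) / f0_naive, tolerance = 1e-12)
})

test_that("dF/F is invariant to multiplicative rescaling of F", {
  set.seed(2)
  raw <- 100 + abs(rnorm(600, 0, 5))
  a <- compute_dff(raw, 30)$values
  b <- compute_dff(3.7 * raw, 30)$values
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("nonpositive baseline raises a signal error", {
  expect_error(compute_dff(rep(0, 300), 30), "F0")
})

test_that("baseline-noise estimate recovers a known simulation parameter", {
  set.seed(3)
  x <- rnorm(20000, 0, 0.1)
  expect_equal(estimate_baseline_noise(x), 0.1, tolerance = 0.1)
  expect_warning(ns <- estimate_baseline_noise(rep(1, 200)), "degenerate")
  expect_equal(ns, 0)
})

test_that("sparse positive transients do not inflate the noise estimate", {
  set.seed(4)
  noise <- rnorm(20000, 0, 0.1)
  with_tr <- noise
  ev <- sample(500:19500, 15)
  for (e in ev) with_tr[e + 0:30] <- with_tr[e + 0:30] + 2
  est_noise <- estimate_baseline_noise(noise)
  est_with <- estimate_baseline_noise(with_tr)
  expect_equal(est_with, est_noise, tolerance = 0.05)
})

test_that("transient masking thresholds correctly and is monotone", {
  set.seed(5)
  x <- rnorm(2000, 0, 0.1)
  x <- pmin(x, 0.25)                       # keep everything below 3 sd
  expect_false(any(detect_significant_transients(x, noise_sd = 0.1)))

  x[1000:1020] <- 0.5                      # one 5-sd transient
  m <- detect_significant_transients(x, noise_sd = 0.1)
  expect_true(all(m[1000:1020]))
  expect_false(any(m[1:900]))

  m3 <- detect_significant_transients(x, noise_sd = 0.1, threshold_sd = 3)
  m4 <- detect_significant_transients(x, noise_sd = 0.1, threshold_sd = 4)
  expect_true(all(which(m4) %in% which(m3)))
})

test_that("spatial maps honour the velocity gate and match a brute-force binning oracle", {
  n_frames <- 3000
  set.seed(6)
  position <- runif(n_frames, 0, 180)
  lap <- rep(1:5, each = 600)
  dff <- matrix(runif(2 * n_frames), 2, n_frames)

  slow <- compute_spatial_map(dff, position, rep(1, n_frames), lap)
  expect_true(all(is.na(slow$maps)))

  const <- compute_spatial_map(matrix(0.7, 1, n_frames), position,
                               rep(10, n_frames), lap)
  expect_equal(as.numeric(const$maps[1, , ][!is.na(const$maps[1, , ])]),
               rep(0.7, sum(!is.na(const$maps[1, , ]))))

  velocity <- runif(n_frames, 0, 10)
  sp <- compute_spatial_map(dff, position, velocity, lap)
  keep <- velocity > 2
  bin <- floor(position / 3.6) + 1
  for (ci in 1:2) for (l in c(1, 4)) for (b in c(3, 27, 50)) {
    idx <- which(keep & lap == l & bin == b)
    want <- if (length(idx)) mean(dff[ci, idx]) else NA_real_
    expect_equal(sp$maps[ci, l, b], want, tolerance = 1e-12)
  }
  ## conservation: occupancy-weighted bin sums equal retained frame sums
  tot_map <- sum(sp$maps[1, , ] * sp$occupancy, na.rm = TRUE)
  expect_equal(tot_map, sum(dff[1, keep]), tolerance = 1e-8)
})

test_that("misaligned streams raise an alignment error", {
  expect_error(compute_spatial_map(matrix(0, 1, 10), runif(9), rep(5, 10),
                                   rep(1, 10)),
               "misaligned")
})
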