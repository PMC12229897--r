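test_that("signed circular shifts wrap and are antisymmetric", {
  expect_equal(pf_shift(50, 50), 0)
  expect_equal(pf_shift(170, 10), 20)       # wraps forward across the seam
  expect_equal(pf_shift(10, 170), -20)
  set.seed(12)
  a <- runif(200, 0, 180); b <- runif(200, 0, 180)
  s <- pf_shift(a, b)
  expect_true(all(s > -90 & s <= 90))
  nb <- abs(pf_shift(a, b)) < 89.9          # away from the antipode
  expect_equal(pf_shift(a, b)[nb], -pf_shift(b, a)[nb])
  expect_error(pf_shift(190, 10), "track_length")
})

test_that("Gaussian shift fit recovers simulated parameters and the 25-cm 3-sd bound", {
  set.seed(13)
  shifts <- rnorm(5000, -1, 25 / 3)
  fit <- fit_shift_gaussian(shifts)
  expect_equal(fit$three_sd, 25, tolerance = 0.1 * 25)
  expect_equal(fit$mu, -1, tolerance = 1)

  d0 <- fit_shift_gaussian(rep(3, 60))
  expect_equal(d0$sigma, 0)

  shifts2 <- rnorm(1000, 5, 12)
  fit2 <- fit_shift_gaussian(shifts2)
  expect_equal(fit2$mu, 5, tolerance = 1.5)
  expect_equal(fit2$sigma, 12, tolerance = 1.5)
})

test_that("consistency chains break at the window and are monotone in it", {
  pf <- rbind(pf_row(day = 1, cell = 1, loc = 10),
              pf_row(day = 2, cell = 1, loc = 41),   # 31 cm: out of 30-cm window
              pf_row(day = 1, cell = 2, loc = 100),
              pf_row(day = 2, cell = 2, loc = 125),  # 25 cm: inside
              pf_row(day = 3, cell = 2, loc = 100))
  ch30 <- build_consistency_chains(pf, window = 30)
  expect_equal(ch30$length[ch30$cell == 1], 1)
  expect_equal(ch30$length[ch30$cell == 2], 3)
  ch20 <- build_consistency_chains(pf, window = 20)
  expect_true(all(ch20$length <= ch30$length))
})

test_that("a missed day ends a chain even if the cell returns", {
  pf <- rbind(pf_row(day = 1, cell = 1, loc = 50),
              pf_row(day = 3, cell = 1, loc = 50))
  ch <- build_consistency_chains(pf)
  expect_equal(ch$length, 1)
  expect_equal(ch$first_day, 1)
})

test_that("cell classification follows both conventions", {
  chains <- data.frame(length = c(1, 2, 3))
  cc <- classify_cells(chains, "counts")
  expect_equal(as.character(cc), c("transient", "transient", "sustained"))
  cp <- classify_cells(chains, "properties")
  expect_equal(as.character(cp), c("transient", NA, "sustained"))
})

test_that("double-exponential fitter recovers the reported time constants within 5%", {
  d <- 1:7
  counts <- 300 * exp(-(d - 1) / 0.67) + 150 * exp(-(d - 1) / 4.6)
  fit <- fit_double_exponential(counts, day = d)
  expect_equal(fit$tau_fast, 0.67, tolerance = 0.05 * 0.67)
  expect_equal(fit$tau_slow, 4.6, tolerance = 0.05 * 4.6)
  expect_equal(fit$Amp1, 300, tolerance = 15)
  expect_equal(fit$Amp2, 150, tolerance = 8)
})

test_that("a pure single exponential yields a vanishing second amplitude", {
  d <- 1:7
  counts <- 400 * exp(-(d - 1) / 1.2)
  fit <- suppressWarnings(fit_double_exponential(counts, day = d))
  ## one amplitude carries the signal; the other is negligible or the
  ## two time constants coincide
  expect_true(min(fit$Amp1, fit$Amp2) < 0.05 * max(fit$Amp1, fit$Amp2) ||
                abs(fit$tau_fast - fit$tau_slow) < 0.1)
})

test_that("fit residual is no worse than a brute-force grid optimum", {
  d <- 1:6
  set.seed(14)
  counts <- 200 * exp(-(d - 1) / 0.8) + 90 * exp(-(d - 1) / 5) +
    rnorm(6, 0, 2)
  fit <- fit_double_exponential(counts, day = d)
  rss_fit <- sum(fit$residuals^2)
  grid <- expand.grid(tf = seq(0.2, 2, by = 0.05), ts = seq(2, 9, by = 0.1))
  rss_grid <- min(apply(grid, 1, function(g) {
    X <- cbind(exp(-(d - 1) / g[1]), exp(-(d - 1) / g[2]))
    sum(stats::lm.fit(X, counts)$residuals^2)
  }))
  expect_lte(rss_fit, rss_grid + 1e-6)
})

test_that("memoryless expectation is zero without place cells and matches Monte Carlo", {
  expect_equal(expected_random_past_pcs(p_pc = 0)$total, 0)
  closed <- expected_random_past_pcs(2511, 0.3, 1 / 3, 7)
  set.seed(15)
  mc <- simulate_random_past_pcs(2511, 0.3, 7, window = 30, n_reps = 60)
  expect_lt(abs(mc$total - closed$total), 3 * mc$se_total)
})

test_that("past/new counts conserve totals and match hand enumeration", {
  pf <- rbind(pf_row(day = 1, cell = 1:5, loc = c(10, 50, 90, 130, 170)))
  pn1 <- count_past_new(pf)
  expect_equal(pn1$past, 0)
  expect_equal(pn1$new, 5)

  ## static population: all past from day 2 on
  pf2 <- rbind(pf, pf_row(day = 2, cell = 1:5, loc = c(10, 50, 90, 130, 170)))
  pn2 <- count_past_new(pf2)
  expect_equal(pn2$past[pn2$day == 2], 5)

  ## crafted example: cells 1 (same place), 2 (moved 40 cm), 3 (new on day 2)
  pf3 <- rbind(pf_row(day = 1, cell = 1, loc = 20),
               pf_row(day = 1, cell = 2, loc = 80),
               pf_row(day = 2, cell = 1, loc = 25),
               pf_row(day = 2, cell = 2, loc = 120),
               pf_row(day = 2, cell = 3, loc = 60))
  pn3 <- count_past_new(pf3)
  d2 <- pn3[pn3$day == 2, ]
  expect_equal(d2$past, 1)
  expect_equal(d2$new, 2)
  expect_equal(d2$past + d2$new, d2$total)
})

test_that("stability index is positive for static cells and near zero for random ones", {
  set.seed(16)
  loc <- runif(40, 0, 180)
  static <- rbind(pf_row(day = 1, cell = 1:40, loc = loc),
                  pf_row(day = 3, cell = 1:40, loc = loc))
  si <- stability_index(static, day = 1, n_boot = 500)
  expect_gt(si$index, 0)

  rand <- rbind(pf_row(day = 1, cell = 1:40, loc = runif(40, 0, 180)),
                pf_row(day = 3, cell = 1:40, loc = runif(40, 0, 180)))
  sr <- stability_index(rand, day = 1, n_boot = 500)
  expect_lt(sr$index, 0.15)

  set.seed(17); a <- stability_index(static, day = 1, n_boot = 300)
  set.seed(17); b <- stability_index(static, day = 1, n_boot = 300)
  expect_identical(a, b)
})
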