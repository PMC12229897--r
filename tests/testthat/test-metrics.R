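test_that("cosine similarity is 1 for identical laps, 0 for disjoint ones, and matches a dot-product oracle", {
  m <- matrix(rep(c(1, 2, 0, 3), each = 4), 4, 4, byrow = FALSE)
  C <- similarity_matrix(matrix(rep(c(1, 2, 0, 3), 4), 4, 4, byrow = TRUE))
  expect_equal(as.numeric(C), rep(1, 16), tolerance = 1e-12)

  disj <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  Cd <- similarity_matrix(disj)
  expect_equal(Cd[1, 2], 0)
  expect_equal(diag(Cd), c(1, 1))

  set.seed(18)
  r <- matrix(runif(6 * 10), 6, 10)
  Cr <- similarity_matrix(r)
  for (i in 1:6) for (j in 1:6)
    expect_equal(Cr[i, j],
                 sum(r[i, ] * r[j, ]) / sqrt(sum(r[i, ]^2) * sum(r[j, ]^2)),
                 tolerance = 1e-12)
})

test_that("similarity is invariant to per-lap positive rescaling", {
  set.seed(19)
  m <- matrix(runif(8 * 20), 8, 20)
  C1 <- similarity_matrix(m)
  C2 <- similarity_matrix(m * runif(8, 0.1, 5))
  expect_equal(unclass(C1), unclass(C2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("discrimination index is 0 for context-identical and 1 for orthogonal activity", {
  lab <- c("RL1", "RL1", "RL2", "RL2")
  same <- matrix(rep(c(1, 0, 2, 0.5), times = 4), 4, 4, byrow = TRUE)
  C <- similarity_matrix(same, lap_condition = lab)
  expect_equal(discrimination_index(C), 0, tolerance = 1e-12)

  orth <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  Co <- similarity_matrix(orth, lap_condition = lab)
  expect_equal(discrimination_index(Co), 1, tolerance = 1e-12)
})

test_that("4-lap discrimination index matches manual arithmetic", {
  lab <- c("RL1", "RL2", "RL1", "RL2")
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0, 1, 1))
  C <- similarity_matrix(m, lap_condition = lab)
  ## manual: rows normalized; within = C[1,3], C[2,4]; between = mean of
  ## the cross terms per row
  manual <- mean(c(C[1, 3] - mean(C[1, c(2, 4)]),
                   C[2, 4] - mean(C[2, c(1, 3)]),
                   C[3, 1] - mean(C[3, c(2, 4)]),
                   C[4, 2] - mean(C[4, c(1, 3)])))
  expect_equal(discrimination_index(C), manual, tolerance = 1e-12)
})

test_that("label-shuffled discrimination index is near zero", {
  set.seed(20)
  lab <- rep(c("RL1", "RL2"), each = 10)
  m <- field_map(n_laps = 20, centre_cm = 60, width_cm = 20)
  m[lab == "RL2", ] <- field_map(n_laps = 10, centre_cm = 140,
                                 width_cm = 20)
  vals <- replicate(200, {
    C <- similarity_matrix(m, lap_condition = sample(lab))
    discrimination_index(C)
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.01)
})

test_that("field-density confidence band calibrates on uniform data and flags a point mass", {
  set.seed(22)
  d <- pf_density(runif(400, 0, 180), n_boot = 1500)
  expect_lte(mean(d$over_represented), 0.04)

  d1 <- pf_density(rep(90, 50), n_boot = 500)
  expect_true(d1$over_represented[26])     # the bin containing 90 cm

  set.seed(23); a <- pf_density(runif(50, 0, 180), n_boot = 300)
  set.seed(23); b <- pf_density(runif(50, 0, 180), n_boot = 300)
  expect_identical(a, b)
})

test_that("onset-lap KS statistic matches a direct CDF-scan oracle", {
  same <- c(1, 2, 3, 4, 5)
  r <- onset_lap_distributions(same, same)
  expect_equal(r$ks_statistic, 0)

  r2 <- onset_lap_distributions(1:5, 11:15)
  expect_equal(r2$ks_statistic, 1)

  set.seed(24)
  a <- rgeom(80, 0.3); b <- rgeom(80, 0.15) + 2
  r3 <- onset_lap_distributions(a, b)
  grid <- sort(unique(c(a, b)))
  sup <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(r3$ks_statistic, sup, tolerance = 1e-12)
})

test_that("day-to-day correlation is 1 for identical days and near 0 for independent maps", {
  set.seed(25)
  mk <- function() {
    maps <- array(runif(12 * 8 * 50), dim = c(12, 8, 50))
    structure(list(maps = maps, lap_condition = rep(c("RL1", "RL2"), 4),
                   track_length = 180, bin_width = 3.6),
              class = "spatial_map")
  }
  a <- mk()
  expect_equal(day_to_day_correlation(a, a, cells = 1:12), 1)
  expect_lt(abs(day_to_day_correlation(a, mk(), cells = 1:12)), 0.1)
  expect_warning(r <- day_to_day_correlation(a, a, cells = 1:5), "fewer")
  expect_true(is.na(r))
})

test_that("licking selectivity is 1 for purely anticipatory licking and 0 for uniform licking", {
  n_laps <- 8
  lab <- rep("RL1", n_laps)
  rb <- c(RL1 = 28)                 # reward bin; anticipatory = bins 25-27
  rand_zone <- 10:12
  only_ant <- matrix(0, n_laps, 50); only_ant[, 25:27] <- 1
  r1 <- licking_selectivity(only_ant, lab, rb, rand_zone)
  expect_equal(r1$selectivity, 1)

  uni <- matrix(1, n_laps, 50)
  r0 <- licking_selectivity(uni, lab, rb, rand_zone)
  expect_equal(r0$selectivity, 0)

  ## toy 4-lap table: licks in anticipatory zone on 3 laps, random zone on 1
  toy <- matrix(0, 4, 50)
  toy[1:3, 26] <- 1; toy[2, 11] <- 1
  rt <- licking_selectivity(toy, rep("RL1", 4), rb, rand_zone)
  expect_equal(rt$selectivity, (0.75 - 0.25) / 0.75, tolerance = 1e-12)
})
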