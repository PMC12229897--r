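test_that("flat activity yields no induction events", {
  expect_equal(nrow(detect_btsp_events(matrix(0, 12, 50))), 0)
  expect_equal(nrow(detect_btsp_events(matrix(0.4, 12, 50))), 0)
})

test_that("an injected induction event is detected on the right lap and re-satisfies the criteria", {
  set.seed(26)
  for (rep in 1:10) {
    m <- matrix(0, 25, 50)
    lap <- sample(3:15, 1); ctr <- runif(1, 0, 180); vel <- runif(1, 10, 30)
    inj <- inject_btsp_event(m, lap, ctr, vel)
    ev <- detect_btsp_events(inj$map, lap_velocity = rep(vel, 25))
    expect_true(any(ev$lap == lap))
    e <- ev[ev$lap == lap, ]
    ## independent re-check of the four printed predicates
    amps <- apply(inj$map, 1, max)
    expect_gte(e$amplitude, quantile(amps[amps > 0], 0.8) - 1e-9)  # (1)
    expect_gte(e$amplitude, 1)                                     # (1)
    expect_gte(e$n_active_post, 3)                                 # (2)+(3)
    expect_lt(e$com_shift_cm, 0)                                   # (4)
  }
})

test_that("a forward-shifted field is rejected by the negative-COM criterion", {
  m <- matrix(0, 20, 50)
  inj <- inject_btsp_event(m, 5, 90, 20, drift_cm = -3)  # forward drift
  ev <- detect_btsp_events(inj$map)
  expect_false(any(ev$lap == 5))
})

test_that("a null injection leaves the map unchanged", {
  m <- field_map(n_laps = 12)
  inj <- inject_btsp_event(m, 4, 90, 20, amplitude = 0)
  expect_identical(inj$map, m)
  expect_equal(nrow(inj$event), 0)
  expect_error(inject_btsp_event(m, 40, 90, 20), "lap")
})

test_that("plateau threshold is the minimum event amplitude and sets the rate", {
  events <- data.frame(amplitude = c(3.2, 2.8), lap = c(4, 9))
  amps <- c(0.8, 1.1, 2.8, 3.2, 3.5)
  r <- plateau_threshold_and_rate(events, amps, n_laps = 50)
  expect_equal(r$threshold, 2.8)
  expect_lte(r$threshold, min(events$amplitude))
  expect_equal(r$n_plateaus, 3)
  expect_equal(r$rate, 3 / 50)

  none <- plateau_threshold_and_rate(events[0, ], amps, 50)
  expect_true(none$flagged)
  expect_true(is.na(none$rate))

  one <- plateau_threshold_and_rate(data.frame(amplitude = 3, lap = 2),
                                    c(3), n_laps = 30)
  expect_equal(one$rate, 1 / 30)
})

test_that("pre/post statistics separate silent pre-laps from robust post firing", {
  m <- matrix(0, 20, 50)
  inj <- inject_btsp_event(m, 8, 90, 20, n_post = 12)
  ev <- detect_btsp_events(inj$map)
  st <- pre_post_event_stats(inj$map, ev)
  expect_equal(st$pre_amplitude, 0)
  expect_gt(st$post_amplitude, 0.5)
  expect_equal(st$pre_reliability, 0)
  expect_gte(st$post_reliability, 0.6)     # 3-of-5 arithmetic bound

  ## toy 10-lap map computed by hand: event lap 3 amp 3; laps 4-8 amp 1
  toy <- matrix(0, 10, 50)
  toy[3, 25] <- 3; for (l in 4:8) toy[l, 24] <- 1
  evt <- data.frame(lap = 3, amplitude = 3, peak_cm = 88.2,
                    com_shift_cm = -1, n_active_post = 5,
                    induction_velocity = NA, pf_width_cm = NA,
                    is_first = TRUE)
  stt <- pre_post_event_stats(toy, evt)
  expect_equal(stt$pre_amplitude, 0)                 # laps 1-2 silent
  expect_equal(stt$post_amplitude, 5 / 7)            # 5 laps of 1 over 7 laps
  expect_equal(stt$post_reliability, 5 / 7)
})

test_that("width-velocity regression recovers the generating line exactly without noise", {
  set.seed(27)
  vel <- runif(30, 8, 35)
  ev <- data.frame(pf_width_cm = 0.8 * vel + 18.95, induction_velocity = vel)
  r <- suppressWarnings(width_velocity_regression(ev))  # perfect-fit note
  expect_equal(r$slope, 0.8, tolerance = 1e-9)
  expect_equal(r$intercept, 18.95, tolerance = 1e-8)

  ## consistent unit change (cm -> bins on both axes) rescales but keeps sign
  ev2 <- data.frame(pf_width_cm = ev$pf_width_cm / 3.6,
                    induction_velocity = vel / 3.6)
  r2 <- suppressWarnings(width_velocity_regression(ev2))
  expect_equal(r2$slope, r$slope, tolerance = 1e-9)
  expect_equal(r2$intercept, r$intercept / 3.6, tolerance = 1e-8)

  ev$induction_velocity <- 20
  expect_error(width_velocity_regression(ev), "degenerate")
})

test_that("membrane-potential plateau detection applies the printed merge rule", {
  fs <- 20000
  expect_equal(nrow(detect_vm_plateaus(rep(-65, fs), fs)), 0)

  one <- synthesize_vm_trace(data.frame(onset_s = 1, duration_ms = 200),
                             duration_s = 3)
  p1 <- detect_vm_plateaus(one, fs)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$duration_ms, 200, tolerance = 10)
  expect_true(p1$long_lasting)

  ## two 100-ms plateaus separated by 100 ms -> one long-lasting plateau
  two <- synthesize_vm_trace(data.frame(onset_s = c(1, 1.2),
                                        duration_ms = c(100, 100)),
                             duration_s = 3)
  p2 <- detect_vm_plateaus(two, fs)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$merged_from, 2)
  expect_true(p2$long_lasting)
  expect_equal(p2$duration_ms, 200, tolerance = 12)

  ## separated by 200 ms -> two distinct plateaus, neither long-lasting
  far <- synthesize_vm_trace(data.frame(onset_s = c(1, 1.3),
                                        duration_ms = c(100, 100)),
                             duration_s = 3)
  p3 <- detect_vm_plateaus(far, fs)
  expect_equal(nrow(p3), 2)
  expect_false(any(p3$long_lasting))
})

test_that("the plateau merge rule is idempotent", {
  runs <- data.frame(start = c(100, 3000, 20000), end = c(600, 3500, 21000))
  m1 <- pfdyn:::merge_plateau_runs(runs, 20000)
  m2 <- pfdyn:::merge_plateau_runs(data.frame(start = m1$start, end = m1$end),
                                   20000)
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(m2$start, m1$start)
})

test_that("an empty plateau specification never crosses the -35 mV threshold", {
  vm <- synthesize_vm_trace(data.frame(onset_s = numeric(),
                                       duration_ms = numeric()),
                            duration_s = 1, n_baseline_spikes = 0)
  expect_false(any(vm > -35))
  expect_error(synthesize_vm_trace(data.frame(onset_s = c(1, 1.05),
                                              duration_ms = c(100, 100))),
               "overlap")
})
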