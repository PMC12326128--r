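test_that("RT detection finds the first armed upward threshold crossing", {
  tr <- function(t, y) data.frame(time_ms = t, pm_max = y)
  t <- seq(0, 600, by = 1)
  # linear ramp crossing 0.30 exactly at onset + 250
  y <- pmin(0.6, pmax(0, (t - 200) * 0.3 / 300))
  d <- detect_rt(tr(t, y), 100, threshold = 0.30)
  expect_equal(d$rt_ms, 400)  # crossing at t = 500, onset 100
  d2 <- detect_rt(tr(t, y), 200)
  expect_equal(d2$rt_ms, 300)
  expect_false(d2$anticipatory)
  # a trace peaking below threshold yields no response
  d3 <- detect_rt(tr(t, pmin(0.29, y)), 200)
  expect_true(is.na(d3$rt_ms) && !d3$responded)
  # crossing 80 ms after onset is flagged anticipatory
  y4 <- ifelse(t >= 280, 0.5, 0)
  d4 <- detect_rt(tr(t, y4), 200)
  expect_equal(d4$rt_ms, 79.6, tolerance = 0.01)
  expect_true(d4$anticipatory)  # faster than the 100 ms cutoff
  # if the trace is above threshold at onset, wait for it to fall first
  y5 <- ifelse(t < 250, 0.5, ifelse(t < 400, 0.1, 0.6))
  d5 <- detect_rt(tr(t, y5), 200)
  expect_gt(d5$rt_ms, 150)
  expect_error(detect_rt(tr(t, y), 700), "outside")
})

test_that("perceived position is the activity barycentre", {
  pos <- unit_positions(180)
  act <- rep(0, 180)
  act[pos == 10] <- 0.7
  expect_equal(perceived_position(act, pos), 10)
  act2 <- rep(0, 180)
  act2[pos == 0] <- 0.4; act2[pos == 10] <- 0.4
  expect_equal(perceived_position(act2, pos), 5)
  act3 <- rep(0, 180)
  act3[pos == 0] <- 0.2; act3[pos == 5] <- 0.6
  expect_equal(perceived_position(act3, pos), 3.75)
  expect_true(is.na(perceived_position(rep(0, 180), pos)))  # no percept
})

test_that("auditory bias is the capture fraction in percent", {
  expect_equal(auditory_bias(10, 10, 0), 0)    # veridical
  expect_equal(auditory_bias(0, 10, 0), 100)   # full visual capture
  expect_equal(auditory_bias(6.5, 10, 0), 35)
  expect_equal(auditory_bias(-6.5, -10, 0), 35)  # mirror placement
  expect_error(auditory_bias(1, 5, 5), "zero")
})

test_that("the ventriloquism protocol yields mirror-averaged bias tables", {
  p <- tpar()
  b <- run_ventriloquism(disparities = c(0, 5), n_reps = 4, params = p,
                         seed = 31)
  expect_s3_class(b, "av_bias_table")
  # the zero-disparity placement is dropped (bias undefined there)
  expect_equal(unique(b$summary$disparity_deg), 5)
  expect_equal(b$summary$n, 8)  # both sides pooled
  expect_setequal(unique(b$trials$side), c(-1, 1))
  expect_true(all(b$trials$bias_pct > -50 & b$trials$bias_pct < 150))
  # repetitions are individually seeded: same experiment seed reproduces
  b2 <- run_ventriloquism(disparities = c(0, 5), n_reps = 4, params = p,
                          seed = 31)
  expect_identical(b$trials, b2$trials)
})

test_that("bias at zero asynchrony equals the synchronous protocol", {
  p <- tpar()
  b1 <- run_ventriloquism(disparities = 10, n_reps = 3, params = p, seed = 9)
  b2 <- run_bias_vs_isi(isis = 0, disparities = 10, n_reps = 3, params = p,
                        seed = 9)
  expect_equal(b1$summary$mean_bias_pct, b2$summary$mean_bias_pct)
})

test_that("the sensitivity sweep holds the excitation/inhibition ratio", {
  p <- tpar()
  out <- run_sensitivity(wva0_values = 0.12, lin0_values = c(3, 5),
                         n_reps = 2, params = p, seed = 5)
  expect_equal(out$la_ex0 / out$la_in0, rep(p$la_ex0 / p$la_in0, 2))
  expect_equal(nrow(out), 2)
  expect_true(all(is.finite(out$switch_cost_ms)))
  # the literally printed cross-modal sweep values are accepted too
  lit <- run_sensitivity(wva0_values = 0.012, lin0_values = 4, n_reps = 1,
                         params = p, seed = 5)
  expect_equal(lit$wva0, 0.012)
})

test_that("RT-task records carry labels, exclusions and perceived positions", {
  p <- tpar()
  task <- run_rt_task(n_trials = 10, params = p, seed = 13)
  r <- task$records
  expect_equal(nrow(r), 10)
  expect_identical(r$label, label_trials(r$modality))
  expect_true(all(is.na(r$rt_ms) | r$rt_ms >= 0))
  expect_true(all(r$anticipatory == (r$responded & !is.na(r$rt_ms) &
                                       r$rt_ms < 100)))
  # perceived positions at central fixation stay near 0 degrees
  expect_true(all(abs(r$perceived_a_deg[r$modality != "V"]) < 10))
  expect_false(any(c("first", "excluded") %in% task$summary$label))
})
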