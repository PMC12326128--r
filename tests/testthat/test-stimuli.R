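test_that("trial labelling follows the repeat/switch rule", {
  expect_equal(label_trials(c("A", "A", "V", "AV")),
               c("first", "RpA", "SwV", "SwV_AV"))
  # unisensory trials after an audiovisual one are neither repeat nor switch
  expect_equal(label_trials(c("AV", "A")), c("first", "excluded"))
  expect_equal(label_trials(c("AV", "AV", "V")),
               c("first", "RpAV", "excluded"))
  expect_equal(label_trials(c("V", "AV")), c("first", "SwV_AV"))
})

test_that("labelling matches a brute-force oracle on random sequences", {
  # independent re-statement of the rule, case by case
  oracle <- function(mods) {
    out <- character(length(mods))
    for (i in seq_along(mods)) {
      out[i] <- if (i == 1) "first"
      else if (mods[i] == mods[i - 1]) paste0("Rp", mods[i])
      else if (mods[i] == "AV") paste0("Sw", mods[i - 1], "_AV")
      else if (mods[i - 1] == "AV") "excluded"
      else paste0("Sw", mods[i])
    }
    out
  }
  set.seed(42)
  for (rep in 1:25) {
    mods <- sample(c("A", "V", "AV"), sample(2:40, 1), replace = TRUE)
    expect_identical(label_trials(mods), oracle(mods))
  }
})

test_that("RT sequences respect the ISI bounds and are reproducible", {
  p <- tpar()
  s1 <- make_rt_sequence(60, p, seed = 7)
  s2 <- make_rt_sequence(60, p, seed = 7)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$events, s2$events)
  isis <- s1$trials$isi_ms[-1]
  expect_true(all(isis >= 1000 & isis <= 3000))
  expect_identical(s1$trials$label, label_trials(s1$trials$modality))
  # audiovisual trials contribute one event per component
  n_ev <- sum(ifelse(s1$trials$modality == "AV", 2L, 1L))
  expect_equal(nrow(s1$events), n_ev)
  # effectiveness jitter stays inside the configured band
  nom <- ifelse(s1$events$modality == "A", p$i0_a, p$i0_v)
  ratio <- s1$events$effectiveness / nom
  expect_true(all(ratio >= 1 - p$jitter_frac & ratio <= 1 + p$jitter_frac))
  expect_error(make_rt_sequence(1, p), "n_trials")
})

test_that("audiovisual pairs place components per disparity and order", {
  p <- tpar()
  pr <- make_av_pair(10, 0, p, seed = 1)
  a <- pr$events[pr$events$modality == "A", ]
  v <- pr$events[pr$events$modality == "V", ]
  expect_equal(a$position_deg, 10)
  expect_equal(v$position_deg, 0)
  expect_equal(a$onset_ms, v$onset_ms)  # synchronous at isi 0
  # mirror disparities are mirror images about the visual position
  pl <- make_av_pair(-5, 0, p, seed = 1)
  pr5 <- make_av_pair(5, 0, p, seed = 1)
  expect_equal(pl$events$position_deg[pl$events$modality == "A"], -5)
  expect_equal(pr5$events$position_deg[pr5$events$modality == "A"], 5)
  # onset asynchrony and lead order
  pv <- make_av_pair(5, 200, p, order = "v_leads", seed = 2)
  pa <- make_av_pair(5, 200, p, order = "a_leads", seed = 2)
  on <- function(x, m) x$events$onset_ms[x$events$modality == m]
  expect_equal(on(pv, "A") - on(pv, "V"), 200)
  expect_equal(on(pa, "V") - on(pa, "A"), 200)
  expect_error(make_av_pair(5, -10, p), "isi_ms")
})

test_that("external fields are Gaussian in space and gated in time", {
  p <- tpar()
  x <- unit_positions(p$n_units)
  e <- stimulus_event("A", 0, 100, 60, 30)
  f <- external_field(e, p$sigma_a, x)
  expect_equal(which.max(f$profile), 91)  # 0 degrees sits at unit 91
  expect_equal(max(f$profile), 30)
  expect_equal(f$profile[91 + p$sigma_a], 30 * exp(-0.5))
  expect_equal(f$onset_ms, 100)
  expect_equal(f$offset_ms, 160)
  expect_error(external_field(e, 0, x), "sigma_r")
  expect_error(stimulus_event("A", 0, -1, 60, 30), "onset")
  expect_error(stimulus_event("A", 0, 0, 0, 30), "duration")
})

test_that("trial sequences round-trip through the tabular format", {
  p <- tpar()
  sq <- make_rt_sequence(12, p, seed = 3)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_trial_sequence(sq, f)
  back <- read_trial_sequence(f)
  expect_setequal(names(back), c("trial", "modality", "position_deg",
                                 "onset_ms", "duration_ms", "effectiveness",
                                 "label"))
  expect_equal(nrow(back), nrow(sq$events))
  merged <- merge(back, sq$trials[, c("trial", "label")], by = "trial")
  expect_true(all(merged$label.x == merged$label.y))
})
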