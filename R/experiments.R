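#' Detect a reaction time from a premotor activity trace
#'
#' The simulated reaction time is the interval between stimulus onset and the
#' first upward crossing of the detection threshold (a fixed fraction of the
#' saturation activity) by the premotor peak trace. If the trace is already
#' above threshold at onset (an earlier response still decaying), the
#' detector waits until it falls below before accepting a new upward
#' crossing. The crossing instant is refined by linear interpolation between
#' samples. Responses faster than the anticipatory cutoff are flagged.
#'
#' @param sim an `av_sim`, or a data frame with `time_ms` and `pm_max`.
#' @param onset_ms stimulus onset; must lie inside the recorded trace.
#' @param threshold detection threshold (default 0.30 of saturation).
#' @param window_ms response window after onset; later crossings count as
#'   no-response.
#' @param anticipatory_cutoff_ms responses faster than this are flagged.
#' @return List: `rt_ms` (NA if no response), `responded`, `anticipatory`.
#' @export
detect_rt <- function(sim, onset_ms, threshold = 0.30, window_ms = 1000,
                      anticipatory_cutoff_ms = 100) {
  trace <- if (inherits(sim, "av_sim")) sim$trace else sim
  tm <- trace$time_ms
  y <- trace$pm_max
  if (onset_ms < tm[1] || onset_ms > tm[length(tm)]) {
    stop("detect_rt: onset_ms lies outside the recorded trace")
  }
  idx <- which(tm >= onset_ms & tm <= onset_ms + window_ms)
  tt <- tm[idx]
  yy <- y[idx]
  armed <- yy[1] < threshold
  rt <- NA_real_
  for (i in seq_along(yy)[-1]) {
    if (!armed) {
      if (yy[i] < threshold) armed <- TRUE
    } else if (yy[i] >= threshold && yy[i - 1] < threshold) {
      frac <- (threshold - yy[i - 1]) / (yy[i] - yy[i - 1])
      rt <- tt[i - 1] + frac * (tt[i] - tt[i - 1]) - onset_ms
      break
    }
  }
  list(rt_ms = rt, responded = !is.na(rt),
       anticipatory = !is.na(rt) && rt < anticipatory_cutoff_ms)
}

#' Perceived position as the barycentre of a population activity
#'
#' Activity-weighted mean of the unit azimuths; the population-vector style
#' readout used for the perceived location of a stimulus in its input area.
#'
#' @param activity non-negative activity vector.
#' @param positions unit azimuths (degrees), same length.
#' @return Perceived azimuth in degrees, or `NA` (no percept) when the total
#'   activity is (numerically) zero.
#' @export
perceived_position <- function(activity, positions) {
  stopifnot(length(activity) == length(positions))
  s <- sum(activity)
  if (!is.finite(s) || s < 1e-12) return(NA_real_)
  sum(activity * positions) / s
}

#' Auditory localization bias as percent of the audiovisual distance
#'
#' `100 * (true_a - perceived_a) / (true_a - true_v)`: 0 means veridical
#' auditory localization, 100 means full capture by the visual position.
#'
#' @param perceived_a perceived auditory azimuth, degrees.
#' @param true_a,true_v actual auditory and visual azimuths; must differ.
#' @return Bias in percent.
#' @export
auditory_bias <- function(perceived_a, true_a, true_v) {
  if (any(true_a == true_v)) {
    stop("auditory_bias is undefined at zero audiovisual disparity")
  }
  100 * (true_a - perceived_a) / (true_a - true_v)
}

# deterministic per-repetition seed derived from the experiment seed
.rep_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629) + 1L
}

# simulate one AV pair and return the auditory bias read out at the offset
# of the auditory component
.bias_one_pair <- function(disparity_deg, isi_ms, params, kernels, seed,
                           order = "v_leads") {
  p <- params
  pair <- make_av_pair(disparity_deg, isi_ms, p, order = order, seed = seed)
  a_ev <- pair$events[pair$events$modality == "A", ]
  readout <- a_ev$onset_ms + a_ev$duration_ms
  sim <- simulate_network(pair$events, p, kernels,
                          t_total_ms = readout + 2 * p$dt_ms)
  i <- which.min(abs(sim$trace$time_ms - readout))
  perceived <- sim$trace$a_bary[i]
  c(perceived_a = perceived,
    bias = auditory_bias(perceived, a_ev$position_deg, 0))
}

#' Spatial ventriloquism experiment
#'
#' Synchronous audiovisual pairs with the visual stimulus at central fixation
#' and the auditory stimulus displaced to the left and to the right by each
#' disparity; the perceived auditory position is the barycentre of the
#' auditory-area activity at stimulus offset, and the bias is expressed as
#' percent of the audiovisual distance. Left and right placements with the
#' same eccentricity are averaged in the summary.
#'
#' @param disparities absolute disparities in degrees (0 entries are dropped
#'   from the bias table: the bias is undefined there).
#' @param n_reps repetitions per placement (effectiveness re-jittered).
#' @param params an `av_params` record.
#' @param seed experiment seed; each repetition uses a derived stream.
#' @return List of class `av_bias_table`: `trials` (per-trial records) and
#'   `summary` (mean and SEM of the bias per absolute disparity).
#' @export
run_ventriloquism <- function(disparities = c(0, 5, 10, 15, 20), n_reps = 100,
                              params = av_params(), seed = 1L) {
  run_bias_vs_isi(isis = 0, disparities = disparities, n_reps = n_reps,
                  params = params, seed = seed)
}

#' Auditory bias across onset asynchrony and disparity
#'
#' Generalization of [run_ventriloquism()] to temporally misaligned pairs:
#' the leading (visual, by default) stimulus is followed by the auditory one
#' after each onset asynchrony, for each spatial disparity. `isis = 0`
#' reproduces the synchronous ventriloquism protocol exactly.
#'
#' @param isis onset asynchronies, ms.
#' @param disparities absolute disparities, degrees (0 dropped).
#' @param n_reps repetitions per (isi, placement).
#' @param params an `av_params` record.
#' @param seed experiment seed.
#' @param order which modality leads for positive asynchronies.
#' @return An `av_bias_table` (see [run_ventriloquism()]), with `isi_ms` in
#'   both tables.
#' @export
run_bias_vs_isi <- function(isis = c(200, 500, 800),
                            disparities = c(5, 10, 15, 20), n_reps = 250,
                            params = av_params(), seed = 1L,
                            order = "v_leads") {
  p <- params
  validate_av_params(p)
  kernels <- build_kernels(p)
  disparities <- unique(abs(disparities))
  disparities <- disparities[disparities > 0]
  grid <- expand.grid(isi_ms = isis, disparity_deg = disparities,
                      side = c(-1, 1), rep = seq_len(n_reps))
  rows <- vector("list", nrow(grid))
  counter <- 0L
  for (g in seq_len(nrow(grid))) {
    counter <- counter + 1L
    d <- grid$disparity_deg[g] * grid$side[g]
    r <- .bias_one_pair(d, grid$isi_ms[g], p, kernels,
                        seed = .rep_seed(seed, counter), order = order)
    rows[[g]] <- data.frame(
      isi_ms = grid$isi_ms[g], disparity_deg = grid$disparity_deg[g],
      side = grid$side[g], rep = grid$rep[g],
      true_a_deg = d, true_v_deg = 0,
      perceived_a_deg = r[["perceived_a"]], bias_pct = r[["bias"]],
      seed = .rep_seed(seed, counter)
    )
  }
  trials <- do.call(rbind, rows)
  agg <- stats::aggregate(bias_pct ~ isi_ms + disparity_deg, data = trials,
                          FUN = function(x) c(mean = mean(x),
                                              sem = stats::sd(x) / sqrt(length(x)),
                                              n = length(x)))
  summary <- data.frame(agg[c("isi_ms", "disparity_deg")],
                        mean_bias_pct = agg$bias_pct[, "mean"],
                        sem_bias_pct = agg$bias_pct[, "sem"],
                        n = agg$bias_pct[, "n"])
  summary <- summary[order(summary$isi_ms, summary$disparity_deg), ]
  rownames(summary) <- NULL
  structure(list(trials = trials, summary = summary, seed = seed,
                 params = p), class = "av_bias_table")
}

# simulate a two-stimulus sequence (modality m1 then m2, positions pos1/pos2,
# onset asynchrony isi) and return the RT to the second stimulus
.pair_rt <- function(m1, m2, pos1, pos2, isi_ms, params, kernels, seed) {
  p <- params
  ev <- withr_seed(seed, {
    mk <- function(m, pos, onset) {
      comps <- if (m == "AV") c("A", "V") else m
      do.call(rbind, lapply(comps, function(cm) {
        nom <- if (cm == "A") p$i0_a else p$i0_v
        stimulus_event(cm, pos, onset, p$stim_duration_ms,
                       .draw_effectiveness(nom, p$jitter_frac))
      }))
    }
    rbind(mk(m1, pos1, 200), mk(m2, pos2, 200 + isi_ms))
  })
  onset2 <- 200 + isi_ms
  sim <- simulate_network(ev, p, kernels,
                          t_total_ms = onset2 + p$response_window_ms + 50)
  detect_rt(sim, onset2, threshold = p$rt_threshold,
            window_ms = p$response_window_ms,
            anticipatory_cutoff_ms = p$anticipatory_cutoff_ms)
}

#' Reaction-time task over the seven repeat/switch configurations
#'
#' Presents randomized sequences of A, V and AV stimuli at central fixation
#' with ISIs uniform in `[isi_low_ms, isi_high_ms]`, simulates the whole
#' sequence without resetting the state (carried-over cross-sensory
#' inhibition is what produces switch costs), and records the RT of every
#' trial together with its repeat/switch label (`RpA`, `SwA`, `RpV`, `SwV`,
#' `RpAV`, `SwA_AV`, `SwV_AV`; unisensory trials after AV are `excluded`).
#'
#' @param n_trials trials per sequence.
#' @param params an `av_params` record.
#' @param seed experiment seed.
#' @param n_sequences independent sequences (state reset between them).
#' @param isi_low_ms,isi_high_ms ISI bounds, ms.
#' @return List of class `av_rt_task`: `records` (one row per trial:
#'   label, rt_ms, responded, anticipatory, perceived positions at stimulus
#'   offset, isi), and `summary` (mean RT, sd, n per label, valid responses
#'   only).
#' @export
run_rt_task <- function(n_trials = 120, params = av_params(), seed = 1L,
                        n_sequences = 1L, isi_low_ms = 1000,
                        isi_high_ms = 3000) {
  p <- params
  validate_av_params(p)
  kernels <- build_kernels(p)
  recs <- vector("list", n_sequences)
  for (sq in seq_len(n_sequences)) {
    sseed <- .rep_seed(seed, sq)
    sq_obj <- make_rt_sequence(n_trials, p, isi_low_ms, isi_high_ms,
                               seed = sseed)
    last <- max(sq_obj$events$onset_ms + sq_obj$events$duration_ms)
    sim <- simulate_network(sq_obj$events, p, kernels,
                            t_total_ms = last + p$response_window_ms,
                            record_stride_ms = p$dt_ms)
    tr <- sq_obj$trials
    out <- lapply(seq_len(nrow(tr)), function(i) {
      det <- detect_rt(sim, tr$onset_ms[i], threshold = p$rt_threshold,
                       window_ms = min(p$response_window_ms,
                                       if (i < nrow(tr)) tr$isi_ms[i + 1] else Inf),
                       anticipatory_cutoff_ms = p$anticipatory_cutoff_ms)
      off <- tr$onset_ms[i] + p$stim_duration_ms
      j <- which.min(abs(sim$trace$time_ms - off))
      data.frame(
        sequence = sq, trial = tr$trial[i], modality = tr$modality[i],
        label = tr$label[i], isi_ms = tr$isi_ms[i],
        rt_ms = det$rt_ms, responded = det$responded,
        anticipatory = det$anticipatory,
        perceived_a_deg = sim$trace$a_bary[j],
        perceived_v_deg = sim$trace$v_bary[j],
        true_pos_deg = tr$position_deg[i], seed = sseed
      )
    })
    recs[[sq]] <- do.call(rbind, out)
  }
  records <- do.call(rbind, recs)
  valid <- records[records$responded & !records$anticipatory &
                     !records$label %in% c("first", "excluded"), ]
  summary <- if (nrow(valid) > 0) {
    agg <- stats::aggregate(rt_ms ~ label, data = valid,
                            FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                                n = length(x)))
    data.frame(label = agg$label, mean_rt_ms = agg$rt_ms[, "mean"],
               sd_rt_ms = agg$rt_ms[, "sd"], n = agg$rt_ms[, "n"])
  } else {
    data.frame(label = character(0), mean_rt_ms = numeric(0),
               sd_rt_ms = numeric(0), n = numeric(0))
  }
  structure(list(records = records, summary = summary, seed = seed,
                 params = p), class = "av_rt_task")
}

#' Switch-trial reaction times over an ISI-by-disparity grid
#'
#' For each grid cell, sequential cross-modal pairs are presented: the
#' leading stimulus at central fixation and the trailing (other-modality)
#' stimulus displaced by the disparity, separated by the onset asynchrony.
#' The RT to the trailing stimulus is recorded; both switch directions
#' (A-then-V and V-then-A) are run and averaged.
#'
#' @param isis onset asynchronies, ms.
#' @param disparities disparities, degrees (unsigned; trailing stimulus is
#'   displaced to the right).
#' @param n_reps repetitions per cell (split over the two directions).
#' @param params an `av_params` record.
#' @param seed experiment seed.
#' @return List of class `av_sw_grid`: `trials` and `summary` (mean RT, SEM,
#'   n responded per cell).
#' @export
run_sw_grid <- function(isis = c(seq(0, 1000, by = 100),
                                 seq(1250, 3000, by = 250)),
                        disparities = seq(0, 20, by = 5), n_reps = 100,
                        params = av_params(), seed = 1L) {
  p <- params
  validate_av_params(p)
  kernels <- build_kernels(p)
  half <- max(1L, floor(n_reps / 2))
  grid <- expand.grid(isi_ms = isis, disparity_deg = disparities,
                      dir = c("SwA", "SwV"), rep = seq_len(half))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    m1 <- if (grid$dir[g] == "SwA") "V" else "A"
    m2 <- if (grid$dir[g] == "SwA") "A" else "V"
    det <- .pair_rt(m1, m2, 0, grid$disparity_deg[g], grid$isi_ms[g], p,
                    kernels, .rep_seed(seed, g))
    rows[[g]] <- data.frame(
      isi_ms = grid$isi_ms[g], disparity_deg = grid$disparity_deg[g],
      direction = as.character(grid$dir[g]), rep = grid$rep[g],
      rt_ms = det$rt_ms, responded = det$responded,
      anticipatory = det$anticipatory
    )
  }
  trials <- do.call(rbind, rows)
  ok <- trials[trials$responded, ]
  agg <- stats::aggregate(rt_ms ~ isi_ms + disparity_deg, data = ok,
                          FUN = function(x) c(mean = mean(x),
                                              sem = stats::sd(x) / sqrt(length(x)),
                                              n = length(x)))
  summary <- data.frame(agg[c("isi_ms", "disparity_deg")],
                        mean_rt_ms = agg$rt_ms[, "mean"],
                        sem_rt_ms = agg$rt_ms[, "sem"], n = agg$rt_ms[, "n"])
  summary <- summary[order(summary$isi_ms, summary$disparity_deg), ]
  rownames(summary) <- NULL
  structure(list(trials = trials, summary = summary, seed = seed,
                 params = p), class = "av_sw_grid")
}

# mean switch cost from two-stimulus pair trials: (Sw - Rp) per unisensory
# modality at random ISI in [isi_low, isi_high], averaged over A and V.
# Matched-pairs design: within a repetition the Sw and Rp trials share the
# same ISI and the same effectiveness draws, so the paired difference
# isolates the carried-over cross-sensory inhibition.
.switch_cost_pairs <- function(params, kernels, n_reps, seed,
                               isi_low_ms = 1000, isi_high_ms = 3000) {
  p <- params
  res <- list(RpA = numeric(n_reps), SwA = numeric(n_reps),
              RpV = numeric(n_reps), SwV = numeric(n_reps))
  for (i in seq_len(n_reps)) {
    rs <- .rep_seed(seed, i)
    isi <- withr_seed(rs + 1L, stats::runif(1, isi_low_ms, isi_high_ms))
    for (m in c("A", "V")) {
      other <- if (m == "A") "V" else "A"
      for (cond in c("Rp", "Sw")) {
        m1 <- if (cond == "Rp") m else other
        det <- .pair_rt(m1, m, 0, 0, isi, p, kernels, rs)
        res[[paste0(cond, m)]][i] <- det$rt_ms
      }
    }
  }
  cost_a <- mean(res$SwA - res$RpA, na.rm = TRUE)
  cost_v <- mean(res$SwV - res$RpV, na.rm = TRUE)
  list(cost_ms = mean(c(cost_a, cost_v)), cost_a_ms = cost_a,
       cost_v_ms = cost_v, rts = res)
}

# audiovisual switch cost from pair trials: RT to an AV stimulus preceded by
# a unisensory stimulus (Sw, averaged over A and V predecessors) minus RT to
# an AV stimulus preceded by an AV stimulus (Rp); matched pairs as above
.switch_cost_av_pairs <- function(params, kernels, n_reps, seed,
                                  isi_low_ms = 1000, isi_high_ms = 3000) {
  p <- params
  sw <- rp <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    rs <- .rep_seed(seed, 5000L + i)
    isi <- withr_seed(rs + 1L, stats::runif(1, isi_low_ms, isi_high_ms))
    sw[i] <- mean(c(.pair_rt("A", "AV", 0, 0, isi, p, kernels, rs)$rt_ms,
                    .pair_rt("V", "AV", 0, 0, isi, p, kernels, rs)$rt_ms))
    rp[i] <- .pair_rt("AV", "AV", 0, 0, isi, p, kernels, rs)$rt_ms
  }
  list(cost_ms = mean(sw - rp, na.rm = TRUE), sw_rt = sw, rp_rt = rp)
}

#' Sensitivity of the switch cost to connection strengths
#'
#' Sweeps the cross-modal effectiveness (`wva0`, with `wav0 = wva0/av_ratio`)
#' and the inhibitory strength of the unisensory lateral kernels (`la_in0` =
#' `lv_in0`, holding the excitation/inhibition ratio fixed), recomputing the
#' unisensory switch cost (sequential same/different-modality pairs at ISI
#' uniform in 1000-3000 ms, averaged over modalities) at every grid point.
#'
#' @param wva0_values cross-modal sweep values; `NULL` picks the default
#'   grid: `c(0.08, 0.12, 0.16)`, or `c(0.08, 0.012, 0.016)` when
#'   `literal_grid = TRUE` (the two variants of the published sweep).
#' @param lin0_values lateral-inhibition sweep values.
#' @param n_reps repetitions per condition per modality.
#' @param params baseline `av_params`.
#' @param seed experiment seed.
#' @param literal_grid use the literally printed cross-modal sweep values.
#' @return Data frame of class `av_sensitivity`: one row per
#'   (`wva0`, `la_in0`) pair with the mean switch cost and its per-modality
#'   components.
#' @export
run_sensitivity <- function(wva0_values = NULL, lin0_values = c(3, 4, 5),
                            n_reps = 100, params = av_params(), seed = 1L,
                            literal_grid = FALSE) {
  if (is.null(wva0_values)) {
    wva0_values <- if (literal_grid) c(0.08, 0.012, 0.016)
                   else c(0.08, 0.12, 0.16)
  }
  p0 <- params
  ratio_a <- p0$la_ex0 / p0$la_in0
  ratio_v <- p0$lv_ex0 / p0$lv_in0
  grid <- expand.grid(wva0 = wva0_values, la_in0 = lin0_values)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- av_params(
      wva0 = grid$wva0[g],
      la_in0 = grid$la_in0[g], la_ex0 = grid$la_in0[g] * ratio_a,
      lv_in0 = grid$la_in0[g], lv_ex0 = grid$la_in0[g] * ratio_v
    )
    keep <- setdiff(names(p0), c("wva0", "wav0", "la_in0", "la_ex0",
                                 "lv_in0", "lv_ex0"))
    for (k in keep) p[[k]] <- p0[[k]]
    p$wav0 <- p$wva0 / p$av_ratio
    validate_av_params(p)
    kernels <- build_kernels(p)
    sc <- .switch_cost_pairs(p, kernels, n_reps, .rep_seed(seed, g))
    rows[[g]] <- data.frame(
      wva0 = grid$wva0[g], la_in0 = grid$la_in0[g],
      la_ex0 = grid$la_in0[g] * ratio_a,
      switch_cost_ms = sc$cost_ms, cost_a_ms = sc$cost_a_ms,
      cost_v_ms = sc$cost_v_ms, n_reps = n_reps
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("av_sensitivity", class(out))
  out
}
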