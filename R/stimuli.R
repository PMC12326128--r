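#' Create a single stimulus event
#'
#' @param modality "A" or "V".
#' @param position_deg azimuth in degrees (within the represented space).
#' @param onset_ms onset time, ms (non-negative).
#' @param duration_ms duration, ms (positive).
#' @param effectiveness absolute input amplitude (after jitter).
#' @return One-row data frame.
#' @export
stimulus_event <- function(modality, position_deg, onset_ms, duration_ms,
                           effectiveness) {
  if (!modality %in% c("A", "V")) stop("modality must be 'A' or 'V'")
  if (duration_ms <= 0) stop("duration_ms must be positive")
  if (onset_ms < 0) stop("onset_ms must be non-negative")
  data.frame(modality = modality, position_deg = position_deg,
             onset_ms = onset_ms, duration_ms = duration_ms,
             effectiveness = effectiveness, stringsAsFactors = FALSE)
}

#' Spatial profile and temporal gate of an external stimulus
#'
#' The external drive a stimulus applies to its input area: a spatial
#' Gaussian of amplitude `effectiveness` and spread `sigma_r`, centred at the
#' application point, gated on during `[onset, onset + duration)` (the
#' temporal low-pass filtering with `tau_a`/`tau_v` happens inside the
#' dynamics).
#'
#' @param event one-row data frame as from [stimulus_event()].
#' @param sigma_r spatial spread of the receptive input, degrees.
#' @param positions unit azimuths.
#' @return List with `profile` (numeric vector over units), `onset_ms`,
#'   `offset_ms`.
#' @export
external_field <- function(event, sigma_r, positions) {
  if (sigma_r <= 0) stop("sigma_r must be strictly positive")
  d <- positions - event$position_deg
  list(
    profile = event$effectiveness * exp(-d^2 / (2 * sigma_r^2)),
    onset_ms = event$onset_ms,
    offset_ms = event$onset_ms + event$duration_ms
  )
}

# uniform effectiveness jitter around the nominal amplitude
.draw_effectiveness <- function(nominal, jitter_frac, n = 1L) {
  nominal * stats::runif(n, 1 - jitter_frac, 1 + jitter_frac)
}

#' Label trials as repeat / switch from the modality sequence
#'
#' Pure labelling rule: the first trial is `"first"`; a trial whose modality
#' equals the previous trial's is `RpA` / `RpV` / `RpAV`; a unisensory trial
#' after the other unisensory modality is `SwA` / `SwV`; an audiovisual trial
#' after a unisensory one is `SwA_AV` / `SwV_AV` (named by the preceding
#' modality); a unisensory trial following an audiovisual one is `"excluded"`
#' (it is neither a repeat nor a switch).
#'
#' @param modalities character vector in `c("A", "V", "AV")`.
#' @return Character vector of labels, same length.
#' @export
label_trials <- function(modalities) {
  stopifnot(all(modalities %in% c("A", "V", "AV")))
  n <- length(modalities)
  if (n == 0L) return(character(0))
  lab <- character(n)
  lab[1] <- "first"
  if (n == 1L) return(lab)
  for (i in 2:n) {
    prev <- modalities[i - 1]
    cur <- modalities[i]
    lab[i] <- if (prev == cur) {
      paste0("Rp", cur)
    } else if (cur == "AV") {
      paste0("Sw", prev, "_AV")
    } else if (prev == "AV") {
      "excluded"
    } else {
      paste0("Sw", cur)
    }
  }
  lab
}

#' Random trial sequence for the reaction-time task
#'
#' Trials of modality A, V or AV (equiprobable by default) at central
#' fixation, with onset-to-onset interstimulus intervals drawn uniformly from
#' `[isi_low_ms, isi_high_ms]`. Each stimulus component gets an independent
#' effectiveness jitter. Repeat/switch condition labels follow
#' [label_trials()].
#'
#' @param n_trials number of trials (>= 2).
#' @param params an `av_params` record (supplies nominal effectiveness,
#'   jitter, duration).
#' @param isi_low_ms,isi_high_ms ISI bounds, ms.
#' @param seed RNG seed for this sequence.
#' @param modal_probs probabilities of A, V, AV (recycled to sum 1).
#' @param position_deg common stimulus azimuth.
#' @param t_start_ms onset of the first trial.
#' @return An `av_sequence`: list with `trials` (trial, modality, onset_ms,
#'   isi_ms, label, position), `events` (one row per stimulus component,
#'   ready for [simulate_network()]), and `seed`.
#' @export
make_rt_sequence <- function(n_trials, params, isi_low_ms = 1000,
                             isi_high_ms = 3000, seed = 1L,
                             modal_probs = c(A = 1, V = 1, AV = 1) / 3,
                             position_deg = 0, t_start_ms = 200) {
  stopifnot(n_trials >= 2, isi_low_ms <= isi_high_ms, isi_low_ms >= 0)
  p <- params
  withr_seed(seed, {
    modality <- sample(c("A", "V", "AV"), n_trials, replace = TRUE,
                       prob = modal_probs / sum(modal_probs))
    isi <- c(0, stats::runif(n_trials - 1, isi_low_ms, isi_high_ms))
    onset <- t_start_ms + cumsum(isi)
    trials <- data.frame(
      trial = seq_len(n_trials), modality = modality, onset_ms = onset,
      isi_ms = isi, label = label_trials(modality),
      position_deg = position_deg, stringsAsFactors = FALSE
    )
    ev <- lapply(seq_len(n_trials), function(i) {
      comps <- if (modality[i] == "AV") c("A", "V") else modality[i]
      do.call(rbind, lapply(comps, function(m) {
        nom <- if (m == "A") p$i0_a else p$i0_v
        cbind(stimulus_event(m, position_deg, onset[i], p$stim_duration_ms,
                             .draw_effectiveness(nom, p$jitter_frac)),
              trial = i)
      }))
    })
    structure(list(trials = trials, events = do.call(rbind, ev), seed = seed),
              class = "av_sequence")
  })
}

#' Audiovisual stimulus pair with spatial disparity and onset asynchrony
#'
#' The visual stimulus sits at `v_position_deg` and the auditory one at
#' `v_position_deg + disparity_deg` (signed). `isi_ms` is the onset
#' asynchrony between the two components; 0 means synchronous. By default
#' the visual component leads; set `order = "a_leads"` for the reverse.
#'
#' @param disparity_deg signed auditory offset from the visual position.
#' @param isi_ms onset asynchrony, ms (>= 0).
#' @param params an `av_params` record.
#' @param v_position_deg visual azimuth.
#' @param order which modality leads for `isi_ms > 0`.
#' @param seed RNG seed (effectiveness jitter); `NULL` uses the current RNG
#'   state.
#' @param t_start_ms onset of the leading component.
#' @return An `av_sequence` with one AV trial (two events).
#' @export
make_av_pair <- function(disparity_deg, isi_ms, params, v_position_deg = 0,
                         order = c("v_leads", "a_leads"), seed = NULL,
                         t_start_ms = 200) {
  order <- match.arg(order)
  stopifnot(isi_ms >= 0)
  p <- params
  build <- function() {
    on_v <- if (order == "v_leads") t_start_ms else t_start_ms + isi_ms
    on_a <- if (order == "v_leads") t_start_ms + isi_ms else t_start_ms
    ev <- rbind(
      cbind(stimulus_event("V", v_position_deg, on_v, p$stim_duration_ms,
                           .draw_effectiveness(p$i0_v, p$jitter_frac)),
            trial = 1L),
      cbind(stimulus_event("A", v_position_deg + disparity_deg, on_a,
                           p$stim_duration_ms,
                           .draw_effectiveness(p$i0_a, p$jitter_frac)),
            trial = 1L)
    )
    trials <- data.frame(
      trial = 1L, modality = "AV", onset_ms = t_start_ms, isi_ms = isi_ms,
      label = "first", position_deg = v_position_deg,
      stringsAsFactors = FALSE
    )
    structure(list(trials = trials, events = ev,
                   seed = if (is.null(seed)) NA_integer_ else seed),
              class = "av_sequence")
  }
  if (is.null(seed)) build() else withr_seed(seed, build())
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Write / read a trial sequence as a flat table
#'
#' One stimulus component per row: `trial`, `modality`, `position_deg`,
#' `onset_ms`, `duration_ms`, `effectiveness`, `label`. Comma-separated,
#' UTF-8, header row, `.` decimal.
#'
#' @param seq_obj an `av_sequence`.
#' @param path output CSV path.
#' @return `path` invisibly (write); the events data frame (read).
#' @export
write_trial_sequence <- function(seq_obj, path) {
  ev <- merge(seq_obj$events,
              seq_obj$trials[, c("trial", "label")], by = "trial")
  ev <- ev[order(ev$onset_ms, ev$modality), ]
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_sequence
#' @export
read_trial_sequence <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
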