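#' Model parameters for the audiovisual network
#'
#' Builds the complete, validated parameter record of the four-layer
#' audiovisual network: unisensory auditory (A) and visual (V) input areas,
#' the competitive interneuron layer (Ia, Iv), the multisensory area (M) and
#' the premotor readout (PM). Each area holds `n_units` topographic units at
#' 1 degree spacing spanning azimuths -90..+89 degrees (0 degrees at unit 91).
#'
#' The three visual-pathway weights are derived from their auditory
#' counterparts through the audiovisual asymmetry divisor `av_ratio`
#' (`wmv0 = wma0/av_ratio`, `wav0 = wva0/av_ratio`, `wiv0 = wia0/av_ratio`);
#' passing any of the derived weights explicitly is only accepted when it
#' satisfies these relations exactly, otherwise validation fails (the record
#' is never silently corrected).
#'
#' @param ... named overrides of any default value (see
#'   [av_params_defaults()] for the full list).
#' @return A named list of class `av_params`, validated.
#' @examples
#' p <- av_params()
#' p$wav0 / p$wva0   # visual cross-modal pathway is stronger (1/av_ratio)
#' @export
av_params <- function(...) {
  over <- list(...)
  p <- av_params_defaults()
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0L) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  derived <- c("wmv0", "wav0", "wiv0")
  p[names(over)] <- over
  # recompute derived weights unless the caller pinned them explicitly
  for (d in setdiff(derived, names(over))) {
    p[[d]] <- switch(d,
      wmv0 = p$wma0 / p$av_ratio,
      wav0 = p$wva0 / p$av_ratio,
      wiv0 = p$wia0 / p$av_ratio
    )
  }
  class(p) <- "av_params"
  validate_av_params(p)
  p
}

#' Default parameter values
#'
#' The static architecture (unit sigmoid, time constants, delays, connection
#' effectiveness and spread) follows the published parameter tables of this
#' model family; input amplitudes, the audiovisual asymmetry divisor, the
#' per-component input gains and the two slow decay constants are calibration
#' values of this package (see the methods vignette for how each was fixed).
#'
#' @return Named list of all model parameters.
#' @export
av_params_defaults <- function() {
  list(
    # -- single neural unit -------------------------------------------------
    n_units   = 180L,  # topographic units per area, 1 degree spacing
    theta     = 25,    # sigmoid central abscissa
    slope     = 0.3,   # sigmoid slope
    tau_unit  = 3,     # membrane time constant, ms
    tau_pm    = 60,   # premotor integration time constant, ms
    # -- external inputs ----------------------------------------------------
    tau_a     = 15,    # auditory input filter, ms
    tau_v     = 25,    # visual input filter, ms
    sigma_a   = 30,    # spatial spread of auditory input, degrees
    sigma_v   = 4,     # spatial spread of visual input, degrees
    i0_a      = 60,    # nominal auditory input effectiveness
    i0_v      = 50,    # nominal visual input effectiveness
    jitter_frac = 0.1, # uniform effectiveness jitter half-width (fraction)
    stim_duration_ms = 60,
    # -- cross-modal pathway ------------------------------------------------
    tau_c        = 3,    # cross-modal rise time constant, ms
    tau_c_decay  = 100,  # cross-modal trace decay, ms (memory trace)
    delta_t_cross = 16,  # cross-modal synaptic delay, ms
    # -- interneuron (competitive) layer -------------------------------------
    tau_iex       = 15,   # interneuron excitatory drive rise, ms
    tau_iex_decay = 1900, # interneuron drive decay, ms (WTA latch)
    wta0          = 10,   # reciprocal interneuron inhibition, one-to-one
    # -- slow feedback inhibition --------------------------------------------
    tau_in = 180,  # feedback inhibition time constant, ms (both directions)
    # -- multisensory and premotor stages ------------------------------------
    tau_mff    = 15,  # feedforward synaptic filter into M, ms
    delta_t_m  = 50,  # transmission delay unisensory -> M, ms
    delta_t_pm = 50,  # transmission delay M -> premotor, ms
    wpmm0      = 1,   # M -> premotor one-to-one strength
    # -- connection effectiveness and spread ----------------------------------
    av_ratio = 0.4,    # visual/auditory pathway asymmetry divisor, in (0, 1]
    wma0 = 0.12, wmv0 = 0.12 / 0.4, wma_sd = 5, wmv_sd = 5,
    wva0 = 0.12, wav0 = 0.12 / 0.4, wva_sd = 5, wav_sd = 7,
    wia0 = 0.2,  wiv0 = 0.2 / 0.4,  wia_sd = 5, wiv_sd = 5,
    laiv0 = 0.0057, lvia0 = 0.016, laiv_sd = 15, lvia_sd = 15,
    la_ex0 = 5, la_ex_sd = 3, la_in0 = 4, la_in_sd = 120,
    lv_ex0 = 5, lv_ex_sd = 3, lv_in0 = 4, lv_in_sd = 120,
    lm_ex0 = 0.4, lm_ex_sd = 4, lm_in0 = 0.3, lm_in_sd = 8,
    # -- per-component input gains (G_i^r) ------------------------------------
    g_ext_a = 1, g_ext_v = 1,
    g_lat_a = 1, g_lat_v = 1, g_lat_m = 1,
    g_cross_a = 15, g_cross_v = 16,
    g_inh_a = 140, g_inh_v = 30,
    g_int_a = 54, g_int_v = 29,
    g_m_a = 52, g_m_v = 27.5,
    g_pm = 70,
    # -- readout and integration ----------------------------------------------
    rt_threshold = 0.30,       # premotor detection threshold (fraction of 1)
    anticipatory_cutoff_ms = 100,
    response_window_ms = 1000,
    dt_ms = 0.5,
    rng_seed = 1L
  )
}

#' Validate a parameter record
#'
#' Checks positivity of time constants, spreads and the integration step,
#' range constraints, the explicit-Euler stability guard
#' (`dt_ms <= tau_unit/3`) and the pathway-asymmetry relations. Any violation
#' is reported as an error naming the offending field.
#'
#' @param p an `av_params` record.
#' @return `p`, invisibly, if valid.
#' @export
validate_av_params <- function(p) {
  stopifnot(is.list(p))
  if (p$rt_threshold <= 0 || p$rt_threshold >= 1) {
    stop("parameter 'rt_threshold' must lie in (0, 1)")
  }
  if (p$av_ratio <= 0 || p$av_ratio > 1) {
    stop("parameter 'av_ratio' must lie in (0, 1]")
  }
  if (p$jitter_frac >= 1) {
    stop("parameter 'jitter_frac' must be < 1")
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  need_pos <- c(
    "theta", "slope", "tau_unit", "tau_pm", "tau_a", "tau_v", "sigma_a",
    "sigma_v", "i0_a", "i0_v", "stim_duration_ms", "tau_c", "tau_c_decay",
    "tau_iex", "tau_iex_decay", "tau_in", "tau_mff", "dt_ms",
    "wma_sd", "wmv_sd", "wva_sd", "wav_sd", "wia_sd", "wiv_sd",
    "laiv_sd", "lvia_sd", "la_ex_sd", "la_in_sd", "lv_ex_sd", "lv_in_sd",
    "lm_ex_sd", "lm_in_sd", "response_window_ms"
  )
  for (k in need_pos) {
    if (!num1(p[[k]]) || p[[k]] <= 0) {
      stop("parameter '", k, "' must be a single strictly positive number")
    }
  }
  need_nonneg <- c(
    "delta_t_cross", "delta_t_m", "delta_t_pm", "jitter_frac",
    "wma0", "wmv0", "wva0", "wav0", "wia0", "wiv0", "laiv0", "lvia0",
    "la_ex0", "la_in0", "lv_ex0", "lv_in0", "lm_ex0", "lm_in0",
    "wta0", "wpmm0", "anticipatory_cutoff_ms",
    "g_ext_a", "g_ext_v", "g_lat_a", "g_lat_v", "g_lat_m",
    "g_cross_a", "g_cross_v", "g_inh_a", "g_inh_v",
    "g_int_a", "g_int_v", "g_m_a", "g_m_v", "g_pm"
  )
  for (k in need_nonneg) {
    if (!num1(p[[k]]) || p[[k]] < 0) {
      stop("parameter '", k, "' must be a single non-negative number")
    }
  }
  if (!is.numeric(p$n_units) || length(p$n_units) != 1L ||
      p$n_units != round(p$n_units) || p$n_units < 3) {
    stop("parameter 'n_units' must be an integer >= 3")
  }
  if (p$dt_ms > p$tau_unit / 3) {
    stop("parameter 'dt_ms' too large for stability: require dt_ms <= tau_unit/3 = ",
         format(p$tau_unit / 3))
  }
  rel <- function(a, b, an, bn, div) {
    if (abs(a - b / div) > 1e-9 * max(1, abs(a))) {
      stop("pathway asymmetry violated: '", an, "' must equal ", bn,
           "/av_ratio (expected ", format(b / div), ", got ", format(a), ")")
    }
  }
  rel(p$wmv0, p$wma0, "wmv0", "wma0", p$av_ratio)
  rel(p$wav0, p$wva0, "wav0", "wva0", p$av_ratio)
  rel(p$wiv0, p$wia0, "wiv0", "wia0", p$av_ratio)
  invisible(p)
}

#' Unit azimuths of the topographic map
#'
#' @param n_units number of units per area.
#' @return Numeric vector of azimuths in degrees; for the default 180 units
#'   it is `-90:89`, with 0 degrees at index 91.
#' @export
unit_positions <- function(n_units = 180L) {
  seq_len(n_units) - (floor(n_units / 2) + 1)
}

#' Write a parameter record to a flat key=value config file
#'
#' One key per line, `key = value`, UTF-8. Round-trips exactly through
#' [read_av_config()].
#'
#' @param p an `av_params` record.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_av_config <- function(p, path) {
  validate_av_params(p)
  keys <- names(av_params_defaults())
  lines <- vapply(keys, function(k) {
    paste0(k, " = ", format(p[[k]], digits = 15, scientific = FALSE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a parameter record from a flat key=value config file
#'
#' Lines starting with `#` and blank lines are ignored. Unknown keys are an
#' error (named in the message). The resulting record is validated.
#'
#' @param path config file path.
#' @return An `av_params` record.
#' @export
read_av_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) == 0L]
  if (length(bad) > 0L) stop("malformed config line: ", bad[[1]])
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- as.numeric(vapply(kv, `[[`, character(1), 3L))
  if (anyNA(vals)) {
    stop("non-numeric value for key: ", keys[which(is.na(vals))[1]])
  }
  names(vals) <- keys
  args <- as.list(vals)
  if ("n_units" %in% names(args)) args$n_units <- as.integer(args$n_units)
  if ("rng_seed" %in% names(args)) args$rng_seed <- as.integer(args$rng_seed)
  do.call(av_params, args)
}
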