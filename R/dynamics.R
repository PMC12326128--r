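#' Construct an all-quiescent network state
#'
#' The state holds the activity vectors of the six populations (A, V, Ia, Iv,
#' M, PM), the filtered external inputs (`ea`, `ev`), the cross-modal traces
#' (`ca`, `cv`), the interneuron excitatory drives (`za`, `zv`), the slow
#' feedback-inhibition states (`ina`, `inv`), the feedforward drive to the
#' multisensory area (`mf`), and the delayed presynaptic outputs used by the
#' transport-delay pathways.
#'
#' @param n_units units per area.
#' @return A list of class `av_state` with all vectors zeroed and `t = 0`.
#' @export
av_state <- function(n_units = 180L) {
  z <- numeric(n_units)
  structure(list(
    ya = z, yv = z, yia = z, yiv = z, ym = z, ypm = z,
    ea = z, ev = z, ca = z, cv = z, za = z, zv = z,
    ina = z, inv = z, mf = z,
    ya_dc = z, yv_dc = z, ya_dm = z, yv_dm = z, ym_dpm = z,
    t = 0
  ), class = "av_state")
}

#' Per-unit net input of one population
#'
#' Reference implementation of the net-input rule used by the integrator:
#' \describe{
#'   \item{A}{`g_ext_a*ea + g_lat_a*(lat_a \%\*\% ya) + g_cross_a*ca - g_inh_a*ina`}
#'   \item{V}{analogous, with the V-side gains, kernels and states}
#'   \item{Ia}{`g_int_a*(za - wta0*yiv)` (one-to-one WTA from Iv)}
#'   \item{Iv}{`g_int_v*(zv - wta0*yia)`}
#'   \item{M}{`mf + g_lat_m*(lat_m \%\*\% ym)` (feedforward drive is filtered
#'     into `mf` upstream, gains `g_m_a`/`g_m_v` applied there)}
#'   \item{PM}{`g_pm * wpmm0 * ym_dpm` (delayed one-to-one drive from M)}
#' }
#' The cross-modal (`ca`, `cv`) and feedforward (`mf`) states are themselves
#' built from delayed presynaptic outputs held in the state.
#'
#' @param state an `av_state`.
#' @param kernels an `av_kernels` set.
#' @param params an `av_params` record.
#' @param area one of `"A"`, `"V"`, `"Ia"`, `"Iv"`, `"M"`, `"PM"`.
#' @return Numeric vector of net inputs, one per unit.
#' @export
net_input <- function(state, kernels, params, area) {
  p <- params
  k <- kernels
  s <- state
  switch(area,
    A = p$g_ext_a * s$ea + p$g_lat_a * drop(k$lat_a %*% s$ya) +
        p$g_cross_a * s$ca - p$g_inh_a * s$ina,
    V = p$g_ext_v * s$ev + p$g_lat_v * drop(k$lat_v %*% s$yv) +
        p$g_cross_v * s$cv - p$g_inh_v * s$inv,
    Ia = p$g_int_a * (s$za - p$wta0 * s$yiv),
    Iv = p$g_int_v * (s$zv - p$wta0 * s$yia),
    M = s$mf + p$g_lat_m * drop(k$lat_m %*% s$ym),
    PM = p$g_pm * p$wpmm0 * s$ym_dpm,
    stop("net_input: unknown area '", area, "'")
  )
}

#' Single explicit-Euler step of the network update
#'
#' Reference (R-level) implementation of the update rule integrated by
#' [simulate_network()]: every synaptic filter relaxes toward its drive with
#' its own time constant (asymmetric rise/decay for the cross-modal trace and
#' the interneuron latch), and every population activity obeys
#' `tau * dy/dt = -y + F(net input)`. Delayed presynaptic outputs are taken
#' from the `*_dc`, `*_dm`, `*_dpm` fields of the state, which the caller is
#' responsible for supplying (the compiled integrator maintains them in ring
#' buffers). Used for unit-level oracle checks; experiments go through
#' [simulate_network()].
#'
#' @param state an `av_state`.
#' @param params an `av_params` record.
#' @param kernels an `av_kernels` set.
#' @param ext_a,ext_v external drive vectors at the current time.
#' @return The updated `av_state` (time advanced by `dt_ms`).
#' @export
step_state <- function(state, params, kernels, ext_a = NULL, ext_v = NULL) {
  p <- params
  k <- kernels
  s <- state
  n <- p$n_units
  if (is.null(ext_a)) ext_a <- numeric(n)
  if (is.null(ext_v)) ext_v <- numeric(n)
  dt <- p$dt_ms
  relax <- function(x, target, tau_rise, tau_decay = tau_rise) {
    tau <- ifelse(target >= x, tau_rise, tau_decay)
    x + dt / tau * (target - x)
  }
  s$ea <- relax(s$ea, ext_a, p$tau_a)
  s$ev <- relax(s$ev, ext_v, p$tau_v)
  s$ca <- relax(s$ca, drop(k$cross_av %*% s$yv_dc), p$tau_c, p$tau_c_decay)
  s$cv <- relax(s$cv, drop(k$cross_va %*% s$ya_dc), p$tau_c, p$tau_c_decay)
  s$za <- relax(s$za, drop(k$ff_ia %*% s$ya), p$tau_iex, p$tau_iex_decay)
  s$zv <- relax(s$zv, drop(k$ff_iv %*% s$yv), p$tau_iex, p$tau_iex_decay)
  s$ina <- relax(s$ina, drop(k$fb_laiv %*% s$yiv), p$tau_in)
  s$inv <- relax(s$inv, drop(k$fb_lvia %*% s$yia), p$tau_in)
  s$mf <- relax(s$mf, p$g_m_a * drop(k$ff_ma %*% s$ya_dm) +
                  p$g_m_v * drop(k$ff_mv %*% s$yv_dm), p$tau_mff)
  F <- function(u) sigmoid(u, p$theta, p$slope)
  upd <- function(y, u, tau) y + dt / tau * (-y + F(u))
  s$ya <- upd(s$ya, net_input(s, k, p, "A"), p$tau_unit)
  s$yv <- upd(s$yv, net_input(s, k, p, "V"), p$tau_unit)
  s$yia <- upd(s$yia, net_input(s, k, p, "Ia"), p$tau_unit)
  s$yiv <- upd(s$yiv, net_input(s, k, p, "Iv"), p$tau_unit)
  s$ym <- upd(s$ym, net_input(s, k, p, "M"), p$tau_unit)
  s$ypm <- upd(s$ypm, net_input(s, k, p, "PM"), p$tau_pm)
  s$t <- s$t + dt
  s
}

#' Simulate the network response to a list of stimulus events
#'
#' Integrates the full six-population network with explicit Euler at step
#' `dt_ms`, driving it with the given stimulus events. The state is never
#' reset during the simulation, so carried-over slow states (feedback
#' inhibition, WTA latch, cross-modal trace) shape responses to later events
#' — this is what produces modality-switch costs.
#'
#' @param events data frame with columns `modality` ("A" or "V"),
#'   `position_deg`, `onset_ms`, `duration_ms`, `effectiveness` (absolute
#'   input amplitude). An audiovisual stimulus is two rows with equal onset.
#' @param params an `av_params` record.
#' @param kernels optional prebuilt `av_kernels` (rebuilt from `params` when
#'   `NULL`); pass them in when simulating many trials.
#' @param t_total_ms total simulated time; defaults to the last stimulus
#'   offset plus `response_window_ms`.
#' @param record_stride_ms sampling interval of the summary trace.
#' @param record_full also record full activity snapshots of A, V, M, PM
#'   every `full_stride_ms` (memory-hungry; for inspection and tests).
#' @param full_stride_ms snapshot interval when `record_full = TRUE`.
#' @return An `av_sim` object: list with `trace` (data frame: `time_ms`,
#'   per-area peak activity, per-area barycentre, `pm_max`), optional `full`
#'   snapshot matrices, the `events`, `params`, and `t_total_ms`.
#' @export
simulate_network <- function(events, params, kernels = NULL,
                             t_total_ms = NULL, record_stride_ms = NULL,
                             record_full = FALSE, full_stride_ms = 5) {
  p <- params
  validate_av_params(p)
  if (is.null(kernels)) kernels <- build_kernels(p)
  events <- validate_events(events, p)
  if (is.null(t_total_ms)) {
    last_off <- if (nrow(events) > 0) {
      max(events$onset_ms + events$duration_ms)
    } else 0
    t_total_ms <- last_off + p$response_window_ms
  }
  if (is.null(record_stride_ms)) record_stride_ms <- p$dt_ms
  stride <- max(1L, as.integer(round(record_stride_ms / p$dt_ms)))
  fstride <- max(1L, as.integer(round(full_stride_ms / p$dt_ms)))
  stim <- cbind(
    ifelse(events$modality == "A", 0, 1),
    events$position_deg, events$onset_ms, events$duration_ms,
    events$effectiveness
  )
  if (nrow(events) == 0L) stim <- matrix(numeric(0), ncol = 5)
  res <- .simulate_cpp(unclass(kernels), p, stim, t_total_ms,
                       stride, record_full, fstride)
  trace <- data.frame(
    time_ms = res$time_ms, pm_max = res$pm_max,
    a_peak = res$a_peak, v_peak = res$v_peak, m_peak = res$m_peak,
    ia_peak = res$ia_peak, iv_peak = res$iv_peak,
    a_bary = res$a_bary, v_bary = res$v_bary, m_bary = res$m_bary
  )
  out <- list(trace = trace, events = events, params = p,
              t_total_ms = t_total_ms)
  if (record_full) {
    out$full <- list(time_ms = res$full_time_ms, a = res$full_a,
                     v = res$full_v, m = res$full_m, pm = res$full_pm)
  }
  class(out) <- "av_sim"
  out
}

validate_events <- function(events, params) {
  req <- c("modality", "position_deg", "onset_ms", "duration_ms",
           "effectiveness")
  if (!is.data.frame(events)) stop("events must be a data frame")
  miss <- setdiff(req, names(events))
  if (length(miss) > 0) stop("events missing column(s): ",
                             paste(miss, collapse = ", "))
  if (nrow(events) == 0L) return(events)
  if (!all(events$modality %in% c("A", "V"))) {
    stop("event modality must be 'A' or 'V'")
  }
  if (any(events$onset_ms < 0)) stop("negative stimulus onsets are not allowed")
  if (any(events$duration_ms <= 0)) stop("stimulus durations must be positive")
  pos <- unit_positions(params$n_units)
  if (any(events$position_deg < min(pos) | events$position_deg > max(pos))) {
    stop("stimulus position outside the represented space [",
         min(pos), ", ", max(pos), "] degrees")
  }
  events[order(events$onset_ms), , drop = FALSE]
}

#' Long-format trajectory table from a full-recording simulation
#'
#' @param sim an `av_sim` produced with `record_full = TRUE`.
#' @param areas subset of `c("A", "V", "M", "PM")`.
#' @return Data frame with columns `time_ms`, `area`, `unit_index`,
#'   `azimuth_deg`, `activity`, suitable for CSV export.
#' @export
trajectory_table <- function(sim, areas = c("A", "V", "M", "PM")) {
  if (is.null(sim$full)) stop("simulation was run without record_full = TRUE")
  pos <- unit_positions(sim$params$n_units)
  key <- c(A = "a", V = "v", M = "m", PM = "pm")
  do.call(rbind, lapply(areas, function(ar) {
    m <- sim$full[[key[[ar]]]]
    data.frame(
      time_ms = rep(sim$full$time_ms, each = nrow(m)),
      area = ar,
      unit_index = rep(seq_len(nrow(m)), times = ncol(m)),
      azimuth_deg = rep(pos, times = ncol(m)),
      activity = as.vector(m)
    )
  }))
}
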