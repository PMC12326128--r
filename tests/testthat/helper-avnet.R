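# shared helpers for the avnet test suite

# single stimulus event row
ev1 <- function(modality, position_deg, onset_ms, duration_ms, effectiveness) {
  data.frame(modality = modality, position_deg = position_deg,
             onset_ms = onset_ms, duration_ms = duration_ms,
             effectiveness = effectiveness, stringsAsFactors = FALSE)
}

# default parameters with optional overrides (kernels cached per test file)
tpar <- function(...) av_params(...)

# a single nominal-effectiveness stimulus at azimuth 0
nominal_stim <- function(p, modality = "A", onset_ms = 200,
                         position_deg = 0) {
  ev1(modality, position_deg, onset_ms, p$stim_duration_ms,
      if (modality == "A") p$i0_a else p$i0_v)
}

# RT of a two-stimulus sequence (modality m1 then m2), nominal effectiveness
pair_rt <- function(p, k, m1, m2, isi_ms, pos1 = 0, pos2 = 0,
                    f1 = 1, f2 = 1) {
  mk <- function(m, pos, onset, f) {
    comps <- if (m == "AV") c("A", "V") else m
    do.call(rbind, lapply(comps, function(cm) {
      nom <- if (cm == "A") p$i0_a else p$i0_v
      ev1(cm, pos, onset, p$stim_duration_ms, nom * f)
    }))
  }
  ev <- rbind(mk(m1, pos1, 200, f1), mk(m2, pos2, 200 + isi_ms, f2))
  sim <- simulate_network(ev, p, k, t_total_ms = 200 + isi_ms + 900)
  detect_rt(sim, 200 + isi_ms, threshold = p$rt_threshold,
            anticipatory_cutoff_ms = p$anticipatory_cutoff_ms)$rt_ms
}
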