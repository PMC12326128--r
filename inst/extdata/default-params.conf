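n_units = 180
theta = 25
slope = 0.3
tau_unit = 3
tau_pm = 60
tau_a = 15
tau_v = 25
sigma_a = 30
sigma_v = 4
i0_a = 60
i0_v = 50
jitter_frac = 0.1
stim_duration_ms = 60
tau_c = 3
tau_c_decay = 100
delta_t_cross = 16
tau_iex = 15
tau_iex_decay = 1900
wta0 = 10
tau_in = 180
tau_mff = 15
delta_t_m = 50
delta_t_pm = 50
wpmm0 = 1
av_ratio = 0.4
wma0 = 0.12
wmv0 = 0.3
wma_sd = 5
wmv_sd = 5
wva0 = 0.12
wav0 = 0.3
wva_sd = 5
wav_sd = 7
wia0 = 0.2
wiv0 = 0.5
wia_sd = 5
wiv_sd = 5
laiv0 = 0.0057
lvia0 = 0.016
laiv_sd = 15
lvia_sd = 15
la_ex0 = 5
la_ex_sd = 3
la_in0 = 4
la_in_sd = 120
lv_ex0 = 5
lv_ex_sd = 3
lv_in0 = 4
lv_in_sd = 120
lm_ex0 = 0.4
lm_ex_sd = 4
lm_in0 = 0.3
lm_in_sd = 8
g_ext_a = 1
g_ext_v = 1
g_lat_a = 1
g_lat_v = 1
g_lat_m = 1
g_cross_a = 15
g_cross_v = 16
g_inh_a = 140
g_inh_v = 30
g_int_a = 54
g_int_v = 29
g_m_a = 52
g_m_v = 27.5
g_pm = 70
rt_threshold = 0.3
anticipatory_cutoff_ms = 100
response_window_ms = 1000
dt_ms = 0.5
rng_seed = 1
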