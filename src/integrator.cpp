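// Explicit-Euler integrator for the four-layer audiovisual network.
// Six populations (A, V, Ia, Iv, M, PM) of n topographic units each, with
// first-order membrane dynamics tau*dy/dt = -y + F(u), first-order synaptic
// filters on the external, cross-modal, interneuron and feedforward drives,
// and pure transport delays (ring buffers) on the cross-modal (A<->V),
// multisensory (A/V -> M) and premotor (M -> PM) pathways.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec sig(const arma::vec& u, double theta, double slope) {
  return 1.0 / (1.0 + arma::exp(-slope * (u - theta)));
}

// asymmetric first-order update: rise constant when drive exceeds state,
// decay constant otherwise (used for the WTA latch and cross-modal trace)
static inline void relax(arma::vec& x, const arma::vec& target,
                         double dt, double tau_rise, double tau_decay) {
  const arma::uword n = x.n_elem;
  for (arma::uword j = 0; j < n; ++j) {
    const double tau = (target[j] >= x[j]) ? tau_rise : tau_decay;
    x[j] += dt / tau * (target[j] - x[j]);
  }
}

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(List kernels, List par, NumericMatrix stim,
                  double t_total, int record_stride,
                  bool record_full, int full_stride) {
  const arma::mat Kav = as<arma::mat>(kernels["cross_av"]);
  const arma::mat Kva = as<arma::mat>(kernels["cross_va"]);
  const arma::mat Kma = as<arma::mat>(kernels["ff_ma"]);
  const arma::mat Kmv = as<arma::mat>(kernels["ff_mv"]);
  const arma::mat Kia = as<arma::mat>(kernels["ff_ia"]);
  const arma::mat Kiv = as<arma::mat>(kernels["ff_iv"]);
  const arma::mat Klaiv = as<arma::mat>(kernels["fb_laiv"]);
  const arma::mat Klvia = as<arma::mat>(kernels["fb_lvia"]);
  const arma::mat Kla = as<arma::mat>(kernels["lat_a"]);
  const arma::mat Klv = as<arma::mat>(kernels["lat_v"]);
  const arma::mat Klm = as<arma::mat>(kernels["lat_m"]);
  const arma::vec pos = as<arma::vec>(kernels["positions"]);

  const int n = pos.n_elem;
  const double dt = as<double>(par["dt_ms"]);
  const double theta = as<double>(par["theta"]);
  const double slope = as<double>(par["slope"]);
  const double tau_unit = as<double>(par["tau_unit"]);
  const double tau_pm = as<double>(par["tau_pm"]);
  const double tau_a = as<double>(par["tau_a"]);
  const double tau_v = as<double>(par["tau_v"]);
  const double tau_c = as<double>(par["tau_c"]);
  const double tau_c_decay = as<double>(par["tau_c_decay"]);
  const double tau_iex = as<double>(par["tau_iex"]);
  const double tau_iex_decay = as<double>(par["tau_iex_decay"]);
  const double tau_in = as<double>(par["tau_in"]);
  const double tau_mff = as<double>(par["tau_mff"]);
  const double sigma_a = as<double>(par["sigma_a"]);
  const double sigma_v = as<double>(par["sigma_v"]);
  const double wta0 = as<double>(par["wta0"]);
  const double wpmm0 = as<double>(par["wpmm0"]);
  const double g_ext_a = as<double>(par["g_ext_a"]);
  const double g_ext_v = as<double>(par["g_ext_v"]);
  const double g_lat_a = as<double>(par["g_lat_a"]);
  const double g_lat_v = as<double>(par["g_lat_v"]);
  const double g_lat_m = as<double>(par["g_lat_m"]);
  const double g_cross_a = as<double>(par["g_cross_a"]);
  const double g_cross_v = as<double>(par["g_cross_v"]);
  const double g_inh_a = as<double>(par["g_inh_a"]);
  const double g_inh_v = as<double>(par["g_inh_v"]);
  const double g_int_a = as<double>(par["g_int_a"]);
  const double g_int_v = as<double>(par["g_int_v"]);
  const double g_m_a = as<double>(par["g_m_a"]);
  const double g_m_v = as<double>(par["g_m_v"]);
  const double g_pm = as<double>(par["g_pm"]);

  const int n_steps = (int) std::ceil(t_total / dt);
  const int d_cross = (int) std::lround(as<double>(par["delta_t_cross"]) / dt);
  const int d_m = (int) std::lround(as<double>(par["delta_t_m"]) / dt);
  const int d_pm = (int) std::lround(as<double>(par["delta_t_pm"]) / dt);
  const int depth_av = std::max(std::max(d_cross, d_m), 1);
  const int depth_m = std::max(d_pm, 1);

  // stimulus table: columns modality(0=A,1=V), position, onset, duration, amp
  const int n_stim = stim.nrow();
  std::vector<arma::vec> profiles(n_stim);
  for (int s = 0; s < n_stim; ++s) {
    const double sd = (stim(s, 0) < 0.5) ? sigma_a : sigma_v;
    arma::vec prof(n);
    for (int j = 0; j < n; ++j) {
      const double d = pos[j] - stim(s, 1);
      prof[j] = stim(s, 4) * std::exp(-d * d / (2.0 * sd * sd));
    }
    profiles[s] = prof;
  }

  // state
  arma::vec ya(n, arma::fill::zeros), yv(n, arma::fill::zeros),
      yia(n, arma::fill::zeros), yiv(n, arma::fill::zeros),
      ym(n, arma::fill::zeros), ypm(n, arma::fill::zeros),
      ea(n, arma::fill::zeros), ev(n, arma::fill::zeros),
      ca(n, arma::fill::zeros), cv(n, arma::fill::zeros),
      za(n, arma::fill::zeros), zv(n, arma::fill::zeros),
      ina(n, arma::fill::zeros), inv_(n, arma::fill::zeros),
      mf(n, arma::fill::zeros);
  arma::mat buf_a(n, depth_av, arma::fill::zeros),
      buf_v(n, depth_av, arma::fill::zeros),
      buf_m(n, depth_m, arma::fill::zeros);

  const int n_rec = n_steps / record_stride + 1;
  arma::vec rt_time(n_rec, arma::fill::zeros);
  arma::vec r_pm(n_rec), r_apk(n_rec), r_vpk(n_rec), r_mpk(n_rec),
      r_iapk(n_rec), r_ivpk(n_rec), r_ab(n_rec), r_vb(n_rec), r_mb(n_rec);
  int n_full = record_full ? (n_steps / full_stride + 1) : 0;
  arma::mat f_a, f_v, f_m, f_pm;
  if (record_full) {
    f_a.zeros(n, n_full); f_v.zeros(n, n_full);
    f_m.zeros(n, n_full); f_pm.zeros(n, n_full);
  }
  arma::vec f_time(std::max(n_full, 1), arma::fill::zeros);

  auto bary = [&](const arma::vec& y) -> double {
    const double s = arma::accu(y);
    if (s < 1e-12) return NA_REAL;
    return arma::dot(pos, y) / s;
  };

  int i_rec = 0, i_full = 0;
  arma::vec ext_a(n), ext_v(n), tmp(n);
  for (int step = 0; step <= n_steps; ++step) {
    const double t = step * dt;

    // record current state
    if (step % record_stride == 0 && i_rec < n_rec) {
      rt_time[i_rec] = t;
      r_pm[i_rec] = ypm.max();
      r_apk[i_rec] = ya.max();  r_vpk[i_rec] = yv.max();
      r_mpk[i_rec] = ym.max();
      r_iapk[i_rec] = yia.max(); r_ivpk[i_rec] = yiv.max();
      r_ab[i_rec] = bary(ya); r_vb[i_rec] = bary(yv); r_mb[i_rec] = bary(ym);
      ++i_rec;
    }
    if (record_full && step % full_stride == 0 && i_full < n_full) {
      f_time[i_full] = t;
      f_a.col(i_full) = ya; f_v.col(i_full) = yv;
      f_m.col(i_full) = ym; f_pm.col(i_full) = ypm;
      ++i_full;
    }
    if (step == n_steps) break;

    // delayed presynaptic outputs (y at t - delay; buffers hold the past)
    const int slot = step % depth_av;
    const int slot_m = step % depth_m;
    // value stored d steps ago (d = 0 means no transport delay)
    auto past = [&](const arma::mat& b, const arma::vec& cur, int d,
                    int dep) -> arma::vec {
      if (d <= 0) return cur;
      if (step < d) return arma::vec(n, arma::fill::zeros);
      return b.col(((step - d) % dep));
    };
    arma::vec ya_dc = past(buf_a, ya, d_cross, depth_av);
    arma::vec yv_dc = past(buf_v, yv, d_cross, depth_av);
    arma::vec ya_dm = past(buf_a, ya, d_m, depth_av);
    arma::vec yv_dm = past(buf_v, yv, d_m, depth_av);
    arma::vec ym_dpm = past(buf_m, ym, d_pm, depth_m);
    // store current outputs for future delayed reads
    buf_a.col(slot) = ya; buf_v.col(slot) = yv; buf_m.col(slot) = ym;

    // external drive at time t
    ext_a.zeros(); ext_v.zeros();
    for (int s = 0; s < n_stim; ++s) {
      if (t >= stim(s, 2) && t < stim(s, 2) + stim(s, 3)) {
        if (stim(s, 0) < 0.5) ext_a += profiles[s]; else ext_v += profiles[s];
      }
    }

    // synaptic filters
    ea += dt / tau_a * (ext_a - ea);
    ev += dt / tau_v * (ext_v - ev);
    tmp = Kav * yv_dc; relax(ca, tmp, dt, tau_c, tau_c_decay);
    tmp = Kva * ya_dc; relax(cv, tmp, dt, tau_c, tau_c_decay);
    tmp = Kia * ya;    relax(za, tmp, dt, tau_iex, tau_iex_decay);
    tmp = Kiv * yv;    relax(zv, tmp, dt, tau_iex, tau_iex_decay);
    ina  += dt / tau_in * (Klaiv * yiv - ina);
    inv_ += dt / tau_in * (Klvia * yia - inv_);
    mf += dt / tau_mff * (g_m_a * (Kma * ya_dm) + g_m_v * (Kmv * yv_dm) - mf);

    // net inputs
    arma::vec ua = g_ext_a * ea + g_lat_a * (Kla * ya) + g_cross_a * ca
                   - g_inh_a * ina;
    arma::vec uv = g_ext_v * ev + g_lat_v * (Klv * yv) + g_cross_v * cv
                   - g_inh_v * inv_;
    arma::vec uia = g_int_a * (za - wta0 * yiv);
    arma::vec uiv = g_int_v * (zv - wta0 * yia);
    arma::vec um = mf + g_lat_m * (Klm * ym);
    arma::vec upm = g_pm * (wpmm0 * ym_dpm);

    // membrane dynamics
    ya += dt / tau_unit * (-ya + sig(ua, theta, slope));
    yv += dt / tau_unit * (-yv + sig(uv, theta, slope));
    yia += dt / tau_unit * (-yia + sig(uia, theta, slope));
    yiv += dt / tau_unit * (-yiv + sig(uiv, theta, slope));
    ym += dt / tau_unit * (-ym + sig(um, theta, slope));
    ypm += dt / tau_pm * (-ypm + sig(upm, theta, slope));
  }

  List out = List::create(
    _["time_ms"] = rt_time.head(i_rec),
    _["pm_max"] = r_pm.head(i_rec),
    _["a_peak"] = r_apk.head(i_rec), _["v_peak"] = r_vpk.head(i_rec),
    _["m_peak"] = r_mpk.head(i_rec),
    _["ia_peak"] = r_iapk.head(i_rec), _["iv_peak"] = r_ivpk.head(i_rec),
    _["a_bary"] = r_ab.head(i_rec), _["v_bary"] = r_vb.head(i_rec),
    _["m_bary"] = r_mb.head(i_rec));
  if (record_full) {
    out["full_time_ms"] = f_time.head(i_full);
    out["full_a"] = f_a.cols(0, i_full - 1);
    out["full_v"] = f_v.cols(0, i_full - 1);
    out["full_m"] = f_m.cols(0, i_full - 1);
    out["full_pm"] = f_pm.cols(0, i_full - 1);
  }
  return out;
}
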