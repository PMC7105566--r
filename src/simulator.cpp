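#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closed-loop Euler-Maruyama integration of the stochastic Wilson-Cowan
// model (or its linearisation about a fixed point) with online
// zero-crossing phase tracking and phase-locked burst stimulation.
//
// The tracker assigns phase 0 at upward crossings of E minus its running
// mean (window `mean_window` seconds), advances the phase linearly at
// 2*pi / previous_period, and is undefined until two crossings have been
// observed.  Stimulation is suppressed while the tracker is undefined.

namespace {

inline double wc_sigmoid(double x, double beta) {
  return 1.0 / (1.0 + std::exp(-beta * (x - 1.0)));
}

struct Tracker {
  double mean_window;   // s, running-mean window for the crossing reference
  double refractory;    // s, minimum spacing between accepted crossings
  double dt;
  std::vector<double> buf;  // circular buffer of E over the mean window
  int bufn, bufpos, buffill;
  double bufsum;
  double prev_y;
  double last_cross, prev_period;
  int n_cross;
  std::vector<double> cross_times;

  Tracker(double mean_window_, double refractory_, double dt_)
      : mean_window(mean_window_), refractory(refractory_), dt(dt_) {
    bufn = std::max(1, (int)std::lround(mean_window / dt));
    buf.assign(bufn, 0.0);
    bufpos = 0; buffill = 0; bufsum = 0.0;
    prev_y = 0.0; last_cross = -1.0; prev_period = -1.0; n_cross = 0;
  }

  bool defined() const { return n_cross >= 2; }

  double phase(double t) const {
    // grows past 2*pi if the current period outlasts the previous one
    return 2.0 * M_PI * (t - last_cross) / prev_period;
  }

  // feed one sample; returns true on an accepted upward crossing
  bool update(double E, double t) {
    double mean = (buffill > 0) ? bufsum / buffill : E;
    double y = E - mean;
    bool crossed = false;
    // only trust crossings once the mean window has filled; debounce by
    // an absolute refractory before the period is known, then by a
    // fraction of the previous period (rejects stimulation-artifact
    // crossings early in the cycle)
    double min_gap = refractory;
    if (prev_period > 0.0 && 0.6 * prev_period > min_gap) {
      min_gap = 0.6 * prev_period;
    }
    if (buffill >= bufn && prev_y < 0.0 && y >= 0.0) {
      if (last_cross < 0.0 || t - last_cross >= min_gap) {
        if (last_cross >= 0.0) prev_period = t - last_cross;
        last_cross = t;
        ++n_cross;
        cross_times.push_back(t);
        crossed = true;
      }
    }
    prev_y = y;
    // push sample into the running-mean buffer
    if (buffill < bufn) {
      buf[bufpos] = E; bufsum += E; ++buffill;
    } else {
      bufsum += E - buf[bufpos];
      buf[bufpos] = E;
    }
    bufpos = (bufpos + 1) % bufn;
    return crossed;
  }
};

struct Pulse { double t; int block; int burst; };

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(int model,            // 0 = Wilson-Cowan, 1 = linearised
                  NumericVector wc,     // wEE wEI wIE thE thI beta tau
                  NumericMatrix J, NumericVector fixed_point,
                  double zeta, double delta_amp, double stim_delay,
                  double dt, double duration,
                  NumericVector block_start, NumericVector block_end,
                  NumericVector block_phase,
                  int pulses_per_burst, double pulse_rate,
                  NumericVector ext_pulses,   // open-loop pulse times
                  NumericVector init,
                  double mean_window, double refractory,
                  int record_every) {
  const int n_steps = (int)std::lround(duration / dt);
  const int n_blocks = block_start.size();
  const double sqdt = std::sqrt(dt);

  double E = init[0], I = init[1];
  double wEE = 0, wEI = 0, wIE = 0, thE = 0, thI = 0, beta = 0, tau = 1;
  if (model == 0) {
    wEE = wc[0]; wEI = wc[1]; wIE = wc[2];
    thE = wc[3]; thI = wc[4]; beta = wc[5]; tau = wc[6];
  }
  const double j11 = J(0, 0), j12 = J(0, 1), j21 = J(1, 0), j22 = J(1, 1);
  const double fpE = fixed_point[0], fpI = fixed_point[1];

  Tracker trk(mean_window, refractory, dt);

  // recorded (thinned) trajectory
  const int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_E(n_rec), rec_I(n_rec), rec_phase(n_rec);
  int n_recorded = 0;

  std::vector<Pulse> pending;     // FIFO of scheduled pulses
  size_t pend_head = 0;
  std::vector<double> pulse_t; std::vector<int> pulse_block, pulse_burst;
  std::vector<double> burst_t; std::vector<int> burst_block, burst_np;

  int cb = 0;                 // current block pointer
  bool fired = false;         // burst already fired in current tracked period
  int ep = 0;                 // external pulse pointer
  bool failed = false; double fail_t = NA_REAL;

  RNGScope scope;

  for (int i = 0; i < n_steps; ++i) {
    const double t = i * dt;

    if (i % record_every == 0 && n_recorded < n_rec) {
      rec_t[n_recorded] = t; rec_E[n_recorded] = E; rec_I[n_recorded] = I;
      rec_phase[n_recorded] = trk.defined() ? trk.phase(t) : NA_REAL;
      ++n_recorded;
    }

    if (trk.update(E, t)) fired = false;  // new period begins at each crossing

    while (cb < n_blocks && t >= block_end[cb]) ++cb;
    const bool in_block = cb < n_blocks && t >= block_start[cb];

    if (in_block && trk.defined() && !fired &&
        trk.phase(t) >= block_phase[cb]) {
      fired = true;
      int np = 0;
      const int bid = (int)burst_t.size();
      for (int k = 0; k < pulses_per_burst; ++k) {
        const double tp = t + stim_delay + k / pulse_rate;
        if (tp <= block_end[cb]) {   // truncate bursts at the block end
          // keep the queue time-ordered: with long delays a new burst can
          // be scheduled before an earlier burst's pulses have fired
          Pulse pu{tp, cb, bid};
          size_t pos = pending.size();
          while (pos > pend_head && pending[pos - 1].t > tp) --pos;
          pending.insert(pending.begin() + pos, pu);
          ++np;
        }
      }
      burst_t.push_back(t); burst_block.push_back(cb); burst_np.push_back(np);
    }

    // stimulation enters the Euler update at the pulse's time step
    double stim = 0.0;
    while (pend_head < pending.size() && pending[pend_head].t < t + dt) {
      stim += delta_amp;
      pulse_t.push_back(pending[pend_head].t);
      pulse_block.push_back(pending[pend_head].block);
      pulse_burst.push_back(pending[pend_head].burst);
      ++pend_head;
    }
    while (ep < ext_pulses.size() && ext_pulses[ep] < t + dt) {
      stim += delta_amp;
      pulse_t.push_back(ext_pulses[ep]); pulse_block.push_back(-1);
      pulse_burst.push_back(-1);
      ++ep;
    }

    double f1, f2;
    if (model == 0) {
      f1 = (-E + wc_sigmoid(thE + wEE * E - wIE * I, beta)) / tau;
      f2 = (-I + wc_sigmoid(thI + wEI * E, beta)) / tau;
    } else {
      const double x1 = E - fpE, x2 = I - fpI;
      f1 = j11 * x1 + j12 * x2;
      f2 = j21 * x1 + j22 * x2;
    }
    double nE = 0.0, nI = 0.0;
    if (zeta > 0.0) { nE = norm_rand(); nI = norm_rand(); }
    E += f1 * dt + zeta * sqdt * nE + stim;
    I += f2 * dt + zeta * sqdt * nI;

    if (!std::isfinite(E) || !std::isfinite(I)) {
      failed = true; fail_t = t;
      break;
    }
  }

  if (n_recorded < n_rec) {
    rec_t = head(rec_t, n_recorded); rec_E = head(rec_E, n_recorded);
    rec_I = head(rec_I, n_recorded); rec_phase = head(rec_phase, n_recorded);
  }

  return List::create(
      _["time"] = rec_t, _["E"] = rec_E, _["I"] = rec_I,
      _["tracked_phase"] = rec_phase,
      _["pulse_t"] = wrap(pulse_t), _["pulse_block"] = wrap(pulse_block),
      _["pulse_burst"] = wrap(pulse_burst),
      _["burst_t"] = wrap(burst_t), _["burst_block"] = wrap(burst_block),
      _["burst_npulses"] = wrap(burst_np),
      _["crossings"] = wrap(trk.cross_times),
      _["failed"] = failed, _["fail_t"] = fail_t);
}

// Standalone online zero-crossing phase tracker over an arbitrary signal,
// using the same rules as the simulator (phase 0 at upward crossings of the
// mean-referenced signal, linear advance at 2*pi / previous period).
// [[Rcpp::export]]
List cpp_track_phase(NumericVector x, double dt,
                     double mean_window, double refractory) {
  const int n = x.size();
  Tracker trk(mean_window, refractory, dt);
  NumericVector phase(n);
  for (int i = 0; i < n; ++i) {
    const double t = i * dt;
    phase[i] = trk.defined() ? trk.phase(t) : NA_REAL;
    trk.update(x[i], t);
  }
  return List::create(_["phase"] = phase,
                      _["crossings"] = wrap(trk.cross_times));
}
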