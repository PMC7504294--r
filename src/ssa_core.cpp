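#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Gillespie direct-method event loop.
//
// State vector order: A_b, A_c, A_o, AR, ARR, R.  A_s is a constant
// source: channel 0 fires at k_2p * A_s and increments A_b; channel 1
// drains A_b without crediting A_s.  Counts are kept in doubles but
// only ever change by +/-1, so they remain exact integers.
//
// Two uniforms are consumed per event from R's RNG stream (u1 for the
// waiting time, u2 for channel selection), which keeps the compiled
// loop bit-compatible with the pure-R reference engine under the same
// seed.  u1 == 0 is resampled so log(u1) stays finite.
//
// Snapshots: each requested grid time records the state immediately
// before the first event at a strictly later time (i.e. the state "in
// force" at that instant).
// [[Rcpp::export]]
List ssa_core(NumericVector init, double A_s, NumericVector rates,
              double t0, double t_end, NumericVector snapshot_times,
              bool keep_log, double max_events) {
  if (init.size() != 6 || rates.size() != 10)
    stop("internal: bad state/rate vector length");

  double Ab = init[0], Ac = init[1], Ao = init[2];
  double AR = init[3], ARR = init[4], R = init[5];
  const double k2p = rates[0], k2n = rates[1], k1p = rates[2],
               k1n = rates[3], kon = rates[4], koff = rates[5],
               kmp = rates[6], kmn = rates[7], kbp = rates[8],
               kbn = rates[9];

  const int nsnap = snapshot_times.size();
  NumericMatrix snaps(nsnap, 6);
  int si = 0;

  std::vector<double> log_t, log_tau;
  std::vector<int> log_ch;
  if (keep_log) {
    log_t.reserve(4096);
    log_tau.reserve(4096);
    log_ch.reserve(4096);
  }

  double t = t0;
  double events = 0.0;
  bool truncated = false, absorbed = false;
  double a[10];

  auto record_upto = [&](double horizon) {
    while (si < nsnap && snapshot_times[si] < horizon) {
      snaps(si, 0) = Ab; snaps(si, 1) = Ac; snaps(si, 2) = Ao;
      snaps(si, 3) = AR; snaps(si, 4) = ARR; snaps(si, 5) = R;
      ++si;
    }
  };

  while (t < t_end) {
    if (events >= max_events) { truncated = true; break; }

    a[0] = k2p * A_s;
    a[1] = k2n * Ab;
    a[2] = k1p * Ab;
    a[3] = k1n * Ac;
    a[4] = kon * Ac;
    a[5] = koff * Ao;
    a[6] = kmp * Ao * R;
    a[7] = kmn * AR;
    a[8] = kbp * AR * R;
    a[9] = kbn * ARR;
    // accumulate in long double, as base R's sum()/cumsum() do, so the
    // compiled and reference engines agree bit-for-bit
    long double acc = 0.0L;
    for (int i = 0; i < 10; ++i) acc += a[i];
    double total = (double)acc;
    if (total <= 0.0) { absorbed = true; break; }

    double u1 = unif_rand();
    while (u1 <= 0.0) u1 = unif_rand();
    double tau = -std::log(u1) / total;
    double tnew = t + tau;

    record_upto(tnew);
    if (tnew > t_end) { t = t_end; break; }

    double u2 = unif_rand();
    double target = u2 * total;
    long double cum = 0.0L;
    int j = 9;
    for (int i = 0; i < 10; ++i) {
      cum += a[i];
      if (target < (double)cum) { j = i; break; }
    }
    // rounding guard: never fire a zero-propensity channel
    while (j > 0 && a[j] == 0.0) --j;

    switch (j) {
      case 0: Ab += 1; break;
      case 1: Ab -= 1; break;
      case 2: Ab -= 1; Ac += 1; break;
      case 3: Ab += 1; Ac -= 1; break;
      case 4: Ac -= 1; Ao += 1; break;
      case 5: Ac += 1; Ao -= 1; break;
      case 6: Ao -= 1; AR += 1; R -= 1; break;
      case 7: Ao += 1; AR -= 1; R += 1; break;
      case 8: AR -= 1; ARR += 1; R -= 1; break;
      case 9: AR += 1; ARR -= 1; R += 1; break;
    }
    if (Ab < 0 || Ac < 0 || Ao < 0 || AR < 0 || ARR < 0 || R < 0)
      stop("internal: negative count after channel %d", j + 1);

    t = tnew;
    events += 1.0;
    if (keep_log) {
      log_t.push_back(t);
      log_tau.push_back(tau);
      log_ch.push_back(j);
    }
  }

  // state persists to the end of the grid (absorbed/truncated included)
  record_upto(R_PosInf);

  NumericVector fin = NumericVector::create(Ab, Ac, Ao, AR, ARR, R);
  List out = List::create(
    _["snapshots"] = snaps, _["final"] = fin, _["t"] = t,
    _["event_count"] = events, _["truncated"] = truncated,
    _["absorbed"] = absorbed);
  if (keep_log)
    out["event_log"] = DataFrame::create(
      _["t"] = wrap(log_t), _["channel"] = wrap(log_ch),
      _["tau"] = wrap(log_tau));
  return out;
}
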