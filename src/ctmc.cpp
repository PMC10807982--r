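#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Seven event channels of the finite-population counterpart of the
// mean-field model. Rates are chosen so that the expected drift of the
// fractions counts/N equals the ODE right-hand side exactly: a pairwise
// channel between classes with fractions x and y and success rate s fires
// at total rate N * x * y * s = (counts_x * counts_y * s) / N.
//
// channel                     rate                 effect on (n, i, e)
// 0 innovation  (i -> e)      mu * Ni              ( 0, -1, +1)
// 1 turnover_i  (i -> n)      m * Ni               (+1, -1,  0)
// 2 turnover_e  (e -> n)      m * Ne               (+1,  0, -1)
// 3 learn_from_i (n -> i)     Nn * Ni * si / N     (-1, +1,  0)
// 4 learn_from_e (n -> e)     Nn * Ne * se / N     (-1,  0, +1)
// 5 exchange_i_to_e (i -> e)  (1-c) * Ni * Ne * se / N  ( 0, -1, +1)
// 6 exchange_e_to_i (e -> i)  (1-c) * Ne * Ni * si / N  ( 0, +1, -1)

static const int STOICH[7][3] = {
  { 0, -1, +1},
  {+1, -1,  0},
  {+1,  0, -1},
  {-1, +1,  0},
  {-1,  0, +1},
  { 0, -1, +1},
  { 0, +1, -1}
};

static inline void channel_rates(const double cnt[3], double N,
                                 double mu, double m, double c,
                                 double se, double si, double r[7]) {
  const double Nn = cnt[0], Ni = cnt[1], Ne = cnt[2];
  r[0] = mu * Ni;
  r[1] = m * Ni;
  r[2] = m * Ne;
  r[3] = Nn * Ni * si / N;
  r[4] = Nn * Ne * se / N;
  r[5] = (1.0 - c) * Ni * Ne * se / N;
  r[6] = (1.0 - c) * Ne * Ni * si / N;
}

// one Gillespie (direct-method) event; returns false when all rates vanish
static inline bool step_event(double cnt[3], double N, double mu, double m,
                              double c, double se, double si, double &t) {
  double r[7];
  channel_rates(cnt, N, mu, m, c, se, si, r);
  double total = 0.0;
  for (int k = 0; k < 7; ++k) total += r[k];
  if (total <= 0.0) return false;
  t += R::exp_rand() / total;
  double u = unif_rand() * total;
  int k = 0;
  double acc = r[0];
  while (u > acc && k < 6) acc += r[++k];
  for (int j = 0; j < 3; ++j) cnt[j] += STOICH[k][j];
  return true;
}

// [[Rcpp::export(name = ".ctmc_sample_cpp")]]
IntegerMatrix ctmc_sample_cpp(IntegerVector counts0, double mu, double m,
                              double c, double se, double si,
                              NumericVector out_times) {
  const double N = counts0[0] + counts0[1] + counts0[2];
  double cnt[3] = {(double)counts0[0], (double)counts0[1], (double)counts0[2]};
  const int n_out = out_times.size();
  IntegerMatrix out(n_out, 3);
  // the sample path is piecewise constant: (t, cnt) is the state after the
  // last applied event; a pending event is peeked but only applied once its
  // firing time precedes the output time being recorded
  double t = 0.0;
  double cnt_pend[3];
  double t_pend = 0.0;
  bool has_pending = false, absorbed = false;
  for (int j = 0; j < n_out; ++j) {
    while (!absorbed) {
      if (!has_pending) {
        for (int k = 0; k < 3; ++k) cnt_pend[k] = cnt[k];
        t_pend = t;
        if (!step_event(cnt_pend, N, mu, m, c, se, si, t_pend)) {
          absorbed = true;
          break;
        }
        has_pending = true;
      }
      if (t_pend > out_times[j]) break;
      t = t_pend;
      for (int k = 0; k < 3; ++k) cnt[k] = cnt_pend[k];
      has_pending = false;
    }
    out(j, 0) = (int)cnt[0];
    out(j, 1) = (int)cnt[1];
    out(j, 2) = (int)cnt[2];
  }
  return out;
}

// [[Rcpp::export(name = ".ctmc_path_cpp")]]
List ctmc_path_cpp(IntegerVector counts0, double mu, double m, double c,
                   double se, double si, double t_max, double max_events) {
  const double N = counts0[0] + counts0[1] + counts0[2];
  double cnt[3] = {(double)counts0[0], (double)counts0[1], (double)counts0[2]};
  std::vector<double> times;
  std::vector<int> nn, ii, ee;
  times.push_back(0.0);
  nn.push_back(counts0[0]); ii.push_back(counts0[1]); ee.push_back(counts0[2]);
  double t = 0.0;
  double n_events = 0.0;
  bool truncated = false;
  while (true) {
    if (n_events >= max_events) { truncated = true; break; }
    double cnt_next[3] = {cnt[0], cnt[1], cnt[2]};
    double t_next = t;
    if (!step_event(cnt_next, N, mu, m, c, se, si, t_next)) break; // absorbed
    if (t_next > t_max) break;
    t = t_next;
    for (int j = 0; j < 3; ++j) cnt[j] = cnt_next[j];
    times.push_back(t);
    nn.push_back((int)cnt[0]); ii.push_back((int)cnt[1]); ee.push_back((int)cnt[2]);
    n_events += 1.0;
  }
  return List::create(_["time"] = wrap(times), _["n"] = wrap(nn),
                      _["i"] = wrap(ii), _["e"] = wrap(ee),
                      _["truncated"] = truncated);
}
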