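#include <Rcpp.h>
using namespace Rcpp;

// Gillespie sampling of a continuous-time Markov chain. Q in s^-1,
// start is a 0-based state index. Returns sojourn start times and the
// 0-based state per sojourn, truncated at total duration. Uses R's RNG
// so results are reproducible under set.seed().
// [[Rcpp::export(name = ".gillespie_cpp")]]
List gillespie_cpp(NumericMatrix Q, int start, double duration) {
  const int n = Q.nrow();
  std::vector<double> exit(n);
  // cumulative jump probabilities per state
  std::vector<std::vector<double>> cum(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i) tot += Q(i, j);
    exit[i] = tot;
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j != i) acc += Q(i, j);
      cum[i][j] = (tot > 0.0) ? acc / tot : 0.0;
    }
  }
  std::vector<double> times;
  std::vector<int> states;
  double t = 0.0;
  int s = start;
  while (t < duration) {
    times.push_back(t);
    states.push_back(s);
    if (exit[s] <= 0.0) {
      if (times.size() > 1)
        stop("absorbing state reached during simulation");
      break;  // single absorbing-start sojourn spans the record
    }
    t += R::exp_rand() / exit[s];
    if (t >= duration) break;
    double u = R::unif_rand();
    int nxt = 0;
    while (nxt < n - 1 && cum[s][nxt] < u) ++nxt;
    s = nxt;
  }
  return List::create(_["jump_times"] = wrap(times),
                      _["states"] = wrap(states));
}

// Viterbi decoding of the most likely class path under Gaussian
// emissions and a uniform switching probability. means/sds per class,
// switch_logp = log(p_switch), stay_logp = log(1 - (K-1)*p_switch).
// Returns 1-based class indices per sample.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericVector x, NumericVector means,
                          NumericVector sds, double p_switch) {
  const int T = x.size();
  const int K = means.size();
  if (T == 0) stop("empty trace");
  const double stay = std::log(std::max(1.0 - (K - 1) * p_switch, 1e-12));
  const double sw = std::log(std::max(p_switch, 1e-300));
  std::vector<double> lognorm(K), inv2v(K);
  for (int k = 0; k < K; ++k) {
    double v = sds[k] * sds[k];
    if (v <= 0.0) stop("non-positive emission sd");
    lognorm[k] = -0.5 * std::log(2.0 * M_PI * v);
    inv2v[k] = 0.5 / v;
  }
  std::vector<double> delta(K), ndelta(K);
  IntegerMatrix back(T, K);
  for (int k = 0; k < K; ++k) {
    double d = x[0] - means[k];
    delta[k] = lognorm[k] - d * d * inv2v[k];
  }
  for (int t = 1; t < T; ++t) {
    // best previous state overall (for switch transitions)
    int argbest = 0;
    for (int k = 1; k < K; ++k)
      if (delta[k] > delta[argbest]) argbest = k;
    double best = delta[argbest];
    for (int k = 0; k < K; ++k) {
      double fromStay = delta[k] + stay;
      double fromSwitch;
      int fromIdx;
      if (argbest != k) {
        fromSwitch = best + sw;
        fromIdx = argbest;
      } else {
        // best other state
        double b2 = -INFINITY; int i2 = k;
        for (int j = 0; j < K; ++j)
          if (j != k && delta[j] > b2) { b2 = delta[j]; i2 = j; }
        fromSwitch = b2 + sw;
        fromIdx = i2;
      }
      double d = x[t] - means[k];
      double emis = lognorm[k] - d * d * inv2v[k];
      if (fromStay >= fromSwitch) {
        ndelta[k] = fromStay + emis;
        back(t, k) = k;
      } else {
        ndelta[k] = fromSwitch + emis;
        back(t, k) = fromIdx;
      }
    }
    std::swap(delta, ndelta);
  }
  IntegerVector path(T);
  int cur = 0;
  for (int k = 1; k < K; ++k)
    if (delta[k] > delta[cur]) cur = k;
  path[T - 1] = cur + 1;
  for (int t = T - 1; t > 0; --t) {
    cur = back(t, cur);
    path[t - 1] = cur + 1;
  }
  return path;
}

// Joint log-likelihood of a class path under the same model (used to
// verify the SKM iteration never decreases the objective).
// [[Rcpp::export(name = ".path_loglik_cpp")]]
double path_loglik_cpp(NumericVector x, IntegerVector path,
                       NumericVector means, NumericVector sds,
                       double p_switch) {
  const int T = x.size();
  const int K = means.size();
  const double stay = std::log(std::max(1.0 - (K - 1) * p_switch, 1e-12));
  const double sw = std::log(std::max(p_switch, 1e-300));
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    int k = path[t] - 1;
    double v = sds[k] * sds[k];
    double d = x[t] - means[k];
    ll += -0.5 * std::log(2.0 * M_PI * v) - d * d / (2.0 * v);
    if (t > 0) ll += (path[t] == path[t - 1]) ? stay : sw;
  }
  return ll;
}
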