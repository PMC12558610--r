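#include <Rcpp.h>
using namespace Rcpp;

// Finite-population public-reputation donation game.
//
// act_idx: prescribed action per context (GG,GB,BG,BB), 0 = C, 1 = D, 2 = P.
// r_mat:   4 x n_actions matrix of assessment-error-adjusted probabilities
//          of a good assignment; implementation (mu_e) and perception
//          (eps_dc) errors are simulated event-by-event here, so r_mat must
//          carry the assessment error mu only.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
List mc_population_cpp(IntegerVector act_idx, NumericMatrix r_mat,
                       double mu_e, double eps_dc, int n, double rounds,
                       double burn, int n_batches) {
  std::vector<int> rep(n, 1); // start all good; burn-in removes the bias
  long n_good = n;
  long long total = (long long)rounds;
  long long burn_rounds = (long long)burn;
  long long kept = total - burn_rounds;
  if (kept < n_batches) stop("too few rounds after burn-in");
  long long batch_len = kept / n_batches;
  kept = batch_len * (long long)n_batches; // drop the remainder

  std::vector<double> good_means(n_batches, 0.0), coop_means(n_batches, 0.0);
  double good_acc = 0.0, coop_acc = 0.0;
  long long in_batch = 0;
  int batch = 0;

  for (long long t = 0; t < total; ++t) {
    int donor = (int)(unif_rand() * n);
    if (donor == n) donor = n - 1;
    int rec = (int)(unif_rand() * (n - 1));
    if (rec >= donor) ++rec;
    int ctx = (rep[donor] ? 0 : 2) + (rep[rec] ? 0 : 1);
    int realized = act_idx[ctx];
    if (realized == 0 && mu_e > 0.0 && unif_rand() < mu_e) realized = 1;
    int perceived = realized;
    if (perceived == 1 && eps_dc > 0.0 && unif_rand() < eps_dc) perceived = 0;
    int new_rep = (unif_rand() < r_mat(ctx, perceived)) ? 1 : 0;
    n_good += new_rep - rep[donor];
    rep[donor] = new_rep;

    if (t >= burn_rounds && batch < n_batches) {
      good_acc += (double)n_good / n;
      coop_acc += (realized == 0) ? 1.0 : 0.0;
      if (++in_batch == batch_len) {
        good_means[batch] = good_acc / batch_len;
        coop_means[batch] = coop_acc / batch_len;
        good_acc = coop_acc = 0.0;
        in_batch = 0;
        ++batch;
      }
    }
  }

  double gm = 0.0, cm = 0.0;
  for (int i = 0; i < n_batches; ++i) { gm += good_means[i]; cm += coop_means[i]; }
  gm /= n_batches; cm /= n_batches;
  double gv = 0.0, cv = 0.0;
  for (int i = 0; i < n_batches; ++i) {
    gv += (good_means[i] - gm) * (good_means[i] - gm);
    cv += (coop_means[i] - cm) * (coop_means[i] - cm);
  }
  gv /= (n_batches - 1); cv /= (n_batches - 1);

  return List::create(_["good_fraction"] = gm,
                      _["good_se"] = std::sqrt(gv / n_batches),
                      _["coop_rate"] = cm,
                      _["coop_se"] = std::sqrt(cv / n_batches));
}
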