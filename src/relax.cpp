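#include <Rcpp.h>
using namespace Rcpp;

// Seeded Gauss-Seidel gradient descent for the three-term elastic energy of
// the texture warp.  Points are visited in a freshly shuffled order each
// iteration (R's RNG, so set.seed() on the R side makes runs reproducible),
// the forces acting on the visited point are summed and the point is moved a
// capped distance along the total force.
//
// pos, rest      n x 2 current and rest (source) positions
// intens         n     source intensity per point (>= 0)
// edges          e x 2 0-based index pairs of the 8-connected bulk springs
// chain          b x 2 0-based index pairs of consecutive border points
// fix_idx        m     0-based indices of fixation points
// fix_target     m x 2 target positions of the fixation points
// zero_rest      springs have rest length 0 (literal displacement springs)
//                instead of the natural rest configuration
// eta            learning rate; eta <= 0 selects per-point preconditioning
//                (step = omega * |f| / k_i, k_i the point's total stiffness)
// [[Rcpp::export]]
List relax_cpp(NumericMatrix pos, NumericMatrix rest, NumericVector intens,
               IntegerMatrix edges, IntegerMatrix chain,
               IntegerVector fix_idx, NumericMatrix fix_target,
               double w_fix, double w_border, double w_bulk,
               double eta, double omega, double step_cap, double tol,
               int max_iters, bool zero_rest) {
  int n = pos.nrow();
  int ne = edges.nrow(), nc = chain.nrow(), nf = fix_idx.size();

  // stiffness of each bulk spring: log(1 + I(p)) * log(1 + I(n))
  std::vector<double> ec(ne);
  for (int e = 0; e < ne; ++e)
    ec[e] = std::log1p(intens[edges(e, 0)]) * std::log1p(intens[edges(e, 1)]);

  // CSR adjacency over both spring sets (edge id, kind 0 = bulk, 1 = chain)
  std::vector<int> deg(n, 0);
  for (int e = 0; e < ne; ++e) { ++deg[edges(e, 0)]; ++deg[edges(e, 1)]; }
  for (int e = 0; e < nc; ++e) { ++deg[chain(e, 0)]; ++deg[chain(e, 1)]; }
  std::vector<int> start(n + 1, 0);
  for (int i = 0; i < n; ++i) start[i + 1] = start[i] + deg[i];
  int tot = start[n];
  std::vector<int> nbr(tot), eid(tot);
  std::vector<char> kind(tot);
  std::vector<int> fill(start.begin(), start.end() - 1);
  for (int e = 0; e < ne; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    nbr[fill[a]] = b; eid[fill[a]] = e; kind[fill[a]++] = 0;
    nbr[fill[b]] = a; eid[fill[b]] = e; kind[fill[b]++] = 0;
  }
  for (int e = 0; e < nc; ++e) {
    int a = chain(e, 0), b = chain(e, 1);
    nbr[fill[a]] = b; eid[fill[a]] = e; kind[fill[a]++] = 1;
    nbr[fill[b]] = a; eid[fill[b]] = e; kind[fill[b]++] = 1;
  }

  std::vector<int> fix_of(n, -1);
  for (int f = 0; f < nf; ++f) fix_of[fix_idx[f]] = f;

  // per-point total stiffness, for the preconditioned step
  std::vector<double> kstiff(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double k = (fix_of[i] >= 0) ? w_fix : 0.0;
    for (int s = start[i]; s < start[i + 1]; ++s)
      k += (kind[s] == 0) ? w_bulk * ec[eid[s]] : w_border;
    kstiff[i] = std::max(k, 1e-12);
  }

  RNGScope scope;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> energy;
  energy.reserve(std::min(max_iters + 1, 100000));
  double prev_e = R_PosInf;
  int incr_run = 0, iter = 0;
  bool converged = false;
  double max_disp = R_PosInf;

  for (iter = 1; iter <= max_iters; ++iter) {
    // Fisher-Yates shuffle with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    max_disp = 0.0;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      double fx = 0.0, fy = 0.0;
      for (int s = start[i]; s < start[i + 1]; ++s) {
        int j = nbr[s];
        double dx = pos(i, 0) - pos(j, 0);
        double dy = pos(i, 1) - pos(j, 1);
        if (!zero_rest) {
          dx -= rest(i, 0) - rest(j, 0);
          dy -= rest(i, 1) - rest(j, 1);
        }
        double wc = (kind[s] == 0) ? w_bulk * ec[eid[s]] : w_border;
        fx -= wc * dx;
        fy -= wc * dy;
      }
      if (fix_of[i] >= 0) {
        fx += w_fix * (fix_target(fix_of[i], 0) - pos(i, 0));
        fy += w_fix * (fix_target(fix_of[i], 1) - pos(i, 1));
      }
      double fn = std::sqrt(fx * fx + fy * fy);
      if (fn <= 0) continue;
      double step = (eta > 0) ? eta * fn : omega * fn / kstiff[i];
      if (step > step_cap) step = step_cap;
      pos(i, 0) += step * fx / fn;
      pos(i, 1) += step * fy / fn;
      if (step > max_disp) max_disp = step;
    }
    // total energy after the sweep
    double E = 0.0;
    for (int e = 0; e < ne; ++e) {
      int a = edges(e, 0), b = edges(e, 1);
      double dx = pos(a, 0) - pos(b, 0), dy = pos(a, 1) - pos(b, 1);
      if (!zero_rest) {
        dx -= rest(a, 0) - rest(b, 0);
        dy -= rest(a, 1) - rest(b, 1);
      }
      E += 0.5 * w_bulk * ec[e] * (dx * dx + dy * dy);
    }
    for (int e = 0; e < nc; ++e) {
      int a = chain(e, 0), b = chain(e, 1);
      double dx = pos(a, 0) - pos(b, 0), dy = pos(a, 1) - pos(b, 1);
      if (!zero_rest) {
        dx -= rest(a, 0) - rest(b, 0);
        dy -= rest(a, 1) - rest(b, 1);
      }
      E += 0.5 * w_border * (dx * dx + dy * dy);
    }
    for (int f = 0; f < nf; ++f) {
      int i = fix_idx[f];
      double dx = pos(i, 0) - fix_target(f, 0);
      double dy = pos(i, 1) - fix_target(f, 1);
      E += 0.5 * w_fix * (dx * dx + dy * dy);
    }
    energy.push_back(E);
    if (!R_finite(E)) stop("step too large");
    if (E > prev_e + 1e-9 * std::max(1.0, std::fabs(prev_e))) {
      if (++incr_run >= 10) stop("step too large");
    } else {
      incr_run = 0;
    }
    prev_e = E;
    if (max_disp < tol) { converged = true; break; }
  }
  if (iter > max_iters) iter = max_iters;

  return List::create(_["pos"] = pos, _["energy"] = NumericVector(energy.begin(), energy.end()),
                      _["iterations"] = iter, _["converged"] = converged,
                      _["final_max_disp"] = max_disp);
}
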