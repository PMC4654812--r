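// Cellular Potts engine: Metropolis copy dynamics with adhesion, area and
// length constraints, local-connectivity penalty, chemotaxis bias, and the
// coupled explicit finite-difference chemoattractant field.
//
// Conventions shared with the R side:
//   * labels: integer matrix, 0 = ECM, 1..ncell = cell identifiers
//   * kind codes: 0 = ECM, 1 = tip, 2 = stalk (indices into J)
//   * coordinates: (row, col), 1-based in R, converted here to 0-based
//   * all randomness comes from R's RNG (unif_rand), so set.seed() on the
//     R side makes runs reproducible
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <utility>
using namespace Rcpp;

// Moore neighborhood offsets (copy neighborhood and 2nd-order adhesion sum)
static const int MOORE_DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int MOORE_DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

struct CellBook {
  // per-label bookkeeping, index 0 unused (ECM)
  std::vector<long long> n, Sr, Sc, Srr, Scc, Src;
};

// Cell length from exact integer moment sums; ellipse convention
// l = 4 * sqrt(lambda_max) of the per-site covariance, with a +1/12
// per-site term so a single site has the extent of a unit square.
static double length_from_sums(long long n, long long Sr, long long Sc,
                               long long Srr, long long Scc, long long Src) {
  if (n <= 0) return 0.0;
  double dn = (double)n;
  double mr = Sr / dn, mc = Sc / dn;
  double crr = Srr / dn - mr * mr + 1.0 / 12.0;
  double ccc = Scc / dn - mc * mc + 1.0 / 12.0;
  double crc = Src / dn - mr * mc;
  double tr = crr + ccc;
  double disc = std::sqrt((crr - ccc) * (crr - ccc) + 4.0 * crc * crc);
  double lmax = 0.5 * (tr + disc);
  if (lmax < 0) lmax = 0;
  return 4.0 * std::sqrt(lmax);
}

static void book_from_labels(const IntegerMatrix& labels, int ncell,
                             CellBook& bk) {
  bk.n.assign(ncell + 1, 0);
  bk.Sr.assign(ncell + 1, 0);
  bk.Sc.assign(ncell + 1, 0);
  bk.Srr.assign(ncell + 1, 0);
  bk.Scc.assign(ncell + 1, 0);
  bk.Src.assign(ncell + 1, 0);
  int H = labels.nrow(), W = labels.ncol();
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int s = labels(r, c);
      if (s > 0) {
        bk.n[s]++; bk.Sr[s] += r; bk.Sc[s] += c;
        bk.Srr[s] += (long long)r * r; bk.Scc[s] += (long long)c * c;
        bk.Src[s] += (long long)r * c;
      }
    }
}

// Adhesion energy change at `tgt` when its label flips from st to ss.
static double dh_adhesion(const IntegerMatrix& labels, int rt, int ct,
                          int ss, int st, const IntegerVector& kind,
                          const NumericMatrix& J) {
  int H = labels.nrow(), W = labels.ncol();
  int ks = (ss > 0) ? kind[ss - 1] : 0;
  int kt = (st > 0) ? kind[st - 1] : 0;
  double dh = 0.0;
  for (int k = 0; k < 8; ++k) {
    int r = rt + MOORE_DR[k], c = ct + MOORE_DC[k];
    if (r < 0 || r >= H || c < 0 || c >= W) continue;
    int sn = labels(r, c);
    int kn = (sn > 0) ? kind[sn - 1] : 0;
    if (sn != ss) dh += J(ks, kn);
    if (sn != st) dh -= J(kt, kn);
  }
  return dh;
}

// Local connectivity test: would removing site (rt, ct) from cell `st`
// split that cell's sites in the Moore neighborhood of the site into more
// than one 8-connected component?
static bool splits_locally(const IntegerMatrix& labels, int rt, int ct,
                           int st) {
  int H = labels.nrow(), W = labels.ncol();
  int mr[8], mc[8], nm = 0;
  for (int k = 0; k < 8; ++k) {
    int r = rt + MOORE_DR[k], c = ct + MOORE_DC[k];
    if (r < 0 || r >= H || c < 0 || c >= W) continue;
    if (labels(r, c) == st) { mr[nm] = r; mc[nm] = c; ++nm; }
  }
  if (nm <= 1) return false;
  // BFS over member sites, adjacency = 8-connectivity (center excluded)
  bool seen[8] = {false};
  int stack[8], top = 0;
  stack[top++] = 0; seen[0] = true;
  int reached = 1;
  while (top > 0) {
    int i = stack[--top];
    for (int j = 0; j < nm; ++j) {
      if (seen[j]) continue;
      if (std::abs(mr[i] - mr[j]) <= 1 && std::abs(mc[i] - mc[j]) <= 1) {
        seen[j] = true; stack[top++] = j; ++reached;
      }
    }
  }
  return reached < nm;
}

// Core (non-bias) energy change of copying label ss onto site (rt, ct)
// currently holding st: adhesion + area + length + connectivity penalty.
static double dh_core(const IntegerMatrix& labels, const CellBook& bk,
                      int rt, int ct, int ss, int st,
                      const IntegerVector& kind, const NumericMatrix& J,
                      double lambda_size, const NumericVector& target_area,
                      const NumericVector& lambda_length,
                      const NumericVector& target_length,
                      double conn_penalty, bool conn_on) {
  double dh = dh_adhesion(labels, rt, ct, ss, st, kind, J);
  if (ss > 0) {
    double A = target_area[ss - 1], a = (double)bk.n[ss];
    dh += lambda_size * ((A - (a + 1)) * (A - (a + 1)) - (A - a) * (A - a));
    if (lambda_length[ss - 1] > 0) {
      double l0 = length_from_sums(bk.n[ss], bk.Sr[ss], bk.Sc[ss],
                                   bk.Srr[ss], bk.Scc[ss], bk.Src[ss]);
      double l1 = length_from_sums(bk.n[ss] + 1, bk.Sr[ss] + rt,
                                   bk.Sc[ss] + ct,
                                   bk.Srr[ss] + (long long)rt * rt,
                                   bk.Scc[ss] + (long long)ct * ct,
                                   bk.Src[ss] + (long long)rt * ct);
      double L = target_length[ss - 1];
      dh += lambda_length[ss - 1] * ((L - l1) * (L - l1) - (L - l0) * (L - l0));
    }
  }
  if (st > 0) {
    double A = target_area[st - 1], a = (double)bk.n[st];
    dh += lambda_size * ((A - (a - 1)) * (A - (a - 1)) - (A - a) * (A - a));
    if (lambda_length[st - 1] > 0) {
      double l0 = length_from_sums(bk.n[st], bk.Sr[st], bk.Sc[st],
                                   bk.Srr[st], bk.Scc[st], bk.Src[st]);
      double l1 = length_from_sums(bk.n[st] - 1, bk.Sr[st] - rt,
                                   bk.Sc[st] - ct,
                                   bk.Srr[st] - (long long)rt * rt,
                                   bk.Scc[st] - (long long)ct * ct,
                                   bk.Src[st] - (long long)rt * ct);
      double L = target_length[st - 1];
      dh += lambda_length[st - 1] * ((L - l1) * (L - l1) - (L - l0) * (L - l0));
    }
    if (conn_on && splits_locally(labels, rt, ct, st)) dh += conn_penalty;
  }
  return dh;
}

// [[Rcpp::export(name = ".delta_h_cpp")]]
double delta_h_cpp(IntegerMatrix labels, IntegerVector kind,
                   NumericVector target_area, NumericVector lambda_length,
                   NumericVector target_length, NumericMatrix J,
                   double lambda_size, double conn_penalty, bool conn_on,
                   int r_src, int c_src, int r_tgt, int c_tgt) {
  int ncell = kind.size();
  CellBook bk;
  book_from_labels(labels, ncell, bk);
  int ss = labels(r_src - 1, c_src - 1);
  int st = labels(r_tgt - 1, c_tgt - 1);
  if (ss == st) return 0.0;
  return dh_core(labels, bk, r_tgt - 1, c_tgt - 1, ss, st, kind, J,
                 lambda_size, target_area, lambda_length, target_length,
                 conn_penalty, conn_on);
}

// One explicit forward-Euler step of the secretion-decay-diffusion field.
// Secretion at rate alpha under cells, decay at rate eps in the ECM,
// 5-point Laplacian with zero-flux (Neumann) boundaries. Writes into the
// caller-provided buffer (src and dst are swapped by the caller).
static void field_step_buf(const double* src, double* dst,
                           const int* labels, int H, int W, double alpha,
                           double eps, double Dcoef, double dt, double dx) {
  double k = Dcoef * dt / (dx * dx);
  for (int c = 0; c < W; ++c) {
    const double* col = src + (size_t)c * H;
    const double* colL = src + (size_t)(c > 0 ? c - 1 : 0) * H;
    const double* colR = src + (size_t)(c < W - 1 ? c + 1 : W - 1) * H;
    const int* lab = labels + (size_t)c * H;
    double* out = dst + (size_t)c * H;
    for (int r = 0; r < H; ++r) {
      double cc = col[r];
      double up = col[r > 0 ? r - 1 : 0];
      double dn = col[r < H - 1 ? r + 1 : H - 1];
      double lap = up + dn + colL[r] + colR[r] - 4.0 * cc;
      double v = cc + k * lap;
      if (lab[r] > 0) v += alpha * dt;
      else v -= eps * dt * cc;
      out[r] = v > 0 ? v : 0;
    }
  }
}

static void field_steps_inplace(NumericMatrix& cfield,
                                const IntegerMatrix& labels, double alpha,
                                double eps, double Dcoef, double dt,
                                double dx, int nsteps,
                                std::vector<double>& scratch) {
  int H = cfield.nrow(), W = cfield.ncol();
  size_t n = (size_t)H * W;
  if (scratch.size() < n) scratch.resize(n);
  double* a = REAL(cfield);
  double* b = scratch.data();
  const int* lab = INTEGER(labels);
  bool in_a = true;
  for (int i = 0; i < nsteps; ++i) {
    field_step_buf(in_a ? a : b, in_a ? b : a, lab, H, W, alpha, eps,
                   Dcoef, dt, dx);
    in_a = !in_a;
  }
  if (!in_a) std::copy(b, b + n, a);
}

// [[Rcpp::export(name = ".field_steps_cpp")]]
NumericMatrix field_steps_cpp(NumericMatrix cfield, IntegerMatrix labels,
                              double alpha, double eps, double Dcoef,
                              double dt, double dx, int nsteps) {
  NumericMatrix f = clone(cfield);
  std::vector<double> scratch;
  field_steps_inplace(f, labels, alpha, eps, Dcoef, dt, dx, nsteps,
                      scratch);
  return f;
}

// Contact map by boundary-link counting in the 4-neighborhood:
//   P[i]   = number of lattice bonds between a site of cell i and a site
//            outside cell i (ECM or another cell),
//   P[i,j] = number of bonds between cells i and j (symmetric).
// [[Rcpp::export(name = ".contact_map_cpp")]]
List contact_map_cpp(IntegerMatrix labels, int ncell) {
  int H = labels.nrow(), W = labels.ncol();
  std::vector<double> P(ncell + 1, 0.0);
  std::map<std::pair<int, int>, double> pairs;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int s = labels(r, c);
      // right and down bonds: each unordered bond visited once
      if (c + 1 < W) {
        int s2 = labels(r, c + 1);
        if (s != s2) {
          if (s > 0) P[s]++;
          if (s2 > 0) P[s2]++;
          if (s > 0 && s2 > 0)
            pairs[std::make_pair(std::min(s, s2), std::max(s, s2))]++;
        }
      }
      if (r + 1 < H) {
        int s2 = labels(r + 1, c);
        if (s != s2) {
          if (s > 0) P[s]++;
          if (s2 > 0) P[s2]++;
          if (s > 0 && s2 > 0)
            pairs[std::make_pair(std::min(s, s2), std::max(s, s2))]++;
        }
      }
    }
  }
  int np = pairs.size();
  IntegerVector pi(np), pj(np);
  NumericVector pn(np);
  int k = 0;
  for (auto& kv : pairs) {
    pi[k] = kv.first.first; pj[k] = kv.first.second; pn[k] = kv.second; ++k;
  }
  NumericVector Pout(ncell);
  for (int i = 1; i <= ncell; ++i) Pout[i - 1] = P[i];
  return List::create(_["membrane"] = Pout, _["i"] = pi, _["j"] = pj,
                      _["links"] = pn);
}

// Run n_mcs Monte Carlo steps. Each MCS performs width*height copy
// attempts; if do_field, steps_per_mcs field updates follow each MCS.
// lambda_c is per cell (already resolved from kind by the caller).
// [[Rcpp::export(name = ".run_mcs_cpp")]]
List run_mcs_cpp(IntegerMatrix labels_in, IntegerVector kind,
                 NumericVector target_area, NumericVector lambda_length,
                 NumericVector target_length, NumericMatrix J,
                 double lambda_size, double mu, double conn_penalty,
                 bool conn_on, NumericVector lambda_c,
                 bool contact_inhibition, NumericMatrix cfield_in,
                 bool do_field, double alpha, double eps, double Dcoef,
                 double dt, double dx, int steps_per_mcs, int n_mcs) {
  IntegerMatrix labels = clone(labels_in);
  NumericMatrix cfield = clone(cfield_in);
  int H = labels.nrow(), W = labels.ncol();
  int ncell = kind.size();
  CellBook bk;
  book_from_labels(labels, ncell, bk);
  long long nsites = (long long)H * W;
  // flat views; the interior-only rule makes neighbor access bounds-free
  int* L = INTEGER(labels);
  const double* C = REAL(cfield);
  const int* kindv = INTEGER(kind);
  const double* Av = REAL(target_area);
  const double* lamLv = REAL(lambda_length);
  const double* Lv = REAL(target_length);
  const double* Jv = REAL(J);
  const double* lcv = REAL(lambda_c);
  int noff[8];
  for (int k = 0; k < 8; ++k) noff[k] = MOORE_DR[k] + MOORE_DC[k] * H;
  std::vector<double> scratch;
  for (int mcs = 0; mcs < n_mcs; ++mcs) {
    for (long long att = 0; att < nsites; ++att) {
      long long idx = (long long)(unif_rand() * nsites);
      if (idx >= nsites) idx = nsites - 1;
      int cs = (int)(idx / H), rs = (int)(idx % H);
      // frozen ECM border: copies from or into the border are rejected
      if (rs == 0 || rs == H - 1 || cs == 0 || cs == W - 1) continue;
      int k = (int)(unif_rand() * 8.0);
      if (k >= 8) k = 7;
      int rt = rs + MOORE_DR[k], ct = cs + MOORE_DC[k];
      if (rt == 0 || rt == H - 1 || ct == 0 || ct == W - 1) continue;
      long long fs = idx;
      long long ft = (long long)ct * H + rt;
      int ss = L[fs], st = L[ft];
      if (ss == st) continue;
      int ks = (ss > 0) ? kindv[ss - 1] : 0;
      int kt = (st > 0) ? kindv[st - 1] : 0;
      // adhesion over the 8 neighbors of the target site
      double dh = 0.0;
      for (int q = 0; q < 8; ++q) {
        int sn = L[ft + noff[q]];
        int kn = (sn > 0) ? kindv[sn - 1] : 0;
        if (sn != ss) dh += Jv[ks + 3 * kn];
        if (sn != st) dh -= Jv[kt + 3 * kn];
      }
      if (ss > 0) {
        double A = Av[ss - 1], a = (double)bk.n[ss];
        dh += lambda_size * ((A - a - 1) * (A - a - 1) - (A - a) * (A - a));
        if (lamLv[ss - 1] > 0) {
          double l0 = length_from_sums(bk.n[ss], bk.Sr[ss], bk.Sc[ss],
                                       bk.Srr[ss], bk.Scc[ss], bk.Src[ss]);
          double l1 = length_from_sums(bk.n[ss] + 1, bk.Sr[ss] + rt,
                                       bk.Sc[ss] + ct,
                                       bk.Srr[ss] + (long long)rt * rt,
                                       bk.Scc[ss] + (long long)ct * ct,
                                       bk.Src[ss] + (long long)rt * ct);
          double Lt = Lv[ss - 1];
          dh += lamLv[ss - 1] * ((Lt - l1) * (Lt - l1) -
                                 (Lt - l0) * (Lt - l0));
        }
      }
      if (st > 0) {
        double A = Av[st - 1], a = (double)bk.n[st];
        dh += lambda_size * ((A - a + 1) * (A - a + 1) - (A - a) * (A - a));
        if (lamLv[st - 1] > 0) {
          double l0 = length_from_sums(bk.n[st], bk.Sr[st], bk.Sc[st],
                                       bk.Srr[st], bk.Scc[st], bk.Src[st]);
          double l1 = length_from_sums(bk.n[st] - 1, bk.Sr[st] - rt,
                                       bk.Sc[st] - ct,
                                       bk.Srr[st] - (long long)rt * rt,
                                       bk.Scc[st] - (long long)ct * ct,
                                       bk.Src[st] - (long long)rt * ct);
          double Lt = Lv[st - 1];
          dh += lamLv[st - 1] * ((Lt - l1) * (Lt - l1) -
                                 (Lt - l0) * (Lt - l0));
        }
        if (conn_on && splits_locally(labels, rt, ct, st))
          dh += conn_penalty;
      }
      // chemotaxis bias, taken for the active (moving) cell's kind
      int active = (ss > 0) ? ss : st;
      double lc = lcv[active - 1];
      if (lc != 0.0 && !(contact_inhibition && ss > 0 && st > 0)) {
        dh += lc * (C[fs] - C[ft]);
      }
      bool accept = (dh <= 0.0) || (unif_rand() < std::exp(-dh / mu));
      if (accept) {
        L[ft] = ss;
        if (ss > 0) {
          bk.n[ss]++; bk.Sr[ss] += rt; bk.Sc[ss] += ct;
          bk.Srr[ss] += (long long)rt * rt;
          bk.Scc[ss] += (long long)ct * ct;
          bk.Src[ss] += (long long)rt * ct;
        }
        if (st > 0) {
          bk.n[st]--; bk.Sr[st] -= rt; bk.Sc[st] -= ct;
          bk.Srr[st] -= (long long)rt * rt;
          bk.Scc[st] -= (long long)ct * ct;
          bk.Src[st] -= (long long)rt * ct;
        }
      }
    }
    if (do_field) {
      field_steps_inplace(cfield, labels, alpha, eps, Dcoef, dt, dx,
                          steps_per_mcs, scratch);
    }
  }
  NumericVector area(ncell), cr(ncell), cc(ncell), len(ncell);
  for (int i = 1; i <= ncell; ++i) {
    area[i - 1] = (double)bk.n[i];
    cr[i - 1] = bk.n[i] > 0 ? (double)bk.Sr[i] / bk.n[i] + 1.0 : NA_REAL;
    cc[i - 1] = bk.n[i] > 0 ? (double)bk.Sc[i] / bk.n[i] + 1.0 : NA_REAL;
    len[i - 1] = length_from_sums(bk.n[i], bk.Sr[i], bk.Sc[i], bk.Srr[i],
                                  bk.Scc[i], bk.Src[i]);
  }
  return List::create(_["labels"] = labels, _["chem"] = cfield,
                      _["area"] = area, _["centroid_row"] = cr,
                      _["centroid_col"] = cc, _["length"] = len);
}

// Zhang-Suen thinning of a binary mask to a 1-site-wide skeleton.
// [[Rcpp::export(name = ".thin_cpp")]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img = clone(mask);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) img(r, c) = img(r, c) > 0 ? 1 : 0;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img(r, c);
  };
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!img(r, c)) continue;
          int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
              p5 = at(r + 1, c + 1), p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
              p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      for (auto& rc : kill) img(rc.first, rc.second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}
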