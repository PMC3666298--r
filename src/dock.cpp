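// Hot path of the docking energy model: gene vector -> ligand coordinates and
// pairwise energy sums. The scalar R term functions are the reference
// implementation; this kernel evaluates the identical forms over precomputed
// per-pair coefficient tables (see make_energy_context()).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct EnergyCtx {
  NumericMatrix rec, lig;
  IntegerVector bparent, bchild;
  List bmoved;
  IntegerVector inter_ri, inter_li, intra_i, intra_j;
  NumericVector iA, iB, iC, iD, iqq, idsol;
  NumericVector aA, aB, aC, aD, aqq, adsol;
  double cutoff2, sigma2, dA, dB, dlambda, dk;
  int n_torsions;

  explicit EnergyCtx(const List& ctx)
      : rec(as<NumericMatrix>(ctx["rec_coords"])),
        lig(as<NumericMatrix>(ctx["lig_coords"])),
        bparent(as<IntegerVector>(ctx["branch_parent"])),
        bchild(as<IntegerVector>(ctx["branch_child"])),
        bmoved(as<List>(ctx["branch_moved"])),
        inter_ri(as<IntegerVector>(ctx["inter_ri"])),
        inter_li(as<IntegerVector>(ctx["inter_li"])),
        intra_i(as<IntegerVector>(ctx["intra_i"])),
        intra_j(as<IntegerVector>(ctx["intra_j"])),
        iA(as<NumericVector>(ctx["inter_A"])), iB(as<NumericVector>(ctx["inter_B"])),
        iC(as<NumericVector>(ctx["inter_C"])), iD(as<NumericVector>(ctx["inter_D"])),
        iqq(as<NumericVector>(ctx["inter_qq"])), idsol(as<NumericVector>(ctx["inter_dsol"])),
        aA(as<NumericVector>(ctx["intra_A"])), aB(as<NumericVector>(ctx["intra_B"])),
        aC(as<NumericVector>(ctx["intra_C"])), aD(as<NumericVector>(ctx["intra_D"])),
        aqq(as<NumericVector>(ctx["intra_qq"])), adsol(as<NumericVector>(ctx["intra_dsol"])) {
    double cutoff = as<double>(ctx["cutoff"]);
    cutoff2 = cutoff * cutoff;
    double sigma = as<double>(ctx["sigma"]);
    sigma2 = sigma * sigma;
    dA = as<double>(ctx["diel_A"]);
    dB = as<double>(ctx["diel_B"]);
    dlambda = as<double>(ctx["diel_lambda"]);
    dk = as<double>(ctx["diel_k"]);
    n_torsions = as<int>(ctx["n_torsions"]);
  }
};

void rodrigues(const double* u, double ang, double R[3][3]) {
  double c = std::cos(ang), s = std::sin(ang), v = 1.0 - c;
  double ux = u[0], uy = u[1], uz = u[2];
  R[0][0] = c + ux * ux * v;      R[0][1] = ux * uy * v - uz * s; R[0][2] = ux * uz * v + uy * s;
  R[1][0] = uy * ux * v + uz * s; R[1][1] = c + uy * uy * v;      R[1][2] = uy * uz * v - ux * s;
  R[2][0] = uz * ux * v - uy * s; R[2][1] = uz * uy * v + ux * s; R[2][2] = c + uz * uz * v;
}

// genes = [t(3), q(4), torsions(n)] -> posed ligand coordinates
void genes_to_coords(const EnergyCtx& c, const double* genes, std::vector<double>& out) {
  const int n = c.lig.nrow();
  out.resize(3 * n);
  for (int i = 0; i < n; ++i) {
    out[3 * i] = c.lig(i, 0);
    out[3 * i + 1] = c.lig(i, 1);
    out[3 * i + 2] = c.lig(i, 2);
  }
  const int nb = c.bparent.size();
  for (int j = nb - 1; j >= 0; --j) {   // innermost (leaves) first
    double ang = genes[7 + j];
    if (ang == 0.0) continue;
    int p = c.bparent[j] - 1, ch = c.bchild[j] - 1;
    double px = out[3 * p], py = out[3 * p + 1], pz = out[3 * p + 2];
    double ax[3] = {out[3 * ch] - px, out[3 * ch + 1] - py, out[3 * ch + 2] - pz};
    double nrm = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    ax[0] /= nrm; ax[1] /= nrm; ax[2] /= nrm;
    double R[3][3];
    rodrigues(ax, ang, R);
    IntegerVector moved = c.bmoved[j];
    for (int m = 0; m < moved.size(); ++m) {
      int a = moved[m] - 1;
      double dx = out[3 * a] - px, dy = out[3 * a + 1] - py, dz = out[3 * a + 2] - pz;
      out[3 * a] = R[0][0] * dx + R[0][1] * dy + R[0][2] * dz + px;
      out[3 * a + 1] = R[1][0] * dx + R[1][1] * dy + R[1][2] * dz + py;
      out[3 * a + 2] = R[2][0] * dx + R[2][1] * dy + R[2][2] * dz + pz;
    }
  }
  // centroid
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += out[3 * i]; cy += out[3 * i + 1]; cz += out[3 * i + 2]; }
  cx /= n; cy /= n; cz /= n;
  // orientation quaternion (w, x, y, z), normalized defensively
  double w = genes[3], x = genes[4], y = genes[5], z = genes[6];
  double qn = std::sqrt(w * w + x * x + y * y + z * z);
  if (qn < 1e-12) { w = 1; x = y = z = 0; } else { w /= qn; x /= qn; y /= qn; z /= qn; }
  double Q[3][3] = {
    {1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y)},
    {2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x)},
    {2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)}};
  for (int i = 0; i < n; ++i) {
    double dx = out[3 * i] - cx, dy = out[3 * i + 1] - cy, dz = out[3 * i + 2] - cz;
    out[3 * i] = Q[0][0] * dx + Q[0][1] * dy + Q[0][2] * dz + genes[0];
    out[3 * i + 1] = Q[1][0] * dx + Q[1][1] * dy + Q[1][2] * dz + genes[1];
    out[3 * i + 2] = Q[2][0] * dx + Q[2][1] * dy + Q[2][2] * dz + genes[2];
  }
}

struct Terms { double ev = 0, eh = 0, ee = 0, ed = 0; };

inline void pair_terms(const EnergyCtx& c, double dx, double dy, double dz,
                       double A, double B, double C, double D, double qq,
                       double dsol, Terms& t) {
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 > c.cutoff2) return;
  double r = std::sqrt(r2);
  double r2i = 1.0 / r2;
  double r6i = r2i * r2i * r2i;
  double r12i = r6i * r6i;
  double r10i = r12i * r2;
  t.ev += A * r12i - B * r6i;
  t.eh += C * r12i - D * r10i;
  double eps = c.dA + c.dB / (1.0 + c.dk * std::exp(-c.dlambda * c.dB * r));
  t.ee += qq / (eps * r);
  t.ed += dsol * std::exp(-r2 / (2.0 * c.sigma2));
}

void energy_components(const EnergyCtx& c, const double* genes, double out[6]) {
  std::vector<double> L;
  genes_to_coords(c, genes, L);
  Terms inter;
  const int np = c.inter_ri.size();
  for (int p = 0; p < np; ++p) {
    int ir = c.inter_ri[p] - 1, il = c.inter_li[p] - 1;
    pair_terms(c, c.rec(ir, 0) - L[3 * il], c.rec(ir, 1) - L[3 * il + 1],
               c.rec(ir, 2) - L[3 * il + 2],
               c.iA[p], c.iB[p], c.iC[p], c.iD[p], c.iqq[p], c.idsol[p], inter);
  }
  Terms intra;
  const int na = c.intra_i.size();
  for (int p = 0; p < na; ++p) {
    int i = c.intra_i[p] - 1, j = c.intra_j[p] - 1;
    pair_terms(c, L[3 * i] - L[3 * j], L[3 * i + 1] - L[3 * j + 1],
               L[3 * i + 2] - L[3 * j + 2],
               c.aA[p], c.aB[p], c.aC[p], c.aD[p], c.aqq[p], c.adsol[p], intra);
  }
  out[0] = inter.ev;
  out[1] = inter.eh;
  out[2] = inter.ee;
  out[3] = intra.ev + intra.eh + intra.ee + intra.ed;  // ligand internal
  out[4] = inter.ed;
  out[5] = out[0] + out[1] + out[2] + out[3] + out[4];
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_pose_coords(List ctx, NumericVector genes) {
  EnergyCtx c(ctx);
  if ((int)genes.size() != 7 + c.n_torsions) stop("gene vector length mismatch");
  std::vector<double> L;
  genes_to_coords(c, genes.begin(), L);
  int n = c.lig.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = L[3 * i]; out(i, 1) = L[3 * i + 1]; out(i, 2) = L[3 * i + 2];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_energy_breakdown(List ctx, NumericVector genes) {
  EnergyCtx c(ctx);
  if ((int)genes.size() != 7 + c.n_torsions) stop("gene vector length mismatch");
  double out[6];
  energy_components(c, genes.begin(), out);
  return NumericVector::create(out[0], out[1], out[2], out[3], out[4], out[5]);
}

// [[Rcpp::export]]
NumericVector cpp_energy_batch(List ctx, NumericMatrix genes) {
  EnergyCtx c(ctx);
  if (genes.ncol() != 7 + c.n_torsions) stop("gene matrix has wrong number of columns");
  int n = genes.nrow();
  NumericVector out(n);
  std::vector<double> row(genes.ncol());
  double comp[6];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < genes.ncol(); ++j) row[j] = genes(i, j);
    energy_components(c, row.data(), comp);
    out[i] = comp[5];
  }
  return out;
}

// Solis-Wets local search on the precomputed energy context. Draws from R's
// random number stream (one normal per gene per iteration, exactly like the
// R reference implementation in solis_wets()), so trajectories are identical.
// [[Rcpp::export]]
List cpp_solis_wets(List ctx, NumericVector genes, double e0,
                    NumericVector scales, NumericVector lower,
                    NumericVector upper, LogicalVector frozen,
                    double rho0, double lb, int n_succ_max, int n_fail_max,
                    int max_iter) {
  EnergyCtx c(ctx);
  const int g = genes.size();
  if (g != 7 + c.n_torsions) stop("gene vector length mismatch");
  std::vector<double> x(genes.begin(), genes.end());
  double e = e0;
  double rho = rho0;
  int n_succ = 0, n_fail = 0, n_evals = 0;
  std::vector<double> d(g), cand(g);
  double comp[6];

  auto repair = [&](std::vector<double>& v) {
    for (int j = 0; j < g; ++j) {
      if (R_FINITE(lower[j]) && v[j] < lower[j]) v[j] = lower[j];
      if (R_FINITE(upper[j]) && v[j] > upper[j]) v[j] = upper[j];
    }
    double qn = std::sqrt(v[3] * v[3] + v[4] * v[4] + v[5] * v[5] + v[6] * v[6]);
    if (qn < 1e-12) { v[3] = 1; v[4] = v[5] = v[6] = 0; }
    else { v[3] /= qn; v[4] /= qn; v[5] /= qn; v[6] /= qn; }
    for (int j = 7; j < g; ++j) {
      v[j] = v[j] - 2.0 * M_PI * std::ceil((v[j] - M_PI) / (2.0 * M_PI));
    }
  };

  for (int iter = 0; iter < max_iter; ++iter) {
    if (rho < lb) break;
    for (int j = 0; j < g; ++j) {
      d[j] = norm_rand() * scales[j] * rho;
      if (frozen[j]) d[j] = 0.0;
    }
    bool improved = false;
    for (int j = 0; j < g; ++j) cand[j] = x[j] + d[j];
    repair(cand);
    energy_components(c, cand.data(), comp);
    ++n_evals;
    if (comp[5] < e) {
      x = cand; e = comp[5]; improved = true;
    } else {
      for (int j = 0; j < g; ++j) cand[j] = x[j] - d[j];
      repair(cand);
      energy_components(c, cand.data(), comp);
      ++n_evals;
      if (comp[5] < e) { x = cand; e = comp[5]; improved = true; }
    }
    if (improved) {
      if (++n_succ >= n_succ_max) { rho *= 2.0; n_succ = 0; }
      n_fail = 0;
    } else {
      if (++n_fail >= n_fail_max) { rho /= 2.0; n_fail = 0; }
      n_succ = 0;
    }
  }
  return List::create(_["genes"] = NumericVector(x.begin(), x.end()),
                      _["energy"] = e, _["n_evals"] = n_evals);
}
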