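// Overdamped Langevin dynamics of bead-spring chromosome chains in a
// spherical nucleus, plus trajectory contact statistics.  Energies in kT,
// lengths in nm, friction coefficient gamma sets the time unit.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// xoshiro-free deterministic RNG: splitmix64-seeded mt19937_64 with an
// explicit Box-Muller transform so draws do not depend on library internals.
struct Gauss {
  std::uint64_t s;
  bool has_spare = false;
  double spare = 0.0;
  explicit Gauss(std::uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  double unif() { // splitmix64, mapped to (0,1)
    std::uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    z = z ^ (z >> 31);
    return (static_cast<double>(z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() { // Marsaglia polar method
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

inline double dist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Neighbour (Verlet) pair list with per-pair interaction cutoff.  Small
// beads are binned in a cell grid; the few enlarged (rDNA) beads are paired
// by a direct sweep since their cutoff would inflate the cells.
struct PairList {
  std::vector<int> ia, ib;
  std::vector<double> cut; // interaction cutoff (mean diameter) per pair
};

void buildPairList(const std::vector<double>& x, const NumericVector& diam,
                   double skin, double small_max, PairList& pl) {
  const int n = diam.size();
  pl.ia.clear(); pl.ib.clear(); pl.cut.clear();
  std::vector<int> small_idx, big_idx;
  for (int i = 0; i < n; ++i)
    (diam[i] <= small_max ? small_idx : big_idx).push_back(i);

  // cell grid over the bounding box of small beads
  if (!small_idx.empty()) {
    double cell = small_max + skin;
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i : small_idx)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], x[3 * i + d]);
        hi[d] = std::max(hi[d], x[3 * i + d]);
      }
    int nc[3];
    for (int d = 0; d < 3; ++d)
      nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
    const int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(n, -1), cidx(n, 0);
    for (int i : small_idx) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        c[d] = (int)std::floor((x[3 * i + d] - lo[d]) / cell);
        c[d] = std::min(std::max(c[d], 0), nc[d] - 1);
      }
      int cc = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
      cidx[i] = cc; nxt[i] = head[cc]; head[cc] = i;
    }
    for (int i : small_idx) {
      int c0 = cidx[i] % nc[0];
      int c1 = (cidx[i] / nc[0]) % nc[1];
      int c2 = cidx[i] / (nc[0] * nc[1]);
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int a0 = c0 + dx, a1 = c1 + dy, a2 = c2 + dz;
          if (a0 < 0 || a1 < 0 || a2 < 0 || a0 >= nc[0] || a1 >= nc[1] || a2 >= nc[2])
            continue;
          for (int j = head[(a2 * nc[1] + a1) * nc[0] + a0]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;
            double cij = 0.5 * (diam[i] + diam[j]);
            double lim = cij + skin;
            double dx0 = x[3*i] - x[3*j], dx1 = x[3*i+1] - x[3*j+1],
                   dx2 = x[3*i+2] - x[3*j+2];
            if (dx0*dx0 + dx1*dx1 + dx2*dx2 < lim * lim) {
              pl.ia.push_back(i); pl.ib.push_back(j); pl.cut.push_back(cij);
            }
          }
        }
    }
  }
  for (size_t bi = 0; bi < big_idx.size(); ++bi) {
    int i = big_idx[bi];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (diam[j] > small_max && j < i) continue; // big-big once
      double cij = 0.5 * (diam[i] + diam[j]);
      double lim = cij + skin;
      double dx0 = x[3*i] - x[3*j], dx1 = x[3*i+1] - x[3*j+1],
             dx2 = x[3*i+2] - x[3*j+2];
      if (dx0*dx0 + dx1*dx1 + dx2*dx2 < lim * lim) {
        pl.ia.push_back(std::min(i, j)); pl.ib.push_back(std::max(i, j));
        pl.cut.push_back(cij);
      }
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos0, NumericVector diam,
                      IntegerMatrix bonds, NumericVector bond_r0,
                      double k_bond, double max_ext_factor,
                      IntegerMatrix angles, NumericVector angle_k,
                      double k_ev, double r_nucleus, double k_wall,
                      IntegerVector cent_idx, NumericVector spb,
                      double L_spb, double k_spb,
                      IntegerVector telo_idx, double f_telo, double telo_shell,
                      double dt, double kT, double gamma,
                      int n_steps, int sample_every, int equil_steps,
                      double max_disp, double skin, double small_max,
                      double seed) {
  const int n = pos0.nrow();
  std::vector<double> x(3 * n), f(3 * n), xref(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos0(i, d);

  const int nb = bonds.nrow(), na = angles.nrow();
  const bool pairs_on = k_ev > 0.0;
  const bool wall_on = r_nucleus > 0.0;
  Gauss rng(static_cast<std::uint64_t>(seed));
  const double mob = dt / gamma;
  const double kick = std::sqrt(2.0 * kT * dt / gamma);

  PairList pl;
  double drift2max = 0.0;
  if (pairs_on) { buildPairList(x, diam, skin, small_max, pl); xref = x; }

  std::vector<double> frames, rg_samp, en_samp;
  std::vector<int> step_samp;
  const int nkeep = (n_steps > equil_steps && sample_every > 0)
      ? (n_steps - equil_steps) / sample_every : 0;
  frames.reserve((size_t)nkeep * 3 * n);

  for (int step = 1; step <= n_steps; ++step) {
    std::fill(f.begin(), f.end(), 0.0);

    // finitely extensible bonds, symmetric about rest length r0
    for (int b = 0; b < nb; ++b) {
      int i = bonds(b, 0), j = bonds(b, 1);
      double dx[3], r2 = 0.0;
      for (int d = 0; d < 3; ++d) { dx[d] = x[3*i+d] - x[3*j+d]; r2 += dx[d]*dx[d]; }
      double r = std::sqrt(r2);
      if (r < 1e-12) continue;
      double r0 = bond_r0[b];
      double delta = (max_ext_factor - 1.0) * r0;
      double e = r - r0;
      double em = 0.999 * delta;
      if (e > em) e = em; else if (e < -em) e = -em;
      double denom = 1.0 - (e / delta) * (e / delta);
      double fmag = -k_bond * e / denom; // >0 pushes apart when compressed
      for (int d = 0; d < 3; ++d) {
        double fd = fmag * dx[d] / r;
        f[3*i+d] += fd; f[3*j+d] -= fd;
      }
    }

    // bending: U = k (1 - cos theta) per bead triplet
    for (int a = 0; a < na; ++a) {
      int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
      double b1[3], b2[3], n1 = 0.0, n2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        b1[d] = x[3*j+d] - x[3*i+d]; n1 += b1[d]*b1[d];
        b2[d] = x[3*k+d] - x[3*j+d]; n2 += b2[d]*b2[d];
      }
      if (n1 < 1e-24 || n2 < 1e-24) continue;
      double in1 = 1.0 / std::sqrt(n1), in2 = 1.0 / std::sqrt(n2);
      double c = 0.0;
      for (int d = 0; d < 3; ++d) c += b1[d] * b2[d];
      c *= in1 * in2;
      double ka = angle_k[a];
      for (int d = 0; d < 3; ++d) {
        double e1 = b1[d] * in1, e2 = b2[d] * in2;
        double fi = -ka * (e2 - c * e1) * in1; // ka * dc/dri
        double fk =  ka * (e1 - c * e2) * in2;
        f[3*i+d] += fi; f[3*k+d] += fk; f[3*j+d] -= (fi + fk);
      }
    }

    // excluded volume: harmonic overlap repulsion, contact at mean diameter
    if (pairs_on) {
      const size_t np = pl.ia.size();
      for (size_t p = 0; p < np; ++p) {
        int i = pl.ia[p], j = pl.ib[p];
        double dx[3], r2 = 0.0;
        for (int d = 0; d < 3; ++d) { dx[d] = x[3*i+d] - x[3*j+d]; r2 += dx[d]*dx[d]; }
        double cij = pl.cut[p];
        if (r2 >= cij * cij) continue;
        double r = std::sqrt(r2);
        if (r < 1e-9) r = 1e-9;
        double fmag = k_ev * (cij - r);
        for (int d = 0; d < 3; ++d) {
          double fd = fmag * dx[d] / r;
          f[3*i+d] += fd; f[3*j+d] -= fd;
        }
      }
    }

    // confinement + telomere envelope attraction
    if (wall_on) {
      for (int i = 0; i < n; ++i) {
        double r2 = x[3*i]*x[3*i] + x[3*i+1]*x[3*i+1] + x[3*i+2]*x[3*i+2];
        double rmax = r_nucleus - 0.5 * diam[i];
        if (r2 > rmax * rmax) {
          double r = std::sqrt(r2);
          double fmag = -k_wall * (r - rmax);
          for (int d = 0; d < 3; ++d) f[3*i+d] += fmag * x[3*i+d] / r;
        }
      }
      for (int t = 0; t < telo_idx.size(); ++t) {
        int i = telo_idx[t];
        double r = std::sqrt(x[3*i]*x[3*i] + x[3*i+1]*x[3*i+1] + x[3*i+2]*x[3*i+2]);
        double rmax = r_nucleus - 0.5 * diam[i];
        if (r > rmax - telo_shell && r > 1e-12)
          for (int d = 0; d < 3; ++d) f[3*i+d] += f_telo * x[3*i+d] / r;
      }
    }

    // SPB tether on centromeric beads
    for (int t = 0; t < cent_idx.size(); ++t) {
      int i = cent_idx[t];
      double u[3], r2 = 0.0;
      for (int d = 0; d < 3; ++d) { u[d] = x[3*i+d] - spb[d]; r2 += u[d]*u[d]; }
      double r = std::sqrt(r2);
      if (r < 1e-12) continue;
      double fmag = -k_spb * (r - L_spb);
      for (int d = 0; d < 3; ++d) f[3*i+d] += fmag * u[d] / r;
    }

    // Euler-Maruyama update with per-bead displacement cap
    double step_max2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx[3], d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        dx[d] = mob * f[3*i+d] + kick * rng.norm();
        d2 += dx[d] * dx[d];
      }
      if (d2 > max_disp * max_disp) {
        double sc = max_disp / std::sqrt(d2);
        for (int d = 0; d < 3; ++d) dx[d] *= sc;
        d2 = max_disp * max_disp;
      }
      for (int d = 0; d < 3; ++d) x[3*i+d] += dx[d];
      if (pairs_on) {
        double drift2 = 0.0;
        for (int d = 0; d < 3; ++d) {
          double dd = x[3*i+d] - xref[3*i+d];
          drift2 += dd * dd;
        }
        if (drift2 > drift2max) drift2max = drift2;
      }
    }
    if (pairs_on && drift2max > 0.25 * skin * skin) {
      buildPairList(x, diam, skin, small_max, pl);
      xref = x; drift2max = 0.0;
    }

    if (step > equil_steps && sample_every > 0 && (step - equil_steps) % sample_every == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(x[3*i]) || !std::isfinite(x[3*i+1]) || !std::isfinite(x[3*i+2]))
          stop("non-finite coordinate at step %d (bead %d): reduce dt", step, i + 1);
      }
      for (int i = 0; i < 3 * n; ++i) frames.push_back(x[i]);
      step_samp.push_back(step);
      // radius of gyration
      double cm[3] = {0, 0, 0};
      for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) cm[d] += x[3*i+d];
      for (int d = 0; d < 3; ++d) cm[d] /= n;
      double rg2 = 0.0;
      for (int i = 0; i < n; ++i) for (int d = 0; d < 3; ++d) {
        double dd = x[3*i+d] - cm[d]; rg2 += dd * dd;
      }
      rg_samp.push_back(std::sqrt(rg2 / n));
      // potential energy
      double en = 0.0;
      for (int b = 0; b < nb; ++b) {
        int i = bonds(b, 0), j = bonds(b, 1);
        double r = dist3(&x[3*i], &x[3*j]);
        double r0 = bond_r0[b], delta = (max_ext_factor - 1.0) * r0;
        double e = std::min(std::max(r - r0, -0.999 * delta), 0.999 * delta);
        en += -0.5 * k_bond * delta * delta * std::log(1.0 - (e/delta)*(e/delta));
      }
      for (int a = 0; a < na; ++a) {
        int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
        double b1[3], b2[3], n1 = 0, n2 = 0, c = 0;
        for (int d = 0; d < 3; ++d) {
          b1[d] = x[3*j+d]-x[3*i+d]; n1 += b1[d]*b1[d];
          b2[d] = x[3*k+d]-x[3*j+d]; n2 += b2[d]*b2[d];
        }
        n1 = std::sqrt(n1); n2 = std::sqrt(n2);
        if (n1 > 1e-12 && n2 > 1e-12) {
          for (int d = 0; d < 3; ++d) c += b1[d]*b2[d]/(n1*n2);
          en += angle_k[a] * (1.0 - c);
        }
      }
      if (pairs_on) {
        for (size_t p = 0; p < pl.ia.size(); ++p) {
          double r = dist3(&x[3*pl.ia[p]], &x[3*pl.ib[p]]);
          if (r < pl.cut[p]) en += 0.5 * k_ev * (pl.cut[p]-r) * (pl.cut[p]-r);
        }
      }
      if (wall_on) {
        for (int i = 0; i < n; ++i) {
          double r = std::sqrt(x[3*i]*x[3*i] + x[3*i+1]*x[3*i+1] + x[3*i+2]*x[3*i+2]);
          double ex = r - (r_nucleus - 0.5*diam[i]);
          if (ex > 0) en += 0.5 * k_wall * ex * ex;
        }
      }
      for (int t = 0; t < cent_idx.size(); ++t) {
        double r = dist3(&x[3*cent_idx[t]], &spb[0]);
        en += 0.5 * k_spb * (r - L_spb) * (r - L_spb);
      }
      en_samp.push_back(en);
    }
  }

  NumericVector fr(frames.begin(), frames.end());
  fr.attr("dim") = IntegerVector::create(3, n, (int)step_samp.size());
  return List::create(_["frames"] = fr,
                      _["steps"] = IntegerVector(step_samp.begin(), step_samp.end()),
                      _["rg"] = NumericVector(rg_samp.begin(), rg_samp.end()),
                      _["energy"] = NumericVector(en_samp.begin(), en_samp.end()));
}

// Contact statistics over a trajectory.  frames has dim (3, n, nframes);
// contacts are bead pairs closer than `cutoff`.  Returns per-chain-pair
// contact counts, intra-chain contact counts by bead separation (genome-wide
// and restricted to pairs involving the centromere bead), and counts per
// genomic-bin pair.
// [[Rcpp::export]]
List cpp_contact_stats(NumericVector frames, IntegerVector chain_id,
                       IntegerVector bin_id, IntegerVector cent_idx,
                       double cutoff, int max_sep, int n_chain, int n_bin) {
  IntegerVector dims = frames.attr("dim");
  const int n = dims[1], nf = dims[2];
  const double* fr = REAL(frames);

  NumericMatrix chain_counts(n_chain, n_chain);
  NumericVector sep_counts(max_sep);   // index s-1 for separation s
  NumericMatrix bin_counts(n_bin, n_bin);

  // cell grid per frame with cell size = cutoff
  std::vector<int> head, nxt(n), cidx(n);
  for (int t = 0; t < nf; ++t) {
    const double* x = fr + (size_t)t * 3 * n;
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], x[3*i+d]); hi[d] = std::max(hi[d], x[3*i+d]);
      }
    int nc[3];
    for (int d = 0; d < 3; ++d)
      nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cutoff) + 1);
    head.assign((size_t)nc[0] * nc[1] * nc[2], -1);
    for (int i = 0; i < n; ++i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        c[d] = std::min(std::max((int)std::floor((x[3*i+d] - lo[d]) / cutoff), 0), nc[d] - 1);
      }
      int cc = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
      cidx[i] = cc; nxt[i] = head[cc]; head[cc] = i;
    }
    for (int i = 0; i < n; ++i) {
      int c0 = cidx[i] % nc[0], c1 = (cidx[i] / nc[0]) % nc[1], c2 = cidx[i] / (nc[0]*nc[1]);
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int a0 = c0+dx, a1 = c1+dy, a2 = c2+dz;
          if (a0 < 0 || a1 < 0 || a2 < 0 || a0 >= nc[0] || a1 >= nc[1] || a2 >= nc[2])
            continue;
          for (int j = head[(a2*nc[1]+a1)*nc[0]+a0]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;
            if (dist3(&x[3*i], &x[3*j]) >= cutoff) continue;
            int ci = chain_id[i], cj = chain_id[j];
            chain_counts(std::min(ci,cj), std::max(ci,cj)) += 1.0;
            if (ci == cj) {
              int s = std::abs(i - j);
              if (s >= 1 && s <= max_sep) sep_counts[s - 1] += 1.0;
            }
            int bi = bin_id[i], bj = bin_id[j];
            bin_counts(std::min(bi,bj), std::max(bi,bj)) += 1.0;
          }
        }
    }
  }

  // centromere-anchored contact frequency by separation: direct distances
  NumericVector cen_counts(max_sep), cen_pairs(max_sep);
  for (int ci = 0; ci < cent_idx.size(); ++ci) {
    int ic = cent_idx[ci];
    int ch = chain_id[ic];
    for (int s = 1; s <= max_sep; ++s) {
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        int j = ic + sgn * s;
        if (j < 0 || j >= n || chain_id[j] != ch) continue;
        cen_pairs[s - 1] += nf;
        for (int t = 0; t < nf; ++t) {
          const double* x = fr + (size_t)t * 3 * n;
          if (dist3(&x[3*ic], &x[3*j]) < cutoff) cen_counts[s - 1] += 1.0;
        }
      }
    }
  }

  return List::create(_["chain_counts"] = chain_counts,
                      _["sep_counts"] = sep_counts,
                      _["cen_counts"] = cen_counts,
                      _["cen_pairs"] = cen_pairs,
                      _["bin_counts"] = bin_counts,
                      _["n_frames"] = nf);
}

// Minimum distance between any two non-adjacent bonds over a trajectory
// (chain-crossing monitor for small systems).
// [[Rcpp::export]]
double cpp_min_bond_gap(NumericVector frames, IntegerMatrix bonds) {
  IntegerVector dims = frames.attr("dim");
  const int n = dims[1], nf = dims[2], nb = bonds.nrow();
  const double* fr = REAL(frames);
  double best = R_PosInf;
  for (int t = 0; t < nf; ++t) {
    const double* x = fr + (size_t)t * 3 * n;
    for (int a = 0; a < nb; ++a) {
      for (int b = a + 1; b < nb; ++b) {
        int i1 = bonds(a,0), j1 = bonds(a,1), i2 = bonds(b,0), j2 = bonds(b,1);
        if (i1 == i2 || i1 == j2 || j1 == i2 || j1 == j2) continue;
        // segment-segment distance
        double p1[3], d1[3], p2[3], d2[3], r[3];
        for (int d = 0; d < 3; ++d) {
          p1[d] = x[3*i1+d]; d1[d] = x[3*j1+d] - p1[d];
          p2[d] = x[3*i2+d]; d2[d] = x[3*j2+d] - p2[d];
          r[d] = p1[d] - p2[d];
        }
        double a11 = 0, a22 = 0, a12 = 0, b1 = 0, b2 = 0;
        for (int d = 0; d < 3; ++d) {
          a11 += d1[d]*d1[d]; a22 += d2[d]*d2[d]; a12 += d1[d]*d2[d];
          b1 += d1[d]*r[d]; b2 += d2[d]*r[d];
        }
        double det = a11*a22 - a12*a12;
        double s, u;
        if (det > 1e-12) {
          s = (a12*b2 - a22*b1) / det;
          u = (a11*b2 - a12*b1) / det;
        } else { s = 0; u = (a22 > 1e-12) ? b2/a22 : 0; }
        s = std::min(std::max(s, 0.0), 1.0);
        u = std::min(std::max(u, 0.0), 1.0);
        double dd = 0.0;
        for (int d = 0; d < 3; ++d) {
          double g = (p1[d] + s*d1[d]) - (p2[d] + u*d2[d]);
          dd += g*g;
        }
        if (dd < best) best = dd;
      }
    }
  }
  return std::sqrt(best);
}
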