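#include <Rcpp.h>
#include <map>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Locally one-dimensional (LOD) backward-Euler diffusion + pointwise implicit
// decay on a regular 2D voxel grid. Dirichlet voxels (mask) are held at the
// boundary value by turning their rows of each tridiagonal system into
// identity rows, so boundary flux enters the interior solve naturally.
// ---------------------------------------------------------------------------

static void thomas_line(std::vector<double>& a, std::vector<double>& b,
                        std::vector<double>& c, std::vector<double>& d) {
  // in-place Thomas solve; a sub, b diag, c super, d rhs -> solution in d
  int n = d.size();
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

// Precomputed Thomas factorization for the "standard line": Dirichlet
// identity rows at both ends, uniform interior coefficients. All interior
// grid lines share this system, so the elimination is done once per sweep
// and each line solve needs no divisions.
struct line_factor {
  std::vector<double> w;     // forward elimination multipliers
  std::vector<double> binv;  // reciprocal pivots
  std::vector<double> sup;   // super-diagonal
  void build(int n, double k) {
    std::vector<double> diag(n), sub(n, 0.0);
    sup.assign(n, 0.0);
    for (int i = 0; i < n; ++i) {
      if (i == 0 || i == n - 1) {
        diag[i] = 1.0;
      } else {
        diag[i] = 1.0 + 2.0 * k;
        sub[i] = -k;
        sup[i] = -k;
      }
    }
    w.assign(n, 0.0);
    for (int i = 1; i < n; ++i) {
      w[i] = sub[i] / diag[i - 1];
      diag[i] -= w[i] * sup[i - 1];
    }
    binv.assign(n, 0.0);
    for (int i = 0; i < n; ++i) binv[i] = 1.0 / diag[i];
  }
};

// solve a standard line in place with the cached factorization
static inline void solve_standard(const line_factor& F, double* d, int n) {
  for (int i = 1; i < n; ++i) d[i] -= F.w[i] * d[i - 1];
  d[n - 1] *= F.binv[n - 1];
  for (int i = n - 2; i >= 0; --i)
    d[i] = (d[i] - F.sup[i] * d[i + 1]) * F.binv[i];
}

// one LOD step in place; returns decayed concentration-sum via `decayed`
static void lod_step(NumericMatrix& u, const LogicalMatrix& mask, double D,
                     double lambda, double dt, double dx,
                     double dirichlet_value, double& decayed) {
  int nx = u.nrow(), ny = u.ncol();
  double k = D * dt / (dx * dx);
  double* up = REAL(u);
  const int* mp = LOGICAL(mask);
  std::vector<double> a, b, c, d;
  if (k > 0.0) {
    // classify lines: "standard" = masked at both ends, unmasked interior
    std::vector<char> col_std(ny, 1), row_std(nx, 1);
    for (int j = 0; j < ny; ++j) {
      if (!mp[0 + j * nx] || !mp[(nx - 1) + j * nx]) col_std[j] = 0;
      for (int i = 1; i < nx - 1 && col_std[j]; ++i)
        if (mp[i + j * nx]) col_std[j] = 0;
    }
    for (int i = 0; i < nx; ++i) {
      if (!mp[i + 0 * nx] || !mp[i + (ny - 1) * nx]) row_std[i] = 0;
      for (int j = 1; j < ny - 1 && row_std[i]; ++j)
        if (mp[i + j * nx]) row_std[i] = 0;
    }
    line_factor Fx, Fy;
    Fx.build(nx, k);
    Fy.build(ny, k);
    d.assign(std::max(nx, ny), 0.0);
    // x sweep: solve along each column (contiguous in memory)
    for (int j = 0; j < ny; ++j) {
      double* col = up + (size_t)j * nx;
      if (col_std[j]) {
        col[0] = dirichlet_value;
        col[nx - 1] = dirichlet_value;
        solve_standard(Fx, col, nx);
      } else {
        a.assign(nx, 0.0); b.assign(nx, 0.0); c.assign(nx, 0.0);
        for (int i = 0; i < nx; ++i) {
          if (mp[i + j * nx]) {
            a[i] = 0.0; b[i] = 1.0; c[i] = 0.0; d[i] = dirichlet_value;
          } else {
            double kl = (i > 0) ? k : 0.0;      // no-flux fallback at edges
            double kr = (i < nx - 1) ? k : 0.0; // (edges are normally masked)
            a[i] = -kl; c[i] = -kr; b[i] = 1.0 + kl + kr; d[i] = col[i];
          }
        }
        thomas_line(a, b, c, d);
        for (int i = 0; i < nx; ++i) col[i] = d[i];
      }
    }
    // y sweep: solve along each row (stride nx)
    for (int i = 0; i < nx; ++i) {
      if (row_std[i]) {
        for (int j = 0; j < ny; ++j) d[j] = up[i + (size_t)j * nx];
        d[0] = dirichlet_value;
        d[ny - 1] = dirichlet_value;
        solve_standard(Fy, d.data(), ny);
        for (int j = 0; j < ny; ++j) up[i + (size_t)j * nx] = d[j];
      } else {
        a.assign(ny, 0.0); b.assign(ny, 0.0); c.assign(ny, 0.0);
        for (int j = 0; j < ny; ++j) {
          if (mp[i + j * nx]) {
            a[j] = 0.0; b[j] = 1.0; c[j] = 0.0; d[j] = dirichlet_value;
          } else {
            double kl = (j > 0) ? k : 0.0;
            double kr = (j < ny - 1) ? k : 0.0;
            a[j] = -kl; c[j] = -kr; b[j] = 1.0 + kl + kr;
            d[j] = up[i + (size_t)j * nx];
          }
        }
        thomas_line(a, b, c, d);
        for (int j = 0; j < ny; ++j) up[i + (size_t)j * nx] = d[j];
      }
    }
  }
  // pointwise implicit decay, then re-pin Dirichlet voxels
  double f = 1.0 / (1.0 + lambda * dt);
  int nvox = nx * ny;
  for (int q = 0; q < nvox; ++q) {
    if (mp[q]) {
      up[q] = dirichlet_value;
    } else {
      double before = up[q];
      up[q] = before * f;
      decayed += before - up[q];
    }
  }
}

// [[Rcpp::export(name = ".lod_diffusion_cpp")]]
List lod_diffusion_cpp(NumericMatrix rho, LogicalMatrix mask, double D,
                       double lambda, double dt, double dx,
                       double dirichlet_value) {
  NumericMatrix u = clone(rho);
  double decayed = 0.0;
  lod_step(u, mask, D, lambda, dt, dx, dirichlet_value, decayed);
  return List::create(_["values"] = u, _["decayed"] = decayed);
}

// implicit per-voxel cell uptake in place; each cell's uptaken mass is its
// conservative share U_i V_i rho' dt of what the voxel loses
static void uptake_step(NumericMatrix& v,
                        const std::vector<int>& ix, const std::vector<int>& iy,
                        const std::vector<double>& uv, double dt,
                        double voxel_volume, std::vector<double>& uptake,
                        double& removed) {
  std::map<std::pair<int, int>, double> tot;
  size_t n = ix.size();
  for (size_t c = 0; c < n; ++c)
    tot[std::make_pair(ix[c], iy[c])] += uv[c];
  for (auto& kv : tot) {
    int i = kv.first.first - 1, j = kv.first.second - 1;
    double rho = v(i, j);
    double rho_new = rho / (1.0 + dt * kv.second / voxel_volume);
    v(i, j) = rho_new;
    removed += (rho - rho_new) * voxel_volume;
    kv.second = rho_new;  // reuse: store rho' for the per-cell pass
  }
  for (size_t c = 0; c < n; ++c)
    uptake[c] = uv[c] * tot[std::make_pair(ix[c], iy[c])] * dt;
}

// [[Rcpp::export(name = ".cell_uptake_cpp")]]
List cell_uptake_cpp(NumericMatrix values, IntegerVector ix, IntegerVector iy,
                     NumericVector uv, double dt, double voxel_volume) {
  NumericMatrix v = clone(values);
  std::vector<int> vix(ix.begin(), ix.end()), viy(iy.begin(), iy.end());
  std::vector<double> vuv(uv.begin(), uv.end()), up(ix.size(), 0.0);
  double removed = 0.0;
  uptake_step(v, vix, viy, vuv, dt, voxel_volume, up, removed);
  return List::create(_["values"] = v, _["uptake"] = wrap(up),
                      _["removed"] = removed);
}

// ---------------------------------------------------------------------------
// Fused diffusion tier: nsub repetitions of [set boundary value; LOD
// diffusion-decay; optional bath refresh; per-cell uptake; optional refresh]
// -- numerically identical to composing the single-step operations, but with
// one call per phenotype step. For a saturable substrate (NPs) the uptake
// coefficient U = rI (1 - nI/n*) is refreshed from the running internalized
// count; otherwise the supplied constant U_i V_i rates are used (oxygen).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".diffusion_tier_cpp")]]
List diffusion_tier_cpp(NumericMatrix rho, LogicalMatrix mask, double D,
                        double lambda, double dt, double dx,
                        double voxel_volume,
                        NumericVector dirichlet_values,  // length nsub
                        IntegerVector ix, IntegerVector iy,
                        NumericVector uv_const, NumericVector volumes,
                        NumericVector nI0, double rI, double n_star,
                        bool saturable, bool refresh) {
  int nsub = dirichlet_values.size();
  int n = ix.size();
  NumericMatrix u = clone(rho);
  int nvox = u.nrow() * u.ncol();
  std::vector<int> vix(ix.begin(), ix.end()), viy(iy.begin(), iy.end());
  std::vector<double> nI(nI0.begin(), nI0.end());
  std::vector<double> acc(n, 0.0), up(n, 0.0), uv(n, 0.0);
  double decayed = 0.0, boundary = 0.0, removed = 0.0;
  for (int s = 0; s < nsub; ++s) {
    double dv = dirichlet_values[s];
    double mass_before = 0.0;
    for (int q = 0; q < nvox; ++q) mass_before += u[q];
    double dec0 = decayed;
    lod_step(u, mask, D, lambda, dt, dx, dv, decayed);
    double mass_after = 0.0;
    for (int q = 0; q < nvox; ++q) mass_after += u[q];
    boundary += (mass_after - mass_before) + (decayed - dec0);
    if (refresh) {
      double before = 0.0;
      for (int q = 0; q < nvox; ++q) before += u[q];
      for (int q = 0; q < nvox; ++q) u[q] = dv;
      boundary += nvox * dv - before;
    }
    if (n > 0) {
      for (int c = 0; c < n; ++c) {
        double U = saturable
          ? rI * std::max(0.0, 1.0 - nI[c] / n_star) * volumes[c]
          : uv_const[c];
        uv[c] = U;
      }
      uptake_step(u, vix, viy, uv, dt, voxel_volume, up, removed);
      for (int c = 0; c < n; ++c) {
        acc[c] += up[c];
        nI[c] += up[c];
      }
      if (refresh) {
        double before = 0.0;
        for (int q = 0; q < nvox; ++q) before += u[q];
        for (int q = 0; q < nvox; ++q) u[q] = dv;
        boundary += nvox * dv - before;
      }
    }
  }
  return List::create(_["values"] = u, _["uptake"] = wrap(acc),
                      _["decayed"] = decayed * voxel_volume,
                      _["boundary"] = boundary * voxel_volume);
}

// ---------------------------------------------------------------------------
// Pairwise adhesion-repulsion velocities for center-based cell agents,
// using the standard polynomial potential: repulsion with compact support
// on the summed radii, adhesion with compact support on a multiple of the
// summed radii. Inertialess regime: velocity = net force / drag.
// Coincident centers repel along a random direction drawn from R's RNG.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".pairwise_velocities_cpp")]]
NumericMatrix pairwise_velocities_cpp(NumericVector x, NumericVector y,
                                      NumericVector radius, double c_adh,
                                      double c_rep, double adh_mult,
                                      double drag) {
  int n = x.size();
  NumericMatrix v(n, 2);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dxx = x[i] - x[j], dyy = y[i] - y[j];
      double d = std::sqrt(dxx * dxx + dyy * dyy);
      double rr = radius[i] + radius[j];
      double ra = adh_mult * rr;
      if (d >= ra) continue;
      double ux, uy;
      if (d < 1e-12) {
        double th = 2.0 * M_PI * unif_rand();
        ux = std::cos(th); uy = std::sin(th);
        d = 0.0;
      } else {
        ux = dxx / d; uy = dyy / d;
      }
      double f = 0.0;
      if (d < rr) {
        double s = 1.0 - d / rr;
        f += c_rep * s * s;
      }
      double sa = 1.0 - d / ra;
      f -= c_adh * sa * sa;
      double fx = f * ux / drag, fy = f * uy / drag;
      v(i, 0) += fx; v(i, 1) += fy;
      v(j, 0) -= fx; v(j, 1) -= fy;
    }
  }
  return v;
}

// ---------------------------------------------------------------------------
// Forward-Euler advance of the per-cell m-state NP release cascade and the
// released intracellular drug pool, sub-stepped for accuracy/stability.
// npop: cells x m matrix of release-state populations; influx (NP number
// over the whole step) arrives uniformly into state 0. alpha[m-1] is 0 in
// the literal cascade and > 0 when exhausted-state removal is enabled.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".cascade_advance_cpp")]]
List cascade_advance_cpp(NumericMatrix npop, NumericVector influx,
                         NumericVector Cdrug, NumericVector alpha,
                         NumericVector rrel, double lambda_np,
                         double lambda_drug, double dt, int nsub) {
  int ncell = npop.nrow(), m = npop.ncol();
  NumericMatrix n = clone(npop);
  NumericVector C = clone(Cdrug);
  double h = dt / nsub;
  double decayed = 0.0, spent = 0.0, released = 0.0, drug_decayed = 0.0;
  std::vector<double> cur(m), nxt(m);
  for (int ic = 0; ic < ncell; ++ic) {
    double inflow = influx[ic] / nsub;
    for (int jj = 0; jj < m; ++jj) cur[jj] = n(ic, jj);
    double Cc = C[ic];
    for (int s = 0; s < nsub; ++s) {
      double rel = 0.0, tot = 0.0;
      for (int jj = 0; jj < m; ++jj) {
        rel += rrel[jj] * cur[jj];
        tot += cur[jj];
      }
      for (int jj = 0; jj < m; ++jj) {
        double in = (jj == 0) ? 0.0 : alpha[jj - 1] * cur[jj - 1];
        nxt[jj] = cur[jj] + h * (in - (alpha[jj] + lambda_np) * cur[jj]);
      }
      nxt[0] += inflow;
      spent += h * alpha[m - 1] * cur[m - 1];
      decayed += h * lambda_np * tot;
      released += h * rel;
      drug_decayed += h * lambda_drug * Cc;
      Cc += h * (rel - lambda_drug * Cc);
      std::swap(cur, nxt);
    }
    for (int jj = 0; jj < m; ++jj) n(ic, jj) = cur[jj];
    C[ic] = Cc;
  }
  return List::create(_["n"] = n, _["C"] = C, _["decayed"] = decayed,
                      _["spent"] = spent, _["released"] = released,
                      _["drug_decayed"] = drug_decayed);
}
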