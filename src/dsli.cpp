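#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Spherical Bessel machinery.
//
// j_l(x): downward recurrence (stable), normalized against j_0 = sin(x)/x.
// y_l(x): upward recurrence (stable).
// Riccati-Bessel: psi_l(x) = x j_l(x), chi_l(x) = -x y_l(x), with
//   psi_l'(x) = x j_{l-1}(x) - l j_l(x)
//   chi_l'(x) = -(x y_{l-1}(x) - l y_l(x))
// where j_{-1}(x) = cos(x)/x and y_{-1}(x) = sin(x)/x.
// ---------------------------------------------------------------------------

// j_{l-1}(x) and j_l(x) for scalar x > 0 (l >= 0)
static inline void sph_j_pair(int l, double x, double &jlm1, double &jl) {
  if (l == 0) { jlm1 = std::cos(x) / x; jl = std::sin(x) / x; return; }
  int lstart = l + (int)std::ceil(std::sqrt(40.0 * (l + 1))) + 20;
  double jp = 0.0, jc = 1e-305, jm;
  double save_l = 0.0, save_lm1 = 0.0, save_0 = 0.0;
  for (int k = lstart; k >= 0; --k) {
    jm = (2.0 * k + 3.0) / x * jc - jp;
    if (std::abs(jm) > 1e250) { // rescale to avoid overflow
      jm *= 1e-250; jc *= 1e-250;
      save_l *= 1e-250; save_lm1 *= 1e-250;
    }
    if (k == l)     save_l   = jm;
    if (k == l - 1) save_lm1 = jm;
    if (k == 0)     save_0   = jm;
    jp = jc; jc = jm;
  }
  double scale = (std::sin(x) / x) / save_0;
  jl = save_l * scale;
  jlm1 = save_lm1 * scale;
}

// y_{l-1}(x) and y_l(x) for scalar x > 0
static inline void sph_y_pair(int l, double x, double &ylm1, double &yl) {
  double ym = std::sin(x) / x;          // y_{-1}
  double yc = -std::cos(x) / x;         // y_0
  if (l == 0) { ylm1 = ym; yl = yc; return; }
  double yn;
  for (int k = 0; k < l; ++k) {
    yn = (2.0 * k + 1.0) / x * yc - ym;
    ym = yc; yc = yn;
  }
  ylm1 = ym; yl = yc;
}

// Riccati-Bessel functions psi, psi', chi, chi' at a single order l for a
// vector of arguments. Used by the R-level layered-sphere solver and Mie code.
// [[Rcpp::export(name = ".riccati_cpp")]]
List riccati_cpp(int l, NumericVector x) {
  int n = x.size();
  NumericVector psi(n), dpsi(n), chi(n), dchi(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    if (!(xi > 0.0)) { psi[i] = dpsi[i] = chi[i] = dchi[i] = NA_REAL; continue; }
    double jlm1, jl, ylm1, yl;
    sph_j_pair(l, xi, jlm1, jl);
    sph_y_pair(l, xi, ylm1, yl);
    psi[i]  = xi * jl;
    dpsi[i] = xi * jlm1 - l * jl;
    chi[i]  = -xi * yl;
    dchi[i] = -(xi * ylm1 - l * yl);
  }
  return List::create(_["psi"] = psi, _["dpsi"] = dpsi,
                      _["chi"] = chi, _["dchi"] = dchi);
}

// Riccati-Bessel functions for all orders 0..lmax at scalar x (Mie series).
// [[Rcpp::export(name = ".riccati_all_cpp")]]
List riccati_all_cpp(int lmax, double x) {
  int L = lmax + 1;
  std::vector<double> j(L + 1), y(L + 1); // orders 0..lmax+? we need -1..lmax
  // y upward from y_{-1}, y_0
  NumericVector psi(L), dpsi(L), chi(L), dchi(L);
  double ym = std::sin(x) / x, yc = -std::cos(x) / x;
  std::vector<double> yv(L + 1); // yv[k] = y_{k-1}, k = 0..L
  yv[0] = ym; yv[1] = yc;
  for (int k = 1; k < L; ++k) yv[k + 1] = (2.0 * (k - 1) + 1.0) / x * yv[k] - yv[k - 1];
  // j downward
  int lstart = L + (int)std::ceil(std::sqrt(40.0 * (L + 1))) + 20;
  std::vector<double> jv(L + 1); // jv[k] = j_{k-1}, k = 0..L
  double jp = 0.0, jc = 1e-305, jm;
  for (int k = lstart; k >= -1; --k) {
    jm = (2.0 * k + 3.0) / x * jc - jp;
    if (std::abs(jm) > 1e250) {
      jm *= 1e-250; jc *= 1e-250;
      for (int t = 0; t <= L; ++t) jv[t] *= 1e-250;
    }
    if (k <= L - 1 && k >= -1) jv[k + 1] = jm;
    jp = jc; jc = jm;
  }
  double scale = (std::sin(x) / x) / jv[1];
  for (int t = 0; t <= L; ++t) jv[t] *= scale;
  for (int l = 0; l <= lmax; ++l) {
    psi[l]  = x * jv[l + 1];
    dpsi[l] = x * jv[l] - l * jv[l + 1];
    chi[l]  = -x * yv[l + 1];
    dchi[l] = -(x * yv[l] - l * yv[l + 1]);
  }
  return List::create(_["psi"] = psi, _["dpsi"] = dpsi,
                      _["chi"] = chi, _["dchi"] = dchi);
}

// Characteristic residual of the bare-sphere eigenvalue condition over a
// wavelength grid. The mode matches the interior regular solution psi_l onto
// the exterior evanescent solution chi_l; the residual is normalized so its
// magnitude is O(1) while its sign changes mark eigenwavelengths.
//   TE:  psi_l(xi) chi_l'(xo) - m chi_l(xo) psi_l'(xi)
//   TM:  m psi_l(xi) chi_l'(xo) - chi_l(xo) psi_l'(xi)
// with xo = pi d n_out / lambda, xi = pi d n_in / lambda, m = n_in/n_out.
// [[Rcpp::export(name = ".wgm_residual_cpp")]]
NumericVector wgm_residual_cpp(NumericVector lambda_nm, int l, double d_um,
                               double n_in, double n_out, int te) {
  int n = lambda_nm.size();
  NumericVector out(n);
  double m = n_in / n_out;
  for (int i = 0; i < n; ++i) {
    double lam = lambda_nm[i];
    if (!(lam > 0.0)) { out[i] = NA_REAL; continue; }
    double xo = M_PI * d_um * 1e3 * n_out / lam;
    double xi = M_PI * d_um * 1e3 * n_in / lam;
    double jlm1, jl, ylm1, yl;
    sph_j_pair(l, xi, jlm1, jl);
    double psi = xi * jl, dpsi = xi * jlm1 - l * jl;
    sph_y_pair(l, xo, ylm1, yl);
    double chi = -xo * yl, dchi = -(xo * ylm1 - l * yl);
    double r;
    if (te) r = psi * dchi - m * chi * dpsi;
    else    r = m * psi * dchi - chi * dpsi;
    double norm = std::hypot(psi, dpsi) * std::hypot(chi, dchi);
    out[i] = (norm > 0.0 && std::isfinite(norm)) ? r / norm : NA_REAL;
  }
  return out;
}

// Both polarizations' residuals over a wavelength grid in one pass (the
// Bessel recurrences are shared).
// [[Rcpp::export(name = ".wgm_residual_both_cpp")]]
List wgm_residual_both_cpp(NumericVector lambda_nm, int l, double d_um,
                           double n_in, double n_out) {
  int n = lambda_nm.size();
  NumericVector te(n), tm(n);
  double m = n_in / n_out;
  for (int i = 0; i < n; ++i) {
    double lam = lambda_nm[i];
    if (!(lam > 0.0)) { te[i] = tm[i] = NA_REAL; continue; }
    double xo = M_PI * d_um * 1e3 * n_out / lam;
    double xi = M_PI * d_um * 1e3 * n_in / lam;
    double jlm1, jl, ylm1, yl;
    sph_j_pair(l, xi, jlm1, jl);
    double psi = xi * jl, dpsi = xi * jlm1 - l * jl;
    sph_y_pair(l, xo, ylm1, yl);
    double chi = -xo * yl, dchi = -(xo * ylm1 - l * yl);
    double norm = std::hypot(psi, dpsi) * std::hypot(chi, dchi);
    if (!(norm > 0.0) || !std::isfinite(norm)) { te[i] = tm[i] = NA_REAL; continue; }
    te[i] = (psi * dchi - m * chi * dpsi) / norm;
    tm[i] = (m * psi * dchi - chi * dpsi) / norm;
  }
  return List::create(_["TE"] = te, _["TM"] = tm);
}

// ---------------------------------------------------------------------------
// Photon-packet Monte Carlo in a scattering slab.
//
// z axis points downward: z = 0 is the detection (top) surface. The scattering
// medium occupies 0 <= z <= L. Standard packet transport: exponential free
// paths with mu_t, weight deposition mu_a/mu_t per interaction, HG (or
// tabulated) scattering, Fresnel refraction/reflection at index-mismatched
// boundaries, Russian roulette termination.
//
// Configurations:
//   0 slab_overlayer: isotropic point source at z = source_depth >= L in a
//     transparent medium (index n_below) beneath the slab; downward photons
//     and photons leaving the slab bottom are lost.
//   1 embedded: isotropic point source at z = source_depth inside the medium;
//     the slab extends to L = zmax (deep photons absorbed at the bottom
//     boundary, tallied as t_bottom).
//   2 beam: collimated pencil beam incident from above (air) at the origin,
//     for integrating-sphere reflectance/transmittance.
// ---------------------------------------------------------------------------

static inline double fresnel_R(double n1, double n2, double ci) {
  // unpolarized reflectance, ci = |cos(theta_i)|
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) return 1.0; // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  if (si < 1e-9) { // normal incidence
    double r = (n1 - n2) / (n1 + n2);
    return r * r;
  }
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

static inline void scatter_dir(double &ux, double &uy, double &uz,
                               double g, NumericVector &inv_cdf) {
  double ct;
  if (inv_cdf.size() > 1) { // tabulated inverse CDF of cos(theta)
    double u = unif_rand() * (inv_cdf.size() - 1);
    int i0 = (int)std::floor(u);
    if (i0 >= inv_cdf.size() - 1) i0 = inv_cdf.size() - 2;
    double f = u - i0;
    ct = inv_cdf[i0] * (1.0 - f) + inv_cdf[i0 + 1] * f;
  } else if (std::abs(g) < 1e-6) {
    ct = 2.0 * unif_rand() - 1.0;
  } else {
    double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
    ct = (1.0 + g * g - t * t) / (2.0 * g);
  }
  if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  double nx, ny, nz;
  if (std::abs(uz) > 0.99999) {
    nx = st * cp; ny = st * sp; nz = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    nz = -st * cp * den + uz * ct;
  }
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / nrm; uy = ny / nrm; uz = nz / nrm;
}

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(double mus, double mua, double g, double n_med,
                double n_above, double n_below,
                double thickness, double source_depth,
                int config, int nphotons,
                double bin, int nbin, double na_cut,
                double w_min, double p_survive,
                NumericVector inv_cdf) {
  // mus, mua in 1/um; lengths in um
  double mut = mus + mua;
  double L = (config == 1) ? thickness : thickness; // embedded: thickness=zmax
  NumericMatrix map(nbin, nbin);
  double half = 0.5 * bin * nbin;
  double r_top = 0.0, t_bottom = 0.0, absorbed = 0.0, lost_down = 0.0;
  double ballistic = 0.0, specular = 0.0;
  double sinna = na_cut; // NA in air
  const int max_steps = 200000;
  bool vacuum = !(mut > 0.0); // non-interacting medium: ballistic only

  for (int ip = 0; ip < nphotons; ++ip) {
    double x = 0.0, y = 0.0, z, ux, uy, uz, w = 1.0;
    long nscat = 0;
    bool alive = true;

    if (config == 2) { // collimated beam from air onto top surface
      double R0 = fresnel_R(n_above, n_med, 1.0);
      specular += R0; w -= R0;
      z = 0.0; ux = 0.0; uy = 0.0; uz = 1.0;
    } else {
      // isotropic point source
      double ct = 2.0 * unif_rand() - 1.0;
      double st = std::sqrt(1.0 - ct * ct);
      double phi = 2.0 * M_PI * unif_rand();
      ux = st * std::cos(phi); uy = st * std::sin(phi); uz = ct;
      z = source_depth;
      if (config == 0) {
        // transparent region below slab: straight travel to slab bottom
        if (uz >= 0.0) { lost_down += w; continue; }
        double gap = source_depth - L;
        if (gap > 0.0) { x += ux * gap / (-uz); y += uy * gap / (-uz); }
        z = L;
        // Fresnel entry n_below -> n_med
        double ci = -uz;
        if (unif_rand() < fresnel_R(n_below, n_med, ci)) { lost_down += w; continue; }
        double ratio = n_below / n_med;
        ux *= ratio; uy *= ratio;
        double s2 = ux * ux + uy * uy;
        uz = -std::sqrt(std::max(0.0, 1.0 - s2));
        z = L - 1e-9;
      }
    }

    int steps = 0;
    while (alive && ++steps < max_steps) {
      double s = vacuum ? 1e30 : -std::log(unif_rand() + 1e-300) / mut;
      // propagate with boundary handling
      while (s > 0.0) {
        double db = 1e300;
        int bnd = 0; // 1 = top, 2 = bottom
        if (uz < 0.0) { db = (0.0 - z) / uz; bnd = 1; }
        else if (uz > 0.0) { db = (L - z) / uz; bnd = 2; }
        if (bnd == 0) { // exactly horizontal in a vacuum layer: drop it
          if (vacuum) { lost_down += w; alive = false; break; }
        }
        if (db < s && bnd != 0) {
          x += ux * db; y += uy * db; z += uz * db;
          s -= db;
          if (bnd == 1) {
            double ci = -uz;
            if (unif_rand() < fresnel_R(n_med, n_above, ci)) {
              uz = -uz; z = 1e-9; // internal reflection
            } else {
              // exits top: tally
              r_top += w;
              if (nscat == 0) ballistic += w;
              // exit angle in air
              double st_med = std::sqrt(std::max(0.0, 1.0 - ci * ci));
              double st_air = n_med / n_above * st_med;
              if (st_air <= sinna) {
                int ixb = (int)std::floor((x + half) / bin);
                int iyb = (int)std::floor((y + half) / bin);
                if (ixb >= 0 && ixb < nbin && iyb >= 0 && iyb < nbin)
                  map(ixb, iyb) += w;
              }
              alive = false;
            }
          } else {
            double ci = uz;
            double nb = (config == 2) ? n_below : n_below;
            if (config == 1) {
              // embedded: absorbing deep boundary
              t_bottom += w; alive = false;
            } else if (unif_rand() < fresnel_R(n_med, nb, ci)) {
              uz = -uz; z = L - 1e-9;
            } else {
              if (config == 2) { t_bottom += w; if (nscat == 0) ballistic += w; }
              else lost_down += w;
              alive = false;
            }
          }
          if (!alive) break;
        } else {
          x += ux * s; y += uy * s; z += uz * s;
          s = 0.0;
          if (vacuum) { lost_down += w; alive = false; break; }
          // interaction site: deposit and scatter
          double dw = w * mua / mut;
          absorbed += dw; w -= dw;
          scatter_dir(ux, uy, uz, g, inv_cdf);
          ++nscat;
          if (w < w_min) { // roulette
            if (unif_rand() < p_survive) w /= p_survive;
            else { alive = false; }
          }
        }
      }
    }
  }
  double n = (double)nphotons;
  return List::create(
    _["map"] = map,
    _["r_top"] = r_top / n,
    _["t_bottom"] = t_bottom / n,
    _["absorbed"] = absorbed / n,
    _["lost_down"] = lost_down / n,
    _["ballistic"] = ballistic / n,
    _["specular"] = specular / n,
    _["n_photons"] = nphotons);
}
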