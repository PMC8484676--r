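#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

static const cw::Ziggurat zig;

// pack/unpack the 4x64-bit generator state as 8 exact uint32 doubles
static NumericVector pack_state(const cw::Xoshiro256 &rng) {
  NumericVector out(8);
  for (int i = 0; i < 4; ++i) {
    out[2 * i] = (double)(uint32_t)(rng.s[i] >> 32);
    out[2 * i + 1] = (double)(uint32_t)(rng.s[i] & 0xffffffffULL);
  }
  return out;
}

static void unpack_state(cw::Xoshiro256 &rng, const NumericVector &st) {
  for (int i = 0; i < 4; ++i) {
    uint64_t hi = (uint64_t)st[2 * i];
    uint64_t lo = (uint64_t)st[2 * i + 1];
    rng.s[i] = (hi << 32) | lo;
  }
}

// Forward-Euler integration of the three-field activator/substrate/F-actin
// system on a masked grid.  The Laplacian uses the mask-weighted five-point
// stencil (zero-flux across the mask boundary); per-pixel Gaussian noise is
// added with opposite signs to A and I, and any negative overshoot is clamped
// to zero with the deficit moved to the conserved partner.
// [[Rcpp::export]]
List cw_simulate_core(NumericMatrix A0, NumericMatrix I0, NumericMatrix F0,
                      IntegerMatrix mask, List par, double h, double dt,
                      int save_every, int n_steps, double t0, double seed,
                      NumericVector rng_state, List comp, bool save_A,
                      bool save_I, bool save_F) {
  const int nr = A0.nrow(), nc = A0.ncol();
  const double DA = par["D_A"], DI = par["D_I"], k0 = par["k0"],
               gam = par["gamma"], Ah = par["A0"], s1 = par["s1"],
               s2 = par["s2"], Fh = par["F0"], kn = par["kn"],
               ks = par["ks"], a1 = par["alpha1"], a2 = par["alpha2"];
  const double A03 = Ah * Ah * Ah;
  const double invh2 = 1.0 / (h * h);
  const bool with_noise = (a1 != 0.0) || (a2 != 0.0);

  // masked pixel list with neighbor indices and neighbor mask weights
  std::vector<int> px;
  px.reserve((size_t)nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c)) px.push_back(r + c * nr);
  const int np = (int)px.size();
  if (np == 0) stop("mask has no active pixels");

  std::vector<int> iu(np), id(np), il(np), ir(np);
  std::vector<double> mu(np), md(np), ml(np), mr(np);
  for (int k = 0; k < np; ++k) {
    int p = px[k], r = p % nr, c = p / nr;
    iu[k] = (r > 0) ? p - 1 : p;
    id[k] = (r < nr - 1) ? p + 1 : p;
    il[k] = (c > 0) ? p - nr : p;
    ir[k] = (c < nc - 1) ? p + nr : p;
    mu[k] = (r > 0 && mask(r - 1, c)) ? 1.0 : 0.0;
    md[k] = (r < nr - 1 && mask(r + 1, c)) ? 1.0 : 0.0;
    ml[k] = (c > 0 && mask(r, c - 1)) ? 1.0 : 0.0;
    mr[k] = (c < nc - 1 && mask(r, c + 1)) ? 1.0 : 0.0;
  }

  const size_t n = (size_t)nr * nc;
  std::vector<double> A(A0.begin(), A0.end()), I(I0.begin(), I0.end()),
      F(F0.begin(), F0.end());
  std::vector<double> An(n, 0.0), In(n, 0.0), Fn(n, 0.0);
  // compensation buffers for the noise increments: with minimal noise
  // (alpha ~ 1e-15) a single increment alpha*xi*dt lies below one ulp of a
  // concentration of order one and would otherwise round away entirely;
  // Kahan-style accumulation lets sub-ulp noise build up until it commits,
  // so the instability of the homogeneous state is seeded at any field
  // magnitude.
  std::vector<double> cA, cI, cF;
  if (with_noise) {
    if (comp.size() == 3) {  // resume: carry the accumulators over
      NumericMatrix mA = comp[0], mI = comp[1], mF = comp[2];
      cA.assign(mA.begin(), mA.end());
      cI.assign(mI.begin(), mI.end());
      cF.assign(mF.begin(), mF.end());
    } else {
      cA.assign(n, 0.0);
      cI.assign(n, 0.0);
      cF.assign(n, 0.0);
    }
  }
  // keep background pixels at zero in the scratch buffers too
  for (size_t q = 0; q < n; ++q) {
    An[q] = A[q];
    In[q] = I[q];
    Fn[q] = F[q];
  }

  cw::Xoshiro256 rng;
  if (rng_state.size() == 8)
    unpack_state(rng, rng_state);
  else
    rng.seed((uint64_t)seed);

  const int n_saves = (save_every > 0) ? n_steps / save_every : 0;
  NumericVector times(n_saves + 1), mass(n_saves + 1);
  NumericVector minA(n_saves + 1), maxA(n_saves + 1), minI(n_saves + 1),
      maxI(n_saves + 1), minF(n_saves + 1), maxF(n_saves + 1);
  NumericVector fA(save_A ? n * (n_saves + 1) : 0);
  NumericVector fI(save_I ? n * (n_saves + 1) : 0);
  NumericVector fF(save_F ? n * (n_saves + 1) : 0);

  int isave = 0;
  auto audit = [&](double t) {
    double m = 0.0, mnA = R_PosInf, mxA = R_NegInf, mnI = R_PosInf,
           mxI = R_NegInf, mnF = R_PosInf, mxF = R_NegInf;
    bool badA = false, badI = false, badF = false;
    for (int k = 0; k < np; ++k) {
      double a = A[px[k]], i = I[px[k]], f = F[px[k]];
      if (!std::isfinite(a)) badA = true;
      if (!std::isfinite(i)) badI = true;
      if (!std::isfinite(f)) badF = true;
      m += a + i;
      if (a < mnA) mnA = a;
      if (a > mxA) mxA = a;
      if (i < mnI) mnI = i;
      if (i > mxI) mxI = i;
      if (f < mnF) mnF = f;
      if (f > mxF) mxF = f;
    }
    if (badA) stop("numerical failure (non-finite values) in field A at t = %f", t);
    if (badI) stop("numerical failure (non-finite values) in field I at t = %f", t);
    if (badF) stop("numerical failure (non-finite values) in field F at t = %f", t);
    times[isave] = t;
    mass[isave] = m;
    minA[isave] = mnA;
    maxA[isave] = mxA;
    minI[isave] = mnI;
    maxI[isave] = mxI;
    minF[isave] = mnF;
    maxF[isave] = mxF;
    if (save_A) std::copy(A.begin(), A.end(), fA.begin() + (size_t)isave * n);
    if (save_I) std::copy(I.begin(), I.end(), fI.begin() + (size_t)isave * n);
    if (save_F) std::copy(F.begin(), F.end(), fF.begin() + (size_t)isave * n);
    ++isave;
  };
  audit(t0);

  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < np; ++k) {
      const int p = px[k];
      const double a = A[p], i = I[p], f = F[p];
      const double a3 = a * a * a;
      const double rate =
          (k0 + gam * a3 / (A03 + a3)) * i - (s1 + s2 * f / (Fh + f)) * a;
      const double LA = mu[k] * (A[iu[k]] - a) + md[k] * (A[id[k]] - a) +
                        ml[k] * (A[il[k]] - a) + mr[k] * (A[ir[k]] - a);
      const double LI = mu[k] * (I[iu[k]] - i) + md[k] * (I[id[k]] - i) +
                        ml[k] * (I[il[k]] - i) + mr[k] * (I[ir[k]] - i);
      double an = a + dt * (rate + DA * invh2 * LA);
      double in = i + dt * (-rate + DI * invh2 * LI);
      double fn = f + dt * (kn * a - ks * f);
      if (with_noise) {
        const double e1 = a1 * zig.draw(rng) * dt;
        double y = e1 + cA[p];
        double t1 = an + y;
        cA[p] = y - (t1 - an);
        an = t1;
        y = -e1 + cI[p];
        t1 = in + y;
        cI[p] = y - (t1 - in);
        in = t1;
        if (an < 0.0) {  // clamp and move the overshoot to the partner
          in += an;
          an = 0.0;
          cA[p] = 0.0;
        } else if (in < 0.0) {
          an += in;
          in = 0.0;
          cI[p] = 0.0;
        }
        const double e2 = a2 * zig.draw(rng) * dt;
        y = e2 + cF[p];
        t1 = fn + y;
        cF[p] = y - (t1 - fn);
        fn = t1;
        if (fn < 0.0) {
          fn = 0.0;
          cF[p] = 0.0;
        }
      }
      An[p] = an;
      In[p] = in;
      Fn[p] = fn;
    }
    A.swap(An);
    I.swap(In);
    F.swap(Fn);
    if (save_every > 0 && step % save_every == 0) {
      audit(t0 + step * dt);
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix Af(nr, nc), If(nr, nc), Ff(nr, nc);
  std::copy(A.begin(), A.end(), Af.begin());
  std::copy(I.begin(), I.end(), If.begin());
  std::copy(F.begin(), F.end(), Ff.begin());

  List comp_out;
  if (with_noise) {
    NumericMatrix mA(nr, nc), mI(nr, nc), mF(nr, nc);
    std::copy(cA.begin(), cA.end(), mA.begin());
    std::copy(cI.begin(), cI.end(), mI.begin());
    std::copy(cF.begin(), cF.end(), mF.begin());
    comp_out = List::create(mA, mI, mF);
  }

  List out = List::create(
      _["times"] = times, _["mass"] = mass, _["minA"] = minA,
      _["maxA"] = maxA, _["minI"] = minI, _["maxI"] = maxI, _["minF"] = minF,
      _["maxF"] = maxF, _["A_final"] = Af, _["I_final"] = If,
      _["F_final"] = Ff, _["rng_state"] = pack_state(rng),
      _["comp"] = comp_out);
  if (save_A) {
    fA.attr("dim") = IntegerVector::create(nr, nc, n_saves + 1);
    out["frames_A"] = fA;
  }
  if (save_I) {
    fI.attr("dim") = IntegerVector::create(nr, nc, n_saves + 1);
    out["frames_I"] = fI;
  }
  if (save_F) {
    fF.attr("dim") = IntegerVector::create(nr, nc, n_saves + 1);
    out["frames_F"] = fF;
  }
  return out;
}

// Coherence distance: for every valid pixel, the largest integer radius r
// (up to r_max) such that the circular standard deviation of the valid wave
// vector angles within the disk of radius r stays below c_cr.  Radii are
// grown one ring at a time with running vector sums and early exit.
// [[Rcpp::export]]
NumericMatrix cw_coherence_core(NumericMatrix theta, LogicalMatrix valid,
                                double c_cr, int r_max, double cap) {
  const int nr = theta.nrow(), nc = theta.ncol();
  // ring offsets: ring r holds offsets with r-1 < dist <= r
  std::vector<std::vector<std::pair<int, int> > > rings(r_max + 1);
  for (int dr = -r_max; dr <= r_max; ++dr)
    for (int dc = -r_max; dc <= r_max; ++dc) {
      if (dr == 0 && dc == 0) continue;
      double d = std::sqrt((double)(dr * dr + dc * dc));
      int r = (int)std::ceil(d - 1e-9);
      if (r <= r_max) rings[r].push_back(std::make_pair(dr, dc));
    }

  std::vector<double> sin_t((size_t)nr * nc, 0.0), cos_t((size_t)nr * nc, 0.0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (valid(r, c)) {
        sin_t[r + (size_t)c * nr] = std::sin(theta(r, c));
        cos_t[r + (size_t)c * nr] = std::cos(theta(r, c));
      }

  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!valid(r, c)) {
        out(r, c) = 0.0;
        continue;
      }
      double ss = sin_t[r + (size_t)c * nr], sc = cos_t[r + (size_t)c * nr];
      long nv = 1;
      int last = 0;
      for (int rad = 1; rad <= r_max; ++rad) {
        const std::vector<std::pair<int, int> > &ring = rings[rad];
        for (size_t q = 0; q < ring.size(); ++q) {
          int rr = r + ring[q].first, cc = c + ring[q].second;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (!valid(rr, cc)) continue;
          ss += sin_t[rr + (size_t)cc * nr];
          sc += cos_t[rr + (size_t)cc * nr];
          ++nv;
        }
        double rbar = std::sqrt(ss * ss + sc * sc) / (double)nv;
        double sd;
        if (rbar >= 1.0)
          sd = 0.0;
        else if (rbar <= 0.0)
          sd = cap;
        else {
          sd = std::sqrt(-2.0 * std::log(rbar));
          if (sd > cap) sd = cap;
        }
        if (sd < c_cr)
          last = rad;
        else
          break;
      }
      out(r, c) = (double)last;
    }
  }
  return out;
}
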