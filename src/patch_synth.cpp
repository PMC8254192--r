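#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Patch-based multi-atlas synthesis core.
//
// For each target voxel, the query MRI patch (edge-replicated at borders)
// is compared against atlas MRI patches at every offset within the search
// radius of the spatially corresponding location, using the L2-normalized
// intensity distance d = || p/|p| - q/|q| ||. The k nearest patches'
// center CT values are blended with Gaussian weights exp(-d^2/h^2),
// h = mean of the k distances. Offsets are visited center-first so that
// exact matches at the corresponding location win distance ties, which
// makes self-atlas retrieval reproduce the paired CT bit-exactly.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericVector cpp_patch_synth(NumericVector mri, List atlas_mri, List atlas_ct,
                              IntegerVector dims, IntegerVector half,
                              int k, int radius, IntegerVector target_idx,
                              double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int hx = half[0], hy = half[1], hz = half[2];
  const int n_entries = atlas_mri.size();
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox, fill);

  // offsets sorted by squared distance: center first, stable tie order
  std::vector<std::array<int, 4>> offs;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        offs.push_back({dx * dx + dy * dy + dz * dz, dx, dy, dz});
  std::stable_sort(offs.begin(), offs.end(),
                   [](const std::array<int, 4> &a,
                      const std::array<int, 4> &b) { return a[0] < b[0]; });

  const int psz = (2 * hx + 1) * (2 * hy + 1) * (2 * hz + 1);
  std::vector<double> p(psz), q(psz);
  std::vector<const double *> amri(n_entries), act(n_entries);
  for (int e = 0; e < n_entries; ++e) {
    amri[e] = REAL(atlas_mri[e]);
    act[e] = REAL(atlas_ct[e]);
  }
  const double *m = REAL(mri);

  std::vector<double> bestd(k), bestv(k);

  for (R_xlen_t t = 0; t < target_idx.size(); ++t) {
    R_xlen_t lin = target_idx[t] - 1;  // 1-based from R
    int vx = (int)(lin % nx);
    int vy = (int)((lin / nx) % ny);
    int vz = (int)(lin / ((R_xlen_t)nx * ny));

    // query patch, edge-replicated
    double sp2 = 0.0;
    {
      int i = 0;
      for (int dz = -hz; dz <= hz; ++dz) {
        int z = clampi(vz + dz, 0, nz - 1);
        for (int dy = -hy; dy <= hy; ++dy) {
          int y = clampi(vy + dy, 0, ny - 1);
          for (int dx = -hx; dx <= hx; ++dx) {
            int x = clampi(vx + dx, 0, nx - 1);
            double v = m[x + nx * (y + (R_xlen_t)ny * z)];
            p[i++] = v;
            sp2 += v * v;
          }
        }
      }
    }
    double np = std::sqrt(sp2);

    int nbest = 0;
    for (int e = 0; e < n_entries; ++e) {
      const double *am = amri[e];
      const double *ac = act[e];
      for (size_t o = 0; o < offs.size(); ++o) {
        int cx = vx + offs[o][1];
        int cy = vy + offs[o][2];
        int cz = vz + offs[o][3];
        if (cx < 0 || cx >= nx || cy < 0 || cy >= ny || cz < 0 || cz >= nz)
          continue;
        double sq2 = 0.0, dot = 0.0;
        int i = 0;
        for (int dz = -hz; dz <= hz; ++dz) {
          int z = clampi(cz + dz, 0, nz - 1);
          for (int dy = -hy; dy <= hy; ++dy) {
            int y = clampi(cy + dy, 0, ny - 1);
            R_xlen_t base = nx * (y + (R_xlen_t)ny * z);
            for (int dx = -hx; dx <= hx; ++dx) {
              int x = clampi(cx + dx, 0, nx - 1);
              double v = am[x + base];
              sq2 += v * v;
              dot += v * p[i++];
            }
          }
        }
        double d2;
        if (np > 0.0 && sq2 > 0.0) {
          d2 = 2.0 - 2.0 * dot / (np * std::sqrt(sq2));
        } else {
          // all-zero patch: unnormalized Euclidean fallback
          d2 = sp2 + sq2 - 2.0 * dot;
        }
        if (d2 < 0.0) d2 = 0.0;
        double d = std::sqrt(d2);
        double cv = ac[cx + nx * (cy + (R_xlen_t)ny * cz)];
        // keep k strictly-smallest; earlier (center-first) wins ties
        if (nbest < k) {
          int pos = nbest++;
          while (pos > 0 && bestd[pos - 1] > d) {
            bestd[pos] = bestd[pos - 1];
            bestv[pos] = bestv[pos - 1];
            --pos;
          }
          bestd[pos] = d;
          bestv[pos] = cv;
        } else if (d < bestd[k - 1]) {
          int pos = k - 1;
          while (pos > 0 && bestd[pos - 1] > d) {
            bestd[pos] = bestd[pos - 1];
            bestv[pos] = bestv[pos - 1];
            --pos;
          }
          bestd[pos] = d;
          bestv[pos] = cv;
        }
      }
    }

    if (nbest == 0) continue;  // unreachable: zero offset always valid
    if (nbest == 1) {
      out[lin] = bestv[0];
      continue;
    }
    double h = 0.0;
    for (int i = 0; i < nbest; ++i) h += bestd[i];
    h /= nbest;
    double wsum = 0.0, acc = 0.0;
    if (h <= 1e-300) {  // all selected patches identical to the query
      for (int i = 0; i < nbest; ++i) acc += bestv[i];
      out[lin] = acc / nbest;
    } else {
      for (int i = 0; i < nbest; ++i) {
        double w = std::exp(-(bestd[i] * bestd[i]) / (h * h));
        wsum += w;
        acc += w * bestv[i];
      }
      out[lin] = acc / wsum;
    }
  }
  out.attr("dim") = dims;
  return out;
}
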