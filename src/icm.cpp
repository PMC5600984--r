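#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One sequential raster-order ICM sweep of the hidden-MRF MAP labeling.
//
// y       intensity values (full volume, column-major)
// labels  current labels: 0 outside the mask, 1..3 = CSF/GM/WM inside
// mask    in-brain indicator
// dims    volume dimensions
// mu, sigma  Gaussian parameters for labels 1..3 (sigma > 0)
// beta    Potts pairwise weight; a discordant in-mask 6-neighbor costs 0.5*beta
//
// Each in-mask voxel takes the label minimizing
//   log(sigma_l) + (y - mu_l)^2 / (2 sigma_l^2) + 0.5*beta * #{discordant neighbors},
// i.e. the negative log of the Gaussian likelihood times the local Gibbs
// prior. Updates are in place, so later voxels in the raster see earlier
// updates (sequential ICM: the total posterior energy cannot increase).
// Ties resolve to the lowest label index.
// [[Rcpp::export]]
IntegerVector icm_sweep_cpp(NumericVector y, IntegerVector labels,
                            LogicalVector mask, IntegerVector dims,
                            NumericVector mu, NumericVector sigma,
                            double beta) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab = clone(labels);
  double logsig[3], inv2var[3];
  for (int l = 0; l < 3; ++l) {
    logsig[l] = std::log(sigma[l]);
    inv2var[l] = 1.0 / (2.0 * sigma[l] * sigma[l]);
  }
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * sz + (R_xlen_t)j * sy;
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = base + i;
        if (!mask[v]) continue;
        // neighbor labels (0 = not a labelled neighbor, skipped)
        int nb[6];
        int nnb = 0;
        if (i > 0      && lab[v - sx] > 0) nb[nnb++] = lab[v - sx];
        if (i < nx - 1 && lab[v + sx] > 0) nb[nnb++] = lab[v + sx];
        if (j > 0      && lab[v - sy] > 0) nb[nnb++] = lab[v - sy];
        if (j < ny - 1 && lab[v + sy] > 0) nb[nnb++] = lab[v + sy];
        if (k > 0      && lab[v - sz] > 0) nb[nnb++] = lab[v - sz];
        if (k < nz - 1 && lab[v + sz] > 0) nb[nnb++] = lab[v + sz];
        int best = 1;
        double bestCost = R_PosInf;
        for (int l = 0; l < 3; ++l) {
          double d = y[v] - mu[l];
          double cost = logsig[l] + d * d * inv2var[l];
          int ndiff = 0;
          for (int q = 0; q < nnb; ++q) if (nb[q] != l + 1) ++ndiff;
          cost += 0.5 * beta * ndiff;
          if (cost < bestCost - 1e-12) {   // strict improvement; ties keep lower label
            bestCost = cost;
            best = l + 1;
          }
        }
        lab[v] = best;
      }
    }
  }
  return lab;
}
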