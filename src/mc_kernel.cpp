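// Monte-Carlo pose refinement kernel.
//
// Stage 1: fixed-temperature Metropolis sampling (translations, rigid
// rotations, torsion rotations). Stage 2: simulated annealing with the
// temperature decreasing linearly to 0 K. Poses placing a heavy atom in an
// excluded voxel, or whose centroid leaves the site sphere, are rejected
// outright. Uses R's RNG stream so runs are reproducible under set.seed();
// the pure-R reference engine in refine_run(engine = "r") consumes the
// stream in the identical order, which the tests exploit.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GAS_R = 1.9872042586e-3; // kcal/mol/K
static const double COUL = 332.06;

static inline double grid_value(const NumericVector &arr, const int *dims,
                                const double *origin, double spacing,
                                double x, double y, double z, bool nearest) {
  double t[3] = {(x - origin[0]) / spacing, (y - origin[1]) / spacing,
                 (z - origin[2]) / spacing};
  for (int k = 0; k < 3; ++k)
    if (t[k] < -0.5 || t[k] > dims[k] - 0.5) return 0.0;
  for (int k = 0; k < 3; ++k) {
    if (t[k] < 0) t[k] = 0;
    if (t[k] > dims[k] - 1) t[k] = dims[k] - 1;
  }
  if (nearest) {
    int i = (int)std::floor(t[0] + 0.5), j = (int)std::floor(t[1] + 0.5),
        k = (int)std::floor(t[2] + 0.5);
    if (i > dims[0] - 1) i = dims[0] - 1;
    if (j > dims[1] - 1) j = dims[1] - 1;
    if (k > dims[2] - 1) k = dims[2] - 1;
    return arr[i + dims[0] * (j + dims[1] * (R_xlen_t)k)];
  }
  int lo[3], hi[3];
  double fr[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = (int)std::floor(t[k]);
    if (lo[k] > dims[k] - 1) lo[k] = dims[k] - 1;
    fr[k] = t[k] - lo[k];
    hi[k] = lo[k] + 1;
    if (hi[k] > dims[k] - 1) hi[k] = dims[k] - 1;
  }
  double v = 0;
  for (int dx = 0; dx < 2; ++dx)
    for (int dy = 0; dy < 2; ++dy)
      for (int dz = 0; dz < 2; ++dz) {
        double w = (dx ? fr[0] : 1 - fr[0]) * (dy ? fr[1] : 1 - fr[1]) *
                   (dz ? fr[2] : 1 - fr[2]);
        int ix = dx ? hi[0] : lo[0], iy = dy ? hi[1] : lo[1],
            iz = dz ? hi[2] : lo[2];
        v += w * arr[ix + dims[0] * (iy + dims[1] * (R_xlen_t)iz)];
      }
  return v;
}

static inline bool voxel_excluded(const LogicalVector &excl, const int *dims,
                                  const double *origin, double spacing,
                                  double x, double y, double z) {
  int idx[3];
  double p[3] = {x, y, z};
  for (int k = 0; k < 3; ++k) {
    idx[k] = (int)std::floor((p[k] - origin[k]) / spacing + 0.5);
    if (idx[k] < 0 || idx[k] > dims[k] - 1) return false; // outside grid
  }
  return excl[idx[0] + dims[0] * (idx[1] + dims[1] * (R_xlen_t)idx[2])];
}

struct MolState {
  NumericMatrix xyz; // working coordinates (n x 3)
  int n;
};

static void rot_matrix(const double *axis, double angle_deg, double R[3][3]) {
  double nrm = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] + axis[2] * axis[2]);
  double a[3] = {axis[0] / nrm, axis[1] / nrm, axis[2] / nrm};
  double th = angle_deg * M_PI / 180.0, c = std::cos(th), s = std::sin(th),
         C = 1 - c;
  R[0][0] = a[0] * a[0] * C + c;
  R[0][1] = a[0] * a[1] * C - a[2] * s;
  R[0][2] = a[0] * a[2] * C + a[1] * s;
  R[1][0] = a[0] * a[1] * C + a[2] * s;
  R[1][1] = a[1] * a[1] * C + c;
  R[1][2] = a[1] * a[2] * C - a[0] * s;
  R[2][0] = a[0] * a[2] * C - a[1] * s;
  R[2][1] = a[1] * a[2] * C + a[0] * s;
  R[2][2] = a[2] * a[2] * C + c;
}

static double dihedral(const NumericMatrix &xyz, int a, int b, int c, int d) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m1[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = xyz(b, k) - xyz(a, k);
    b2[k] = xyz(c, k) - xyz(b, k);
    b3[k] = xyz(d, k) - xyz(c, k);
  }
  n1[0] = b1[1] * b2[2] - b1[2] * b2[1];
  n1[1] = b1[2] * b2[0] - b1[0] * b2[2];
  n1[2] = b1[0] * b2[1] - b1[1] * b2[0];
  n2[0] = b2[1] * b3[2] - b2[2] * b3[1];
  n2[1] = b2[2] * b3[0] - b2[0] * b3[2];
  n2[2] = b2[0] * b3[1] - b2[1] * b3[0];
  m1[0] = n1[1] * b2[2] - n1[2] * b2[1];
  m1[1] = n1[2] * b2[0] - n1[0] * b2[2];
  m1[2] = n1[0] * b2[1] - n1[1] * b2[0];
  double b2n = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double y = (m1[0] * n2[0] + m1[1] * n2[1] + m1[2] * n2[2]) / b2n;
  return std::atan2(y, x);
}

// [[Rcpp::export(name = ".mc_refine_kernel")]]
List mc_refine_kernel(NumericMatrix coords, IntegerVector cls, List map_arrays,
                      IntegerVector dims_, NumericVector origin_, double spacing,
                      LogicalVector excl, NumericVector site_center,
                      double site_radius, IntegerMatrix torsions,
                      List torsion_moving, IntegerMatrix nb_pairs,
                      NumericVector lj_rmin2, NumericVector lj_eps,
                      NumericVector pcharges, double torsion_barrier,
                      int stage1_steps, double s1_dt, double s1_dr, double s1_dd,
                      int anneal_steps, double a_dt, double a_dr, double a_dd,
                      double startT, bool nearest) {
  int n = coords.nrow();
  int dims[3] = {dims_[0], dims_[1], dims_[2]};
  double origin[3] = {origin_[0], origin_[1], origin_[2]};
  int ntors = torsions.nrow();
  int nmaps = map_arrays.size();
  std::vector<NumericVector> maps(nmaps);
  for (int m = 0; m < nmaps; ++m) maps[m] = as<NumericVector>(map_arrays[m]);

  NumericMatrix cur(clone(coords));

  auto lgfe = [&](const NumericMatrix &xyz) {
    double s = 0;
    for (int i = 0; i < n; ++i) {
      int c = cls[i];
      if (c < 0) continue;
      s += grid_value(maps[c], dims, origin, spacing, xyz(i, 0), xyz(i, 1),
                      xyz(i, 2), nearest);
    }
    return s;
  };
  auto intra = [&](const NumericMatrix &xyz) {
    double e = 0;
    for (int p = 0; p < nb_pairs.nrow(); ++p) {
      int i = nb_pairs(p, 0) - 1, j = nb_pairs(p, 1) - 1;
      double dx = xyz(i, 0) - xyz(j, 0), dy = xyz(i, 1) - xyz(j, 1),
             dz = xyz(i, 2) - xyz(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz, r = std::sqrt(r2);
      double rmin = lj_rmin2[i] + lj_rmin2[j];
      double eps = std::sqrt(lj_eps[i] * lj_eps[j]);
      double sr6 = std::pow(rmin / r, 6);
      e += eps * (sr6 * sr6 - 2 * sr6);
      e += COUL * pcharges[i] * pcharges[j] / (4 * r2);
    }
    for (int t = 0; t < ntors; ++t) {
      double phi = dihedral(xyz, torsions(t, 0) - 1, torsions(t, 1) - 1,
                            torsions(t, 2) - 1, torsions(t, 3) - 1);
      e += torsion_barrier * (1 + std::cos(3 * phi));
    }
    return e;
  };
  auto violates = [&](const NumericMatrix &xyz) {
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < n; ++i) {
      if (voxel_excluded(excl, dims, origin, spacing, xyz(i, 0), xyz(i, 1),
                         xyz(i, 2)))
        return true;
      cx += xyz(i, 0); cy += xyz(i, 1); cz += xyz(i, 2);
    }
    cx /= n; cy /= n; cz /= n;
    double dx = cx - site_center[0], dy = cy - site_center[1],
           dz = cz - site_center[2];
    return dx * dx + dy * dy + dz * dz > site_radius * site_radius;
  };

  double cur_lgfe = lgfe(cur), cur_intra = intra(cur);
  double cur_e = cur_lgfe + cur_intra;
  NumericMatrix best(clone(cur));
  double best_e = cur_e, best_lgfe = cur_lgfe;
  int total_steps = stage1_steps + anneal_steps;
  NumericVector trace(total_steps);
  int accepted = 0, rej_geom = 0, rej_mc = 0;
  NumericMatrix prop(n, 3);

  for (int step = 0; step < total_steps; ++step) {
    bool annealing = step >= stage1_steps;
    double T = annealing
                   ? startT * (1.0 - (double)(step - stage1_steps + 1) / anneal_steps)
                   : startT;
    double mdt = annealing ? a_dt : s1_dt;
    double mdr = annealing ? a_dr : s1_dr;
    double mdd = annealing ? a_dd : s1_dd;
    int nk = ntors > 0 ? 3 : 2;
    int kind = (int)(unif_rand() * nk);
    if (kind >= nk) kind = nk - 1;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) prop(i, k) = cur(i, k);
    if (kind == 0) { // translation
      double z = 2 * unif_rand() - 1;
      double phi = 2 * M_PI * unif_rand();
      double rr = std::sqrt(std::max(0.0, 1 - z * z));
      double mag = unif_rand() * mdt;
      double v[3] = {rr * std::cos(phi) * mag, rr * std::sin(phi) * mag, z * mag};
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) prop(i, k) += v[k];
    } else if (kind == 1) { // rigid rotation about centroid
      double z = 2 * unif_rand() - 1;
      double phi = 2 * M_PI * unif_rand();
      double rr = std::sqrt(std::max(0.0, 1 - z * z));
      double axis[3] = {rr * std::cos(phi), rr * std::sin(phi), z};
      double ang = (2 * unif_rand() - 1) * mdr;
      double R[3][3];
      rot_matrix(axis, ang, R);
      double ctr[3] = {0, 0, 0};
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) ctr[k] += cur(i, k) / n;
      for (int i = 0; i < n; ++i) {
        double d[3] = {cur(i, 0) - ctr[0], cur(i, 1) - ctr[1], cur(i, 2) - ctr[2]};
        for (int k = 0; k < 3; ++k)
          prop(i, k) = ctr[k] + R[k][0] * d[0] + R[k][1] * d[1] + R[k][2] * d[2];
      }
    } else { // torsion rotation
      int t = (int)(unif_rand() * ntors);
      if (t >= ntors) t = ntors - 1;
      double ang = (2 * unif_rand() - 1) * mdd;
      int b = torsions(t, 1) - 1, c = torsions(t, 2) - 1;
      double axis[3] = {cur(c, 0) - cur(b, 0), cur(c, 1) - cur(b, 1),
                        cur(c, 2) - cur(b, 2)};
      double R[3][3];
      rot_matrix(axis, ang, R);
      IntegerVector mov = torsion_moving[t];
      for (int mi = 0; mi < mov.size(); ++mi) {
        int i = mov[mi] - 1;
        double d[3] = {cur(i, 0) - cur(b, 0), cur(i, 1) - cur(b, 1),
                       cur(i, 2) - cur(b, 2)};
        for (int k = 0; k < 3; ++k)
          prop(i, k) = cur(b, k) + R[k][0] * d[0] + R[k][1] * d[1] + R[k][2] * d[2];
      }
    }

    if (violates(prop)) {
      ++rej_geom;
      trace[step] = best_e;
      continue;
    }
    double p_lgfe = lgfe(prop);
    double p_e = p_lgfe + intra(prop);
    double de = p_e - cur_e;
    bool accept;
    if (de <= 0)
      accept = true;
    else if (T <= 0)
      accept = false;
    else
      accept = unif_rand() < std::exp(-de / (GAS_R * T));
    if (accept) {
      ++accepted;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) cur(i, k) = prop(i, k);
      cur_e = p_e;
      cur_lgfe = p_lgfe;
      if (cur_e < best_e) {
        best_e = cur_e;
        best_lgfe = cur_lgfe;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < 3; ++k) best(i, k) = cur(i, k);
      }
    } else {
      ++rej_mc;
    }
    trace[step] = best_e;
  }

  return List::create(_["coordinates"] = best, _["total_energy"] = best_e,
                      _["lgfe"] = best_lgfe, _["accepted"] = accepted,
                      _["rejected_geometry"] = rej_geom,
                      _["rejected_metropolis"] = rej_mc, _["trace"] = trace);
}
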