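#include <Rcpp.h>
using namespace Rcpp;

// Forward lichen kernel over many districts at once. Arithmetic mirrors the
// R reference simulate_lichen() step for step so the two agree to rounding;
// this kernel only exists because the leave-one-out estimator evaluates it
// thousands of times per fit.
//
// dist columns: z0, area, arb_pool, feeding, g, hm, infra_w (already /25 and
//               sensitivity-scaled), rotation (0/1)
// rd: n x (nyears*4) reindeer-days, season-major within year (wi,sp,su,au)
// p: p_wi_1, p_wi_2, p_su_1, p_su_2
// cfg: demand_wi, demand_sp, demand_su, demand_au, z_half, feed_sub,
//      arb_cap, K, r0, gompertz (0/1), infra_winter_only (0/1),
//      days_wi, spring_exposure_fraction
// [[Rcpp::export]]
NumericMatrix cpp_simulate_districts(NumericMatrix dist, NumericMatrix rd,
                                     NumericVector p, NumericVector cfg) {
  const int n = dist.nrow();
  const int nyears = rd.ncol() / 4;
  NumericMatrix traj(n, nyears + 1);

  const double d_wi = cfg[0], d_sp = cfg[1], d_su = cfg[2], d_au = cfg[3];
  const double zh = cfg[4], feed_sub = cfg[5], arb_cap = cfg[6];
  const double K = cfg[7], r0 = cfg[8];
  const bool gompertz = cfg[9] != 0.0;
  const bool infra_winter_only = cfg[10] != 0.0;
  const double days_wi = cfg[11], sp_expo = cfg[12];
  const double demand[4] = {d_wi, d_sp, d_su, d_au};

  for (int i = 0; i < n; ++i) {
    const double area = dist(i, 1), pool0 = dist(i, 2), feeding = dist(i, 3);
    const double g = dist(i, 4), hm = dist(i, 5), infra_w = dist(i, 6);
    const bool rotation = dist(i, 7) != 0.0;
    double z = dist(i, 0);
    traj(i, 0) = z;
    for (int y = 0; y < nyears; ++y) {
      for (int e = 0; e < 4; ++e) {
        const double rde = rd(i, 4 * y + e);
        double expo = 1.0;
        if (rotation) expo = (e == 0) ? 1.0 : (e == 1 ? sp_expo : 0.0);
        double gi = demand[e] * z / (z + zh);
        if (e == 0) {
          const double fd = feeding * feed_sub / days_wi;
          const double ab = (rde > 0) ? std::min(arb_cap, pool0 / rde) : 0.0;
          gi = std::max(0.0, gi - fd - ab);
        }
        double W;
        if (e == 0) W = p[0] + (p[1] - p[0]) * z / 1000.0;
        else {
          W = p[2] + (p[3] - p[2]) * z / 1000.0;
          if (e != 2) W *= 0.5;
        }
        if (!(infra_winter_only && e != 0)) W += infra_w;
        double rem = gi * (1.0 + W) * rde * expo / area;
        if (rem > z) rem = z;
        z -= rem;
      }
      double G = gompertz ? (z > 0 ? r0 * z * std::log(K / z) : 0.0)
                          : r0 * z * (1.0 - z / K);
      double gr = g * hm * G;
      if (gr < 0) gr = 0;
      if (gr > K - z) gr = std::max(0.0, K - z);
      z += gr;
      traj(i, y + 1) = z;
    }
  }
  return traj;
}
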