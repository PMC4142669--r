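#include <Rcpp.h>
using namespace Rcpp;

// Random sequential adsorption of disks inside a circular boundary.
//
// Radii arrive sorted in decreasing order (largest placed first, into the
// emptiest section). Candidate centers are drawn uniformly on the disk of
// radius (nerve_radius - r_i), so every accepted disk lies wholly inside the
// nerve; a candidate is rejected if it overlaps any previously placed disk.
// Uses R's RNG, so results are reproducible under set.seed().
//
// Returns an n x 2 matrix of centers, or stops with an error message
// beginning "packing:" when a disk exhausts max_attempts.
// [[Rcpp::export]]
NumericMatrix rsa_pack_disks(NumericVector radii, double nerve_radius,
                             int max_attempts) {
  const int n = radii.size();
  NumericMatrix centers(n, 2);
  std::vector<double> xs, ys, rs;
  xs.reserve(n); ys.reserve(n); rs.reserve(n);

  for (int i = 0; i < n; ++i) {
    const double r = radii[i];
    const double rmax = nerve_radius - r;
    if (rmax < 0.0)
      stop("packing: fiber of radius %f cannot fit inside nerve of radius %f",
           r, nerve_radius);
    bool placed = false;
    for (int attempt = 0; attempt < max_attempts; ++attempt) {
      // uniform point in a disk of radius rmax
      const double u = R::unif_rand();
      const double theta = R::unif_rand() * 2.0 * M_PI;
      const double rad = rmax * std::sqrt(u);
      const double cx = rad * std::cos(theta);
      const double cy = rad * std::sin(theta);
      bool ok = true;
      for (size_t j = 0; j < xs.size(); ++j) {
        const double dx = cx - xs[j], dy = cy - ys[j];
        const double lim = r + rs[j];
        if (dx * dx + dy * dy < lim * lim) { ok = false; break; }
      }
      if (ok) {
        xs.push_back(cx); ys.push_back(cy); rs.push_back(r);
        centers(i, 0) = cx; centers(i, 1) = cy;
        placed = true;
        break;
      }
    }
    if (!placed)
      stop("packing: could not place fiber %d of %d (radius %f) within %d attempts",
           i + 1, n, r, max_attempts);
  }
  return centers;
}
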