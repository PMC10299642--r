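#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-cost path through a voxel grid on the 26-connected graph.
// Edge cost between neighbours u,v is the mean darkness penalty
// ((imax - I_u + 1) + (imax - I_v + 1)) / 2 multiplied by the physical
// step length, so bright ridges (filaments) are cheap and the physical
// anisotropy of confocal stacks is respected. NA intensities mark
// masked voxels that the path may not enter.
//
// intensity: stack values in R array order (z fastest, then y, then x)
// dim:       (nz, ny, nx)
// start/goal: 0-based linear indices
// Returns 0-based linear indices of the optimal path, start first.
// [[Rcpp::export]]
List dijkstra_trace(NumericVector intensity, IntegerVector dim,
                    int start, int goal, double sxy, double sz) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long long nv = (long long)nz * ny * nx;
  if (start < 0 || start >= nv || goal < 0 || goal >= nv)
    stop("seed voxel outside the grid");
  if (NumericVector::is_na(intensity[start]) ||
      NumericVector::is_na(intensity[goal]))
    stop("seed voxel is masked (NA intensity)");

  double imax = R_NegInf;
  for (long long i = 0; i < nv; ++i) {
    if (!NumericVector::is_na(intensity[i]) && intensity[i] > imax)
      imax = intensity[i];
  }

  // precompute the 26 neighbour offsets and physical step lengths
  int offs[26][3];
  double slen[26];
  int no = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        offs[no][0] = dz; offs[no][1] = dy; offs[no][2] = dx;
        slen[no] = std::sqrt((double)dx * dx * sxy * sxy +
                             (double)dy * dy * sxy * sxy +
                             (double)dz * dz * sz * sz);
        ++no;
      }

  std::vector<double> distv(nv, R_PosInf);
  std::vector<int> prev(nv, -1);
  std::vector<char> done(nv, 0);
  typedef std::pair<double, int> PDI;
  std::priority_queue<PDI, std::vector<PDI>, std::greater<PDI> > pq;
  distv[start] = 0.0;
  pq.push(PDI(0.0, start));

  while (!pq.empty()) {
    PDI top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (u == goal) break;
    int uz = u % nz, uy = (u / nz) % ny, ux = u / (nz * ny);
    double pu = imax - intensity[u] + 1.0;
    for (int k = 0; k < no; ++k) {
      int vz = uz + offs[k][0], vy = uy + offs[k][1], vx = ux + offs[k][2];
      if (vz < 0 || vz >= nz || vy < 0 || vy >= ny || vx < 0 || vx >= nx)
        continue;
      int v = vz + nz * (vy + (long long)ny * vx);
      if (done[v] || NumericVector::is_na(intensity[v])) continue;
      double w = 0.5 * (pu + (imax - intensity[v] + 1.0)) * slen[k];
      if (distv[u] + w < distv[v]) {
        distv[v] = distv[u] + w;
        prev[v] = u;
        pq.push(PDI(distv[v], v));
      }
    }
  }

  if (!std::isfinite(distv[goal]))
    stop("tip seed is unreachable from the base seed (masked region?)");

  std::vector<int> rev;
  for (int v = goal; v != -1; v = prev[v]) rev.push_back(v);
  IntegerVector path(rev.size());
  for (size_t i = 0; i < rev.size(); ++i) path[i] = rev[rev.size() - 1 - i];
  return List::create(_["path"] = path, _["cost"] = distv[goal]);
}
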