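#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact closest point on a triangle (Ericson, Real-Time Collision Detection,
// section 5.1.5): handles interior, edge and vertex regions.
static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Precomputed triangle soup: per-face vertex triples, centroids and bounding
// radii. Built once per mesh and reused by every query batch (ICP issues
// hundreds of batches against the same surface).
struct MeshIndex {
  int nf;
  std::vector<double> tv, cen, rad;
};

static MeshIndex *build_index(const NumericMatrix &vertices,
                              const IntegerMatrix &faces) {
  const int nf = faces.nrow();
  if (nf == 0) stop("mesh has no faces");
  MeshIndex *mi = new MeshIndex();
  mi->nf = nf;
  mi->tv.resize(9 * nf);
  mi->cen.resize(3 * nf);
  mi->rad.resize(nf);
  std::vector<double> &tv = mi->tv;
  std::vector<double> &cen = mi->cen;
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int vi = faces(f, k) - 1; // 1-based from R
      for (int i = 0; i < 3; ++i) tv[9 * f + 3 * k + i] = vertices(vi, i);
    }
    for (int i = 0; i < 3; ++i) {
      cen[3 * f + i] = (tv[9 * f + i] + tv[9 * f + 3 + i] + tv[9 * f + 6 + i]) / 3.0;
    }
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        double d = tv[9 * f + 3 * k + i] - cen[3 * f + i];
        d2 += d * d;
      }
      if (d2 > r2) r2 = d2;
    }
    mi->rad[f] = std::sqrt(r2);
  }
  return mi;
}

// [[Rcpp::export]]
SEXP cpp_mesh_index(NumericMatrix vertices, IntegerMatrix faces) {
  XPtr<MeshIndex> xp(build_index(vertices, faces), true);
  return xp;
}

static List query_index(const MeshIndex &mi, const NumericMatrix &queries) {
  const int nf = mi.nf, nq = queries.nrow();
  const double *tv = mi.tv.data();
  const double *cen = mi.cen.data();
  const double *rad = mi.rad.data();
  NumericMatrix pts(nq, 3);
  NumericVector dist(nq);
  IntegerVector face_id(nq);
  std::vector<double> d2cen(nf);
  double q[3], best_pt[3], cand[3];

  for (int j = 0; j < nq; ++j) {
    for (int i = 0; i < 3; ++i) q[i] = queries(j, i);
    // squared centroid distances; the nearest centroid seeds a tight bound
    int seed_f = 0;
    double seed_d2 = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double d2 = 0.0;
      const double *cf = &cen[3 * f];
      for (int i = 0; i < 3; ++i) {
        double d = q[i] - cf[i];
        d2 += d * d;
      }
      d2cen[f] = d2;
      if (d2 < seed_d2) {
        seed_d2 = d2;
        seed_f = f;
      }
    }
    closest_on_triangle(q, &tv[9 * seed_f], &tv[9 * seed_f + 3],
                        &tv[9 * seed_f + 6], best_pt);
    double best = 0.0;
    for (int i = 0; i < 3; ++i) {
      double d = q[i] - best_pt[i];
      best += d * d;
    }
    int best_f = seed_f;
    double bd = std::sqrt(best);
    // cull: a triangle whose centroid lies further than the current best
    // distance plus its own bounding radius cannot contain a closer point
    for (int f = 0; f < nf; ++f) {
      if (f == seed_f) continue;
      double reach = bd + rad[f];
      if (d2cen[f] > reach * reach) continue;
      closest_on_triangle(q, &tv[9 * f], &tv[9 * f + 3], &tv[9 * f + 6], cand);
      double d2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        double d = q[i] - cand[i];
        d2 += d * d;
      }
      if (d2 < best) {
        best = d2;
        best_f = f;
        bd = std::sqrt(best);
        for (int i = 0; i < 3; ++i) best_pt[i] = cand[i];
      }
    }
    for (int i = 0; i < 3; ++i) pts(j, i) = best_pt[i];
    dist[j] = std::sqrt(best);
    face_id[j] = best_f + 1;
  }
  return List::create(
      _["point"] = pts, _["distance"] = dist, _["face"] = face_id);
}

// [[Rcpp::export]]
List cpp_index_query(SEXP index, NumericMatrix queries) {
  XPtr<MeshIndex> xp(index);
  return query_index(*xp, queries);
}

// An index loaded from a serialized object deserializes as a null pointer;
// callers check validity and rebuild lazily.
// [[Rcpp::export]]
bool cpp_index_valid(SEXP index) {
  return TYPEOF(index) == EXTPTRSXP && R_ExternalPtrAddr(index) != NULL;
}

// One-shot convenience entry (builds a throwaway index).
// [[Rcpp::export]]
List cpp_nearest_surface(NumericMatrix vertices, IntegerMatrix faces,
                         NumericMatrix queries) {
  MeshIndex *mi = build_index(vertices, faces);
  List out = query_index(*mi, queries);
  delete mi;
  return out;
}
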