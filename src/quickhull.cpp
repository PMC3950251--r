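// Incremental 3D Quickhull with conflict lists.
//
// Facets are triangles oriented counter-clockwise seen from outside; the
// volume is accumulated by the divergence theorem against the centroid of
// the hull vertices, so it is exact (to floating point) for polytopes and
// translation-invariant by construction.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;       // vertex indices
  Vec3 n;            // unit outward normal
  double off;        // plane offset, n . x = off for x on the plane
  bool alive;
  std::vector<int> outside;  // conflict points strictly above the plane
  int far_p;
  double far_d;
};

inline double plane_dist(const Face &f, const Vec3 &p) {
  return dot(f.n, p) - f.off;
}

inline std::uint64_t edge_key(int u, int v) {
  return (static_cast<std::uint64_t>(static_cast<std::uint32_t>(u)) << 32) |
         static_cast<std::uint32_t>(v);
}

class Hull {
 public:
  Hull(const NumericMatrix &pts) : n_(pts.nrow()) {
    P_.resize(n_);
    double scale = 0.0;
    for (int i = 0; i < n_; ++i) {
      P_[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
      scale = std::max(scale, std::max(std::fabs(P_[i].x),
                       std::max(std::fabs(P_[i].y), std::fabs(P_[i].z))));
    }
    eps_ = 1e-10 * std::max(scale, 1e-300);
  }

  // returns false (with rank_ set) when the input is degenerate
  bool build() {
    if (!init_simplex()) return false;
    std::vector<int> stack;
    for (int f = 0; f < 4; ++f)
      if (!faces_[f].outside.empty()) stack.push_back(f);
    while (!stack.empty()) {
      int fi = stack.back();
      stack.pop_back();
      if (!faces_[fi].alive || faces_[fi].outside.empty()) continue;
      int p = faces_[fi].far_p;
      add_point(p, fi, stack);
    }
    return true;
  }

  int rank_ = 3;

  List result() {
    // interior reference: centroid of hull vertices
    std::vector<char> on_hull(n_, 0);
    int n_faces = 0;
    for (const Face &f : faces_)
      if (f.alive) {
        on_hull[f.a] = on_hull[f.b] = on_hull[f.c] = 1;
        ++n_faces;
      }
    Vec3 o = {0, 0, 0};
    int nv = 0;
    for (int i = 0; i < n_; ++i)
      if (on_hull[i]) {
        o.x += P_[i].x; o.y += P_[i].y; o.z += P_[i].z;
        ++nv;
      }
    o.x /= nv; o.y /= nv; o.z /= nv;

    double vol = 0.0, area = 0.0;
    IntegerMatrix tri(n_faces, 3);
    int k = 0;
    for (const Face &f : faces_) {
      if (!f.alive) continue;
      Vec3 u = sub(P_[f.b], P_[f.a]), v = sub(P_[f.c], P_[f.a]);
      Vec3 cr = cross(u, v);
      // orient outward relative to the interior point
      int a = f.a, b = f.b, c = f.c;
      Vec3 w = sub(o, P_[f.a]);
      if (dot(cr, w) > 0) { std::swap(b, c); cr.x = -cr.x; cr.y = -cr.y; cr.z = -cr.z; }
      area += 0.5 * norm(cr);
      // signed tetrahedron (o, a, b, c), positive for outward facets
      Vec3 pa = sub(P_[a], o), pb = sub(P_[b], o), pc = sub(P_[c], o);
      vol += dot(pa, cross(pb, pc)) / 6.0;
      tri(k, 0) = a + 1; tri(k, 1) = b + 1; tri(k, 2) = c + 1;
      ++k;
    }
    IntegerVector vert(nv);
    k = 0;
    for (int i = 0; i < n_; ++i)
      if (on_hull[i]) vert[k++] = i + 1;
    return List::create(_["volume"] = vol, _["area"] = area,
                        _["vertices"] = vert, _["faces"] = tri);
  }

 private:
  int n_;
  double eps_;
  std::vector<Vec3> P_;
  std::vector<Face> faces_;
  std::unordered_map<std::uint64_t, int> edge2face_;  // directed edge -> face

  void register_face(int fi) {
    const Face &f = faces_[fi];
    edge2face_[edge_key(f.a, f.b)] = fi;
    edge2face_[edge_key(f.b, f.c)] = fi;
    edge2face_[edge_key(f.c, f.a)] = fi;
  }
  void unregister_face(int fi) {
    const Face &f = faces_[fi];
    edge2face_.erase(edge_key(f.a, f.b));
    edge2face_.erase(edge_key(f.b, f.c));
    edge2face_.erase(edge_key(f.c, f.a));
  }

  int make_face(int a, int b, int c, const Vec3 &interior) {
    Face f;
    f.a = a; f.b = b; f.c = c;
    Vec3 cr = cross(sub(P_[b], P_[a]), sub(P_[c], P_[a]));
    double len = norm(cr);
    if (len < 1e-300) len = 1e-300;
    f.n = {cr.x / len, cr.y / len, cr.z / len};
    f.off = dot(f.n, P_[a]);
    if (dot(f.n, interior) - f.off > 0) {  // flip to point outward
      std::swap(f.b, f.c);
      f.n.x = -f.n.x; f.n.y = -f.n.y; f.n.z = -f.n.z;
      f.off = -f.off;
    }
    f.alive = true;
    f.far_p = -1;
    f.far_d = 0.0;
    faces_.push_back(f);
    int fi = static_cast<int>(faces_.size()) - 1;
    register_face(fi);
    return fi;
  }

  void assign_point(int p, const std::vector<int> &cand) {
    for (int fi : cand) {
      Face &f = faces_[fi];
      if (!f.alive) continue;
      double d = plane_dist(f, P_[p]);
      if (d > eps_) {
        f.outside.push_back(p);
        if (d > f.far_d) { f.far_d = d; f.far_p = p; }
        return;
      }
    }
  }

  bool init_simplex() {
    // most distant pair among the 6 axis extremes
    int ext[6] = {0, 0, 0, 0, 0, 0};
    for (int i = 1; i < n_; ++i) {
      if (P_[i].x < P_[ext[0]].x) ext[0] = i;
      if (P_[i].x > P_[ext[1]].x) ext[1] = i;
      if (P_[i].y < P_[ext[2]].y) ext[2] = i;
      if (P_[i].y > P_[ext[3]].y) ext[3] = i;
      if (P_[i].z < P_[ext[4]].z) ext[4] = i;
      if (P_[i].z > P_[ext[5]].z) ext[5] = i;
    }
    int i0 = 0, i1 = 0;
    double best = -1.0;
    for (int a = 0; a < 6; ++a)
      for (int b = a + 1; b < 6; ++b) {
        double d = norm(sub(P_[ext[a]], P_[ext[b]]));
        if (d > best) { best = d; i0 = ext[a]; i1 = ext[b]; }
      }
    if (best <= eps_) { rank_ = 0; return false; }
    // farthest from the line i0-i1
    Vec3 dir = sub(P_[i1], P_[i0]);
    double dn = norm(dir);
    int i2 = -1;
    best = eps_;
    for (int i = 0; i < n_; ++i) {
      double d = norm(cross(sub(P_[i], P_[i0]), dir)) / dn;
      if (d > best) { best = d; i2 = i; }
    }
    if (i2 < 0) { rank_ = 1; return false; }
    // farthest from the plane i0-i1-i2
    Vec3 nrm = cross(dir, sub(P_[i2], P_[i0]));
    double nn = norm(nrm);
    int i3 = -1;
    best = eps_;
    for (int i = 0; i < n_; ++i) {
      double d = std::fabs(dot(nrm, sub(P_[i], P_[i0]))) / nn;
      if (d > best) { best = d; i3 = i; }
    }
    if (i3 < 0) { rank_ = 2; return false; }

    Vec3 interior = {(P_[i0].x + P_[i1].x + P_[i2].x + P_[i3].x) / 4.0,
                     (P_[i0].y + P_[i1].y + P_[i2].y + P_[i3].y) / 4.0,
                     (P_[i0].z + P_[i1].z + P_[i2].z + P_[i3].z) / 4.0};
    interior_ = interior;
    make_face(i0, i1, i2, interior);
    make_face(i0, i1, i3, interior);
    make_face(i0, i2, i3, interior);
    make_face(i1, i2, i3, interior);
    std::vector<int> all = {0, 1, 2, 3};
    for (int p = 0; p < n_; ++p) {
      if (p == i0 || p == i1 || p == i2 || p == i3) continue;
      assign_point(p, all);
    }
    return true;
  }

  Vec3 interior_;

  void add_point(int p, int start, std::vector<int> &stack) {
    const Vec3 &pt = P_[p];
    // visible faces via breadth-first search over edge neighbours
    std::vector<int> visible;
    std::vector<char> seen(faces_.size(), 0), is_visible(faces_.size(), 0);
    std::vector<int> queue = {start};
    seen[start] = 1;
    is_visible[start] = 1;
    while (!queue.empty()) {
      int fi = queue.back();
      queue.pop_back();
      visible.push_back(fi);
      const Face &f = faces_[fi];
      const int es[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (auto &e : es) {
        auto it = edge2face_.find(edge_key(e[1], e[0]));
        if (it == edge2face_.end()) continue;
        int nb = it->second;
        if (seen[nb]) continue;
        seen[nb] = 1;
        if (plane_dist(faces_[nb], pt) > eps_) {
          is_visible[nb] = 1;
          queue.push_back(nb);
        }
      }
    }
    // horizon: directed edges of visible faces whose twin face survives
    std::vector<std::pair<int, int>> horizon;
    std::vector<int> orphans;
    for (int fi : visible) {
      Face &f = faces_[fi];
      const int es[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (auto &e : es) {
        auto it = edge2face_.find(edge_key(e[1], e[0]));
        if (it == edge2face_.end() || !is_visible[it->second])
          horizon.push_back({e[0], e[1]});
      }
      orphans.insert(orphans.end(), f.outside.begin(), f.outside.end());
      f.outside.clear();
    }
    for (int fi : visible) {
      unregister_face(fi);
      faces_[fi].alive = false;
    }
    std::vector<int> fresh;
    for (auto &e : horizon) fresh.push_back(make_face(e.first, e.second, p, interior_));
    for (int q : orphans) {
      if (q == p) continue;
      assign_point(q, fresh);
    }
    for (int fi : fresh)
      if (!faces_[fi].outside.empty()) stack.push_back(fi);
  }
};

}  // namespace

// [[Rcpp::export(name = ".qhull3d")]]
List qhull3d(NumericMatrix pts) {
  if (pts.ncol() != 3) stop("point matrix must have 3 columns");
  if (pts.nrow() < 4) {
    return List::create(_["error"] = "degenerate", _["rank"] = std::min<int>(pts.nrow(), 3) - 1);
  }
  Hull h(pts);
  if (!h.build()) {
    return List::create(_["error"] = "degenerate", _["rank"] = h.rank_);
  }
  return h.result();
}
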