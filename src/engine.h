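#ifndef MEMTUBE_ENGINE_H
#define MEMTUBE_ENGINE_H

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <cmath>
#include <cstdint>

// Minimal deterministic RNG (xorshift-free; mt19937_64 with hand-rolled
// variate transforms so draws are identical across standard libraries).
struct Rng {
  std::uint64_t s[4];
  explicit Rng(std::uint64_t seed) {
    // splitmix64 expansion of the seed
    std::uint64_t x = seed + 0x9E3779B97f4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      std::uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline std::uint64_t next() { // xoshiro256**
    std::uint64_t r = rotl(s[1] * 5, 7) * 9;
    std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; } // [0,1)
  inline double unif(double a, double b) { return a + (b - a) * unif(); }
  inline int unif_int(int n) { return (int)(unif() * n) % n; } // 0..n-1
  inline double expo(double rate) { return -std::log(1.0 - unif()) / rate; }
  // uniform point in a ball of radius r
  inline void ball(double r, double* out) {
    for (;;) {
      double x = unif(-1, 1), y = unif(-1, 1), z = unif(-1, 1);
      if (x * x + y * y + z * z <= 1.0) {
        out[0] = r * x; out[1] = r * y; out[2] = r * z; return;
      }
    }
  }
  // random unit vector
  inline void sphere(double* out) {
    for (;;) {
      double x = unif(-1, 1), y = unif(-1, 1), z = unif(-1, 1);
      double n2 = x * x + y * y + z * z;
      if (n2 > 1e-12 && n2 <= 1.0) {
        double n = std::sqrt(n2);
        out[0] = x / n; out[1] = y / n; out[2] = z / n; return;
      }
    }
  }
};

struct Vec3 {
  double x, y, z;
};
static inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }

// One filament: nodes 0..nseg, base segment (nodes 0,1) immutable.
struct Fil {
  std::vector<Vec3> node;
  double Lp, delta, diam;
  bool rigid;
  int nseg() const { return (int)node.size() - 1; }
};

struct MembraneParams {
  double kappa, gamma, z, a_min, a_max, d_mem, d_fil;
  double r_ins;        // insertion disk radius, in the triangle plane (nm)
  double h_ins;        // insertion half-thickness along the normal (nm)
  bool gc;             // grand-canonical exchange on?
  double v_ins() const { return M_PI * r_ins * r_ins * 2.0 * h_ins; }
};

struct Spring {
  std::vector<int> ids; // attachment vertex ids (internal)
  double anchor, k;     // anchor height (nm), stiffness (kBT/nm^2)
  bool active;
};

struct Counters {
  long disp_acc = 0, disp_try = 0, flip_acc = 0, flip_try = 0;
  long ins_acc = 0, ins_try = 0, rem_acc = 0, rem_try = 0;
  long fil_acc = 0, fil_try = 0;
  // grand-canonical rejection causes (diagnostics)
  long ins_rej_tether = 0, ins_rej_quality = 0, ins_rej_clash = 0,
       ins_rej_metro = 0;
  long rem_rej_pick = 0, rem_rej_geom = 0, rem_rej_metro = 0;
};

class Engine {
public:
  double Lx, Ly;
  std::vector<Vec3> pos;
  std::vector<char> frozen, alive;
  std::vector<std::array<int, 3>> tri;
  std::vector<char> tri_alive;
  std::vector<std::vector<int>> vtri; // incident triangles per vertex
  std::vector<int> free_v, free_t;
  std::vector<double> Ev, Av;         // cached per-vertex energy / area
  std::vector<int> deg3;              // removable (degree-3, mobile) vertices
  std::vector<int> deg3_pos;          // index into deg3, -1 if absent
  int n_alive_v = 0, n_alive_t = 0;
  MembraneParams par;
  Spring spr;
  std::vector<Fil> fil;
  Counters cnt;
  Rng rng;
  double amp;       // displacement amplitude (nm)
  double fil_amp;   // filament rotation amplitude (rad)
  int fil_excl = 4; // same-filament index exclusion for sterics

  // cell lists (cell >= 10 nm so all pair checks use the 27-neighbourhood)
  double cell;
  int ncx, ncy;
  std::unordered_map<std::int64_t, std::vector<std::int64_t>> cells;

  Engine(Rcpp::NumericMatrix V, Rcpp::IntegerMatrix F,
         Rcpp::LogicalVector frz, double lx, double ly,
         Rcpp::List params, std::uint64_t seed);

  // geometry -------------------------------------------------------------
  inline Vec3 mi(Vec3 d) const { // minimum image (x,y periodic)
    d.x -= Lx * std::round(d.x / Lx);
    d.y -= Ly * std::round(d.y / Ly);
    return d;
  }
  inline double dist2(const Vec3& a, const Vec3& b) const {
    Vec3 d = mi(a - b);
    return dot(d, d);
  }
  void wrap(Vec3& p) const;
  double vertex_energy(int v, double* area_out = nullptr,
                       double* H_out = nullptr, Vec3* n_out = nullptr) const;
  double spring_energy() const;
  double mean_attach_z() const;
  double total_area() const;
  double max_height() const;
  void refresh_cache();

  // cell list ------------------------------------------------------------
  std::int64_t cell_key(const Vec3& p) const;
  void cell_insert(std::int64_t id, const Vec3& p);
  void cell_erase(std::int64_t id, const Vec3& p);
  void rebuild_cells();
  // id encoding: membrane vertex v -> v ; filament (f, node i) -> -(1 + f * 100000 + i)
  static inline std::int64_t fil_id(int f, int i) {
    return -(std::int64_t)(1 + (std::int64_t)f * 100000 + i);
  }
  bool clash(const Vec3& p, std::int64_t self, double r_mem, double r_fil,
             int self_fil = -1, int self_idx = -1,
             const int* skip_mem = nullptr, int n_skip = 0) const;

  // triangle shape guard: rejects slivers on which the discrete curvature
  // operator degenerates (any angle > ~135 deg, i.e. cot < -1, or tiny area)
  inline bool tri_quality(const Vec3& a, const Vec3& b, const Vec3& c) const {
    Vec3 ab = mi(b - a), ac = mi(c - a), bc = mi(c - b);
    double twoA = norm(cross(ab, ac));
    if (twoA < 2.0) return false; // area >= 1 nm^2
    if (dot(ab, ac) < -twoA) return false;        // angle at a
    if (dot(-1.0 * ab, bc) < -twoA) return false; // angle at b
    if (dot(-1.0 * ac, -1.0 * bc) < -twoA) return false; // angle at c
    return true;
  }

  // topology helpers -----------------------------------------------------
  int other_triangle(int t, int a, int b) const;
  int degree(int v) const { return (int)vtri[v].size(); }
  bool edge_exists(int a, int b) const;
  // keep the removable-vertex list in sync after degree changes
  inline void sync_deg3(int v) {
    bool want = v < (int)pos.size() && alive[v] && !frozen[v] &&
                degree(v) == 3;
    int& p = deg3_pos[v];
    if (want && p < 0) {
      p = (int)deg3.size();
      deg3.push_back(v);
    } else if (!want && p >= 0) {
      int last = deg3.back();
      deg3[p] = last;
      deg3_pos[last] = p;
      deg3.pop_back();
      p = -1;
    }
  }

  // moves ----------------------------------------------------------------
  bool move_displace();
  bool move_flip();
  bool move_insert();
  bool move_remove();
  bool move_filament();
  void sweep(double f_disp, double f_flip, double f_ins, double f_rem,
             bool move_fils);

  // filament steric gate for growth
  bool fil_node_ok(int f, const Vec3& p, int new_idx) const;
  bool fil_node_clash_move(int f, const Vec3& p, int idx, int lo, int hi,
                           double r_mf) const;

  int pick_alive_triangle();
  int pick_alive_vertex();

  // export ---------------------------------------------------------------
  Rcpp::List export_mesh() const;
  Rcpp::List export_filaments() const;
};

#endif
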