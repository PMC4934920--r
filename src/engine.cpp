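#include "engine.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// construction
// ---------------------------------------------------------------------------

Engine::Engine(NumericMatrix V, IntegerMatrix F, LogicalVector frz,
               double lx, double ly, List params, std::uint64_t seed)
  : Lx(lx), Ly(ly), rng(seed) {
  int nv = V.nrow(), nf = F.nrow();
  pos.resize(nv);
  frozen.assign(nv, 0);
  alive.assign(nv, 1);
  for (int i = 0; i < nv; ++i) {
    pos[i] = {V(i, 0), V(i, 1), V(i, 2)};
    if (frz[i]) frozen[i] = 1;
  }
  tri.resize(nf);
  tri_alive.assign(nf, 1);
  vtri.assign(nv, {});
  for (int t = 0; t < nf; ++t) {
    tri[t] = {F(t, 0) - 1, F(t, 1) - 1, F(t, 2) - 1};
    for (int k = 0; k < 3; ++k) vtri[tri[t][k]].push_back(t);
  }
  n_alive_v = nv;
  n_alive_t = nf;

  par.kappa = as<double>(params["kappa"]);
  par.gamma = as<double>(params["gamma"]);
  par.z     = as<double>(params["z"]);
  par.a_min = as<double>(params["a_min"]);
  par.a_max = as<double>(params["a_max"]);
  par.d_mem = as<double>(params["d_mem"]);
  par.d_fil = as<double>(params["d_fil"]);
  par.r_ins = as<double>(params["r_ins"]);
  par.h_ins = as<double>(params["h_ins"]);
  par.gc    = as<bool>(params["gc"]);
  amp = 1.0;
  fil_amp = 0.3;
  spr.active = false;

  deg3_pos.assign(nv, -1);
  for (int v = 0; v < nv; ++v) sync_deg3(v);
  rebuild_cells();
  refresh_cache();
}

void Engine::wrap(Vec3& p) const {
  p.x -= Lx * std::floor(p.x / Lx);
  p.y -= Ly * std::floor(p.y / Ly);
}

// ---------------------------------------------------------------------------
// cell list
// ---------------------------------------------------------------------------

void Engine::rebuild_cells() {
  ncx = std::max(1, (int)std::floor(Lx / 10.0));
  ncy = std::max(1, (int)std::floor(Ly / 10.0));
  cells.clear();
  for (size_t v = 0; v < pos.size(); ++v)
    if (alive[v]) cell_insert((std::int64_t)v, pos[v]);
  for (size_t f = 0; f < fil.size(); ++f)
    for (size_t i = 0; i < fil[f].node.size(); ++i)
      cell_insert(fil_id((int)f, (int)i), fil[f].node[i]);
}

std::int64_t Engine::cell_key(const Vec3& p) const {
  Vec3 q = p;
  wrap(q);
  int ix = std::min((int)(q.x / (Lx / ncx)), ncx - 1);
  int iy = std::min((int)(q.y / (Ly / ncy)), ncy - 1);
  int iz = (int)std::floor(q.z / 10.0) + 1000000;
  return ((std::int64_t)iz << 40) | ((std::int64_t)iy << 20) | (std::int64_t)ix;
}

void Engine::cell_insert(std::int64_t id, const Vec3& p) {
  cells[cell_key(p)].push_back(id);
}

void Engine::cell_erase(std::int64_t id, const Vec3& p) {
  auto it = cells.find(cell_key(p));
  if (it == cells.end()) return;
  auto& v = it->second;
  for (size_t k = 0; k < v.size(); ++k)
    if (v[k] == id) { v[k] = v.back(); v.pop_back(); return; }
}

// hard-core overlap test for a point against membrane vertices (< r_mem) and
// filament nodes (< r_fil), with the usual self/bonded exclusions
bool Engine::clash(const Vec3& p, std::int64_t self, double r_mem, double r_fil,
                   int self_fil, int self_idx,
                   const int* skip_mem, int n_skip) const {
  double rm2 = r_mem * r_mem, rf2 = r_fil * r_fil;
  Vec3 q = p;
  wrap(q);
  int ix0 = std::min((int)(q.x / (Lx / ncx)), ncx - 1);
  int iy0 = std::min((int)(q.y / (Ly / ncy)), ncy - 1);
  int iz0 = (int)std::floor(q.z / 10.0) + 1000000;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ix = (ix0 + dx + ncx) % ncx;
        int iy = (iy0 + dy + ncy) % ncy;
        std::int64_t key = ((std::int64_t)(iz0 + dz) << 40) |
                           ((std::int64_t)iy << 20) | (std::int64_t)ix;
        auto it = cells.find(key);
        if (it == cells.end()) continue;
        for (std::int64_t id : it->second) {
          if (id >= 0) { // membrane vertex
            if (id == self) continue;
            bool skip = false;
            for (int k = 0; k < n_skip; ++k)
              if (skip_mem[k] == (int)id) { skip = true; break; }
            if (skip) continue;
            if (dist2(p, pos[(size_t)id]) < rm2) return true;
          } else {       // filament node
            std::int64_t code = -id - 1;
            int f = (int)(code / 100000), i = (int)(code % 100000);
            if (f == self_fil) {
              if (std::abs(i - self_idx) <= fil_excl) continue;
              // own nodes being moved in the same rigid block are excluded
              // via self_idx bookkeeping by the caller (see move_filament)
            }
            if (dist2(p, fil[f].node[i]) < rf2) return true;
          }
        }
      }
  return false;
}

// ---------------------------------------------------------------------------
// geometry / energy
// ---------------------------------------------------------------------------

// Edge-dihedral discrete mean curvature with barycentric vertex areas:
// H_v = (sum over one-ring edges of l_e theta_e) / (4 A_v), with theta_e
// the signed dihedral angle between the two triangle normals sharing the
// edge. Positive-definite in folds (no sliver/thin-neck cancellations)
// and convergent to the continuum on smooth shapes (sphere, cylinder).
// E_v = kappa/2 * (2 H_v)^2 * A_v + gamma * A_v
double Engine::vertex_energy(int v, double* area_out, double* H_out,
                             Vec3* n_out) const {
  double A = 0.0, S = 0.0;
  Vec3 nrm = {0, 0, 0};
  const Vec3 xv = pos[v];
  for (int t : vtri[v]) {
    const auto& T = tri[t];
    int iv = (T[0] == v) ? 0 : (T[1] == v ? 1 : 2);
    int p = T[(iv + 1) % 3], q = T[(iv + 2) % 3];
    Vec3 vp = mi(pos[p] - xv), vq = mi(pos[q] - xv);
    Vec3 n1 = cross(vp, vq);
    double twoA = norm(n1);
    A += twoA / 6.0; // barycentric share
    nrm = nrm + n1;
    // each one-ring edge (v,p) is the directed edge v->p of exactly one
    // incident triangle, so this loop visits it exactly once
    int t2 = other_triangle(t, v, p);
    if (t2 < 0) continue;
    const auto& U = tri[t2];
    int iu = (U[0] == v) ? 0 : (U[1] == v ? 1 : 2);
    // t2 holds the directed edge p->v; its third vertex is next after p
    int r = U[(iu + 1) % 3];
    Vec3 vr = mi(pos[r] - xv);
    Vec3 n2 = cross(vr, vp); // triangle (v, r, p) orientation
    double l = norm(vp);
    double d1 = std::max(norm(n1), 1e-14), d2 = std::max(norm(n2), 1e-14);
    Vec3 u1 = (1.0 / d1) * n1, u2 = (1.0 / d2) * n2;
    double sth = dot(cross(u1, u2), (1.0 / std::max(l, 1e-14)) * vp);
    double cth = dot(u1, u2);
    S += l * std::atan2(sth, cth);
  }
  double nn = norm(nrm);
  Vec3 nu = (nn > 1e-14) ? (1.0 / nn) * nrm : Vec3{0, 0, 1};
  double H = (A > 1e-14) ? S / (4.0 * A) : 0.0;
  if (area_out) *area_out = A;
  if (H_out) *H_out = H;
  if (n_out) *n_out = nu;
  return 0.5 * par.kappa * (2.0 * H) * (2.0 * H) * A + par.gamma * A;
}

double Engine::mean_attach_z() const {
  double s = 0;
  for (int v : spr.ids) s += pos[v].z;
  return s / spr.ids.size();
}

double Engine::spring_energy() const {
  if (!spr.active) return 0.0;
  double d = mean_attach_z() - spr.anchor;
  return 0.5 * spr.k * d * d;
}

double Engine::total_area() const {
  double s = 0;
  for (size_t v = 0; v < pos.size(); ++v)
    if (alive[v]) s += Av[v];
  return s;
}

double Engine::max_height() const {
  double m = -1e300;
  for (size_t v = 0; v < pos.size(); ++v)
    if (alive[v] && pos[v].z > m) m = pos[v].z;
  return m;
}

void Engine::refresh_cache() {
  Ev.assign(pos.size(), 0.0);
  Av.assign(pos.size(), 0.0);
  for (size_t v = 0; v < pos.size(); ++v)
    if (alive[v]) Ev[v] = vertex_energy((int)v, &Av[v]);
}

// ---------------------------------------------------------------------------
// topology helpers
// ---------------------------------------------------------------------------

int Engine::other_triangle(int t, int a, int b) const {
  for (int u : vtri[a]) {
    if (u == t || !tri_alive[u]) continue;
    const auto& T = tri[u];
    if (T[0] == b || T[1] == b || T[2] == b) return u;
  }
  return -1;
}

bool Engine::edge_exists(int a, int b) const {
  for (int u : vtri[a]) {
    if (!tri_alive[u]) continue;
    const auto& T = tri[u];
    if (T[0] == b || T[1] == b || T[2] == b) return true;
  }
  return false;
}

int Engine::pick_alive_triangle() {
  for (;;) {
    int t = rng.unif_int((int)tri.size());
    if (tri_alive[t]) return t;
  }
}

int Engine::pick_alive_vertex() {
  for (;;) {
    int v = rng.unif_int((int)pos.size());
    if (alive[v]) return v;
  }
}

static void ring_of(const Engine& E, int v, std::vector<int>& out) {
  out.clear();
  for (int t : E.vtri[v])
    for (int k = 0; k < 3; ++k) {
      int u = E.tri[t][k];
      if (u == v) continue;
      bool seen = false;
      for (int w : out) if (w == u) { seen = true; break; }
      if (!seen) out.push_back(u);
    }
}

// ---------------------------------------------------------------------------
// Monte Carlo moves
// ---------------------------------------------------------------------------

bool Engine::move_displace() {
  cnt.disp_try++;
  int v = pick_alive_vertex();
  if (frozen[v]) return false;
  Vec3 old = pos[v];
  Vec3 d = {rng.unif(-amp, amp), rng.unif(-amp, amp), rng.unif(-amp, amp)};
  Vec3 np = old + d;
  wrap(np);

  static thread_local std::vector<int> ring;
  ring_of(*this, v, ring);
  for (int u : ring) {
    double r2 = dist2(np, pos[u]);
    if (r2 < par.a_min * par.a_min || r2 > par.a_max * par.a_max) return false;
  }
  for (int t : vtri[v]) {
    const auto& T = tri[t];
    Vec3 q[3];
    for (int k = 0; k < 3; ++k) q[k] = (T[k] == v) ? np : pos[T[k]];
    if (!tri_quality(q[0], q[1], q[2])) return false;
  }
  if (clash(np, v, par.d_mem, 0.5 * (par.d_mem + par.d_fil), -1, -1,
            ring.data(), (int)ring.size()))
    return false;

  double e_old = Ev[v], e_spr_old = 0, e_spr_new = 0;
  for (int u : ring) e_old += Ev[u];
  if (spr.active) e_spr_old = spring_energy();
  pos[v] = np;
  static thread_local std::vector<double> enew, anew;
  enew.assign(ring.size() + 1, 0.0);
  anew.assign(ring.size() + 1, 0.0);
  double e_new = enew[0] = vertex_energy(v, &anew[0]);
  for (size_t k = 0; k < ring.size(); ++k) {
    enew[k + 1] = vertex_energy(ring[k], &anew[k + 1]);
    e_new += enew[k + 1];
  }
  if (spr.active) e_spr_new = spring_energy();
  double dE = (e_new + e_spr_new) - (e_old + e_spr_old);
  if (dE > 0 && rng.unif() >= std::exp(-dE)) {
    pos[v] = old;
    return false;
  }
  // accept
  Ev[v] = enew[0];
  Av[v] = anew[0];
  for (size_t k = 0; k < ring.size(); ++k) {
    Ev[ring[k]] = enew[k + 1];
    Av[ring[k]] = anew[k + 1];
  }
  if (cell_key(old) != cell_key(np)) {
    cell_erase(v, old);
    cell_insert(v, np);
  }
  cnt.disp_acc++;
  return true;
}

bool Engine::move_flip() {
  cnt.flip_try++;
  int t = pick_alive_triangle();
  int e = rng.unif_int(3);
  int a = tri[t][e], b = tri[t][(e + 1) % 3], c = tri[t][(e + 2) % 3];
  int t2 = other_triangle(t, a, b);
  if (t2 < 0) return false;
  const auto& T2 = tri[t2];
  int d = -1;
  for (int k = 0; k < 3; ++k)
    if (T2[k] != a && T2[k] != b) d = T2[k];
  if (d < 0 || d == c) return false;
  if (degree(a) <= 3 || degree(b) <= 3) return false;
  if (edge_exists(c, d)) return false;
  double cd2 = dist2(pos[c], pos[d]);
  if (cd2 < par.a_min * par.a_min || cd2 > par.a_max * par.a_max) return false;
  // a and b become non-bonded after the flip: hard core applies again
  if (dist2(pos[a], pos[b]) < par.d_mem * par.d_mem) return false;

  // shape guard on the two new triangles
  if (!tri_quality(pos[c], pos[a], pos[d]) ||
      !tri_quality(pos[d], pos[b], pos[c]))
    return false;

  double e_old = Ev[a] + Ev[b] + Ev[c] + Ev[d];
  std::array<int, 3> sav_t = tri[t], sav_t2 = tri[t2];
  // apply: t -> (c,a,d), t2 -> (d,b,c)
  tri[t] = {c, a, d};
  tri[t2] = {d, b, c};
  auto rm = [&](int v, int tt) {
    auto& L = vtri[v];
    for (size_t k = 0; k < L.size(); ++k)
      if (L[k] == tt) { L[k] = L.back(); L.pop_back(); return; }
  };
  rm(a, t2);
  rm(b, t);
  vtri[c].push_back(t2);
  vtri[d].push_back(t);

  double e_new = vertex_energy(a) + vertex_energy(b) + vertex_energy(c) +
                 vertex_energy(d);
  double dE = e_new - e_old;
  if (dE > 0 && rng.unif() >= std::exp(-dE)) {
    tri[t] = sav_t;
    tri[t2] = sav_t2;
    rm(c, t2);
    rm(d, t);
    vtri[a].push_back(t2);
    vtri[b].push_back(t);
    return false;
  }
  for (int v : {a, b, c, d}) sync_deg3(v);
  double ar;
  for (int v : {a, b, c, d}) {
    Ev[v] = vertex_energy(v, &ar);
    Av[v] = ar;
  }
  cnt.flip_acc++;
  return true;
}

bool Engine::move_insert() {
  cnt.ins_try++;
  int t = pick_alive_triangle();
  int a = tri[t][0], b = tri[t][1], c = tri[t][2];
  Vec3 xa = pos[a];
  Vec3 pb = mi(pos[b] - xa), pc = mi(pos[c] - xa);
  Vec3 cen = (1.0 / 3.0) * (pb + pc);
  // proposal: uniform in an oriented cylinder about the centroid -- a disk
  // in the triangle plane (cheap in bending energy) with thin normal extent
  Vec3 nrm = cross(pb, pc);
  double nn = norm(nrm);
  if (nn < 1e-12) return false;
  nrm = (1.0 / nn) * nrm;
  Vec3 e1 = (1.0 / norm(pb)) * pb;
  Vec3 e2 = cross(nrm, e1);
  double rr = par.r_ins * std::sqrt(rng.unif());
  double phi = rng.unif(0, 2 * M_PI);
  double hh = rng.unif(-par.h_ins, par.h_ins);
  Vec3 wl = cen + (rr * std::cos(phi)) * e1 + (rr * std::sin(phi)) * e2 +
            hh * nrm;
  // tether bounds on the three new edges
  double d1 = norm(wl), d2 = norm(wl - pb), d3 = norm(wl - pc);
  for (double dd : {d1, d2, d3})
    if (dd < par.a_min || dd > par.a_max) { cnt.ins_rej_tether++; return false; }
  Vec3 wp = xa + wl;
  wrap(wp);
  if (!tri_quality(pos[a], pos[b], wp) || !tri_quality(pos[b], pos[c], wp) ||
      !tri_quality(pos[c], pos[a], wp)) {
    cnt.ins_rej_quality++;
    return false;
  }
  int skip3[3] = {a, b, c};
  if (clash(wp, -999999999, par.d_mem, 0.5 * (par.d_mem + par.d_fil), -1, -1,
            skip3, 3)) {
    cnt.ins_rej_clash++;
    return false;
  }

  int F_before = n_alive_t;
  // allocate vertex
  int w;
  if (!free_v.empty()) {
    w = free_v.back();
    free_v.pop_back();
    pos[w] = wp;
    alive[w] = 1;
    frozen[w] = 0;
    vtri[w].clear();
  } else {
    w = (int)pos.size();
    pos.push_back(wp);
    alive.push_back(1);
    frozen.push_back(0);
    vtri.push_back({});
    Ev.push_back(0.0);
    Av.push_back(0.0);
    deg3_pos.push_back(-1);
  }
  // allocate two triangles, reuse t as (a,b,w)
  auto alloc_tri = [&](std::array<int, 3> T) {
    int id;
    if (!free_t.empty()) {
      id = free_t.back();
      free_t.pop_back();
      tri[id] = T;
      tri_alive[id] = 1;
    } else {
      id = (int)tri.size();
      tri.push_back(T);
      tri_alive.push_back(1);
    }
    return id;
  };
  std::array<int, 3> sav_t = tri[t];
  tri[t] = {a, b, w};
  int tb = alloc_tri({b, c, w});
  int tc = alloc_tri({c, a, w});
  auto rm = [&](int v, int tt) {
    auto& L = vtri[v];
    for (size_t k = 0; k < L.size(); ++k)
      if (L[k] == tt) { L[k] = L.back(); L.pop_back(); return; }
  };
  // vtri updates: b gains tb, c gains tb+tc and loses t, a gains tc
  vtri[b].push_back(tb);
  rm(c, t);
  vtri[c].push_back(tb);
  vtri[c].push_back(tc);
  vtri[a].push_back(tc);
  vtri[w] = {t, tb, tc};
  n_alive_t += 2;
  n_alive_v += 1;
  for (int v : {a, b, c, w}) sync_deg3(v);

  double e_old = Ev[a] + Ev[b] + Ev[c];
  double e_new = vertex_energy(a) + vertex_energy(b) + vertex_energy(c) +
                 vertex_energy(w);
  double dE = e_new - e_old;
  double lnr = std::log(par.z) + std::log((double)F_before * par.v_ins()) -
               std::log((double)deg3.size()) - dE;
  bool acc = (lnr >= 0) || (std::log(rng.unif() + 1e-300) < lnr);
  if (!acc) {
    cnt.ins_rej_metro++;
    // revert
    n_alive_t -= 2;
    n_alive_v -= 1;
    tri[t] = sav_t;
    tri_alive[tb] = 0;
    tri_alive[tc] = 0;
    free_t.push_back(tb);
    free_t.push_back(tc);
    rm(b, tb);
    rm(c, tb);
    rm(c, tc);
    rm(a, tc);
    vtri[c].push_back(t);
    alive[w] = 0;
    free_v.push_back(w);
    for (int v : {a, b, c, w}) sync_deg3(v);
    return false;
  }
  double ar;
  for (int v : {a, b, c, w}) {
    Ev[v] = vertex_energy(v, &ar);
    Av[v] = ar;
  }
  cell_insert(w, wp);
  cnt.ins_acc++;
  return true;
}

bool Engine::move_remove() {
  cnt.rem_try++;
  if (deg3.empty()) { cnt.rem_rej_pick++; return false; }
  int N_rem_before = (int)deg3.size();
  int w = deg3[rng.unif_int(N_rem_before)];
  if (spr.active)
    for (int v : spr.ids)
      if (v == w) return false;
  // ordered outer ring (a,b,c) from the oriented fan
  int t0 = vtri[w][0];
  int iv = (tri[t0][0] == w) ? 0 : (tri[t0][1] == w ? 1 : 2);
  int a = tri[t0][(iv + 1) % 3], b = tri[t0][(iv + 2) % 3];
  int t1 = other_triangle(t0, b, w); // fan triangle containing edge b->? and w
  if (t1 < 0) return false;
  int c = -1;
  for (int k = 0; k < 3; ++k)
    if (tri[t1][k] != b && tri[t1][k] != w) c = tri[t1][k];
  int t2 = -1;
  for (int u : vtri[w])
    if (u != t0 && u != t1) t2 = u;
  if (c < 0 || t2 < 0 || c == a || c == b) return false;
  if (degree(a) <= 3 || degree(b) <= 3 || degree(c) <= 3) return false;
  // reject if the outer triangle already exists elsewhere
  for (int u : vtri[a]) {
    if (u == t0 || u == t1 || u == t2 || !tri_alive[u]) continue;
    const auto& T = tri[u];
    bool hb = (T[0] == b || T[1] == b || T[2] == b);
    bool hc = (T[0] == c || T[1] == c || T[2] == c);
    if (hb && hc) return false;
  }
  // reverse-insertion region membership (oriented cylinder of the outer
  // triangle, same construction as move_insert)
  Vec3 xa = pos[a];
  Vec3 pb = mi(pos[b] - xa), pc = mi(pos[c] - xa);
  Vec3 cen = (1.0 / 3.0) * (pb + pc);
  Vec3 nrm = cross(pb, pc);
  double nn = norm(nrm);
  if (nn < 1e-12) return false;
  nrm = (1.0 / nn) * nrm;
  Vec3 wl = mi(pos[w] - xa);
  Vec3 dv = wl - cen;
  double hh = dot(dv, nrm);
  Vec3 rv = dv - hh * nrm;
  if (std::abs(hh) > par.h_ins || norm(rv) > par.r_ins) {
    cnt.rem_rej_geom++;
    return false;
  }
  if (!tri_quality(pos[a], pos[b], pos[c])) { cnt.rem_rej_geom++; return false; }

  double e_old = Ev[a] + Ev[b] + Ev[c] + Ev[w];
  // apply: t0 -> (a,b,c); t1, t2 die; w dies
  std::array<int, 3> sav_t0 = tri[t0], sav_t1 = tri[t1], sav_t2 = tri[t2];
  auto rm = [&](int v, int tt) {
    auto& L = vtri[v];
    for (size_t k = 0; k < L.size(); ++k)
      if (L[k] == tt) { L[k] = L.back(); L.pop_back(); return; }
  };
  tri[t0] = {a, b, c};
  tri_alive[t1] = 0;
  tri_alive[t2] = 0;
  for (int v : {a, b, c}) {
    rm(v, t1);
    rm(v, t2);
  }
  bool c_has_t0 = false;
  for (int u : vtri[c]) if (u == t0) c_has_t0 = true;
  if (!c_has_t0) vtri[c].push_back(t0);
  alive[w] = 0;
  n_alive_v -= 1;
  n_alive_t -= 2;
  for (int v : {a, b, c, w}) sync_deg3(v);

  double e_new = vertex_energy(a) + vertex_energy(b) + vertex_energy(c);
  double dE = e_new - e_old;
  double lnr = -std::log(par.z) + std::log((double)N_rem_before) -
               std::log((double)n_alive_t * par.v_ins()) - dE;
  bool acc = (lnr >= 0) || (std::log(rng.unif() + 1e-300) < lnr);
  if (!acc) {
    cnt.rem_rej_metro++;
    alive[w] = 1;
    n_alive_v += 1;
    n_alive_t += 2;
    tri[t0] = sav_t0;
    tri[t1] = sav_t1;
    tri[t2] = sav_t2;
    tri_alive[t1] = 1;
    tri_alive[t2] = 1;
    if (!c_has_t0) rm(c, t0);
    // restore fans: recompute incident lists of a,b,c,w from the three tris
    for (int v : {a, b, c}) {
      for (int tt : {t1, t2}) {
        const auto& T = tri[tt];
        if (T[0] == v || T[1] == v || T[2] == v) vtri[v].push_back(tt);
      }
    }
    for (int v : {a, b, c, w}) sync_deg3(v);
    return false;
  }
  cell_erase(w, pos[w]);
  free_t.push_back(t1);
  free_t.push_back(t2);
  free_v.push_back(w);
  double ar;
  for (int v : {a, b, c}) {
    Ev[v] = vertex_energy(v, &ar);
    Av[v] = ar;
  }
  Ev[w] = 0;
  Av[w] = 0;
  cnt.rem_acc++;
  return true;
}

// ---------------------------------------------------------------------------
// filament moves
// ---------------------------------------------------------------------------

static Vec3 rotate_about(const Vec3& p, const Vec3& origin, const Vec3& axis,
                         double ang) {
  // Rodrigues rotation
  Vec3 v = p - origin;
  double c = std::cos(ang), s = std::sin(ang);
  Vec3 r = c * v + s * cross(axis, v) + (1 - c) * dot(axis, v) * axis;
  return origin + r;
}

bool Engine::move_filament() {
  if (fil.empty()) return false;
  int f = rng.unif_int((int)fil.size());
  Fil& F = fil[f];
  int n = F.nseg();
  if (F.rigid || n < 2) return false;
  cnt.fil_try++;

  int lo, hi;                    // moved node range (inclusive)
  double dE = 0.0;
  static thread_local std::vector<Vec3> np;
  bool crank = (n >= 3) && (rng.unif() < 0.5);
  if (!crank) {
    // pivot: rotate nodes j+1..n about random axis through node j
    int j = 1 + rng.unif_int(n - 1); // 1..n-1
    double ax[3];
    rng.sphere(ax);
    Vec3 axis = {ax[0], ax[1], ax[2]};
    double ang = rng.unif(-fil_amp, fil_amp);
    lo = j + 1;
    hi = n;
    np.assign(hi - lo + 1, {0, 0, 0});
    for (int i = lo; i <= hi; ++i)
      np[i - lo] = rotate_about(F.node[i], F.node[j], axis, ang);
    double inv = 1.0 / F.delta;
    Vec3 tj = inv * (F.node[j] - F.node[j - 1]);
    Vec3 t_old = inv * (F.node[j + 1] - F.node[j]);
    Vec3 t_new = inv * (np[0] - F.node[j]);
    dE = (F.Lp / F.delta) * (dot(tj, t_old) - dot(tj, t_new));
  } else {
    // crankshaft: rotate nodes i+1..j-1 about the chord through nodes i, j
    int i = 1 + rng.unif_int(n - 2);           // 1..n-2
    int smax = std::min(6, n - i);
    int s = 2 + rng.unif_int(std::max(1, smax - 1)); // 2..smax
    int j = std::min(i + s, n);
    if (j - i < 2) return false;
    Vec3 chord = F.node[j] - F.node[i];
    double cn = norm(chord);
    if (cn < 1e-9) return false;
    Vec3 axis = (1.0 / cn) * chord;
    double ang = rng.unif(-fil_amp, fil_amp);
    lo = i + 1;
    hi = j - 1;
    np.assign(hi - lo + 1, {0, 0, 0});
    for (int k = lo; k <= hi; ++k)
      np[k - lo] = rotate_about(F.node[k], F.node[i], axis, ang);
    // only the two boundary joints change; the rotated block is rigid and
    // nodes i, j lie on the rotation axis
    double inv = 1.0 / F.delta;
    Vec3 ti = inv * (F.node[i] - F.node[i - 1]);
    Vec3 told_i = inv * (F.node[i + 1] - F.node[i]);
    Vec3 tnew_i = inv * (np[0] - F.node[i]);
    dE += (F.Lp / F.delta) * (dot(ti, told_i) - dot(ti, tnew_i));
    if (j < n) { // joint at j exists only if an outgoing segment follows
      Vec3 tout = inv * (F.node[j + 1] - F.node[j]);
      Vec3 told_j = inv * (F.node[j] - F.node[j - 1]);
      Vec3 tnew_j = inv * (F.node[j] - np[hi - lo]);
      dE += (F.Lp / F.delta) * (dot(told_j, tout) - dot(tnew_j, tout));
    }
  }

  // Metropolis on bending energy
  if (dE > 0 && rng.unif() >= std::exp(-dE)) return false;

  // steric gate on moved nodes
  double r_mf = 0.5 * (par.d_mem + par.d_fil);
  for (int i = lo; i <= hi; ++i) {
    const Vec3& p = np[i - lo];
    if (fil_node_clash_move(f, p, i, lo, hi, r_mf)) return false;
  }

  // accept
  for (int i = lo; i <= hi; ++i) {
    cell_erase(fil_id(f, i), F.node[i]);
    F.node[i] = np[i - lo];
    cell_insert(fil_id(f, i), F.node[i]);
  }
  cnt.fil_acc++;
  return true;
}

// clash test for a proposed filament-node position during a block move:
// own nodes inside [lo,hi] are part of the moving rigid block (internal
// distances preserved) and are skipped.
bool Engine::fil_node_clash_move(int f, const Vec3& p, int idx, int lo, int hi,
                                 double r_mf) const {
  double rm2 = r_mf * r_mf, rf2 = par.d_fil * par.d_fil;
  Vec3 q = p;
  wrap(q);
  int ix0 = std::min((int)(q.x / (Lx / ncx)), ncx - 1);
  int iy0 = std::min((int)(q.y / (Ly / ncy)), ncy - 1);
  int iz0 = (int)std::floor(q.z / 10.0) + 1000000;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ix = (ix0 + dx + ncx) % ncx;
        int iy = (iy0 + dy + ncy) % ncy;
        std::int64_t key = ((std::int64_t)(iz0 + dz) << 40) |
                           ((std::int64_t)iy << 20) | (std::int64_t)ix;
        auto it = cells.find(key);
        if (it == cells.end()) continue;
        for (std::int64_t id : it->second) {
          if (id >= 0) {
            if (dist2(p, pos[(size_t)id]) < rm2) return true;
          } else {
            std::int64_t code = -id - 1;
            int ff = (int)(code / 100000), i = (int)(code % 100000);
            if (ff == f) {
              if (i >= lo && i <= hi) continue;
              if (std::abs(i - idx) <= fil_excl) continue;
            }
            if (dist2(p, fil[ff].node[i]) < rf2) return true;
          }
        }
      }
  return false;
}

// steric gate for adding node new_idx at p to filament f (polymerization)
bool Engine::fil_node_ok(int f, const Vec3& p, int new_idx) const {
  double r_mf = 0.5 * (par.d_mem + par.d_fil);
  return !clash(p, -999999999, r_mf, par.d_fil, f, new_idx);
}

// ---------------------------------------------------------------------------
// sweeps
// ---------------------------------------------------------------------------

void Engine::sweep(double f_disp, double f_flip, double f_ins, double f_rem,
                   bool move_fils) {
  int nd = (int)std::lround(f_disp * n_alive_v);
  int nf = (int)std::lround(f_flip * n_alive_v);
  int ni = par.gc ? (int)std::lround(f_ins * n_alive_v) : 0;
  int nr = par.gc ? (int)std::lround(f_rem * n_alive_v) : 0;
  for (int k = 0; k < nd; ++k) move_displace();
  for (int k = 0; k < nf; ++k) move_flip();
  for (int k = 0; k < ni + nr; ++k) {
    if (rng.unif() < 0.5) move_insert(); else move_remove();
  }
  if (move_fils) {
    int tot = 0;
    for (auto& F : fil)
      if (!F.rigid) tot += F.nseg();
    for (int k = 0; k < tot; ++k) move_filament();
  }
}

// ---------------------------------------------------------------------------
// export
// ---------------------------------------------------------------------------

List Engine::export_mesh() const {
  std::vector<int> map(pos.size(), -1);
  int nv = 0;
  for (size_t v = 0; v < pos.size(); ++v)
    if (alive[v]) map[v] = nv++;
  NumericMatrix V(nv, 3);
  LogicalVector frz(nv);
  for (size_t v = 0; v < pos.size(); ++v)
    if (alive[v]) {
      int i = map[v];
      V(i, 0) = pos[v].x;
      V(i, 1) = pos[v].y;
      V(i, 2) = pos[v].z;
      frz[i] = frozen[v] != 0;
    }
  int nt = 0;
  for (size_t t = 0; t < tri.size(); ++t)
    if (tri_alive[t]) nt++;
  IntegerMatrix F(nt, 3);
  int j = 0;
  for (size_t t = 0; t < tri.size(); ++t)
    if (tri_alive[t]) {
      for (int k = 0; k < 3; ++k) F(j, k) = map[tri[t][k]] + 1;
      j++;
    }
  return List::create(_["vertices"] = V, _["triangles"] = F,
                      _["frozen"] = frz, _["Lx"] = Lx, _["Ly"] = Ly);
}

List Engine::export_filaments() const {
  List out((int)fil.size());
  for (size_t f = 0; f < fil.size(); ++f) {
    const Fil& F = fil[f];
    NumericMatrix M((int)F.node.size(), 3);
    for (size_t i = 0; i < F.node.size(); ++i) {
      M(i, 0) = F.node[i].x;
      M(i, 1) = F.node[i].y;
      M(i, 2) = F.node[i].z;
    }
    out[f] = List::create(_["nodes"] = M, _["Lp"] = F.Lp,
                          _["delta"] = F.delta, _["d"] = F.diam,
                          _["rigid"] = F.rigid);
  }
  return out;
}
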