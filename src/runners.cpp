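#include "engine.h"
using namespace Rcpp;

// shared setup helpers --------------------------------------------------------

static void attach_filaments(Engine& E, List filaments) {
  int nf = filaments.size();
  for (int f = 0; f < nf; ++f) {
    List Fl = filaments[f];
    NumericMatrix M = Fl["nodes"];
    Fil F;
    F.Lp = as<double>(Fl["Lp"]);
    F.delta = as<double>(Fl["delta"]);
    F.diam = as<double>(Fl["d"]);
    F.rigid = as<bool>(Fl["rigid"]);
    if (!std::isfinite(F.Lp)) { F.rigid = true; F.Lp = 1e12; }
    F.node.resize(M.nrow());
    for (int i = 0; i < M.nrow(); ++i) F.node[i] = {M(i, 0), M(i, 1), M(i, 2)};
    E.fil.push_back(F);
  }
  if (nf > 0) E.rebuild_cells();
}

static void attach_spring(Engine& E, Nullable<List> spring) {
  if (spring.isNull()) { E.spr.active = false; return; }
  List S(spring);
  IntegerVector ids = S["ids"];
  E.spr.ids.clear();
  for (int i = 0; i < ids.size(); ++i) E.spr.ids.push_back(ids[i] - 1);
  E.spr.anchor = as<double>(S["anchor"]);
  E.spr.k = as<double>(S["stiffness"]);
  E.spr.active = !E.spr.ids.empty() && E.spr.k > 0;
}

static void maybe_tune(Engine& E, Counters& prev, bool fils) {
  long dt = E.cnt.disp_try - prev.disp_try;
  long da = E.cnt.disp_acc - prev.disp_acc;
  if (dt > 50) {
    double r = (double)da / dt;
    if (r < 0.30) E.amp *= 0.8;
    else if (r > 0.50) E.amp *= 1.25;
    E.amp = std::min(4.0, std::max(0.02, E.amp));
  }
  if (fils) {
    long ft = E.cnt.fil_try - prev.fil_try;
    long fa = E.cnt.fil_acc - prev.fil_acc;
    if (ft > 50) {
      double r = (double)fa / ft;
      if (r < 0.30) E.fil_amp *= 0.8;
      else if (r > 0.50) E.fil_amp *= 1.25;
      E.fil_amp = std::min(1.5, std::max(0.005, E.fil_amp));
    }
  }
  prev = E.cnt;
}

static double total_E(const Engine& E) {
  double s = 0;
  for (size_t v = 0; v < E.pos.size(); ++v)
    if (E.alive[v]) s += E.Ev[v];
  return s + E.spring_energy();
}

static List counters_list(const Counters& c) {
  return List::create(
      _["disp_acc"] = (double)c.disp_acc, _["disp_try"] = (double)c.disp_try,
      _["flip_acc"] = (double)c.flip_acc, _["flip_try"] = (double)c.flip_try,
      _["ins_acc"] = (double)c.ins_acc, _["ins_try"] = (double)c.ins_try,
      _["rem_acc"] = (double)c.rem_acc, _["rem_try"] = (double)c.rem_try,
      _["fil_acc"] = (double)c.fil_acc, _["fil_try"] = (double)c.fil_try,
      _["ins_rej_tether"] = (double)c.ins_rej_tether,
      _["ins_rej_quality"] = (double)c.ins_rej_quality,
      _["ins_rej_clash"] = (double)c.ins_rej_clash,
      _["ins_rej_metro"] = (double)c.ins_rej_metro,
      _["rem_rej_pick"] = (double)c.rem_rej_pick,
      _["rem_rej_geom"] = (double)c.rem_rej_geom,
      _["rem_rej_metro"] = (double)c.rem_rej_metro);
}

// per-vertex geometry (area, signed mean curvature, outward normal, energy)
// [[Rcpp::export]]
List cpp_vertex_data(NumericMatrix V, IntegerMatrix F, LogicalVector frozen,
                     double Lx, double Ly, List params) {
  Engine E(V, F, frozen, Lx, Ly, params, 1);
  int n = V.nrow();
  NumericVector area(n), H(n), energy(n);
  NumericMatrix nrm(n, 3);
  for (int v = 0; v < n; ++v) {
    double a, h;
    Vec3 nu;
    energy[v] = E.vertex_energy(v, &a, &h, &nu);
    area[v] = a;
    H[v] = h;
    nrm(v, 0) = nu.x;
    nrm(v, 1) = nu.y;
    nrm(v, 2) = nu.z;
  }
  return List::create(_["area"] = area, _["H"] = H, _["normal"] = nrm,
                      _["energy"] = energy);
}

// incremental energy change for displacing vertex v (1-based) to newpos,
// touching only the one-ring neighbourhood
// [[Rcpp::export]]
double cpp_energy_delta_disp(NumericMatrix V, IntegerMatrix F,
                             LogicalVector frozen, double Lx, double Ly,
                             List params, int v, NumericVector newpos,
                             Nullable<List> spring = R_NilValue) {
  Engine E(V, F, frozen, Lx, Ly, params, 1);
  attach_spring(E, spring);
  int vi = v - 1;
  std::vector<int> ring;
  for (int t : E.vtri[vi])
    for (int k = 0; k < 3; ++k) {
      int u = E.tri[t][k];
      if (u == vi) continue;
      bool seen = false;
      for (int w : ring) if (w == u) seen = true;
      if (!seen) ring.push_back(u);
    }
  double e_old = E.Ev[vi] + E.spring_energy();
  for (int u : ring) e_old += E.Ev[u];
  Vec3 np = {newpos[0], newpos[1], newpos[2]};
  E.wrap(np);
  E.pos[vi] = np;
  double e_new = E.vertex_energy(vi) + E.spring_energy();
  for (int u : ring) e_new += E.vertex_energy(u);
  return e_new - e_old;
}

// full constraint check; returns ok flag plus a description of the first
// violation found (tether bound, membrane/membrane, membrane/filament,
// filament/filament hard cores)
// [[Rcpp::export]]
List cpp_constraint_check(NumericMatrix V, IntegerMatrix F,
                          LogicalVector frozen, double Lx, double Ly,
                          List params, List filaments) {
  Engine E(V, F, frozen, Lx, Ly, params, 1);
  attach_filaments(E, filaments);
  int nv = V.nrow();
  // tether bounds on all edges
  for (size_t t = 0; t < E.tri.size(); ++t) {
    for (int k = 0; k < 3; ++k) {
      int a = E.tri[t][k], b = E.tri[t][(k + 1) % 3];
      if (a > b) continue;
      double d = std::sqrt(E.dist2(E.pos[a], E.pos[b]));
      if (d < E.par.a_min || d > E.par.a_max)
        return List::create(_["ok"] = false, _["what"] = "tether",
                            _["i"] = a + 1, _["j"] = b + 1, _["dist"] = d);
    }
  }
  double dmm = E.par.d_mem, dmf = 0.5 * (E.par.d_mem + E.par.d_fil),
         dff = E.par.d_fil;
  // membrane-membrane hard core applies to non-bonded pairs only
  for (int i = 0; i < nv; ++i)
    for (int j = i + 1; j < nv; ++j) {
      double d2 = E.dist2(E.pos[i], E.pos[j]);
      if (d2 < dmm * dmm && !E.edge_exists(i, j))
        return List::create(_["ok"] = false, _["what"] = "mem-mem",
                            _["i"] = i + 1, _["j"] = j + 1,
                            _["dist"] = std::sqrt(d2));
    }
  for (size_t f = 0; f < E.fil.size(); ++f)
    for (size_t i = 0; i < E.fil[f].node.size(); ++i) {
      const Vec3& p = E.fil[f].node[i];
      for (int v = 0; v < nv; ++v)
        if (E.dist2(p, E.pos[v]) < dmf * dmf)
          return List::create(_["ok"] = false, _["what"] = "mem-fil",
                              _["i"] = v + 1, _["j"] = (int)(f + 1),
                              _["dist"] = std::sqrt(E.dist2(p, E.pos[v])));
      for (size_t g = f; g < E.fil.size(); ++g) {
        size_t j0 = (g == f) ? i + 1 : 0;
        for (size_t j = j0; j < E.fil[g].node.size(); ++j) {
          if (g == f && (int)(j - i) <= E.fil_excl) continue;
          if (E.dist2(p, E.fil[g].node[j]) < dff * dff)
            return List::create(
                _["ok"] = false, _["what"] = "fil-fil", _["i"] = (int)(f + 1),
                _["j"] = (int)(g + 1),
                _["dist"] = std::sqrt(E.dist2(p, E.fil[g].node[j])));
        }
      }
    }
  return List::create(_["ok"] = true, _["what"] = "none");
}

// configurational Monte Carlo driver (fixed-N or grand-canonical)
// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix V, IntegerMatrix F, LogicalVector frozen,
                double Lx, double Ly, List params, List schedule,
                List filaments, Nullable<List> spring, int n_sweeps,
                int sample_every, int warmup, bool tune, int record_every,
                bool move_fils, double seed) {
  Engine E(V, F, frozen, Lx, Ly, params, (std::uint64_t)seed);
  attach_filaments(E, filaments);
  attach_spring(E, spring);
  E.amp = as<double>(schedule["amplitude"]);
  E.fil_amp = as<double>(schedule["fil_amplitude"]);
  double fd = as<double>(schedule["displace"]);
  double ff = as<double>(schedule["flip"]);
  double fi = as<double>(schedule["insert"]);
  double fr = as<double>(schedule["remove"]);

  Counters prev = E.cnt;
  for (int s = 0; s < warmup; ++s) {
    E.sweep(fd, ff, fi, fr, move_fils);
    if (tune && (s % 25) == 24) maybe_tune(E, prev, move_fils);
  }
  E.cnt = Counters();

  int nsamp = (sample_every > 0) ? n_sweeps / sample_every : 0;
  NumericVector c_sweep(nsamp), c_V(nsamp), c_F(nsamp), c_area(nsamp),
      c_E(nsamp), c_zbar(nsamp), c_force(nsamp), c_hmax(nsamp);
  List snaps, fil_snaps;
  int isamp = 0;
  for (int s = 1; s <= n_sweeps; ++s) {
    E.sweep(fd, ff, fi, fr, move_fils);
    if (sample_every > 0 && (s % sample_every) == 0 && isamp < nsamp) {
      c_sweep[isamp] = s;
      c_V[isamp] = E.n_alive_v;
      c_F[isamp] = E.n_alive_t;
      c_area[isamp] = E.total_area();
      c_E[isamp] = total_E(E);
      double zb = E.spr.active ? E.mean_attach_z() : NA_REAL;
      c_zbar[isamp] = zb;
      c_force[isamp] = E.spr.active ? E.spr.k * (E.spr.anchor - zb) : NA_REAL;
      c_hmax[isamp] = E.max_height();
      isamp++;
    }
    if (record_every > 0 && (s % record_every) == 0) {
      List m = E.export_mesh();
      snaps.push_back(m["vertices"]);
      if (move_fils) fil_snaps.push_back(E.export_filaments());
    }
  }
  DataFrame samples = DataFrame::create(
      _["sweep"] = c_sweep, _["V"] = c_V, _["F"] = c_F, _["area"] = c_area,
      _["energy"] = c_E, _["zbar"] = c_zbar, _["force"] = c_force,
      _["hmax"] = c_hmax);
  // spring attachment ids, remapped to the compacted export indexing
  IntegerVector spr_out;
  if (E.spr.active) {
    std::vector<int> map(E.pos.size(), -1);
    int nvm = 0;
    for (size_t v = 0; v < E.pos.size(); ++v)
      if (E.alive[v]) map[v] = nvm++;
    for (int v : E.spr.ids)
      if (map[v] >= 0) spr_out.push_back(map[v] + 1);
  }
  return List::create(_["spring_ids"] = spr_out,
                      _["mesh"] = E.export_mesh(),
                      _["filaments"] = E.export_filaments(),
                      _["samples"] = samples,
                      _["counters"] = counters_list(E.cnt),
                      _["amplitude"] = E.amp, _["fil_amplitude"] = E.fil_amp,
                      _["snapshots"] = snaps, _["fil_snapshots"] = fil_snaps);
}

// kinetic Monte Carlo growth driver: exponential waiting times with total
// rate N_fil (kon0 + koff); nu configurational sweeps per unit reaction time
// [[Rcpp::export]]
List cpp_run_growth(NumericMatrix V, IntegerMatrix F, LogicalVector frozen,
                    double Lx, double Ly, List params, List schedule,
                    List filaments, double kon0, double koff, double nu,
                    double max_time, double stop_height, int stop_nseg,
                    int warmup, bool tune, double snapshot_dt, double seed) {
  Engine E(V, F, frozen, Lx, Ly, params, (std::uint64_t)seed);
  attach_filaments(E, filaments);
  E.amp = as<double>(schedule["amplitude"]);
  E.fil_amp = as<double>(schedule["fil_amplitude"]);
  double fd = as<double>(schedule["displace"]);
  double ff = as<double>(schedule["flip"]);
  double fi = as<double>(schedule["insert"]);
  double fr = as<double>(schedule["remove"]);

  double z_ref = 0;
  int nfz = 0;
  for (size_t v = 0; v < E.pos.size(); ++v)
    if (E.frozen[v]) { z_ref += E.pos[v].z; nfz++; }
  if (nfz > 0) z_ref /= nfz;

  Counters prev = E.cnt;
  for (int s = 0; s < warmup; ++s) {
    E.sweep(fd, ff, fi, fr, true);
    if (tune && (s % 25) == 24) maybe_tune(E, prev, true);
  }
  E.cnt = Counters();

  int nf = (int)E.fil.size();
  double rate_tot = nf * (kon0 + koff);
  double t = 0, sweep_debt = 0, t_formed = NA_REAL, next_snap = snapshot_dt;
  std::vector<double> ev_t, ev_L;
  std::vector<int> ev_fil, ev_type, ev_acc, ev_n;
  List snaps;

  while (t < max_time && rate_tot > 0) {
    double dt = E.rng.expo(rate_tot);
    t += dt;
    if (t > max_time) break;
    sweep_debt += nu * dt;
    while (sweep_debt >= 1.0) {
      E.sweep(fd, ff, fi, fr, true);
      sweep_debt -= 1.0;
    }
    if (snapshot_dt > 0 && t >= next_snap) {
      snaps.push_back(List::create(_["t"] = t,
                                   _["filaments"] = E.export_filaments(),
                                   _["mesh"] = E.export_mesh()));
      next_snap += snapshot_dt;
    }
    int f = E.rng.unif_int(nf);
    bool on = (E.rng.unif() < kon0 / (kon0 + koff));
    Fil& FL = E.fil[f];
    int acc = 0;
    if (on) {
      int n = FL.nseg();
      Vec3 tip = FL.node[n];
      Vec3 tan = (1.0 / FL.delta) * (FL.node[n] - FL.node[n - 1]);
      Vec3 nn = tip + FL.delta * tan;
      if (E.fil_node_ok(f, nn, n + 1)) {
        FL.node.push_back(nn);
        E.cell_insert(Engine::fil_id(f, n + 1), nn);
        acc = 1;
      }
    } else {
      int n = FL.nseg();
      if (n >= 2) {
        E.cell_erase(Engine::fil_id(f, n), FL.node[n]);
        FL.node.pop_back();
        acc = 1;
      }
    }
    double L = E.max_height() - z_ref;
    ev_t.push_back(t);
    ev_fil.push_back(f + 1);
    ev_type.push_back(on ? 1 : -1);
    ev_acc.push_back(acc);
    ev_n.push_back(FL.nseg());
    ev_L.push_back(L);
    if (stop_height > 0 && L >= stop_height) {
      t_formed = t;
      break;
    }
    if (stop_nseg > 0) {
      bool hit = false;
      for (auto& FF : E.fil)
        if (FF.nseg() >= stop_nseg) hit = true;
      if (hit) { t_formed = t; break; }
    }
  }

  DataFrame events = DataFrame::create(
      _["t"] = ev_t, _["filament"] = ev_fil, _["type"] = ev_type,
      _["accepted"] = ev_acc, _["nseg"] = ev_n, _["height"] = ev_L);
  return List::create(_["mesh"] = E.export_mesh(),
                      _["filaments"] = E.export_filaments(),
                      _["events"] = events, _["t_end"] = t,
                      _["t_formed"] = t_formed,
                      _["counters"] = counters_list(E.cnt),
                      _["amplitude"] = E.amp, _["fil_amplitude"] = E.fil_amp,
                      _["snapshots"] = snaps);
}

// discretized worm-like-chain bending energy (kBT)
// [[Rcpp::export]]
double cpp_wlc_energy(NumericMatrix nodes, double Lp, double delta) {
  int n = nodes.nrow() - 1; // segments
  double E = 0;
  for (int i = 1; i < n; ++i) {
    Vec3 t1 = {(nodes(i, 0) - nodes(i - 1, 0)) / delta,
               (nodes(i, 1) - nodes(i - 1, 1)) / delta,
               (nodes(i, 2) - nodes(i - 1, 2)) / delta};
    Vec3 t2 = {(nodes(i + 1, 0) - nodes(i, 0)) / delta,
               (nodes(i + 1, 1) - nodes(i, 1)) / delta,
               (nodes(i + 1, 2) - nodes(i, 2)) / delta};
    E += (Lp / delta) * (1.0 - dot(t1, t2));
  }
  return E;
}

// continuous-time simulation of the birth-death ladder: first passage times
// from n0 to the absorbing state nstar; kon[k] is the rate n=k -> n=k+1
// (k = 1..nstar-1), koff the uniform backward rate (suppressed at n = 1)
// [[Rcpp::export]]
NumericVector cpp_bd_first_passage(NumericVector kon, double koff, int n0,
                                   int nstar, int nrep, double tmax,
                                   double seed) {
  Rng rng((std::uint64_t)seed);
  NumericVector out(nrep);
  for (int r = 0; r < nrep; ++r) {
    int n = n0;
    double t = 0;
    for (;;) {
      double ku = (n < nstar) ? kon[n - 1] : 0.0;
      double kd = (n > 1) ? koff : 0.0;
      double kt = ku + kd;
      if (kt <= 0) { t = NA_REAL; break; }
      t += rng.expo(kt);
      if (t > tmax) { t = NA_REAL; break; }
      if (rng.unif() < ku / kt) {
        n++;
        if (n >= nstar) break;
      } else {
        n--;
      }
    }
    out[r] = t;
  }
  return out;
}
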