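// Core engine: voxel lattice state, contact + volume-constraint Hamiltonian,
// Metropolis index-copy dynamics, the per-MCS compartment lifecycle, and
// 3D face-connected component labeling.
//
// Conventions shared with the R side:
//   * type codes: 0 = medium, 1 = cell, 2 = ECMst, 3 = ECMv (-1 = retired id)
//   * the medium is compartment id 0 and carries no volume constraint
//   * contact bonds are counted once per unordered neighbor pair; under the
//     fixed-medium boundary, out-of-lattice sites are virtual medium voxels
//     and each in-lattice/virtual bond is counted once
//   * all randomness comes from R's RNG (unif_rand/norm_rand), so set.seed()
//     on the R side fixes the whole trajectory.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int T_MED = 0, T_CELL = 1, T_ST = 2, T_V = 3, T_DEAD = -1;

// event codes for the lifecycle log
static const int EV_MITOSIS = 1, EV_SEC_ST = 2, EV_SEC_V = 3,
                 EV_ECM_DEL = 4, EV_CELL_DEATH = 5, EV_BLOCKED = 6;

struct Offsets {
  std::vector<int> dx, dy, dz;
  std::vector<bool> pos;  // lexicographically positive half (for once-per-pair sums)
  int n() const { return (int)dx.size(); }
};

static Offsets make_offsets(int order) {
  if (order < 1 || order > 3) stop("neighborhood order must be 1, 2 or 3");
  Offsets o;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int l1 = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (l1 == 0 || l1 > order) continue;
        o.dx.push_back(dx); o.dy.push_back(dy); o.dz.push_back(dz);
        o.pos.push_back(dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0))));
      }
  return o;
}

struct Par {
  double J[4][4];
  double lambda, Tm;
  int order;
  bool periodic;
  bool lifecycle, mitosis_preempts, ecm_constrained;
  double v_g, P_M, V_A, V_Death, V_parent, V_daughter;
  double P_st, P_v, V_ECMInit, v_d, V_Delete;
  bool constrained(int type) const {
    if (type == T_CELL) return true;
    if (type == T_ST || type == T_V) return ecm_constrained;
    return false;
  }
};

static Par parse_par(const List& p) {
  Par q;
  NumericMatrix J = p["J"];
  if (J.nrow() != 4 || J.ncol() != 4) stop("J must be a 4x4 matrix");
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) q.J[a][b] = J(a, b);
  q.lambda = as<double>(p["lambda_vol"]);
  q.Tm = as<double>(p["Tm"]);
  if (q.Tm <= 0) stop("Tm must be > 0");
  q.order = as<int>(p["neighborhood_order"]);
  q.periodic = as<bool>(p["periodic"]);
  q.lifecycle = as<bool>(p["lifecycle"]);
  q.mitosis_preempts = as<bool>(p["mitosis_preempts"]);
  q.ecm_constrained = as<bool>(p["ecm_constrained"]);
  q.v_g = as<double>(p["v_g"]);
  q.P_M = as<double>(p["P_M"]);
  q.V_A = as<double>(p["V_A"]);
  q.V_Death = as<double>(p["V_Death"]);
  q.V_parent = as<double>(p["V_parent"]);
  q.V_daughter = as<double>(p["V_daughter"]);
  q.P_st = as<double>(p["P_ECMst"]);
  q.P_v = as<double>(p["P_ECMv"]);
  q.V_ECMInit = as<double>(p["V_ECMInit"]);
  q.v_d = as<double>(p["v_d"]);
  q.V_Delete = as<double>(p["V_Delete"]);
  return q;
}

struct State {
  int nx, ny, nz;
  long N;
  std::vector<int> lab;              // voxel -> compartment id
  std::vector<int> type_of;          // id -> type code (index 0 = medium)
  std::vector<long> vol;             // id -> voxel count
  std::vector<double> tgt;           // id -> target volume
  std::vector<std::vector<int> > vox; // id -> voxel list (id >= 1)
  std::vector<int> pos;              // voxel -> index in its compartment's list
  long medium_vol;
  Offsets off;
  Par par;
  int mcs;
  // counters
  double attempts, accepted;
  long n_mitosis, n_sec_st, n_sec_v, n_ecm_del, n_cell_death, n_blocked, n_annihilated;
  bool record;
  std::vector<int> ev_mcs, ev_code, ev_id;

  long idx(int x, int y, int z) const { return x + (long)nx * (y + (long)ny * z); }
  void coords(long v, int& x, int& y, int& z) const {
    x = (int)(v % nx); long r = v / nx; y = (int)(r % ny); z = (int)(r / ny);
  }
  // label of neighbor site; -1 marks an out-of-lattice site under fixed boundary
  // (callers treat it as virtual medium for energy, unusable as a copy target)
  int label_at(int x, int y, int z) const {
    if (par.periodic) {
      x = (x % nx + nx) % nx; y = (y % ny + ny) % ny; z = (z % nz + nz) % nz;
      return lab[idx(x, y, z)];
    }
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return -1;
    return lab[idx(x, y, z)];
  }
  int type_lab(int l) const { return l <= 0 ? T_MED : type_of[l]; }

  void track_add(int id, long v) {
    pos[v] = (int)vox[id].size();
    vox[id].push_back((int)v);
  }
  void track_remove(int id, long v) {
    int i = pos[v];
    int last = vox[id].back();
    vox[id][i] = last;
    pos[last] = i;
    vox[id].pop_back();
  }
  void set_label(long v, int newid) {
    int old = lab[v];
    if (old == newid) return;
    if (old > 0) { track_remove(old, v); vol[old]--; } else medium_vol--;
    lab[v] = newid;
    if (newid > 0) { track_add(newid, v); vol[newid]++; } else medium_vol++;
    if (old > 0 && vol[old] == 0) {  // annihilated under dynamics
      type_of[old] = T_DEAD;
      n_annihilated++;
    }
  }
  int new_comp(int type, double target) {
    type_of.push_back(type);
    vol.push_back(0);
    tgt.push_back(target);
    vox.push_back(std::vector<int>());
    return (int)type_of.size() - 1;
  }
  void event(int code, int id) {
    if (record) { ev_mcs.push_back(mcs); ev_code.push_back(code); ev_id.push_back(id); }
  }

  // ---- energy ----------------------------------------------------------
  double delta_h(int src_label, long t) const {
    int oldl = lab[t];
    int told = type_lab(oldl), tnew = type_lab(src_label);
    int x, y, z; coords(t, x, y, z);
    double dc = 0.0;
    for (int k = 0; k < off.n(); ++k) {
      int l = label_at(x + off.dx[k], y + off.dy[k], z + off.dz[k]);
      int tl = type_lab(l);
      int ln = (l == -1) ? 0 : l;  // virtual medium
      if (src_label != ln) dc += par.J[tnew][tl];
      if (oldl != ln) dc -= par.J[told][tl];
    }
    double dv = 0.0;
    if (oldl > 0 && par.constrained(told)) {
      double d = vol[oldl] - tgt[oldl];
      dv += par.lambda * ((d - 1.0) * (d - 1.0) - d * d);
    }
    if (src_label > 0 && par.constrained(tnew)) {
      double d = vol[src_label] - tgt[src_label];
      dv += par.lambda * ((d + 1.0) * (d + 1.0) - d * d);
    }
    return dc + dv;
  }

  // one index-copy attempt; returns 1 accepted, 0 rejected, -1 same-label no-op
  int attempt(double* dh_out = 0, long* t_out = 0, int* src_out = 0) {
    long t = (long)(unif_rand() * N); if (t >= N) t = N - 1;
    int k = (int)(unif_rand() * off.n()); if (k >= off.n()) k = off.n() - 1;
    int x, y, z; coords(t, x, y, z);
    int src = label_at(x + off.dx[k], y + off.dy[k], z + off.dz[k]);
    if (src == -1) src = 0;  // copy from a virtual medium site
    attempts += 1;
    if (t_out) *t_out = t;
    if (src_out) *src_out = src;
    if (src == lab[t]) return -1;
    double dh = delta_h(src, t);
    if (dh_out) *dh_out = dh;
    if (dh <= 0 || unif_rand() < std::exp(-dh / par.Tm)) {
      set_label(t, src);
      accepted += 1;
      return 1;
    }
    return 0;
  }

  // ---- lifecycle -------------------------------------------------------
  void delete_comp(int id) {
    for (size_t i = 0; i < vox[id].size(); ++i) {
      lab[vox[id][i]] = 0;
      medium_vol++;
    }
    vol[id] = 0;
    vox[id].clear();
    type_of[id] = T_DEAD;
  }

  // split along a random-orientation plane: voxels are ordered by their
  // projection on a random unit normal and cut at the median, so the plane
  // passes through the centroid of symmetric bodies and halves differ by <= 1
  int divide(int id) {
    std::vector<int>& vl = vox[id];
    size_t n = vl.size();
    if (n < 2) return -1;
    double gx = 0, gy = 0, gz = 0;
    do { gx = norm_rand(); gy = norm_rand(); gz = norm_rand(); }
    while (gx * gx + gy * gy + gz * gz < 1e-12);
    std::vector<std::pair<double, int> > proj(n);
    for (size_t i = 0; i < n; ++i) {
      int x, y, z; coords(vl[i], x, y, z);
      proj[i] = std::make_pair(gx * x + gy * y + gz * z, vl[i]);
    }
    std::sort(proj.begin(), proj.end());
    size_t keep = (n + 1) / 2;  // parent keeps the lower half (+1 if odd)
    int daughter = new_comp(T_CELL, par.V_daughter);
    for (size_t i = keep; i < n; ++i) set_label(proj[i].second, daughter);
    tgt[id] = par.V_parent;
    n_mitosis++;
    event(EV_MITOSIS, id);
    return daughter;
  }

  // seed a new ECM compartment (up to a 2x2x2 block) at medium voxels
  // face-adjacent to the secreting cell; fails silently if fully enclosed
  int secrete(int cell_id, int kind) {
    static const int fdx[6] = {1, -1, 0, 0, 0, 0};
    static const int fdy[6] = {0, 0, 1, -1, 0, 0};
    static const int fdz[6] = {0, 0, 0, 0, 1, -1};
    std::vector<long> cand;
    const std::vector<int>& vl = vox[cell_id];
    for (size_t i = 0; i < vl.size(); ++i) {
      int x, y, z; coords(vl[i], x, y, z);
      for (int f = 0; f < 6; ++f) {
        int xx = x + fdx[f], yy = y + fdy[f], zz = z + fdz[f];
        if (par.periodic) {
          xx = (xx % nx + nx) % nx; yy = (yy % ny + ny) % ny; zz = (zz % nz + nz) % nz;
        } else if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
          continue;
        }
        long v = idx(xx, yy, zz);
        if (lab[v] == 0) cand.push_back(v);
      }
    }
    if (cand.empty()) {
      n_blocked++;
      event(EV_BLOCKED, cell_id);
      return -1;
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    long anchor = cand[(size_t)(unif_rand() * cand.size()) % cand.size()];
    int ax, ay, az; coords(anchor, ax, ay, az);
    // choose, among the 8 2x2x2 blocks containing the anchor, one holding the
    // most medium voxels (ties broken by RNG)
    int best = -1; std::vector<int> best_corners;
    for (int c = 0; c < 8; ++c) {
      int ox = ax - (c & 1), oy = ay - ((c >> 1) & 1), oz = az - ((c >> 2) & 1);
      int cnt = 0;
      for (int u = 0; u < 8; ++u) {
        int xx = ox + (u & 1), yy = oy + ((u >> 1) & 1), zz = oz + ((u >> 2) & 1);
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        if (lab[idx(xx, yy, zz)] == 0) cnt++;
      }
      if (cnt > best) { best = cnt; best_corners.clear(); }
      if (cnt == best) best_corners.push_back(c);
    }
    int c = best_corners[(size_t)(unif_rand() * best_corners.size()) % best_corners.size()];
    int ox = ax - (c & 1), oy = ay - ((c >> 1) & 1), oz = az - ((c >> 2) & 1);
    int id = new_comp(kind, par.V_ECMInit);
    for (int u = 0; u < 8; ++u) {
      int xx = ox + (u & 1), yy = oy + ((u >> 1) & 1), zz = oz + ((u >> 2) & 1);
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      long v = idx(xx, yy, zz);
      if (lab[v] == 0) set_label(v, id);
    }
    if (kind == T_ST) { n_sec_st++; event(EV_SEC_ST, id); }
    else { n_sec_v++; event(EV_SEC_V, id); }
    return id;
  }

  void update_cell(int id) {
    tgt[id] += par.v_g;
    if ((double)vol[id] > par.V_Death) {
      delete_comp(id);
      n_cell_death++;
      event(EV_CELL_DEATH, id);
      return;
    }
    if ((double)vol[id] > par.V_A) {
      bool did_mitosis = false;
      if (unif_rand() < par.P_M) did_mitosis = divide(id) >= 0;
      if (!did_mitosis || !par.mitosis_preempts) {
        if (unif_rand() < par.P_st) secrete(id, T_ST);
        if (unif_rand() < par.P_v) secrete(id, T_V);
      }
    }
  }

  void update_ecm(int id) {
    tgt[id] -= par.v_d;
    if ((double)vol[id] < par.V_Delete) {
      delete_comp(id);
      n_ecm_del++;
      event(EV_ECM_DEL, id);
    }
  }

  void lifecycle_sweep() {
    std::vector<int> live;
    for (int id = 1; id < (int)type_of.size(); ++id)
      if (type_of[id] != T_DEAD) live.push_back(id);
    // Fisher-Yates shuffle: compartments created this sweep act from the next MCS
    for (int i = (int)live.size() - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1)); if (j > i) j = i;
      std::swap(live[i], live[j]);
    }
    for (size_t i = 0; i < live.size(); ++i) {
      int id = live[i];
      if (type_of[id] == T_DEAD) continue;
      if (type_of[id] == T_CELL) update_cell(id);
      else update_ecm(id);
    }
  }

  void run(int n_mcs, double attempts_per_mcs) {
    long A = (long)attempts_per_mcs;
    for (int s = 0; s < n_mcs; ++s) {
      for (long a = 0; a < A; ++a) attempt();
      if (par.lifecycle) lifecycle_sweep();
      mcs++;
      if ((s & 15) == 0) R_CheckUserInterrupt();
    }
  }
};

static State build_state(IntegerVector labels, IntegerVector ids, IntegerVector types,
                         NumericVector volumes, NumericVector targets, const List& par,
                         int mcs, bool record) {
  State st;
  IntegerVector dim = labels.attr("dim");
  if (dim.size() != 3) stop("labels must be a 3D array");
  st.nx = dim[0]; st.ny = dim[1]; st.nz = dim[2];
  st.N = (long)st.nx * st.ny * st.nz;
  st.par = parse_par(par);
  st.off = make_offsets(st.par.order);
  st.mcs = mcs;
  st.record = record;
  st.attempts = st.accepted = 0;
  st.n_mitosis = st.n_sec_st = st.n_sec_v = st.n_ecm_del = 0;
  st.n_cell_death = st.n_blocked = st.n_annihilated = 0;

  int max_id = 0;
  for (int i = 0; i < ids.size(); ++i) {
    if (ids[i] <= 0) stop("compartment ids must be positive");
    if (ids[i] > max_id) max_id = ids[i];
  }
  st.type_of.assign(max_id + 1, T_DEAD);
  st.type_of[0] = T_MED;
  st.vol.assign(max_id + 1, 0);
  st.tgt.assign(max_id + 1, 0.0);
  st.vox.assign(max_id + 1, std::vector<int>());
  for (int i = 0; i < ids.size(); ++i) {
    st.type_of[ids[i]] = types[i];
    st.tgt[ids[i]] = targets[i];
  }
  st.lab.assign(st.N, 0);
  st.pos.assign(st.N, 0);
  st.medium_vol = 0;
  for (long v = 0; v < st.N; ++v) {
    int l = labels[v];
    if (l < 0 || l > max_id || (l > 0 && st.type_of[l] == T_DEAD))
      stop("lattice label %d is not a registered compartment", l);
    st.lab[v] = l;
    if (l == 0) st.medium_vol++;
    else { st.vol[l]++; st.track_add(l, v); }
  }
  for (int i = 0; i < ids.size(); ++i) {
    if ((double)st.vol[ids[i]] != volumes[i])
      stop("registry volume for id %d (%g) does not match the lattice (%d)",
           ids[i], volumes[i], (int)st.vol[ids[i]]);
  }
  return st;
}

static List state_to_list(const State& st) {
  long n_live = 0;
  for (size_t id = 1; id < st.type_of.size(); ++id)
    if (st.type_of[id] != T_DEAD) n_live++;
  IntegerVector ids((int)n_live), types((int)n_live);
  NumericVector vols((int)n_live), tgts((int)n_live);
  int k = 0;
  for (size_t id = 1; id < st.type_of.size(); ++id) {
    if (st.type_of[id] == T_DEAD) continue;
    ids[k] = (int)id; types[k] = st.type_of[id];
    vols[k] = (double)st.vol[id]; tgts[k] = st.tgt[id];
    k++;
  }
  IntegerVector labels((int)st.N);
  for (long v = 0; v < st.N; ++v) labels[v] = st.lab[v];
  labels.attr("dim") = IntegerVector::create(st.nx, st.ny, st.nz);
  NumericVector counters = NumericVector::create(
      _["attempts"] = st.attempts, _["accepted"] = st.accepted,
      _["mitosis"] = (double)st.n_mitosis,
      _["secrete_ECMst"] = (double)st.n_sec_st,
      _["secrete_ECMv"] = (double)st.n_sec_v,
      _["ecm_deleted"] = (double)st.n_ecm_del,
      _["cell_death"] = (double)st.n_cell_death,
      _["secretion_blocked"] = (double)st.n_blocked,
      _["annihilated"] = (double)st.n_annihilated);
  return List::create(
      _["labels"] = labels, _["ids"] = ids, _["types"] = types,
      _["volumes"] = vols, _["targets"] = tgts,
      _["medium_volume"] = (double)st.medium_vol,
      _["mcs"] = st.mcs, _["counters"] = counters,
      _["ev_mcs"] = wrap(st.ev_mcs), _["ev_code"] = wrap(st.ev_code),
      _["ev_id"] = wrap(st.ev_id));
}

// [[Rcpp::export(.cpm_run)]]
List cpm_run(IntegerVector labels, IntegerVector ids, IntegerVector types,
             NumericVector volumes, NumericVector targets, List par,
             int n_mcs, double attempts_per_mcs, int mcs0, bool record_events) {
  State st = build_state(labels, ids, types, volumes, targets, par, mcs0, record_events);
  st.run(n_mcs, attempts_per_mcs);
  return state_to_list(st);
}

// [[Rcpp::export(.cpm_attempt)]]
List cpm_attempt(IntegerVector labels, IntegerVector ids, IntegerVector types,
                 NumericVector volumes, NumericVector targets, List par) {
  State st = build_state(labels, ids, types, volumes, targets, par, 0, false);
  double dh = NA_REAL; long t = -1; int src = -1;
  int res = st.attempt(&dh, &t, &src);
  List out = state_to_list(st);
  out["accepted"] = (res == 1);
  out["same_label"] = (res == -1);
  out["delta_h"] = dh;
  out["target_voxel"] = (double)(t + 1);  // 1-based linear index
  out["source_label"] = src;
  return out;
}

// [[Rcpp::export(.cpm_delta_h)]]
double cpm_delta_h(IntegerVector labels, IntegerVector ids, IntegerVector types,
                   NumericVector volumes, NumericVector targets, List par,
                   int source_label, double target_voxel) {
  State st = build_state(labels, ids, types, volumes, targets, par, 0, false);
  long t = (long)target_voxel - 1;
  if (t < 0 || t >= st.N) stop("target voxel outside lattice");
  if (source_label == st.lab[t]) stop("source and target voxels carry the same label");
  return st.delta_h(source_label, t);
}

// [[Rcpp::export(.cpm_lifecycle_op)]]
List cpm_lifecycle_op(IntegerVector labels, IntegerVector ids, IntegerVector types,
                      NumericVector volumes, NumericVector targets, List par,
                      int id, std::string op, int kind) {
  State st = build_state(labels, ids, types, volumes, targets, par, 0, true);
  if (id <= 0 || id >= (int)st.type_of.size() || st.type_of[id] == T_DEAD)
    stop("unknown compartment id %d", id);
  int result = NA_INTEGER;
  if (op == "update_cell") {
    if (st.type_of[id] != T_CELL) stop("compartment %d is not a cell", id);
    st.update_cell(id);
  } else if (op == "update_ecm") {
    if (st.type_of[id] != T_ST && st.type_of[id] != T_V)
      stop("compartment %d is not an ECM compartment", id);
    st.update_ecm(id);
  } else if (op == "divide") {
    if (st.type_of[id] != T_CELL) stop("compartment %d is not a cell", id);
    result = st.divide(id);
    if (result < 0) stop("compartment %d has fewer than 2 voxels and cannot divide", id);
  } else if (op == "secrete") {
    if (st.type_of[id] != T_CELL) stop("compartment %d is not a cell", id);
    if (kind != T_ST && kind != T_V) stop("kind must be the ECMst or ECMv type code");
    result = st.secrete(id, kind);
    if (result < 0) result = NA_INTEGER;  // blocked: no adjacent medium
  } else {
    stop("unknown lifecycle op '%s'", op.c_str());
  }
  List out = state_to_list(st);
  out["result_id"] = result;
  return out;
}

// total contact energy, one count per unordered neighbor pair; under the fixed
// boundary each bond to a virtual out-of-lattice medium site counts once
// [[Rcpp::export(.cpm_contact_energy)]]
double cpm_contact_energy(IntegerVector labels, IntegerVector ids, IntegerVector types,
                          NumericMatrix J, int order, bool periodic) {
  IntegerVector dim = labels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  int max_id = 0;
  for (int i = 0; i < ids.size(); ++i) if (ids[i] > max_id) max_id = ids[i];
  std::vector<int> type_of(max_id + 1, T_MED);
  for (int i = 0; i < ids.size(); ++i) type_of[ids[i]] = types[i];
  Offsets off = make_offsets(order);
  double H = 0.0;
  for (long v = 0; v < N; ++v) {
    int l = labels[v];
    int tl = l == 0 ? T_MED : type_of[l];
    int x = (int)(v % nx); long r = v / nx; int y = (int)(r % ny); int z = (int)(r / ny);
    for (int k = 0; k < off.n(); ++k) {
      int xx = x + off.dx[k], yy = y + off.dy[k], zz = z + off.dz[k];
      int ln;
      bool outside = false;
      if (periodic) {
        xx = (xx % nx + nx) % nx; yy = (yy % ny + ny) % ny; zz = (zz % nz + nz) % nz;
        ln = labels[xx + (long)nx * (yy + (long)ny * zz)];
      } else if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
        outside = true; ln = 0;
      } else {
        ln = labels[xx + (long)nx * (yy + (long)ny * zz)];
      }
      if (!outside && !off.pos[k]) continue;  // in-lattice bonds: half the offsets
      if (outside && l == 0) continue;        // medium-virtual medium: same compartment
      if (!outside && ln == l) continue;      // same compartment
      int tn = ln == 0 ? T_MED : type_of[ln];
      H += J(tl, tn);
    }
  }
  return H;
}

// per-unordered-type-pair bond counts between distinct compartments (energy audit)
// [[Rcpp::export(.cpm_bond_counts)]]
NumericMatrix cpm_bond_counts(IntegerVector labels, IntegerVector ids, IntegerVector types,
                              int order, bool periodic) {
  IntegerVector dim = labels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  int max_id = 0;
  for (int i = 0; i < ids.size(); ++i) if (ids[i] > max_id) max_id = ids[i];
  std::vector<int> type_of(max_id + 1, T_MED);
  for (int i = 0; i < ids.size(); ++i) type_of[ids[i]] = types[i];
  Offsets off = make_offsets(order);
  NumericMatrix cnt(4, 4);
  for (long v = 0; v < N; ++v) {
    int l = labels[v];
    int tl = l == 0 ? T_MED : type_of[l];
    int x = (int)(v % nx); long r = v / nx; int y = (int)(r % ny); int z = (int)(r / ny);
    for (int k = 0; k < off.n(); ++k) {
      int xx = x + off.dx[k], yy = y + off.dy[k], zz = z + off.dz[k];
      int ln; bool outside = false;
      if (periodic) {
        xx = (xx % nx + nx) % nx; yy = (yy % ny + ny) % ny; zz = (zz % nz + nz) % nz;
        ln = labels[xx + (long)nx * (yy + (long)ny * zz)];
      } else if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
        outside = true; ln = 0;
      } else {
        ln = labels[xx + (long)nx * (yy + (long)ny * zz)];
      }
      if (!outside && !off.pos[k]) continue;
      if (outside && l == 0) continue;
      if (!outside && ln == l) continue;
      int tn = ln == 0 ? T_MED : type_of[ln];
      int a = std::min(tl, tn), b = std::max(tl, tn);
      cnt(a, b) += 1;
    }
  }
  return cnt;
}

// unordered neighbor-pair count between two compartment ids (0 = medium;
// includes virtual medium sites under the fixed boundary)
// [[Rcpp::export(.cpm_contact_area)]]
double cpm_contact_area(IntegerVector labels, int id_a, int id_b, int order, bool periodic) {
  IntegerVector dim = labels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  if (id_a == id_b) return 0.0;  // the (1 - delta) factor
  Offsets off = make_offsets(order);
  double cnt = 0;
  for (long v = 0; v < N; ++v) {
    int l = labels[v];
    if (l != id_a && l != id_b) continue;
    int want = (l == id_a) ? id_b : id_a;
    int x = (int)(v % nx); long r = v / nx; int y = (int)(r % ny); int z = (int)(r / ny);
    for (int k = 0; k < off.n(); ++k) {
      int xx = x + off.dx[k], yy = y + off.dy[k], zz = z + off.dz[k];
      int ln; bool outside = false;
      if (periodic) {
        xx = (xx % nx + nx) % nx; yy = (yy % ny + ny) % ny; zz = (zz % nz + nz) % nz;
        ln = labels[xx + (long)nx * (yy + (long)ny * zz)];
      } else if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
        outside = true; ln = 0;
      } else {
        ln = labels[xx + (long)nx * (yy + (long)ny * zz)];
      }
      if (!outside && !off.pos[k]) continue;
      if (ln == want && (outside ? want == 0 : true)) {
        if (outside && want != 0) continue;
        cnt += 1;
      }
    }
  }
  return cnt;
}

// face-connected (order-1) component labeling over non-medium voxels
// (mode 0: all matter; mode 1: cell voxels only); returns per-voxel component
// index (0 = background) and, per registered compartment, the component
// holding the majority of its voxels
// [[Rcpp::export(.cpm_components)]]
List cpm_components(IntegerVector labels, IntegerVector ids, IntegerVector types,
                    int mode) {
  IntegerVector dim = labels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  int max_id = 0;
  for (int i = 0; i < ids.size(); ++i) if (ids[i] > max_id) max_id = ids[i];
  std::vector<int> type_of(max_id + 1, T_MED);
  for (int i = 0; i < ids.size(); ++i) type_of[ids[i]] = types[i];
  std::vector<char> in_mask(N, 0);
  for (long v = 0; v < N; ++v) {
    int l = labels[v];
    if (l == 0) continue;
    int t = type_of[l];
    in_mask[v] = (mode == 0) ? (t != T_MED) : (t == T_CELL);
  }
  static const int fdx[6] = {1, -1, 0, 0, 0, 0};
  static const int fdy[6] = {0, 0, 1, -1, 0, 0};
  static const int fdz[6] = {0, 0, 0, 0, 1, -1};
  IntegerVector comp(labels.size(), 0);
  int K = 0;
  std::deque<long> q;
  for (long s = 0; s < N; ++s) {
    if (!in_mask[s] || comp[s] != 0) continue;
    K++;
    comp[s] = K;
    q.push_back(s);
    while (!q.empty()) {
      long v = q.front(); q.pop_front();
      int x = (int)(v % nx); long r = v / nx; int y = (int)(r % ny); int z = (int)(r / ny);
      for (int f = 0; f < 6; ++f) {
        int xx = x + fdx[f], yy = y + fdy[f], zz = z + fdz[f];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        long w = xx + (long)nx * (yy + (long)ny * zz);
        if (in_mask[w] && comp[w] == 0) { comp[w] = K; q.push_back(w); }
      }
    }
  }
  comp.attr("dim") = dim;
  // majority component per compartment id
  std::vector<std::vector<int> > tab(ids.size());
  std::vector<int> id_row(max_id + 1, -1);
  for (int i = 0; i < ids.size(); ++i) { id_row[ids[i]] = i; tab[i].assign(1, 0); }
  std::vector<std::vector<std::pair<int,int> > > counts(ids.size());
  for (long v = 0; v < N; ++v) {
    int l = labels[v];
    if (l == 0 || comp[v] == 0) continue;
    int i = id_row[l];
    if (i < 0) continue;
    bool found = false;
    for (size_t j = 0; j < counts[i].size(); ++j)
      if (counts[i][j].first == comp[v]) { counts[i][j].second++; found = true; break; }
    if (!found) counts[i].push_back(std::make_pair((int)comp[v], 1));
  }
  IntegerVector majority(ids.size(), NA_INTEGER);
  for (int i = 0; i < ids.size(); ++i) {
    int bc = 0, bk = NA_INTEGER;
    for (size_t j = 0; j < counts[i].size(); ++j)
      if (counts[i][j].second > bc) { bc = counts[i][j].second; bk = counts[i][j].first; }
    majority[i] = bk;
  }
  return List::create(_["comp"] = comp, _["n_components"] = K, _["majority"] = majority);
}
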