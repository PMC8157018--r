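// Core behavioral rules and the per-tick simulation loop.
//
// Conventions shared with the R side:
//   * matrices are laid out [row, col] with row 0 (C++) = top of the map;
//     "north" (compass 0) is row - 1, east is col + 1.
//   * directions are compass degrees in {0,45,...,315}, 0 = north, clockwise;
//     -1 is the "no direction" sentinel.
//   * structure codes: 0 normal, 1 obstacle, 2 left exit, 3 right exit.
//   * exits: 1 = left, 2 = right; 0 = "none" where an exit may be absent.
//   * agent cognitive states: 0 WALK, 1 WAIT, 2 PANIC.
//   * occupancy matrix holds the 1-based agent id, 0 = free.
//
// All randomness comes from R's RNG (unif_rand), so set.seed() on the R side
// fully determines a run.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int SCAN_ANG[8] = {0, 45, 90, 135, 180, 225, 270, 315};
// angular offsets from the heading, scanned in dial order:
// ahead, +45 (clockwise), -45, +90, -90, +135, -135, behind
static const int DIAL_OFF[8] = {0, 45, 315, 90, 270, 135, 225, 180};

static inline void ang2d(int ang, int* dr, int* dc) {
  switch (ang) {
    case 0:   *dr = -1; *dc =  0; break;
    case 45:  *dr = -1; *dc =  1; break;
    case 90:  *dr =  0; *dc =  1; break;
    case 135: *dr =  1; *dc =  1; break;
    case 180: *dr =  1; *dc =  0; break;
    case 225: *dr =  1; *dc = -1; break;
    case 270: *dr =  0; *dc = -1; break;
    case 315: *dr = -1; *dc = -1; break;
    default:  *dr =  0; *dc =  0; break;
  }
}

// uniform integer in [0, n)
static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

struct Probs {
  double emot_dev;  // emotional agent in panic adopts neighbor's exit
  double s2_same;   // rational, no panic, Ae == Ne
  double s2_diff;   // rational, no panic, Ae != Ne
  double s3[8];     // indexed by panic*4 + (Ae!=Ne)*2 + (Ae!=Ep)
};

static Probs probs_from_list(List probs) {
  Probs P;
  P.emot_dev = as<double>(probs["emotional_deviation"]);
  P.s2_same  = as<double>(probs["rational_same"]);
  P.s2_diff  = as<double>(probs["rational_diff"]);
  NumericVector t = probs["s3_table"];
  if (t.size() != 8) stop("s3_table must have 8 entries");
  for (int i = 0; i < 8; ++i) P.s3[i] = t[i];
  return P;
}

// Exit decision for one activation. ne/ep/me are 0 when absent.
static int decide_core(int strategy, bool rational, int panic, int ae,
                       int ne, int ep, int me, const Probs& P) {
  int alt = (ae == 1) ? 2 : 1;
  if (strategy == 1) return ae;
  if (strategy == 2 || strategy == 4) {
    if (!rational) {
      if (ne != 0 && ae != ne && panic > 0 && unif_rand() < P.emot_dev)
        return ne;
      return ae;
    }
    if (panic <= 0) {
      if (ne == 0) return ae;
      double p = (ae == ne) ? P.s2_same : P.s2_diff;
      return (unif_rand() < p) ? alt : ae;
    }
    if (strategy == 4) return (me != 0) ? me : ae;
    if (ne != 0 && ae == ne) return alt;  // panicking rational: anti-herding
    return ae;
  }
  // strategy 3: rational agents only; needs both a neighbor and a dominant
  // exit potential, otherwise the influence channels are silent -> keep
  if (!rational) return ae;
  if (ne == 0 || ep == 0) return ae;
  int idx = (panic > 0 ? 4 : 0) + (ae != ne ? 2 : 0) + (ae != ep ? 1 : 0);
  double p = P.s3[idx];
  if (p >= 1.0) return alt;
  if (p <= 0.0) return ae;
  return (unif_rand() < p) ? alt : ae;
}

// Dial scan around the heading: first in-bounds, walkable, free cell.
static bool sel_next(const IntegerMatrix& S, const IntegerMatrix& occ,
                     int r, int c, int heading,
                     int& nr, int& nc, int& rank) {
  if (heading < 0) return false;
  for (int k = 0; k < 8; ++k) {
    int ang = (heading + DIAL_OFF[k]) % 360;
    int dr, dc;
    ang2d(ang, &dr, &dc);
    int rr = r + dr, cc = c + dc;
    if (rr < 0 || cc < 0 || rr >= S.nrow() || cc >= S.ncol()) continue;
    if (S(rr, cc) == 1) continue;
    if (occ(rr, cc) != 0) continue;
    nr = rr; nc = cc; rank = k + 1;
    return true;
  }
  return false;
}

static inline int next_state(bool moved, int waiting_index, int threshold) {
  if (moved) return 0;
  return (waiting_index < threshold) ? 1 : 2;
}

static inline double mi_update(double mi, int state, double sens) {
  if (state == 0) return mi + 1.0;
  if (state == 1) return mi - 1.0;
  return mi - mi * sens;
}

static void seed_pot(NumericMatrix& pv, const IntegerMatrix& S, int r, int c) {
  for (int k = 0; k < 8; ++k) {
    int dr, dc;
    ang2d(SCAN_ANG[k], &dr, &dc);
    int rr = r + dr, cc = c + dc;
    if (rr < 0 || cc < 0 || rr >= S.nrow() || cc >= S.ncol()) continue;
    if (S(rr, cc) == 1) continue;  // obstacles never carry potential
    pv(rr, cc) = 1.0;
  }
}

// Agent-borne spread, synchronous from a snapshot of the field.
static void spread_pot(const IntegerMatrix& S, NumericMatrix& pv,
                       const IntegerMatrix& occ, double atten) {
  NumericMatrix src = clone(pv);
  int H = S.nrow(), W = S.ncol();
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (occ(r, c) == 0) continue;
      double p = src(r, c);
      if (p <= 0) continue;
      double v = atten * p;
      for (int k = 0; k < 8; ++k) {
        int dr, dc;
        ang2d(SCAN_ANG[k], &dr, &dc);
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || cc < 0 || rr >= H || cc >= W) continue;
        if (S(rr, cc) == 1) continue;
        if (src(rr, cc) < p && pv(rr, cc) < v) pv(rr, cc) = v;
      }
    }
  }
}

static void decay_pot(NumericMatrix& pv, double f) {
  int n = pv.size();
  for (int i = 0; i < n; ++i) {
    double v = pv[i] * f;
    pv[i] = (v < 1e-6) ? 0.0 : v;
  }
}

// ---------------------------------------------------------------------------
// engine state

struct Eng {
  IntegerMatrix S, dom_l, dom_r, occ;
  NumericMatrix pv_l, pv_r;
  IntegerVector alive, row, col, type, cstate, cexit,
                mov, wai, pan, heading, distant, everp;
  NumericVector mi;
  int tick, exited_l, exited_r, maxpan, everp_r, everp_e, n0;
};

static Eng eng_from_list(List st) {
  Eng E;
  E.S      = clone(as<IntegerMatrix>(st["structure"]));
  E.dom_l  = clone(as<IntegerMatrix>(st["dom_left"]));
  E.dom_r  = clone(as<IntegerMatrix>(st["dom_right"]));
  E.occ    = clone(as<IntegerMatrix>(st["occupancy"]));
  E.pv_l   = clone(as<NumericMatrix>(st["pv_left"]));
  E.pv_r   = clone(as<NumericMatrix>(st["pv_right"]));
  List ag  = st["agents"];
  E.alive   = clone(as<IntegerVector>(ag["alive"]));
  E.row     = clone(as<IntegerVector>(ag["row"]));
  E.col     = clone(as<IntegerVector>(ag["col"]));
  E.type    = clone(as<IntegerVector>(ag["type"]));
  E.cstate  = clone(as<IntegerVector>(ag["state"]));
  E.cexit   = clone(as<IntegerVector>(ag["exit"]));
  E.mov     = clone(as<IntegerVector>(ag["moving_index"]));
  E.wai     = clone(as<IntegerVector>(ag["waiting_index"]));
  E.pan     = clone(as<IntegerVector>(ag["panic_index"]));
  E.heading = clone(as<IntegerVector>(ag["heading"]));
  E.distant = clone(as<IntegerVector>(ag["distant"]));
  E.everp   = clone(as<IntegerVector>(ag["ever_panicked"]));
  E.mi      = clone(as<NumericVector>(ag["mobility_index"]));
  E.tick     = as<int>(st["tick"]);
  E.exited_l = as<int>(st["exited_left"]);
  E.exited_r = as<int>(st["exited_right"]);
  E.maxpan   = as<int>(st["max_concurrent_panic"]);
  E.everp_r  = as<int>(st["ever_panicked_rational"]);
  E.everp_e  = as<int>(st["ever_panicked_emotional"]);
  E.n0       = as<int>(st["n_initial"]);
  return E;
}

static List eng_to_list(const Eng& E) {
  List ag = List::create(
    _["alive"] = E.alive, _["row"] = E.row, _["col"] = E.col,
    _["type"] = E.type, _["state"] = E.cstate, _["exit"] = E.cexit,
    _["moving_index"] = E.mov, _["waiting_index"] = E.wai,
    _["panic_index"] = E.pan, _["heading"] = E.heading,
    _["distant"] = E.distant, _["ever_panicked"] = E.everp,
    _["mobility_index"] = E.mi);
  List st = List::create(
    _["structure"] = E.S, _["dom_left"] = E.dom_l, _["dom_right"] = E.dom_r,
    _["occupancy"] = E.occ, _["pv_left"] = E.pv_l, _["pv_right"] = E.pv_r,
    _["agents"] = ag, _["tick"] = E.tick,
    _["exited_left"] = E.exited_l, _["exited_right"] = E.exited_r,
    _["max_concurrent_panic"] = E.maxpan,
    _["ever_panicked_rational"] = E.everp_r,
    _["ever_panicked_emotional"] = E.everp_e,
    _["n_initial"] = E.n0);
  st.attr("class") = "sim_state";
  return st;
}

struct TraceBuf {
  std::vector<int> tick, id, row, col, state, cexit;
  std::vector<double> mi;
};

// One tick: sequential random activation; per agent
// decide -> heading -> select cell -> move/state/indices -> MI.
static void step_one(Eng& E, int strategy, int threshold, double sens,
                     double decay, double atten, const Probs& P,
                     TraceBuf* trace) {
  int n = E.alive.size();
  std::vector<int> ord;
  ord.reserve(n);
  for (int i = 0; i < n; ++i)
    if (E.alive[i]) ord.push_back(i);
  for (int i = (int)ord.size() - 1; i > 0; --i) {
    int j = rand_below(i + 1);
    int tmp = ord[i]; ord[i] = ord[j]; ord[j] = tmp;
  }

  for (size_t k = 0; k < ord.size(); ++k) {
    int a = ord[k];
    int r = E.row[a], c = E.col[a];
    int ne = 0, ep = 0, me = 0;
    bool rational = (E.type[a] == 1);

    if (strategy >= 2) {
      int nb[8], nn = 0;
      for (int q = 0; q < 8; ++q) {
        int dr, dc;
        ang2d(SCAN_ANG[q], &dr, &dc);
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || cc < 0 || rr >= E.S.nrow() || cc >= E.S.ncol()) continue;
        int id = E.occ(rr, cc);
        if (id != 0) nb[nn++] = id;
      }
      if (nn > 0) ne = E.cexit[nb[rand_below(nn)] - 1];
      if (strategy == 3) {
        double pl = E.pv_l(r, c), pr = E.pv_r(r, c);
        ep = (pl > pr) ? 1 : (pr > pl) ? 2 : 0;
      }
      if (strategy == 4 && rational && E.pan[a] > 0) {
        // max-MI contact among local neighbors plus the distant tie
        int cand[9], ncand = 0;
        for (int q = 0; q < nn; ++q) cand[ncand++] = nb[q];
        int d = E.distant[a];
        if (d > 0 && E.alive[d - 1]) cand[ncand++] = d;
        if (ncand > 0) {
          double best = R_NegInf;
          for (int q = 0; q < ncand; ++q)
            if (E.mi[cand[q] - 1] > best) best = E.mi[cand[q] - 1];
          int ties[9], nt = 0;
          for (int q = 0; q < ncand; ++q)
            if (E.mi[cand[q] - 1] == best) ties[nt++] = cand[q];
          int pick = (nt > 1) ? ties[rand_below(nt)] : ties[0];
          me = E.cexit[pick - 1];
        }
      }
    }

    E.cexit[a] = decide_core(strategy, rational, E.pan[a], E.cexit[a],
                             ne, ep, me, P);

    int dom = (E.cexit[a] == 1) ? E.dom_l(r, c) : E.dom_r(r, c);
    if (dom >= 0) E.heading[a] = dom;  // else keep previous heading

    int nr = 0, nc = 0, rank = 0;
    bool moved = sel_next(E.S, E.occ, r, c, E.heading[a], nr, nc, rank);
    if (moved) {
      E.occ(r, c) = 0;
      int sc = E.S(nr, nc);
      if (sc == 2 || sc == 3) {
        // stepped onto an exit patch: leave the simulation immediately
        E.alive[a] = 0;
        if (sc == 2) E.exited_l++; else E.exited_r++;
        if (strategy == 3) {
          if (sc == 2) seed_pot(E.pv_l, E.S, nr, nc);
          else         seed_pot(E.pv_r, E.S, nr, nc);
        }
        if (trace) {
          trace->tick.push_back(E.tick + 1); trace->id.push_back(a + 1);
          trace->row.push_back(nr); trace->col.push_back(nc);
          trace->state.push_back(-1); trace->cexit.push_back(sc == 2 ? 1 : 2);
          trace->mi.push_back(E.mi[a]);
        }
        continue;
      }
      E.occ(nr, nc) = a + 1;
      E.row[a] = nr; E.col[a] = nc;
    }

    int st = next_state(moved, E.wai[a], threshold);
    E.cstate[a] = st;
    if (st == 0)      { E.mov[a]++; E.wai[a] = 0; E.pan[a] = 0; }
    else if (st == 1) { E.wai[a]++; E.mov[a] = 0; E.pan[a] = 0; }
    else {
      E.pan[a]++; E.mov[a] = 0; E.wai[a] = 0;
      if (!E.everp[a]) {
        E.everp[a] = 1;
        if (rational) E.everp_r++; else E.everp_e++;
      }
    }
    E.mi[a] = mi_update(E.mi[a], st, sens);

    if (trace) {
      trace->tick.push_back(E.tick + 1); trace->id.push_back(a + 1);
      trace->row.push_back(E.row[a]); trace->col.push_back(E.col[a]);
      trace->state.push_back(E.cstate[a]); trace->cexit.push_back(E.cexit[a]);
      trace->mi.push_back(E.mi[a]);
    }
  }

  if (strategy == 3) {
    spread_pot(E.S, E.pv_l, E.occ, atten);
    spread_pot(E.S, E.pv_r, E.occ, atten);
    decay_pot(E.pv_l, decay);
    decay_pot(E.pv_r, decay);
  }

  int np = 0;
  for (int i = 0; i < n; ++i)
    if (E.alive[i] && E.cstate[i] == 2) np++;
  if (np > E.maxpan) E.maxpan = np;
  E.tick++;
}

struct Cfg {
  int strategy, threshold, max_ticks;
  double sens, decay, atten;
  Probs P;
};

static Cfg cfg_from_list(List config) {
  Cfg C;
  C.strategy  = as<int>(config["strategy"]);
  C.threshold = as<int>(config["panic_threshold"]);
  C.max_ticks = as<int>(config["max_ticks"]);
  C.sens      = as<double>(config["sensitivity"]);
  C.decay     = as<double>(config["decay_factor"]);
  C.atten     = as<double>(config["spread_attenuation"]);
  C.P         = probs_from_list(config["probs"]);
  return C;
}

// [[Rcpp::export]]
List cpp_step(List state, List config) {
  Eng E = eng_from_list(state);
  Cfg C = cfg_from_list(config);
  step_one(E, C.strategy, C.threshold, C.sens, C.decay, C.atten, C.P, NULL);
  return eng_to_list(E);
}

// [[Rcpp::export]]
List cpp_run(List state, List config, bool record_log, bool record_trace) {
  Eng E = eng_from_list(state);
  Cfg C = cfg_from_list(config);
  TraceBuf trace;
  std::vector<int> log_tick, log_pop, log_el, log_er, log_pan;

  int alive = 0;
  for (int i = 0; i < E.alive.size(); ++i)
    if (E.alive[i]) alive++;

  while (alive > 0 && E.tick < C.max_ticks) {
    step_one(E, C.strategy, C.threshold, C.sens, C.decay, C.atten, C.P,
             record_trace ? &trace : NULL);
    alive = 0;
    for (int i = 0; i < E.alive.size(); ++i)
      if (E.alive[i]) alive++;
    if (record_log) {
      log_tick.push_back(E.tick);
      log_pop.push_back(alive);
      log_el.push_back(E.exited_l);
      log_er.push_back(E.exited_r);
      int np = 0;
      for (int i = 0; i < E.alive.size(); ++i)
        if (E.alive[i] && E.cstate[i] == 2) np++;
      log_pan.push_back(np);
    }
  }

  List out = List::create(
    _["state"] = eng_to_list(E),
    _["exit_time"] = E.tick,
    _["exited_left"] = E.exited_l,
    _["exited_right"] = E.exited_r,
    _["max_concurrent_panic"] = E.maxpan,
    _["ever_panicked_rational"] = E.everp_r,
    _["ever_panicked_emotional"] = E.everp_e,
    _["terminated"] = (alive == 0));
  if (record_log) {
    out["log"] = DataFrame::create(
      _["tick"] = log_tick, _["population"] = log_pop,
      _["exited_left"] = log_el, _["exited_right"] = log_er,
      _["panicking"] = log_pan);
  }
  if (record_trace) {
    out["trace"] = DataFrame::create(
      _["tick"] = trace.tick, _["id"] = trace.id,
      _["row"] = trace.row, _["col"] = trace.col,
      _["state"] = trace.state, _["exit"] = trace.cexit,
      _["mobility_index"] = trace.mi);
  }
  return out;
}

// ---------------------------------------------------------------------------
// fine-grained exports: the R module surface wraps these, so unit-level
// operations and the engine run identical code

// n replicated decisions under fixed context; returns chosen exits
// [[Rcpp::export]]
IntegerVector cpp_decide_exit(int n, int strategy, bool rational, int panic,
                              int ae, int ne, int ep, int me, List probs) {
  Probs P = probs_from_list(probs);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = decide_core(strategy, rational, panic, ae, ne, ep, me, P);
  return out;
}

// [[Rcpp::export]]
List cpp_select_next_cell(IntegerMatrix S, IntegerMatrix occ,
                          int r, int c, int heading) {
  int nr = 0, nc = 0, rank = 0;
  bool moved = sel_next(S, occ, r, c, heading, nr, nc, rank);
  return List::create(_["moved"] = moved, _["row"] = nr, _["col"] = nc,
                      _["rank"] = rank);
}

// state machine + index bookkeeping after a move attempt
// [[Rcpp::export]]
List cpp_post_move_update(bool moved, int moving_index, int waiting_index,
                          int panic_index, int threshold) {
  int st = next_state(moved, waiting_index, threshold);
  int mov = moving_index, wai = waiting_index, pan = panic_index;
  if (st == 0)      { mov++; wai = 0; pan = 0; }
  else if (st == 1) { wai++; mov = 0; pan = 0; }
  else              { pan++; mov = 0; wai = 0; }
  return List::create(_["state"] = st, _["moving_index"] = mov,
                      _["waiting_index"] = wai, _["panic_index"] = pan);
}

// [[Rcpp::export]]
double cpp_update_mi(double mi, int state, double sensitivity) {
  return mi_update(mi, state, sensitivity);
}

// [[Rcpp::export]]
NumericMatrix cpp_seed_potential(NumericMatrix pv, IntegerMatrix S,
                                 int r, int c) {
  NumericMatrix out = clone(pv);
  seed_pot(out, S, r, c);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_spread_potential(IntegerMatrix S, NumericMatrix pv,
                                   IntegerMatrix occ, double atten) {
  NumericMatrix out = clone(pv);
  spread_pot(S, out, occ, atten);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_decay_potential(NumericMatrix pv, double factor) {
  NumericMatrix out = clone(pv);
  decay_pot(out, factor);
  return out;
}

// uniform draw of an occupant id from the Moore neighborhood, 0 if empty
// [[Rcpp::export]]
int cpp_pick_random_neighbor(IntegerMatrix occ, int r, int c) {
  int nb[8], nn = 0;
  for (int q = 0; q < 8; ++q) {
    int dr, dc;
    ang2d(SCAN_ANG[q], &dr, &dc);
    int rr = r + dr, cc = c + dc;
    if (rr < 0 || cc < 0 || rr >= occ.nrow() || cc >= occ.ncol()) continue;
    if (occ(rr, cc) != 0) nb[nn++] = occ(rr, cc);
  }
  if (nn == 0) return 0;
  return nb[rand_below(nn)];
}

// argmax with uniform tie-break; returns 1-based index into x, 0 if empty
// [[Rcpp::export]]
int cpp_pick_max_index(NumericVector x) {
  int n = x.size();
  if (n == 0) return 0;
  double best = R_NegInf;
  for (int i = 0; i < n; ++i)
    if (x[i] > best) best = x[i];
  std::vector<int> ties;
  for (int i = 0; i < n; ++i)
    if (x[i] == best) ties.push_back(i + 1);
  if (ties.size() == 1) return ties[0];
  return ties[rand_below((int)ties.size())];
}
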