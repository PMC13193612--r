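// Core per-frame policies of the prey-pursuit game.
//
// All positions are in pixels; speed and radius constants arrive from R
// already resolved into the units used here (degrees for speeds and threat
// radii, pixels for arena geometry). The policies are fully deterministic:
// candidate ties break toward the lowest angle index so that identical
// states always produce identical steps.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct EngineCfg {
  double W, H;          // arena, px
  double ppd;           // px per degree
  double fr;            // frames per second
  double char_r;        // character radius, px
  double esc_w, cent_w; // prey cost weights
  int n_cand;           // candidate count
  double spacing;       // candidate spacing, radians
  double threat_r;      // deg: full prey speed within this opponent distance
  double sig_c, sig_k;  // prey speed sigmoid centre (deg) and steepness (1/deg)
  double lookahead_s;   // autopilot prediction horizon, s
  int ap_hist;          // autopilot history length, frames
  double horizon;       // direction-decision horizon, s
  double ux[32], uy[32]; // precomputed unit offsets for candidate angles
};

EngineCfg parse_cfg(const List& cfg) {
  EngineCfg c;
  c.W = cfg["arena_width"];
  c.H = cfg["arena_height"];
  c.ppd = cfg["px_per_deg"];
  c.fr = cfg["frame_rate"];
  c.char_r = cfg["character_radius_px"];
  c.esc_w = cfg["escape_weight"];
  c.cent_w = cfg["centrality_weight"];
  c.n_cand = cfg["candidate_count"];
  double spacing_deg = cfg["candidate_spacing"];
  c.spacing = spacing_deg * M_PI / 180.0;
  c.threat_r = cfg["threat_radius"];
  c.sig_c = cfg["sigmoid_center"];
  c.sig_k = cfg["sigmoid_steepness"];
  c.lookahead_s = cfg["autopilot_lookahead"];
  c.ap_hist = cfg["autopilot_history"];
  c.horizon = cfg["decision_horizon"];
  for (int k = 0; k < c.n_cand && k < 32; ++k) {
    c.ux[k] = std::cos(k * c.spacing);
    c.uy[k] = std::sin(k * c.spacing);
  }
  return c;
}

inline double edist(double ax, double ay, double bx, double by) {
  double dx = ax - bx, dy = ay - by;
  return std::sqrt(dx * dx + dy * dy);
}

inline bool in_bounds(double x, double y, const EngineCfg& c) {
  return x >= c.char_r && x <= c.W - c.char_r &&
         y >= c.char_r && y <= c.H - c.char_r;
}

// Enumerate candidate positions step px away, angles k * spacing, then drop
// those overlapping a border or another character. Returns count; fills
// cx/cy/idx (idx keeps the original angle index for deterministic ties).
int gen_candidates(double x, double y, double step, const EngineCfg& c,
                   const double* ox, const double* oy, int n_others,
                   double* cx, double* cy, int* idx) {
  int m = 0;
  double rr = 4.0 * c.char_r * c.char_r;  // squared overlap radius
  for (int k = 0; k < c.n_cand; ++k) {
    double px = x + step * c.ux[k];
    double py = y + step * c.uy[k];
    if (!in_bounds(px, py, c)) continue;
    bool clash = false;
    for (int j = 0; j < n_others; ++j) {
      double dx = px - ox[j], dy = py - oy[j];
      if (dx * dx + dy * dy < rr) { clash = true; break; }
    }
    if (clash) continue;
    cx[m] = px; cy[m] = py; idx[m] = k; ++m;
  }
  return m;
}

inline void minmax_norm(double* v, int n) {
  double lo = v[0], hi = v[0];
  for (int i = 1; i < n; ++i) { if (v[i] < lo) lo = v[i]; if (v[i] > hi) hi = v[i]; }
  double r = hi - lo;
  for (int i = 0; i < n; ++i) v[i] = (r > 0) ? (v[i] - lo) / r : 0.0;
}

// Prey speed (deg/s): full max while the opponent is within the threat
// radius, then a logistic decay that is < 2% of max beyond 50 deg.
double prey_speed_deg(double d_opp_deg, double max_speed, const EngineCfg& c) {
  if (d_opp_deg <= c.threat_r) return max_speed;
  return max_speed / (1.0 + std::exp(c.sig_k * (d_opp_deg - c.sig_c)));
}

// Prey direction decision. Candidates are evaluated at the decision
// horizon (speed * horizon px from the agent); hist holds up to 2 previous
// prey positions for the revisit rule, whose exclusion radius is half a
// per-frame step. Returns the chosen horizon position (the prey's
// predicted next decision-scale position) and the chosen angle index, or
// found = false when fully cornered.
void prey_choose(double px, double py,
                 const double* hx, const double* hy, int nh,
                 double opx, double opy, double plx, double ply,
                 double prey_max, const EngineCfg& c,
                 double& chx, double& chy, int& chk, bool& found) {
  double d_opp = edist(px, py, opx, opy) / c.ppd;
  double sp_px = prey_speed_deg(d_opp, prey_max, c) * c.ppd;
  double step_h = sp_px * c.horizon;
  double step_f = sp_px / c.fr;
  if (step_h <= 0) { chx = px; chy = py; chk = -1; found = true; return; }

  double cx[32], cy[32], esc[32], cen[32];
  int idx[32];
  double ox[2] = {opx, plx}, oy[2] = {opy, ply};
  int m = gen_candidates(px, py, step_h, c, ox, oy, 2, cx, cy, idx);
  if (m == 0) { found = false; chx = px; chy = py; chk = -1; return; }

  double d0p = edist(px, py, plx, ply), d0o = edist(px, py, opx, opy);
  for (int i = 0; i < m; ++i) {
    // escape: larger summed distance increase is better, so negate
    esc[i] = -((edist(cx[i], cy[i], plx, ply) - d0p) +
               (edist(cx[i], cy[i], opx, opy) - d0o));
    cen[i] = edist(cx[i], cy[i], c.W / 2.0, c.H / 2.0);
  }
  minmax_norm(esc, m);
  minmax_norm(cen, m);

  double rev2 = (step_f / 2.0) * (step_f / 2.0);
  int best = -1, best_all = -1;
  double bc = 0, bca = 0;
  for (int i = 0; i < m; ++i) {
    double cost = c.esc_w * esc[i] + c.cent_w * cen[i];
    if (best_all < 0 || cost < bca) { best_all = i; bca = cost; }
    bool revisited = false;
    for (int h = 0; h < nh; ++h) {
      double dx = cx[i] - hx[h], dy = cy[i] - hy[h];
      if (dx * dx + dy * dy < rev2) { revisited = true; break; }
    }
    if (revisited) continue;
    if (best < 0 || cost < bc) { best = i; bc = cost; }
  }
  if (best < 0) best = best_all;  // all excluded by revisit rule
  chx = cx[best]; chy = cy[best]; chk = idx[best]; found = true;
}

// One per-frame prey step: a speed/frame_rate displacement along the
// chosen decision direction.
void prey_move(double px, double py,
               const double* hx, const double* hy, int nh,
               double opx, double opy, double plx, double ply,
               double prey_max, const EngineCfg& c,
               double& outx, double& outy) {
  double chx, chy; int chk; bool found;
  prey_choose(px, py, hx, hy, nh, opx, opy, plx, ply, prey_max, c,
              chx, chy, chk, found);
  if (!found || chk < 0) { outx = px; outy = py; return; }
  double d_opp = edist(px, py, opx, opy) / c.ppd;
  double step_f = prey_speed_deg(d_opp, prey_max, c) * c.ppd / c.fr;
  outx = px + step_f * c.ux[chk];
  outy = py + step_f * c.uy[chk];
}

// The opponent's internal model of the prey: the escape core of the prey
// algorithm in continuous form. The prey is predicted to move one decision
// horizon along the unit-sum of its flee directions from the (hypothetical)
// opponent position and the player, at the sigmoid-governed speed. Unlike
// the prey's own 24-degree-quantized argmin, this prediction responds
// continuously to the opponent's candidate, which is what lets the
// F-weighted cost express graded intention frame by frame.
void predict_prey(double px, double py, double ox, double oy,
                  double plx, double ply, double prey_max,
                  const EngineCfg& c, double& qx, double& qy) {
  double d_opp_px = edist(px, py, ox, oy);
  double d_pla_px = edist(px, py, plx, ply);
  double ex = 0, ey = 0;
  if (d_opp_px > 0) { ex += (px - ox) / d_opp_px; ey += (py - oy) / d_opp_px; }
  if (d_pla_px > 0) { ex += (px - plx) / d_pla_px; ey += (py - ply) / d_pla_px; }
  double en = std::sqrt(ex * ex + ey * ey);
  double step_h = prey_speed_deg(d_opp_px / c.ppd, prey_max, c) * c.ppd *
    c.horizon;
  if (en > 1e-12) { qx = px + step_h * ex / en; qy = py + step_h * ey / en; }
  else { qx = px; qy = py; }  // pincered prey predicted to hold position
}

// One opponent step: for each horizon candidate, predict the prey's next
// decision-scale position with the continuous prey model (candidate
// substituted as the opponent), compute d_play (predicted prey to current
// player) and d_oppo (predicted prey to the candidate), min-max normalize
// each across candidates (as the prey's own costs are), and minimize
// F * d_play + (1 - F) * d_oppo. Without the normalization d_oppo varies
// with the candidate on every frame while d_play moves only when the
// prey's discrete choice flips, so the raw mixture degenerates to pure
// interception for nearly all F. Move one frame step along the chosen
// direction.
void opp_move(double opx, double opy,
              double px, double py,
              const double* phx, const double* phy, int nh,
              double plx, double ply,
              double F, double opp_speed, double prey_max,
              const EngineCfg& c,
              double& outx, double& outy) {
  double step_h = opp_speed * c.ppd * c.horizon;
  double step_f = opp_speed * c.ppd / c.fr;
  double cx[32], cy[32], dplay[32], doppo[32];
  int idx[32];
  double ox[2] = {px, plx}, oy[2] = {py, ply};
  int m = gen_candidates(opx, opy, step_h, c, ox, oy, 2, cx, cy, idx);
  if (m == 0) { outx = opx; outy = opy; return; }

  for (int i = 0; i < m; ++i) {
    double qx, qy;
    predict_prey(px, py, cx[i], cy[i], plx, ply, prey_max, c, qx, qy);
    dplay[i] = edist(qx, qy, plx, ply);
    doppo[i] = edist(qx, qy, cx[i], cy[i]);
  }
  minmax_norm(dplay, m);
  minmax_norm(doppo, m);
  int best = -1;
  double bc = 0;
  for (int i = 0; i < m; ++i) {
    double cost = F * dplay[i] + (1.0 - F) * doppo[i];
    if (best < 0 || cost < bc) { best = i; bc = cost; }
  }
  outx = opx + step_f * c.ux[idx[best]];
  outy = opy + step_f * c.uy[idx[best]];
}

// Autopilot: aim at the prey's position extrapolated lookahead_s ahead from
// its mean per-frame displacement over the last ap_hist frames.
void ap_move(double plx, double ply,
             const double* phx, const double* phy, int nh,
             double px, double py,
             double speed, const EngineCfg& c,
             double& outx, double& outy) {
  double dx = 0, dy = 0;
  if (nh > 0) {
    int k = nh < c.ap_hist ? nh : c.ap_hist;
    // history: previous prey positions, most recent last
    dx = (px - phx[nh - k]) / k;
    dy = (py - phy[nh - k]) / k;
  }
  double nfr = c.lookahead_s * c.fr;
  double tx = px + dx * nfr, ty = py + dy * nfr;
  double step = speed * c.ppd / c.fr;
  double d = edist(plx, ply, tx, ty);
  double nx, ny;
  if (d <= step || d == 0) { nx = tx; ny = ty; }
  else {
    nx = plx + step * (tx - plx) / d;
    ny = ply + step * (ty - ply) / d;
  }
  if (nx < c.char_r) nx = c.char_r;
  if (nx > c.W - c.char_r) nx = c.W - c.char_r;
  if (ny < c.char_r) ny = c.char_r;
  if (ny > c.H - c.char_r) ny = c.H - c.char_r;
  outx = nx; outy = ny;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_candidates(double x, double y, double step,
                             NumericMatrix others, List cfg) {
  EngineCfg c = parse_cfg(cfg);
  double cx[32], cy[32];
  int idx[32];
  int n_others = others.nrow();
  std::vector<double> ox(n_others), oy(n_others);
  for (int j = 0; j < n_others; ++j) { ox[j] = others(j, 0); oy[j] = others(j, 1); }
  int m = gen_candidates(x, y, step, c, ox.data(), oy.data(), n_others,
                         cx, cy, idx);
  NumericMatrix out(m, 3);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = cx[i]; out(i, 1) = cy[i]; out(i, 2) = idx[i] + 1;
  }
  colnames(out) = CharacterVector::create("x", "y", "index");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_prey_step(NumericVector prey, NumericMatrix prey_hist,
                            NumericVector opponent, NumericVector player,
                            double prey_max, List cfg) {
  EngineCfg c = parse_cfg(cfg);
  int nh = prey_hist.nrow();
  std::vector<double> hx(nh), hy(nh);
  for (int i = 0; i < nh; ++i) { hx[i] = prey_hist(i, 0); hy[i] = prey_hist(i, 1); }
  double ox, oy;
  prey_move(prey[0], prey[1], hx.data(), hy.data(), nh,
            opponent[0], opponent[1], player[0], player[1], prey_max, c, ox, oy);
  return NumericVector::create(ox, oy);
}

// [[Rcpp::export]]
NumericVector cpp_opponent_step(NumericVector opponent, NumericVector prey,
                                NumericMatrix prey_hist, NumericVector player,
                                double F, double opp_speed, double prey_max,
                                List cfg) {
  EngineCfg c = parse_cfg(cfg);
  int nh = prey_hist.nrow();
  std::vector<double> hx(nh), hy(nh);
  for (int i = 0; i < nh; ++i) { hx[i] = prey_hist(i, 0); hy[i] = prey_hist(i, 1); }
  double ox, oy;
  opp_move(opponent[0], opponent[1], prey[0], prey[1],
           hx.data(), hy.data(), nh, player[0], player[1],
           F, opp_speed, prey_max, c, ox, oy);
  return NumericVector::create(ox, oy);
}

// [[Rcpp::export]]
NumericVector cpp_autopilot_step(NumericVector player, NumericMatrix prey_hist,
                                 NumericVector prey, double speed, List cfg) {
  EngineCfg c = parse_cfg(cfg);
  int nh = prey_hist.nrow();
  std::vector<double> hx(nh), hy(nh);
  for (int i = 0; i < nh; ++i) { hx[i] = prey_hist(i, 0); hy[i] = prey_hist(i, 1); }
  double ox, oy;
  ap_move(player[0], player[1], hx.data(), hy.data(), nh,
          prey[0], prey[1], speed, c, ox, oy);
  return NumericVector::create(ox, oy);
}

// [[Rcpp::export]]
double cpp_prey_speed(double d_opp_deg, double prey_max, List cfg) {
  EngineCfg c = parse_cfg(cfg);
  return prey_speed_deg(d_opp_deg, prey_max, c);
}

// Run one phase until capture or the frame cap. All three agents are
// advanced simultaneously from the committed previous frame. If both
// pursuers enter the capture radius on the same frame the player wins the
// tie (deterministic, favours the participant).
//
// player_mode: 0 autopilot, 1 replay (player_path row t used for frame t).
// Returns the trajectory including the initial frame as row 1.
// [[Rcpp::export]]
List cpp_run_phase(NumericVector prey0, NumericVector opp0, NumericVector play0,
                   double F, double prey_max, double opp_speed,
                   double player_speed, int player_mode,
                   NumericMatrix player_path,
                   double capture_radius, int max_frames, List cfg) {
  EngineCfg c = parse_cfg(cfg);
  NumericMatrix traj(max_frames + 1, 6);
  double px = prey0[0], py = prey0[1];
  double ox = opp0[0], oy = opp0[1];
  double lx = play0[0], ly = play0[1];

  // prey position history (previous frames, most recent last)
  std::vector<double> hx, hy;
  hx.reserve(max_frames); hy.reserve(max_frames);

  traj(0, 0) = px; traj(0, 1) = py;
  traj(0, 2) = ox; traj(0, 3) = oy;
  traj(0, 4) = lx; traj(0, 5) = ly;

  int captured = 0, n_steps = 0;
  for (int t = 1; t <= max_frames; ++t) {
    int nh = hx.size();
    int nrev = nh < 2 ? nh : 2;
    const double* rhx = hx.data() + nh - nrev;
    const double* rhy = hy.data() + nh - nrev;
    double npx, npy, nox, noy, nlx, nly;
    prey_move(px, py, rhx, rhy, nrev, ox, oy, lx, ly, prey_max, c, npx, npy);
    opp_move(ox, oy, px, py, rhx, rhy, nrev, lx, ly, F, opp_speed, prey_max,
             c, nox, noy);
    if (player_mode == 1) {
      nlx = player_path(t - 1, 0); nly = player_path(t - 1, 1);
    } else {
      int nap = nh < c.ap_hist ? nh : c.ap_hist;
      ap_move(lx, ly, hx.data() + nh - nap, hy.data() + nh - nap, nap,
              px, py, player_speed, c, nlx, nly);
    }
    hx.push_back(px); hy.push_back(py);
    px = npx; py = npy; ox = nox; oy = noy; lx = nlx; ly = nly;
    traj(t, 0) = px; traj(t, 1) = py;
    traj(t, 2) = ox; traj(t, 3) = oy;
    traj(t, 4) = lx; traj(t, 5) = ly;
    n_steps = t;
    if (edist(lx, ly, px, py) <= capture_radius) { captured = 1; break; }
    if (edist(ox, oy, px, py) <= capture_radius) { captured = 2; break; }
  }

  NumericMatrix out(n_steps + 1, 6);
  for (int i = 0; i <= n_steps; ++i)
    for (int j = 0; j < 6; ++j) out(i, j) = traj(i, j);
  colnames(out) = CharacterVector::create("prey_x", "prey_y", "oppo_x",
                                          "oppo_y", "play_x", "play_y");
  return List::create(_["trajectory"] = out,
                      _["captured"] = captured,
                      _["n_steps"] = n_steps,
                      _["duration"] = n_steps / c.fr);
}

// Pairwise agent distances (deg) per frame: prey-oppo, prey-play, oppo-play.
// [[Rcpp::export]]
NumericMatrix cpp_pair_distances(NumericMatrix traj, double ppd) {
  int n = traj.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = edist(traj(i, 0), traj(i, 1), traj(i, 2), traj(i, 3)) / ppd;
    out(i, 1) = edist(traj(i, 0), traj(i, 1), traj(i, 4), traj(i, 5)) / ppd;
    out(i, 2) = edist(traj(i, 2), traj(i, 3), traj(i, 4), traj(i, 5)) / ppd;
  }
  colnames(out) = CharacterVector::create("d_prey_oppo", "d_prey_play",
                                          "d_oppo_play");
  return out;
}
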