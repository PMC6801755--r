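#include <Rcpp.h>
using namespace Rcpp;

// Stochastic engines for the kinesin chemomechanical cycle.
//
// State machine (shared by both engines):
//  - Two-head-bound (THB): trailing and leading heads on adjacent lattice
//    sites, each EMPTY (phi) or holding ATP (ADP states resolve
//    instantaneously).
//  - INT: one-head-bound intermediate; the tethered ADP-head waits above
//    the bound head, remembering which site it came from (rear/front).
//  Transitions: ATP binding at kb*[ATP] to any phi head; ATP dissociation
//  from the leading head at k1 (k2 elsewhere, 0 in the model); hydrolysis
//  (ATPase) at k_plus (trailing) / k_minus (leading), force-independent.
//  A hydrolysing head detaches to INT with probability p0 (side-resolved:
//  a backward load acts on the leading head only, an assisting load on the
//  trailing head only); otherwise ADP is released in place and the head is
//  phi again.  In INT, once the bound head holds ATP its neck linker docks
//  immediately and the tethered head rebinds instantly: forward site with
//  probability pe, rear site with 1-pe.  Centre of mass advances +/- d only
//  on completed steps.
//
// Event codes: 1 ATP_BIND, 2 ATP_DISSOC, 3 HYDROLYSIS_TRAILING,
// 4 HYDROLYSIS_LEADING, 5 DETACH_TO_INT, 6 REBIND_FORWARD,
// 7 REBIND_BACKWARD, 8 REBIND_SAME.
// Detail: for ATP_BIND/ATP_DISSOC the head (0 trailing, 1 leading,
// 2 INT-bound); for DETACH_TO_INT the origin (0 rear/trailing, 1
// front/leading); for REBIND_SAME the site rebound (0 rear, 1 front);
// otherwise -1.

namespace {

struct Recorder {
  bool keep;
  std::vector<double> time;
  std::vector<int> kind;
  std::vector<int> detail;
  std::vector<double> com;
  void rec(double t, int k, int det, double x) {
    if (keep) {
      time.push_back(t);
      kind.push_back(k);
      detail.push_back(det);
      com.push_back(x);
    }
  }
};

struct Engine {
  // rate constants and branch probabilities
  double k_plus, k_minus, p0_trail, p0_lead, pe, kbA, k1, k2, d;
  bool saturating;
  // state
  int config;        // 0 THB, 1 INT
  int nt_t, nt_l;    // THB nucleotides (0 phi, 1 ATP)
  int nt_b, origin;  // INT bound-head nucleotide, tethered origin
  double com;
  // counters (events at or after t_burn)
  double t_burn;
  long n_hyd, n_fwd, n_back, n_futile;
  Recorder rec;
  // sampling of the centre-of-mass series
  NumericVector sample_times;
  NumericVector com_samples;
  R_xlen_t si;

  void init() {
    config = 0;
    nt_t = nt_l = saturating ? 1 : 0;
    nt_b = 0;
    origin = 0;
    com = 0.0;
    n_hyd = n_fwd = n_back = n_futile = 0;
    si = 0;
  }

  void sample_upto(double t) {
    while (si < sample_times.size() && sample_times[si] < t) {
      com_samples[si] = com;
      si++;
    }
  }

  void finish() {
    while (si < sample_times.size()) {
      com_samples[si] = com;
      si++;
    }
  }

  // dock + instantaneous rebind once the INT bound head holds ATP
  void resolve_int(double t) {
    double u = unif_rand();
    if (origin == 0) {  // tethered head came from the rear site
      if (u < pe) {
        com += d;
        if (t >= t_burn) n_fwd++;
        rec.rec(t, 6, -1, com);
        nt_t = 1;  // bound head (held ATP) is now trailing
        nt_l = 0;  // rebound head released ADP, awaits ATP
      } else {
        if (t >= t_burn) n_futile++;
        rec.rec(t, 8, 0, com);
        nt_t = 0;
        nt_l = 1;
      }
    } else {  // tethered head came from the front site
      if (u < pe) {
        if (t >= t_burn) n_futile++;
        rec.rec(t, 8, 1, com);
        nt_t = 1;
        nt_l = 0;
      } else {
        com -= d;
        if (t >= t_burn) n_back++;
        rec.rec(t, 7, -1, com);
        nt_t = 0;
        nt_l = 1;
      }
    }
    config = 0;
    if (saturating) nt_t = nt_l = 1;
  }

  void hydrolysis(double t, bool trailing) {
    if (t >= t_burn) n_hyd++;
    rec.rec(t, trailing ? 3 : 4, -1, com);
    double p0 = trailing ? p0_trail : p0_lead;
    if (unif_rand() < p0) {
      // detach to INT; the remaining bound head keeps its nucleotide
      nt_b = trailing ? nt_l : nt_t;
      origin = trailing ? 0 : 1;
      config = 1;
      rec.rec(t, 5, origin, com);
      if (saturating) nt_b = 1;
      if (nt_b == 1) resolve_int(t);
    } else {
      // stays bound; ADP released immediately, head is phi
      if (t >= t_burn) n_futile++;
      if (trailing) nt_t = saturating ? 1 : 0;
      else nt_l = saturating ? 1 : 0;
    }
  }

  void run_exact(double t_max) {
    double t = 0.0;
    for (;;) {
      double r_hyd_t = 0, r_hyd_l = 0, r_bind_t = 0, r_bind_l = 0,
             r_diss_t = 0, r_diss_l = 0, r_bind_b = 0;
      if (config == 0) {
        if (nt_t == 1) { r_hyd_t = k_plus; r_diss_t = k2; }
        else if (!saturating) r_bind_t = kbA;
        if (nt_l == 1) { r_hyd_l = k_minus; r_diss_l = k1; }
        else if (!saturating) r_bind_l = kbA;
        if (saturating) { r_diss_t = 0; r_diss_l = 0; }
      } else {
        r_bind_b = kbA;  // bound head is phi (else INT resolves instantly)
      }
      double total = r_hyd_t + r_hyd_l + r_bind_t + r_bind_l + r_diss_t +
                     r_diss_l + r_bind_b;
      if (total <= 0) break;
      t += exp_rand() / total;
      if (t > t_max) break;
      sample_upto(t);
      double u = unif_rand() * total;
      if (u < r_hyd_t) {
        hydrolysis(t, true);
      } else if (u < r_hyd_t + r_hyd_l) {
        hydrolysis(t, false);
      } else if (u < r_hyd_t + r_hyd_l + r_bind_t) {
        nt_t = 1; rec.rec(t, 1, 0, com);
      } else if (u < r_hyd_t + r_hyd_l + r_bind_t + r_bind_l) {
        nt_l = 1; rec.rec(t, 1, 1, com);
      } else if (u < r_hyd_t + r_hyd_l + r_bind_t + r_bind_l + r_diss_t) {
        nt_t = 0; rec.rec(t, 2, 0, com);
      } else if (u <
                 r_hyd_t + r_hyd_l + r_bind_t + r_bind_l + r_diss_t + r_diss_l) {
        nt_l = 0; rec.rec(t, 2, 1, com);
      } else {
        nt_b = 1; rec.rec(t, 1, 2, com);
        resolve_int(t);
      }
    }
    finish();
  }

  void run_fixed(double t_max, double dt) {
    long n_steps = (long)std::ceil(t_max / dt);
    for (long i = 1; i <= n_steps; i++) {
      double t = i * dt;
      if (t > t_max) break;
      sample_upto(t);
      if (config == 0) {
        // trailing head: at most one chemical transition per step
        if (nt_t == 1) {
          if (unif_rand() < k_plus * dt) {
            hydrolysis(t, true);
          } else if (k2 > 0 && !saturating && unif_rand() < k2 * dt) {
            nt_t = 0; rec.rec(t, 2, 0, com);
          }
        } else if (!saturating && kbA > 0 && unif_rand() < kbA * dt) {
          nt_t = 1; rec.rec(t, 1, 0, com);
        }
        // leading head, unless the trailing transition left THB
        if (config == 0) {
          if (nt_l == 1) {
            if (k_minus > 0 && unif_rand() < k_minus * dt) {
              hydrolysis(t, false);
            } else if (config == 0 && k1 > 0 && !saturating &&
                       unif_rand() < k1 * dt) {
              nt_l = 0; rec.rec(t, 2, 1, com);
            }
          } else if (!saturating && kbA > 0 && unif_rand() < kbA * dt) {
            nt_l = 1; rec.rec(t, 1, 1, com);
          }
        }
      } else {
        if (!saturating && kbA > 0 && unif_rand() < kbA * dt) {
          nt_b = 1; rec.rec(t, 1, 2, com);
          resolve_int(t);
        }
      }
    }
    sample_upto(t_max + dt);
    finish();
  }
};

}  // namespace

// [[Rcpp::export]]
List sim_trace_cpp(double k_plus, double k_minus, double p0_trail,
                   double p0_lead, double pe, double kbA, double k1,
                   double k2, double d, bool saturating, double t_max,
                   double dt, double t_burn, NumericVector sample_times,
                   bool record_events) {
  Engine e;
  e.k_plus = k_plus; e.k_minus = k_minus;
  e.p0_trail = p0_trail; e.p0_lead = p0_lead; e.pe = pe;
  e.kbA = kbA; e.k1 = k1; e.k2 = k2; e.d = d;
  e.saturating = saturating;
  e.t_burn = t_burn;
  e.sample_times = sample_times;
  e.com_samples = NumericVector(sample_times.size());
  e.rec.keep = record_events;
  e.init();
  if (dt > 0) e.run_fixed(t_max, dt);
  else e.run_exact(t_max);

  List out = List::create(
      _["n_hyd"] = (double)e.n_hyd, _["n_fwd"] = (double)e.n_fwd,
      _["n_back"] = (double)e.n_back, _["n_futile"] = (double)e.n_futile,
      _["com_end"] = e.com, _["com_samples"] = e.com_samples);
  if (record_events) {
    out["event_time"] = wrap(e.rec.time);
    out["event_kind"] = wrap(e.rec.kind);
    out["event_detail"] = wrap(e.rec.detail);
    out["event_com"] = wrap(e.rec.com);
  }
  return out;
}
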