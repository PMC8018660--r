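#ifndef EMOBOOK_DYNAMICS_H
#define EMOBOOK_DYNAMICS_H

#include <cmath>
#include <algorithm>

// Closed-form LIKE update rules. All four bookkeeping dynamics are pairs of
// one increase kind and one decrease kind; the constants are pre-calibrated
// on the R side (make_dynamics) so that the timing contracts hold exactly:
//   * min -> max under uninterrupted grooming takes linc_period minutes,
//   * exponential decay halves the value every lhw minutes,
//   * logistic decay starting at the upper bound crosses 0.5 after lhw minutes,
//   * the lhw = 0 rule (linear decrease) empties the full range in 50 minutes.
namespace emobook {

enum IncKind { INC_LINEAR = 0, INC_LOGISTIC = 1 };
enum DecKind { DEC_EXPONENTIAL = 0, DEC_LOGISTIC = 1, DEC_LINEAR = 2 };

struct Dyn {
  int inc_kind;
  int dec_kind;
  double a;        // linear increase slope (LIKE / min)
  double k_inc;    // logistic increase steepness (1 / min)
  double k_dec;    // logistic decrease steepness (1 / min)
  double lhw;      // exponential half-life (min)
  double lin_rate; // linear decrease rate for the lhw = 0 rule (LIKE / min)
  double lower;
  double upper;
};

inline double clamp01(double v, double lo, double hi) {
  return std::min(hi, std::max(lo, v));
}

// Sigmoid inversion is exact (logit), so composing updates over split
// durations is associative to rounding error (semigroup law).
inline double groom_increase(double v, double t, const Dyn& d) {
  if (t <= 0.0) return v;
  double out;
  if (d.inc_kind == INC_LINEAR) {
    out = v + d.a * t;
  } else {
    double p = std::min(std::max(v, 1e-12), 1.0 - 1e-12);
    double x0 = std::log(p / (1.0 - p)) / d.k_inc;
    out = 1.0 / (1.0 + std::exp(-d.k_inc * (x0 + t)));
  }
  return clamp01(out, d.lower, d.upper);
}

inline double idle_decay(double v, double t, const Dyn& d) {
  if (t <= 0.0) return v;
  double out;
  if (d.dec_kind == DEC_EXPONENTIAL) {
    out = v * std::pow(0.5, t / d.lhw);
  } else if (d.dec_kind == DEC_LINEAR) {
    out = v - d.lin_rate * t;
  } else {
    double p = std::min(std::max(v, 1e-12), 1.0 - 1e-12);
    double x0 = std::log((1.0 - p) / p) / d.k_dec; // v = 1/(1+e^(k x))
    out = 1.0 / (1.0 + std::exp(d.k_dec * (x0 + t)));
  }
  return clamp01(out, d.lower, d.upper);
}

} // namespace emobook

#endif
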