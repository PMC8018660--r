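#include <Rcpp.h>
#include "dynamics.h"

using namespace Rcpp;
using emobook::Dyn;

Dyn dyn_from_list(const List& p) {
  Dyn d;
  d.inc_kind = as<int>(p["inc_kind"]);
  d.dec_kind = as<int>(p["dec_kind"]);
  d.a        = as<double>(p["a"]);
  d.k_inc    = as<double>(p["k_inc"]);
  d.k_dec    = as<double>(p["k_dec"]);
  d.lhw      = as<double>(p["lhw_eff"]);
  d.lin_rate = as<double>(p["lin_rate"]);
  d.lower    = as<double>(p["lower"]);
  d.upper    = as<double>(p["upper"]);
  return d;
}

// [[Rcpp::export]]
NumericVector emo_increase_cpp(NumericVector value, NumericVector minutes, List params) {
  Dyn d = dyn_from_list(params);
  R_xlen_t n = std::max(value.size(), minutes.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = emobook::groom_increase(value[i % value.size()], minutes[i % minutes.size()], d);
  return out;
}

// [[Rcpp::export]]
NumericVector emo_decay_cpp(NumericVector value, NumericVector minutes, List params) {
  Dyn d = dyn_from_list(params);
  R_xlen_t n = std::max(value.size(), minutes.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = emobook::idle_decay(value[i % value.size()], minutes[i % minutes.size()], d);
  return out;
}
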