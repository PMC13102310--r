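#include <Rcpp.h>
using namespace Rcpp;

// Deterministic trial-by-trial state-space recursion shared by the
// simulator and the fitting objective. Directions are target-relative with
// the countering direction positive; the cursor is hand - r.
//
// trial_code: 0 = movement with visual feedback (feedback / aiming-report /
//             probe trials), 1 = no-feedback movement aimed at the target
//             (exclusion, null, washout, no-feedback probe), 2 = passive
//             proprioception test (no movement).
// instructed: 1 while the explicit state is clamped to aim_ref.
// model_kind: 0 = PPE, 1 = PE, 2 = SPE, 3 = TWO_STATE.
// form:       0 = linear, 1 = exponential, 2 = power-law.
// clamp_explicit: per-trial observed explicit series overriding x_e
//             (length 0 disables clamping).
// [[Rcpp::export(name = ".sim_trajectory_cpp")]]
NumericMatrix sim_trajectory_cpp(NumericVector rotation,
                                 IntegerVector trial_code,
                                 IntegerVector instructed,
                                 NumericVector aim_ref,
                                 List params,
                                 NumericVector clamp_explicit,
                                 bool pe_reaiming) {
  const int n = rotation.size();
  const double Ae = params["Ae"], Be = params["Be"];
  const double Ai = params["Ai"], Bi = params["Bi"];
  const double k = params["k"], b = params["b"];
  const double su = params["sigma_u"], sp = params["sigma_p"];
  const double gamma = params["gamma"];
  const int kind = params["kind"], form = params["form"];
  double Af = 0, Bf = 0, As = 0, Bs = 0;
  if (kind == 3) {
    Af = params["Af"]; Bf = params["Bf"];
    As = params["As"]; Bs = params["Bs"];
  }
  const bool clamp = clamp_explicit.size() == n;
  const double iv_u = 1.0 / (su * su), iv_p = 1.0 / (sp * sp);

  NumericMatrix out(n, 12);
  colnames(out) = CharacterVector::create(
      "x_e", "x_i", "hand", "cursor", "e_pe", "e_spe", "e_pe_reaim",
      "e_ppe", "sigma_v", "perceived", "x_i_fast", "x_i_slow");

  double xe = 0, xi = 0, xif = 0, xis = 0;

  for (int t = 0; t < n; ++t) {
    const int code = trial_code[t];
    const bool instr = instructed[t] == 1;
    const double r = rotation[t];
    if (clamp) xe = clamp_explicit[t];
    if (instr) xe = aim_ref[t];

    out(t, 0) = xe;
    out(t, 1) = xi;
    out(t, 10) = kind == 3 ? xif : NA_REAL;
    out(t, 11) = kind == 3 ? xis : NA_REAL;

    if (code == 0) {
      const double xu = instr ? aim_ref[t] : xe;
      const double hand = (instr ? aim_ref[t] : xe) + xi;
      const double xv = hand - r;
      const double e_pe = xv;            // target at 0
      const double e_spe = xv - xu;
      const double e_rea = instr ? xv - aim_ref[t] : NA_REAL;
      const double ecc = std::abs(xv - xu);
      double sv;
      if (form == 0)      sv = k * ecc + b;
      else if (form == 1) sv = b * std::exp(k * ecc);
      else                sv = b + k * std::pow(ecc, gamma);
      const double iv_v = 1.0 / (sv * sv);
      const double S = iv_u + iv_p + iv_v;
      const double percept = (iv_u * xu + iv_p * hand + iv_v * xv) / S;
      const double e_ppe = percept - xu;

      out(t, 2) = hand;  out(t, 3) = xv;
      out(t, 4) = e_pe;  out(t, 5) = e_spe; out(t, 6) = e_rea;
      out(t, 7) = e_ppe; out(t, 8) = sv;    out(t, 9) = percept;

      double err_i;
      if (kind == 0)      err_i = e_ppe;
      else if (kind == 1) err_i = (instr && pe_reaiming) ? e_rea : e_pe;
      else if (kind == 2) err_i = e_spe;
      else                err_i = 0;  // TWO_STATE handled componentwise

      if (kind == 3) {
        const double e_fast = (instr && pe_reaiming) ? e_rea : e_pe;
        xif = Af * xif - Bf * e_fast;
        xis = As * xis - Bs * e_spe;
        xi = xif + xis;
      } else {
        xi = Ai * xi - Bi * err_i;
      }
      if (!instr && !clamp) xe = Ae * xe - Be * e_pe;
    } else {
      // no visual feedback: retention-only decay of both states
      if (code == 1) {
        out(t, 2) = xi;        // aimed at the target, implicit only
        out(t, 3) = NA_REAL;
      } else {
        out(t, 2) = NA_REAL;   // passive proprioception test
        out(t, 3) = NA_REAL;
      }
      out(t, 4) = NA_REAL; out(t, 5) = NA_REAL; out(t, 6) = NA_REAL;
      out(t, 7) = NA_REAL; out(t, 8) = NA_REAL; out(t, 9) = NA_REAL;
      if (kind == 3) {
        xif *= Af; xis *= As; xi = xif + xis;
      } else {
        xi *= Ai;
      }
      if (!instr && !clamp) xe *= Ae;
    }
  }
  return out;
}
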