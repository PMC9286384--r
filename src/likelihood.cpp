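#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Speaker production fractions for the positive and negative adjective at
// every grid point, for one comparison class, via explicit soft-max on the
// normalized literal-listener posteriors. d: the class's degree prior mass
// (normalized); Lp/Ln: normalized literal-listener posteriors for the
// positive/negative form (all-zero if the form is nowhere true). costexp:
// exp(-alpha * cost) for (positive, negative, silence).
// pow(0, 0) == 1, so alpha == 0 yields the uniform 1/3 speaker everywhere,
// matching the soft-max limit. This is the reference (fallback) path.
static void speaker_frac(const std::vector<double>& d,
                         const std::vector<double>& Lp,
                         const std::vector<double>& Ln,
                         double alpha, const double* costexp,
                         std::vector<double>& spos,
                         std::vector<double>& sneg) {
  const int n = (int)d.size();
  for (int i = 0; i < n; ++i) {
    double ap = std::pow(Lp[i], alpha) * costexp[0];
    double an = std::pow(Ln[i], alpha) * costexp[1];
    double as = std::pow(d[i], alpha) * costexp[2];
    double den = ap + an + as;
    if (den > 0.0) {
      spos[i] = ap / den;
      sneg[i] = an / den;
    } else {
      spos[i] = 0.0;
      sneg[i] = 0.0;
    }
  }
}

// Fast equivalent of speaker_frac exploiting the structure of the literal
// listener: L0pos(i) = d_i * i / zpos and L0neg(i) = d_i * (n-1-i) / zneg,
// so the class prior d_i cancels from the soft-max odds against silence:
//   u_i = (i / zpos)^alpha * exp(-alpha (c_pos - c_sil))
//   v_i = ((n-1-i) / zneg)^alpha * exp(-alpha (c_neg - c_sil))
//   spos = u / (u + v + 1),  sneg = v / (u + v + 1).
// Tpos/Tneg hold exp(alpha * log(i)) and exp(alpha * log(n-1-i)) computed
// once per call. Where d_i == 0 this disagrees with the reference path
// (which returns 0), but every consumer weights the fractions by d_i (or by
// a referent prior that underflowed with it), so the sums agree.
// Returns false (caller must fall back) when the scalar magnitude bound
// risks overflow, e.g. degenerate zpos/zneg.
static bool speaker_frac_fast(double alpha, double zpos, double zneg,
                              const std::vector<double>& Tpos,
                              const std::vector<double>& Tneg,
                              const double* costs,
                              std::vector<double>& spos,
                              std::vector<double>& sneg) {
  const int n = (int)Tpos.size();
  if (alpha == 0.0) {
    for (int i = 0; i < n; ++i) {
      spos[i] = 1.0 / 3.0;
      sneg[i] = 1.0 / 3.0;
    }
    return true;
  }
  if (!(zpos > 0.0) || !(zneg > 0.0)) return false;
  double lmax = std::log((double)(n - 1));
  double epos = alpha * (lmax - std::log(zpos) - (costs[0] - costs[2]));
  double eneg = alpha * (lmax - std::log(zneg) - (costs[1] - costs[2]));
  if (!R_finite(epos) || !R_finite(eneg) || epos > 600.0 || eneg > 600.0) {
    return false;
  }
  const double cu = std::exp(-alpha * (std::log(zpos) + costs[0] - costs[2]));
  const double cv = std::exp(-alpha * (std::log(zneg) + costs[1] - costs[2]));
  for (int i = 0; i < n; ++i) {
    double u = Tpos[i] * cu;
    double v = Tneg[i] * cv;
    double den = u + v + 1.0;
    spos[i] = u / den;
    sneg[i] = v / den;
  }
  return true;
}

// Unnormalized theta-count weights and their prior-weighted sums.
static void l0_sums(const std::vector<double>& d, double& zpos, double& zneg) {
  const int n = (int)d.size();
  zpos = 0.0;
  zneg = 0.0;
  for (int i = 0; i < n; ++i) {
    zpos += d[i] * (double)i;
    zneg += d[i] * (double)(n - 1 - i);
  }
}

// Normalized literal-listener posteriors (fallback path only).
static void literal_L0(const std::vector<double>& d, double zpos, double zneg,
                       std::vector<double>& Lp, std::vector<double>& Ln) {
  const int n = (int)d.size();
  for (int i = 0; i < n; ++i) {
    Lp[i] = zpos > 0.0 ? d[i] * (double)i / zpos : 0.0;
    Ln[i] = zneg > 0.0 ? d[i] * (double)(n - 1 - i) / zneg : 0.0;
  }
}

// Speaker fractions for one class at one optimality: fast path with
// reference fallback.
static void class_speaker(const std::vector<double>& d, double zpos,
                          double zneg, double alpha, const double* costs,
                          const double* costexp,
                          const std::vector<double>& Tpos,
                          const std::vector<double>& Tneg,
                          std::vector<double>& spos,
                          std::vector<double>& sneg,
                          std::vector<double>& scratch_p,
                          std::vector<double>& scratch_n) {
  if (speaker_frac_fast(alpha, zpos, zneg, Tpos, Tneg, costs, spos, sneg)) {
    return;
  }
  literal_L0(d, zpos, zneg, scratch_p, scratch_n);
  speaker_frac(d, scratch_p, scratch_n, alpha, costexp, spos, sneg);
}

// Model predictions for every category in one shot: the hot path of the
// Bayesian data analysis. Returns, per category j (with Gaussian degree
// prior N(sub_mean[j], sub_sd[j]) truncated to the grid, superordinate
// fixed at the grid-truncated unit normal, subordinate-class prior
// p_sub[j]):
//   p_cc:    P(c_sub | u, k) for u = (positive, negative)
//            (pragmatic listener if listener_type == 0, the rival
//             literal class listener if listener_type == 1)
//   e_sub:   endorsement probability, explicit subordinate class
//   e_super: endorsement probability, explicit superordinate class
//   ok:      false when the category's prior underflows off the grid
// [[Rcpp::export]]
List rsa_predictions_cpp(NumericVector grid, NumericVector sub_mean,
                         NumericVector sub_sd, NumericVector p_sub,
                         double alpha1, double alpha2, NumericVector costs,
                         int listener_type) {
  const int n = grid.size();
  const int m = sub_mean.size();

  double cst[3], ce1[3], ce2[3];
  for (int u = 0; u < 3; ++u) {
    cst[u] = costs[u];
    ce1[u] = std::exp(-alpha1 * costs[u]);
    ce2[u] = std::exp(-alpha2 * costs[u]);
  }

  // theta-count power tables, one set per optimality
  std::vector<double> Tp1(n), Tn1(n), Tp2(n), Tn2(n);
  for (int i = 0; i < n; ++i) {
    double li = i > 0 ? std::log((double)i) : R_NegInf;
    double lni = (n - 1 - i) > 0 ? std::log((double)(n - 1 - i)) : R_NegInf;
    Tp1[i] = alpha1 > 0.0 ? std::exp(alpha1 * li) : 1.0;
    Tn1[i] = alpha1 > 0.0 ? std::exp(alpha1 * lni) : 1.0;
    Tp2[i] = alpha2 > 0.0 ? std::exp(alpha2 * li) : 1.0;
    Tn2[i] = alpha2 > 0.0 ? std::exp(alpha2 * lni) : 1.0;
  }

  // superordinate class: unit normal on the grid
  std::vector<double> q(n);
  double zq = 0.0;
  for (int i = 0; i < n; ++i) {
    q[i] = std::exp(-0.5 * grid[i] * grid[i]);
    zq += q[i];
  }
  for (int i = 0; i < n; ++i) q[i] /= zq;
  double qzp, qzn;
  l0_sums(q, qzp, qzn);

  std::vector<double> sc1(n), sc2(n);  // fallback scratch
  std::vector<double> q_sp1(n), q_sn1(n), q_sp2(n), q_sn2(n);
  class_speaker(q, qzp, qzn, alpha1, cst, ce1, Tp1, Tn1, q_sp1, q_sn1, sc1, sc2);
  class_speaker(q, qzp, qzn, alpha2, cst, ce2, Tp2, Tn2, q_sp2, q_sn2, sc1, sc2);

  // P(utterance true | class = super) for the literal class listener
  const double tq_pos = qzp / (double)n;
  const double tq_neg = qzn / (double)n;

  NumericMatrix p_cc(m, 2), e_sub(m, 2), e_super(m, 2);
  LogicalVector ok(m);

  std::vector<double> p(n);
  std::vector<double> sp1(n), sn1(n), sp2(n), sn2(n);

  for (int j = 0; j < m; ++j) {
    const double mu = sub_mean[j], sd = sub_sd[j];
    double zp = 0.0;
    for (int i = 0; i < n; ++i) {
      double z = (grid[i] - mu) / sd;
      p[i] = std::exp(-0.5 * z * z);
      zp += p[i];
    }
    if (!(zp > 0.0) || !R_finite(zp)) {
      ok[j] = false;
      for (int u = 0; u < 2; ++u) {
        p_cc(j, u) = NA_REAL;
        e_sub(j, u) = NA_REAL;
        e_super(j, u) = NA_REAL;
      }
      continue;
    }
    ok[j] = true;
    for (int i = 0; i < n; ++i) p[i] /= zp;
    double pzp, pzn;
    l0_sums(p, pzp, pzn);

    if (listener_type == 0) {
      // pragmatic: class marginal of L1(x, c | u, k), k-prior = sub prior
      class_speaker(p, pzp, pzn, alpha1, cst, ce1, Tp1, Tn1, sp1, sn1,
                    sc1, sc2);
      double Apos = 0.0, Aneg = 0.0, Bpos = 0.0, Bneg = 0.0;
      for (int i = 0; i < n; ++i) {
        Apos += sp1[i] * p[i];
        Aneg += sn1[i] * p[i];
        Bpos += q_sp1[i] * p[i];
        Bneg += q_sn1[i] * p[i];
      }
      double dpos = p_sub[j] * Apos + (1.0 - p_sub[j]) * Bpos;
      double dneg = p_sub[j] * Aneg + (1.0 - p_sub[j]) * Bneg;
      p_cc(j, 0) = dpos > 0.0 ? p_sub[j] * Apos / dpos : NA_REAL;
      p_cc(j, 1) = dneg > 0.0 ? p_sub[j] * Aneg / dneg : NA_REAL;
    } else {
      // literal class listener: evidence is just P(u true | class)
      double tp_pos = pzp / (double)n;
      double tp_neg = pzn / (double)n;
      double dpos = p_sub[j] * tp_pos + (1.0 - p_sub[j]) * tq_pos;
      double dneg = p_sub[j] * tp_neg + (1.0 - p_sub[j]) * tq_neg;
      p_cc(j, 0) = dpos > 0.0 ? p_sub[j] * tp_pos / dpos : NA_REAL;
      p_cc(j, 1) = dneg > 0.0 ? p_sub[j] * tp_neg / dneg : NA_REAL;
    }

    // endorsement submodel: expected speaker production probability of the
    // adjective over the referent's degree prior, optimality alpha2
    class_speaker(p, pzp, pzn, alpha2, cst, ce2, Tp2, Tn2, sp2, sn2,
                  sc1, sc2);
    double es_pos = 0.0, es_neg = 0.0, eq_pos = 0.0, eq_neg = 0.0;
    for (int i = 0; i < n; ++i) {
      es_pos += p[i] * sp2[i];
      es_neg += p[i] * sn2[i];
      eq_pos += p[i] * q_sp2[i];
      eq_neg += p[i] * q_sn2[i];
    }
    e_sub(j, 0) = es_pos;
    e_sub(j, 1) = es_neg;
    e_super(j, 0) = eq_pos;
    e_super(j, 1) = eq_neg;
  }

  return List::create(_["p_cc"] = p_cc, _["e_sub"] = e_sub,
                      _["e_super"] = e_super, _["ok"] = ok);
}
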