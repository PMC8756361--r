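#include <Rcpp.h>
using namespace Rcpp;

// Block-exchangeable genotype simulator.
//
// Haplotype alleles within an LD block share a per-individual latent draw:
// allele_j = a0 (the block draw, Bernoulli(maf)) with probability s_j, else a
// fresh Bernoulli(maf_j). With a common within-block allele frequency this
// gives pairwise allele (and dosage) correlation exactly s^2, so a target
// within-block r^2 is hit by s = r2^(1/4). Dosage = sum of two independent
// haplotypes, hence Hardy-Weinberg marginals.
//
// Uses R's RNG stream (unif_rand / norm_rand) so results are reproducible
// via set.seed().

static void sim_one_individual(int m, const double *pm, const double *ps,
                               const int *pbl, const double *pb1,
                               const double *pb2, int *buf, double *acc1,
                               double *acc2) {
  std::fill(buf, buf + m, 0);
  for (int h = 0; h < 2; ++h) {
    int cur = INT_MIN, a0 = 0;
    for (int j = 0; j < m; ++j) {
      if (pbl[j] != cur) {
        cur = pbl[j];
        a0 = (unif_rand() < pm[j]) ? 1 : 0;
      }
      double sj = ps[j], u = unif_rand();
      int a = (u < sj) ? a0 : (((u - sj) / (1.0 - sj) < pm[j]) ? 1 : 0);
      buf[j] += a;
    }
  }
  double g1 = 0.0, g2 = 0.0;
  for (int j = 0; j < m; ++j) {
    g1 += buf[j] * pb1[j];
    g2 += buf[j] * pb2[j];
  }
  *acc1 = g1;
  *acc2 = g2;
}

// Plain chunk generator: returns every simulated individual (SNV-major
// layout, m x n) plus the two genetic liability components.
// [[Rcpp::export]]
List sim_dosage_chunk(int n, NumericVector maf, IntegerVector block_id,
                      NumericVector s, NumericVector b_shared,
                      NumericVector b_specific) {
  int m = maf.size();
  if (block_id.size() != m || s.size() != m || b_shared.size() != m ||
      b_specific.size() != m)
    stop("all per-SNV vectors must have the same length");
  IntegerMatrix D(m, n);
  NumericVector g1(n), g2(n);
  int *dp = INTEGER(D);
  for (int i = 0; i < n; ++i) {
    sim_one_individual(m, REAL(maf), REAL(s), INTEGER(block_id),
                       REAL(b_shared), REAL(b_specific),
                       dp + (R_xlen_t)i * m, &g1[i], &g2[i]);
  }
  return List::create(_["dosages"] = D, _["g_shared"] = g1,
                      _["g_specific"] = g2);
}

// Quota-aware liability-threshold rejection sampler. Draws individuals one
// at a time, assigns class by the two-layer liability rule
//   case   <=> g_shared - center1 + e1 > t1          (e1 ~ N(0, sd_e1))
//   TRS    <=> case and g_specific - center2 + e2 > t2 (e2 ~ N(0, sd_e2))
// and stores only individuals still needed for a quota (1 = TRS case,
// 2 = non-TRS case, 3 = control). Stops after max_draw draws or when all
// quotas are filled. Only accepted individuals are materialized, so the
// rejection pool costs RNG time but no memory.
// [[Rcpp::export]]
List sim_cohort_quota(NumericVector maf, IntegerVector block_id,
                      NumericVector s, NumericVector b_shared,
                      NumericVector b_specific, double center1,
                      double center2, double t1, double sd_e1, double t2,
                      double sd_e2, int need_trs, int need_nontrs,
                      int need_control, int max_draw) {
  int m = maf.size();
  int total_need = need_trs + need_nontrs + need_control;
  IntegerMatrix D(m, total_need);
  IntegerVector cls(total_need);
  NumericVector g1(total_need), g2(total_need);
  NumericVector l1(total_need), l2(total_need);
  std::vector<int> buf(m);
  int kept = 0, drawn = 0, case_seen = 0, trs_seen = 0;
  int got_trs = 0, got_nontrs = 0, got_control = 0;

  while (drawn < max_draw &&
         (got_trs < need_trs || got_nontrs < need_nontrs ||
          got_control < need_control)) {
    double gi1, gi2;
    sim_one_individual(m, REAL(maf), REAL(s), INTEGER(block_id),
                       REAL(b_shared), REAL(b_specific), buf.data(), &gi1,
                       &gi2);
    ++drawn;
    gi1 -= center1;
    gi2 -= center2;
    double li1 = gi1 + sd_e1 * norm_rand();
    double li2 = gi2 + sd_e2 * norm_rand();
    int klass;
    if (li1 > t1) {
      ++case_seen;
      klass = (li2 > t2) ? 1 : 2;
      if (klass == 1) ++trs_seen;
    } else {
      klass = 3;
    }
    bool want = (klass == 1 && got_trs < need_trs) ||
                (klass == 2 && got_nontrs < need_nontrs) ||
                (klass == 3 && got_control < need_control);
    if (!want) continue;
    if (klass == 1) ++got_trs;
    else if (klass == 2) ++got_nontrs;
    else ++got_control;
    std::copy(buf.begin(), buf.end(), INTEGER(D) + (R_xlen_t)kept * m);
    cls[kept] = klass;
    g1[kept] = gi1;
    g2[kept] = gi2;
    l1[kept] = li1;
    l2[kept] = li2;
    ++kept;
  }
  return List::create(_["dosages"] = D, _["class"] = cls,
                      _["g_shared"] = g1, _["g_specific"] = g2,
                      _["liab1"] = l1, _["liab2"] = l2, _["kept"] = kept,
                      _["drawn"] = drawn, _["case_seen"] = case_seen,
                      _["trs_seen"] = trs_seen);
}
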