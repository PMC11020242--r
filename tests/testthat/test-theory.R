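test_that("the Poisson observation rate follows d(1-r)^k(l-k+1)/l", {
  expect_equal(lambda_rate(5, 0.01, 21, 150), 5 * 0.99^21 * 130 / 150)
  expect_equal(lambda_rate(0, 0.01, 21, 150), 0)
  # r = 0, l >> k approaches d
  expect_equal(lambda_rate(5, 0, 21, 1e6), 5 * (1e6 - 20) / 1e6, tolerance = 1e-12)
  expect_error(lambda_rate(5, 0.01, 21, 21), "exceed k")
})

test_that("absence probability is (1+lambda)exp(-lambda)", {
  expect_equal(absence_prob(0), 1)
  lam <- lambda_rate(5, 0.01, 21, 150)
  expect_equal(absence_prob(lam), (1 + lam) * exp(-lam))
  expect_equal(absence_prob(lam), 0.13496, tolerance = 1e-3)
  expect_lt(absence_prob(500), 1e-100)
  expect_equal(presence_prob(lam), 1 - absence_prob(lam))
  expect_error(absence_prob(-1), ">= 0")
})

test_that("coverage false-positive rate reproduces the closed-form reference values", {
  # n = 5: ~4.4e-5 with the default nearest-integer m rule (m = 3)
  f1_5 <- fp_coverage(theory_params(n = 5, d = 5, l = 150, r = 0.01, k = 21))
  expect_equal(f1_5, 4.4e-5, tolerance = 0.015)
  # n = 10 (m = 7): ~1.9e-9
  f1_10 <- fp_coverage(theory_params(n = 10, d = 5, l = 150, r = 0.01, k = 21))
  expect_equal(f1_10, 1.9e-9, tolerance = 0.02)
  # deep sequencing makes coverage false positives vanish
  expect_lt(fp_coverage(theory_params(n = 5, d = 100)), 1e-140)
})

test_that("heterozygosity false-positive rate is allele-symmetric with the right limit", {
  tp <- theory_params(n = 5, d = 5, l = 150, r = 0.01, k = 21)
  for (x in c(0.1, 0.25, 0.4))
    expect_equal(fp_heterozygosity(tp, x), fp_heterozygosity(tp, 1 - x))
  # p_h1 -> 0: allele 2 carries the full rate, allele 1 contributes ~q^n * 0
  f1 <- fp_coverage(tp)
  expect_equal(fp_heterozygosity(tp, 1e-12), f1, tolerance = 1e-6)
  expect_error(fp_heterozygosity(tp, 0), "inside")
  expect_error(fp_heterozygosity(tp, 1), "inside")
})

test_that("total false-positive rate is the kh-weighted convex combination", {
  tp0 <- theory_params(n = 5, h = 0)
  expect_identical(fp_total(tp0), fp_coverage(tp0))
  tp <- theory_params(n = 5, h = 0.001)
  hd <- het_allele_distribution()
  f <- fp_total(tp, hd)
  # independent term-by-term recomputation
  f2s <- vapply(hd$values, function(x) fp_heterozygosity(tp, x), 0)
  kh <- tp$k * tp$h
  expect_equal(f, (1 - kh) * fp_coverage(tp) + kh * sum(f2s * hd$probs))
  # convex bounds
  lo <- min(fp_coverage(tp), min(f2s)); hi <- max(fp_coverage(tp), max(f2s))
  expect_gte(f, lo); expect_lte(f, hi)
  expect_error(fp_total(theory_params(n = 5, h = 0.05, k = 21)), "k \\* h")
})

test_that("the default allele distribution is the built-in 5-point table", {
  hd <- het_allele_distribution()
  expect_equal(hd$values, c(0.05, 0.15, 0.25, 0.35, 0.45))
  expect_equal(sum(hd$probs), 1, tolerance = 1e-12)
  expect_error(het_allele_distribution(values = c(0.2, 0.6),
                                       probs = c(0.5, 0.5)), "0.5")
  expect_error(het_allele_distribution(probs = c(0.9, 0.02, 0.02, 0.02, 0.02)),
               "sum to 1")
})

test_that("marker TPR is the >= m-of-n binomial tail of the presence probability", {
  tp <- theory_params(n = 5, d = 5, l = 150, r = 0.01, k = 21)
  expect_equal(tpr_msk(tp), 0.980, tolerance = 1e-3)
  # n = 1, m = 1: TPR is the single-individual presence probability
  tp1 <- theory_params(n = 1, d = 5)
  expect_equal(tpr_msk(tp1), presence_prob(lambda_rate(5, 0.01, 21, 150)))
  # saturating depth
  expect_equal(tpr_msk(theory_params(n = 5, d = 200)), 1, tolerance = 1e-9)
  # halving the effective depth lowers the TPR
  expect_lt(tpr_msk(tp, effective_depth = 2.5), tpr_msk(tp))
})

test_that("read-sorting probability is the binomial upper tail with exact small cases", {
  expect_equal(read_sort_prob(N = 10, M = 0, p = 0.3), 1)
  expect_equal(read_sort_prob(N = 5, M = 6, p = 0.99), 0)
  # N = 3, M = 2, p = 0.5: enumeration over 2^3 outcomes gives 4/8
  expect_equal(read_sort_prob(N = 3, M = 2, p = 0.5), 0.5)
  # p from (1 - r3)^k
  expect_equal(read_sort_prob(N = 70, M = 7, r3 = 0.1, k = 21),
               read_sort_prob(N = 70, M = 7, p = 0.9^21))
  # monotone in p and N, antitone in M
  grid <- expand.grid(N = c(10, 20), M = c(2, 5), p = c(0.3, 0.6))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_lte(read_sort_prob(g$N, g$M, g$p), read_sort_prob(g$N, g$M, g$p + 0.2))
    expect_lte(read_sort_prob(g$N, g$M, g$p), read_sort_prob(g$N + 5, g$M, g$p))
    expect_gte(read_sort_prob(g$N, g$M, g$p), read_sort_prob(g$N, g$M + 1, g$p))
  }
})

test_that("multi-heterozygous-site and misidentification probabilities are as derived", {
  expect_equal(het_multi_site_prob(21, 0.001), 2.1e-4, tolerance = 0.02)
  expect_equal(het_multi_site_prob(21, 0), 0)
  # k = 2, h = 0.5: both sites heterozygous with probability 1/4 (enumeration)
  expect_equal(het_multi_site_prob(2, 0.5), 0.25)
  expect_equal(misid_prob(21, 0.01), 0.99^20 * 0.01 / 3)
  expect_equal(round(misid_prob(21, 0.01), 3), 0.003)  # "0.3%"
  expect_equal(misid_prob(21, 0), 0)
  expect_equal(misid_prob(2, 0.03), 0.97 * 0.01)
})

test_that("marker precision combines the census with the error rates", {
  expect_equal(msk_precision(100, 900, 0.9, 0), 1)
  expect_equal(msk_precision(100, 900, 0.9, 0.1), 0.5)
  expect_equal(msk_precision(100, 900, 0, 0.1), 0)
  expect_error(msk_precision(10, 10, 0, 0), "zero")
})

test_that("rates stay in [0,1] and f1 decreases with depth and cohort size", {
  for (n in c(1, 3, 5, 10)) for (d in c(1, 3, 10)) {
    tp <- theory_params(n = n, d = d, h = 0.001)
    for (v in c(fp_coverage(tp), fp_total(tp), tpr_msk(tp),
                fp_heterozygosity(tp, 0.3))) {
      expect_gte(v, 0); expect_lte(v, 1)
    }
  }
  # non-increasing in d
  f_by_d <- vapply(c(2, 4, 8, 16), function(d) fp_coverage(theory_params(n = 5, d = d)), 0)
  expect_true(all(diff(f_by_d) <= 0))
  # non-increasing in n where m/n is constant (n multiples of 3)
  f_by_n <- vapply(c(3, 6, 9, 12), function(n) fp_coverage(theory_params(n = n)), 0)
  expect_true(all(diff(f_by_n) <= 0))
})

test_that("closed forms agree with explicit Monte-Carlo simulation (quick check)", {
  # moderate-depth regime so the event probabilities are well away from 0
  set.seed(606)
  reps <- 2e5
  n <- 4; m <- male_presence_threshold(4)
  lam <- lambda_rate(1.5, 0.01, 21, 150)
  tp <- theory_params(n = 4, d = 1.5, l = 150, r = 0.01, k = 21)

  mc <- mc_fp_coverage(n, lam, m, reps)
  expect_lt(abs(fp_coverage(tp) - mc$est), 3 * mc$se)

  mc <- mc_tpr(n, lam, m, reps)
  expect_lt(abs(tpr_msk(tp) - mc$est), 3 * mc$se)

  mc <- mc_read_sort(20, 5, 0.35, reps)
  expect_lt(abs(read_sort_prob(20, 5, 0.35) - mc$est), 3 * mc$se)
})
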