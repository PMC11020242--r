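#' Parameter bundle for the marker error models
#'
#' Collects the symbols of the closed-form models: `n` individuals per sex
#' are sequenced to depth `d` with reads of length `l` and per-site error
#' `r`; markers are k-mers of length `k`; `h` is the per-site heterozygosity
#' rate on autosomes; `r3` is the per-site error of long reads. A k-mer is
#' present in an individual when seen at least `presence_min` times, and a
#' marker needs presence in at least `m` males with `m` = `m_rule`(2n/3).
#'
#' @param n individuals per sex (>= 1).
#' @param d short-read depth per individual (x).
#' @param l short-read length (bp), must exceed `k`.
#' @param r short-read per-site error rate in `[0, 1]`.
#' @param k k-mer length.
#' @param h autosomal per-site heterozygosity rate in `[0, 1]`.
#' @param r3 long-read per-site error rate in `[0, 1]`.
#' @param presence_min per-individual presence threshold (the models assume
#'   2: "present" means observed more than once).
#' @param m_rule rounding rule for the male-presence threshold.
#' @return a `theory_params` list.
#' @export
theory_params <- function(n = 5, d = 5, l = 150, r = 0.01, k = 21, h = 0,
                          r3 = 0, presence_min = 2,
                          m_rule = c("round", "ceil", "floor")) {
  m_rule <- match.arg(m_rule)
  stopifnot(n >= 1, n == as.integer(n), d >= 0, l > k, k >= 1)
  for (rate in list(r = r, h = h, r3 = r3))
    if (rate < 0 || rate > 1) stop("rates r, h, r3 must lie in [0, 1]")
  structure(list(n = as.integer(n), d = d, l = l, r = r, k = as.integer(k),
                 h = h, r3 = r3, presence_min = as.integer(presence_min),
                 m_rule = m_rule),
            class = "theory_params")
}

#' Poisson rate of k-mer observations in one individual
#'
#' The number of times a (single-copy, haploid-equivalent) k-mer is observed
#' in an individual's reads is modelled as Poisson with rate
#' `lambda = d (1 - r)^k (l - k + 1) / l`: depth times the probability that
#' a k-mer is sequenced error-free, times the fraction of read positions
#' that start a full k-window.
#'
#' @param d sequencing depth.
#' @param r per-site error rate.
#' @param k k-mer length.
#' @param l read length (> k).
#' @return the Poisson rate lambda.
#' @export
lambda_rate <- function(d, r, k, l) {
  if (l <= k) stop("read length l must exceed k")
  if (d < 0) stop("depth d must be >= 0")
  d * (1 - r)^k * (l - k + 1) / l
}

#' Absence and presence probability of a k-mer in one individual
#'
#' Under the Poisson observation model, a k-mer is *absent* when seen fewer
#' than twice: `q_o = P(X = 0) + P(X = 1) = (1 + lambda) exp(-lambda)`;
#' presence is the complement.
#'
#' @param lambda Poisson rate (>= 0).
#' @return probability in `[0, 1]`.
#' @export
absence_prob <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  (1 + lambda) * exp(-lambda)
}

#' @rdname absence_prob
#' @export
presence_prob <- function(lambda) 1 - absence_prob(lambda)

# Upper binomial tail P(X >= m), X ~ Binom(n, p), numerically stable.
binom_tail <- function(m, n, p) {
  if (m <= 0) return(1)
  if (m > n) return(0)
  pbinom(m - 1, n, p, lower.tail = FALSE)
}

#' False-positive rate from genomic coverage
#'
#' An autosomal/X k-mer becomes a false marker when, by coverage chance
#' alone, it is present in at least m of the n males while absent from all n
#' females: `f1 = q_o^n * sum_{i=m}^{n} C(n,i) p_o^i q_o^(n-i)`.
#'
#' @param params a [theory_params()] bundle.
#' @return f1 in `[0, 1]`.
#' @examples
#' fp_coverage(theory_params(n = 5, d = 5, l = 150, r = 0.01, k = 21))  # ~4.4e-5
#' @export
fp_coverage <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  m <- male_presence_threshold(params$n, params$m_rule)
  q <- absence_prob(lambda_rate(params$d, params$r, params$k, params$l))
  q^params$n * binom_tail(m, params$n, 1 - q)
}

#' False-positive rate from population heterozygosity
#'
#' At a polymorphic autosomal site the two alleles generate two k-mers with
#' population frequencies `p_h1` and `p_h2 = 1 - p_h1`; allele j is observed
#' at rate `lambda_j = p_hj * lambda`. Either allele k-mer can be mistaken
#' for a marker by the same presence/absence mechanism, so
#' `f2 = sum_j q_oj^n * sum_{i=m}^{n} C(n,i) p_oj^i q_oj^(n-i)`.
#' The function is symmetric in `p_h1 <-> 1 - p_h1`.
#'
#' @inheritParams fp_coverage
#' @param p_h1 frequency of allele 1, in (0, 1).
#' @return f2 in `[0, 1]`.
#' @export
fp_heterozygosity <- function(params, p_h1) {
  stopifnot(inherits(params, "theory_params"))
  if (p_h1 <= 0 || p_h1 >= 1) stop("p_h1 must lie strictly inside (0, 1)")
  m <- male_presence_threshold(params$n, params$m_rule)
  lam <- lambda_rate(params$d, params$r, params$k, params$l)
  sum(vapply(c(p_h1, 1 - p_h1), function(ph) {
    q <- absence_prob(ph * lam)
    q^params$n * binom_tail(m, params$n, 1 - q)
  }, 0))
}

#' Empirical allele-frequency distribution for heterozygous k-mers
#'
#' Five-point discrete distribution of the allele-1 proportion `p_h1` at
#' biallelic SNVs, estimated from large human population panels: values
#' 0.05, 0.15, 0.25, 0.35, 0.45 with probabilities 92.77%, 2.59%, 1.80%,
#' 1.48%, 1.36%. User-overridable.
#'
#' @param values allele-1 proportions, each in (0, 0.5].
#' @param probs matching probabilities, summing to 1 (tolerance 1e-9).
#' @return a `het_allele_distribution` list with `values` and `probs`.
#' @export
het_allele_distribution <- function(values = c(0.05, 0.15, 0.25, 0.35, 0.45),
                                    probs = c(0.9277, 0.0259, 0.0180, 0.0148, 0.0136)) {
  stopifnot(length(values) == length(probs))
  if (any(values <= 0 | values > 0.5)) stop("p_h1 values must lie in (0, 0.5]")
  if (abs(sum(probs) - 1) > 1e-9) stop("probabilities must sum to 1")
  structure(list(values = values, probs = probs), class = "het_allele_distribution")
}

#' Total false-positive rate of marker identification
#'
#' Weighted average of the two sources: a k-mer overlaps a heterozygous site
#' with probability ~ `k h`, so
#' `f = (1 - k h) f1 + k h * sum_x f2(x) P(p_h1 = x)`.
#'
#' @inheritParams fp_coverage
#' @param het_dist a [het_allele_distribution()].
#' @return f in `[0, 1]`.
#' @export
fp_total <- function(params, het_dist = het_allele_distribution()) {
  stopifnot(inherits(params, "theory_params"),
            inherits(het_dist, "het_allele_distribution"))
  kh <- params$k * params$h
  if (kh >= 1) stop("k * h must be < 1 for the weighting to be a probability")
  f1 <- fp_coverage(params)
  if (params$h == 0) return(f1)
  f2_bar <- sum(vapply(het_dist$values, function(x) fp_heterozygosity(params, x), 0) *
                het_dist$probs)
  (1 - kh) * f1 + kh * f2_bar
}

#' True-positive rate of marker identification
#'
#' Probability that a genuine sex-limited-chromosome k-mer passes the
#' >= m-of-n male presence rule; the female-absence factor is ~1 (a true
#' marker is never carried by females, and error-generated copies are
#' negligible): `TPR = sum_{i=m}^{n} C(n,i) p_o^i q_o^(n-i)`.
#'
#' `effective_depth` is exposed because the depth a single-copy Y k-mer sees
#' may be interpreted as d or d/2 depending on depth bookkeeping; default d.
#'
#' @inheritParams fp_coverage
#' @param effective_depth depth at which lambda is evaluated (default
#'   `params$d`).
#' @return TPR in `[0, 1]`.
#' @export
tpr_msk <- function(params, effective_depth = NULL) {
  stopifnot(inherits(params, "theory_params"))
  d_eff <- effective_depth %||% params$d
  if (d_eff <= 0) stop("effective_depth must be > 0")
  m <- male_presence_threshold(params$n, params$m_rule)
  q <- absence_prob(lambda_rate(d_eff, params$r, params$k, params$l))
  binom_tail(m, params$n, 1 - q)
}

#' Probability of sorting a long read
#'
#' A long read spanning a region with `N` specific markers retains each one
#' only if its k bases are sequenced correctly, probability
#' `p = (1 - r3)^k`. The read is sorted when at least `M` markers survive:
#' the binomial upper tail `sum_{i=M}^{N} C(N,i) p^i (1-p)^(N-i)`. In the
#' sorter, `M` is the density threshold times the read length.
#'
#' @param N markers spanned by the read (>= 0).
#' @param M markers required (>= 0); `M = 0` gives 1, `M > N` gives 0.
#' @param p per-marker survival probability; alternatively give `r3` and `k`.
#' @param r3,k long-read per-site error rate and k-mer length, used when `p`
#'   is missing.
#' @return probability in `[0, 1]`.
#' @examples
#' read_sort_prob(N = 70, M = 7, r3 = 0.1, k = 21)
#' @export
read_sort_prob <- function(N, M, p = NULL, r3 = NULL, k = NULL) {
  if (is.null(p)) {
    if (is.null(r3) || is.null(k)) stop("give either p or both r3 and k")
    p <- (1 - r3)^k
  }
  stopifnot(N >= 0, M >= 0, p >= 0, p <= 1)
  binom_tail(M, N, p)
}

#' Probability a k-mer contains more than one heterozygous site
#'
#' `1 - (1-h)^k - k h (1-h)^(k-1)`; at k = 21 and h = 0.001 this is
#' ~2.1e-4, which is why multi-site heterozygous k-mers are neglected in
#' the error models.
#'
#' @param k k-mer length.
#' @param h per-site heterozygosity rate in `[0, 1]`.
#' @return probability in `[0, 1]`.
#' @export
het_multi_site_prob <- function(k, h) {
  stopifnot(h >= 0, h <= 1, k >= 1)
  1 - (1 - h)^k - k * h * (1 - h)^(k - 1)
}

#' Probability of converting one k-mer into a specific neighbour by error
#'
#' A sequencing error turns k-mer-1 into one *specific* edit-distance-1
#' k-mer-2 with probability `(1-r)^(k-1) * r / 3` (the other k-1 bases read
#' correctly; the one error hits the right site and picks the right base of
#' the three alternatives). ~0.3% at k = 21, r = 0.01 -- small enough that
#' allele cross-identification is neglected in the models.
#'
#' @param k k-mer length.
#' @param r per-site error rate in `[0, 1]`.
#' @return probability in `[0, 1]`.
#' @export
misid_prob <- function(k, r) {
  stopifnot(r >= 0, r <= 1, k >= 1)
  (1 - r)^(k - 1) * r / 3
}

#' Theoretical precision of marker identification
#'
#' `YSK * TPR / (YSK * TPR + AXK * FPR)`, where YSK is the number of true
#' sex-limited-chromosome-specific k-mers and AXK the number of autosome+X
#' k-mers.
#'
#' @param ysk,axk k-mer census counts (>= 0).
#' @param tpr,fpr true- and false-positive rates in `[0, 1]`.
#' @return precision in `[0, 1]`.
#' @export
msk_precision <- function(ysk, axk, tpr, fpr) {
  stopifnot(ysk >= 0, axk >= 0, tpr >= 0, tpr <= 1, fpr >= 0, fpr <= 1)
  den <- ysk * tpr + axk * fpr
  if (den == 0) stop("undefined precision: YSK*TPR + AXK*FPR is zero")
  ysk * tpr / den
}
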