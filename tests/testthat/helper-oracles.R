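# Independent oracles used across the suite. These deliberately avoid the
# package's own C++ paths: plain-R enumeration, brute-force loops, and
# explicit Monte-Carlo simulation.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

revcomp_r <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""), ""))
}

canonical_r <- function(s) {
  rc <- unname(revcomp_r(toupper(s)))
  ifelse(rc < toupper(s), rc, toupper(s))
}

# brute-force canonical k-mer counting via substring windows
count_kmers_r <- function(reads, k) {
  kmers <- unlist(lapply(toupper(reads), function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    w <- substring(s, 1:(n - k + 1), k:n)
    w[grepl("^[ACGT]+$", w)]
  }))
  if (!length(kmers)) return(integer(0))
  tab <- table(canonical_r(kmers))
  setNames(as.integer(tab), names(tab))
}

# brute-force double loop over (k-mer, individual) for marker selection
msk_brute <- function(male_sets, female_sets, m) {
  universe <- unique(unlist(c(male_sets, female_sets)))
  keep <- vapply(universe, function(km) {
    in_males <- sum(vapply(male_sets, function(s) km %in% s, TRUE))
    in_females <- sum(vapply(female_sets, function(s) km %in% s, TRUE))
    in_males >= m && in_females == 0
  }, TRUE)
  sort(universe[keep])
}

# naive per-window marker membership scan
scan_brute <- function(seq, k, markers, distinct = FALSE) {
  n <- nchar(seq)
  if (n < k) return(0L)
  w <- substring(toupper(seq), 1:(n - k + 1), k:n)
  w <- w[grepl("^[ACGT]+$", w)]
  hit <- canonical_r(w)[canonical_r(w) %in% canonical_r(markers)]
  if (distinct) length(unique(hit)) else length(hit)
}

# ---- Monte-Carlo oracles for the closed-form models -------------------------
# Explicit per-individual Poisson/Bernoulli draws; return estimate and its MC
# standard error.

mc_fp_coverage <- function(n, lambda, m, reps, presence_min = 2) {
  males <- matrix(stats::rpois(reps * n, lambda), ncol = n)
  females <- matrix(stats::rpois(reps * n, lambda), ncol = n)
  hit <- rowSums(males >= presence_min) >= m & rowSums(females >= presence_min) == 0
  list(est = mean(hit), se = stats::sd(hit) / sqrt(reps))
}

mc_fp_heterozygosity <- function(n, lambda, p_h1, m, reps, presence_min = 2) {
  one_allele <- function(ph) {
    males <- matrix(stats::rpois(reps * n, ph * lambda), ncol = n)
    females <- matrix(stats::rpois(reps * n, ph * lambda), ncol = n)
    rowSums(males >= presence_min) >= m & rowSums(females >= presence_min) == 0
  }
  h1 <- one_allele(p_h1)
  h2 <- one_allele(1 - p_h1)
  list(est = mean(h1) + mean(h2),
       se = sqrt(stats::var(h1) / reps + stats::var(h2) / reps))
}

mc_tpr <- function(n, lambda, m, reps, presence_min = 2) {
  males <- matrix(stats::rpois(reps * n, lambda), ncol = n)
  hit <- rowSums(males >= presence_min) >= m
  list(est = mean(hit), se = stats::sd(hit) / sqrt(reps))
}

mc_read_sort <- function(N, M, p, reps) {
  surviving <- stats::rbinom(reps, N, p)
  hit <- surviving >= M
  list(est = mean(hit), se = stats::sd(hit) / sqrt(reps))
}

# tiny genome shared by several structural tests
tiny_truth <- function(seed = 42) {
  generate_genome(genome_config(autosome_len = 6e4, x_len = 3e4, y_len = 1.5e4,
                                par_len = 2e3, seed = seed))
}
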