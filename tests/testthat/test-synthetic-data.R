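test_that("genome generation is deterministic given the seed", {
  cfg <- genome_config(autosome_len = 2e4, x_len = 1e4, y_len = 5e3,
                       par_len = 1e3, seed = 99)
  t1 <- generate_genome(cfg)
  t2 <- generate_genome(cfg)
  expect_identical(t1$sequences, t2$sequences)
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(generate_genome(cfg2)$sequences, t1$sequences))
})

test_that("a Y identical to the X yields no specific k-mers", {
  cfg <- genome_config(autosome_len = 2e4, x_len = 1e4, y_len = 4e3,
                       par_len = 4e3, xy_divergence = 0, y_novel_frac = 0,
                       seed = 7)
  truth <- generate_genome(cfg)
  expect_length(true_specific_kmers(truth, 21), 0)
})

test_that("truth k-mers equal the brute-force canonical set difference", {
  cfg <- genome_config(autosome_len = 5e3, x_len = 3e3, y_len = 1500,
                       par_len = 300, seed = 31)
  truth <- generate_genome(cfg)
  for (k in c(11, 21)) {
    got <- sort(true_specific_kmers(truth, k))
    y_k <- names(count_kmers_r(truth$sequences$Y, k))
    ax_k <- names(count_kmers_r(c(truth$sequences$A, truth$sequences$X), k))
    expect_equal(got, sort(setdiff(y_k, ax_k)))
  }
})

test_that("longer k-mers containing a specific shorter k-mer are themselves specific", {
  truth <- generate_genome(genome_config(autosome_len = 5e3, x_len = 3e3,
                                         y_len = 1500, par_len = 300, seed = 33))
  t21 <- true_specific_kmers(truth, 21)
  t51 <- true_specific_kmers(truth, 51)
  # every 51-window of Y that contains a specific 21-mer must be in t51
  y <- truth$sequences$Y
  w51 <- substring(y, 1:(nchar(y) - 50), 51:nchar(y))
  contains_specific <- vapply(w51, function(w) {
    sub21 <- substring(w, 1:31, 21:51)
    any(canonical_r(sub21) %in% t21)
  }, TRUE)
  expect_true(all(canonical_r(w51[contains_specific]) %in% t51))
})

test_that("individuals carry the right chromosome dosage and heterozygosity", {
  truth <- tiny_truth(41)
  male <- derive_individual(truth, "male", seed = 1)
  female <- derive_individual(truth, "female", seed = 2)
  expect_named(male$haplotypes, c("A1", "A2", "X1", "Y"))
  expect_named(female$haplotypes, c("A1", "A2", "X1", "X2"))
  expect_false(any(grepl("Y", names(female$haplotypes))))
  # h = 0: haplotypes identical to the reference
  expect_identical(male$haplotypes$A1, truth$sequences$A)
  expect_identical(male$haplotypes$A2, truth$sequences$A)

  # private-mutation model: expected het site count ~ h * autosome_len
  h <- 0.005
  len <- nchar(truth$sequences$A)
  ind <- derive_individual(truth, "male", h = h, seed = 3)
  n_het <- sum(strsplit(ind$haplotypes$A1, "")[[1]] !=
               strsplit(ind$haplotypes$A2, "")[[1]])
  expect_lt(abs(n_het - h * len), 4 * sqrt(h * len))

  # panel model: realised het rate matches h in expectation
  panel <- polymorphism_panel(truth, h, seed = 4)
  het_rates <- vapply(1:6, function(i) {
    ind <- derive_individual(truth, "male", h = h, panel = panel, seed = 10 + i)
    sum(strsplit(ind$haplotypes$A1, "")[[1]] !=
        strsplit(ind$haplotypes$A2, "")[[1]]) / len
  }, 0)
  expect_lt(abs(mean(het_rates) - h), 4 * sqrt(h / (6 * len)))
})

test_that("short-read simulation conserves coverage and is error-free at r = 0", {
  truth <- tiny_truth(43)
  ind <- derive_individual(truth, "male", seed = 5)
  d <- 5; l <- 150
  reads <- simulate_short_reads(ind, depth = d, read_len = l, error_rate = 0, seed = 6)
  genome_size <- sum(nchar(unlist(ind$haplotypes)))
  expect_lt(abs(sum(nchar(reads)) - d * genome_size) / (d * genome_size), 0.01)
  # r = 0: every read k-mer exists in the source genome
  src_k <- count_kmers(unlist(ind$haplotypes), k = 21)
  read_k <- count_kmers(reads, k = 21)
  expect_true(all(read_k$kmer %in% src_k$kmer))
  # female reads contain no Y-specific k-mer
  fem <- derive_individual(truth, "female", seed = 7)
  fem_reads <- simulate_short_reads(fem, depth = 3, error_rate = 0, seed = 8)
  tk <- true_specific_kmers(truth, 21)
  expect_equal(sum(scan_sequence(fem_reads, tk)$msk_hits), 0)
})

test_that("systematic tiling covers every k-window at least twice", {
  truth <- generate_genome(genome_config(autosome_len = 5e3, x_len = 2e3,
                                         y_len = 1e3, par_len = 200, seed = 45))
  ind <- derive_individual(truth, "male", seed = 9)
  reads <- simulate_short_reads(ind, systematic = TRUE, error_rate = 0,
                                k_guard = 21, seed = 10)
  tab <- count_kmers(reads, k = 21)
  src <- count_kmers(unlist(ind$haplotypes), k = 21)
  expect_true(all(src$kmer %in% tab$kmer))
  # every genomic k-mer is observed at least twice
  expect_true(all(tab$count[tab$kmer %in% src$kmer] >= 2))
})

test_that("long-read simulation respects origins, lengths, and error presets", {
  truth <- tiny_truth(47)
  sim <- simulate_long_reads(truth, "hifi", depth = c(A = 4, X = 4, Y = 4),
                             seed = 11, mean_len = 2000, sd_len = 200,
                             min_len = 500, sub = 0, ins = 0, del = 0)
  # error-free reads are exact substrings of their source chromosome
  for (i in head(seq_len(nrow(sim$info)), 25)) {
    info <- sim$info[i, ]
    src <- truth$sequences[[info$chrom]]
    expect_identical(unname(sim$reads[[i]]),
                     substr(src, info$start, info$end))
  }
  # read-base share per chromosome tracks depth x length
  bases <- tapply(nchar(sim$reads), sim$info$chrom, sum)
  lens <- vapply(truth$sequences, nchar, 1L)[names(bases)]
  expect_lt(max(abs(bases / lens - 4)), 0.5)  # all at ~4x
  # presets differ only in configured rates/lengths
  expect_false(identical(long_read_preset("hifi"), long_read_preset("ont")))
  # determinism
  sim2 <- simulate_long_reads(truth, "hifi", depth = c(A = 4, X = 4, Y = 4),
                              seed = 11, mean_len = 2000, sd_len = 200,
                              min_len = 500, sub = 0, ins = 0, del = 0)
  expect_identical(sim$reads, sim2$reads)
})

test_that("long-read origin labels apply the non-PAR majority rule", {
  truth <- tiny_truth(49)
  sim <- simulate_long_reads(truth, "hifi", depth = c(A = 1, X = 1, Y = 8),
                             seed = 13, mean_len = 1500, sd_len = 300, min_len = 500)
  info <- sim$info
  expect_true(all(info$origin_label[info$chrom != "Y"] %in% c("A", "X")))
  y <- info[info$chrom == "Y", ]
  expect_true(all(y$origin_label[y$y_nonpar_frac >= 0.5] == "Y"))
  expect_true(all(y$origin_label[y$y_nonpar_frac < 0.5] == "Y-par"))
})
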