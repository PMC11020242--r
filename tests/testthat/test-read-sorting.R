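make_marked_read <- function(len, k, markers_at, marker_pool) {
  # build a read of length len with marker k-mers planted at given positions
  s <- strsplit(rand_dna(len), "")[[1]]
  planted <- character(0)
  for (i in seq_along(markers_at)) {
    km <- marker_pool[i]
    s[markers_at[i]:(markers_at[i] + k - 1)] <- strsplit(km, "")[[1]]
    planted <- c(planted, km)
  }
  list(seq = paste(s, collapse = ""), markers = planted)
}

test_that("density is hits per kilobase over the full read length", {
  set.seed(501)
  k <- 21
  pool <- unique(vapply(1:50, function(i) canonical_r(rand_dna(k)), ""))
  # 1000 bp read with 8 planted markers, far apart -> 8 hits, density 8/kb
  r <- make_marked_read(1000, k, seq(1, 8 * 120, by = 120), pool)
  sc <- scan_sequence(c(read1 = r$seq), r$markers)
  hits <- scan_brute(r$seq, k, r$markers)
  expect_equal(sc$msk_hits, hits)
  expect_equal(sc$density_per_kb, hits * 1000 / 1000)
  expect_true(sc$density_per_kb >= 7)  # selected at the default threshold

  # read with no marker hits scores 0 and is never selected
  rd0 <- rand_dna(800)
  sc0 <- scan_sequence(c(read2 = rd0), pool[1:5])
  expect_equal(sc0$msk_hits, scan_brute(rd0, k, pool[1:5]))
  srt <- sort_reads(c(read2 = substr(r$seq, 1, 30)), pool[40:45], threshold_per_kb = 0)
  expect_false(any(srt$scores$selected))  # min_hits = 1 guards threshold 0

  # 500 bp read with 2 hits -> density 4/kb, rejected at 7/kb
  r2 <- make_marked_read(500, k, c(1, 200), pool[10:12])
  sc2 <- scan_sequence(c(read3 = r2$seq), r2$markers)
  expect_equal(sc2$density_per_kb, sc2$msk_hits * 2)
  if (sc2$msk_hits == 2) expect_equal(sc2$density_per_kb, 4)
  srt2 <- sort_reads(c(read3 = r2$seq), r2$markers, threshold_per_kb = 7)
  expect_false(any(srt2$scores$selected))
})

test_that("scanning equals the naive window-membership loop on random sequences", {
  set.seed(502)
  k <- 11
  markers <- unique(vapply(1:30, function(i) canonical_r(rand_dna(k)), ""))
  for (trial in 1:5) {
    s <- rand_dna(sample(2000:10000, 1))
    sc <- scan_sequence(s, markers)
    expect_equal(sc$msk_hits, scan_brute(s, k, markers))
    scd <- scan_sequence(s, markers, distinct = TRUE)
    expect_equal(scd$msk_hits, scan_brute(s, k, markers, distinct = TRUE))
  }
})

test_that("sorting partitions reads exhaustively, deterministically, monotonically", {
  set.seed(503)
  truth <- tiny_truth(13)
  tk <- true_specific_kmers(truth, 21)
  sim <- simulate_long_reads(truth, "hifi", depth = c(A = 3, X = 3, Y = 6),
                             seed = 5, mean_len = 2000, sd_len = 300, min_len = 500)
  srt <- sort_reads(sim$reads, tk)
  # exhaustive + disjoint partition
  expect_equal(sort(c(names(srt$selected), names(srt$rejected))),
               sort(names(sim$reads)))
  expect_length(intersect(names(srt$selected), names(srt$rejected)), 0)
  # determinism: identical inputs give identical outputs
  srt2 <- sort_reads(sim$reads, tk)
  expect_identical(srt$scores, srt2$scores)
  # raising the threshold never adds a selected read
  srt_hi <- sort_reads(sim$reads, tk, threshold_per_kb = 20)
  expect_true(all(names(srt_hi$selected) %in% names(srt$selected)))
})

test_that("a read exactly at the threshold is selected (lower is excluded, equal is not)", {
  set.seed(504)
  k <- 21
  pool <- unique(vapply(1:20, function(i) canonical_r(rand_dna(k)), ""))
  r <- make_marked_read(1000, k, seq(1, 7 * 130, by = 130), pool)  # 7 hits / kb
  sc <- scan_sequence(c(x = r$seq), r$markers)
  if (sc$msk_hits == 7) {
    srt <- sort_reads(c(x = r$seq), r$markers, threshold_per_kb = 7)
    expect_true(srt$scores$selected)
  }
  # strictly below the threshold is rejected
  r6 <- make_marked_read(1000, k, seq(1, 6 * 130, by = 130), pool)
  sc6 <- scan_sequence(c(x = r6$seq), r6$markers)
  srt6 <- sort_reads(c(x = r6$seq), r6$markers, threshold_per_kb = 7)
  if (sc6$msk_hits == 6) expect_false(srt6$scores$selected)
})

test_that("contig sorting picks the target-chromosome contig", {
  truth <- tiny_truth(17)
  tk <- true_specific_kmers(truth, 21)
  contigs <- c(ctgY = truth$sequences$Y, ctgX = truth$sequences$X,
               ctgA = substr(truth$sequences$A, 1, 2e4))
  res <- sort_contigs(contigs, tk, threshold_per_kb = 7)
  expect_equal(names(res$selected), "ctgY")
  expect_setequal(names(res$rejected), c("ctgX", "ctgA"))
  # empty input gives empty partitions
  empty <- sort_contigs(character(0), tk)
  expect_equal(nrow(empty$scores), 0)
})

test_that("threshold estimation from a reference averages marker density", {
  set.seed(505)
  truth <- tiny_truth(19)
  tk <- true_specific_kmers(truth, 21)
  y <- truth$sequences$Y
  est <- estimate_density_threshold(tk, y)
  expect_equal(est, sum(scan_sequence(y, tk)$msk_hits) * 1000 / nchar(y))
  # no reference -> the default human-Y value
  expect_equal(estimate_density_threshold(tk), 7.0)
  # reference without hits -> 0 with a warning
  expect_warning(z <- estimate_density_threshold("AAAAAAAAAAAAAAAAAAAAA",
                                                 rand_dna(2e4)), "no marker hits")
  expect_equal(z, 0)
  expect_error(estimate_density_threshold(tk, rand_dna(5000)), "too short")
})

test_that("file-based sorting writes verbatim partitions and a score table", {
  set.seed(506)
  truth <- tiny_truth(23)
  tk <- true_specific_kmers(truth, 21)
  sim <- simulate_long_reads(truth, "hifi", depth = c(A = 2, X = 2, Y = 4),
                             seed = 6, mean_len = 1500, sd_len = 200, min_len = 500)
  fq <- tempfile(fileext = ".fq.gz")
  mskit:::write_sequences(sim$reads, fq)
  outdir <- tempfile()
  res <- sort_reads(fq, tk, output_dir = outdir)
  expect_true(file.exists(file.path(outdir, "selected.fq")))
  expect_true(file.exists(file.path(outdir, "scores.tsv")))
  sel <- mskit:::read_sequences(file.path(outdir, "selected.fq"))
  expect_equal(unname(sel), unname(as.character(res$selected)),
               ignore_attr = TRUE)
  sc <- read.delim(file.path(outdir, "scores.tsv"))
  expect_equal(nrow(sc), length(sim$reads))
  expect_named(sc, c("read_id", "length", "msk_hits", "density_per_kb", "selected"))
  unlink(c(fq, outdir), recursive = TRUE)
})
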