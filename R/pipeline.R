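#' Simulate a population and identify its male-specific k-mers
#'
#' End-to-end marker pipeline on synthetic data: derive `n_males` +
#' `n_females` individuals (distinct derived seeds each), simulate their
#' short reads, count k-mers into sorted per-individual tables on disk, and
#' run the streaming group comparison. Temporary tables are removed on
#' exit.
#'
#' @param truth a `synthetic_truth`.
#' @param n_males,n_females individuals per group.
#' @param h heterozygosity rate; with `panel` given, the shared-polymorphism
#'   model is used.
#' @param panel optional [polymorphism_panel()].
#' @param depth,read_len,error_rate short-read parameters (per haploid
#'   copy depth).
#' @param systematic deterministic double-coverage tiling instead of random
#'   placement (see [simulate_short_reads()]).
#' @param k k-mer length.
#' @param min_count presence threshold.
#' @param rule male-presence threshold rule.
#' @param depth_band optional pooled-count band, passed through.
#' @param seed master seed; all per-individual seeds derive from it.
#' @param work_dir directory for the temporary tables.
#' @return a `marker_set`.
#' @export
simulate_population_markers <- function(truth, n_males, n_females, h = 0,
                                        panel = NULL, depth = 5, read_len = 150,
                                        error_rate = 0.009, systematic = FALSE,
                                        k = 21, min_count = 2, rule = "round",
                                        depth_band = NULL, seed = 1,
                                        work_dir = tempfile("msk_pop_")) {
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  on.exit(unlink(work_dir, recursive = TRUE), add = TRUE)
  if (h > 0 && is.null(panel))
    panel <- polymorphism_panel(truth, h, seed = derive_seed(seed, 999983))
  make_tables <- function(sex, count, offset) {
    vapply(seq_len(count), function(i) {
      ind <- derive_individual(truth, sex = sex, h = h, panel = panel,
                               seed = derive_seed(seed, offset + 2 * i))
      reads <- simulate_short_reads(ind, depth = depth, read_len = read_len,
                                    error_rate = error_rate,
                                    systematic = systematic, k_guard = k,
                                    seed = derive_seed(seed, offset + 2 * i + 1))
      path <- file.path(work_dir, sprintf("%s%02d.tsv.gz", sex, i))
      count_kmers(reads, k = k, output = path,
                  source_label = sprintf("%s%02d", sex, i))
      path
    }, "")
  }
  male_files <- make_tables("male", n_males, 0)
  female_files <- make_tables("female", n_females, 10000)
  select_male_specific(male_files, female_files, rule = rule,
                       min_count = min_count, depth_band = depth_band)
}
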