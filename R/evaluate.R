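make_eval_report <- function(tp, fp, fn, context) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, context = context),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s]: tp=%d fp=%d fn=%d  precision=%.4f recall=%.4f F1=%.4f\n",
              x$context, x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate a marker set against truth
#'
#' Set comparison of predicted markers against the exact truth set:
#' `tp = |P n T|`, `fp = |P \ T|`, `fn = |T \ P|`, with the usual
#' precision/recall/F1 (0 by convention when a denominator is 0).
#'
#' @param predicted a `marker_set` or character vector.
#' @param truth character vector of true specific k-mers (same k).
#' @return an `eval_report` with context `"markers"`.
#' @export
eval_marker_set <- function(predicted, truth) {
  p <- unique(marker_kmers(predicted))
  t <- unique(as.character(truth))
  if (length(p) && length(t) && nchar(p[1]) != nchar(t[1]))
    stop("predicted and truth k-mer lengths differ")
  tp <- sum(p %in% t)
  make_eval_report(tp = tp, fp = length(p) - tp, fn = length(t) - tp,
                   context = "markers")
}

#' Evaluate a read partition against origin labels
#'
#' Per-read evaluation of a sorting run: `tp` = selected reads whose origin
#' is the target chromosome, `fp` = selected reads of other origin, `fn` =
#' rejected reads of target origin.
#'
#' @param scores the `scores` data.frame of [sort_reads()] (needs `read_id`
#'   and `selected`).
#' @param origins read origins: named character vector (`read_id` ->
#'   chromosome label) or a data.frame with columns `read_id` and `origin`
#'   (or `origin_label`).
#' @param target origin label counted as positive (default `"Y"`).
#' @return an `eval_report` with context `"reads"`.
#' @export
eval_read_partition <- function(scores, origins, target = "Y") {
  stopifnot(is.data.frame(scores), all(c("read_id", "selected") %in% names(scores)))
  if (is.data.frame(origins)) {
    ocol <- intersect(c("origin", "origin_label"), names(origins))[1]
    if (is.na(ocol)) stop("origins data.frame needs an 'origin' or 'origin_label' column")
    origins <- setNames(as.character(origins[[ocol]]), origins$read_id)
  }
  lab <- origins[scores$read_id]
  if (anyNA(lab)) {
    missing <- scores$read_id[is.na(lab)]
    stop("no origin label for read(s): ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else "")
  }
  pos <- lab == target
  make_eval_report(tp = sum(scores$selected & pos),
                   fp = sum(scores$selected & !pos),
                   fn = sum(!scores$selected & pos),
                   context = "reads")
}

#' Degrade a marker set to a target precision
#'
#' Spikes decoy k-mers (drawn from the autosome+X k-mer pool, i.e. genuine
#' non-target genomic sequence) into a true marker set so the resulting
#' precision is `target_precision`. By default all true markers are kept and
#' `ceil(n_true (1 - pi) / pi)` decoys are added.
#'
#' When `decoy_density_per_kb` and `decoy_span_bp` are given, the decoy
#' count is fixed at `density * span / 1000` -- the physically meaningful
#' quantity for read sorting, since decoys land on non-target sequence at
#' that spatial density -- and the true markers are subsampled so the
#' precision still comes out at `target_precision` exactly. This mirrors
#' marker identification at large genome scale, where the identified set is
#' a subset of all true specific k-mers (recall < 1) plus false positives
#' whose genomic density is far below the sorting threshold.
#'
#' @param markers true markers: `marker_set` or character vector.
#' @param target_precision target precision in (0, 1].
#' @param decoy_pool character vector of non-target k-mers to sample decoys
#'   from (true markers are excluded automatically).
#' @param seed integer seed; sampling is deterministic given it.
#' @param decoy_density_per_kb,decoy_span_bp optional decoy spatial density
#'   cap (markers/kb over the span the pool was drawn from).
#' @return a `marker_set` with extra fields `n_true`, `n_decoys`,
#'   `achieved_precision`, and `is_true` (logical vector aligned with
#'   `kmers`).
#' @export
degrade_marker_precision <- function(markers, target_precision, decoy_pool,
                                     seed = 1, decoy_density_per_kb = NULL,
                                     decoy_span_bp = NULL) {
  if (target_precision <= 0 || target_precision > 1)
    stop("target_precision must lie in (0, 1]")
  true_km <- unique(marker_kmers(markers))
  pool <- setdiff(unique(as.character(decoy_pool)), true_km)
  with_seed(seed, {
    if (target_precision == 1) {
      keep <- true_km
      decoys <- character(0)
    } else if (!is.null(decoy_density_per_kb)) {
      if (is.null(decoy_span_bp)) stop("decoy_span_bp required with decoy_density_per_kb")
      n_decoys <- round(decoy_density_per_kb * decoy_span_bp / 1000)
      n_keep <- round(n_decoys * target_precision / (1 - target_precision))
      if (n_keep > length(true_km)) {  # density cap not binding: plain spiking
        n_keep <- length(true_km)
        n_decoys <- ceiling(n_keep * (1 - target_precision) / target_precision -
                            1e-9)
      }
      if (n_decoys > length(pool))
        stop("decoy pool too small: need ", n_decoys, ", have ", length(pool))
      keep <- sample(true_km, n_keep)
      decoys <- sample(pool, n_decoys)
    } else {
      n_decoys <- ceiling(length(true_km) * (1 - target_precision) /
                          target_precision - 1e-9)
      if (n_decoys > length(pool))
        stop("decoy pool too small: need ", n_decoys, ", have ", length(pool))
      keep <- true_km
      decoys <- sample(pool, n_decoys)
    }
    kmers <- c(keep, decoys)
    ord <- order(kmers, method = "radix")
    is_true <- c(rep(TRUE, length(keep)), rep(FALSE, length(decoys)))[ord]
    structure(list(k = nchar(kmers[1]), kmers = kmers[ord],
                   n_males = NA_integer_, n_females = NA_integer_,
                   m_threshold = NA_integer_, rule = NA_character_,
                   min_count = NA_integer_, depth_band = NULL,
                   n_true = length(keep), n_decoys = length(decoys),
                   achieved_precision = length(keep) / length(kmers),
                   is_true = is_true),
              class = "marker_set")
  })
}

#' Population-size / heterozygosity sweep of marker identification
#'
#' For every combination of individuals-per-sex `n` and heterozygosity `h`,
#' simulates a fresh genome and population, runs the full marker pipeline
#' (count, presence, select) and scores the marker set against the exact
#' truth. Heterozygosity uses the shared polymorphism-panel model (see
#' [derive_individual()]). Replicate seeds are derived from `seed` by
#' counter.
#'
#' @param n_values integer vector of individuals per sex.
#' @param het_values numeric vector of heterozygosity rates.
#' @param config base [genome_config()] (its `seed` field is replaced per
#'   replicate).
#' @param depth,read_len,error_rate short-read simulation parameters.
#' @param k k-mer length.
#' @param min_count presence threshold.
#' @param rule male-presence threshold rule.
#' @param replicates replicates per combination.
#' @param seed master seed.
#' @return data.frame with one row per (n, h, replicate): `n`, `h`, `rep`,
#'   `precision`, `recall`, `f1`, `n_markers`, `n_truth`.
#' @export
run_population_sweep <- function(n_values = c(2, 4, 6), het_values = c(0, 0.003),
                                 config = genome_config(autosome_len = 4e5,
                                                        x_len = 1.5e5,
                                                        y_len = 6e4,
                                                        par_len = 5e3),
                                 depth = 5, read_len = 150, error_rate = 0.009,
                                 k = 21, min_count = 2, rule = "round",
                                 replicates = 5, seed = 1) {
  stopifnot(replicates >= 1)
  rows <- list()
  counter <- 0
  for (rep_i in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, rep_i)
    truth <- generate_genome(cfg)
    truth_km <- true_specific_kmers(truth, k)
    for (h in het_values) {
      panel <- polymorphism_panel(truth, h, seed = derive_seed(seed, 7000 + rep_i))
      for (n in n_values) {
        counter <- counter + 1
        ms <- simulate_population_markers(
          truth, n_males = n, n_females = n, h = h, panel = panel,
          depth = depth, read_len = read_len, error_rate = error_rate,
          k = k, min_count = min_count, rule = rule,
          seed = derive_seed(seed, 100 * counter))
        ev <- eval_marker_set(ms, truth_km)
        rows[[length(rows) + 1]] <- data.frame(
          n = n, h = h, rep = rep_i, precision = ev$precision,
          recall = ev$recall, f1 = ev$f1, n_markers = length(ms$kmers),
          n_truth = length(truth_km))
      }
    }
  }
  do.call(rbind, rows)
}

#' Marker-precision sweep of long-read sorting
#'
#' For every marker precision level and long-read technology preset:
#' degrade the exact truth markers with autosome+X decoys, simulate labelled
#' long reads, sort at the density threshold, and score the partition
#' against the origin labels.
#'
#' @param precisions precision levels in (0, 1].
#' @param presets long-read preset names, or a named list of preset
#'   configuration lists (see [long_read_preset()]).
#' @param truth a `synthetic_truth` (generated once; replicates vary read
#'   and degradation seeds).
#' @param k k-mer length.
#' @param depth per-chromosome long-read depth (named or scalar).
#' @param threshold_per_kb sorting threshold.
#' @param min_hits minimum marker hits.
#' @param decoy_density_per_kb optional decoy spatial density (see
#'   [degrade_marker_precision()]).
#' @param replicates replicates per combination.
#' @param seed master seed.
#' @return data.frame with one row per (precision, preset, replicate):
#'   adds `precision_markers`, `tech`, `rep`, and the read-partition
#'   `precision`, `recall`, `f1`, plus `n_reads`.
#' @export
run_precision_sweep <- function(precisions = c(1, 0.9, 0.8, 0.7),
                                presets = "hifi",
                                truth = generate_genome(genome_config(
                                  autosome_len = 4e5, x_len = 1.5e5,
                                  y_len = 6e4, par_len = 5e3)),
                                k = 21, depth = c(A = 50, X = 50, Y = 25),
                                threshold_per_kb = 7, min_hits = 1,
                                decoy_density_per_kb = NULL,
                                replicates = 3, seed = 1) {
  truth_km <- true_specific_kmers(truth, k)
  span <- nchar(truth$sequences$A) + nchar(truth$sequences$X)
  if (!is.list(presets)) presets <- setNames(lapply(presets, long_read_preset), presets)
  pool <- NULL
  rows <- list()
  counter <- 0
  for (pi_lvl in precisions) {
    if (pi_lvl < 1 && is.null(pool))
      pool <- kmer_set_diff_cpp(c(truth$sequences$A, truth$sequences$X),
                                truth$sequences$Y, as.integer(k))
    for (tech in names(presets)) {
      for (rep_i in seq_len(replicates)) {
        counter <- counter + 1
        ms <- if (pi_lvl < 1)
          degrade_marker_precision(truth_km, pi_lvl, pool,
                                   seed = derive_seed(seed, counter),
                                   decoy_density_per_kb = decoy_density_per_kb,
                                   decoy_span_bp = if (is.null(decoy_density_per_kb)) NULL else span)
        else structure(list(k = k, kmers = truth_km), class = "marker_set")
        sim <- simulate_long_reads(truth, preset = presets[[tech]], depth = depth,
                                   seed = derive_seed(seed, 5000 + counter))
        srt <- sort_reads(sim$reads, ms, threshold_per_kb = threshold_per_kb,
                          min_hits = min_hits)
        ev <- eval_read_partition(srt$scores, sim$info, target = "Y")
        rows[[length(rows) + 1]] <- data.frame(
          precision_markers = pi_lvl, tech = tech, rep = rep_i,
          precision = ev$precision, recall = ev$recall, f1 = ev$f1,
          n_reads = nrow(srt$scores))
      }
    }
  }
  do.call(rbind, rows)
}
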