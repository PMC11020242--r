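#' Male-presence threshold m
#'
#' A k-mer qualifies as male-specific only if it is present in at least
#' `m = 2n/3` of the `n` males. The default rounding rule is
#' nearest-integer (half away from zero): it is the rule that reproduces the
#' closed-form false-positive values of the coverage model at both n = 5 and
#' n = 10, whereas a ceiling does not at n = 5. `ceil` and `floor` are kept
#' as options. The result is clamped to `[1, n]`.
#'
#' @param n number of male individuals (>= 1).
#' @param rule rounding rule for 2n/3: `"round"`, `"ceil"` or `"floor"`.
#' @return integer threshold m.
#' @examples
#' male_presence_threshold(5)   # 3
#' male_presence_threshold(10)  # 7
#' @export
male_presence_threshold <- function(n, rule = c("round", "ceil", "floor")) {
  rule <- match.arg(rule)
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != as.integer(n))
    stop("n must be a single integer >= 1")
  x <- 2 * n / 3
  m <- switch(rule,
    round = floor(x + 0.5),  # half away from zero (x > 0 here)
    ceil  = ceiling(x),
    floor = floor(x))
  as.integer(min(max(m, 1), n))
}

# Normalize one population group into either a list of presence sets
# (in-memory route) or a character vector of table file paths (streaming
# route). Returns list(kind, k, sets | files, n).
normalize_group <- function(x, min_count, label) {
  if (is.character(x)) {
    if (!all(file.exists(x)))
      stop(label, " group: file(s) not found: ",
           paste(x[!file.exists(x)], collapse = ", "))
    ks <- vapply(x, peek_k, 1L)
    k <- ks[is.finite(ks)][1]
    return(list(kind = "files", k = as.integer(k), files = x, n = length(x)))
  }
  if (!is.list(x) || length(x) == 0)
    stop(label, " group must be a non-empty list of presence sets / k-mer ",
         "tables, or a character vector of table file paths")
  sets <- lapply(x, function(el) {
    if (inherits(el, "presence_set")) el
    else if (inherits(el, c("kmer_table", "kmer_table_ref"))) presence_set(el, min_count)
    else if (is.character(el)) structure(list(k = nchar(el[1]), kmers = unique(el),
                                              min_count = min_count),
                                         class = "presence_set")
    else stop(label, " group: unsupported element of class ", class(el)[1])
  })
  ks <- unique(vapply(sets, function(s) as.integer(s$k), 1L))
  if (length(ks) > 1) stop(label, " group mixes k-mer lengths: ", paste(ks, collapse = ", "))
  list(kind = "memory", k = ks, sets = sets, n = length(sets))
}

#' Select male-specific k-mers (MSK)
#'
#' A canonical k-mer is selected iff it is present (count >= `min_count`) in
#' at least `m` of the male individuals and in **none** of the female
#' individuals, where `m` comes from [male_presence_threshold()]. Female
#' exclusion is absolute. Optionally the pooled male count must additionally
#' lie inside `depth_band` (the "half sequencing depth" filter; off by
#' default, since the operational selection rule is presence/absence only).
#'
#' Two input routes give identical results: in-memory lists of presence
#' sets/k-mer tables, or character vectors of sorted table files, which are
#' merged by a streaming k-way join so population-scale tables never need to
#' be in memory at once.
#'
#' In a ZW system, swap the group arguments (pass females as `males`) to
#' obtain W-specific k-mers.
#'
#' @param males,females population groups: lists of `presence_set` /
#'   `kmer_table` objects (or plain character k-mer sets), or character
#'   vectors of table file paths.
#' @param rule rounding rule passed to [male_presence_threshold()].
#' @param min_count per-individual presence threshold (default 2).
#' @param depth_band optional numeric `c(low, high)` window on the pooled
#'   male count (file route only, where counts are available).
#' @return a `marker_set`: fields `k`, `kmers` (sorted), `n_males`,
#'   `n_females`, `m_threshold`, `rule`, `min_count`, `depth_band`.
#' @export
select_male_specific <- function(males, females, rule = c("round", "ceil", "floor"),
                                 min_count = 2, depth_band = NULL) {
  rule <- match.arg(rule)
  g_m <- normalize_group(males, min_count, "male")
  g_f <- normalize_group(females, min_count, "female")
  if (g_m$n < 1) stop("male group is empty")
  if (g_f$n < 1) stop("female group is empty")
  if (!is.na(g_m$k) && !is.na(g_f$k) && g_m$k != g_f$k)
    stop("male and female groups disagree on k (", g_m$k, " vs ", g_f$k, ")")
  if (g_m$kind != g_f$kind)
    stop("both groups must use the same input route (in-memory or files)")
  m <- male_presence_threshold(g_m$n, rule)
  if (!is.null(depth_band)) {
    stopifnot(length(depth_band) == 2, depth_band[1] <= depth_band[2])
    if (g_m$kind == "memory")
      stop("depth_band requires pooled counts; use the table-file route")
  }
  if (g_m$kind == "files") {
    band <- depth_band %||% c(0, Inf)
    kmers <- msk_select_files_cpp(g_m$files, g_f$files,
                                  as.integer(min_count), as.integer(m),
                                  band[1], band[2])
  } else {
    male_kmers <- unlist(lapply(g_m$sets, function(s) unique(s$kmers)), use.names = FALSE)
    tab <- table(male_kmers)
    candidates <- names(tab)[tab >= m]
    female_union <- unique(unlist(lapply(g_f$sets, `[[`, "kmers"), use.names = FALSE))
    kmers <- sort(setdiff(candidates, female_union))
  }
  structure(list(k = g_m$k, kmers = kmers, n_males = g_m$n, n_females = g_f$n,
                 m_threshold = m, rule = rule, min_count = as.integer(min_count),
                 depth_band = depth_band),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d k-mers (k=%d) from %d males (m>=%d) vs %d females\n",
              length(x$kmers), x$k, x$n_males, x$m_threshold, x$n_females))
  invisible(x)
}

#' Pooled-depth band filter
#'
#' Keeps k-mers whose pooled male count lies within
#' `[width[1] * E, width[2] * E]` where `E` is the expected pooled haploid
#' depth (`n * d / 2` for whole-genome male data): sequence carried on a
#' single chromosome copy sits at half the diploid depth, so a band around
#' the haploid expectation strips diploid (autosomal) k-mers.
#'
#' @param pooled_male_counts a `kmer_table` of counts pooled over males.
#' @param expected_haploid_depth expected pooled haploid-copy depth (> 0).
#' @param width multipliers for the band (default `c(0.5, 1.5)`).
#' @return character vector of k-mers inside the band.
#' @export
depth_band_filter <- function(pooled_male_counts, expected_haploid_depth,
                              width = c(0.5, 1.5)) {
  stopifnot(inherits(pooled_male_counts, "kmer_table"))
  if (!is.finite(expected_haploid_depth) || expected_haploid_depth <= 0)
    stop("expected_haploid_depth must be > 0")
  stopifnot(length(width) == 2, width[1] <= width[2])
  lo <- width[1] * expected_haploid_depth
  hi <- width[2] * expected_haploid_depth
  pooled_male_counts$kmer[pooled_male_counts$count >= lo &
                          pooled_male_counts$count <= hi]
}

#' Write / read a marker set
#'
#' The marker file holds one canonical k-mer per line; a JSON sidecar
#' (`<path>.json`) records the selection provenance (k, group sizes, m,
#' depth band).
#'
#' @param markers a `marker_set`.
#' @param path output path for the marker list.
#' @return `path`, invisibly.
#' @export
write_marker_set <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(unlink(tmp), add = TRUE)
  writeLines(markers$kmers, tmp)
  file.rename(tmp, path)
  meta <- markers[c("k", "n_males", "n_females", "m_threshold", "rule", "min_count")]
  meta$depth_band <- markers$depth_band
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_marker_set
#' @export
read_marker_set <- function(path) {
  kmers <- readLines(path)
  kmers <- kmers[nzchar(kmers)]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  structure(list(k = meta$k %||% (if (length(kmers)) nchar(kmers[1]) else NA_integer_),
                 kmers = kmers,
                 n_males = meta$n_males %||% NA_integer_,
                 n_females = meta$n_females %||% NA_integer_,
                 m_threshold = meta$m_threshold %||% NA_integer_,
                 rule = meta$rule %||% "round",
                 min_count = meta$min_count %||% 2L,
                 depth_band = meta$depth_band),
            class = "marker_set")
}

# Coerce marker input (marker_set or character vector) to a character set.
marker_kmers <- function(markers) {
  if (inherits(markers, "marker_set")) markers$kmers
  else if (is.character(markers)) markers
  else stop("markers must be a marker_set or a character vector of k-mers")
}

marker_k <- function(markers) {
  km <- marker_kmers(markers)
  if (!length(km)) stop("marker set is empty")
  nchar(km[1])
}
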