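#' Score sequences by marker density
#'
#' Counts, for every sequence, the k-window positions whose canonical k-mer
#' belongs to the marker set (occurrences by default; `distinct = TRUE`
#' counts distinct markers), and reports the density in markers per
#' kilobase, `hits * 1000 / length`. The denominator is the full sequence
#' length, matching the "per kilobase" convention; for long reads the
#' difference from `length - k + 1` is negligible. Sequences shorter than k
#' score zero.
#'
#' @param seqs sequences: named character vector, `DNAStringSet`, or a
#'   FASTA/FASTQ path.
#' @param markers a `marker_set` or character vector of canonical k-mers.
#' @param distinct count distinct markers instead of marker positions.
#' @return data.frame with columns `read_id`, `length`, `msk_hits`,
#'   `density_per_kb`.
#' @export
scan_sequence <- function(seqs, markers, distinct = FALSE) {
  km <- marker_kmers(markers)
  if (!length(km)) stop("marker set is empty")
  k <- nchar(km[1])
  x <- as_sequences(seqs)
  ids <- names(x) %||% sprintf("seq%d", seq_along(x))
  if (is.null(names(x)) && length(x)) ids <- sprintf("seq%d", seq_along(x))
  hits <- if (length(x)) scan_hits_cpp(unname(x), as.integer(k), km, distinct) else integer(0)
  len <- nchar(x, type = "bytes")
  data.frame(read_id = as.character(ids), length = as.integer(len),
             msk_hits = as.integer(hits),
             density_per_kb = ifelse(len > 0, hits * 1000 / len, 0),
             stringsAsFactors = FALSE)
}

#' Sort long reads by marker density
#'
#' Partitions reads into a selected (candidate sex-limited chromosome) set
#' and a rejected set. A read is selected iff its marker density is at least
#' `threshold_per_kb` **and** it carries at least `min_hits` marker
#' positions. Equality with the threshold selects (only *lower* density is
#' excluded). The partition is exhaustive and disjoint, and selected reads
#' are written verbatim (sequence and qualities untouched).
#'
#' The default threshold of 7 markers/kb is the average marker density
#' observed across a human Y chromosome; use
#' [estimate_density_threshold()] to recompute it from a reference.
#'
#' @param reads named character vector, `DNAStringSet`, or FASTA/FASTQ path
#'   (plain or gzip).
#' @param markers a `marker_set` or character vector.
#' @param threshold_per_kb minimum density in markers/kb (>= 0).
#' @param min_hits minimum marker positions (guards against marker-free
#'   reads when the threshold is 0).
#' @param distinct count distinct markers instead of positions.
#' @param output_dir if given (file input), write `selected.*` and
#'   `rejected.*` mirroring the input format plus `scores.tsv`.
#' @return list with `scores` (the [scan_sequence()] table plus a `selected`
#'   logical column), `selected` and `rejected` (named character vectors of
#'   sequences), and `summary` counts.
#' @export
sort_reads <- function(reads, markers, threshold_per_kb = 7.0, min_hits = 1,
                       distinct = FALSE, output_dir = NULL) {
  if (threshold_per_kb < 0) stop("threshold_per_kb must be >= 0")
  from_file <- is.character(reads) && length(reads) == 1 && file.exists(reads)
  input_path <- if (from_file) reads else NULL
  x <- as_sequences(reads)
  if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
  scores <- scan_sequence(x, markers, distinct = distinct)
  scores$selected <- scores$density_per_kb >= threshold_per_kb &
    scores$msk_hits >= min_hits
  sel <- x[scores$selected]
  rej <- x[!scores$selected]
  q <- attr(x, "qualities")
  if (!is.null(q)) {
    attr(sel, "qualities") <- q[scores$selected]
    attr(rej, "qualities") <- q[!scores$selected]
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (!is.null(input_path) && is_fastq_path(input_path)) "fq" else "fa"
    write_sequences(sel, file.path(output_dir, paste0("selected.", ext)))
    write_sequences(rej, file.path(output_dir, paste0("rejected.", ext)))
    tmp <- file.path(output_dir, ".scores.tsv.tmp")
    write.table(scores, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    file.rename(tmp, file.path(output_dir, "scores.tsv"))
  }
  list(scores = scores, selected = sel, rejected = rej,
       summary = c(n_input = nrow(scores), n_selected = sum(scores$selected),
                   n_rejected = sum(!scores$selected)))
}

#' Sort assembled contigs by marker density
#'
#' Identical contract to [sort_reads()] applied to contig records: markers
#' can pick sex-limited chromosome contigs out of a whole-genome assembly.
#'
#' @inheritParams sort_reads
#' @param contigs FASTA path, named character vector or `DNAStringSet`.
#' @return see [sort_reads()].
#' @export
sort_contigs <- function(contigs, markers, threshold_per_kb = 7.0, min_hits = 1,
                         distinct = FALSE, output_dir = NULL) {
  sort_reads(contigs, markers, threshold_per_kb = threshold_per_kb,
             min_hits = min_hits, distinct = distinct, output_dir = output_dir)
}

#' Density threshold from a reference
#'
#' With a reference sequence for the sex-limited chromosome, the sorting
#' threshold is the average marker density across it: total marker-hit
#' positions x 1000 / reference length. Without a reference the default of
#' 7 markers/kb (the human Y average) is returned -- the average density
#' cannot be computed before an assembly of the target chromosome exists,
#' so the constant is this package's resolution of that chicken-and-egg,
#' exposed for overriding.
#'
#' @param markers a `marker_set` or character vector.
#' @param y_reference optional reference: FASTA path or character sequence(s)
#'   of total length >= 10 kb (shorter references give unstable estimates
#'   and are rejected).
#' @param default value returned when no reference is supplied.
#' @return density threshold in markers per kb.
#' @export
estimate_density_threshold <- function(markers, y_reference = NULL, default = 7.0) {
  if (is.null(y_reference)) return(default)
  seqs <- as_sequences(y_reference)
  total_len <- sum(nchar(seqs))
  if (total_len < 1e4) stop("reference too short (", total_len, " bp < 10 kb): estimate unstable")
  hits <- sum(scan_sequence(seqs, markers)$msk_hits)
  if (hits == 0) warning("no marker hits on the reference: threshold estimate is 0")
  hits * 1000 / total_len
}
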