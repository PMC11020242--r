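#' Validate a k-mer length
#'
#' Odd k between 3 and 63 is accepted; odd k avoids self-reverse-complement
#' k-mers so the canonical form is never ambiguous. Analyses in this package
#' default to k = 21 (k = 51 is the usual alternative for repeat-rich
#' targets); tiny k is allowed for worked examples.
#'
#' @param k k-mer length in bases.
#' @return `k` as an integer, invisibly on success.
#' @export
validate_k <- function(k) {
  if (length(k) != 1 || !is.finite(k) || k != as.integer(k))
    stop("k must be a single integer")
  k <- as.integer(k)
  if (k < 3 || k > 63) stop("k must be between 3 and 63 (got ", k, ")")
  if (k %% 2 == 0) stop("k must be odd so canonical k-mers are unambiguous")
  invisible(k)
}

#' Canonical form of a k-mer
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement, uppercased. This matches the convention of standard
#' k-mer counters, so dumps from external tools interoperate.
#'
#' @param seq character vector of DNA strings (case-insensitive).
#' @param on_invalid what to do with strings containing non-ACGT symbols:
#'   `"error"` (default), `"na"`, or `"drop"`.
#' @return character vector of canonical k-mers.
#' @examples
#' canonical_kmer(c("ACG", "TTT", "CGT"))  # "ACG" "AAA" "ACG"
#' @export
canonical_kmer <- function(seq, on_invalid = c("error", "na", "drop")) {
  on_invalid <- match.arg(on_invalid)
  out <- canonical_kmer_cpp(as.character(seq))
  bad <- is.na(out) & !is.na(seq)
  if (any(bad)) {
    if (on_invalid == "error")
      stop("non-ACGT symbol in k-mer(s): ", paste(head(seq[bad], 3), collapse = ", "))
    if (on_invalid == "drop") out <- out[!bad]
  }
  out
}

#' Count canonical k-mers in a set of reads
#'
#' Every window of length `k` consisting only of A/C/G/T contributes one
#' count to its canonical k-mer; windows containing any other symbol are
#' skipped entirely. Counting is exact (a hash table, no sketches).
#'
#' @param reads character vector of sequences, path(s) to FASTA/FASTQ files
#'   (plain or gzipped), or a `DNAStringSet`.
#' @param k k-mer length (odd, 3-63).
#' @param min_count keep only k-mers with count >= `min_count` (default 1:
#'   the full table; the presence rule of the marker pipeline is applied
#'   later, see [presence_set()]).
#' @param output optional file path: stream the sorted table straight to a
#'   KMC-dump-compatible TSV (gzipped when the path ends in `.gz`) instead of
#'   materialising it in R. Returns a lightweight table reference.
#' @param source_label identifier of the individual the reads came from.
#' @return a `kmer_table` (fields `k`, `kmer`, `count`, `total_windows`,
#'   `source_label`) or, when `output` is given, a `kmer_table_ref` with the
#'   file path and summary counts.
#' @examples
#' tab <- count_kmers("ACGTA", k = 3)
#' setNames(tab$count, tab$kmer)  # ACG: 2, GTA: 1
#' @export
count_kmers <- function(reads, k = 21, min_count = 1, output = NULL,
                        source_label = NULL) {
  k <- as.integer(validate_k(k))
  stopifnot(min_count >= 1)
  seqs <- as_sequences(reads)
  if (length(seqs) == 0) warning("empty read stream: returning an empty k-mer table")
  if (!is.null(output)) {
    res <- count_kmers_file_cpp(as.character(seqs), k, as.integer(min_count), output)
    return(structure(list(k = k, path = output, n_kmers = res$n_kmers,
                          total_windows = res$total_windows,
                          source_label = source_label),
                     class = "kmer_table_ref"))
  }
  res <- count_kmers_cpp(as.character(seqs), k, as.integer(min_count))
  structure(list(k = k, kmer = res$kmer, count = res$count,
                 total_windows = res$total_windows, source_label = source_label),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k=%d, %d distinct k-mers, %s windows counted%s\n",
              x$k, length(x$kmer), format(x$total_windows, big.mark = ","),
              if (is.null(x$source_label)) "" else paste0(" [", x$source_label, "]")))
  invisible(x)
}

#' @export
print.kmer_table_ref <- function(x, ...) {
  cat(sprintf("kmer_table_ref: k=%d, %s k-mers at %s\n", x$k,
              format(x$n_kmers, big.mark = ","), x$path))
  invisible(x)
}

#' Presence set of an individual
#'
#' A k-mer is considered *present* in an individual only if it was observed
#' at least `min_count` times in that individual's reads (default 2, i.e.
#' "more than once"), which filters k-mers created by isolated sequencing
#' errors.
#'
#' @param table a `kmer_table`, `kmer_table_ref`, or a table file path.
#' @param min_count presence threshold (>= 1).
#' @return a `presence_set`: fields `k`, `kmers` (canonical, sorted),
#'   `min_count`.
#' @export
presence_set <- function(table, min_count = 2) {
  stopifnot(min_count >= 1)
  if (is.character(table)) table <- read_kmer_table(table)
  if (inherits(table, "kmer_table_ref")) table <- read_kmer_table(table$path)
  stopifnot(inherits(table, "kmer_table"))
  keep <- table$count >= min_count
  structure(list(k = table$k, kmers = table$kmer[keep],
                 min_count = as.integer(min_count)),
            class = "presence_set")
}

#' Write a k-mer count table
#'
#' Two TAB-separated columns (uppercase canonical k-mer, count), sorted
#' lexicographically -- the dump dialect of standard k-mer counters. A `.gz`
#' extension triggers gzip compression.
#'
#' @param table a `kmer_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_table"))
  ord <- order(table$kmer, method = "radix")
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(unlink(tmp), add = TRUE)
  write_table_lines_cpp(table$kmer[ord], as.integer(table$count[ord]), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a k-mer count table
#'
#' Reads the TSV dialect written by [write_kmer_table()] (gzip detected
#' automatically). Malformed lines -- wrong column count, non-ACGT symbols,
#' non-integer counts, unsorted input -- raise an error naming the line.
#'
#' @param path table file path.
#' @param source_label optional individual label to attach.
#' @return a `kmer_table`.
#' @export
read_kmer_table <- function(path, source_label = NULL) {
  stopifnot(file.exists(path))
  res <- read_table_cpp(path)
  k <- if (is.na(res$k)) NA_integer_ else as.integer(res$k)
  structure(list(k = k, kmer = res$kmer, count = res$count,
                 total_windows = sum(as.double(res$count)),
                 source_label = source_label),
            class = "kmer_table")
}

# k of a table file from its first record
peek_k <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  line <- readLines(con, n = 1L)
  if (length(line) == 0) return(NA_integer_)
  nchar(strsplit(line, "\t", fixed = TRUE)[[1]][1])
}
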