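# Internal helpers: seeded evaluation, seed derivation, sequence I/O.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream. seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-unit seeds below 2^31, distinct across counters.
derive_seed <- function(master, counter) {
  s <- (as.double(master) + 1000003 * as.double(counter)) %% 2147483647
  as.integer(s) + 1L
}

is_fastq_path <- function(path) {
  grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
}

# Read FASTA/FASTQ (plain or gzip) into a named character vector of sequences;
# FASTQ qualities, when present, are kept in attr(, "qualities").
read_sequences <- function(path) {
  stopifnot(length(path) == 1, file.exists(path))
  if (is_fastq_path(path)) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    seqs <- as.character(x)
    q <- S4Vectors::mcols(x)$qualities
    if (!is.null(q)) attr(seqs, "qualities") <- as.character(q)
    seqs
  } else {
    as.character(Biostrings::readDNAStringSet(path, format = "fasta"))
  }
}

# Write sequences (named character) as FASTA or FASTQ mirroring `path`'s
# extension. Writes atomically (temp file + rename).
write_sequences <- function(seqs, path, qualities = NULL) {
  dna <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(dna) <- if (is.null(names(seqs))) sprintf("seq%d", seq_along(seqs)) else names(seqs)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(unlink(tmp), add = TRUE)
  compress <- grepl("\\.gz$", path)
  if (is_fastq_path(path)) {
    if (is.null(qualities)) qualities <- attr(seqs, "qualities")
    if (is.null(qualities))
      qualities <- vapply(nchar(as.character(seqs)), function(n) strrep("I", n), "")
    Biostrings::writeXStringSet(dna, tmp, format = "fastq",
                                qualities = Biostrings::BStringSet(qualities),
                                compress = compress)
  } else {
    Biostrings::writeXStringSet(dna, tmp, format = "fasta", compress = compress)
  }
  file.rename(tmp, path)
  invisible(path)
}

# Interpret `reads` as sequences: character sequences pass through, file
# paths are loaded, Biostrings containers are converted.
as_sequences <- function(reads) {
  if (methods::is(reads, "DNAStringSet")) return(as.character(reads))
  if (!is.character(reads)) stop("reads must be a character vector, file path(s) or a DNAStringSet")
  looks_like_path <- length(reads) > 0 && all(nchar(reads) < 500) &&
    all(grepl("\\.(fa|fasta|fna|fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
  if (looks_like_path) {
    missing <- reads[!file.exists(reads)]
    if (length(missing)) stop("input file(s) not found: ", paste(missing, collapse = ", "))
    out <- lapply(reads, read_sequences)
    return(do.call(c, out))
  }
  reads
}

`%||%` <- function(a, b) if (is.null(a)) b else a
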