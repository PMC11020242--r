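#' Synthetic genome configuration
#'
#' Describes a three-chromosome genome: an autosome, an X-analog, and a
#' Y-analog built from the X. The Y carries a PAR-like segment shared
#' verbatim with the X (where no specific k-mers can exist), an X-derived
#' segment mutated at `xy_divergence` per site, and a fraction of novel
#' (unrelated) sequence emulating ampliconic/heterochromatic Y content.
#' Defaults are the desk-scale stand-in for a mammalian genome: 5 Mb
#' autosome, 2 Mb X, 0.5 Mb Y with a 20 kb PAR and 1% X-Y divergence.
#'
#' @param autosome_len,x_len,y_len chromosome lengths in bases.
#' @param par_len bases shared verbatim between X and Y (<= min(x, y)).
#' @param xy_divergence per-site substitution rate between X and Y outside
#'   the PAR, in `[0, 1]`.
#' @param y_novel_frac fraction of the non-PAR Y that is novel random
#'   sequence rather than X-derived.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `genome_config` list.
#' @export
genome_config <- function(autosome_len = 5e6, x_len = 2e6, y_len = 5e5,
                          par_len = 2e4, xy_divergence = 0.01,
                          y_novel_frac = 0.2, seed = 1) {
  stopifnot(autosome_len >= 0, x_len >= 0, y_len >= 0, par_len >= 0,
            xy_divergence >= 0, xy_divergence <= 1,
            y_novel_frac >= 0, y_novel_frac <= 1)
  if (par_len > min(x_len, y_len)) stop("par_len exceeds min(x_len, y_len)")
  derived_len <- round((y_len - par_len) * (1 - y_novel_frac))
  if (par_len + derived_len > x_len)
    stop("x_len too short for the requested PAR + X-derived Y segment")
  structure(list(autosome_len = as.integer(autosome_len), x_len = as.integer(x_len),
                 y_len = as.integer(y_len), par_len = as.integer(par_len),
                 xy_divergence = xy_divergence, y_novel_frac = y_novel_frac,
                 seed = as.integer(seed)),
            class = "genome_config")
}

#' Generate a ground-truth genome
#'
#' Autosome and X are i.i.d. uniform ACGT sequence (no repeat structure; at
#' desk scale random k-mer collisions are negligible for k = 21). The Y is
#' PAR (copied verbatim from the start of the X), then an X-derived segment
#' substituted at `xy_divergence` per site, then novel random sequence.
#'
#' @param config a [genome_config()].
#' @return a `synthetic_truth`: `config`, `sequences` (named list `A`, `X`,
#'   `Y`), `par_len`, and `y_regions` (1-based coordinates of the `par`,
#'   `derived` and `novel` Y segments).
#' @export
generate_genome <- function(config = genome_config()) {
  stopifnot(inherits(config, "genome_config"))
  with_seed(config$seed, {
    a <- random_dna_cpp(config$autosome_len)
    x <- random_dna_cpp(config$x_len)
    par <- substr(x, 1L, config$par_len)
    derived_len <- round((config$y_len - config$par_len) * (1 - config$y_novel_frac))
    derived_src <- substr(x, config$par_len + 1L, config$par_len + derived_len)
    derived <- if (derived_len > 0) mutate_seq_cpp(derived_src, config$xy_divergence)$seq else ""
    novel_len <- config$y_len - config$par_len - derived_len
    novel <- if (novel_len > 0) random_dna_cpp(novel_len) else ""
    y <- paste0(par, derived, novel)
    structure(list(config = config,
                   sequences = list(A = a, X = x, Y = y),
                   par_len = config$par_len,
                   y_regions = list(par = c(1L, config$par_len),
                                    derived = c(config$par_len + 1L,
                                                config$par_len + derived_len),
                                    novel = c(config$par_len + derived_len + 1L,
                                              config$y_len))),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: A=%s bp, X=%s bp, Y=%s bp (PAR %s bp, divergence %.3g, seed %d)\n",
              format(nchar(x$sequences$A), big.mark = ","),
              format(nchar(x$sequences$X), big.mark = ","),
              format(nchar(x$sequences$Y), big.mark = ","),
              format(x$par_len, big.mark = ","),
              x$config$xy_divergence, x$config$seed))
  invisible(x)
}

#' Ground-truth Y-specific k-mers
#'
#' The canonical k-mers of the Y minus the canonical k-mers of autosome and
#' X -- computed exactly; this is the reference standard every marker-set
#' evaluation compares against.
#'
#' @param truth a `synthetic_truth`.
#' @param k k-mer length.
#' @return character vector of canonical k-mers.
#' @export
true_specific_kmers <- function(truth, k = 21) {
  stopifnot(inherits(truth, "synthetic_truth"))
  validate_k(k)
  kmer_set_diff_cpp(truth$sequences$Y,
                    c(truth$sequences$A, truth$sequences$X), as.integer(k))
}

#' Population polymorphism panel
#'
#' Shared autosomal SNPs for a simulated population: site density is chosen
#' so the realised per-individual heterozygosity rate is `h` -- a site with
#' minor-allele frequency p is heterozygous in a random individual with
#' probability `2 p (1 - p)`, so density = `h / E[2 p (1 - p)]` under
#' `het_dist`. Each site gets a minor-allele frequency drawn from
#' `het_dist` and a random alternative base. Heterozygosity is modelled on
#' the autosome only (X/Y are left monomorphic, as in the error models).
#'
#' @param truth a `synthetic_truth`.
#' @param h target per-individual per-site heterozygosity rate.
#' @param het_dist a [het_allele_distribution()] for minor-allele
#'   frequencies.
#' @param seed integer seed.
#' @return data.frame with columns `pos`, `freq_alt`, `ref`, `alt`
#'   (positions on the autosome, 1-based).
#' @export
polymorphism_panel <- function(truth, h, het_dist = het_allele_distribution(),
                               seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), h >= 0, h <= 0.01)
  len <- nchar(truth$sequences$A)
  if (h == 0 || len == 0)
    return(data.frame(pos = integer(0), freq_alt = numeric(0),
                      ref = character(0), alt = character(0)))
  e_het <- sum(2 * het_dist$values * (1 - het_dist$values) * het_dist$probs)
  density <- min(1, h / e_het)
  with_seed(seed, {
    n_sites <- rbinom(1, len, density)
    pos <- sort(sample.int(len, n_sites))
    freq <- sample(het_dist$values, n_sites, replace = TRUE, prob = het_dist$probs)
    ref <- substring(truth$sequences$A, pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    data.frame(pos = pos, freq_alt = freq, ref = unname(ref), alt = unname(alt),
               stringsAsFactors = FALSE)
  })
}

#' Derive one diploid individual from the reference genome
#'
#' Males carry two autosome haplotypes, one X and one Y; females carry two
#' autosome haplotypes and two X copies. Heterozygosity is applied to the
#' autosome haplotypes only, under one of two models:
#' * with a [polymorphism_panel()], each haplotype carries the panel's
#'   alternative allele with the site's population frequency (shared
#'   polymorphism -- the model behind the heterozygosity false-positive
#'   rate, and the default for population sweeps);
#' * without a panel and `h > 0`, each site is made heterozygous with
#'   probability `h` by mutating one random haplotype (private mutations).
#'
#' @param truth a `synthetic_truth`.
#' @param sex `"male"` or `"female"`.
#' @param h per-site heterozygosity rate (used by the private-mutation
#'   model, and as a sanity cap).
#' @param panel optional [polymorphism_panel()] shared by the population.
#' @param seed integer seed (give every individual a distinct one).
#' @return an `individual`: `sex`, `haplotypes` (named list of sequences),
#'   `copies` (integer copy number per haplotype, all 1 here since
#'   haplotypes are explicit).
#' @export
derive_individual <- function(truth, sex = c("male", "female"), h = 0,
                              panel = NULL, seed = 1) {
  sex <- match.arg(sex)
  stopifnot(inherits(truth, "synthetic_truth"), h >= 0, h <= 0.01)
  a <- truth$sequences$A
  with_seed(seed, {
    haps <- list()
    if (!is.null(panel) && nrow(panel) > 0) {
      for (hap in 1:2) {
        carried <- runif(nrow(panel)) < panel$freq_alt
        haps[[paste0("A", hap)]] <-
          if (any(carried)) apply_snps_cpp(a, panel$pos[carried], panel$alt[carried]) else a
      }
    } else if (h > 0 && nchar(a) > 0) {
      n_het <- rbinom(1, nchar(a), h)
      pos <- sort(sample.int(nchar(a), n_het))
      which_hap <- sample(1:2, n_het, replace = TRUE)
      ref <- substring(a, pos, pos)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      for (hap in 1:2) {
        sel <- which_hap == hap
        haps[[paste0("A", hap)]] <-
          if (any(sel)) apply_snps_cpp(a, pos[sel], unname(alt[sel])) else a
      }
    } else {
      haps$A1 <- a
      haps$A2 <- a
    }
    if (sex == "male") {
      haps$X1 <- truth$sequences$X
      haps$Y <- truth$sequences$Y
    } else {
      haps$X1 <- truth$sequences$X
      haps$X2 <- truth$sequences$X
    }
    structure(list(sex = sex, haplotypes = haps,
                   copies = setNames(rep(1L, length(haps)), names(haps))),
              class = "individual")
  })
}

#' Simulate short reads from an individual
#'
#' Substitution-only Illumina-like reads (defaults r = 0.009, l = 150 bp,
#' d = 5x; indels at the per-mille level are negligible for
#' presence/absence k-mer analysis and are omitted). `depth` is per haploid
#' copy, so a diploid autosome receives 2 x `depth` in total and the single
#' X/Y copy of a male half the autosomal depth -- the dosage signal the
#' marker models assume. Read placement is uniform per haplotype
#' (`round(depth * len / l)` reads each); `systematic = TRUE` instead tiles
#' reads deterministically and emits each twice, guaranteeing every k-window
#' (k <= `k_guard`) is covered at least twice -- the noise-free regime where
#' marker recovery is exact.
#'
#' @param individual an [derive_individual()] result.
#' @param depth per-haploid-copy depth (x).
#' @param read_len read length (bp).
#' @param error_rate per-base substitution rate.
#' @param systematic deterministic tiling instead of random placement.
#' @param k_guard k-mer length whose windows the tiling must double-cover.
#' @param seed integer seed.
#' @return character vector of read sequences.
#' @export
simulate_short_reads <- function(individual, depth = 5, read_len = 150,
                                 error_rate = 0.009, systematic = FALSE,
                                 k_guard = 21, seed = 1) {
  stopifnot(inherits(individual, "individual"), depth >= 0,
            read_len > 0, error_rate >= 0, error_rate <= 1)
  haps <- unlist(individual$haplotypes, use.names = FALSE)
  with_seed(seed,
    sim_short_reads_cpp(haps, individual$copies, depth, as.integer(read_len),
                        error_rate, systematic, as.integer(k_guard)))
}

#' Long-read technology presets
#'
#' Error-rate and length-distribution stand-ins for the common long-read
#' technologies: `hifi` (0.4% substitution / 0.3% insertion / 0.3% deletion,
#' 12 kb +/- 1 kb), `clr` (5% / 3% / 2%, 7.5 kb +/- 3 kb), `ont`
#' (4% / 2% / 3%, 15 kb +/- 8 kb). All fields can be overridden in
#' [simulate_long_reads()].
#'
#' @param name `"hifi"`, `"clr"` or `"ont"`.
#' @return list with `sub`, `ins`, `del`, `mean_len`, `sd_len`, `min_len`.
#' @export
long_read_preset <- function(name = c("hifi", "clr", "ont")) {
  name <- match.arg(name)
  switch(name,
    hifi = list(sub = 0.004, ins = 0.003, del = 0.003,
                mean_len = 12000, sd_len = 1000, min_len = 1000),
    clr  = list(sub = 0.05, ins = 0.03, del = 0.02,
                mean_len = 7500, sd_len = 3000, min_len = 500),
    ont  = list(sub = 0.04, ins = 0.02, del = 0.03,
                mean_len = 15000, sd_len = 8000, min_len = 500))
}

#' Simulate labelled long reads from the reference genome
#'
#' Reads are drawn per chromosome until the requested depth is met, with
#' truncated-Gaussian lengths and substitution/insertion/deletion errors at
#' the preset rates. Every read id encodes its true chromosome of origin
#' and template coordinates; Y reads additionally carry the fraction of
#' their template inside the non-PAR Y, and the origin label applies the
#' >= 50% rule (a read mostly inside the PAR is not labelled `Y`, since no
#' specific marker can cover it by construction).
#'
#' @param truth a `synthetic_truth`.
#' @param preset a [long_read_preset()] name or list; individual fields can
#'   be overridden via `...`.
#' @param depth per-chromosome depth: single number or named vector over
#'   `c("A", "X", "Y")` (e.g. `c(A = 50, X = 50, Y = 25)`).
#' @param seed integer seed.
#' @param ... preset field overrides (`sub`, `ins`, `del`, `mean_len`,
#'   `sd_len`, `min_len`).
#' @return list with `reads` (named character vector) and `info`
#'   (data.frame: `read_id`, `chrom`, `start`, `end`, `length`,
#'   `y_nonpar_frac`, `origin_label`).
#' @export
simulate_long_reads <- function(truth, preset = "hifi", depth = 25, seed = 1, ...) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- if (is.character(preset)) long_read_preset(preset) else preset
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(cfg$sub >= 0, cfg$ins >= 0, cfg$del >= 0, cfg$min_len >= 1)
  chroms <- c("A", "X", "Y")
  dep <- if (length(depth) == 1) setNames(rep(depth, 3), chroms) else depth[chroms]
  if (any(is.na(dep))) stop("depth must be a single number or named over A, X, Y")
  seqs <- unlist(truth$sequences[chroms], use.names = FALSE)
  res <- with_seed(seed,
    sim_long_reads_cpp(seqs, as.numeric(dep), cfg$mean_len, cfg$sd_len,
                       as.integer(cfg$min_len), cfg$sub, cfg$ins, cfg$del))
  chrom <- chroms[res$origin]
  len <- nchar(res$seq)
  par <- truth$par_len
  nonpar_frac <- ifelse(chrom == "Y",
                        pmax(0, res$end - pmax(res$start, par + 1) + 1) /
                          (res$end - res$start + 1),
                        0)
  label <- ifelse(chrom == "Y", ifelse(nonpar_frac >= 0.5, "Y", "Y-par"), chrom)
  ids <- sprintf("lr%06d|%s:%d-%d", seq_along(chrom), chrom,
                 as.integer(res$start), as.integer(res$end))
  info <- data.frame(read_id = ids, chrom = chrom,
                     start = as.integer(res$start), end = as.integer(res$end),
                     length = as.integer(len), y_nonpar_frac = nonpar_frac,
                     origin_label = label, stringsAsFactors = FALSE)
  list(reads = setNames(res$seq, ids), info = info)
}

#' Write long-read origin labels
#'
#' TSV `read_id <TAB> origin` ground-truth file matching the simulated
#' reads.
#'
#' @param sim result of [simulate_long_reads()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_read_origins <- function(sim, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(unlink(tmp), add = TRUE)
  write.table(sim$info[, c("read_id", "origin_label")], tmp, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = c("read_id", "origin"))
  file.rename(tmp, path)
  invisible(path)
}
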