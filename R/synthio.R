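#' 454-style error model
#'
#' Parameters of the simulated sequencing error process. Substitutions are
#' applied independently per base. Homopolymer indels — the signature 454
#' error class — are applied per maximal run of identical bases: a run of
#' length `k` suffers an indel event with probability
#' `min(0.5, hp_indel_base * hp_slope^(k - 1))`, and an event inserts or
#' deletes one repeat unit with equal probability.
#'
#' The platform's true error rates were never published at this marker, so
#' the defaults (`sub_rate = 0.005`, `hp_indel_base = 0.01`,
#' `hp_slope = 1.5`) are documented placeholders of the right order of
#' magnitude, not measured values.
#'
#' @param sub_rate per-base substitution probability in `[0, 1]`.
#' @param hp_indel_base indel probability for a homopolymer run of length 1.
#' @param hp_slope multiplicative increase in indel probability per extra
#'   repeat unit (`>= 0`).
#' @param max_indel maximum inserted/deleted bases per event (the model
#'   moves one repeat unit per event, so this must be `>= 1`).
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.005, hp_indel_base = 0.01,
                        hp_slope = 1.5, max_indel = 1L) {
  stopifnot(sub_rate >= 0, sub_rate <= 1,
            hp_indel_base >= 0, hp_indel_base <= 1,
            hp_slope >= 0, max_indel >= 1)
  structure(list(sub_rate = sub_rate, hp_indel_base = hp_indel_base,
                 hp_slope = hp_slope, max_indel = as.integer(max_indel)),
            class = "error_model")
}

#' Community specification for read simulation
#'
#' Describes one multiplexed amplicon sample: the member taxa with their
#' template sequences, their pre-PCR molar fractions, a per-taxon
#' amplification odds multiplier (mock-community skew), the number of reads
#' to emit and the read decorations. The default layout is
#' `[MID][primer5][template][primer3]` on the forward strand only,
#' mirroring a unidirectional amplicon protocol; the default MID (10 nt)
#' plus forward primer (8 nt) span exactly the 18 bases removed by the
#' default 5' trim, and the default 3' context spans the 22 bases removed
#' by the 3' trim, so error-free simulated reads round-trip to their
#' templates.
#'
#' @param taxa named character vector of template sequences (names are taxon
#'   labels) or a data frame with columns `name` and `seq` as returned by
#'   [make_taxa()].
#' @param fractions pre-PCR molar fractions, nonnegative, summing to 1
#'   (default equimolar).
#' @param bias per-taxon amplification odds multipliers (`>= 0`, default 1).
#' @param n_reads total number of reads to emit (`>= 0`).
#' @param seed integer RNG seed; fixes the output byte-for-byte.
#' @param mid sample barcode (MID) string.
#' @param primer5,primer3 flanking primer/context strings.
#' @param sample sample label used in read identifiers.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(taxa, fractions = NULL, bias = NULL,
                           n_reads = 1000L, seed = 1L,
                           mid = "ACGAGTGCGT", primer5 = "TCCGTAGG",
                           primer3 = "CGTTCAAAGATTCGATGGTTCA",
                           sample = "S1") {
  if (is.data.frame(taxa)) taxa <- setNames(taxa$seq, taxa$name)
  if (is.null(names(taxa)) || any(!nzchar(names(taxa))))
    stop("taxa must be named")
  k <- length(taxa)
  if (k < 1L) stop("at least one taxon is required")
  if (is.null(fractions)) fractions <- rep(1 / k, k)
  if (is.null(bias)) bias <- rep(1, k)
  if (length(fractions) != k || length(bias) != k)
    stop("taxa, fractions and bias must have equal length")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be nonnegative and sum to 1")
  if (any(bias < 0)) stop("bias multipliers must be nonnegative")
  if (n_reads < 0) stop("n_reads must be >= 0")
  structure(list(taxa = taxa, fractions = as.numeric(fractions),
                 bias = as.numeric(bias), n_reads = as.integer(n_reads),
                 seed = as.integer(seed), mid = toupper(mid),
                 primer5 = toupper(primer5), primer3 = toupper(primer3),
                 sample = sample),
            class = "community_spec")
}

#' Generate synthetic reference taxa
#'
#' Draws `n_taxa` random nucleotide templates of the given length and
#' enforces a minimum pairwise Hamming divergence, redrawing a conflicting
#' sequence up to `max_attempts` times. These templates stand in for
#' curated culture-collection reference sequences so the whole pipeline can
#' run with no download.
#'
#' @param n_taxa number of taxa (`>= 1`).
#' @param length template length in bases (`>= 50`).
#' @param min_divergence minimum pairwise divergence as a fraction of
#'   `length`; every pair must differ at `>= ceiling(min_divergence *
#'   length)` positions.
#' @param seed integer RNG seed.
#' @param max_attempts redraw budget per sequence before giving up.
#' @return A data frame with columns `name` and `seq`.
#' @export
make_taxa <- function(n_taxa, length, min_divergence, seed = 1L,
                      max_attempts = 1000L) {
  stopifnot(n_taxa >= 1, length >= 50,
            min_divergence >= 0, min_divergence <= 1)
  need <- ceiling(min_divergence * length)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(as.integer(seed), {
    seqs <- character(n_taxa)
    mats <- vector("list", n_taxa)
    for (i in seq_len(n_taxa)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- sample(bases, length, replace = TRUE)
        if (i == 1L || all(vapply(mats[seq_len(i - 1L)],
                                  function(m) sum(m != cand), 0L) >= need)) {
          mats[[i]] <- cand
          seqs[i] <- paste(cand, collapse = "")
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(paste0("could not draw taxon %d at minimum divergence ",
                            "%.3f after %d attempts"),
                     i, min_divergence, max_attempts))
    }
    data.frame(name = sprintf("taxon%02d", seq_len(n_taxa)), seq = seqs,
               stringsAsFactors = FALSE)
  })
}

#' Apply per-taxon amplification bias to molar fractions
#'
#' Models preferential PCR amplification: the post-PCR read fraction of
#' taxon *i* is proportional to `fractions[i] * bias[i]`, renormalised to
#' sum to 1. An equimolar mock community with a bias odds ratio of 86:14
#' therefore yields the 86%/14% read skew seen in real mock-community
#' controls.
#'
#' @param fractions pre-PCR molar fractions summing to 1.
#' @param bias amplification odds multipliers (`>= 0`), same length.
#' @return Post-PCR read fractions summing to 1.
#' @export
apply_bias <- function(fractions, bias) {
  if (length(fractions) != length(bias))
    stop("fractions and bias must have equal length")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be nonnegative and sum to 1")
  if (any(bias < 0)) stop("bias multipliers must be nonnegative")
  prod <- fractions * bias
  if (all(prod == 0)) stop("all fraction * bias products are zero")
  prod / sum(prod)
}

# one homopolymer-indel pass over a template; RNG draws: one runif per
# maximal run, plus one runif per event for the insert/delete choice
apply_homopolymer_errors <- function(chars, err) {
  if (err$hp_indel_base == 0 || !length(chars)) return(chars)
  r <- rle(chars)
  runs <- r$lengths
  vals <- r$values
  p <- pmin(0.5, err$hp_indel_base * err$hp_slope^(runs - 1))
  u <- runif(length(runs))
  out <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    len <- runs[i]
    if (u[i] < p[i]) {
      if (runif(1) < 0.5) len <- len + 1L      # insert one repeat unit
      else len <- len - 1L                     # delete one repeat unit
    }
    out[[i]] <- rep(vals[i], max(0L, len))
  }
  unlist(out, use.names = FALSE)
}

apply_substitutions <- function(chars, err) {
  if (err$sub_rate == 0 || !length(chars)) return(chars)
  bases <- c("A", "C", "G", "T")
  hit <- which(runif(length(chars)) < err$sub_rate)
  for (i in hit) {
    alt <- bases[bases != chars[i]]
    chars[i] <- alt[sample.int(3L, 1L)]
  }
  chars
}

#' Simulate a multiplexed 454-style amplicon read set
#'
#' Emits exactly `spec$n_reads` reads. For each read, in this fixed order
#' of RNG consumption: (1) a taxon is drawn from the post-bias fractions,
#' (2) one homopolymer-indel pass runs over the template's maximal runs
#' from left to right, (3) per-base substitutions are applied, and (4) the
#' read is decorated as `[MID][primer5][core][primer3]`. With all error
#' rates zero and unit bias every read core equals its template exactly.
#' The taxon of origin is recorded both in the read identifier and in the
#' `taxon` column.
#'
#' @param spec a [community_spec].
#' @param err an [error_model].
#' @param path optional output path; when given, reads are written as FASTQ
#'   (`format = "fastq"`) or a FASTA+QUAL pair (`format = "fasta"`), and a
#'   ground-truth TSV (`<path>.truth.tsv`, read id to taxon) is always
#'   written beside them.
#' @param format output file format, ignored when `path` is `NULL`.
#' @param quality constant per-base Phred quality used for output (quality
#'   is not consumed downstream; it only keeps the files valid).
#' @return A [phy_reads] object (invisibly when `path` is given).
#' @export
simulate_reads <- function(spec, err = error_model(), path = NULL,
                           format = c("fastq", "fasta"), quality = 30L) {
  stopifnot(inherits(spec, "community_spec"), inherits(err, "error_model"))
  format <- match.arg(format)
  fr <- apply_bias(spec$fractions, spec$bias)
  templates <- strsplit(unname(spec$taxa), "")
  reads <- withr::with_seed(spec$seed, {
    ids <- character(spec$n_reads)
    seqs <- character(spec$n_reads)
    taxon <- character(spec$n_reads)
    for (r in seq_len(spec$n_reads)) {
      t_i <- sample.int(length(templates), 1L, prob = fr)
      core <- apply_homopolymer_errors(templates[[t_i]], err)
      core <- apply_substitutions(core, err)
      taxon[r] <- names(spec$taxa)[t_i]
      ids[r] <- sprintf("%s_read%06d", spec$sample, r)
      seqs[r] <- paste0(spec$mid, spec$primer5,
                        paste(core, collapse = ""), spec$primer3)
    }
    list(ids = ids, seqs = seqs, taxon = taxon)
  })
  qual <- vapply(nchar(reads$seqs),
                 function(n) strrep(rawToChar(as.raw(quality + 33L)), n), "")
  out <- phy_reads(id = reads$ids, seq = reads$seqs, qual = qual,
                   taxon = reads$taxon)
  if (!is.null(path)) {
    if (format == "fastq") write_reads_fastq(out, path)
    else write_reads_fasta_qual(out, path)
    truth <- data.frame(read_id = out$id, taxon = out$taxon)
    write_tsv(truth, paste0(path, ".truth.tsv"))
    return(invisible(out))
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
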