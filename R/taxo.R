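#' Read an annotated reference FASTA
#'
#' Reference description lines carry the annotation as
#' `>name genus=...; species=...; clade=...`. Missing keys become `NA`.
#' Clade labels follow the controlled vocabularies used for these genera
#' (for *Trebouxia* the Helms clades A/G/I/S; for *Asterochloris* clades
#' A/B/C).
#'
#' @param path FASTA file path.
#' @return A data frame with columns `name`, `genus`, `species`, `clade`,
#'   `seq`.
#' @export
read_reference_fasta <- function(path) {
  fa <- read_fasta(path)
  hdr <- names(fa)
  name <- sub("\\s.*$", "", hdr)
  pull <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^;]*"), hdr))
    out <- rep(NA_character_, length(hdr))
    has <- grepl(paste0(key, "="), hdr)
    out[has] <- sub(paste0("^", key, "="), "", m)
    trimws(out)
  }
  if (anyDuplicated(name)) stop("reference names must be unique")
  data.frame(name = name, genus = pull("genus"), species = pull("species"),
             clade = pull("clade"), seq = unname(fa),
             stringsAsFactors = FALSE)
}

#' Write an annotated reference FASTA
#' @param refs data frame with columns `name`, `genus`, `species`, `clade`,
#'   `seq`.
#' @param path output path.
#' @export
write_reference_fasta <- function(refs, path) {
  hdr <- sprintf("%s genus=%s; species=%s; clade=%s", refs$name, refs$genus,
                 refs$species, refs$clade)
  write_fasta(setNames(refs$seq, hdr), path)
}

#' Assign a consensus sequence to its best reference taxon
#'
#' Finds the reference with the highest percent identity to the query
#' (ties broken by coverage, then by reference name), reusing the same
#' score-/length-coverage definitions as clustering. The assignment is
#' accepted when identity and coverage meet the thresholds, otherwise the
#' status is `unassigned`. Species-level naming additionally requires
#' `>= species_identity` percent identity; matches between `min_identity`
#' and that bound carry the genus only.
#'
#' @param consensus non-empty query sequence.
#' @param refs annotated reference data frame (see
#'   [read_reference_fasta()]).
#' @param min_identity minimum percent identity for assignment (default 90).
#' @param min_coverage minimum percent coverage for assignment (default 95).
#' @param species_identity percent identity above which the species epithet
#'   is reported (default 97).
#' @return A one-row data frame: `best_ref`, `genus`, `species`, `clade`,
#'   `identity`, `coverage`, `status`.
#' @export
assign_taxon <- function(consensus, refs, min_identity = 90,
                         min_coverage = 95, species_identity = 97) {
  if (!nzchar(consensus)) stop("empty consensus sequence")
  stopifnot(nrow(refs) >= 1)
  stats <- lapply(refs$seq, function(r) pairwise_identity(consensus, r))
  ident <- 100 * vapply(stats, `[[`, 0, "score_coverage")
  cover <- 100 * vapply(stats, `[[`, 0, "length_coverage")
  best <- order(-ident, -cover, refs$name)[1L]
  ok <- ident[best] >= min_identity && cover[best] >= min_coverage
  species <- if (ok && ident[best] >= species_identity)
    refs$species[best] else NA_character_
  data.frame(best_ref = refs$name[best],
             genus = if (ok) refs$genus[best] else NA_character_,
             species = species,
             clade = if (ok) refs$clade[best] else NA_character_,
             identity = ident[best], coverage = cover[best],
             status = if (ok) "assigned" else "unassigned",
             stringsAsFactors = FALSE)
}

parse_otu_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)
  bad <- lengths(parts) != 3L |
    vapply(parts, function(p) is.na(suppressWarnings(as.integer(p[3]))), TRUE)
  if (any(bad)) stop("malformed OTU name: ", name[bad][1L])
  data.frame(treatment = vapply(parts, `[`, "", 1L),
             cluster = as.integer(vapply(parts, `[`, "", 2L)),
             n_seqs = as.integer(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' OTU-by-treatment abundance table
#'
#' Tabulates read counts per OTU and treatment from named clusters, and —
#' when assignments are supplied — derives per-treatment genus-level
#' fractions. Column totals equal the retained non-singleton read counts of
#' each treatment.
#'
#' @param named_clusters_by_treatment named list (by treatment) of
#'   [name_otus()] results; alternatively a ready count matrix (OTUs in
#'   rows, treatments in columns).
#' @param assignments optional data frame mapping `otu` to `genus` (one row
#'   per OTU) used for the genus fractions.
#' @return An object of class `abundance_table`: a list with `counts`
#'   (integer matrix), and when assignments are given `genus_fractions`
#'   (genus-by-treatment fractions summing to 1 per non-empty column).
#' @export
abundance_table <- function(named_clusters_by_treatment, assignments = NULL) {
  if (is.matrix(named_clusters_by_treatment)) {
    counts <- named_clusters_by_treatment
    storage.mode(counts) <- "integer"
  } else {
    rows <- list()
    for (tr in names(named_clusters_by_treatment)) {
      cls <- named_clusters_by_treatment[[tr]]
      for (cl in cls) {
        if (is.null(cl$name)) stop("clusters must be named (see name_otus)")
        parse_otu_name(cl$name)
        rows[[length(rows) + 1L]] <-
          data.frame(otu = cl$name, treatment = tr,
                     n = length(cl$members), stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) {
      counts <- matrix(integer(), 0, 0)
    } else {
      counts <- as.matrix(stats::xtabs(n ~ otu + treatment, data = df))
      counts <- counts[, unique(df$treatment), drop = FALSE]
      class(counts) <- "matrix"
      storage.mode(counts) <- "integer"
    }
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  out <- list(counts = counts)
  if (!is.null(assignments) && nrow(counts)) {
    genus <- assignments$genus[match(rownames(counts), assignments$otu)]
    genus[is.na(genus)] <- "unassigned"
    gm <- rowsum(counts, group = genus)
    fr <- sweep(gm, 2L, colSums(gm), `/`)
    fr[, colSums(gm) == 0] <- NA_real_
    out$genus_counts <- gm
    out$genus_fractions <- fr
  }
  structure(out, class = "abundance_table")
}

#' Label OTUs as epithalline or intrathalline fractions
#'
#' Applies the washing-experiment partition rule, in order of precedence:
#' (1) OTUs in the verified intrathalline core set are `intrathalline`
#' wherever they were detected; (2) OTUs detected only in washing
#' treatments are `epithalline`; (3) OTUs detected in washing *and* thallus
#' treatments are `epithalline-fraction`; (4) OTUs detected only in thallus
#' treatments are `intrathalline`.
#'
#' @param presence logical (or 0/1) matrix, OTUs in rows, treatments in
#'   columns.
#' @param washing_treatments,thallus_treatments disjoint treatment label
#'   sets.
#' @param core_intrathalline OTU names whose intrathalline residence is
#'   independently verified (e.g. by microscopy or specific PCR).
#' @return Named character vector of labels, one per OTU (a partition of
#'   the detected OTUs).
#' @export
partition_fractions <- function(presence, washing_treatments,
                                thallus_treatments,
                                core_intrathalline = character()) {
  if (length(intersect(washing_treatments, thallus_treatments)))
    stop("washing and thallus treatment sets must be disjoint")
  stopifnot(all(c(washing_treatments, thallus_treatments) %in%
                  colnames(presence)))
  pres <- presence[, , drop = FALSE] > 0
  if (any(rowSums(pres) == 0))
    stop("OTU with no detections: ",
         rownames(pres)[rowSums(pres) == 0][1L])
  in_wash <- rowSums(pres[, washing_treatments, drop = FALSE]) > 0
  in_thal <- rowSums(pres[, thallus_treatments, drop = FALSE]) > 0
  lab <- ifelse(rownames(pres) %in% core_intrathalline, "intrathalline",
         ifelse(in_wash & !in_thal, "epithalline",
         ifelse(in_wash & in_thal, "epithalline-fraction", "intrathalline")))
  setNames(lab, rownames(pres))
}

#' Design OTU-discriminating forward primers
#'
#' Scans every `k`-mer of the target consensus and keeps those whose best
#' (minimum-mismatch) ungapped match in *every* other consensus still has
#' at least `min_mismatches` mismatches. Candidates are ranked by that
#' minimum cross-mismatch count (descending), then by the number of
#' mismatches falling in the primer's five 3'-terminal positions at the
#' closest cross-match (descending — 3'-end mismatches suppress
#' mispriming most), then by position. An empty result means no k-mer
#' discriminates the target, as happens for near-identical consensuses.
#'
#' @param target non-empty target consensus sequence.
#' @param others character vector of the other consensus sequences.
#' @param k primer length (default 20; must not exceed the target length).
#' @param min_mismatches minimum cross-mismatch count required (default 3).
#' @return A data frame with `primer`, `start` (1-based), `cross_mismatch`
#'   and `end3_mismatch`, best candidate first.
#' @export
design_probe <- function(target, others, k = 20L, min_mismatches = 3L) {
  target <- toupper(target)
  if (!nzchar(target)) stop("empty target sequence")
  if (k > nchar(target)) stop("k exceeds the target length")
  others <- toupper(others)
  mm <- kmer_cross_mismatch_cpp(target, others, as.integer(k))
  cross <- mm[1L, ]
  end3 <- mm[2L, ]
  keep <- which(cross >= min_mismatches)
  if (!length(keep))
    return(data.frame(primer = character(), start = integer(),
                      cross_mismatch = integer(), end3_mismatch = integer()))
  ord <- keep[order(-cross[keep], -end3[keep], keep)]
  data.frame(primer = substring(target, ord, ord + k - 1L), start = ord,
             cross_mismatch = cross[ord], end3_mismatch = end3[ord],
             stringsAsFactors = FALSE)
}
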