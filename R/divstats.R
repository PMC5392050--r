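#' Alpha-diversity report for one treatment
#'
#' Computes, from per-OTU read counts: richness `S` (OTUs with positive
#' counts), total reads `N`, the Margalef index `Dmg = (S - 1) / ln(N)`,
#' the Shannon index `H` in bits (`-sum p_i log2 p_i`), the reciprocal
#' Simpson index `D = 1 / sum(p_i^2)` and Pielou evenness
#' `J = H / log2(S)` (defined as 0 when `S = 1`). Shannon and the
#' evenness denominator are computed in base 2; see the vignette for why
#' bits rather than nats are the consistent choice for these reports.
#' Shannon and Simpson are delegated to [vegan::diversity()].
#'
#' @param counts nonnegative per-OTU read counts, at least one positive.
#' @param log_base logarithm base for Shannon and evenness (default 2).
#' @return A one-row data frame with `S`, `N`, `Dmg`, `H`, `D`, `J`.
#' @export
diversity_report <- function(counts, log_base = 2) {
  counts <- as.numeric(counts)
  if (!length(counts) || all(counts == 0)) stop("all counts are zero")
  if (any(counts < 0)) stop("counts must be nonnegative")
  pos <- counts[counts > 0]
  S <- length(pos)
  N <- sum(pos)
  H <- as.numeric(vegan::diversity(matrix(pos, nrow = 1), "shannon",
                                   base = log_base))
  D <- as.numeric(vegan::diversity(matrix(pos, nrow = 1), "invsimpson"))
  data.frame(S = S, N = N,
             Dmg = if (N > 1) (S - 1) / log(N) else 0,
             H = H, D = D,
             J = if (S > 1) H / (log(S) / log(log_base)) else 0)
}

#' Rank-abundance curve for one treatment
#'
#' Orders the positive OTU abundances from most to least abundant; ties
#' keep the input OTU order, so the result is deterministic.
#'
#' @param counts per-OTU read counts (optionally named), at least one
#'   positive.
#' @param treatment treatment label attached to the result.
#' @return A data frame with `rank`, `otu`, `abundance` and a `treatment`
#'   column.
#' @export
rank_abundance <- function(counts, treatment = NA_character_) {
  if (!length(counts)) stop("empty counts")
  if (is.null(names(counts))) names(counts) <- sprintf("OTU%d",
                                                       seq_along(counts))
  counts <- counts[counts > 0]
  if (!length(counts)) stop("at least one positive count is required")
  ord <- order(-counts)  # stable: ties keep input order
  data.frame(rank = seq_along(ord), otu = names(counts)[ord],
             abundance = as.numeric(counts[ord]), treatment = treatment,
             stringsAsFactors = FALSE)
}

#' Assemble the summary report bundle
#'
#' Combines QC counts, per-treatment OTU inventories, assignments and
#' diversity rows into the standard report shapes: a sequencing summary
#' (raw / filtered / singleton counts and per-genus OTU counts per
#' treatment), an OTU-by-treatment count table with per-treatment
#' nonzero-OTU totals, an all-genera diversity table, and one
#' genus-restricted diversity table per requested genus (indices recomputed
#' on the genus's counts only).
#'
#' @param qc data frame with at least `treatment`, `raw`, `filtered`,
#'   `singletons` columns (counts per treatment).
#' @param abundance an [abundance_table()].
#' @param assignments data frame mapping `otu` to `genus`.
#' @param by_genus genera for which restricted diversity tables are built.
#' @return A list of data frames: `summary`, `otu_counts`, `diversity`,
#'   and `diversity_<genus>` entries.
#' @export
assemble_tables <- function(qc, abundance, assignments = NULL,
                            by_genus = character()) {
  counts <- abundance$counts
  treatments <- colnames(counts)
  if (!is.null(qc)) {
    if (!all(treatments %in% qc$treatment))
      stop("treatment labels in abundance and qc do not match")
    summary_df <- qc
    if (!is.null(assignments) && length(treatments)) {
      genus <- assignments$genus[match(rownames(counts), assignments$otu)]
      genus[is.na(genus)] <- "unassigned"
      for (g in unique(genus)) {
        col <- paste0("otus_", gsub("\\s+", "_", g))
        summary_df[[col]] <- vapply(summary_df$treatment, function(tr) {
          if (!tr %in% treatments) return(0L)
          sum(counts[genus == g, tr, drop = FALSE] > 0)
        }, 0L)
      }
    }
  } else summary_df <- NULL

  otu_counts <- as.data.frame(counts)
  if (nrow(otu_counts)) otu_counts <- cbind(otu = rownames(counts),
                                            otu_counts, row.names = NULL)
  totals <- colSums(counts > 0)

  div <- do.call(rbind, lapply(treatments, function(tr) {
    col <- counts[, tr]
    if (all(col == 0))
      return(data.frame(treatment = tr, S = 0L, N = 0L, Dmg = NA_real_,
                        H = NA_real_, D = NA_real_, J = NA_real_))
    cbind(treatment = tr, diversity_report(col))
  }))

  out <- list(summary = summary_df, otu_counts = otu_counts,
              otu_totals = totals, diversity = div)

  for (g in by_genus) {
    if (is.null(assignments)) stop("by_genus requires assignments")
    genus <- assignments$genus[match(rownames(counts), assignments$otu)]
    sub <- counts[!is.na(genus) & genus == g, , drop = FALSE]
    gdiv <- do.call(rbind, lapply(treatments, function(tr) {
      col <- sub[, tr]
      if (!length(col) || all(col == 0))
        return(data.frame(treatment = tr, S = 0L, N = 0L, Dmg = NA_real_,
                          H = NA_real_, D = NA_real_, J = NA_real_))
      cbind(treatment = tr, diversity_report(col))
    }))
    out[[paste0("diversity_", gsub("\\s+", "_", g))]] <- gdiv
  }
  out
}

#' Write a report bundle as TSV files
#' @param bundle result of [assemble_tables()].
#' @param dir output directory (created if needed).
#' @export
write_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (is.data.frame(x)) write_tsv(x, file.path(dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
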