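#' MID barcode map
#'
#' Maps treatment-specific multiplex identifier (MID) barcodes to treatment
#' codes. Barcodes and treatment codes must be unique and barcodes must not
#' be prefix-nested (one barcode a prefix of another), since prefix-nested
#' sets make exact-prefix demultiplexing ambiguous.
#'
#' @param barcode character vector of non-empty MID sequences.
#' @param treatment character vector of unique treatment codes.
#' @return An object of class `mid_map` (a data frame).
#' @export
mid_map <- function(barcode, treatment) {
  barcode <- toupper(as.character(barcode))
  treatment <- as.character(treatment)
  stopifnot(length(barcode) == length(treatment))
  if (any(!nzchar(barcode))) stop("barcodes must be non-empty")
  if (anyDuplicated(barcode)) stop("barcodes must be unique")
  if (anyDuplicated(treatment)) stop("treatment codes must be unique")
  for (i in seq_along(barcode)) {
    for (j in seq_along(barcode)) {
      if (i != j && startsWith(barcode[j], barcode[i]))
        stop(sprintf("barcodes are prefix-nested ('%s' prefixes '%s'): %s",
                     barcode[i], barcode[j],
                     "assignment would be ambiguous"))
    }
  }
  structure(data.frame(barcode = barcode, treatment = treatment,
                       stringsAsFactors = FALSE),
            class = c("mid_map", "data.frame"))
}

#' Read a MID map from a two-column TSV (barcode, treatment)
#' @param path TSV file path with columns `barcode` and `treatment`.
#' @return A [mid_map].
#' @export
read_mid_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  mid_map(df$barcode, df$treatment)
}

#' Sort reads into treatments by their MID barcode
#'
#' Assigns each read to the unique treatment whose barcode exactly prefixes
#' the read sequence; reads matching no barcode are collected separately.
#' The barcode is left in place — removal happens during trimming. With
#' `tolerate_one_mismatch = TRUE` a read whose prefix is within Hamming
#' distance 1 of exactly one barcode (all barcodes compared at their own
#' length) is rescued; ambiguous rescues stay unassigned.
#'
#' @param reads a [phy_reads] object, not yet demultiplexed or trimmed.
#' @param mids a [mid_map].
#' @param tolerate_one_mismatch allow a single barcode mismatch
#'   (default `FALSE`: exact matching, as vendor demultiplexers do).
#' @return A list with `assigned` (named list of per-treatment [phy_reads])
#'   and `unassigned` (a [phy_reads]).
#' @export
demultiplex <- function(reads, mids, tolerate_one_mismatch = FALSE) {
  stopifnot(inherits(reads, "phy_reads"), inherits(mids, "mid_map"))
  if (isTRUE(attr(reads, "trimmed")))
    stop("reads are already trimmed: the barcode has been removed")
  if (isTRUE(attr(reads, "demultiplexed")))
    stop("reads are already demultiplexed")
  hit <- rep(NA_integer_, nrow(reads))
  for (b in seq_len(nrow(mids))) {
    m <- startsWith(reads$seq, mids$barcode[b])
    if (any(m & !is.na(hit)))
      stop("internal error: read matched two barcodes")  # excluded by mid_map
    hit[m] <- b
  }
  if (tolerate_one_mismatch && anyNA(hit)) {
    for (r in which(is.na(hit))) {
      d1 <- integer(0)
      for (b in seq_len(nrow(mids))) {
        bc <- mids$barcode[b]
        pre <- substr(reads$seq[r], 1L, nchar(bc))
        if (nchar(pre) == nchar(bc) &&
            sum(strsplit(pre, "")[[1]] != strsplit(bc, "")[[1]]) == 1L)
          d1 <- c(d1, b)
      }
      if (length(d1) == 1L) hit[r] <- d1
    }
  }
  assigned <- lapply(seq_len(nrow(mids)), function(b) {
    sub <- reads[which(hit == b), , drop = FALSE]
    sub$treatment <- rep(mids$treatment[b], nrow(sub))
    attr(sub, "demultiplexed") <- TRUE
    sub
  })
  names(assigned) <- mids$treatment
  list(assigned = assigned,
       unassigned = reads[which(is.na(hit)), , drop = FALSE])
}

#' Trim fixed read ends and drop short cores
#'
#' Removes the first `n5` bases (sequencing primer and MID) and the last
#' `n3` bases (low-quality tail) of every read, trimming any quality string
#' in register, then rejects reads whose remaining core is shorter than
#' `min_len`. Input order is preserved in both outputs; degenerate reads
#' (core empty) are rejected, never an error.
#'
#' @param reads a [phy_reads] object.
#' @param n5 number of 5'-end bases to remove (default 18).
#' @param n3 number of 3'-end bases to remove (default 22).
#' @param min_len minimum retained core length; the default mirrors a
#'   typical final-alignment length for this marker (see the vignette).
#' @return A list with `retained` and `rejected` [phy_reads] objects.
#' @export
trim_and_filter <- function(reads, n5 = 18L, n3 = 22L, min_len = 150L) {
  stopifnot(inherits(reads, "phy_reads"), n5 >= 0, n3 >= 0, min_len >= 0)
  len <- nchar(reads$seq)
  core_len <- pmax(0L, len - n5 - n3)
  seqs <- ifelse(core_len > 0L, substr(reads$seq, n5 + 1L, len - n3), "")
  quals <- ifelse(!is.na(reads$qual) & core_len > 0L,
                  substr(reads$qual, n5 + 1L, len - n3), NA_character_)
  keep <- core_len >= min_len & core_len > 0L
  out <- reads
  out$seq <- seqs
  out$qual <- quals
  attr(out, "trimmed") <- TRUE
  list(retained = out[which(keep), , drop = FALSE],
       rejected = reads[which(!keep), , drop = FALSE])
}

#' Per-treatment quality-control report
#'
#' Tabulates, per treatment, the read counts flowing through demultiplexing
#' and trimming: assigned, filtered out as short, and retained
#' (`retained = assigned - filtered_short`). Only length-based rejections
#' are counted; no other reliability call is made.
#'
#' @param demux result of [demultiplex()].
#' @param trimmed named list (by treatment) of [trim_and_filter()] results.
#' @param n5,n3,min_len the trim parameters used.
#' @return A data frame of class `qc_report` with one row per treatment
#'   plus attributes `unassigned` and `raw_total`.
#' @export
qc_report <- function(demux, trimmed, n5 = 18L, n3 = 22L, min_len = 150L) {
  tr <- names(demux$assigned)
  stopifnot(setequal(tr, names(trimmed)))
  assigned <- vapply(demux$assigned, nrow, 0L)[tr]
  short <- vapply(trimmed, function(x) nrow(x$rejected), 0L)[tr]
  retained <- vapply(trimmed, function(x) nrow(x$retained), 0L)[tr]
  stopifnot(all(retained == assigned - short))
  structure(data.frame(treatment = tr, assigned = assigned,
                       filtered_short = short, retained = retained,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("qc_report", "data.frame"),
            unassigned = nrow(demux$unassigned),
            raw_total = sum(assigned) + nrow(demux$unassigned),
            n5 = n5, n3 = n3, min_len = min_len)
}

#' Write a QC report as TSV and JSON
#' @param report a [qc_report].
#' @param path output path without extension; writes `<path>.tsv` and
#'   `<path>.json`.
#' @export
write_qc_report <- function(report, path) {
  write_tsv(as.data.frame(report), paste0(path, ".tsv"))
  obj <- list(treatments = as.data.frame(report),
              unassigned = attr(report, "unassigned"),
              raw_total = attr(report, "raw_total"),
              n5 = attr(report, "n5"), n3 = attr(report, "n3"),
              min_len = attr(report, "min_len"))
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
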