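#' Amplicon read sets
#'
#' A `phy_reads` object is a plain data frame with one row per read and
#' columns `id`, `seq`, `qual` (Sanger/+33-encoded quality string or `NA`),
#' `treatment` (sample label, `NA` until demultiplexed) and `taxon`
#' (simulation ground truth, `NA` for real data). Two attributes track the
#' processing state: `demultiplexed` and `trimmed`. The state flags guard
#' against re-demultiplexing reads whose barcodes have already been trimmed
#' off.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of nucleotide sequences over `A`,`C`,`G`,`T`,`N`.
#' @param qual optional character vector of Sanger-encoded quality strings
#'   (one character per base).
#' @param treatment optional character vector of sample labels.
#' @param taxon optional character vector with the taxon of origin.
#' @param demultiplexed,trimmed logical state flags.
#' @return A `phy_reads` data frame.
#' @export
phy_reads <- function(id = character(), seq = character(), qual = NA_character_,
                      treatment = NA_character_, taxon = NA_character_,
                      demultiplexed = FALSE, trimmed = FALSE) {
  stopifnot(length(id) == length(seq))
  df <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                   qual = rep_len(as.character(qual), length(id)),
                   treatment = rep_len(as.character(treatment), length(id)),
                   taxon = rep_len(as.character(taxon), length(id)),
                   stringsAsFactors = FALSE)
  bad_q <- !is.na(df$qual) & nchar(df$qual) != nchar(df$seq)
  if (any(bad_q))
    stop("quality string length must equal sequence length (read ",
         df$id[which(bad_q)[1]], ")")
  if (length(df$seq) && any(grepl("[^ACGTN]", df$seq)))
    stop("sequences must be over the alphabet {A,C,G,T,N}")
  structure(df, class = c("phy_reads", "data.frame"),
            demultiplexed = demultiplexed, trimmed = trimmed)
}

#' @export
print.phy_reads <- function(x, ...) {
  cat(sprintf("<phy_reads> %d reads (demultiplexed: %s, trimmed: %s)\n",
              nrow(x), attr(x, "demultiplexed"), attr(x, "trimmed")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# keep class + state flags through subsetting
#' @export
`[.phy_reads` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out))
    out <- structure(out, class = c("phy_reads", "data.frame"),
                     demultiplexed = attr(x, "demultiplexed"),
                     trimmed = attr(x, "trimmed"))
  out
}

qual_string <- function(scores) {
  vapply(scores, function(s) rawToChar(as.raw(s + 33L)), character(1))
}

qual_scores <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(NULL)
    as.integer(charToRaw(q)) - 33L
  })
}

#' Read and write amplicon read files
#'
#' `read_reads_fastq()` and `write_reads_fastq()` handle Sanger-encoded
#' FASTQ; `read_reads_fasta_qual()` and `write_reads_fasta_qual()` handle
#' the 454-style FASTA plus `.qual` pair with space-separated integer
#' quality scores.
#'
#' @param reads a [phy_reads] object.
#' @param path file path (for the FASTA/QUAL pair, the FASTA path; the
#'   quality file replaces the extension with `.qual`).
#' @return The file path (writers, invisibly) or a [phy_reads] object
#'   (readers).
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- ifelse(is.na(reads$qual),
                 vapply(nchar(reads$seq),
                        function(n) strrep(rawToChar(as.raw(63L)), n), ""),
                 reads$qual)
  lines <- character(4L * nrow(reads))
  if (nrow(reads)) {
    lines[seq(1, length(lines), 4)] <- paste0("@", reads$id)
    lines[seq(2, length(lines), 4)] <- reads$seq
    lines[seq(3, length(lines), 4)] <- "+"
    lines[seq(4, length(lines), 4)] <- qual
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(phy_reads())
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1, length(lines), 4)])
  ids <- sub("\\s.*$", "", ids)
  phy_reads(id = ids, seq = lines[seq(2, length(lines), 4)],
            qual = lines[seq(4, length(lines), 4)])
}

#' @rdname write_reads_fastq
#' @export
write_reads_fasta_qual <- function(reads, path) {
  qual_path <- paste0(sub("\\.[^.]*$", "", path), ".qual")
  writeLines(as.character(rbind(paste0(">", reads$id), reads$seq)), path)
  qual <- ifelse(is.na(reads$qual),
                 vapply(nchar(reads$seq),
                        function(n) strrep(rawToChar(as.raw(63L)), n), ""),
                 reads$qual)
  vals <- vapply(qual_scores(qual), paste, "", collapse = " ")
  writeLines(as.character(rbind(paste0(">", reads$id), vals)), qual_path)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fasta_qual <- function(path) {
  qual_path <- paste0(sub("\\.[^.]*$", "", path), ".qual")
  fa <- read_fasta(path)
  if (!length(fa)) return(phy_reads())
  reads <- phy_reads(id = names(fa), seq = unname(fa))
  if (file.exists(qual_path)) {
    ql <- readLines(qual_path)
    hdr <- grepl("^>", ql)
    grp <- cumsum(hdr)
    ids <- sub("^>", "", ql[hdr])
    vals <- vapply(split(ql[!hdr], grp[!hdr]), paste, "", collapse = " ")
    scores <- lapply(vals, function(v)
      as.integer(strsplit(trimws(v), "\\s+")[[1]]))
    reads$qual <- unname(qual_string(scores)[match(reads$id, ids)])
  }
  reads
}

# minimal FASTA reader/writer used for plain sequence records
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) return(setNames(character(), character()))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  setNames(toupper(seqs), sub("^>", "", lines[hdr]))
}

write_fasta <- function(seqs, path) {
  writeLines(as.character(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}
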