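#' Pairwise identity under score- and length-coverage semantics
#'
#' Computes a global (Needleman-Wunsch, affine-gap) alignment of two
#' sequences with the documented scoring (match `+1`, mismatch `-1`, gap
#' open `-2`, gap extension `-1` per base; a gap of length *k* costs
#' `open + k * ext`) and reports:
#'
#' * `score_coverage` — identical positions divided by alignment columns,
#'   excluding terminal gap columns;
#' * `length_coverage` — alignment columns excluding terminal gaps, divided
#'   by the length of the longer sequence;
#' * `alignment_length` — alignment columns excluding terminal gaps.
#'
#' Both measures are symmetric in the two sequences.
#'
#' @param a,b non-empty nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend alignment scoring parameters.
#' @param band half-width of the alignment band around the length-difference
#'   diagonal corridor; `NULL` (default) computes the exact unbanded
#'   alignment.
#' @return A list with `score_coverage`, `length_coverage`,
#'   `alignment_length` and `score`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1, gap_open = 2,
                              gap_extend = 1, band = NULL) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  # canonical argument order makes the traceback tie-break symmetric
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  st <- align_stats_cpp(a, b, match, mismatch, abs(gap_open), abs(gap_extend),
                        if (is.null(band)) -1L else as.integer(band))
  if (st$kept == 0)
    return(list(score_coverage = 0, length_coverage = 0,
                alignment_length = 0L, score = st$score))
  # internal gaps can push the span past the longer length for highly
  # divergent pairs; coverage is capped at 1
  list(score_coverage = st$ident / st$kept,
       length_coverage = min(1, st$kept / max(nchar(a), nchar(b))),
       alignment_length = st$kept, score = st$score)
}

default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = 2, gap_extend = 1)
}

#' Single-linkage OTU clustering at joint identity thresholds
#'
#' Links two reads when their `score_coverage` is at least `S` *and* their
#' `length_coverage` is at least `L`; OTUs are the connected components of
#' the link graph (single linkage). Identical reads are dereplicated before
#' alignment, which is lossless for single linkage. Clusters are numbered
#' by descending member count, ties broken by the lexicographically
#' smallest member id, so the result is invariant to input order.
#'
#' A banded alignment (pad `band`, widened by the pair's length difference)
#' and, at `S >= 0.97`, an 8-mer prefilter (skip pairs sharing < 60% of
#' 8-mers) keep the all-pairs scan tractable; both are necessary-condition
#' screens that cannot remove a true link at those thresholds (see the
#' vignette for the argument).
#'
#' @param reads a [phy_reads] object or a named character vector of
#'   sequences (names are read ids).
#' @param S score-coverage threshold in `[0, 1]` (default 0.99).
#' @param L length-coverage threshold in `[0, 1]` (default 0.9).
#' @param method `"single"` (connected components, default) or
#'   `"centroid"` (greedy centroid joining, for comparison only).
#' @param band band pad for the aligner; `NULL` uses exact alignment.
#' @param scoring alignment scoring parameters, see [pairwise_identity()].
#' @return An object of class `otu_cluster_set`: a list of clusters, each
#'   with `members` (read ids) and `seqs` (member sequences), ordered as
#'   described.
#' @export
cluster_reads <- function(reads, S = 0.99, L = 0.9,
                          method = c("single", "centroid"), band = 16L,
                          scoring = default_scoring()) {
  method <- match.arg(method)
  stopifnot(S >= 0, S <= 1, L >= 0, L <= 1)
  if (inherits(reads, "phy_reads")) {
    ids <- reads$id; seqs <- toupper(reads$seq)
  } else {
    ids <- names(reads); seqs <- toupper(unname(reads))
    if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  }
  if (!length(seqs))
    return(structure(list(), class = "otu_cluster_set", S = S, L = L))
  if (any(!nzchar(seqs))) stop("sequences must be non-empty")

  # dereplicate: identical sequences always co-cluster
  tab <- sort(table(seqs), decreasing = TRUE)
  uniq <- names(tab)
  uniq <- uniq[order(-as.integer(tab), uniq)]  # count desc, then lexicographic

  comp <- if (method == "single") {
    cluster_components_cpp(uniq, S, L, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend,
                           if (is.null(band)) -1L else as.integer(band),
                           S >= 0.97, 0.6)
  } else {
    centroid_components(uniq, S, L, band, scoring)
  }

  read_comp <- comp[match(seqs, uniq)]
  groups <- split(seq_along(ids), read_comp)
  clusters <- lapply(groups, function(ix) {
    ord <- order(ids[ix])
    list(members = ids[ix][ord], seqs = seqs[ix][ord])
  })
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  first_id <- vapply(clusters, function(cl) cl$members[1L], "")
  clusters <- clusters[order(-sizes, first_id)]
  names(clusters) <- NULL
  structure(clusters, class = "otu_cluster_set", S = S, L = L,
            method = method, scoring = scoring)
}

# greedy centroid joining, exposed for comparison with single linkage
centroid_components <- function(uniq, S, L, band, scoring) {
  comp <- integer(length(uniq))
  centroids <- integer(0)
  for (i in seq_along(uniq)) {
    hit <- 0L
    for (c_i in centroids) {
      pid <- pairwise_identity(uniq[i], uniq[c_i],
                               match = scoring$match,
                               mismatch = scoring$mismatch,
                               gap_open = scoring$gap_open,
                               gap_extend = scoring$gap_extend, band = band)
      if (pid$score_coverage >= S && pid$length_coverage >= L) {
        hit <- comp[c_i]
        break
      }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      comp[i] <- length(centroids)
    } else comp[i] <- hit
  }
  comp
}

#' @export
print.otu_cluster_set <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$members), 0L)
  cat(sprintf("<otu_cluster_set> %d clusters (S = %s, L = %s); sizes: %s\n",
              length(x), attr(x, "S"), attr(x, "L"),
              paste(utils::head(sizes, 10L), collapse = ", ")))
  invisible(x)
}

#' Remove singleton clusters
#'
#' Drops clusters with a single member (unique sequences are treated as
#' unreliable) and reports how many were removed. Multi-member clusters
#' keep their order.
#'
#' @param clusters an `otu_cluster_set` from [cluster_reads()].
#' @return A list with `clusters` (the surviving `otu_cluster_set`) and
#'   `n_singletons` (count removed).
#' @export
drop_singletons <- function(clusters) {
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  keep <- sizes >= 2L
  out <- structure(clusters[keep], class = "otu_cluster_set",
                   S = attr(clusters, "S"), L = attr(clusters, "L"),
                   method = attr(clusters, "method"),
                   scoring = attr(clusters, "scoring"))
  list(clusters = out, n_singletons = sum(!keep))
}

iupac_code <- local({
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  function(bases) {
    key <- paste(sort(unique(bases)), collapse = "")
    unname(codes[key])
  }
})

seq_profile <- function(seq, weight) {
  chars <- strsplit(seq, "")[[1]]
  m <- matrix(0, nrow = 5L, ncol = length(chars),
              dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  ix <- match(chars, rownames(m))
  ix[is.na(ix)] <- 5L  # N and friends carry no base vote
  m[cbind(ix, seq_along(chars))] <- weight
  m
}

#' Majority-rule consensus of cluster members
#'
#' Aligns the member sequences progressively along a UPGMA guide tree built
#' on pairwise score-coverage (members are dereplicated first and weighted
#' by multiplicity), then calls one base per column: columns with more than
#' 50% gap weight are dropped, the weighted majority base is taken
#' elsewhere, and exact ties are encoded as IUPAC ambiguity codes.
#'
#' @param member_seqs character vector of member sequences (one entry per
#'   read; repeat sequences to weight them), or a single cluster from
#'   [cluster_reads()].
#' @param scoring alignment scoring, see [pairwise_identity()].
#' @return The consensus sequence (single string).
#' @export
consensus <- function(member_seqs, scoring = default_scoring()) {
  if (is.list(member_seqs) && !is.null(member_seqs$seqs))
    member_seqs <- member_seqs$seqs
  member_seqs <- toupper(member_seqs)
  if (!length(member_seqs)) stop("consensus of an empty cluster")
  tab <- table(member_seqs)
  uniq <- names(tab)
  w <- as.numeric(tab)
  ord <- order(-w, uniq)
  uniq <- uniq[ord]; w <- w[ord]

  if (length(uniq) == 1L) {
    prof <- seq_profile(uniq, w)
  } else {
    idm <- identity_matrix_cpp(uniq, scoring$match, scoring$mismatch,
                               scoring$gap_open, scoring$gap_extend, -1L)
    d <- as.dist(1 - idm$score_coverage)
    hc <- hclust(d, method = "average")  # UPGMA guide tree
    profs <- vector("list", nrow(hc$merge))
    leaf <- function(i) seq_profile(uniq[i], w[i])
    for (m in seq_len(nrow(hc$merge))) {
      a <- hc$merge[m, 1L]; b <- hc$merge[m, 2L]
      pa <- if (a < 0) leaf(-a) else profs[[a]]
      pb <- if (b < 0) leaf(-b) else profs[[b]]
      profs[[m]] <- profile_align_cpp(pa, pb, scoring$match, scoring$mismatch,
                                      scoring$gap_open, scoring$gap_extend)
    }
    prof <- profs[[nrow(hc$merge)]]
  }

  base_names <- c("A", "C", "G", "T")
  total <- sum(prof[, 1L])
  out <- character(0)
  for (j in seq_len(ncol(prof))) {
    col <- prof[, j]
    if (col[5L] > total / 2) next  # majority-gap column dropped
    bases <- col[1:4]
    top <- base_names[bases == max(bases)]
    out <- c(out, iupac_code(top))
  }
  paste(out, collapse = "")
}

#' Calibrate the clustering threshold on a reference set
#'
#' Clusters an annotated reference sequence set at each candidate
#' score-coverage threshold and counts the clusters formed. The chosen
#' threshold is the lowest one achieving the maximal cluster count:
#' thresholds above it separate no additional taxa but are more prone to
#' splitting reads that differ only by homopolymer sequencing errors into
#' extra singletons.
#'
#' @param reference data frame with columns `name` and `seq` (names must be
#'   unique), e.g. from [make_taxa()] or [read_reference_fasta()].
#' @param thresholds increasing vector of score-coverage thresholds.
#' @param L length-coverage threshold held fixed during calibration.
#' @return A list with `rows` (data frame of `threshold`, `n_clusters`) and
#'   `chosen` (the selected threshold).
#' @export
calibrate <- function(reference, thresholds = c(0.90, 0.95, 0.97, 0.99, 1.00),
                      L = 0.9) {
  stopifnot(nrow(reference) >= 2)
  if (anyDuplicated(reference$name)) stop("reference names must be unique")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted increasing")
  n <- vapply(thresholds, function(S) {
    length(cluster_reads(setNames(reference$seq, reference$name), S = S,
                         L = L))
  }, 0L)
  rows <- data.frame(threshold = thresholds, n_clusters = n)
  list(rows = rows, chosen = thresholds[which(n == max(n))[1L]])
}

#' Name OTU clusters
#'
#' Applies the canonical naming scheme
#' `<treatment code>_<cluster number>_<number of sequences>`, with cluster
#' numbers taken from the [cluster_reads()] ordering (descending size).
#'
#' @param clusters an `otu_cluster_set`.
#' @param treatment_code non-empty treatment code without underscores
#'   (underscores would break name parsing).
#' @return The cluster set with a `name` field added to each cluster; the
#'   list itself is named by OTU name.
#' @export
name_otus <- function(clusters, treatment_code) {
  if (!nzchar(treatment_code)) stop("treatment code must be non-empty")
  if (grepl("_", treatment_code, fixed = TRUE))
    stop("treatment code must not contain underscores")
  out <- clusters
  nm <- character(length(clusters))
  for (i in seq_along(clusters)) {
    nm[i] <- sprintf("%s_%d_%d", treatment_code, i,
                     length(clusters[[i]]$members))
    out[[i]]$name <- nm[i]
  }
  names(out) <- nm
  out
}

#' Write cluster membership as TSV (read id, OTU name)
#' @param named_clusters result of [name_otus()].
#' @param path output TSV path.
#' @export
write_membership <- function(named_clusters, path) {
  df <- do.call(rbind, lapply(named_clusters, function(cl)
    data.frame(read_id = cl$members, otu = cl$name)))
  if (is.null(df)) df <- data.frame(read_id = character(), otu = character())
  write_tsv(df, path)
}
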