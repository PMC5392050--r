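#' Pairwise genetic distance matrix from aligned sequences
#'
#' Computes pairwise distances (substitutions per site) from an alignment,
#' excluding gap- or ambiguity-containing sites pairwise. Models: raw
#' p-distance, Jukes-Cantor (JC69) and Kimura two-parameter (K2P, the
#' default). Model corrections are delegated to [ape::dist.dna()].
#'
#' @param aligned_seqs named character vector of equal-length aligned
#'   sequences.
#' @param model `"K2P"`, `"JC69"` or `"p"`.
#' @return An object of class `dist_matrix`: list with `labels`, `d`
#'   (symmetric matrix) and `model`.
#' @export
distance_matrix <- function(aligned_seqs, model = c("K2P", "JC69", "p")) {
  model <- match.arg(model)
  if (is.null(names(aligned_seqs)))
    names(aligned_seqs) <- sprintf("seq%03d", seq_along(aligned_seqs))
  if (length(unique(nchar(aligned_seqs))) > 1L)
    stop("sequences must be aligned (equal length)")
  mat <- do.call(rbind, strsplit(tolower(aligned_seqs), ""))
  rownames(mat) <- names(aligned_seqs)
  bin <- ape::as.DNAbin(mat)
  ape_model <- c(K2P = "K80", JC69 = "JC69", p = "raw")[model]
  d <- ape::dist.dna(bin, model = ape_model, pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (any(!is.finite(d)))
    stop("undefined distance for at least one pair (no comparable sites ",
         "or saturated correction)")
  structure(list(labels = names(aligned_seqs), d = d, model = model),
            class = "dist_matrix")
}

# one recursive barcode-gap split of the labels in `ix`
abgd_split <- function(d, ix, P, X) {
  if (length(ix) < 2L) return(list(ix))
  sub <- d[ix, ix, drop = FALSE]
  dv <- sort(sub[upper.tri(sub)])
  # barcode gap: smallest distance > P whose spacing to its predecessor
  # exceeds X times the mean spacing among all distances <= the predecessor
  dstar <- NA_real_
  for (i in seq_along(dv)) {
    if (dv[i] <= P || i < 3L) next  # need >= 2 predecessors for a mean spacing
    pred <- dv[i - 1L]
    mean_sp <- (pred - dv[1L]) / (i - 2L)
    if ((dv[i] - pred) > X * mean_sp && dv[i] > pred) {
      dstar <- dv[i]
      break
    }
  }
  if (is.na(dstar)) return(list(ix))
  link <- sub < dstar
  comp <- connected_components(link)
  groups <- split(ix, comp)
  if (length(groups) == 1L) return(list(ix))
  out <- list()
  for (g in groups) out <- c(out, abgd_split(d, g, P, X))
  out
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Recursive barcode-gap species delimitation
#'
#' For each prior intraspecific divergence `P` on a log-spaced grid from
#' `Pmin` to `Pmax`, sorts all pairwise distances, finds the smallest
#' distance above `P` whose spacing to its predecessor exceeds `X` times
#' the mean spacing among the distances up to that predecessor (the
#' barcode gap), groups the labels as the connected components of the graph
#' linking pairs closer than the gap, and recurses within each group until
#' no further gap is found. Without a gap all labels form one group.
#'
#' This gap rule is a documented simplification of the published
#' barcode-gap-discovery procedure; the grid defaults follow its published
#' defaults.
#'
#' @param dm a `dist_matrix` from [distance_matrix()].
#' @param Pmin,Pmax prior grid bounds, `0 < Pmin <= Pmax`.
#' @param steps number of grid points (`>= 1`).
#' @param X relative gap width (default 1.5).
#' @return A list of partitions, one per prior: each has `prior` and
#'   `groups` (named integer vector assigning each label to a group id).
#' @export
abgd_partition <- function(dm, Pmin = 0.001, Pmax = 0.1, steps = 10L,
                           X = 1.5) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (!(Pmin > 0 && Pmin <= Pmax && steps >= 1))
    stop("invalid prior grid: need 0 < Pmin <= Pmax and steps >= 1")
  priors <- if (steps == 1L) Pmin else
    exp(seq(log(Pmin), log(Pmax), length.out = steps))
  labels <- dm$labels
  lapply(priors, function(P) {
    groups <- abgd_split(dm$d, seq_along(labels), P, X)
    assign <- integer(length(labels))
    # deterministic group ids: by smallest member index
    groups <- groups[order(vapply(groups, min, 0L))]
    for (g in seq_along(groups)) assign[groups[[g]]] <- g
    list(prior = P, groups = setNames(assign, labels))
  })
}

#' Collapse aligned sequences into haplotypes
#'
#' Merges identical aligned sequences; each haplotype's frequency is the
#' summed count of its members and its label is the lexicographically
#' smallest member name.
#'
#' @param aligned_seqs named character vector of aligned sequences.
#' @param counts per-sequence counts (default 1 each).
#' @return A data frame with `label`, `seq`, `freq`, plus a `members` list
#'   column.
#' @export
collapse_haplotypes <- function(aligned_seqs, counts = NULL) {
  if (!length(aligned_seqs))
    return(data.frame(label = character(), seq = character(),
                      freq = integer()))
  if (is.null(names(aligned_seqs)))
    names(aligned_seqs) <- sprintf("seq%03d", seq_along(aligned_seqs))
  if (is.null(counts)) counts <- rep(1L, length(aligned_seqs))
  stopifnot(length(counts) == length(aligned_seqs))
  key <- toupper(aligned_seqs)
  groups <- split(seq_along(key), key)
  df <- do.call(rbind, lapply(groups, function(ix) {
    data.frame(label = min(names(aligned_seqs)[ix]),
               seq = key[ix[1L]], freq = sum(counts[ix]),
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$label), , drop = FALSE]
  df$members <- lapply(split(seq_along(key), key)[
    match(df$seq, names(groups))],
    function(ix) sort(names(aligned_seqs)[ix]))
  rownames(df) <- NULL
  df
}

hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  if (length(x) != length(y)) stop("sequences must be aligned (equal length)")
  sum(x != y)
}

#' Statistical-parsimony haplotype network
#'
#' Builds a minimum spanning network (all ties retained) over haplotypes
#' from their pairwise Hamming distances, connecting only pairs within the
#' parsimony connection `limit`; pairs beyond the limit end up in separate
#' subnetworks. Every multi-step edge is subdivided by inferred (missing)
#' intermediate haplotypes of frequency zero, so each drawn line represents
#' one mutational step.
#'
#' @param haplotypes data frame from [collapse_haplotypes()].
#' @param limit maximum mutational steps for a connection (`>= 1`).
#' @return An object of class `haplo_network`: list with `nodes` (`name`,
#'   `freq`, `observed`), `edges` (unit-step edges after subdivision),
#'   `msn_edges` (`from`, `to`, `steps` before subdivision) and `limit`.
#' @export
parsimony_network <- function(haplotypes, limit = 10L) {
  stopifnot(limit >= 1)
  n <- nrow(haplotypes)
  labels <- haplotypes$label
  if (n && length(unique(nchar(haplotypes$seq))) > 1L)
    stop("haplotypes must be aligned (equal length)")
  D <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
    D[i, j] <- D[j, i] <- hamming(haplotypes$seq[i], haplotypes$seq[j])

  # minimum spanning network: Kruskal over distance classes, keeping every
  # tie that joins two components as of the start of its class
  comp <- seq_len(n)
  msn <- data.frame(from = character(), to = character(), steps = integer(),
                    stringsAsFactors = FALSE)
  for (d in sort(unique(D[upper.tri(D)]))) {
    if (d < 1L || d > limit) next
    snapshot <- comp
    joins <- which(upper.tri(D) & D == d, arr.ind = TRUE)
    joins <- joins[order(joins[, 1L], joins[, 2L]), , drop = FALSE]
    for (r in seq_len(nrow(joins))) {
      i <- joins[r, 1L]; j <- joins[r, 2L]
      if (snapshot[i] != snapshot[j]) {
        msn <- rbind(msn, data.frame(from = labels[i], to = labels[j],
                                     steps = d, stringsAsFactors = FALSE))
        old <- comp[j]
        comp[comp == old] <- comp[i]
      }
    }
  }

  nodes <- data.frame(name = labels, freq = haplotypes$freq,
                      observed = TRUE, stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(),
                      steps = integer(), stringsAsFactors = FALSE)
  inferred <- 0L
  for (r in seq_len(nrow(msn))) {
    d <- msn$steps[r]
    chain <- msn$from[r]
    if (d > 1L) {
      for (s in seq_len(d - 1L)) {
        inferred <- inferred + 1L
        nm <- sprintf("inferred%03d", inferred)
        nodes <- rbind(nodes, data.frame(name = nm, freq = 0L,
                                         observed = FALSE))
        chain <- c(chain, nm)
      }
    }
    chain <- c(chain, msn$to[r])
    for (s in seq_len(length(chain) - 1L))
      edges <- rbind(edges, data.frame(from = chain[s], to = chain[s + 1L],
                                       steps = 1L, stringsAsFactors = FALSE))
  }
  structure(list(nodes = nodes, edges = edges, msn_edges = msn,
                 limit = as.integer(limit)),
            class = "haplo_network")
}

#' Convert a haplotype network to an igraph graph
#' @param network a `haplo_network`.
#' @param subdivided use the unit-step edges (`TRUE`, default) or the raw
#'   minimum-spanning-network edges with step weights.
#' @return An [igraph::igraph] object.
#' @export
as_igraph <- function(network, subdivided = TRUE) {
  ed <- if (subdivided) network$edges else network$msn_edges
  vertices <- if (subdivided) network$nodes else
    network$nodes[network$nodes$observed, , drop = FALSE]
  vertices$observed <- as.integer(vertices$observed)  # DOT-safe attribute
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = vertices)
  igraph::E(g)$weight <- ed$steps
  g
}

#' Write a haplotype network as GraphML and DOT
#' @param network a `haplo_network`.
#' @param path output path without extension; writes `<path>.graphml` and
#'   `<path>.dot`.
#' @export
write_network <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  igraph::write_graph(g, paste0(path, ".dot"), format = "dot")
  invisible(path)
}

#' Write a distance matrix as square TSV
#' @param dm a `dist_matrix`.
#' @param path output TSV path.
#' @param phylip_header prepend the sequence count (PHYLIP-style).
#' @export
write_distance_matrix <- function(dm, path, phylip_header = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (phylip_header) writeLines(as.character(length(dm$labels)), con)
  utils::write.table(dm$d, con, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Write delimitation partitions as TSV (one file per prior)
#' @param partitions result of [abgd_partition()].
#' @param path_prefix output path prefix; each prior writes
#'   `<prefix>_P<prior>.tsv`.
#' @export
write_partitions <- function(partitions, path_prefix) {
  for (p in partitions) {
    df <- data.frame(label = names(p$groups), group = unname(p$groups))
    write_tsv(df, sprintf("%s_P%.6f.tsv", path_prefix, p$prior))
  }
  invisible(path_prefix)
}
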