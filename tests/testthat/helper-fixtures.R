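# fixture builders shared across the suite; everything is generated in code

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# substitute the bases at `pos` with a different base (deterministic shift)
mutate_at <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    alt <- BASES[BASES != chars[p]]
    chars[p] <- alt[1L]
  }
  paste(chars, collapse = "")
}

# a family of sequences derived from one template by substitutions at the
# given per-sequence positions (list), named s1, s2, ...
seq_family <- function(template, positions) {
  out <- vapply(positions, function(p)
    if (length(p)) mutate_at(template, p) else template, "")
  setNames(out, sprintf("s%02d", seq_along(out)))
}

# independent single-linkage oracle: transitive closure over the all-pairs
# link matrix computed with exact (unbanded) pairwise_identity
brute_force_components <- function(seqs, S, L) {
  n <- length(seqs)
  link <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    pid <- pairwise_identity(seqs[i], seqs[j])
    link[i, j] <- link[j, i] <-
      pid$score_coverage >= S && pid$length_coverage >= L
  }
  reach <- link
  for (k in seq_len(n))
    reach <- reach | (reach[, k, drop = FALSE] %*% reach[k, , drop = FALSE] > 0)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[reach[i, ]] <- cur
    }
  }
  comp
}

# cluster composition as a canonical set-of-sets on member ids
cluster_sets <- function(clusters) {
  sets <- lapply(clusters, function(cl) sort(cl$members))
  sets[order(vapply(sets, `[`, "", 1L))]
}

table_fixture <- function(name) {
  system.file("extdata", name, package = "phycodive", mustWork = TRUE)
}
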