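test_that("pairwise identity matches direct counting on crafted pairs", {
  a <- strrep("ACGT", 50)  # 200 nt
  expect_equal(pairwise_identity(a, a)$score_coverage, 1)
  expect_equal(pairwise_identity(a, a)$length_coverage, 1)

  b <- mutate_at(a, c(10, 50))
  pid <- pairwise_identity(a, b)
  expect_equal(pid$score_coverage, 0.99)  # 198 / 200

  half <- pairwise_identity(a, substr(a, 1, 100))
  expect_equal(half$length_coverage, 0.5)
  expect_equal(half$score_coverage, 1)

  expect_error(pairwise_identity("", a), "non-empty")
})

test_that("pairwise identity is symmetric and its score matches Biostrings", {
  library(Biostrings)
  set.seed(31)
  sm <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                     baseOnly = TRUE)
  for (i in 1:15) {
    a <- rand_seq(sample(60:140, 1))
    b <- if (i %% 2) mutate_at(a, sample(nchar(a), sample(1:10, 1)))
         else rand_seq(sample(60:140, 1))
    p1 <- pairwise_identity(a, b)
    p2 <- pairwise_identity(b, a)
    expect_equal(p1$score_coverage, p2$score_coverage)
    expect_equal(p1$length_coverage, p2$length_coverage)
    ref <- score(pairwiseAlignment(DNAString(a), DNAString(b),
                                   substitutionMatrix = sm, gapOpening = 2,
                                   gapExtension = 1, type = "global"))
    expect_equal(p1$score, ref)
  }
})

test_that("clustering follows single-linkage semantics", {
  empty <- cluster_reads(character())
  expect_length(empty, 0L)

  one <- cluster_reads(c(r1 = rand_seq(100)))
  expect_length(one, 1L)

  set.seed(32)
  t <- rand_seq(200)
  seqs <- c(a = t, b = t, c = mutate_at(t, 1:10))  # c at 95% to both
  cl <- cluster_reads(seqs, S = 0.99, L = 0.9)
  expect_length(cl, 2L)
  expect_equal(cluster_sets(cl), list(c("a", "b"), "c"))

  # chain: a-b 99.5%, b-c 99.5%, a-c 99.0% < S -> one cluster via linkage
  chain <- c(a = t, b = mutate_at(t, 10), c = mutate_at(t, c(10, 50)))
  cl2 <- cluster_reads(chain, S = 0.992, L = 0.9)
  expect_length(cl2, 1L)
  expect_setequal(cl2[[1]]$members, c("a", "b", "c"))
})

test_that("clustering equals the brute-force transitive-closure oracle", {
  set.seed(33)
  for (rep in 1:4) {
    t1 <- rand_seq(120); t2 <- rand_seq(120)
    positions <- lapply(1:10, function(i) sample(120, sample(0:6, 1)))
    seqs <- c(seq_family(t1, positions[1:6]),
              vapply(positions[7:10], function(p) mutate_at(t2, p), ""))
    names(seqs) <- sprintf("q%02d", seq_along(seqs))
    for (S in c(0.95, 0.97, 0.99)) {
      oracle <- brute_force_components(seqs, S, 0.9)
      got <- cluster_reads(seqs, S = S, L = 0.9)
      member_comp <- setNames(rep(seq_along(got),
                                  vapply(got, function(cl)
                                    length(cl$members), 0L)),
                              unlist(lapply(got, `[[`, "members")))
      mc <- unname(member_comp[names(seqs)])
      # same partition: identical co-membership structure
      expect_equal(outer(mc, mc, `==`), outer(oracle, oracle, `==`))
    }
  }
})

test_that("cluster count is non-decreasing in S and order-invariant", {
  set.seed(34)
  t <- rand_seq(150)
  seqs <- seq_family(t, lapply(1:12, function(i) sample(150, sample(0:5, 1))))
  counts <- vapply(c(0.95, 0.97, 0.98, 0.99, 1.0), function(S)
    length(cluster_reads(seqs, S = S, L = 0.9)), 0L)
  expect_true(all(diff(counts) >= 0))

  perm <- sample(length(seqs))
  a <- cluster_reads(seqs, S = 0.98, L = 0.9)
  b <- cluster_reads(seqs[perm], S = 0.98, L = 0.9)
  expect_equal(cluster_sets(a), cluster_sets(b))
  expect_equal(names(name_otus(a, "T")), names(name_otus(b, "T")))
})

test_that("singleton removal keeps multi-member clusters in order", {
  ds0 <- drop_singletons(structure(list(), class = "otu_cluster_set"))
  expect_length(ds0$clusters, 0L)
  expect_equal(ds0$n_singletons, 0L)

  fake <- structure(lapply(c(5, 1, 3, 1, 1), function(n)
    list(members = sprintf("m%d", seq_len(n)), seqs = rep("A", n))),
    class = "otu_cluster_set")
  ds <- drop_singletons(fake)
  expect_equal(vapply(ds$clusters, function(cl) length(cl$members), 0L),
               c(5L, 3L))
  expect_equal(ds$n_singletons, 3L)

  allsing <- structure(lapply(1:4, function(i)
    list(members = "m", seqs = "A")), class = "otu_cluster_set")
  expect_equal(drop_singletons(allsing)$n_singletons, 4L)
})

test_that("consensus applies majority rule, IUPAC ties and gap dropping", {
  set.seed(35)
  t <- rand_seq(80)
  expect_equal(consensus(rep(t, 4)), t)

  v <- c(t, t, mutate_at(t, 30))
  cons <- consensus(v)
  expect_equal(cons, t)  # majority A,A,C style column -> majority base

  tA <- t; substr(tA, 40, 40) <- "A"
  tC <- t; substr(tC, 40, 40) <- "C"
  cons2 <- consensus(c(tA, tC))
  expect_equal(substr(cons2, 40, 40), "M")  # tie A/C -> IUPAC M
  expect_equal(substr(cons2, 1, 39), substr(t, 1, 39))
  expect_equal(substr(cons2, 41, 80), substr(t, 41, 80))

  # an insertion carried by a minority of members is a majority-gap column
  ins <- paste0(substr(t, 1, 40), "G", substr(t, 41, 80))
  cons3 <- consensus(c(t, t, ins))
  expect_equal(cons3, t)

  expect_error(consensus(character()), "empty")
})

test_that("threshold calibration picks the lowest maximal threshold", {
  set.seed(36)
  t <- rand_seq(250)
  pos <- split(1:115, rep(1:23, each = 5))  # disjoint -> pairwise 96% identity
  refs <- data.frame(name = sprintf("ref%02d", 1:23),
                     seq = vapply(pos, function(p) mutate_at(t, p), ""))
  cal <- calibrate(refs, thresholds = c(0.95, 0.99, 1.00))
  expect_equal(cal$rows$n_clusters, c(1L, 23L, 23L))
  expect_equal(cal$chosen, 0.99)

  same <- data.frame(name = c("a", "b", "c"), seq = rep(t, 3))
  cal2 <- calibrate(same, thresholds = c(0.90, 0.99, 1.00))
  expect_true(all(cal2$rows$n_clusters == 1L))
  expect_equal(cal2$chosen, 0.90)

  pair <- data.frame(name = c("x", "y"),
                     seq = c(t, mutate_at(t, seq(1, 22, by = 3))))
  cal3 <- calibrate(pair, thresholds = c(0.95, 0.99))
  expect_equal(cal3$rows$n_clusters, c(1L, 2L))
  expect_equal(cal3$chosen, 0.99)

  expect_error(calibrate(data.frame(name = c("a", "a"), seq = c(t, t))),
               "unique")
})

test_that("OTU names encode treatment, cluster number and size", {
  set.seed(37)
  t <- rand_seq(100)
  seqs <- setNames(c(rep(t, 10), rep(mutate_at(t, 1:20), 2)),
                   sprintf("r%02d", 1:12))
  named <- name_otus(cluster_reads(seqs, S = 0.99), "HW")
  expect_equal(names(named), c("HW_1_10", "HW_2_2"))
  expect_error(name_otus(cluster_reads(seqs), "H_W"), "underscore")
  expect_error(name_otus(cluster_reads(seqs), ""), "non-empty")
  expect_length(name_otus(cluster_reads(character()), "A"), 0L)
})

test_that("greedy centroid clustering is available for comparison", {
  set.seed(38)
  t <- rand_seq(150)
  seqs <- setNames(c(rep(t, 5), rep(mutate_at(t, 1:12), 3)),
                   sprintf("r%d", 1:8))
  cl <- cluster_reads(seqs, S = 0.99, method = "centroid")
  expect_length(cl, 2L)
})
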