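test_that("distance models match closed-form values", {
  set.seed(51)
  t <- rand_seq(100)
  same <- c(a = t, b = t)
  expect_equal(unname(distance_matrix(same, model = "p")$d["a", "b"]), 0)

  b <- mutate_at(t, c(3, 20, 41, 77, 95))
  dm <- distance_matrix(c(a = t, b = b), model = "p")
  expect_equal(unname(dm$d["a", "b"]), 0.05)

  # 5 transitions, 0 transversions: K2P exceeds p and matches its closed form
  chars <- strsplit(t, "")[[1]]
  pos <- which(chars %in% c("A", "G"))[1:5]
  chars[pos] <- ifelse(chars[pos] == "A", "G", "A")
  ts <- paste(chars, collapse = "")
  p <- 0.05
  k2p <- distance_matrix(c(a = t, b = ts), model = "K2P")$d["a", "b"]
  expect_gt(k2p, p)
  expect_equal(unname(k2p), -0.5 * log(1 - 2 * p) - 0.25 * log(1),
               tolerance = 1e-9)
  jc <- distance_matrix(c(a = t, b = ts), model = "JC69")$d["a", "b"]
  expect_equal(unname(jc), -3 / 4 * log(1 - 4 / 3 * p), tolerance = 1e-9)

  # gap-containing sites are excluded pairwise
  g <- paste0("----------", substr(b, 11, 100))
  dmg <- distance_matrix(c(a = t, b = g), model = "p")
  mism <- sum(strsplit(substr(t, 11, 100), "")[[1]] !=
                strsplit(substr(b, 11, 100), "")[[1]])
  expect_equal(unname(dmg$d["a", "b"]), mism / 90)

  expect_error(distance_matrix(c(a = "ACGT", b = "ACG")), "aligned")
  expect_error(distance_matrix(c(a = "AC--", b = "--GT"), model = "p"),
               "undefined")
})

test_that("barcode-gap partitioning splits well-separated blocks", {
  set.seed(52)
  t1 <- rand_seq(200)
  t2 <- mutate_at(t1, sample(200, 30))  # ~15% inter-block distance
  blockA <- seq_family(t1, lapply(1:5, function(i) sample(200, 1)))
  blockB <- vapply(1:4, function(i) mutate_at(t2, sample(200, 1)), "")
  seqs <- c(blockA, setNames(blockB, sprintf("t%02d", 1:4)))
  dm <- distance_matrix(seqs, model = "p")
  parts <- abgd_partition(dm, Pmin = 0.02, Pmax = 0.02, steps = 1)
  expect_length(parts, 1L)
  g <- parts[[1]]$groups
  expect_equal(length(unique(g)), 2L)
  expect_equal(length(unique(g[names(blockA)])), 1L)
  expect_true(g[names(blockA)[1]] != g["t01"])

  # all-zero distances: one group at every prior
  zero <- distance_matrix(c(a = t1, b = t1, c = t1), model = "p")
  for (p in abgd_partition(zero))
    expect_equal(length(unique(p$groups)), 1L)

  expect_error(abgd_partition(dm, Pmin = 0, Pmax = 0.1), "grid")
})

test_that("group counts shrink as the prior grows and vanish beyond the max", {
  set.seed(53)
  for (rep in 1:3) {
    t1 <- rand_seq(150)
    fam <- lapply(1:3, function(i) mutate_at(t1, sample(150, 12 * i)))
    seqs <- c(t1, unlist(lapply(fam, function(f)
      c(f, mutate_at(f, sample(150, 1))))))
    names(seqs) <- sprintf("s%02d", seq_along(seqs))
    dm <- distance_matrix(seqs, model = "p")
    parts <- abgd_partition(dm, Pmin = 0.005, Pmax = 0.3, steps = 8)
    counts <- vapply(parts, function(p) length(unique(p$groups)), 0L)
    expect_true(all(diff(counts) <= 0))
    # a prior above the largest distance leaves a single group
    pmax_all <- max(dm$d)
    one <- abgd_partition(dm, Pmin = pmax_all + 0.01,
                          Pmax = pmax_all + 0.02, steps = 2)
    expect_true(all(vapply(one, function(p)
      length(unique(p$groups)), 0L) == 1L))
  }
})

test_that("haplotype collapsing merges identical sequences with counts", {
  expect_equal(nrow(collapse_haplotypes(character())), 0L)

  seqs <- c(z9 = "ACGT", a1 = "ACGT", b2 = "ACGT", c3 = "AGGT", a0 = "ACGT")
  h <- collapse_haplotypes(seqs)
  expect_equal(nrow(h), 2L)
  expect_equal(h$freq[h$seq == "ACGT"], 4L)
  expect_equal(h$label[h$seq == "ACGT"], "a0")  # lexicographically smallest
  expect_equal(h$label[h$seq == "AGGT"], "c3")

  hw <- collapse_haplotypes(c(x = "AAAA", y = "AAAA", z = "TTTT"),
                            counts = c(2L, 3L, 4L))
  expect_equal(sort(hw$freq), c(4L, 5L))
})

test_that("parsimony networks honour the connection limit and subdivide", {
  one <- parsimony_network(collapse_haplotypes(c(a = "ACGTACGT")))
  expect_equal(nrow(one$nodes), 1L)
  expect_equal(nrow(one$edges), 0L)

  # chain at distances 1 and 1 (ends at 2): path, no extra tie edge
  h <- collapse_haplotypes(c(a = "AAAAAA", b = "AAAAAT", c = "AAAATT"))
  net <- parsimony_network(h, limit = 5)
  expect_equal(nrow(net$msn_edges), 2L)
  expect_true(all(net$msn_edges$steps == 1L))
  expect_equal(nrow(net$edges), 2L)

  # two haplotypes at distance 3: connected under limit 5 via 2 inferred
  # nodes, disconnected under limit 2
  far <- collapse_haplotypes(c(a = "AAAAAA", b = "TTTAAA"))
  net5 <- parsimony_network(far, limit = 5)
  expect_equal(nrow(net5$msn_edges), 1L)
  expect_equal(net5$msn_edges$steps, 3L)
  expect_equal(sum(!net5$nodes$observed), 2L)
  expect_true(all(net5$nodes$freq[!net5$nodes$observed] == 0L))
  expect_equal(nrow(net5$edges), 3L)
  expect_true(all(net5$edges$steps == 1L))

  net2 <- parsimony_network(far, limit = 2)
  expect_equal(nrow(net2$msn_edges), 0L)
  g2 <- as_igraph(net2)
  expect_equal(igraph::components(g2)$no, 2L)
})

test_that("network node frequencies conserve the input sequence count", {
  set.seed(54)
  for (rep in 1:3) {
    t <- rand_seq(40)
    n <- sample(8:14, 1)
    seqs <- vapply(seq_len(n), function(i)
      mutate_at(t, sample(40, sample(0:3, 1))), "")
    names(seqs) <- sprintf("s%02d", seq_len(n))
    h <- collapse_haplotypes(seqs)
    net <- parsimony_network(h, limit = 10)
    expect_equal(sum(net$nodes$freq), n)
  }
})

test_that("the minimum spanning network contains a minimum spanning tree", {
  set.seed(55)
  for (rep in 1:4) {
    t <- rand_seq(30)
    seqs <- unique(vapply(1:8, function(i)
      mutate_at(t, sample(30, sample(0:4, 1))), ""))
    names(seqs) <- sprintf("h%02d", seq_along(seqs))
    h <- collapse_haplotypes(seqs)
    lim <- 30L  # everything connectable
    net <- parsimony_network(h, limit = lim)

    full <- expand.grid(i = seq_len(nrow(h)), j = seq_len(nrow(h)))
    full <- full[full$i < full$j, ]
    full$w <- mapply(function(i, j)
      sum(strsplit(h$seq[i], "")[[1]] != strsplit(h$seq[j], "")[[1]]),
      full$i, full$j)
    g_full <- igraph::graph_from_data_frame(
      data.frame(from = h$label[full$i], to = h$label[full$j]),
      directed = FALSE, vertices = h$label)
    igraph::E(g_full)$weight <- full$w
    g_msn <- as_igraph(net, subdivided = FALSE)

    w_full <- sum(igraph::E(igraph::mst(g_full))$weight)
    w_msn <- sum(igraph::E(igraph::mst(g_msn))$weight)
    expect_equal(w_msn, w_full)  # an MST of the data lives inside the MSN
  }
})

test_that("network and distance writers emit readable files", {
  h <- collapse_haplotypes(c(a = "AAAAAA", b = "AAAATT", c = "AAAAAT"))
  net <- parsimony_network(h, limit = 5)
  out <- tempfile()
  write_network(net, out)
  expect_true(file.exists(paste0(out, ".graphml")))
  expect_true(file.exists(paste0(out, ".dot")))

  dm <- distance_matrix(c(a = "AAAAAA", b = "AAAATT"), model = "p")
  f <- tempfile(fileext = ".tsv")
  write_distance_matrix(dm, f, phylip_header = TRUE)
  expect_equal(readLines(f)[1], "2")
  write_partitions(abgd_partition(dm, Pmin = 0.01, Pmax = 0.02, steps = 2),
                   tempfile())
})
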