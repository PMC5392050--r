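refs_fixture <- read_reference_fasta(table_fixture("synthetic_reference_set.fasta"))

test_that("annotated reference FASTA parses genus/species/clade fields", {
  expect_gte(nrow(refs_fixture), 8L)
  expect_true(all(c("name", "genus", "species", "clade", "seq") %in%
                    names(refs_fixture)))
  tj <- refs_fixture[refs_fixture$genus == "Trebouxia", ]
  expect_gte(nrow(tj), 3L)
  expect_true(all(tj$clade %in% c("A", "G", "I", "S")))
  expect_true(all(grepl("^[ACGT]+$", refs_fixture$seq)))

  # round trip
  f <- tempfile(fileext = ".fasta")
  write_reference_fasta(refs_fixture, f)
  back <- read_reference_fasta(f)
  expect_equal(back$seq, refs_fixture$seq)
  expect_equal(back$genus, refs_fixture$genus)
})

test_that("assignment picks the best reference and applies thresholds", {
  r1 <- refs_fixture[1, ]
  hit <- assign_taxon(r1$seq, refs_fixture)
  expect_equal(hit$best_ref, r1$name)
  expect_equal(hit$identity, 100)
  expect_equal(hit$coverage, 100)
  expect_equal(hit$status, "assigned")
  expect_equal(hit$genus, r1$genus)
  expect_equal(hit$species, r1$species)

  set.seed(41)
  t <- rand_seq(200)
  refs2 <- data.frame(name = c("X", "Y"), genus = c("Gx", "Gy"),
                      species = c("X sp.", "Y sp."), clade = c("A", "B"),
                      seq = c(mutate_at(t, 1:6), mutate_at(t, 101:116)))
  q <- t  # 97% to X (6 subs), 92% to Y (16 subs)
  hit2 <- assign_taxon(q, refs2)
  expect_equal(hit2$best_ref, "X")
  expect_equal(hit2$identity, 97)
  expect_equal(hit2$species, "X sp.")  # >= 97 keeps the species epithet

  # 90-97% identity: genus only, no species
  hit3 <- assign_taxon(mutate_at(t, seq(2, 200, by = 2)[1:8]), refs2,
                       min_identity = 90)
  expect_equal(hit3$status, "assigned")
  expect_true(is.na(hit3$species))

  # below the identity floor everywhere -> unassigned
  far <- rand_seq(200)
  hit4 <- assign_taxon(far, refs2)
  expect_equal(hit4$status, "unassigned")
  expect_true(is.na(hit4$genus))

  expect_error(assign_taxon("", refs2), "empty")
})

test_that("assignment is invariant to reference order", {
  set.seed(42)
  t <- rand_seq(150)
  refs2 <- data.frame(name = sprintf("R%d", 1:5),
                      genus = sprintf("G%d", 1:5),
                      species = sprintf("G%d sp.", 1:5),
                      clade = rep("A", 5),
                      seq = vapply(1:5, function(i)
                        mutate_at(t, sample(150, i * 2)), ""))
  q <- mutate_at(t, 1:3)
  base <- assign_taxon(q, refs2)
  for (i in 1:5) {
    perm <- sample(5)
    expect_equal(assign_taxon(q, refs2[perm, ]), base)
  }
})

test_that("abundance tables count reads per OTU and conserve column totals", {
  set.seed(43)
  t <- rand_seq(120)
  mk <- function(code, sizes) {
    seqs <- unlist(lapply(seq_along(sizes), function(i)
      rep(mutate_at(t, seq_len(i * 15)), sizes[i])))
    names(seqs) <- sprintf("%s_r%03d", code, seq_along(seqs))
    name_otus(cluster_reads(seqs, S = 0.99), code)
  }
  named <- list(HW = mk("HW", 10))
  ab <- abundance_table(named)
  expect_equal(unname(ab$counts[1, 1]), 10L)
  expect_equal(colnames(ab$counts), "HW")

  named2 <- list(HW = mk("HW", c(6, 3)), A = mk("A", c(5, 4, 2)))
  assn <- data.frame(otu = c(names(named2$HW), names(named2$A)),
                     genus = c("Trebouxia", "Asterochloris", "Trebouxia",
                               "Trebouxia", "Elliptochloris"))
  ab2 <- abundance_table(named2, assignments = assn)
  expect_equal(unname(colSums(ab2$counts)), c(9L, 11L))
  # genus aggregation conserves column totals
  expect_equal(colSums(ab2$genus_counts), colSums(ab2$counts))
  expect_equal(unname(colSums(ab2$genus_fractions)), c(1, 1))

  empty <- abundance_table(list())
  expect_equal(dim(empty$counts), c(0L, 0L))

  bad <- list(HW = structure(list(list(members = "r1", seqs = "A",
                                       name = "HW_only")),
                             class = "otu_cluster_set"))
  expect_error(abundance_table(bad), "malformed")
})

test_that("epithalline/intrathalline partition follows the precedence rule", {
  pres <- matrix(0L, nrow = 4, ncol = 5,
                 dimnames = list(c("Elliptochloris", "TR9", "OTU7", "OTU6"),
                                 c("HW", "MW", "A", "M", "B")))
  pres["Elliptochloris", "HW"] <- 1L            # washing only
  pres["TR9", c("HW", "A", "M", "B")] <- 1L     # everywhere, but core set
  pres["OTU7", c("HW", "B")] <- 1L              # washing + thallus
  pres["OTU6", c("A", "M", "B")] <- 1L          # thallus only
  lab <- partition_fractions(pres, washing_treatments = c("HW", "MW"),
                             thallus_treatments = c("A", "M", "B"),
                             core_intrathalline = "TR9")
  expect_equal(unname(lab["Elliptochloris"]), "epithalline")
  expect_equal(unname(lab["TR9"]), "intrathalline")
  expect_equal(unname(lab["OTU7"]), "epithalline-fraction")
  expect_equal(unname(lab["OTU6"]), "intrathalline")
  expect_equal(sort(names(lab)), sort(rownames(pres)))  # a partition

  pres["OTU6", ] <- 0L
  expect_error(partition_fractions(pres, c("HW", "MW"), c("A", "M", "B")),
               "no detections")
  expect_error(partition_fractions(pres[1:3, ], c("HW", "A"), c("A", "M")),
               "disjoint")
})

test_that("probe design finds discriminating k-mers and ranks them", {
  set.seed(44)
  target <- rand_seq(150)
  # an 'other' diverging only inside a 20-nt island at 61..80
  other <- mutate_at(target, c(65, 69, 72, 75, 79))
  probes <- design_probe(target, other, k = 20, min_mismatches = 3)
  expect_gt(nrow(probes), 0L)
  expect_true(all(probes$cross_mismatch >= 3))
  # every candidate must overlap enough of the island to see 3+ mismatches
  expect_true(all(probes$start >= 65 - 19 & probes$start <= 79))
  expect_equal(probes$cross_mismatch[1], max(probes$cross_mismatch))
  # verify the reported mismatch count for the top candidate by brute force
  top <- probes$primer[1]
  mm <- min(vapply(1:(nchar(other) - 19), function(s)
    sum(strsplit(top, "")[[1]] !=
          strsplit(substr(other, s, s + 19), "")[[1]]), 0L))
  expect_equal(probes$cross_mismatch[1], mm)

  expect_equal(nrow(design_probe(target, target, k = 20)), 0L)
  expect_error(design_probe(target, other, k = 200), "exceeds")
  expect_error(design_probe("", other), "empty")
})
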