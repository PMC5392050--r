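# phycodive

Desk-scale profiling of green-microalgal (photobiont) communities from
multiplexed ITS1-5.8S amplicon reads of lichen thalli.

A single lichen thallus can host several algal partners — typically one or
two dominant *Trebouxia* lineages and a tail of rare *Asterochloris* and
other chlorophytes, split between intrathalline (inside the thallus) and
epithalline (surface) fractions. This package implements, as explicit and
tested functions, the full computational chain that turns barcoded,
error-prone amplicon reads into that community description:

* **Read QC** — MID (barcode) demultiplexing, fixed-end trimming (18 nt
  from the 5' end, 22 nt from the 3' end), minimum-length filtering.
* **OTU clustering** — single-linkage clustering under joint thresholds on
  *score coverage* (identical positions / alignment columns excluding
  terminal gaps; default S ≥ 0.99) and *length coverage* (aligned span /
  longer sequence length; default L ≥ 0.9), computed from a global
  affine-gap alignment (match +1, mismatch −1, gap open −2, extension −1);
  singleton removal; weighted majority-rule consensus with IUPAC tie
  codes; threshold calibration on a reference panel; canonical OTU names
  `<treatment>_<cluster>_<nSeqs>`.
* **Taxonomy** — best-match assignment against a local annotated reference
  FASTA (≥ 90% identity, ≥ 95% coverage; species epithet only at ≥ 97%),
  OTU × treatment abundance tables, the epithalline/intrathalline washing
  partition, and discriminating-primer design.
* **Species delimitation & networks** — p/JC69/K2P distance matrices,
  recursive barcode-gap partitioning, and statistical-parsimony
  (minimum-spanning) haplotype networks with inferred intermediates.
* **Diversity** — Margalef `(S−1)/ln N`, Shannon `H' = −Σ p log2 p`
  (bits), reciprocal Simpson `1/Σ p²`, Pielou `J' = H'/log2 S`,
  rank-abundance curves, and the standard summary-table shapes.
* **Simulation** — a seeded 454-style read generator (per-taxon PCR bias,
  substitution errors, homopolymer-run indels, MID/primer decoration) so
  the whole pipeline runs and is tested with no external data.

## Worked example: a two-taxon mock community

```r
library(phycodive)

taxa <- make_taxa(n_taxa = 2, length = 250, min_divergence = 0.05, seed = 42)
spec <- community_spec(taxa, n_reads = 2000, seed = 42, sample = "Mock")
res  <- run_sample_pipeline(spec)   # demultiplex, trim 18/22, cluster, drop singletons
res$clusters
#> <otu_cluster_set> 2 clusters (S = 0.99, L = 0.9); sizes: 394, 364

otus <- name_otus(res$clusters, "Mock")
cons <- vapply(otus, consensus, "")
refs <- data.frame(name = c("T_jamesii", "T_asymmetrica"), genus = "Trebouxia",
                   species = c("Trebouxia jamesii", "Trebouxia asymmetrica"),
                   clade = c("S", "G"), seq = taxa$seq)
do.call(rbind, lapply(names(otus), function(nm)
  cbind(otu = nm, assign_taxon(cons[[nm]], refs)[, c("best_ref", "identity",
                                                     "coverage", "status")])))
#>         otu      best_ref identity coverage   status
#>  Mock_1_394     T_jamesii      100      100 assigned
#>  Mock_2_364 T_asymmetrica      100      100 assigned

round(diversity_report(vapply(otus, function(cl) length(cl$members), 0L)), 3)
#>  S   N   Dmg     H     D     J
#>  2 758 0.151 0.999 1.997 0.999
```

Reading the output: the simulator emitted 2000 reads under the default
error model (0.5% substitutions plus homopolymer indels); 1242 reads ended
up as singleton clusters of unique error patterns and were removed, and the
surviving reads form exactly the two expected OTUs, whose error-corrected
consensus sequences match their source taxa at 100% identity. The
diversity row shows an essentially even two-member community (`H'` ≈ 1 bit,
reciprocal Simpson ≈ 2, evenness ≈ 1). Amplification bias is modelled
separately as odds multipliers:

```r
apply_bias(c(0.5, 0.5), c(86 / 14, 1))
#> [1] 0.86 0.14
```

i.e. an equimolar mock input whose amplification odds favour one taxon
86:14 yields the skewed read fractions seen in real mock controls.

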