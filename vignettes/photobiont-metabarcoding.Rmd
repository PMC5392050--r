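---
title: "Profiling lichen photobiont communities from multiplexed amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling lichen photobiont communities from multiplexed amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycodive)
```

## The problem

Lichens host green-microalgal photosynthetic partners (photobionts), and a
single thallus can harbour several algal taxa at very uneven abundances: one
or two dominant *Trebouxia* lineages plus a tail of rare *Asterochloris* and
other chlorophytes, some living inside the thallus (intrathalline) and some
only on its surface (epithalline). Multiplexed ITS1-5.8S amplicon sequencing
resolves this community, but turning a pool of barcoded, error-prone reads
into a defensible OTU inventory takes a chain of decisions — demultiplexing,
trimming, clustering thresholds, singleton handling, consensus calling,
taxonomic assignment, species delimitation and diversity summaries — each of
which this package implements as an explicit, tested function.

Because the historical 454 read sets behind such studies are not available
at desk scale, the package also ships a seeded read simulator that emulates
the relevant features of that platform, so every downstream stage is
exercised end to end without any download.

## Pipeline overview

1. **Simulation** (`make_taxa()`, `community_spec()`, `simulate_reads()`) —
   synthetic reference taxa, community fractions with PCR amplification
   bias, and 454-style reads.
2. **Read QC** (`demultiplex()`, `trim_and_filter()`, `qc_report()`) — MID
   sorting, fixed-end trimming, length filtering.
3. **OTU clustering** (`pairwise_identity()`, `cluster_reads()`,
   `drop_singletons()`, `consensus()`, `calibrate()`, `name_otus()`).
4. **Taxonomy** (`assign_taxon()`, `abundance_table()`,
   `partition_fractions()`, `design_probe()`).
5. **Delimitation and networks** (`distance_matrix()`, `abgd_partition()`,
   `collapse_haplotypes()`, `parsimony_network()`).
6. **Diversity reporting** (`diversity_report()`, `rank_abundance()`,
   `assemble_tables()`).

`run_sample_pipeline()` chains stages 1-3 for one simulated sample.

## The read simulator

`simulate_reads()` emits reads laid out as `[MID][primer5][template with
errors][primer3]` on the forward strand only, matching a unidirectional
("one-way reads") amplicon protocol. The default MID is 10 nt and the
default forward primer fragment 8 nt, so the 18 bases removed by the default
5' trim are exactly the sequencing decorations; the default 3' context is 22
nt, the span of the default 3' trim. Quality strings are constant Q30 —
downstream stages never consult them, they only keep FASTQ/QUAL files valid.

Two error processes act on each template copy, in a documented RNG order
(taxon draw, then one homopolymer pass over maximal runs left to right, then
per-base substitutions), so a fixed seed reproduces the output byte for
byte:

* **Substitutions** at `sub_rate` per base (default 0.005), replacement base
  uniform over the three alternatives.
* **Homopolymer indels**, the platform's signature error class: a maximal
  run of length $k$ suffers an event with probability
  $\min(0.5,\; p_1 \cdot s^{k-1})$ (defaults $p_1 = 0.01$, $s = 1.5$), and
  an event inserts or deletes one repeat unit with equal probability.

The platform's true error rates at this marker were never published; these
defaults are placeholders of a plausible order of magnitude, chosen once and
not tuned. The simulator does **not** model chimeras, paired ends, flowgram
noise or quality-score decay, so passing recovery tests demonstrate the
pipeline's behaviour under substitution + homopolymer noise, not under every
artefact of real amplicon data.

**Amplification bias.** `apply_bias()` converts pre-PCR molar fractions
$f_i$ and per-taxon odds multipliers $b_i$ into read fractions
$f_i b_i / \sum_j f_j b_j$. An equimolar two-taxon mixture with an 86:14
odds ratio reproduces the read skew typical of mock-community controls —
the read fractions of a mock community are a property of amplification, not
of the input molarity.

## Read QC

`demultiplex()` assigns a read to the unique treatment whose MID exactly
prefixes it (the `mid_map()` constructor rejects prefix-nested barcode sets,
which would make this ambiguous). A Hamming-1 rescue exists behind a flag
and is off by default, matching vendor demultiplexer behaviour. State flags
on the read table make re-demultiplexing trimmed reads an error rather than
a silent mistake: after trimming, the barcode is gone.

`trim_and_filter()` is positional: 18 nt off the 5' end, 22 nt off the 3'
end, then a minimum core length. Trimming is deliberately not
primer-matching — the upstream protocol fixes the decoration lengths, and a
fixed trim is reproducible where fuzzy primer search is not. The default
`min_len = 150` is a typical final-alignment length for this marker; the
rule ("shorter than the final alignment") is principled, the number is a
configurable default. Only length-based rejections are reported; the
package makes no other "unreliable read" call because no reproducible
definition of one exists.

## OTU clustering

`pairwise_identity()` computes a global Needleman-Wunsch-Gotoh alignment
(match $+1$, mismatch $-1$, gap of length $k$ costs $2 + k$) and defines:

* **score coverage** $S$ = identical columns / alignment columns excluding
  terminal gaps;
* **length coverage** $L$ = alignment columns excluding terminal gaps /
  length of the longer sequence (capped at 1; highly divergent pairs can
  accumulate internal gap columns past the longer length).

The historical clustering tool's exact "score coverage" is underdocumented;
this definition is recorded here and in the code and behaves like the tool
on near-identical amplicons. The longer-sequence convention for $L$ is an
explicit choice (the alternative — the shorter sequence — is not exposed).
Arguments are ordered canonically before alignment so both measures are
exactly symmetric, and the scoring convention is verified in the test suite
against an independent aligner (`Biostrings::pairwiseAlignment`).

`cluster_reads()` links two reads when $S \ge 0.99$ **and** $L \ge 0.9$
(defaults) and takes connected components — single linkage, matching the
referenced tool's semantics; a greedy-centroid mode exists behind a flag for
comparison. Determinism: clusters are numbered by descending size, ties by
lexicographically smallest member id, so composition and naming are
invariant to input order.

Three exact accelerations keep the all-pairs scan tractable:

* **Dereplication** — identical reads always co-cluster under single
  linkage, so clustering runs on unique sequences weighted by multiplicity.
* **Banded alignment** — a pair can only link at $S \ge 0.97$ if it has at
  most a few edit columns, so the optimal path stays within a narrow band
  around the length-difference diagonal corridor (default pad 16). For
  pairs whose optimum leaves the band the banded identity can only be
  *under*-estimated, which cannot create a false link; true links are
  computed exactly.
* **8-mer screen** (enabled only at $S \ge 0.97$) — one substitution or
  one-base indel changes at most 8 distinct 8-mers, so a linkable pair
  shares at least $n_{\min} - 8\,e_{\max}$ distinct 8-mers, with
  $e_{\max}$ a generous bound on the edit count at threshold $S$. Pairs
  below that floor (or below the coarser 60%-shared screen) are skipped
  without alignment. Both screens are necessary conditions, so the result
  equals the brute-force link graph — which the test suite checks against
  a transitive-closure oracle on small instances.

`drop_singletons()` removes single-member clusters, mirroring the practice
of discarding unique sequences as unverifiable at this error rate.

**Consensus.** Members are dereplicated and weighted, a UPGMA guide tree is
built on pairwise score coverage, profiles are merged progressively with an
affine-gap profile aligner, and each column is called by weighted majority:
columns with more than 50% gap weight are dropped, and exact base ties are
encoded as IUPAC ambiguity codes (A/C → M, and so on). All tie-breaks are
deterministic.

**Calibration.** `calibrate()` clusters an annotated reference set across a
threshold ladder and picks the *lowest* threshold achieving the maximal
cluster count: anything higher separates no additional taxa but splits
homopolymer-damaged reads into extra singletons. This reproduces the
rationale for preferring 99% over 100% score coverage.

## Taxonomic assignment and the washing partition

`assign_taxon()` reuses the clustering identity definitions (one identity
definition across the package) against a local annotated reference FASTA —
a deliberate replacement for live database BLAST, whose results drift with
database versions. Defaults: assignment needs ≥ 90% identity and ≥ 95%
coverage; the species epithet is only reported at ≥ 97% identity, matches
between 90% and 97% carry the genus alone. The shipped
`synthetic_reference_set.fasta` contains synthetic stand-in sequences (the
file name says so) annotated with the genus/species/clade vocabulary of the
real reference panels.

`partition_fractions()` encodes the washing-experiment logic with an
explicit precedence: a verified intrathalline core set first (taxa known to
reside inside the thallus stay intrathalline even when washing water also
contains them), then washing-only → epithalline, washing + thallus →
epithalline fraction, thallus-only → intrathalline. The core-set precedence
is an interpretation of the verbal rule and is therefore injected as an
argument rather than hard-coded.

`design_probe()` ranks candidate forward primers (default 20-mers) by their
worst-case discrimination: the minimum mismatch count against every other
consensus, then the number of those mismatches in the five 3'-terminal
positions (3' mismatches suppress mispriming most). No thermodynamic
modelling is attempted.

## Species delimitation and haplotype networks

`distance_matrix()` supports p-distance, JC69 and K2P (default K2P), with
gapped sites excluded pairwise; corrections are delegated to
`ape::dist.dna()` and verified against closed forms in the tests. Undefined
pairs (no comparable sites, saturated corrections) raise errors rather than
propagating `NaN`.

`abgd_partition()` implements recursive barcode-gap discovery: for each
prior $P$ on a log grid (defaults 0.001-0.1 in 10 steps, the published
defaults of the procedure it simplifies), the sorted pairwise distances are
scanned for the first distance above $P$ whose spacing to its predecessor
exceeds $X = 1.5$ times the mean spacing below it; groups are components
under that gap and the rule recurses within groups. A candidate needs at
least two smaller distances so a mean spacing exists. This is a documented
simplification of the published procedure, which the source study cites but
does not restate; the test suite checks its invariants (monotone group
counts in $P$, collapse to one group above the distance maximum) rather
than equivalence to the original software.

`parsimony_network()` builds a minimum spanning network — Kruskal over
distance classes keeping every tie that joins two components as of the
start of its class — over haplotypes within a parsimony connection `limit`
(injected, default 10 steps; the 95% statistical-parsimony limit estimator
is intentionally not built in, so tests control the limit explicitly).
Multi-step edges are subdivided by inferred zero-frequency haplotypes, so
each drawn edge is one mutational step; pairs beyond the limit fall into
separate subnetworks. The network provably contains a minimum spanning
tree, which the tests verify against an independent MST.

## Diversity indices

For per-OTU counts with richness $S$ and total $N$:
$D_{mg} = (S-1)/\ln N$, $H' = -\sum_i p_i \log_2 p_i$,
$D' = 1/\sum_i p_i^2$, $J' = H'/\log_2 S$ (0 when $S = 1$).

Two conventions are forced by the published report format this reproduces:

* **Shannon in bits.** A published row with $H' = 3.13$ at $S = 18$ is
  impossible in nats ($\ln 18 \approx 2.89 < 3.13$), and base 2 makes
  every published evenness equal $H'/\log_2 S$ within rounding of the
  2-dp inputs. A `log_base` argument still allows nats, clearly labelled.
* **Simpson as reciprocal** ($1/\sum p_i^2$), since published values
  exceed 1 throughout.

Margalef uses the natural log with $N$ = the treatment's retained read
count, the only reading consistent with the one published cell whose $N$
is printed alongside. Several other published Margalef cells are mutually
inconsistent with any single $N$ under this formula; the implementation
follows the formula and does not fit those cells. Shannon and inverse
Simpson are computed by `vegan::diversity()`; the tests hold them against
direct formula evaluation.

`assemble_tables()` produces the report shapes (sequencing summary,
OTU-by-treatment counts with nonzero-OTU totals, all-genera and
genus-restricted diversity tables); genus-restricted rows recompute the
indices on that genus's counts alone.

## Problem sizes used in the checks

The packaged checks run at deliberately desk-scale sizes, chosen once: the
two-taxon mock community at 2000 reads (1000 per taxon) and the
single-culture runs at 1000-2000 reads, both under the default error model;
threshold calibration on 23 synthetic references; and the $k$-taxon
recovery sweep at $k = 2..6$, 100 reads per taxon, 20 seeds per $k$, on
error-free reads. Error-free reads are the condition under which exact
$k$-OTU recovery is a theorem rather than a tendency: under the default
error model the same sweep occasionally (roughly one run in six at this
depth) produces one extra non-singleton cluster when two reads draw the
same multi-error pattern — at 1000 reads per taxon the denser link graph
absorbs these, which is exactly why singleton removal alone suffices there.

## Known limitations

* The simulator omits chimeras, strand artefacts and quality decay; real
  454 data would add error classes the recovery tests do not probe.
* The barcode-gap rule and the "score coverage" definition are documented
  reconstructions, not re-implementations of the historical binaries.
* All-pairs clustering is quadratic in unique sequences; tens of thousands
  of unique reads per sample are beyond its intended scale.
* Taxonomic assignment is only as good as the local reference set; the
  shipped references are synthetic stand-ins for tests and examples, not
  curated biology.
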