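#' Run the read-to-OTU pipeline on one simulated sample
#'
#' Convenience wrapper chaining the full preprocessing and clustering path
#' on a simulated community: simulate multiplexed reads, demultiplex by
#' MID, trim the fixed ends (18 nt from the 5' end covering MID plus
#' sequencing primer, 22 nt from the 3' end), drop short cores, cluster at
#' the score-/length-coverage thresholds and remove singleton clusters.
#'
#' @param spec a [community_spec].
#' @param err an [error_model].
#' @param S,L clustering thresholds (defaults 0.99 / 0.9).
#' @param n5,n3,min_len trimming parameters, see [trim_and_filter()].
#' @return A list with `clusters` (non-singleton `otu_cluster_set`),
#'   `n_singletons`, `n_otus`, `qc` (the [qc_report()]) and `reads` (the
#'   retained trimmed reads).
#' @export
run_sample_pipeline <- function(spec, err = error_model(), S = 0.99,
                                L = 0.9, n5 = 18L, n3 = 22L,
                                min_len = 150L) {
  reads <- simulate_reads(spec, err)
  mids <- mid_map(spec$mid, spec$sample)
  dmx <- demultiplex(reads, mids)
  tf <- trim_and_filter(dmx$assigned[[spec$sample]], n5 = n5, n3 = n3,
                        min_len = min_len)
  qc <- qc_report(dmx, setNames(list(tf), spec$sample), n5 = n5, n3 = n3,
                  min_len = min_len)
  cl <- cluster_reads(tf$retained, S = S, L = L)
  ds <- drop_singletons(cl)
  list(clusters = ds$clusters, n_singletons = ds$n_singletons,
       n_otus = length(ds$clusters), qc = qc, reads = tf$retained)
}

#' Count OTUs recovered from a simulated k-taxon community
#'
#' Simulates a community of `n_taxa` synthetic taxa at the given minimum
#' pairwise divergence, runs the full pipeline
#' (demultiplex, trim 18/22, cluster, drop singletons) and returns the
#' number of non-singleton OTUs recovered. Used to verify that the
#' pipeline recovers exactly one OTU per sufficiently diverged taxon.
#'
#' @param n_taxa number of community members.
#' @param reads_per_taxon reads simulated per taxon (total reads =
#'   `n_taxa * reads_per_taxon`, equimolar, no amplification bias).
#' @param divergence minimum pairwise taxon divergence (fraction).
#' @param length template length in bases.
#' @param seed RNG seed for both taxon generation and read simulation.
#' @param err an [error_model].
#' @param ... passed to [run_sample_pipeline()].
#' @return Number of non-singleton OTU clusters (integer).
#' @export
recover_otus <- function(n_taxa, reads_per_taxon = 100L, divergence = 0.03,
                         length = 250L, seed = 1L, err = error_model(),
                         ...) {
  taxa <- make_taxa(n_taxa, length, divergence, seed = seed)
  spec <- community_spec(taxa, n_reads = n_taxa * reads_per_taxon,
                         seed = seed)
  run_sample_pipeline(spec, err = err, ...)$n_otus
}
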