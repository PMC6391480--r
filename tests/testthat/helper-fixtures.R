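# Shared fixtures, built in code.

# A tiny hand-checkable partition: chr1 of length 100 with two core TADs.
tiny_partition <- function() {
  cm <- chrom_map("chr1", 100)
  tads <- genomic_intervals(c("chr1", "chr1"), c(10, 50), c(30, 80))
  build_partition(tads, cm)
}

# Calibration configuration: gap-free TAD chains with narrow length spread
# and GR domains every 6th TAD, so the five domains of each center/flank
# set are exchangeable under the null and sets are disjoint. See the
# methods vignette for the rationale.
calibration_config <- function(seed, n_chromosomes = 10) {
  simulation_config(seed = seed, n_chromosomes = n_chromosomes,
                    n_core_tads = 607, tad_sdlog = 0.2, gap_meanlog = NULL,
                    telomere_length = 0, centromere_length = 0,
                    gr_placement = "spaced", gr_spacing = 6)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
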