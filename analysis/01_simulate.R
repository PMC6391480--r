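# Generate the synthetic study inputs: a TAD partition with GR-bearing
# domains, a six-cluster differential table, H3K27ac-like feature
# placements enriched in GR domains, and region sequences with planted
# GRE instances. Everything downstream reads these files.

source("analysis/00_config.R")

sim <- simulate_partition(STUDY_CFG)
part <- sim$partition
cls <- S4Vectors::mcols(part)$domain_class

# chrom.sizes + typed partition + core-TAD call set
writeLines(paste(GenomeInfoDb::seqnames(sim$chrom_map),
                 GenomeInfoDb::seqlengths(sim$chrom_map), sep = "\t"),
           file.path(DATA_DIR, "genome.chrom.sizes"))
part_out <- part
S4Vectors::mcols(part_out)$id <- paste0(
  S4Vectors::mcols(part)$domain_id, "|", cls)
write_bed(part_out, file.path(DATA_DIR, "partition.bed"))
core <- part[cls == "core_tad"]
S4Vectors::mcols(core)$id <- S4Vectors::mcols(core)$domain_id
write_bed(core, file.path(DATA_DIR, "core_tads.bed"))
write_bed(sim$gr_peaks, file.path(DATA_DIR, "gr_peaks.bed"))
writeLines(sim$gr_domains, file.path(DATA_DIR, "gr_domains.txt"))

# differential table + ground truth
diff <- simulate_differential_table(STUDY_CFG)
write_differential_table(diff$stats, file.path(DATA_DIR, "differential.tsv"))
write.table(diff$truth, file.path(DATA_DIR, "differential_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# feature placements (a quarter induced, the rest non-responsive)
feats <- simulate_features(part, sim$gr_domains,
                           n_induced = round(STUDY_CFG$n_features / 4),
                           n_background = round(3 * STUDY_CFG$n_features / 4),
                           theta = STUDY_CFG$enrichment_odds, seed = SEED)
write_bed(feats, file.path(DATA_DIR, "h3k27ac_peaks.bed"))
write.table(data.frame(id = S4Vectors::mcols(feats)$id,
                       label = S4Vectors::mcols(feats)$label),
            file.path(DATA_DIR, "h3k27ac_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# region sequences with planted GREs
sq <- simulate_sequences(STUDY_CFG)
Biostrings::writeXStringSet(sq$sequences, file.path(DATA_DIR, "regions.fa"))
write.table(sq$truth, file.path(DATA_DIR, "sequence_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
# background sequences: same model, nothing planted
bg_cfg <- STUDY_CFG; bg_cfg$motif_plant_fraction <- 0; bg_cfg$seed <- SEED + 1
bg <- simulate_sequences(bg_cfg)
Biostrings::writeXStringSet(bg$sequences,
                            file.path(DATA_DIR, "background.fa"))

msg("simulated %d domains (%d core TADs, %d inter-TADs), %d GR domains",
    length(part), sum(cls == "core_tad"), sum(cls == "inter_tad"),
    length(sim$gr_domains))
msg("wrote synthetic inputs under %s", DATA_DIR)
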