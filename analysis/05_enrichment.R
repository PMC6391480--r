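# The core statistics: select GR-bearing center domains with GR-free
# flanks, run the adjacent-domain strict-maximum binomial test for induced
# features, and the hypergeometric test for concentration of induced
# features in GR-bearing domains.

source("analysis/00_config.R")

counts <- read.table(file.path(OUT_DIR, "domain_counts.tsv"), header = TRUE,
                     sep = "\t")
cm <- read_chrom_sizes(file.path(DATA_DIR, "genome.chrom.sizes"))
full <- read_bed(file.path(DATA_DIR, "partition.bed"))
typed <- sub("^.*\\|", "", S4Vectors::mcols(full)$id)
strip <- function(x) { S4Vectors::mcols(x) <- NULL; x }
core <- read_bed(file.path(DATA_DIR, "core_tads.bed"))
part <- build_partition(core, cm,
                        centromeres = strip(full[typed == "centromere"]),
                        telomeres = strip(full[typed == "telomere"]))
gr_domains <- readLines(file.path(DATA_DIR, "gr_domains.txt"))

sets <- select_center_domains(part, gr_domains)
num <- setNames(counts$H3K27ac.induced, counts$domain_id)
den <- setNames(counts$total_H3K27ac, counts$domain_id)
adj <- adjacent_tad_test(sets, num, den)
print(adj)

lab <- read.table(file.path(DATA_DIR, "h3k27ac_labels.tsv"), header = TRUE,
                  sep = "\t")
feats <- read_bed(file.path(DATA_DIR, "h3k27ac_peaks.bed"),
                  feature_class = "H3K27ac", chrom_map = cm)
assignment <- assign_to_domains(feats, part)
hyper <- domain_hypergeometric_enrichment(
  assignment, lab$id[lab$label == "induced"], gr_domains)

jsonlite::write_json(list(
  adjacent = list(n_sets = adj$n_sets, n_successes = adj$n_successes,
                  null_probability = adj$null_probability,
                  p_value = adj$p_value),
  hypergeometric = hyper
), file.path(OUT_DIR, "enrichment.json"), auto_unbox = TRUE, digits = NA)
write.table(adj$detail, file.path(OUT_DIR, "adjacent_detail.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

msg("%d GR-bearing TADs with GR-free double flanks; %d/%d strict maxima",
    adj$n_sets, adj$n_successes, adj$n_sets)
msg("adjacent-TAD binomial p = %.3g; hypergeometric p = %.3g (%.0f%% of %d induced in GR TADs)",
    adj$p_value, hyper$p_value, 100 * hyper$fraction_in_marked,
    hyper$n_draws)
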