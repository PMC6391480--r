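# Assign features to domains by the midpoint rule, build the per-domain
# count matrix, and run the proximity analyses: GR peaks near induced
# features (edge-to-edge, 500 bp), GR peak pairs within 30 kb, and the
# GR-in-open-chromatin overlap fraction.

source("analysis/00_config.R")

cm <- read_chrom_sizes(file.path(DATA_DIR, "genome.chrom.sizes"))
full <- read_bed(file.path(DATA_DIR, "partition.bed"))
typed <- sub("^.*\\|", "", S4Vectors::mcols(full)$id)
strip <- function(x) { S4Vectors::mcols(x) <- NULL; x }
core <- read_bed(file.path(DATA_DIR, "core_tads.bed"))
part <- build_partition(core, cm,
                        centromeres = strip(full[typed == "centromere"]),
                        telomeres = strip(full[typed == "telomere"]))

feats <- read_bed(file.path(DATA_DIR, "h3k27ac_peaks.bed"),
                  feature_class = "H3K27ac", chrom_map = cm)
lab <- read.table(file.path(DATA_DIR, "h3k27ac_labels.tsv"), header = TRUE,
                  sep = "\t")
gr_peaks <- read_bed(file.path(DATA_DIR, "gr_peaks.bed"),
                     feature_class = "GR_peak", chrom_map = cm)

assignment <- assign_to_domains(feats, part)
ft <- data.frame(id = S4Vectors::mcols(feats)$id,
                 feature_class = "H3K27ac",
                 label = lab$label[match(S4Vectors::mcols(feats)$id,
                                         lab$id)])
counts <- domain_count_matrix(assignment, ft, part)
write.table(counts, file.path(OUT_DIR, "domain_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

induced <- feats[ft$label == "induced"]
near <- features_within(gr_peaks, induced, 500)
cp <- close_pairs(gr_peaks, 30000)
write.table(cp$pairs, file.path(OUT_DIR, "gr_close_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ov <- overlap_fraction(gr_peaks, feats)

jsonlite::write_json(list(
  n_features = length(feats),
  n_domains_with_induced = sum(counts$H3K27ac.induced > 0),
  gr_near_induced_500bp = length(unique(near$a_id)),
  gr_close_pairs_30kb = nrow(cp$pairs),
  gr_multi_peak_loci = length(unique(stats::na.omit(cp$loci$locus))),
  gr_overlap_fraction = ov
), file.path(OUT_DIR, "assignment_summary.json"), auto_unbox = TRUE,
  digits = NA)

msg("%d/%d GR peaks lie within 500 bp of an induced feature",
    length(unique(near$a_id)), length(gr_peaks))
msg("%d GR peak pairs within 30 kb in %d multi-peak loci; overlap fraction %.2f",
    nrow(cp$pairs), length(unique(stats::na.omit(cp$loci$locus))), ov)
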