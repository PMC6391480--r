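# Integrate the datasets in a hypothesis-free way at the TAD level:
# pairwise Spearman correlations of per-domain counts (induced features,
# non-responsive features, totals, GR occupancy) and average-linkage
# clustering on 1 - rho.

source("analysis/00_config.R")

counts <- read.table(file.path(OUT_DIR, "domain_counts.tsv"), header = TRUE,
                     sep = "\t")
gr_domains <- readLines(file.path(DATA_DIR, "gr_domains.txt"))

mat <- cbind(
  H3K27ac_induced = counts$H3K27ac.induced,
  H3K27ac_stable = counts$H3K27ac.ns,
  H3K27ac_total = counts$total_H3K27ac,
  GR_binding = as.integer(counts$domain_id %in% gr_domains))
rownames(mat) <- counts$domain_id

sc <- spearman_cluster(mat)
write.table(round(sc$correlation, 4),
            file.path(OUT_DIR, "tad_spearman_correlation.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
if (!is.null(sc$hclust)) {
  writeLines(dendrogram_newick(sc$hclust),
             file.path(OUT_DIR, "tad_clustering.nwk"))
}

msg("Spearman rho (induced vs GR binding): %.3f",
    sc$correlation["H3K27ac_induced", "GR_binding"])
msg("Spearman rho (induced vs stable):     %.3f",
    sc$correlation["H3K27ac_induced", "H3K27ac_stable"])
msg("dendrogram: %s", dendrogram_newick(sc$hclust))
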