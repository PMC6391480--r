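# Scan the region sequences for the GRE consensus (GRACANNNTGTYC) and the
# steroid receptor half-site (CCNGGNACA), compute frequency-difference
# enrichment against the background set, and the 40 x 20 bp positional
# density of GRE hits around region centers.

source("analysis/00_config.R")

seqs <- Biostrings::readDNAStringSet(file.path(DATA_DIR, "regions.fa"))
bg <- Biostrings::readDNAStringSet(file.path(DATA_DIR, "background.fa"))

out <- list()
for (motif in list(gre_motif(), steroid_half_site())) {
  hits <- scan_motif(seqs, motif)
  hits_bg <- scan_motif(bg, motif)
  tf <- region_hit_frequency(hits, names(seqs))
  bf <- region_hit_frequency(hits_bg, names(bg))
  out[[motif$name]] <- list(target_frequency = tf,
                            background_frequency = bf,
                            enrichment = motif_enrichment(tf, bf),
                            n_hits = nrow(hits))
  msg("%s: %.1f%% of targets, %.1f%% of background (enrichment %+.2f)",
      motif$name, 100 * tf, 100 * bf, motif_enrichment(tf, bf))
}

gre_hits <- scan_motif(seqs, gre_motif())
dens <- positional_density(gre_hits,
                           setNames(Biostrings::width(seqs), names(seqs)),
                           gre_motif()$length)
write.table(dens, file.path(OUT_DIR, "gre_positional_density.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(out, file.path(OUT_DIR, "motif_enrichment.json"),
                     auto_unbox = TRUE, digits = NA)

center_mass <- sum(dens$count[dens$lower >= -100 & dens$upper <= 100]) /
  max(1, sum(dens$count))
msg("GRE density: %.0f%% of in-span hits within 100 bp of region centers",
    100 * center_mass)
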