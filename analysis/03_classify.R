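# Classify the differential table into treatment-response directions and
# the six clusters obtained by crossing the treatment response with the
# differentiation dynamic, then tabulate Venn overlaps and stratification.

source("analysis/00_config.R")

stats <- read_differential_table(file.path(DATA_DIR, "differential.tsv"))
labels <- classify_responses(stats)
write.table(labels, file.path(OUT_DIR, "response_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

strat <- stratification_table(labels)
venn_up <- venn_counts(labels$id[!is.na(labels$ta_mo) & labels$ta_mo == "up"],
                       labels$id[!is.na(labels$ta_mf) & labels$ta_mf == "up"])
venn_down <- venn_counts(
  labels$id[!is.na(labels$ta_mo) & labels$ta_mo == "down"],
  labels$id[!is.na(labels$ta_mf) & labels$ta_mf == "down"])

jsonlite::write_json(list(
  totals = as.list(attr(strat, "totals")),
  clusters = strat,
  venn_up = as.list(venn_up),
  venn_down = as.list(venn_down)
), file.path(OUT_DIR, "classification.json"), auto_unbox = TRUE, digits = NA)

# check against planted truth
truth <- read.table(file.path(DATA_DIR, "differential_truth.tsv"),
                    header = TRUE, sep = "\t")
called <- ifelse(is.na(labels$cluster), 0L, labels$cluster)
msg("responsive features: %d of %d; planted-label agreement %.1f%%",
    unname(attr(strat, "totals")["responsive"]), nrow(stats),
    100 * mean(called == truth$cluster))
up <- strat[strat$direction == "up", ]
msg("of the up-regulated: %.0f%% Mf-high, %.0f%% static, %.0f%% Mo-high",
    up$pct_within_direction[1], up$pct_within_direction[2],
    up$pct_within_direction[3])
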