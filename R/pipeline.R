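#' Run the TAD-integration pipeline end to end
#'
#' Executes the stages in dependency order — simulate (or load) inputs,
#' build the partition, classify differential features, assign features to
#' domains and count, run the adjacent-domain and hypergeometric enrichment
#' tests, scan motifs, and correlate datasets at the TAD level — writing
#' every derived artifact under `out_dir` and recording an ordered manifest
#' (stage, role, path, md5 checksum, parameters). Rerunning with an
#' identical config reproduces identical checksums.
#'
#' With the default synthetic mode all inputs are generated from the
#' config seed. A stage failure aborts with the stage name in the message.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim_config A [simulation_config()]; its seed drives every
#'   stochastic stage.
#' @param thresholds A [response_thresholds()].
#' @param adj_config An [adjacent_tad_config()].
#' @param motifs List of [consensus_motif()] objects to scan.
#' @return Invisibly, a list with `manifest` (data.frame) and `results`
#'   (per-stage R objects).
#' @export
run_pipeline <- function(out_dir,
                         sim_config = simulation_config(),
                         thresholds = response_thresholds(),
                         adj_config = adjacent_tad_config(),
                         motifs = list(gre_motif(), steroid_half_site())) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(), role = character(),
                         path = character(), md5 = character())
  note <- function(stage, role, path) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, role = role, path = path,
      md5 = unname(tools::md5sum(path))))
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list()

  run_stage("simulate", function() {
    sim <- simulate_partition(sim_config)
    diff <- simulate_differential_table(sim_config)
    seqs <- simulate_sequences(sim_config, motifs[[1]])
    results$sim <<- sim; results$diff <<- diff; results$seqs <<- seqs
    p <- file.path(out_dir, "partition.bed")
    part_out <- sim$partition
    S4Vectors::mcols(part_out)$id <- paste0(
      S4Vectors::mcols(part_out)$domain_id, "|",
      S4Vectors::mcols(part_out)$domain_class)
    write_bed(part_out, p); note("simulate", "output", p)
    if (length(sim$gr_peaks)) {
      p <- file.path(out_dir, "gr_peaks.bed")
      write_bed(sim$gr_peaks, p); note("simulate", "output", p)
    }
    p <- file.path(out_dir, "differential.tsv")
    write_differential_table(diff$stats, p); note("simulate", "output", p)
    p <- file.path(out_dir, "regions.fa")
    Biostrings::writeXStringSet(seqs$sequences, p)
    note("simulate", "output", p)
  })

  run_stage("classify", function() {
    labels <- classify_responses(results$diff$stats, thresholds)
    results$labels <<- labels
    p <- file.path(out_dir, "labels.tsv")
    utils::write.table(labels, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("classify", "output", p)
    strat <- stratification_table(labels)
    p <- file.path(out_dir, "stratification.json")
    jsonlite::write_json(list(clusters = strat,
                              totals = as.list(attr(strat, "totals"))),
                         p, auto_unbox = TRUE, digits = NA)
    note("classify", "output", p)
  })

  run_stage("assign_count", function() {
    sim <- results$sim
    feats <- simulate_features(sim$partition, sim$gr_domains,
                               n_induced = round(sim_config$n_features / 4),
                               n_background =
                                 round(3 * sim_config$n_features / 4),
                               theta = sim_config$enrichment_odds,
                               seed = sim_config$seed,
                               feature_width = sim_config$feature_width)
    assignment <- assign_to_domains(feats, sim$partition)
    ft <- data.frame(id = S4Vectors::mcols(feats)$id,
                     feature_class = S4Vectors::mcols(feats)$feature_class,
                     label = S4Vectors::mcols(feats)$label)
    counts <- domain_count_matrix(assignment, ft, sim$partition)
    results$features <<- feats
    results$assignment <<- assignment
    results$counts <<- counts
    p <- file.path(out_dir, "domain_counts.tsv")
    utils::write.table(counts, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("assign_count", "output", p)
  })

  run_stage("enrichment", function() {
    sim <- results$sim
    counts <- results$counts
    sets <- select_center_domains(sim$partition, sim$gr_domains,
                                  config = adj_config)
    num <- stats::setNames(counts$H3K27ac.induced, counts$domain_id)
    den <- stats::setNames(counts$total_H3K27ac, counts$domain_id)
    adj <- adjacent_tad_test(sets, num, den, adj_config)
    ft <- results$features
    hyper <- domain_hypergeometric_enrichment(
      results$assignment,
      S4Vectors::mcols(ft)$id[S4Vectors::mcols(ft)$label == "induced"],
      sim$gr_domains)
    results$adjacent <<- adj
    results$hypergeometric <<- hyper
    p <- file.path(out_dir, "enrichment.json")
    jsonlite::write_json(
      list(adjacent = list(n_sets = adj$n_sets,
                           n_successes = adj$n_successes,
                           null_probability = adj$null_probability,
                           p_value = adj$p_value,
                           detail = adj$detail),
           hypergeometric = hyper),
      p, auto_unbox = TRUE, digits = NA)
    note("enrichment", "output", p)
  })

  run_stage("motifs", function() {
    seqs <- results$seqs
    out <- lapply(motifs, function(m) {
      hits <- scan_motif(seqs$sequences, m)
      list(motif = m, hits = hits,
           frequency = region_hit_frequency(hits, names(seqs$sequences)))
    })
    results$motifs <<- out
    p <- file.path(out_dir, "motif_hits.tsv")
    all_hits <- do.call(rbind, lapply(out, function(x) {
      if (nrow(x$hits)) cbind(motif = x$motif$name, x$hits) else NULL
    }))
    if (is.null(all_hits)) {
      all_hits <- data.frame(motif = character(), region_id = character(),
                             offset = integer(), strand = character(),
                             match = character())
    }
    utils::write.table(all_hits, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("motifs", "output", p)
    p <- file.path(out_dir, "motif_frequencies.json")
    jsonlite::write_json(
      stats::setNames(lapply(out, function(x) x$frequency),
                      vapply(out, function(x) x$motif$name, character(1))),
      p, auto_unbox = TRUE, digits = NA)
    note("motifs", "output", p)
  })

  run_stage("correlate", function() {
    counts <- results$counts
    mat <- as.matrix(counts[, setdiff(names(counts), "domain_id")])
    rownames(mat) <- counts$domain_id
    sc <- spearman_cluster(mat)
    results$correlation <<- sc
    p <- file.path(out_dir, "correlation.tsv")
    utils::write.table(round(sc$correlation, 6), p, sep = "\t",
                       quote = FALSE, col.names = NA)
    note("correlate", "output", p)
  })

  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(stages = manifest,
         parameters = list(
           seed = sim_config$seed,
           thresholds = unclass(thresholds),
           adjacent = unclass(adj_config),
           motifs = vapply(motifs, function(m) m$pattern, character(1)))),
    mp, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results))
}
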