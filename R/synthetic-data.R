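## Derive an integer seed < 2^31 from (seed, call tag) so each generator
## consumes its own stream and adding a generator never perturbs another's
## output.
stream_seed <- function(seed, tag) {
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483629
  as.integer((abs(seed) * 48271 + h) %% 2147483629)
}

## Evaluate expr under a tag-derived seed, restoring the caller's RNG state.
with_stream <- function(seed, tag, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(stream_seed(seed, tag))
  expr
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the shapes
#' of the motivating study at roughly one-third genome scale: ~1,200 core
#' TADs with log-normal lengths (median 500 kb), a wide-spread inter-TAD
#' complement including many ~10 kb interstitial gaps, per-chromosome
#' telomeres and one centromere, a minority of GR-bearing TADs, features of
#' ~600 bp (the H3K27ac peak scale), a six-cluster differential table with
#' cluster proportions taken from the reported stratification percentages,
#' and 200 bp region sequences with a consensus motif planted in a stated
#' fraction.
#'
#' @param seed Master seed; every generator derives its own stream from it.
#' @param n_chromosomes,n_core_tads Chromosome count and core TADs per
#'   chromosome.
#' @param tad_meanlog,tad_sdlog Log-normal TAD length parameters (bp).
#' @param gap_meanlog,gap_sdlog Log-normal inter-TAD gap parameters; set
#'   `gap_meanlog = NULL` for gap-free TAD chains (used by the calibration
#'   harness, where exchangeability of adjacent domains is required).
#' @param telomere_length,centromere_length Annotation lengths in bp; set
#'   to 0 to omit.
#' @param gr_domain_fraction Fraction of core TADs flagged GR-bearing.
#' @param gr_placement `"random"` or `"spaced"` (every `gr_spacing`-th core
#'   TAD; gives disjoint, independent center/flank sets).
#' @param gr_spacing Spacing for `"spaced"` placement.
#' @param gr_peak_width Width of the synthetic GR peak placed at each
#'   GR domain's midpoint.
#' @param n_features Total features placed by [simulate_features()] when a
#'   count is not given explicitly.
#' @param enrichment_odds Placement odds theta (>= 1) of induced features
#'   in GR domains; 1 is the exact null.
#' @param feature_width Feature interval width in bp (default 600).
#' @param n_diff_features Rows of the simulated differential table.
#' @param cluster_proportions Length-6 vector of cluster probabilities
#'   (sum <= 1; remainder is unresponsive). Default crosses a 20%
#'   responsive rate with the reported up/down split and the within-
#'   direction differentiation percentages (up: 51/32/17 Mf-high/static/
#'   Mo-high; down: 16/27/57).
#' @param effect_size_log2fc,stat_noise_sd Planted log2FC effect and noise.
#' @param shared_response_fraction Fraction of responsive features
#'   significant in both cell types (same sign).
#' @param expressed_fraction Fraction of unresponsive features above the
#'   expression floor.
#' @param n_sequences,sequence_length,motif_plant_fraction Sequence
#'   simulation: number, length (bp) and planted-motif fraction.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 8,
                              n_core_tads = 150,
                              tad_meanlog = log(5e5), tad_sdlog = 0.6,
                              gap_meanlog = log(3e4), gap_sdlog = 1.8,
                              telomere_length = 1e4,
                              centromere_length = 3e6,
                              gr_domain_fraction = 0.1,
                              gr_placement = c("random", "spaced"),
                              gr_spacing = 6,
                              gr_peak_width = 200,
                              n_features = 20000,
                              enrichment_odds = 4,
                              feature_width = 600,
                              n_diff_features = 10000,
                              cluster_proportions = c(
                                0.2 * 0.574 * c(0.51, 0.32, 0.17),
                                0.2 * 0.426 * c(0.16, 0.27, 0.57)),
                              effect_size_log2fc = 2,
                              stat_noise_sd = 0.25,
                              shared_response_fraction = 0.2,
                              expressed_fraction = 0.7,
                              n_sequences = 2000,
                              sequence_length = 200,
                              motif_plant_fraction = 0.3) {
  gr_placement <- match.arg(gr_placement)
  stopifnot(length(cluster_proportions) == 6,
            all(cluster_proportions >= 0),
            sum(cluster_proportions) <= 1 + 1e-12,
            enrichment_odds >= 1,
            gr_domain_fraction >= 0, gr_domain_fraction <= 1,
            motif_plant_fraction >= 0, motif_plant_fraction <= 1,
            expressed_fraction >= 0, expressed_fraction <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a genome partition with GR-bearing domains
#'
#' Core TAD lengths are drawn from the configured log-normal and laid down
#' sequentially, separated by log-normal inter-TAD gaps (which the
#' partition builder turns into `inter_tad` domains); a telomere caps each
#' chromosome end and one centromere sits mid-chromosome. Chromosome length
#' is the sum of the pieces. A fraction of core TADs is then flagged as
#' GR-bearing and one synthetic GR peak is placed at each such domain's
#' midpoint. Fully reproducible from the config seed.
#'
#' @param config A [simulation_config()].
#' @return List with `partition` (from [build_partition()]), `chrom_map`,
#'   `gr_domains` (character `domain_id`s), and `gr_peaks` (`GRanges`).
#' @export
simulate_partition <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_stream(config$seed, "partition", {
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    core <- list(); cen <- list(); tel <- list(); lens <- numeric()
    for (ci in seq_along(chroms)) {
      n <- config$n_core_tads
      tad_len <- ceiling(stats::rlnorm(n, config$tad_meanlog,
                                       config$tad_sdlog))
      gap_len <- if (is.null(config$gap_meanlog)) {
        rep(0, n + 1)
      } else {
        ceiling(stats::rlnorm(n + 1, config$gap_meanlog, config$gap_sdlog))
      }
      half <- floor(n / 2)
      body_len <- as.vector(rbind(gap_len[seq_len(n)], tad_len))
      body_type <- rep(c("gap", "tad"), n)
      if (config$centromere_length > 0) {
        at <- 2 * half
        body_len <- c(body_len[seq_len(at)], gap_len[n + 1],
                      config$centromere_length,
                      body_len[seq.int(at + 1, 2 * n)])
        body_type <- c(body_type[seq_len(at)], "gap", "cen",
                       body_type[seq.int(at + 1, 2 * n)])
      }
      len <- c(config$telomere_length, body_len, config$telomere_length)
      type <- c("tel", body_type, "tel")
      keep <- len > 0
      pieces <- data.frame(len = len[keep], type = type[keep])
      ends <- cumsum(pieces$len)
      starts <- ends - pieces$len
      lens[chroms[ci]] <- ends[length(ends)]
      sel <- function(type) {
        k <- pieces$type == type
        if (!any(k)) return(NULL)
        data.frame(chrom = chroms[ci], start = starts[k], end = ends[k])
      }
      core[[ci]] <- sel("tad"); cen[[ci]] <- sel("cen")
      tel[[ci]] <- sel("tel")
    }
    cm <- chrom_map(chroms, unname(lens))
    bind <- function(lst) {
      lst <- lst[!vapply(lst, is.null, logical(1))]
      if (!length(lst)) return(NULL)
      df <- do.call(rbind, lst)
      genomic_intervals(df$chrom, df$start, df$end)
    }
    core_gr <- bind(core)
    S4Vectors::mcols(core_gr)$id <- paste0("MACTAD", seq_along(core_gr))
    part <- build_partition(core_gr, cm, centromeres = bind(cen),
                            telomeres = bind(tel))
    core_ids <- S4Vectors::mcols(part)$domain_id[
      S4Vectors::mcols(part)$domain_class == "core_tad"]
    gr_domains <- if (config$gr_placement == "spaced") {
      core_ids[seq_along(core_ids) %% config$gr_spacing == 0]
    } else {
      sort(sample(core_ids,
                  round(config$gr_domain_fraction * length(core_ids))))
    }
    gr_peaks <- NULL
    if (length(gr_domains)) {
      dom <- part[match(gr_domains, S4Vectors::mcols(part)$domain_id)]
      mid <- interval_midpoint(dom)
      w <- config$gr_peak_width
      gr_peaks <- genomic_intervals(
        as.character(GenomeInfoDb::seqnames(dom)),
        pmax(GenomicRanges::start(dom) - 1, mid - floor(w / 2)),
        pmin(GenomicRanges::end(dom), mid + ceiling(w / 2)),
        id = paste0("GRpk", seq_along(dom)),
        feature_class = "GR_peak", chrom_map = cm)
    }
    list(partition = part, chrom_map = cm, gr_domains = gr_domains,
         gr_peaks = gr_peaks)
  })
}

#' Simulate per-domain feature counts under planted enrichment
#'
#' The count marginal of [simulate_features()]: `n` features land in
#' domains with probability proportional to domain length, multiplied by
#' `theta` for GR-bearing domains; `theta = 1` is the exact null of
#' placement independent of GR occupancy.
#'
#' @param partition A partition.
#' @param gr_domains `domain_id`s of GR-bearing domains.
#' @param n Number of features.
#' @param theta Enrichment odds (>= 1).
#' @param seed Integer seed for this draw.
#' @param tag Stream tag (change to draw an independent replicate).
#' @return Named integer vector of counts per `domain_id`.
#' @export
simulate_feature_counts <- function(partition, gr_domains, n, theta, seed,
                                    tag = "feature_counts") {
  stopifnot(theta >= 1)
  ids <- S4Vectors::mcols(partition)$domain_id
  w <- as.numeric(GenomicRanges::width(partition))
  w[ids %in% gr_domains] <- w[ids %in% gr_domains] * theta
  with_stream(seed, tag, {
    stats::setNames(as.integer(stats::rmultinom(1, n, w)), ids)
  })
}

#' Simulate feature placements under planted enrichment
#'
#' Places `n_induced` induced and `n_background` non-induced features.
#' Induced features land in domain d with probability proportional to
#' `length(d) * theta` for GR-bearing d and `length(d)` otherwise;
#' non-induced features follow length alone. Within its domain a feature is
#' a fixed-width interval centred at a uniform position, clipped to the
#' domain, so the midpoint assignment rule recovers the planted domain
#' exactly.
#'
#' @param partition A partition.
#' @param gr_domains GR-bearing `domain_id`s.
#' @param n_induced,n_background Feature counts.
#' @param theta Enrichment odds (>= 1).
#' @param seed Integer seed.
#' @param feature_width Interval width in bp.
#' @param feature_class Stored feature class.
#' @return A `GRanges` with metadata `id`, `feature_class`, `label`
#'   (`"induced"` / `"ns"`) and `true_domain`.
#' @export
simulate_features <- function(partition, gr_domains, n_induced,
                              n_background, theta, seed,
                              feature_width = 600,
                              feature_class = "H3K27ac") {
  counts_ind <- simulate_feature_counts(partition, gr_domains, n_induced,
                                        theta, seed, tag = "features_induced")
  counts_bg <- simulate_feature_counts(partition, character(), n_background,
                                       1, seed, tag = "features_background")
  ids <- S4Vectors::mcols(partition)$domain_id
  dom_idx <- c(rep(seq_along(ids), counts_ind),
               rep(seq_along(ids), counts_bg))
  label <- c(rep("induced", n_induced), rep("ns", n_background))
  s0 <- GenomicRanges::start(partition) - 1
  e0 <- GenomicRanges::end(partition)
  with_stream(seed, "feature_positions", {
    center <- floor(s0[dom_idx] +
                      stats::runif(length(dom_idx)) * (e0[dom_idx] - s0[dom_idx]))
    half <- floor(feature_width / 2)
    fs <- pmax(s0[dom_idx], center - half)
    fe <- pmin(e0[dom_idx], center + (feature_width - half))
    fe <- pmax(fe, fs + 1)
    gr <- genomic_intervals(
      as.character(GenomeInfoDb::seqnames(partition))[dom_idx], fs, fe,
      id = paste0(ifelse(label == "induced", "ind", "bg"),
                  seq_along(dom_idx)),
      feature_class = feature_class)
    S4Vectors::mcols(gr)$label <- label
    S4Vectors::mcols(gr)$true_domain <- ids[dom_idx]
    gr
  })
}

#' Simulate a six-cluster differential table
#'
#' Features are allocated to the six response clusters (or the unresponsive
#' remainder) by the configured proportions. Significant contrasts receive
#' `log2fc = sign * (effect + Normal(0, noise))` and `padj ~ U(0, 0.04)`;
#' null contrasts receive `log2fc ~ Normal(0, noise)` and
#' `padj ~ U(0.06, 1)`, so at default thresholds an all-null table yields
#' zero responsive calls by construction. Responsive features are always
#' expressed (base mean above the floor); a configured fraction of
#' unresponsive features is expressed. Ground truth is returned alongside.
#'
#' Cluster semantics: 1-3 treatment-up, 4-6 treatment-down; within each
#' direction the differentiation dynamic is Mf-high / static / Mo-high.
#' The treatment response is planted in the monocyte contrast, with a
#' configured fraction also responding (same sign) in macrophages.
#'
#' @param config A [simulation_config()].
#' @return List with `stats` (data.frame in the differential-table layout)
#'   and `truth` (data.frame `id`, `cluster` 0-6, `direction`, `mo_mf`).
#' @export
simulate_differential_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_diff_features
  p6 <- config$cluster_proportions
  with_stream(config$seed, "differential_table", {
    counts <- as.integer(stats::rmultinom(1, n, c(1 - sum(p6), p6)))
    cluster <- rep(0:6, counts)
    id <- paste0("g", seq_len(n))
    eff <- config$effect_size_log2fc
    sd <- config$stat_noise_sd
    sig_lfc <- function(k, sign) sign * (eff + stats::rnorm(k, 0, sd))
    null_lfc <- function(k) stats::rnorm(k, 0, sd)
    sig_p <- function(k) stats::runif(k, 0, 0.04)
    null_p <- function(k) stats::runif(k, 0.06, 1)
    direction <- c("none", rep("up", 3), rep("down", 3))[cluster + 1]
    mo_mf <- c("static", rep(c("mf_high", "static", "mo_high"), 2))[
      cluster + 1]
    lfc_mo <- null_lfc(n); p_mo <- null_p(n)
    lfc_mf <- null_lfc(n); p_mf <- null_p(n)
    lfc_dd <- null_lfc(n); p_dd <- null_p(n)
    up <- direction == "up"; down <- direction == "down"
    resp <- up | down
    sgn <- ifelse(up, 1, -1)
    lfc_mo[resp] <- sig_lfc(sum(resp), sgn[resp])
    p_mo[resp] <- sig_p(sum(resp))
    shared <- resp & stats::runif(n) < config$shared_response_fraction
    lfc_mf[shared] <- sig_lfc(sum(shared), sgn[shared])
    p_mf[shared] <- sig_p(sum(shared))
    mf_high <- mo_mf == "mf_high"; mo_high <- mo_mf == "mo_high"
    lfc_dd[mf_high] <- sig_lfc(sum(mf_high), 1)
    p_dd[mf_high] <- sig_p(sum(mf_high))
    lfc_dd[mo_high] <- sig_lfc(sum(mo_high), -1)
    p_dd[mo_high] <- sig_p(sum(mo_high))
    floor_bm <- 20
    base_mean <- floor_bm + stats::rlnorm(n, log(100), 1)
    silent <- !resp & stats::runif(n) > config$expressed_fraction
    base_mean[silent] <- stats::runif(sum(silent), 0, floor_bm)
    mo_mf_truth <- mo_mf
    mo_mf_truth[silent] <- "static"
    stats <- data.frame(id = id, base_mean = base_mean,
                        log2fc_ta_mo = lfc_mo, padj_ta_mo = p_mo,
                        log2fc_ta_mf = lfc_mf, padj_ta_mf = p_mf,
                        log2fc_mo_mf = lfc_dd, padj_mo_mf = p_dd)
    truth <- data.frame(id = id, cluster = cluster, direction = direction,
                        mo_mf = mo_mf_truth)
    list(stats = stats, truth = truth)
  })
}

#' Simulate region sequences with planted motif instances
#'
#' A fraction of sequences receives exactly one realization of the
#' consensus motif (IUPAC ambiguity letters resolved uniformly at random)
#' at a uniform position and strand; all other bases are uniform ACGT.
#'
#' @param config A [simulation_config()].
#' @param motif A [consensus_motif()]; default the GRE consensus.
#' @return List with `sequences` (named `DNAStringSet`) and `truth`
#'   (data.frame `region_id`, `planted`, `offset` 0-based or `NA`,
#'   `strand`, `realization`).
#' @export
simulate_sequences <- function(config, motif = gre_motif()) {
  stopifnot(inherits(config, "simulation_config"),
            config$sequence_length >= motif$length)
  n <- config$n_sequences
  L <- config$sequence_length
  m <- motif$length
  letters_pat <- strsplit(motif$pattern, "")[[1]]
  with_stream(config$seed, "sequences", {
    bases <- c("A", "C", "G", "T")
    mat <- matrix(sample(bases, n * L, replace = TRUE), nrow = n)
    planted <- stats::runif(n) < config$motif_plant_fraction
    offset <- rep(NA_integer_, n)
    strand <- rep(NA_character_, n)
    realization <- rep(NA_character_, n)
    for (i in which(planted)) {
      inst <- vapply(letters_pat,
                     function(l) sample(IUPAC_SETS[[l]], 1), character(1))
      str <- sample(c("+", "-"), 1)
      if (str == "-") {
        inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
      }
      off <- sample.int(L - m + 1, 1) - 1L
      mat[i, (off + 1):(off + m)] <- inst
      offset[i] <- off
      strand[i] <- str
      realization[i] <- paste(inst, collapse = "")
    }
    ids <- paste0("seq", seq_len(n))
    seqs <- Biostrings::DNAStringSet(apply(mat, 1, paste, collapse = ""))
    names(seqs) <- ids
    list(sequences = seqs,
         truth = data.frame(region_id = ids, planted = planted,
                            offset = offset, strand = strand,
                            realization = realization))
  })
}
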