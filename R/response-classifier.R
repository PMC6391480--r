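#' Differential-response thresholds
#'
#' Thresholds used to call a feature responsive in a contrast. Defaults
#' follow the transcript analysis: base mean expression above 20 normalized
#' reads, |log2FC| > 1 and adjusted p < 0.05. Histone-region sets are
#' typically classified without the base-mean gate (`min_base_mean = 0`),
#' and broad H3K4me1 regions with the lowered 1.5-fold cut-off, available as
#' `alt_min_abs_log2fc_k4me1`; the override is applied per feature class,
#' not globally.
#'
#' @param min_abs_log2fc Minimum |log2 fold change|; default 1 (two-fold).
#' @param max_padj Maximum adjusted p-value; default 0.05.
#' @param min_base_mean Expression floor in normalized reads; default 20.
#'   Features at or below the floor are non-significant in all contrasts.
#' @param alt_min_abs_log2fc_k4me1 Alternative fold-change cut-off for
#'   H3K4me1 regions; default `log2(1.5)`.
#' @return A list of class `"tadenrich_thresholds"`.
#' @export
response_thresholds <- function(min_abs_log2fc = 1, max_padj = 0.05,
                                min_base_mean = 20,
                                alt_min_abs_log2fc_k4me1 = log2(1.5)) {
  stopifnot(min_abs_log2fc > 0, max_padj > 0, max_padj < 1,
            min_base_mean >= 0, alt_min_abs_log2fc_k4me1 > 0)
  structure(list(min_abs_log2fc = min_abs_log2fc,
                 max_padj = max_padj,
                 min_base_mean = min_base_mean,
                 alt_min_abs_log2fc_k4me1 = alt_min_abs_log2fc_k4me1),
            class = "tadenrich_thresholds")
}

## Direction call for one contrast: "up" / "down" / "ns".
call_direction <- function(log2fc, padj, min_lfc, max_padj, expressed) {
  up <- expressed & !is.na(log2fc) & !is.na(padj) &
    log2fc > min_lfc & padj < max_padj
  down <- expressed & !is.na(log2fc) & !is.na(padj) &
    log2fc < -min_lfc & padj < max_padj
  ifelse(up, "up", ifelse(down, "down", "ns"))
}

## The six response clusters: treatment direction crossed with the
## differentiation dynamic of the same feature.
CLUSTER_TABLE <- data.frame(
  cluster = 1:6,
  direction = rep(c("up", "down"), each = 3),
  mo_mf = c("mf_high", "static", "mo_high", "mf_high", "static", "mo_high"),
  label = c("TA-up & Mf-high", "TA-up & static", "TA-up & Mo-high",
            "TA-down & Mf-high", "TA-down & static", "TA-down & Mo-high")
)

#' Classify features into response clusters
#'
#' Per contrast, a feature is `up` if `log2fc > min_abs_log2fc` and
#' `padj < max_padj`, `down` for the mirrored condition, else `ns`; features
#' with `base_mean <= min_base_mean` are `ns` everywhere. The
#' differentiation contrast is labelled analogously as `mf_high` /
#' `mo_high` / `static`. The overall treatment direction is `up` (`down`)
#' if the feature is up (down) in either cell type; a feature up in one and
#' down in the other is labelled `discordant` — an explicit error label, so
#' such features can never be silently misfiled into a cluster (none were
#' observed in the motivating data). Responsive features get a cluster 1-6
#' from crossing direction with the differentiation label.
#'
#' Features with any missing statistic are routed to an `unclassifiable`
#' bin (direction `NA`), reported in the output, never imputed.
#'
#' @param stats A data.frame as from [read_differential_table()].
#' @param thresholds A [response_thresholds()] object.
#' @param feature_class Optional character (scalar or per-row): rows of
#'   class `"H3K4me1"` use the alternative fold-change cut-off.
#' @param p_adjusted Set to `FALSE` if the table carries raw p-values; they
#'   are then Benjamini-Hochberg adjusted per contrast (with a message)
#'   before thresholding.
#' @return A data.frame with columns `id`, `ta_mo`, `ta_mf`, `mo_mf`,
#'   `direction` (`up`/`down`/`none`/`discordant`/`NA` for unclassifiable),
#'   `cluster` (integer 1-6 or `NA`), `cluster_label`, `unclassifiable`.
#' @export
classify_responses <- function(stats, thresholds = response_thresholds(),
                               feature_class = NULL, p_adjusted = TRUE) {
  stopifnot(inherits(thresholds, "tadenrich_thresholds"))
  if (!p_adjusted) {
    message("raw p-values supplied: applying Benjamini-Hochberg ",
            "adjustment per contrast")
    for (cn in c("padj_ta_mo", "padj_ta_mf", "padj_mo_mf")) {
      stats[[cn]] <- stats::p.adjust(stats[[cn]], method = "BH")
    }
  }
  n <- nrow(stats)
  complete <- stats::complete.cases(stats[, DIFF_COLUMNS])
  min_lfc <- rep(thresholds$min_abs_log2fc, n)
  if (!is.null(feature_class)) {
    fc <- rep(as.character(feature_class), length.out = n)
    min_lfc[fc == "H3K4me1"] <- thresholds$alt_min_abs_log2fc_k4me1
  }
  expressed <- !is.na(stats$base_mean) &
    stats$base_mean > thresholds$min_base_mean
  ta_mo <- call_direction(stats$log2fc_ta_mo, stats$padj_ta_mo,
                          min_lfc, thresholds$max_padj, expressed)
  ta_mf <- call_direction(stats$log2fc_ta_mf, stats$padj_ta_mf,
                          min_lfc, thresholds$max_padj, expressed)
  dd <- call_direction(stats$log2fc_mo_mf, stats$padj_mo_mf,
                       min_lfc, thresholds$max_padj, expressed)
  mo_mf <- c(up = "mf_high", down = "mo_high", ns = "static")[dd]
  any_up <- ta_mo == "up" | ta_mf == "up"
  any_down <- ta_mo == "down" | ta_mf == "down"
  direction <- ifelse(any_up & any_down, "discordant",
                      ifelse(any_up, "up",
                             ifelse(any_down, "down", "none")))
  direction[!complete] <- NA_character_
  key <- paste(direction, mo_mf, sep = "|")
  lut <- stats::setNames(CLUSTER_TABLE$cluster,
                         paste(CLUSTER_TABLE$direction, CLUSTER_TABLE$mo_mf,
                               sep = "|"))
  cluster <- unname(lut[key])
  cluster[is.na(direction) | !(direction %in% c("up", "down"))] <- NA_integer_
  out <- data.frame(
    id = stats$id,
    ta_mo = ifelse(complete, ta_mo, NA_character_),
    ta_mf = ifelse(complete, ta_mf, NA_character_),
    mo_mf = ifelse(complete, unname(mo_mf), NA_character_),
    direction = direction,
    cluster = as.integer(cluster),
    cluster_label = CLUSTER_TABLE$label[match(cluster, CLUSTER_TABLE$cluster)],
    unclassifiable = !complete
  )
  out
}

#' Venn counts of two responsive-feature id sets
#'
#' @param ids_mo,ids_mf Character vectors of feature ids called responsive
#'   (in a given direction) in monocytes and macrophages respectively.
#' @return Named integer vector `c(mo_only, mf_only, both)`; the three
#'   counts are disjoint and sum to the size of the union.
#' @export
venn_counts <- function(ids_mo, ids_mf) {
  ids_mo <- unique(ids_mo)
  ids_mf <- unique(ids_mf)
  both <- length(intersect(ids_mo, ids_mf))
  c(mo_only = length(ids_mo) - both,
    mf_only = length(ids_mf) - both,
    both = both)
}

#' Six-cluster stratification table
#'
#' Counts per response cluster plus percentages within each treatment
#' direction (so percentages answer "of the up-regulated features, how many
#' are Mf-high / static / Mo-high", the form used to stratify responses by
#' differentiation dynamics).
#'
#' @param labels Output of [classify_responses()].
#' @return A data.frame with one row per cluster: `cluster`, `label`,
#'   `direction`, `count`, `pct_within_direction`; attribute `totals` holds
#'   the responsive / unresponsive / discordant / unclassifiable counts.
#' @export
stratification_table <- function(labels) {
  tab <- CLUSTER_TABLE
  tab$count <- vapply(tab$cluster, function(k) {
    sum(!is.na(labels$cluster) & labels$cluster == k)
  }, integer(1))
  dir_tot <- stats::ave(tab$count, tab$direction, FUN = sum)
  tab$pct_within_direction <- ifelse(dir_tot > 0, 100 * tab$count / dir_tot,
                                     0)
  out <- tab[, c("cluster", "label", "direction", "count",
                 "pct_within_direction")]
  attr(out, "totals") <- c(
    responsive = sum(!is.na(labels$cluster)),
    unresponsive = sum(!is.na(labels$direction) & labels$direction == "none"),
    discordant = sum(!is.na(labels$direction) &
                       labels$direction == "discordant"),
    unclassifiable = sum(labels$unclassifiable)
  )
  out
}
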