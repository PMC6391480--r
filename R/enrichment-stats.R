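## log(sum(exp(x))) without overflow; -Inf-safe.
log_sum_exp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Exact upper binomial tail
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, the exact one-sided p-value of the
#' adjacent-domain test. Summed in log space over log binomial coefficients
#' (log-sum-exp), never via `1 - CDF`, so tails far below machine epsilon
#' (e.g. 1e-32) keep full relative precision.
#'
#' @param k Number of successes (0 <= k <= n); vectorised.
#' @param n Number of trials.
#' @param p Success probability under the null.
#' @return `P(X >= k)`, same length as `k`.
#' @examples
#' binomial_tail(134, 249, 0.2)  # 4.39e-32
#' @export
binomial_tail <- function(k, n, p) {
  if (length(n) != 1 || length(p) != 1) stop("n and p must be scalars")
  if (is.na(n) || n < 0 || n != round(n)) stop("n must be a nonnegative integer")
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (any(is.na(k)) || any(k < 0) || any(k > n) || any(k != round(k))) {
    stop("k must be an integer in [0, n]")
  }
  vapply(k, function(ki) {
    if (ki == 0) return(1)
    if (p == 0) return(0)
    if (p == 1) return(1)
    i <- ki:n
    exp(log_sum_exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
  }, numeric(1))
}

#' Exact upper hypergeometric tail
#'
#' `P(X >= k)` when drawing `n_draws` items without replacement from a
#' population of `N_population` containing `K_successes` successes; used for
#' domain-level enrichment of responsive features in GR-bound domains.
#' Computed in log space over log binomial coefficients.
#'
#' @param k Observed successes among the draws; vectorised.
#' @param n_draws Number of draws.
#' @param K_successes Successes in the population.
#' @param N_population Population size.
#' @return `P(X >= k)`, same length as `k`.
#' @export
hypergeometric_tail <- function(k, n_draws, K_successes, N_population) {
  if (length(n_draws) != 1 || length(K_successes) != 1 ||
      length(N_population) != 1) {
    stop("n_draws, K_successes and N_population must be scalars")
  }
  if (K_successes > N_population || n_draws > N_population) {
    stop("impossible configuration: K <= N and n <= N required")
  }
  if (any(k < 0) || any(k > pmin(n_draws, K_successes)) ||
      any(k != round(k))) {
    stop("k must be an integer in [0, min(n_draws, K_successes)]")
  }
  lower <- max(0, n_draws - (N_population - K_successes))
  upper <- min(n_draws, K_successes)
  ldenom <- lchoose(N_population, n_draws)
  vapply(k, function(ki) {
    i <- max(ki, lower):upper
    if (ki > upper) return(0)
    exp(log_sum_exp(lchoose(K_successes, i) +
                      lchoose(N_population - K_successes, n_draws - i) -
                      ldenom))
  }, numeric(1))
}

#' Adjacent-domain test configuration
#'
#' @param flank_width Domains per side used as flanks; default 2 (the two
#'   left and two right neighbouring domains, chosen because well-defined
#'   TADs are often flanked by tiny interstitial domains that a one-domain
#'   flank could miss).
#' @param null_probability Null success probability; by construction
#'   `1/(2 * flank_width + 1)` (1/5 by default) unless overridden.
#' @param tie_policy `"fail"` (default): a center tied with the flank
#'   maximum is a failure — the conservative reading that makes the strict
#'   maximum have exact null probability 1/5. `"random"`: ties broken
#'   uniformly at random (for calibration studies).
#' @return A list of class `"adjacent_tad_config"`.
#' @export
adjacent_tad_config <- function(flank_width = 2, null_probability = NULL,
                                tie_policy = c("fail", "random")) {
  stopifnot(flank_width >= 1, flank_width == round(flank_width))
  if (is.null(null_probability)) {
    null_probability <- 1 / (2 * flank_width + 1)
  }
  stopifnot(null_probability > 0, null_probability < 1)
  structure(list(flank_width = flank_width,
                 null_probability = null_probability,
                 tie_policy = match.arg(tie_policy)),
            class = "adjacent_tad_config")
}

#' Select center domains and their flanks
#'
#' Centers are domains containing at least one qualifying GR peak that (i)
#' possess exactly `flank_width` neighbours on each side on the same
#' chromosome (domains too close to a chromosome end are excluded, not
#' padded) and (ii) have all `2 * flank_width` flanking domains free of GR
#' peaks. By construction the selected centers are mutually non-adjacent.
#'
#' `flank_exclude_domains` controls which peak set defines "GR-free": by
#' default the same set that defines centers, but the stricter reading —
#' excluding any GR peak from a wider set — is obtained by passing the
#' domains of the full peak set.
#'
#' @param partition A partition from [build_partition()].
#' @param center_domains Character vector of `domain_id`s bearing a
#'   qualifying GR peak.
#' @param flank_exclude_domains `domain_id`s whose presence disqualifies a
#'   flank; default `center_domains`.
#' @param config An [adjacent_tad_config()].
#' @return data.frame with columns `center` and `flank_1` ..
#'   `flank_<2*flank_width>` (left flanks outermost-first, then right
#'   flanks). Zero rows if nothing is eligible.
#' @export
select_center_domains <- function(partition, center_domains,
                                  flank_exclude_domains = center_domains,
                                  config = adjacent_tad_config()) {
  idx <- partition_index(partition)
  w <- config$flank_width
  pos_of <- stats::setNames(seq_len(nrow(idx)), idx$domain_id)
  is_center <- idx$domain_id %in% center_domains
  has_gr <- idx$domain_id %in% flank_exclude_domains
  sets <- list()
  for (i in which(is_center)) {
    ch <- idx$chrom[i]
    offs <- c(-(w:1), 1:w)
    neigh <- i + offs
    if (any(neigh < 1 | neigh > nrow(idx))) next
    if (any(idx$chrom[neigh] != ch)) next
    if (any(has_gr[neigh])) next
    sets[[length(sets) + 1]] <- c(idx$domain_id[i], idx$domain_id[neigh])
  }
  if (!length(sets)) {
    out <- as.data.frame(matrix(character(), ncol = 2 * w + 1, nrow = 0))
  } else {
    out <- as.data.frame(do.call(rbind, sets))
  }
  names(out) <- c("center", paste0("flank_", seq_len(2 * w)))
  out
}

#' Adjacent-domain strict-maximum binomial test
#'
#' For each center/flank set the responsive-feature count in every domain
#' is normalized by that domain's relevant total (expressed transcripts or
#' all epigenetic features of the class; 0/0 counts as ratio 0). A set is a
#' success iff the center's ratio strictly exceeds all flank ratios; under
#' the null of no association between GR occupancy and responsive-feature
#' placement, with exchangeable domains, the success probability is exactly
#' `1/(2 * flank_width + 1)`. The p-value is the exact upper binomial tail
#' of the success count.
#'
#' @param sets data.frame from [select_center_domains()].
#' @param numerator Named numeric vector: responsive-feature count per
#'   `domain_id` (missing domains count 0).
#' @param denominator Named numeric vector: per-domain totals.
#' @param config An [adjacent_tad_config()].
#' @return A list of class `"enrichment_result"`: `n_sets`, `n_successes`,
#'   `p_value`, `null_probability`, and `detail` (per-set center ratio,
#'   flank ratios, success flag).
#' @export
adjacent_tad_test <- function(sets, numerator, denominator,
                              config = adjacent_tad_config()) {
  if (!nrow(sets)) stop("no eligible center domains")
  ratio_of <- function(ids) {
    num <- numerator[ids]
    den <- denominator[ids]
    num[is.na(num)] <- 0
    den[is.na(den)] <- 0
    ifelse(den > 0, num / den, 0)
  }
  center_ratio <- ratio_of(sets$center)
  flank_cols <- grep("^flank_", names(sets), value = TRUE)
  flank_ratios <- vapply(flank_cols, function(cn) ratio_of(sets[[cn]]),
                         numeric(nrow(sets)))
  flank_ratios <- matrix(flank_ratios, nrow = nrow(sets))
  flank_max <- apply(flank_ratios, 1, max)
  if (config$tie_policy == "fail") {
    success <- center_ratio > flank_max
  } else {
    tied <- center_ratio == flank_max
    n_top <- rowSums(cbind(flank_ratios, center_ratio) ==
                       pmax(center_ratio, flank_max))
    success <- center_ratio > flank_max |
      (tied & stats::runif(nrow(sets)) < 1 / n_top)
  }
  k <- sum(success)
  n <- nrow(sets)
  res <- list(
    n_sets = n,
    n_successes = k,
    p_value = binomial_tail(k, n, config$null_probability),
    null_probability = config$null_probability,
    detail = data.frame(center = sets$center,
                        center_ratio = unname(center_ratio),
                        flank_max_ratio = unname(flank_max),
                        success = unname(success))
  )
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Adjacent-domain enrichment: %d/%d successes (null p = %.3g), p-value = %.3g\n",
    x$n_successes, x$n_sets, x$null_probability, x$p_value))
  invisible(x)
}

#' Hypergeometric enrichment of labelled features in marked domains
#'
#' Default parameterization of the domain-level enrichment question "do
#' GR-bound domains concentrate induced features": population = all
#' features of the class, population successes = features lying in marked
#' (GR-bearing) domains, draws = the labelled (induced) features, observed
#' = labelled features in marked domains.
#'
#' @param assignment Named character vector from [assign_to_domains()].
#' @param labelled_ids Feature ids with the label of interest (e.g.
#'   induced).
#' @param marked_domains `domain_id`s that carry the mark (e.g. a GR peak).
#' @return List with the four hypergeometric parameters, the fraction of
#'   labelled features in marked domains, and `p_value`.
#' @export
domain_hypergeometric_enrichment <- function(assignment, labelled_ids,
                                             marked_domains) {
  in_marked <- assignment %in% marked_domains
  is_lab <- names(assignment) %in% labelled_ids
  k <- sum(in_marked & is_lab)
  res <- list(
    k = k,
    n_draws = sum(is_lab),
    K_successes = sum(in_marked),
    N_population = length(assignment),
    fraction_in_marked = if (sum(is_lab)) k / sum(is_lab) else NA_real_,
    p_value = hypergeometric_tail(k, sum(is_lab), sum(in_marked),
                                  length(assignment))
  )
  res
}

#' TAD-level Spearman correlation and hierarchical clustering
#'
#' Pairwise Spearman rank correlations (average ranks for ties) between
#' per-domain count vectors of several datasets, hierarchically clustered
#' by average linkage on distance `1 - rho`. A dataset constant across
#' domains has undefined rank correlations: it is reported as `NA` in the
#' matrix and excluded from the clustering with a warning.
#'
#' @param counts Numeric matrix or data.frame: rows = domains, columns =
#'   datasets (>= 2).
#' @return List with `correlation` (symmetric matrix, unit diagonal),
#'   `hclust` (an [stats::hclust] object over the non-constant datasets,
#'   `NULL` if fewer than 2 remain) and `excluded` (names of constant
#'   datasets).
#' @export
spearman_cluster <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 datasets")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("dataset", seq_len(ncol(counts)))
  }
  constant <- apply(counts, 2, function(x) length(unique(x)) == 1)
  rho <- suppressWarnings(stats::cor(counts, method = "spearman"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1
  hc <- NULL
  if (any(constant)) {
    warning("constant dataset(s) excluded from clustering: ",
            paste(colnames(counts)[constant], collapse = ", "))
  }
  keep <- !constant
  if (sum(keep) >= 2) {
    d <- stats::as.dist(1 - rho[keep, keep, drop = FALSE])
    hc <- stats::hclust(d, method = "average")
  }
  list(correlation = rho, hclust = hc,
       excluded = colnames(counts)[constant])
}

#' Dendrogram as a Newick string
#'
#' @param hc An [stats::hclust] object (e.g. from [spearman_cluster()]).
#' @return A Newick-format string (requires the `ape` package).
#' @export
dendrogram_newick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the ape package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(hc))
}
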