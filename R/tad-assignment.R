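#' Assign features to domains
#'
#' Every feature is assigned to the unique domain containing its interval
#' midpoint (BED-coordinate midpoint, see [interval_midpoint()]). Over a
#' genome-covering partition the midpoint rule makes assignment total and
#' unambiguous. An any-overlap mode with largest-overlap tie-break is
#' available as an alternative; `"tss"` mode assigns by the interval start
#' (for transcript sets where the annotated start is the TSS).
#'
#' @param features `GRanges` with an `id` metadata column.
#' @param partition A partition from [build_partition()].
#' @param mode `"midpoint"` (default), `"overlap"` or `"tss"`.
#' @return Character vector of `domain_id`s, named by feature id.
#' @export
assign_to_domains <- function(features, partition,
                              mode = c("midpoint", "overlap", "tss")) {
  mode <- match.arg(mode)
  ids <- S4Vectors::mcols(features)$id
  if (is.null(ids)) ids <- paste0("feat", seq_along(features))
  known <- GenomeInfoDb::seqlevels(partition)
  seen <- as.character(GenomeInfoDb::seqnames(features))
  bad <- !(seen %in% known)
  if (any(bad)) {
    stop("features on chromosome(s) absent from the partition: ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  if (mode == "overlap") {
    hits <- GenomicRanges::findOverlaps(features, partition,
                                        ignore.strand = TRUE)
    ov <- overlap_bp(features[S4Vectors::queryHits(hits)],
                     partition[S4Vectors::subjectHits(hits)])
    ord <- order(S4Vectors::queryHits(hits), -ov,
                 S4Vectors::subjectHits(hits))
    hits <- hits[ord]
    keep <- !duplicated(S4Vectors::queryHits(hits))
    sel <- S4Vectors::subjectHits(hits)[keep]
    qi <- S4Vectors::queryHits(hits)[keep]
  } else {
    pos0 <- if (mode == "tss") {
      GenomicRanges::start(features) - 1
    } else {
      interval_midpoint(features)
    }
    pts <- GenomicRanges::GRanges(
      seqnames = GenomeInfoDb::seqnames(features),
      ranges = IRanges::IRanges(start = pos0 + 1, width = 1)
    )
    hits <- GenomicRanges::findOverlaps(pts, partition, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    sel <- S4Vectors::subjectHits(hits)
  }
  if (length(qi) != length(features) || anyDuplicated(qi)) {
    stop("assignment is not total and unique; is the partition ",
         "genome-covering for these features?")
  }
  out <- character(length(features))
  out[qi] <- S4Vectors::mcols(partition)$domain_id[sel]
  stats::setNames(out, ids)
}

#' Per-domain count matrix
#'
#' Cross-tabulates assigned features by domain and by group (typically
#' `feature_class` crossed with a response label), and adds per-domain
#' totals per feature class. Every feature counts exactly once, so column
#' sums reproduce the global per-group counts.
#'
#' @param assignment Named character vector from [assign_to_domains()]
#'   (names = feature ids, values = domain ids).
#' @param feature_table data.frame with columns `id`, `feature_class` and
#'   optionally `label`; must cover exactly the assigned ids.
#' @param partition The partition the assignment was made over (fixes the
#'   row universe so feature-free domains appear with zero counts).
#' @return A data.frame with one row per domain (`domain_id`), one count
#'   column per `class.label` combination, and one `total_<class>` column
#'   per feature class.
#' @export
domain_count_matrix <- function(assignment, feature_table, partition) {
  if (!all(c("id", "feature_class") %in% names(feature_table))) {
    stop("feature_table needs columns id and feature_class")
  }
  missing_ids <- setdiff(names(assignment), feature_table$id)
  extra_ids <- setdiff(feature_table$id, names(assignment))
  if (length(missing_ids) || length(extra_ids)) {
    stop("assignment and feature_table cover different ids (",
         length(missing_ids), " unlabelled, ", length(extra_ids),
         " unassigned)")
  }
  dom <- unname(assignment[feature_table$id])
  domain_ids <- S4Vectors::mcols(partition)$domain_id
  dom <- factor(dom, levels = domain_ids)
  cls <- as.character(feature_table$feature_class)
  lab <- if ("label" %in% names(feature_table)) {
    as.character(feature_table$label)
  } else {
    rep("all", nrow(feature_table))
  }
  grp <- paste(cls, lab, sep = ".")
  counts <- table(dom, grp)
  out <- data.frame(domain_id = domain_ids)
  for (g in colnames(counts)) out[[g]] <- as.integer(counts[, g])
  for (k in unique(cls)) {
    tot <- table(dom[cls == k])
    out[[paste0("total_", k)]] <- as.integer(tot[domain_ids])
  }
  out
}

#' Feature pairs within an edge-to-edge distance
#'
#' All (a, b) pairs whose edge-to-edge gap is at most `max_distance` bp on
#' the same chromosome; overlapping intervals have gap 0 and the bound is
#' inclusive, so "within 500 bp" includes a gap of exactly 500.
#'
#' @param a,b `GRanges` with `id` metadata.
#' @param max_distance Maximum gap in bp (>= 0).
#' @return data.frame with columns `a_id`, `b_id`, `gap_bp`.
#' @export
features_within <- function(a, b, max_distance) {
  if (length(max_distance) != 1 || is.na(max_distance) || max_distance < 0) {
    stop("max_distance must be a single nonnegative number")
  }
  hits <- GenomicRanges::findOverlaps(a, b, maxgap = max_distance,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gap <- pmax(0L, pmax(GenomicRanges::start(a)[qi],
                       GenomicRanges::start(b)[si]) -
                pmin(GenomicRanges::end(a)[qi],
                     GenomicRanges::end(b)[si]) - 1L)
  a_id <- S4Vectors::mcols(a)$id
  b_id <- S4Vectors::mcols(b)$id
  if (is.null(a_id)) a_id <- paste0("a", seq_along(a))
  if (is.null(b_id)) b_id <- paste0("b", seq_along(b))
  data.frame(a_id = a_id[qi], b_id = b_id[si], gap_bp = as.integer(gap))
}

#' Close peak pairs and the multi-peak loci they define
#'
#' Unordered peak pairs whose midpoint separation is at most
#' `max_separation` bp (inclusive), plus the loci obtained by chaining:
#' connected components of the pair graph. Peak spacing is a
#' center-to-center notion, so midpoint distance is used here (contrast
#' [features_within()], which uses edge-to-edge gaps).
#'
#' @param peaks `GRanges` with `id` metadata.
#' @param max_separation Maximum midpoint separation in bp; default 30000.
#' @return List with `pairs` (data.frame `id1`, `id2`, `separation_bp`) and
#'   `loci` (data.frame `id`, `locus`) where `locus` numbers the connected
#'   components with at least two peaks; singleton peaks get locus `NA`.
#' @export
close_pairs <- function(peaks, max_separation = 30000) {
  ids <- S4Vectors::mcols(peaks)$id
  if (is.null(ids)) ids <- paste0("peak", seq_along(peaks))
  mid <- interval_midpoint(peaks)
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  ord <- order(chrom, mid)
  pairs <- list()
  ## Pairing by midpoint distance chains in 1-D: components are runs of
  ## consecutive (sorted) midpoints whose successive gaps stay <= cutoff.
  comp <- integer(length(peaks))
  comp_id <- 0L
  for (ch in unique(chrom)) {
    idx <- ord[chrom[ord] == ch]
    if (!length(idx)) next
    m <- mid[idx]
    newrun <- c(TRUE, diff(m) > max_separation)
    runs <- cumsum(newrun)
    comp[idx] <- runs + comp_id
    comp_id <- comp_id + max(runs)
    for (i in seq_along(idx)) {
      j <- i + 1
      while (j <= length(idx) && m[j] - m[i] <= max_separation) {
        pairs[[length(pairs) + 1]] <- data.frame(
          id1 = ids[idx[i]], id2 = ids[idx[j]],
          separation_bp = m[j] - m[i])
        j <- j + 1
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else {
    data.frame(id1 = character(), id2 = character(),
               separation_bp = numeric())
  }
  multi <- comp %in% which(tabulate(comp) >= 2)
  locus <- ifelse(multi, match(comp, sort(unique(comp[multi]))), NA_integer_)
  list(pairs = pairs,
       loci = data.frame(id = ids, locus = as.integer(locus)))
}

#' Fraction of query features overlapping a reference set
#'
#' @param query,reference `GRanges`.
#' @return Fraction in [0, 1] of query features with at least 1 bp of
#'   overlap with any reference feature. An empty query is an error (the
#'   fraction is undefined).
#' @export
overlap_fraction <- function(query, reference) {
  if (!length(query)) stop("empty query set: overlap fraction undefined")
  mean(GenomicRanges::countOverlaps(query, reference,
                                    ignore.strand = TRUE) > 0)
}
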