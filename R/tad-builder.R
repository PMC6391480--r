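#' Build the typed genome partition
#'
#' Constructs an ordered, non-overlapping, genome-covering set of typed
#' domains from a core TAD call set plus optional centromere and telomere
#' annotations. Core TADs are emitted unchanged; centromeres and telomeres
#' become their own typed domains; every remaining uncovered span becomes an
#' `inter_tad` domain (the "inter-TAD" complement regions between called
#' TADs). Zero-length gaps between abutting TADs produce nothing.
#'
#' Centromere/telomere intervals may carve the complement but may never
#' overlap a core TAD: the TAD call set is treated as fixed, so such an
#' overlap is an input error rather than being silently resolved.
#'
#' @param core_tads `GRanges` of called TADs (non-overlapping).
#' @param chrom_map `Seqinfo` giving chromosome lengths.
#' @param centromeres,telomeres Optional `GRanges` annotations.
#' @return A sorted `GRanges` tiling every chromosome exactly, with metadata
#'   columns `domain_class` (factor: `core_tad`, `inter_tad`, `centromere`,
#'   `telomere`), `domain_id` (stable `"{prefix}.{chrom}.{ordinal}"` assigned
#'   left-to-right) and `name` (external label from BED column 4 for core
#'   TADs, `NA` otherwise).
#' @examples
#' cm <- chrom_map("chr1", 100)
#' tads <- genomic_intervals(c("chr1", "chr1"), c(10, 50), c(30, 80))
#' build_partition(tads, cm)
#' @export
build_partition <- function(core_tads, chrom_map, centromeres = NULL,
                            telomeres = NULL) {
  core_tads <- validate_against_map(core_tads, chrom_map)
  self_ov <- GenomicRanges::findOverlaps(core_tads, drop.self = TRUE,
                                         drop.redundant = TRUE)
  if (length(self_ov)) {
    i <- S4Vectors::queryHits(self_ov)[1]
    j <- S4Vectors::subjectHits(self_ov)[1]
    stop(sprintf("core TADs overlap: [%s:%d-%d) and [%s:%d-%d)",
                 GenomeInfoDb::seqnames(core_tads)[i],
                 GenomicRanges::start(core_tads)[i] - 1,
                 GenomicRanges::end(core_tads)[i],
                 GenomeInfoDb::seqnames(core_tads)[j],
                 GenomicRanges::start(core_tads)[j] - 1,
                 GenomicRanges::end(core_tads)[j]))
  }
  carved <- GenomicRanges::GRanges(seqinfo = chrom_map)
  pieces <- list()
  add_typed <- function(gr, class) {
    if (is.null(gr) || !length(gr)) return(NULL)
    gr <- validate_against_map(gr, chrom_map)
    S4Vectors::mcols(gr) <- NULL
    S4Vectors::mcols(gr)$domain_class <- class
    gr
  }
  cen <- add_typed(centromeres, "centromere")
  tel <- add_typed(telomeres, "telomere")
  annot <- c(list(cen), list(tel))
  annot <- annot[!vapply(annot, is.null, logical(1))]
  if (length(annot)) {
    carved <- do.call(c, annot)
    ov <- GenomicRanges::findOverlaps(carved, drop.self = TRUE,
                                      drop.redundant = TRUE)
    if (length(ov)) {
      stop("centromere/telomere annotation intervals overlap each other")
    }
    hit <- GenomicRanges::findOverlaps(carved, core_tads)
    if (length(hit)) {
      i <- S4Vectors::queryHits(hit)[1]
      stop(sprintf(
        "annotation interval [%s:%d-%d) overlaps a core TAD; %s",
        GenomeInfoDb::seqnames(carved)[i],
        GenomicRanges::start(carved)[i] - 1,
        GenomicRanges::end(carved)[i],
        "centromeres/telomeres may only carve the complement"))
    }
  }
  core <- core_tads
  ext_name <- S4Vectors::mcols(core)$id
  S4Vectors::mcols(core) <- NULL
  S4Vectors::mcols(core)$domain_class <- "core_tad"
  S4Vectors::mcols(core)$name <- if (is.null(ext_name)) {
    NA_character_
  } else {
    ext_name
  }
  if (length(carved)) {
    S4Vectors::mcols(carved)$name <- NA_character_
  }
  covered <- c(GenomicRanges::granges(core), GenomicRanges::granges(carved))
  whole <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(chrom_map),
    ranges = IRanges::IRanges(1, GenomeInfoDb::seqlengths(chrom_map)),
    seqinfo = chrom_map
  )
  inter <- GenomicRanges::setdiff(whole, covered, ignore.strand = TRUE)
  if (length(inter)) {
    S4Vectors::mcols(inter)$domain_class <- "inter_tad"
    S4Vectors::mcols(inter)$name <- NA_character_
  }
  part <- c(core, if (length(carved)) carved else NULL,
            if (length(inter)) inter else NULL)
  part <- GenomicRanges::sort(part, ignore.strand = TRUE)
  S4Vectors::mcols(part)$domain_class <- factor(
    S4Vectors::mcols(part)$domain_class,
    levels = c("core_tad", "inter_tad", "centromere", "telomere"))
  prefix <- c(core_tad = "T", inter_tad = "I", centromere = "C",
              telomere = "E")[as.character(S4Vectors::mcols(part)$domain_class)]
  chroms <- as.character(GenomeInfoDb::seqnames(part))
  ordinal <- stats::ave(seq_along(part), chroms, FUN = seq_along)
  S4Vectors::mcols(part)$domain_id <- paste0(prefix, ".", chroms, ".", ordinal)
  stopifnot(sum(as.numeric(GenomicRanges::width(part))) ==
              sum(as.numeric(GenomeInfoDb::seqlengths(chrom_map))))
  part
}

#' Summarise domain sizes
#'
#' Size statistics (count, min, median, mean, max) over the domain lengths of
#' the selected class(es), plus an optional histogram. An empty selection
#' yields a zero-count summary, not an error.
#'
#' @param partition A partition from [build_partition()].
#' @param classes Character vector of domain classes to keep; `NULL` keeps
#'   all.
#' @param breaks Optional numeric vector of histogram bin edges (bp).
#' @return A list with `count`, `min`, `median`, `mean`, `max`, and if
#'   `breaks` was given, `histogram` (a data.frame of bin edges and counts).
#' @export
size_summary <- function(partition, classes = NULL, breaks = NULL) {
  cls <- as.character(S4Vectors::mcols(partition)$domain_class)
  keep <- if (is.null(classes)) rep(TRUE, length(partition)) else cls %in% classes
  w <- GenomicRanges::width(partition)[keep]
  out <- list(
    count = length(w),
    min = if (length(w)) min(w) else NA_real_,
    median = if (length(w)) stats::median(w) else NA_real_,
    mean = if (length(w)) mean(w) else NA_real_,
    max = if (length(w)) max(w) else NA_real_
  )
  if (!is.null(breaks)) {
    h <- graphics::hist(w[w >= min(breaks) & w <= max(breaks)],
                        breaks = breaks, plot = FALSE)
    out$histogram <- data.frame(lower = utils::head(breaks, -1),
                                upper = breaks[-1], count = h$counts)
  }
  out
}

#' Neighbour table of a partition
#'
#' For each domain, the `domain_id`s of up to `flank_width` neighbours on
#' each side on the same chromosome, in genomic order. Used by the
#' adjacent-domain test's center/flank selection.
#'
#' @param partition A partition from [build_partition()].
#' @return A data.frame with columns `domain_id`, `chrom`, `pos` (ordinal
#'   within chromosome).
#' @keywords internal
partition_index <- function(partition) {
  chroms <- as.character(GenomeInfoDb::seqnames(partition))
  data.frame(domain_id = S4Vectors::mcols(partition)$domain_id,
             chrom = chroms,
             pos = stats::ave(seq_along(partition), chroms, FUN = seq_along))
}
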