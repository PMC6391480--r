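#' Build a chromosome map
#'
#' A chromosome map is the genome skeleton every region set is validated
#' against: a set of uniquely named chromosomes with strictly positive
#' lengths, held as a [GenomeInfoDb::Seqinfo] object. Following the study
#' design (not all blood donors carry one), `chrY` is dropped by default.
#'
#' @param chroms Character vector of chromosome names (unique).
#' @param lengths Integer vector of chromosome lengths in bp (> 0).
#' @param exclude Chromosome names to drop; default `"chrY"`. Use
#'   `character()` to keep everything.
#' @return A `Seqinfo` object.
#' @examples
#' chrom_map(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
chrom_map <- function(chroms, lengths, exclude = "chrY") {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths)) {
    stop("chroms and lengths must have equal length")
  }
  if (anyDuplicated(chroms)) {
    stop("duplicate chromosome names: ",
         paste(unique(chroms[duplicated(chroms)]), collapse = ", "))
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be strictly positive")
  }
  keep <- !(chroms %in% exclude)
  GenomeInfoDb::Seqinfo(seqnames = chroms[keep],
                        seqlengths = as.integer(lengths[keep]))
}

#' Read a UCSC chrom.sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path Path to the chrom.sizes file.
#' @inheritParams chrom_map
#' @return A `Seqinfo` object.
#' @export
read_chrom_sizes <- function(path, exclude = "chrY") {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  chrom_map(tab$chrom, tab$length, exclude = exclude)
}

#' Construct genomic intervals in BED coordinates
#'
#' Coordinates on disk and in this constructor follow the BED convention:
#' 0-based half-open `[start, end)`. Internally intervals are held as
#' [GenomicRanges::GRanges] (1-based closed), the standard Bioconductor
#' container; all exported arithmetic (`overlap_bp()`, `interval_midpoint()`)
#' is defined, documented and tested in BED coordinates.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open.
#' @param id Optional character vector of unique feature identifiers.
#' @param feature_class Optional feature class (recycled), e.g. `"H3K27ac"`,
#'   `"GR_peak"`, `"transcript"`, `"DHS"`.
#' @param chrom_map Optional `Seqinfo`; when given, intervals are validated
#'   against chromosome bounds and unknown chromosomes are an error.
#' @return A `GRanges` with optional `id` and `feature_class` metadata.
#' @examples
#' genomic_intervals("chr1", 10, 30, id = "pk1")
#' @export
genomic_intervals <- function(chrom, start, end, id = NULL,
                              feature_class = NULL, chrom_map = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop("interval coordinates must be finite")
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop("invalid interval(s) (need 0 <= start < end) at index ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start + 1, end = end)
  )
  if (!is.null(id)) {
    if (anyDuplicated(id)) {
      stop("duplicate interval ids: ",
           paste(unique(id[duplicated(id)]), collapse = ", "))
    }
    S4Vectors::mcols(gr)$id <- as.character(id)
  }
  if (!is.null(feature_class)) {
    S4Vectors::mcols(gr)$feature_class <- as.character(feature_class)
  }
  if (!is.null(chrom_map)) {
    gr <- validate_against_map(gr, chrom_map)
  }
  gr
}

## Attach a Seqinfo and fail loudly on out-of-bounds or unknown chromosomes.
validate_against_map <- function(gr, chrom_map) {
  known <- GenomeInfoDb::seqnames(chrom_map)
  seen <- as.character(unique(GenomeInfoDb::seqnames(gr)))
  unknown <- setdiff(seen, known)
  if (length(unknown)) {
    stop("intervals on chromosome(s) absent from the chromosome map: ",
         paste(unknown, collapse = ", "))
  }
  lens <- GenomeInfoDb::seqlengths(chrom_map)[
    as.character(GenomeInfoDb::seqnames(gr))]
  over <- which(GenomicRanges::end(gr) > lens)
  if (length(over)) {
    stop("interval(s) extend beyond chromosome end at index ",
         paste(utils::head(over, 5), collapse = ", "))
  }
  GenomeInfoDb::seqlevels(gr) <- known
  GenomeInfoDb::seqinfo(gr) <- chrom_map
  gr
}

#' Base pairs of overlap between paired intervals
#'
#' Element-wise overlap in bp between two equal-length `GRanges`:
#' `max(0, min(end) - max(start))` in BED coordinates, 0 when chromosomes
#' differ. Abutting half-open intervals overlap by 0.
#'
#' @param a,b `GRanges` of equal length.
#' @return Integer vector of overlap widths in bp.
#' @export
overlap_bp <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  same <- as.character(GenomeInfoDb::seqnames(a)) ==
    as.character(GenomeInfoDb::seqnames(b))
  ov <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  as.integer(ifelse(same, pmax(0L, ov), 0L))
}

#' Interval midpoints in BED coordinates
#'
#' Midpoint of `[start, end)` defined as `floor((start + end) / 2)` on the
#' 0-based scale; this is the position used by the midpoint assignment rule.
#'
#' @param gr A `GRanges`.
#' @return Numeric vector of 0-based midpoint positions.
#' @export
interval_midpoint <- function(gr) {
  s0 <- GenomicRanges::start(gr) - 1
  e0 <- GenomicRanges::end(gr)
  floor((s0 + e0) / 2)
}

#' Read a BED3/BED4 file
#'
#' Columns: chrom, start, end, and optionally a name column that becomes the
#' feature `id`. Coordinates are 0-based half-open. Malformed lines and
#' inverted coordinates are errors naming the offending line.
#'
#' @param path Path to a BED file (plain text, tab-separated).
#' @param feature_class Optional feature class stored on every record.
#' @param chrom_map Optional `Seqinfo` used for validation.
#' @return A `GRanges` with `id` (and `feature_class`) metadata.
#' @export
read_bed <- function(path, feature_class = NULL, chrom_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(genomic_intervals(character(), numeric(), numeric(),
                             feature_class = feature_class))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line (fewer than 3 fields) at line ",
         which(nf < 3)[1])
  }
  chroms <- vapply(fields, `[[`, character(1), 1)
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad)) {
    stop("non-numeric BED coordinates at line ", bad[1])
  }
  inv <- which(starts >= ends)
  if (length(inv)) {
    stop("BED interval with start >= end at line ", inv[1])
  }
  ids <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                character(1)),
                paste0("feat", seq_along(fields)))
  genomic_intervals(chroms, starts, ends, id = ids,
                    feature_class = feature_class, chrom_map = chrom_map)
}

#' Write intervals to BED4
#'
#' Inverse of [read_bed()]: coordinates are converted back to 0-based
#' half-open; `id` metadata (or generated names) fills column 4. Round-trip
#' through `write_bed()` then `read_bed()` is exact on chrom/start/end/id.
#'
#' @param gr A `GRanges`, optionally carrying `id` metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  ids <- S4Vectors::mcols(gr)$id
  if (is.null(ids)) ids <- paste0("feat", seq_along(gr))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = format(GenomicRanges::start(gr) - 1, scientific = FALSE,
                   trim = TRUE),
    end = format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE),
    id = ids
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Canonical column names of a differential-statistics table: one base mean
## plus (log2 fold change, adjusted p) for the three contrasts.
DIFF_COLUMNS <- c("base_mean",
                  "log2fc_ta_mo", "padj_ta_mo",
                  "log2fc_ta_mf", "padj_ta_mf",
                  "log2fc_mo_mf", "padj_mo_mf")

#' Read a differential-statistics table
#'
#' Tab-separated table with a header naming an `id` column and the seven
#' statistic columns: `base_mean`, and `log2fc_*` / `padj_*` for the three
#' contrasts `ta_mo` (treatment effect in monocytes), `ta_mf` (treatment
#' effect in macrophages) and `mo_mf` (differentiation). These are consumed
#' as produced by an upstream differential analysis (e.g. DESeq2); no
#' refitting happens here. Unparsable numeric cells become `NA` and are
#' flagged, never silently dropped.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with one row per feature, columns `id` +
#'   the seven statistics, and a logical column `complete` (TRUE when all
#'   seven statistics parsed).
#' @export
read_differential_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (!"id" %in% names(tab)) stop("differential table lacks an 'id' column")
  missing_cols <- setdiff(DIFF_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("differential table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate feature id(s) in differential table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  out <- data.frame(id = tab$id)
  for (cn in DIFF_COLUMNS) {
    out[[cn]] <- suppressWarnings(as.numeric(tab[[cn]]))
  }
  for (cn in grep("^padj", DIFF_COLUMNS, value = TRUE)) {
    bad <- which(!is.na(out[[cn]]) & (out[[cn]] < 0 | out[[cn]] > 1))
    if (length(bad)) {
      stop("adjusted p-value outside [0,1] for id ",
           paste(utils::head(out$id[bad], 5), collapse = ", "))
    }
  }
  if (any(!is.na(out$base_mean) & out$base_mean < 0)) {
    stop("negative base_mean encountered")
  }
  out$complete <- stats::complete.cases(out[, DIFF_COLUMNS])
  out
}

#' Write a differential-statistics table
#'
#' @param stats A `data.frame` as returned by [read_differential_table()]
#'   (the `complete` column, if present, is not written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(stats, path) {
  cols <- c("id", DIFF_COLUMNS)
  utils::write.table(stats[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
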