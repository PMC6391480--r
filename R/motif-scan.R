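## IUPAC nucleotide codes -> set of concrete bases.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Define an IUPAC consensus motif
#'
#' Exact-consensus motifs are used rather than weight matrices: the two
#' steroid-response motifs of interest are published as consensus strings,
#' and exact IUPAC matching is reproducible without any external motif
#' model files. [gre_motif()] and [steroid_half_site()] return the
#' glucocorticoid response element (`GRACANNNTGTYC`) and the steroid
#' receptor half-site (`CCNGGNACA`).
#'
#' @param name Motif name.
#' @param pattern Non-empty IUPAC string (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @return A list of class `"consensus_motif"`.
#' @export
consensus_motif <- function(name, pattern) {
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) stop("empty motif pattern")
  letters <- strsplit(pattern, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC letter(s) in motif: ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, pattern = pattern, length = nchar(pattern)),
            class = "consensus_motif")
}

#' @rdname consensus_motif
#' @export
gre_motif <- function() consensus_motif("GRE", "GRACANNNTGTYC")

#' @rdname consensus_motif
#' @export
steroid_half_site <- function() consensus_motif("AR-half", "CCNGGNACA")

## Normalize input sequences to a named DNAStringSet, rejecting non-ACGTN.
as_region_sequences <- function(sequences) {
  if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      names(sequences) <- paste0("region", seq_along(sequences))
    }
    sequences <- toupper(sequences)
    bad <- grepl("[^ACGTN]", sequences)
    if (any(bad)) {
      stop("invalid base(s) outside ACGTN in region: ",
           paste(utils::head(names(sequences)[bad], 5), collapse = ", "))
    }
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (!methods::is(sequences, "DNAStringSet")) {
    stop("sequences must be a character vector or DNAStringSet")
  }
  freq <- Biostrings::alphabetFrequency(sequences)
  allowed <- c("A", "C", "G", "T", "N")
  other <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(other > 0)) {
    stop("invalid base(s) outside ACGTN in region: ",
         paste(utils::head(names(sequences)[other > 0], 5), collapse = ", "))
  }
  sequences
}

#' Scan sequences for an IUPAC consensus motif
#'
#' Reports all matches of the consensus on both strands: the pattern is
#' matched on the forward sequence, and its reverse complement is matched
#' on the forward sequence to give minus-strand hits. A position is a match
#' when every subject base is contained in the corresponding pattern
#' letter's IUPAC set (so a subject `N` only matches a pattern `N`).
#' Overlapping matches are all reported. A match identical on both strands
#' at the same position (palindrome) is counted once, on the plus strand.
#'
#' @param sequences Named character vector or `DNAStringSet` of region
#'   sequences (ACGTN only).
#' @param motif A [consensus_motif()].
#' @return data.frame with columns `region_id`, `offset` (0-based from
#'   region start to match start), `strand`, `match` (the matched
#'   substring).
#' @export
scan_motif <- function(sequences, motif) {
  stopifnot(inherits(motif, "consensus_motif"))
  sequences <- as_region_sequences(sequences)
  fwd <- Biostrings::DNAString(motif$pattern)
  rev <- Biostrings::reverseComplement(fwd)
  hit_frame <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, sequences, fixed = "subject")
    n_per <- lengths(m)
    if (!sum(n_per)) {
      return(data.frame(region_id = character(), offset = integer(),
                        strand = character(), match = character()))
    }
    starts <- unlist(lapply(m, IRanges::start), use.names = FALSE)
    region <- rep(names(sequences), n_per)
    seqs <- rep(sequences, n_per)
    match <- as.character(Biostrings::subseq(seqs, start = starts,
                                             width = motif$length))
    data.frame(region_id = region, offset = starts - 1L,
               strand = strand, match = match)
  }
  hits <- rbind(hit_frame(fwd, "+"), hit_frame(rev, "-"))
  if (nrow(hits)) {
    key <- paste(hits$region_id, hits$offset, hits$match)
    ord <- order(hits$strand != "+")  # "+" first: palindromes keep "+"
    hits <- hits[ord, ][!duplicated(key[ord]), ]
    hits <- hits[order(hits$region_id, hits$offset, hits$strand), ]
    rownames(hits) <- NULL
  }
  hits
}

#' Fraction of regions with at least one motif hit
#'
#' Invariant to duplicate hits within a region.
#'
#' @param hits data.frame from [scan_motif()].
#' @param region_ids Character vector of all scanned region ids (non-empty;
#'   defines the denominator).
#' @return Fraction in [0, 1].
#' @export
region_hit_frequency <- function(hits, region_ids) {
  if (!length(region_ids)) stop("empty region set: frequency undefined")
  mean(region_ids %in% hits$region_id)
}

#' Motif enrichment as a frequency difference
#'
#' Enrichment is the difference between motif frequency in the target
#' regions and in a background region set (may be negative).
#'
#' @param target_freq,background_freq Frequencies in [0, 1].
#' @return `target_freq - background_freq`.
#' @export
motif_enrichment <- function(target_freq, background_freq) {
  stopifnot(target_freq >= 0, target_freq <= 1,
            background_freq >= 0, background_freq <= 1)
  target_freq - background_freq
}

#' Positional density of motif hits around region centers
#'
#' Offsets of motif centers relative to region centers, binned over a
#' symmetric span (default 40 bins of 20 bp covering [-400, +400); an
#' offset of 0 falls in bin 21 of 40, the first bin right of center). Hits
#' outside the span are dropped from the bins and counted separately.
#'
#' @param hits data.frame from [scan_motif()].
#' @param region_lengths Named numeric vector: length in bp per region id.
#' @param motif_length Motif length in bp.
#' @param n_bins,bin_width Binning; total span `n_bins * bin_width` must be
#'   even so the span is symmetric around the center.
#' @return data.frame with `bin` (1-based), `lower`, `upper` (offsets, bp)
#'   and `count`; attribute `n_out_of_span` counts dropped hits.
#' @export
positional_density <- function(hits, region_lengths, motif_length,
                               n_bins = 40, bin_width = 20) {
  span <- n_bins * bin_width
  if (span %% 2 != 0) {
    stop("n_bins * bin_width must be even (symmetric span)")
  }
  half <- span / 2
  if (nrow(hits)) {
    reg_center <- floor(region_lengths[hits$region_id] / 2)
    motif_center <- hits$offset + floor(motif_length / 2)
    rel <- motif_center - reg_center
    idx <- floor((rel + half) / bin_width)
    in_span <- idx >= 0 & idx < n_bins
    counts <- tabulate(idx[in_span] + 1L, nbins = n_bins)
    dropped <- sum(!in_span)
  } else {
    counts <- integer(n_bins)
    dropped <- 0L
  }
  out <- data.frame(bin = seq_len(n_bins),
                    lower = -half + (seq_len(n_bins) - 1) * bin_width,
                    upper = -half + seq_len(n_bins) * bin_width,
                    count = counts)
  attr(out, "n_out_of_span") <- dropped
  out
}

#' Extract region sequences from a genome FASTA
#'
#' Convenience utility: reads a genome FASTA with
#' [Biostrings::readDNAStringSet()] and extracts the sequence under each
#' region. No genome download is required anywhere in the package; the
#' synthetic generator produces region FASTA directly.
#'
#' @param genome_fasta Path to a FASTA whose record names are chromosome
#'   names.
#' @param regions `GRanges` with `id` metadata.
#' @return A `DNAStringSet` named by region id.
#' @export
extract_region_sequences <- function(genome_fasta, regions) {
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chroms <- as.character(GenomeInfoDb::seqnames(regions))
  missing_chr <- setdiff(unique(chroms), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from genome FASTA: ",
         paste(missing_chr, collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(vapply(seq_along(regions), function(i) {
    as.character(Biostrings::subseq(genome[[chroms[i]]],
                                    start = GenomicRanges::start(regions)[i],
                                    end = GenomicRanges::end(regions)[i]))
  }, character(1)))
  ids <- S4Vectors::mcols(regions)$id
  names(out) <- if (is.null(ids)) paste0("region", seq_along(regions)) else ids
  out
}
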