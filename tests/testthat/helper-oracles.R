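# Independent oracles used across tests. These deliberately avoid the code
# paths they check: exhaustive enumeration for the exact tails, a naive
# letter-by-letter matcher for motif scanning, and all-pairs scans for the
# proximity and adjacent-domain procedures.

# P(X >= k) for X ~ Binomial(n, p) by enumerating all 2^n outcome vectors.
enum_binomial_tail <- function(k, n, p) {
  if (n == 0) return(if (k == 0) 1 else 0)
  outcomes <- expand.grid(rep(list(c(0, 1)), n))
  s <- rowSums(outcomes)
  probs <- p^s * (1 - p)^(n - s)
  sum(probs[s >= k])
}

# Upper hypergeometric tail by enumerating all size-n subsets of an urn of
# N items of which the first K are successes.
enum_hypergeom_tail <- function(k, n, K, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  subsets <- utils::combn(N, n)
  succ <- colSums(subsets <= K)
  mean(succ >= k)
}

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Letter-compatibility table from the definition: subject letter s is
# allowed under pattern letter p iff set(s) is contained in set(p), so a
# subject N matches only a pattern N.
iupac_allowed <- local({
  ltr <- names(iupac_sets)
  m <- outer(ltr, ltr, Vectorize(function(s, p) {
    all(iupac_sets[[s]] %in% iupac_sets[[p]])
  }))
  dimnames(m) <- list(subject = ltr, pattern = ltr)
  m
})

# One-strand naive scan: position-by-position containment check.
naive_scan_one <- function(seq, pattern) {
  sv <- strsplit(seq, "")[[1]]
  pv <- strsplit(pattern, "")[[1]]
  L <- length(sv); m <- length(pv)
  if (L < m) return(integer())
  si <- match(sv, rownames(iupac_allowed))
  pi <- match(pv, colnames(iupac_allowed))
  ok <- rep(TRUE, L - m + 1)
  for (j in seq_len(m)) {
    ok <- ok & iupac_allowed[cbind(si[j:(j + L - m)], pi[j])]
  }
  which(ok) - 1L  # 0-based offsets
}

# Both-strand naive scan with palindromic dedup by (offset, matched string).
naive_scan <- function(seq, pattern) {
  fwd <- naive_scan_one(seq, pattern)
  rev <- naive_scan_one(seq, revcomp_chr(pattern))
  m <- nchar(pattern)
  sub_at <- function(off) substr(seq, off + 1, off + m)
  hits <- rbind(
    if (length(fwd)) data.frame(offset = fwd, strand = "+",
                                match = vapply(fwd, sub_at, character(1))),
    if (length(rev)) data.frame(offset = rev, strand = "-",
                                match = vapply(rev, sub_at, character(1))))
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(offset = integer(), strand = character(),
                      match = character()))
  }
  key <- paste(hits$offset, hits$match)
  ord <- order(hits$strand != "+")
  hits <- hits[ord, ][!duplicated(key[ord]), ]
  hits[order(hits$offset), ]
}

# All-pairs brute-force close-pair scan on midpoints.
brute_close_pairs <- function(chrom, mid, max_sep) {
  n <- length(mid)
  out <- 0L
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (chrom[i] == chrom[j] && abs(mid[i] - mid[j]) <= max_sep) {
        out <- out + 1L
      }
    }
  }
  out
}

# Re-count adjacent-domain successes with an explicit per-set loop.
brute_adjacent_successes <- function(sets, num, den) {
  ratio <- function(id) {
    nn <- ifelse(id %in% names(num), num[id], 0)
    dd <- ifelse(id %in% names(den), den[id], 0)
    if (is.na(dd) || dd == 0) 0 else nn / dd
  }
  succ <- 0L
  flank_cols <- grep("^flank_", names(sets), value = TRUE)
  for (r in seq_len(nrow(sets))) {
    cr <- ratio(sets$center[r])
    fr <- vapply(flank_cols, function(cn) ratio(sets[[cn]][r]), numeric(1))
    if (all(cr > fr)) succ <- succ + 1L
  }
  succ
}
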