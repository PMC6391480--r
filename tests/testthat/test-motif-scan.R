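test_that("motif validation accepts IUPAC and rejects junk", {
  expect_identical(gre_motif()$pattern, "GRACANNNTGTYC")
  expect_identical(steroid_half_site()$pattern, "CCNGGNACA")
  expect_error(consensus_motif("bad", ""), "empty")
  expect_error(consensus_motif("bad", "ACGTX"), "invalid IUPAC")
})

test_that("consensus scanning resolves ambiguity codes on both strands", {
  # R matches G and Y matches C at offset 0; the GRE consensus is its own
  # reverse complement, so the palindromic hit is reported once, on "+"
  h <- scan_motif(c(r1 = "GGACATTTTGTCC"), gre_motif())
  expect_identical(nrow(h), 1L)
  expect_identical(h$offset, 0L)
  expect_identical(h$strand, "+")
  expect_identical(h$match, "GGACATTTTGTCC")
  # no match in a homopolymer
  expect_identical(nrow(scan_motif(c(r1 = strrep("A", 40)), gre_motif())),
                   0L)
  # a minus-strand-only instance is found
  half <- steroid_half_site()  # CCNGGNACA, not palindromic
  inst <- "CCTGGTACA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(inst)))
  h2 <- scan_motif(c(r1 = paste0("AAAA", rc, "AAAA")), half)
  expect_identical(h2$strand, "-")
  expect_identical(h2$offset, 4L)
  expect_error(scan_motif(c(r1 = "ACGTQACGT"), gre_motif()), "invalid base")
})

test_that("scanning agrees with the naive matcher on random sequences", {
  for (s in 1:6) {
    seq <- random_dna(2000, seed = 100 + s)
    for (motif in list(gre_motif(), steroid_half_site(),
                       consensus_motif("w", "WWSSWW"))) {
      got <- scan_motif(stats::setNames(seq, "r"), motif)
      want <- naive_scan(seq, motif$pattern)
      expect_identical(got$offset, want$offset)
      expect_identical(got$strand, want$strand)
      expect_identical(got$match, want$match)
    }
  }
  # strand symmetry: the reverse complement has the same hit count
  seq <- random_dna(5000, seed = 321)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  expect_identical(nrow(scan_motif(c(r = seq), gre_motif())),
                   nrow(scan_motif(c(r = rc), gre_motif())))
})

test_that("an all-N pattern matches every position", {
  # every position matches on both strands with the same forward-strand
  # text, so after both-strand canonicalization each position reports one
  # hit, on "+"
  seq <- random_dna(100, seed = 5)
  h <- scan_motif(c(r = seq), consensus_motif("anyN", strrep("N", 8)))
  expect_identical(h$offset, 0:92)
  expect_identical(unique(h$strand), "+")
})

test_that("region frequency and enrichment behave as fractions", {
  hits <- data.frame(region_id = c("r1", "r1", "r2"), offset = 0L,
                     strand = "+", match = "X")
  expect_equal(region_hit_frequency(hits, paste0("r", 1:4)), 0.5)
  expect_equal(region_hit_frequency(hits, c("r1", "r2")), 1.0)
  expect_error(region_hit_frequency(hits, character()), "empty region")
  expect_equal(motif_enrichment(0.79, 0.18), 0.61, tolerance = 1e-12)
  expect_equal(motif_enrichment(0.5, 0.5), 0)
  expect_equal(motif_enrichment(0.0, 0.5), -0.5)
})

test_that("positional density bins a symmetric span around the center", {
  lens <- c(r = 1000)
  mk_hit <- function(offset) {
    data.frame(region_id = "r", offset = offset, strand = "+", match = "M")
  }
  m <- 20  # even motif length: center = offset + 10
  # motif centered exactly on the region center falls in bin 21 (offset 0)
  d <- positional_density(mk_hit(500 - 10), lens, m)
  expect_identical(d$count[21], 1L)
  expect_identical(sum(d$count), 1L)
  # span edges: -400 in bin 1, +399 in bin 40
  d_lo <- positional_density(mk_hit(500 - 10 - 400), lens, m)
  expect_identical(d_lo$count[1], 1L)
  d_hi <- positional_density(mk_hit(500 - 10 + 399), lens, m)
  expect_identical(d_hi$count[40], 1L)
  # just outside the span is dropped and counted separately
  d_out <- positional_density(mk_hit(500 - 10 + 400), lens, m)
  expect_identical(sum(d_out$count), 0L)
  expect_identical(attr(d_out, "n_out_of_span"), 1L)
  expect_error(positional_density(mk_hit(0), lens, m, n_bins = 3,
                                  bin_width = 7), "even")
  # uniform offsets stay within 4 sigma of the multinomial expectation
  set.seed(99)
  n <- 10000
  offs <- sample(0:(1000 - m), n, replace = TRUE)
  du <- positional_density(data.frame(region_id = "r", offset = offs,
                                      strand = "+", match = "M"), lens, m)
  in_span <- sum(du$count)
  sigma <- sqrt(in_span * (1 / 40) * (39 / 40))
  expect_true(all(abs(du$count - in_span / 40) < 4 * sigma))
})

test_that("genome FASTA extraction returns the sequence under each region", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 test", "ACGTACGTACGTACGTACGT"), fa)
  regions <- genomic_intervals(c("chr1", "chr1"), c(0, 4), c(4, 12),
                               id = c("x", "y"))
  seqs <- extract_region_sequences(fa, regions)
  expect_identical(as.character(seqs), c(x = "ACGT", y = "ACGTACGT"))
  bad <- genomic_intervals("chr9", 0, 4, id = "z")
  expect_error(extract_region_sequences(fa, bad), "absent")
})
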