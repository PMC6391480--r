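---
title: "TAD-level integration of glucocorticoid-response genomics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TAD-level integration of glucocorticoid-response genomics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadenrich)
```

## The scientific problem

Glucocorticoids act through the glucocorticoid receptor (GR), a
ligand-activated transcription factor that binds a few hundred genomic
sites in primary human monocytes (Mo) and monocyte-derived macrophages
(Mf), yet thousands of regulatory regions — most visibly H3K27ac-marked
enhancers — change activity after treatment. Many induced regions carry
neither a GR peak nor a recognizable glucocorticoid response element
(GRE), which suggests that they respond *in cis* to GR bound elsewhere in
the same regulatory neighbourhood. Topologically associating domains
(TADs) are a natural candidate for those neighbourhoods: if GR signalling
is confined by TAD boundaries, GR-bound TADs should concentrate induced
features relative to their immediate neighbours, and features placed in
the same TAD should co-vary across data types.

`tadenrich` implements that integration strategy as a tested pipeline:

1. a typed, genome-covering **domain partition** built from a TAD call
   set (core TADs, the inter-TAD complement, centromeres, telomeres);
2. **response classification** of differential statistics into
   up/down/unresponsive calls and six clusters crossing the treatment
   response with differentiation dynamics;
3. **midpoint assignment** of features to domains and per-domain count
   matrices, plus proximity analyses;
4. the **adjacent-domain strict-maximum binomial test** and
   **hypergeometric domain enrichment**;
5. **IUPAC consensus scanning** for steroid-response motifs;
6. **TAD-level Spearman correlation** with average-linkage clustering;
7. a **synthetic-data generator** that reproduces the statistical
   structure of all of these inputs, so every stage is testable without
   any external download.

## The domain partition

Published TAD calls leave a large fraction of the genome unassigned. To
chart whole chromosomes, every uncovered span between core TADs becomes
an `inter_tad` domain; centromere and telomere annotations become their
own typed domains. Three rules keep the construction honest:

* core TADs are never truncated — an annotation interval overlapping a
  core TAD is an input **error**, not something to resolve silently,
  because the TAD call set is treated as fixed upstream input;
* zero-length gaps between abutting TADs produce nothing;
* the partition must tile each chromosome exactly (the builder asserts
  that summed domain lengths equal chromosome lengths).

Domain identifiers are `"{class}.{chrom}.{ordinal}"` assigned
left-to-right, stable across runs; external labels from BED column 4
(e.g. published TAD numbers) are preserved in a `name` field.

Coordinates follow the BED convention (0-based, half-open) in every file
this package reads or writes. Internally intervals are `GRanges`
(1-based, closed) — the standard Bioconductor container, whose interval
algebra implements the overlap and complement operations — and the
exported arithmetic (`overlap_bp()`, `interval_midpoint()`) is defined
and tested on the BED scale. Strand is ignored throughout: all region
sets here are unstranded. Conversion from any 1-based external source is
the caller's responsibility.

## Response classification

A feature is called responsive in a contrast when
`|log2FC| > min_abs_log2fc` (default 1, i.e. two-fold) with
`padj < max_padj` (default 0.05), and its base mean expression exceeds
`min_base_mean` (default 20 normalized reads). The defaults mirror the
transcript analysis the upstream differential tables come from; histone
region sets are typically classified with `min_base_mean = 0`, and broad
H3K4me1 regions support a lowered 1.5-fold cut-off applied **per feature
class** (a region spanning dozens of nucleosomes can show a robust but
numerically modest aggregate fold change).

The same thresholds are reused for the Mo-to-Mf differentiation contrast
(`mf_high` / `mo_high` / `static`); a single thresholds object keeps the
pipeline internally consistent, and each cut-off is configurable. The six
clusters cross the overall treatment direction (up/down in either cell
type) with the differentiation label; cluster 1 is "up & Mf-high",
cluster 6 "down & Mo-high". Two guard rails matter:

* a feature up in one cell type and down in the other receives an
  explicit `discordant` label and no cluster — such features were not
  observed in the motivating data, and the code must never misfile one;
* features with missing statistics go to an `unclassifiable` bin that is
  reported, never imputed and never silently dropped.

Adjusted p-values are taken as input; if raw p-values are supplied
instead, Benjamini–Hochberg is applied per contrast and announced.

## Assignment and proximity

Features are assigned to the unique domain containing their interval
midpoint (`floor((start + end) / 2)` on the BED scale). Over a partition
the midpoint rule makes assignment total and unambiguous, which is why it
is the default rather than fractional overlap; an any-overlap mode with
largest-overlap tie-break, and a TSS mode for transcript sets, are
provided. Two distance conventions coexist deliberately:

* `features_within()` uses **edge-to-edge gaps** (inclusive): "induction
  within 500 bp of a peak" reads most naturally as clearance between
  region edges, and a gap of exactly 500 bp is included;
* `close_pairs()` uses **midpoint separation** (inclusive): spacing
  between peaks is a center-to-center notion. Chained pairs are merged
  into multi-peak loci (connected components).

For the adjacent-domain test's denominators, "expressed transcripts" per
domain means transcripts above the base-mean floor, and "epigenetic
features" means all assigned peaks of the relevant class.

## The adjacent-domain test

For each domain bearing at least one qualifying GR peak we ask whether
the domain's *normalized* responsive-feature count strictly exceeds that
of its two left and two right neighbours. Two flanking domains per side
are used because well-defined TADs are often flanked by tiny interstitial
domains that a single-domain flank could not see past. Centers must have
exactly two neighbours on each side on their own chromosome (domains near
chromosome ends are excluded, not padded) and all four flanks must be
free of GR peaks — by default free of *any* GR peak, the stricter reading;
a mode restricting the exclusion to the center-defining peak set is
available. By construction selected centers are mutually non-adjacent.

Each set contributes one Bernoulli trial: success iff the center's ratio
(responsive count divided by the domain total; 0/0 counts as 0) strictly
exceeds all four flank ratios. Under the null that feature placement is
independent of GR occupancy, **and** that the five domains' ratios are
exchangeable, the strict maximum lands on the center with probability
exactly 1/5 — this is precisely why ties count as failures (conservative;
a randomized tie-break is available for calibration studies). The
p-value is the exact upper binomial tail of the success count at null
probability 1/5:

```{r}
binomial_tail(134, 249, 0.2)
```

Tails are computed by log-sum-exp over log binomial coefficients, never
via `1 - CDF`, so values around 1e-32 retain full relative precision.
The hypergeometric tail used for domain enrichment is computed the same
way. The default hypergeometric parameterization is: population = all
features of the class, population successes = features in GR-bearing
domains, draws = induced features, observed = induced features in
GR-bearing domains; the test function itself is
parameterization-agnostic.

## TAD-level correlation

Per-domain count vectors of each dataset are compared by Spearman rank
correlation (average ranks under ties — hence invariance to any strictly
monotone transform of a dataset) and clustered by average linkage on
`1 - rho`. A dataset constant across domains has undefined rank
correlations; it is reported as `NA` and excluded from clustering with a
warning rather than failing the run. Merge order is deterministic
(`stats::hclust` with tie-break by index); the dendrogram can be exported
as Newick.

## Motif scanning

The two steroid-response motifs are published as consensus strings — GRE
`GRACANNNTGTYC` and the androgen-receptor half-site `CCNGGNACA` — so the
scanner does exact IUPAC consensus matching, which is reproducible
without any external motif-model files; position weight matrices are a
non-goal. A subject base matches a pattern letter when its IUPAC set is
contained in the pattern letter's set (so a subject `N` matches only a
pattern `N`). Both strands are scanned by matching the pattern and its
reverse complement against the forward sequence; hits are canonicalized
by (region, offset, forward-strand text), so a site whose two strand
readings both satisfy the consensus is reported once, on "+". Enrichment
is the plain frequency difference between target and background region
sets, and positional density bins motif-center offsets around region
centers (default 40 bins of 20 bp over [-400, +400); an offset of 0
falls in the first bin right of center).

Consensus frequencies are not comparable to frequencies obtained with
probabilistic motif scoring on real genome sequence; the synthetic
sequences here are the intended test substrate.

## The synthetic-data generator

The generator's defaults emulate the study's data shapes at roughly
one-third genome scale: 8 chromosomes with 150 core TADs each (log-normal
lengths, median 500 kb, sdlog 0.6), a wide-spread inter-TAD complement
(log-normal gaps, median 30 kb, sdlog 1.8, so many interstitial domains
of a few kb), 10 kb telomeres and a 3 Mb centromere per chromosome, 10%
of core TADs GR-bearing, 600 bp features (the H3K27ac peak scale), and a
differential table whose six-cluster proportions cross a 20% responsive
rate and a 57/43 up/down split with the reported within-direction
differentiation splits (up: 51/32/17 Mf-high/static/Mo-high; down:
16/27/57). Planted effects are ±2 log2 units with Gaussian noise
(sd 0.25); significant contrasts draw `padj ~ U(0, 0.04)` and null
contrasts `padj ~ U(0.06, 1)`, so a zero-noise table is recovered
exactly and an all-null table yields zero calls by construction. Region
sequences are uniform ACGT with one motif realization (ambiguities
resolved uniformly) planted at a uniform position and strand in a
configured fraction of sequences.

Induced features land in domain *d* with probability proportional to
`length(d) * theta` for GR-bearing *d* and `length(d)` otherwise;
`theta = 1` is the exact placement null. Placement is implemented as a
multinomial draw of per-domain counts followed by uniform positions
within the domain (features are clipped to domain bounds, so midpoint
assignment provably recovers the planted domain). Every generator derives
an isolated RNG stream from `(seed, call tag)` and restores the caller's
RNG state, so adding a generator never perturbs another's output and all
outputs are byte-identical across runs.

What the generator does **not** emulate: correlated placement of
distinct feature classes, sequence composition bias, peak-width
variation, chromosome-specific TAD density, and real TAD nesting
("large inter-TADs may be several unresolved TADs"). Passing tests
therefore demonstrate correctness of the procedures under the stated
placement laws, not fidelity to any particular genome.

## Calibration design

The 1/5 null of the adjacent-domain test is exact only when the five
ratios of a center/flank set are exchangeable. In study-shaped
partitions they are not quite: flanks are often tiny interstitial
domains whose ratios are noisier than the center's, so the strict
maximum lands on the center slightly less often than 1/5 — the same
structural caveat that motivated using two flanking domains per side in
the first place. The calibration harness therefore verifies the
implementation under the null's own premise: gap-free TAD chains with a
narrow length spread (sdlog 0.2), GR domains placed on every 6th TAD so
center/flank sets are disjoint and independent, and per-domain expected
counts large (hundreds per domain) so ratio ties are negligible. Under
those conditions ~1,000 center sets per genome give a success fraction
within three binomial standard errors of 1/5 and near-nominal type-I
error at alpha = 0.05. P-value uniformity is judged on the randomized
probability integral transform `P(X > k) + U * P(X = k)`: the exact
test's p-values are discrete (granularity about 0.03 at a thousand
sets), so the raw values can never pass a Kolmogorov–Smirnov test
against the continuous uniform, while their randomized PIT is exactly
Uniform(0, 1) precisely when the success counts follow the
Binomial(n, 1/5) null. Power is verified to increase
strictly over placement odds theta in {1, 2, 4, 8} at low per-domain
induced counts, where the success probability has room to rise before
saturating.

Problem sizes used by the test-suite and the acceptance script — a
6,070-domain calibration genome with 3 million placed features for the
single full-pipeline null run, 1,000 count-level replicates for type-I
error and uniformity, a 2,428-domain genome for the power curve, 10,000
differential rows, and 2,000 sequences of 200 bp — were chosen as the
smallest sizes at which the binomial/multinomial error bands in these
checks are decisively narrower than the effects being verified.

## Numerical and degenerate-input choices

* Exact tails in log space (`lchoose` + log-sum-exp); `k = 0` returns 1
  identically; out-of-range parameters are errors, not clamped.
* Ratios `0/0` count as 0 in the adjacent test (an empty domain cannot
  be a strict maximum, and cannot be beaten by an equally empty flank).
* Empty selections are empty results (`size_summary` of no domains, zero
  eligible centers in `select_center_domains`), but running the test on
  zero sets is an error ("no eligible domains").
* An empty query set makes `overlap_fraction` undefined — an error, not
  `NaN`.
* BED parsing errors name the offending line; duplicate feature ids and
  inverted coordinates are errors everywhere.

## Real-data counts

Counts tied to the motivating study's real data — numbers of induced
transcripts and dynamic H3K27ac regions, inter-TAD counts, GR-TAD
capture percentages, and the reported hypergeometric p-values (whose
exact population definitions are not recoverable) — require the
deposited sequencing datasets plus the external macrophage TAD call set
and a centromere/telomere annotation source. They are deliberately
not asserted anywhere in this package; the property-based synthetic
suite above stands in for them. The printed adjacent-TAD success counts
(134, 100 and 28 of 249), by contrast, are pure inputs to the exact
binomial tail and are reproduced to three significant figures by
`binomial_tail()`.
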