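# tadenrich

Integration of glucocorticoid-response genomics at the level of
topologically associating domains (TADs), for regulatory genomicists who
want to test whether a transcription factor's chromosomal binding events
concentrate responsive features within domain boundaries.

Glucocorticoids acting through the glucocorticoid receptor (GR) induce
thousands of H3K27ac and transcript changes in primary human monocytes
and macrophages, while GR itself binds only a few hundred sites. Many
induced regions carry neither a GR peak nor a glucocorticoid response
element (GRE), suggesting *cis* effects confined by TAD boundaries. This
package implements the TAD-based test of that idea, plus everything
around it: a typed genome partition (core TADs, the inter-TAD
complement, centromeres, telomeres), differential-feature
classification into six response clusters, midpoint assignment of
features to domains, proximity analyses, IUPAC consensus scanning for
steroid-response motifs, TAD-level Spearman clustering, and a
synthetic-data generator so that the whole pipeline is testable offline.

## The core statistic

For each domain bearing a qualifying GR peak, whose two left and two
right neighbours are GR-free (and exist on the same chromosome), compare
the center's normalized count of responsive features,

r_d = (responsive features in d) / (total features in d),

with the four flank ratios. A set is a success iff the center's ratio is
the **strict maximum** of the five; ties are failures. Under the null
that feature placement is independent of GR occupancy, with exchangeable
domains, P(success) = 1/5 exactly, and the p-value for k successes in n
sets is the exact upper binomial tail

P(X >= k), X ~ Binomial(n, 1/5),

computed in log space so extreme tails (1e-32 and beyond) retain full
relative precision. Hypergeometric domain enrichment, six-cluster
stratification (|log2FC| > 1, padj < 0.05, base mean > 20), exact IUPAC
consensus scanning for `GRACANNNTGTYC` (GRE) and `CCNGGNACA` (steroid
half-site), and Spearman/average-linkage TAD clustering complete the
pipeline. See `vignettes/tad-integration.Rmd` for the methods account.

## Worked example

Simulate a 4-chromosome genome, place induced features with 4-fold odds
of landing in GR-bearing TADs, and run the adjacent-domain test:

```r
library(tadenrich)

cfg <- simulation_config(seed = 1, n_chromosomes = 4, n_core_tads = 80)
sim <- simulate_partition(cfg)
feats <- simulate_features(sim$partition, sim$gr_domains,
                           n_induced = 2500, n_background = 7500,
                           theta = 4, seed = 1)
assignment <- assign_to_domains(feats, sim$partition)
ft <- data.frame(id = S4Vectors::mcols(feats)$id,
                 feature_class = "H3K27ac",
                 label = S4Vectors::mcols(feats)$label)
counts <- domain_count_matrix(assignment, ft, sim$partition)
sets <- select_center_domains(sim$partition, sim$gr_domains)
adjacent_tad_test(sets,
                  setNames(counts$H3K27ac.induced, counts$domain_id),
                  setNames(counts$total_H3K27ac, counts$domain_id))
#> Adjacent-domain enrichment: 21/24 successes (null p = 0.2), p-value = 2.25e-12
```

24 GR-bearing TADs have full GR-free double flanks; in 21 of them the
induced-feature ratio strictly tops all four neighbours, which under the
1-in-5 null is overwhelming evidence that induced features concentrate
in GR-bound domains. At `theta = 1` (placement independent of GR) the
success fraction settles at 1/5 and the test is calibrated — that is
exactly what the acceptance checks verify.

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `07_correlate.R`) that runs these stages over a
study-shaped synthetic genome and writes tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

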