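test_that("binomial tail matches enumeration, bounds and monotonicity", {
  # small cases against exhaustive outcome enumeration
  for (n in c(1, 3, 6, 9, 12)) {
    p <- 0.2
    for (k in 0:n) {
      expect_equal(binomial_tail(k, n, p), enum_binomial_tail(k, n, p),
                   tolerance = 1e-12)
    }
  }
  expect_equal(binomial_tail(2, 3, 0.2), 0.104, tolerance = 1e-12)
  expect_equal(binomial_tail(0, 10, 0.3), 1.0)
  # non-increasing in k, non-decreasing in p
  tails <- binomial_tail(0:20, 20, 0.3)
  expect_true(all(diff(tails) <= 0))
  expect_true(all(diff(vapply(seq(0.05, 0.95, by = 0.05),
                              function(p) binomial_tail(7, 20, p),
                              numeric(1))) >= 0))
  expect_error(binomial_tail(5, 3, 0.2), "k must")
  expect_error(binomial_tail(1, 3, 1.2), "p must")
})

test_that("extreme binomial tails keep full relative precision", {
  # an extreme tail far below double-subtraction resolution, against the
  # independent log-space survival function
  got <- binomial_tail(400, 500, 0.2)
  want <- stats::pbinom(399, 500, 0.2, lower.tail = FALSE)
  expect_equal(got, want, tolerance = 1e-10)
  expect_lt(got, 1e-150)
  expect_gt(got, 0)
})

test_that("hypergeometric tail matches subset enumeration", {
  expect_equal(hypergeometric_tail(2, 2, 3, 5), 0.3, tolerance = 1e-12)
  expect_equal(hypergeometric_tail(0, 4, 3, 9), 1.0)
  expect_equal(hypergeometric_tail(5, 5, 5, 5), 1.0)
  for (N in c(5, 8, 12)) {
    for (K in c(2, N %/% 2, N)) {
      for (n in c(1, N %/% 2, N)) {
        for (k in max(0, n - (N - K)):min(n, K)) {
          expect_equal(hypergeometric_tail(k, n, K, N),
                       enum_hypergeom_tail(k, n, K, N), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeometric_tail(1, 6, 8, 5), "impossible")
  # cross-check against the survival function on a larger case
  expect_equal(hypergeometric_tail(60, 100, 300, 1000),
               stats::phyper(59, 300, 700, 100, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("center selection enforces flank freedom and full flanks", {
  cm <- chrom_map("chr1", 700)
  tads <- genomic_intervals(rep("chr1", 7), 100 * (0:6), 100 * (1:7))
  p <- build_partition(tads, cm)
  ids <- S4Vectors::mcols(p)$domain_id
  # GR in T3 only: eligible, flanks are T1 T2 T4 T5
  sets <- select_center_domains(p, ids[3])
  expect_identical(nrow(sets), 1L)
  expect_identical(sets$center, ids[3])
  expect_identical(unname(unlist(sets[1, -1])), ids[c(1, 2, 4, 5)])
  # GR in T3 and T4: each lies in the other's flank window
  expect_identical(nrow(select_center_domains(p, ids[3:4])), 0L)
  # GR in T2: only one left neighbour, excluded not padded
  expect_identical(nrow(select_center_domains(p, ids[2])), 0L)
  # wider exclusion set: a non-center peak in a flank disqualifies
  expect_identical(
    nrow(select_center_domains(p, ids[3],
                               flank_exclude_domains = ids[c(3, 5)])), 0L)
})

test_that("the strict-maximum rule and its tie policy drive the test", {
  sets <- data.frame(center = c("c1", "c2"),
                     flank_1 = c("a1", "a2"), flank_2 = c("b1", "b2"),
                     flank_3 = c("d1", "d2"), flank_4 = c("e1", "e2"))
  num <- c(c1 = 5, a1 = 4, b1 = 2, d1 = 1, e1 = 0,
           c2 = 1, a2 = 2, b2 = 1, d2 = 0, e2 = 0)
  den <- c(c1 = 10, a1 = 10, b1 = 10, d1 = 10, e1 = 10,
           c2 = 10, a2 = 10, b2 = 10, d2 = 10, e2 = 10)
  res <- adjacent_tad_test(sets, num, den)
  expect_identical(res$n_successes, 1L)
  expect_equal(res$p_value, 1 - 0.8^2, tolerance = 1e-12)
  # all ratios equal: ties are failures, p = 1
  num_tie <- stats::setNames(rep(1, 10), names(num))
  res_tie <- adjacent_tad_test(sets, num_tie, den)
  expect_identical(res_tie$n_successes, 0L)
  expect_equal(res_tie$p_value, 1.0)
  # 0/0 domains count as ratio 0
  num0 <- c(c1 = 1); den0 <- c(c1 = 2)
  res0 <- adjacent_tad_test(sets[1, ], num0, den0)
  expect_identical(res0$n_successes, 1L)
  expect_error(adjacent_tad_test(sets[0, ], num, den), "no eligible")
})

test_that("adjacent successes agree with a brute-force re-count", {
  cfg <- calibration_config(seed = 77, n_chromosomes = 1)
  sim <- simulate_partition(cfg)
  sets <- select_center_domains(sim$partition, sim$gr_domains)
  sets <- sets[seq_len(min(50, nrow(sets))), ]
  ni <- simulate_feature_counts(sim$partition, sim$gr_domains, 5e4, 2,
                                seed = 77, tag = "ind")
  nb <- simulate_feature_counts(sim$partition, character(), 2e5, 1,
                                seed = 77, tag = "bg")
  res <- adjacent_tad_test(sets, ni, ni + nb)
  expect_identical(res$n_successes,
                   brute_adjacent_successes(sets, ni, ni + nb))
})

test_that("Spearman clustering is correct, tie-aware and guarded", {
  x <- c(1, 2, 3, 4)
  m <- cbind(a = x, b = c(1, 3, 2, 4), c = x * 10)
  sc <- spearman_cluster(m)
  expect_equal(sc$correlation["a", "b"], 0.8, tolerance = 1e-12)
  expect_equal(sc$correlation["a", "c"], 1.0)
  expect_true(isSymmetric(sc$correlation))
  expect_equal(unname(diag(sc$correlation)), rep(1, 3))
  # the first merge joins the perfectly correlated pair
  expect_identical(sort(-sc$hclust$merge[1, ]), c(1L, 3L))
  # invariance to strictly monotone transforms
  m2 <- cbind(a = exp(x), b = c(1, 3, 2, 4), c = x * 10)
  expect_equal(spearman_cluster(m2)$correlation, sc$correlation)
  # constant dataset excluded with a warning
  m3 <- cbind(a = x, b = c(1, 3, 2, 4), k = rep(2, 4))
  expect_warning(sc3 <- spearman_cluster(m3), "constant")
  expect_true(all(is.na(sc3$correlation["k", c("a", "b")])))
  expect_identical(sc3$excluded, "k")
  expect_identical(length(sc3$hclust$order), 2L)
  expect_error(spearman_cluster(m[, 1, drop = FALSE]), "at least 2")
})

test_that("hypergeometric domain enrichment uses the stated parameters", {
  assignment <- stats::setNames(
    c("d1", "d1", "d2", "d2", "d3", "d3", "d3", "d4"),
    paste0("f", 1:8))
  labelled <- c("f1", "f2", "f3")  # induced features
  marked <- c("d1")                # GR-bearing domains
  res <- domain_hypergeometric_enrichment(assignment, labelled, marked)
  expect_identical(res$k, 2L)
  expect_identical(res$n_draws, 3L)
  expect_identical(res$K_successes, 2L)
  expect_identical(res$N_population, 8L)
  expect_equal(res$p_value, enum_hypergeom_tail(2, 3, 2, 8),
               tolerance = 1e-12)
})
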