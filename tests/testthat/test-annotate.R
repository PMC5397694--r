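test_that("level binning partitions tested CpGs with documented boundaries", {
  calls <- make_calls(p_value = rep(0.01, 4), delta = c(0.05, 0.10, 0.45, 0.29))
  bins <- bin_calls_by_level(calls, "hmc")
  expect_equal(as.character(bins), c("0-10%", "10-20%", ">30%", "20-30%"))
  expect_equal(sum(table(bins)), nrow(calls))  # partition
  expect_error(bin_calls_by_level(calls, edges = numeric(0)), "edges")
  expect_error(bin_calls_by_level(calls, edges = c(0.2, 0.1)), "increasing")
})

test_that("observed/expected enrichment matches closed-form arithmetic", {
  # 100 CpGs, one feature covering the first 10; set entirely inside it
  all_cpgs <- data.frame(chrom = "chr1", pos = seq(0L, 990L, 10L))
  feat <- genomic_intervals("chr1", 0, 100, "F")
  cpg_set <- all_cpgs[1:4, ]
  res <- observed_expected_enrichment(cpg_set, all_cpgs, feat)
  expect_equal(res$oe, 4 / (4 * 10 / 100))  # O/E = 10
  expect_equal(res$expected, 0.4)
  expect_error(observed_expected_enrichment(
    data.frame(chrom = "chr2", pos = 5L), all_cpgs, feat), "subset")
  expect_warning(observed_expected_enrichment(
    cpg_set, all_cpgs, genomic_intervals("chr1", 5000, 5100, "empty")),
    "skipped")
})

test_that("hypergeometric overlap p equals exhaustive enumeration", {
  # 20 CpGs, 5 in the feature, sets of size 4: enumerate all C(20,4) draws
  all_cpgs <- data.frame(chrom = "chr1", pos = seq(0L, 190L, 10L))
  feat <- genomic_intervals("chr1", 0, 50, "F")  # first 5 CpGs
  sets <- utils::combn(20, 4)
  k_obs <- colSums(sets <= 5)
  res <- observed_expected_enrichment(all_cpgs[c(1, 2, 3, 11), ], all_cpgs,
                                      feat)
  expect_equal(res$observed, 3)
  expect_equal(res$p_enrich, mean(k_obs >= 3))
  expect_equal(res$p_deplete, mean(k_obs <= 3))
})

test_that("uniform random CpG subsets give O/E near one", {
  set.seed(6)
  all_cpgs <- data.frame(chrom = "chr1", pos = seq(0L, 19990L, 10L))
  feats <- genomic_intervals("chr1", c(0, 5000), c(4000, 12000),
                             c("A", "B"))
  oe <- replicate(100, {
    cpg_set <- all_cpgs[sample.int(2000, 400), ]
    observed_expected_enrichment(cpg_set, all_cpgs, feats)$oe
  })
  # mean permuted O/E brackets 1 within Monte Carlo error
  expect_lt(abs(mean(oe[1, ]) - 1), 3 * sd(oe[1, ]) / sqrt(100))
  expect_lt(abs(mean(oe[2, ]) - 1), 3 * sd(oe[2, ]) / sqrt(100))
  # ... and the central 95% of permuted O/E ratios bracket 1
  expect_true(quantile(oe[1, ], 0.025) < 1 && 1 < quantile(oe[1, ], 0.975))
})

test_that("per-region hydroxymethylated-CpG fractions are exact ratios", {
  calls <- make_calls(p_value = c(rep(0.01, 3), rep(0.5, 3)),
                      delta = rep(0.2, 6), pos = c(0L, 10L, 20L, 30L, 40L, 50L))
  fr <- region_hmc_fraction(calls, genomic_intervals("chr1", 0, 60))
  expect_equal(fr$n_cpg, 6L)
  expect_equal(fr$n_hmc_cpg, 3L)
  expect_equal(fr$fraction, 0.5)

  calls2 <- make_calls(p_value = c(rep(0.01, 2), rep(0.5, 11)),
                       delta = rep(0.2, 13),
                       pos = seq(0L, 120L, 10L))
  fr2 <- region_hmc_fraction(calls2, genomic_intervals("chr1", 0, 130))
  expect_equal(fr2$fraction, 2 / 13, tolerance = 1e-12)

  fr3 <- region_hmc_fraction(calls2, genomic_intervals("chr1", 500, 600))
  expect_true(is.na(fr3$fraction))
})

test_that("5hmC contribution to total modification matches per-CpG recount", {
  calls <- make_calls(p_value = c(0.01, 0.5), delta = c(0.2, 0.1),
                      p_bis = c(0.5, 0.3), pos = c(0L, 10L))
  ctr <- region_hmc_contribution(calls, genomic_intervals("chr1", 0, 20))
  expect_equal(ctr$avg_hmc, 0.1)   # (0.2 + imputed 0) / 2
  expect_equal(ctr$avg_modc, 0.4)
  expect_equal(ctr$contribution, 0.25)

  # all non-significant: contribution 0
  calls0 <- make_calls(p_value = c(0.5, 0.5), delta = c(0.2, 0.1),
                       p_bis = c(0.5, 0.3), pos = c(0L, 10L))
  ctr0 <- region_hmc_contribution(calls0, genomic_intervals("chr1", 0, 20))
  expect_equal(ctr0$contribution, 0)

  # random inputs against an independent per-CpG recomputation
  set.seed(7)
  n <- 200
  callsr <- make_calls(p_value = runif(n), delta = runif(n, -0.2, 0.4),
                       p_bis = runif(n, 0.1, 0.9),
                       pos = sort(sample.int(2000, n)) - 1L)
  starts <- seq(0L, 1900L, 100L)
  regions <- genomic_intervals("chr1", starts, starts + 100L)
  got <- region_hmc_contribution(callsr, regions)
  want <- vapply(seq_len(nrow(regions)), function(i) {
    sel <- callsr$pos >= regions$start[i] & callsr$pos < regions$end[i]
    if (!any(sel)) return(NA_real_)
    h <- ifelse(callsr$significant[sel], callsr$delta[sel], 0)
    mean(h) / mean(callsr$p_bis[sel])
  }, numeric(1))
  expect_equal(got$contribution, want)
})

test_that("platform overlap classes partition and KW matches hand ranks", {
  wg <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  arr <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  mx <- c(0.5, 0.4, 0.1, 0.05, 0.6, 0.15)
  ov <- platform_overlap(wg, arr, mx)
  expect_equal(as.integer(ov$counts),
               c(both = 2L, wg_only = 1L, array_only = 2L, neither = 1L),
               ignore_attr = TRUE)
  expect_equal(sum(ov$counts), 6L)
  # hand-computed Kruskal-Wallis H on the both/array_only values
  vals <- c(0.5, 0.6, 0.1, 0.15)  # ranks 3 4 | 1 2, no ties
  rbar <- c(mean(c(3, 4)), mean(c(1, 2)))
  H <- 12 / (4 * 5) * sum(2 * (rbar - 2.5)^2)
  expect_equal(unname(ov$kw$statistic), H)

  expect_warning(platform_overlap(c(TRUE, FALSE), c(TRUE, FALSE), c(1, 2)),
                 "skipped")
})
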