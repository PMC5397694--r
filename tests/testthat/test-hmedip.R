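test_that("extended fragments increment exactly the tiles they overlap", {
  fr <- data.frame(chrom = "chr1", start = c(0L, 250L))
  tl <- count_fragments_on_tiles(fr, chrom_len = c(chr1 = 1200L))
  expect_equal(tl$count, c(2L, 1L, 0L, 0L))  # [0,300) twice, [300,600) once

  # random fragments against a naive O(n*m) interval-overlap oracle
  set.seed(8)
  frr <- data.frame(chrom = "chr1", start = sample.int(5000, 300) - 1L)
  tlr <- count_fragments_on_tiles(frr, chrom_len = c(chr1 = 5300L))
  naive <- vapply(seq_len(nrow(tlr)), function(i) {
    sum(pmin(frr$start + 300L, 5300L) > tlr$start[i] &
          frr$start < tlr$end[i])
  }, numeric(1))
  expect_equal(tlr$count, as.integer(naive))
})

test_that("low-count tiles are removed on the summed-count rule", {
  tl <- data.frame(chrom = "chr1", start = c(0L, 300L), end = c(300L, 600L),
                   ip_1 = c(5L, 5L), ip_2 = c(5L, 5L), input = c(9L, 10L))
  expect_equal(nrow(filter_low_tiles(tl, min_total = 20)), 1)     # 19 < 20
  expect_equal(filter_low_tiles(tl, min_total = 20)$start, 300L)  # 20 kept
  expect_equal(nrow(filter_low_tiles(tl, min_total = 0)), 2)
})

test_that("NB exact test is symmetric and exact in the Poisson limit", {
  eq <- nb_exact_test(10, 10, lib_sizes = c(100, 100))
  expect_equal(eq$logfc, 0)
  expect_equal(eq$p_value, 1)

  # Poisson limit: conditional binomial with tail doubling
  t_tot <- c(1, 7, 20, 35)
  for (t in t_tot) {
    y1 <- 0:t
    got <- nb_exact_test(y1, t - y1, dispersion = 1e-8,
                         lib_sizes = c(1, 1))$p_value
    want <- pmin(1, 2 * pmin(pbinom(y1, t, 0.5),
                             pbinom(y1 - 1, t, 0.5, lower.tail = FALSE)))
    expect_true(all(abs(got - want) < 1e-6))
  }

  # swapping IP and input negates logFC and preserves p-values
  set.seed(9)
  a <- rpois(50, 20); b <- rpois(50, 8)
  fwd <- nb_exact_test(a, b)
  rev <- nb_exact_test(b, a, lib_sizes = c(sum(b), sum(a)))
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$logfc, -rev$logfc)

  expect_error(nb_exact_test(1, 1, dispersion = -1), "dispersion")
})

test_that("enrichment calls respect the FDR and logFC rules", {
  tab <- data.frame(logfc = c(2, 1, -1), fdr = c(0.05, 0.2, 0.01))
  expect_equal(call_enriched(tab), c(TRUE, FALSE, FALSE))
  expect_equal(as.character(bin_logfc(data.frame(
    logfc = c(1.0, 1.8, 2.0, 2.4, 3.0)))),
    c("low", "low", "medium", "medium", "high"))
})

test_that("null tiles are called at no more than the FDR level", {
  set.seed(10)
  n <- 4000
  ip <- rpois(n, 15)
  inp <- rpois(n, 15)
  res <- nb_exact_test(ip, inp)
  expect_lte(mean(call_enriched(res)), 0.1)
})

test_that("summit windows and gaps tile the chromosome disjointly", {
  summits <- data.frame(chrom = "chr1", pos = c(500L, 700L, 3000L))
  seg <- hydroxycall:::summit_segments(summits, chrom_len = 5000L)
  expect_equal(sum(seg$end - seg$start), 5000L)
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))  # no gaps/overlap
  # touching windows merged; window widths 301 unless clipped/merged
  expect_equal(sum(seg$label == "window"), 2L)
})

test_that("summit-gap comparison separates planted 5hmC", {
  set.seed(11)
  n <- 2000
  hot <- seq(100, 1900, 200)  # CpG indices carrying 5hmC clusters
  p5h <- rep(0, n)
  for (h in hot) p5h[h:(h + 2)] <- 0.4
  truth <- true_methylome(p_5mc = 0.3, p_5hmc = p5h, chem = perfect_chem())
  cnt <- simulate_bisoxbis_counts(truth, mean_coverage = 40, seed = 11)
  calls <- call_hmc(cnt$bis, cnt$oxbis)
  chrom_len <- attr(truth, "chrom_len")
  summits <- data.frame(chrom = "chr1", pos = truth$pos[hot + 1L])
  sg <- summit_gap_hmc(summits, calls, chrom_len)
  expect_gt(median(sg$windows$avg_hmc[sg$windows$defined]),
            median(sg$gaps$avg_hmc[sg$gaps$defined]))
  expect_lt(sg$kw$p.value, 0.01)

  # identical content in windows and gaps: balanced ranks, p = 1
  calls_flat <- make_calls(p_value = rep(0.01, 4),
                           delta = c(0.1, 0.1, 0.3, 0.3),
                           pos = c(100L, 350L, 600L, 850L))
  sm <- data.frame(chrom = "chr1", pos = c(100L, 600L))
  sg2 <- summit_gap_hmc(sm, calls_flat, chrom_len = 1000L)
  expect_equal(sg2$kw$p.value, 1)
})

test_that("permutation null is beaten by planted summits and conserves length", {
  set.seed(12)
  n <- 2000
  hot <- seq(100, 1900, 150)
  p5h <- rep(0, n)
  for (h in hot) p5h[h:(h + 3)] <- 0.5
  truth <- true_methylome(p_5mc = 0.3, p_5hmc = p5h, chem = perfect_chem())
  cnt <- simulate_bisoxbis_counts(truth, mean_coverage = 40, seed = 12)
  calls <- call_hmc(cnt$bis, cnt$oxbis)
  summits <- data.frame(chrom = "chr1", pos = truth$pos[hot + 1L])
  pn <- permutation_null(summits, calls, attr(truth, "chrom_len"),
                         n_perm = 199, seed = 13)
  expect_gt(pn$observed, max(pn$null))
  expect_equal(pn$p_value, 1 / 200)
  expect_error(permutation_null(summits, calls, 1000L, n_perm = 0), "n_perm")
})

test_that("peak specificity audit enforces the all-CpGs-covered rule", {
  bis <- data.frame(chrom = "chr1", pos = c(10L, 50L, 110L),
                    nc = c(20L, 5L, 0L), n = c(30L, 9L, 30L))
  ox <- data.frame(chrom = "chr1", pos = c(10L, 50L, 110L),
                   nc = c(5L, 1L, 0L), n = c(30L, 30L, 30L))
  peaks <- genomic_intervals("chr1", c(0L, 100L), c(60L, 120L))
  res <- classify_peaks_by_hmc(peaks, bis, ox)
  # peak 1 contains the 9x CpG: ineligible
  expect_equal(res$eligible, c(FALSE, TRUE))
  expect_equal(res$fraction_positive, 0)  # pos 110 has delta 0 -> imputed 0

  # planted 5hmC at peaks exceeds the random-placement expectation
  set.seed(14)
  n <- 1500
  hot <- seq(50, 1450, 100)
  p5h <- rep(0, n)
  for (h in hot) p5h[h:(h + 4)] <- 0.5
  truth <- true_methylome(p_5mc = 0.3, p_5hmc = p5h, chem = perfect_chem())
  cnt <- simulate_bisoxbis_counts(truth, mean_coverage = 40, seed = 14)
  pk_start <- truth$pos[hot] - 10L
  pk <- genomic_intervals("chr1", pk_start, truth$pos[hot + 4L] + 10L)
  res2 <- classify_peaks_by_hmc(pk, cnt$bis, cnt$oxbis,
                                chrom_len = attr(truth, "chrom_len"),
                                n_perm = 99, seed = 15)
  expect_gt(res2$fraction_positive,
            quantile(res2$null_fractions, 0.975))
})
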