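test_that("two-proportion test matches prop.test on exhaustive small tables", {
  for (n1 in 1:10) for (n2 in 1:10) {
    grid <- expand.grid(x1 = 0:n1, x2 = 0:n2)
    mine <- two_proportion_test(grid$x1, n1, grid$x2, n2)
    ref <- mapply(function(x1, x2) {
      suppressWarnings(prop.test(c(x1, x2), c(n1, n2)))$p.value
    }, grid$x1, grid$x2)
    comparable <- is.finite(ref)
    expect_true(all(abs(mine$p_value[comparable] - ref[comparable]) < 1e-12))
    # degenerate pooled proportions (prop.test returns NaN) give p = 1
    expect_true(all(mine$p_value[!comparable] == 1))
  }
})

test_that("two-proportion test handles canonical small tables", {
  eq <- two_proportion_test(8, 10, 8, 10)
  expect_equal(eq$delta, 0)
  expect_equal(eq$p_value, 1)

  ext <- two_proportion_test(10, 10, 0, 10)
  expect_equal(ext$delta, 1)
  expect_lt(ext$p_value, 0.001)
  expect_lt(fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value, 0.001)

  # independent hand computation of the Yates-corrected 2x2 chi-square
  x1 <- 9; n1 <- 10; x2 <- 1; n2 <- 10
  phat <- (x1 + x2) / (n1 + n2)
  e <- c(n1 * phat, n1 * (1 - phat), n2 * phat, n2 * (1 - phat))
  o <- c(x1, n1 - x1, x2, n2 - x2)
  stat <- sum((abs(o - e) - 0.5)^2 / e)
  mine <- two_proportion_test(x1, n1, x2, n2)
  expect_equal(mine$delta, 0.8)
  expect_equal(mine$p_value, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_error(two_proportion_test(0, 0, 1, 10), "coverage")
  expect_error(two_proportion_test(11, 10, 1, 10), "NC")
})

test_that("caller applies the 10x-in-both filter and one-sided rule", {
  bis <- data.frame(chrom = "chr1", pos = c(0L, 10L, 20L, 30L),
                    nc = c(9L, 25L, 5L, 10L), n = c(9L, 30L, 30L, 30L))
  ox <- data.frame(chrom = "chr1", pos = c(0L, 10L, 20L, 40L),
                   nc = c(0L, 5L, 20L, 1L), n = c(50L, 30L, 30L, 30L))
  calls <- call_hmc(bis, ox, min_cov = 10)
  # pos 0 fails coverage in Bis; pos 30/40 not shared
  expect_equal(calls$pos, c(10L, 20L))
  # pos 20 has delta < 0: tested but never significant
  expect_lt(calls$delta[2], 0)
  expect_false(calls$significant[2])
  expect_true(calls$significant[1])
  expect_s3_class(calls, "hmc_calls")
  expect_warning(
    empty <- call_hmc(bis, data.frame(chrom = "chr2", pos = 0L, nc = 0L,
                                      n = 30L)),
    "no CpGs shared"
  )
  expect_equal(nrow(empty), 0)
})

test_that("region averaging follows the discard/impute rules", {
  calls <- make_calls(p_value = c(0.01, 0.2), delta = c(0.30, 0.05),
                      pos = c(5L, 15L))
  avg <- region_average_hmc(calls, genomic_intervals("chr1", 0, 20))
  expect_equal(avg$avg_hmc, 0.15)  # mean(0.30, 0)
  expect_equal(avg$n_contrib, 2L)

  calls2 <- make_calls(p_value = c(0.2, 0.5), delta = c(0.15, -0.02),
                       pos = c(5L, 15L))
  avg2 <- region_average_hmc(calls2, genomic_intervals("chr1", 0, 20))
  expect_true(is.na(avg2$avg_hmc))
  expect_false(avg2$defined)

  # the 10% boundary imputes to zero rather than discarding
  calls3 <- make_calls(p_value = 0.2, delta = 0.10, pos = 5L)
  avg3 <- region_average_hmc(calls3, genomic_intervals("chr1", 0, 20))
  expect_equal(avg3$avg_hmc, 0)

  # random tables against the independently coded rule-by-rule oracle
  set.seed(42)
  n <- 300
  calls4 <- make_calls(p_value = runif(n), delta = runif(n, -0.3, 0.5),
                       pos = sort(sample.int(3000, n)) - 1L)
  starts <- sort(sample.int(2900, 40)) - 1L
  regions <- genomic_intervals("chr1", starts, starts + 100L)
  got <- region_average_hmc(calls4, regions)$avg_hmc
  expect_equal(got, oracle_region_average(calls4, regions))
})

test_that("region classification counts significant CpGs", {
  calls <- make_calls(p_value = c(0.01, 0.2), delta = c(0.3, 0.2),
                      pos = c(5L, 15L))
  regions <- genomic_intervals("chr1", c(0, 10), c(10, 20))
  expect_equal(classify_hydroxymethylated_region(calls, regions),
               c(TRUE, FALSE))
  expect_equal(classify_hydroxymethylated_region(calls, regions,
                                                 min_sig = 2),
               c(FALSE, FALSE))
})

test_that("power function reproduces the normal approximation", {
  expect_equal(power_two_proportion(0.5, 0.5, 100), 0.05)
  expect_gt(power_two_proportion(0.9, 0.1, 100), 0.999)
  expect_error(power_two_proportion(0.5, 0.8, 10), "p2 <= p1")
  expect_equal(power_two_proportion(0.8, 0.7, 60),
               power.prop.test(n = 60, p1 = 0.8, p2 = 0.7)$power)
})

test_that("delta summary reports the genome-wide 5hmC picture", {
  expect_error(delta_density_summary(make_calls(numeric(0), numeric(0))),
               "empty")
  # null simulation: the delta distribution is centred at zero
  truth <- true_methylome(p_5mc = 0.5, p_5hmc = rep(0, 4000),
                          chem = perfect_chem())
  cnt <- simulate_bisoxbis_counts(truth, mean_coverage = 30, seed = 19)
  calls <- call_hmc(cnt$bis, cnt$oxbis)
  ds <- delta_density_summary(calls)
  se <- sd(calls$delta) / sqrt(nrow(calls))
  expect_lt(abs(ds$mean_delta), 3 * se)
  expect_lt(ds$frac_significant, 0.05)
  expect_equal(ds$n, nrow(calls))
})

test_that("sensitivity grows with coverage on planted 5hmC", {
  truth <- true_methylome(p_5mc = 0.5, p_5hmc = rep(0.3, 2000),
                          chem = perfect_chem())
  sens <- vapply(c(10, 60), function(cov) {
    cnt <- simulate_bisoxbis_counts(truth, mean_coverage = cov, seed = 23)
    calls <- call_hmc(cnt$bis, cnt$oxbis)
    mean(calls$significant)
  }, numeric(1))
  expect_gt(sens[2], sens[1])
})
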