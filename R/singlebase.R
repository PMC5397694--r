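#' Two-sample proportion test for paired Bis/OxBis counts
#'
#' Vectorised chi-square test of equal proportions on the 2x2 table
#' `(NC_Bis, N_Bis - NC_Bis; NC_OxBis, N_OxBis - NC_OxBis)`, with Yates
#' continuity correction by default. The statistic, correction and p-value
#' reproduce `stats::prop.test()` exactly; degenerate tables whose pooled
#' proportion is 0 or 1 get `p_value = 1`.
#'
#' @param nc_bis,n_bis Retained count and coverage in the Bis experiment.
#' @param nc_oxbis,n_oxbis Retained count and coverage in OxBis.
#' @param correct Apply the Yates continuity correction (default TRUE).
#'
#' @return `data.frame` with columns `delta` (`p_Bis - p_OxBis`, the 5hmC
#'   estimate), `statistic` and `p_value` (two-sided).
#' @export
two_proportion_test <- function(nc_bis, n_bis, nc_oxbis, n_oxbis,
                                correct = TRUE) {
  if (any(n_bis < 1L) || any(n_oxbis < 1L)) {
    stop("zero coverage: filter CpGs before testing")
  }
  if (any(nc_bis < 0L | nc_bis > n_bis) ||
      any(nc_oxbis < 0L | nc_oxbis > n_oxbis)) {
    stop("counts must satisfy 0 <= NC <= N")
  }
  p1 <- nc_bis / n_bis
  p2 <- nc_oxbis / n_oxbis
  phat <- (nc_bis + nc_oxbis) / (n_bis + n_oxbis)
  # |observed - expected| is the same in all four cells of the 2x2 table
  dev <- abs(p1 - p2) / (1 / n_bis + 1 / n_oxbis)
  yates <- if (correct) pmin(0.5, dev) else 0
  inv_e <- 1 / (n_bis * phat) + 1 / (n_bis * (1 - phat)) +
    1 / (n_oxbis * phat) + 1 / (n_oxbis * (1 - phat))
  stat <- (dev - yates)^2 * inv_e
  degenerate <- phat <= 0 | phat >= 1
  stat[degenerate] <- 0
  data.frame(delta = p1 - p2, statistic = stat,
             p_value = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Call hydroxymethylated CpGs from paired Bis/OxBis count tables
#'
#' The whole-genome 5hmC caller: CpGs present in both tables with coverage
#' of at least `min_cov` in *both* treatments are tested with
#' [two_proportion_test()]; a CpG is significantly hydroxymethylated when
#' `p_value < alpha` and `delta = p_Bis - p_OxBis > 0`. All tested CpGs are
#' retained in the output, significant or not.
#'
#' No multiple-testing correction is applied by default (the whole-genome
#' rule operates on raw p-values); set `p_adjust = "BH"` for
#' Benjamini-Hochberg control instead.
#'
#' @param bis,oxbis CpG count tables (`chrom`, `pos`, `nc`, `n`).
#' @param min_cov Minimum coverage in each treatment (default 10).
#' @param alpha Significance level on the (possibly adjusted) p-value.
#' @param correct Yates continuity correction, passed to the test.
#' @param p_adjust `"none"` (default) or any `stats::p.adjust` method.
#'
#' @return An object of class `hmc_calls`: a `data.frame` with columns
#'   `chrom`, `pos`, `n_bis`, `n_oxbis`, `p_bis`, `p_oxbis`, `delta`,
#'   `p_value`, `significant`, plus attributes `alpha`, `min_cov`.
#' @export
call_hmc <- function(bis, oxbis, min_cov = 10L, alpha = 0.05,
                     correct = TRUE, p_adjust = "none") {
  key_b <- paste(bis$chrom, bis$pos)
  key_o <- paste(oxbis$chrom, oxbis$pos)
  m <- match(key_b, key_o)
  shared <- which(!is.na(m))
  if (!length(shared)) {
    warning("no CpGs shared between the Bis and OxBis tables")
  }
  b <- bis[shared, , drop = FALSE]
  o <- oxbis[m[shared], , drop = FALSE]
  keep <- b$n >= min_cov & o$n >= min_cov
  b <- b[keep, , drop = FALSE]
  o <- o[keep, , drop = FALSE]
  if (nrow(b)) {
    tst <- two_proportion_test(b$nc, b$n, o$nc, o$n, correct = correct)
    pv <- p.adjust(tst$p_value, method = p_adjust)
    out <- data.frame(
      chrom = b$chrom, pos = b$pos, n_bis = b$n, n_oxbis = o$n,
      p_bis = b$nc / b$n, p_oxbis = o$nc / o$n,
      delta = tst$delta, p_value = pv,
      significant = pv < alpha & tst$delta > 0,
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      n_bis = integer(0), n_oxbis = integer(0),
                      p_bis = numeric(0), p_oxbis = numeric(0),
                      delta = numeric(0), p_value = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "min_cov") <- min_cov
  attr(out, "correct") <- correct
  class(out) <- c("hmc_calls", "data.frame")
  out
}

#' @export
print.hmc_calls <- function(x, ...) {
  cat(sprintf(
    "hmc_calls: %d CpGs tested (min coverage %dx), %d significant (%.2f%%) at alpha = %g\n",
    nrow(x), attr(x, "min_cov"), sum(x$significant),
    if (nrow(x)) 100 * mean(x$significant) else 0, attr(x, "alpha")
  ))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' @export
summary.hmc_calls <- function(object, ...) {
  out <- list(
    n_tested = nrow(object),
    n_significant = sum(object$significant),
    frac_significant = if (nrow(object)) mean(object$significant) else NA_real_,
    delta_quantiles = if (nrow(object))
      quantile(object$delta, c(0, 0.25, 0.5, 0.75, 1)) else NULL,
    alpha = attr(object, "alpha"), min_cov = attr(object, "min_cov")
  )
  class(out) <- "summary.hmc_calls"
  out
}

#' @export
print.summary.hmc_calls <- function(x, ...) {
  cat(sprintf("CpGs tested:      %d (>= %dx in both treatments)\n",
              x$n_tested, x$min_cov))
  cat(sprintf("Significant 5hmC: %d (%.2f%%) at p < %g, delta > 0\n",
              x$n_significant, 100 * x$frac_significant, x$alpha))
  if (!is.null(x$delta_quantiles)) {
    cat("delta (p_Bis - p_OxBis) quantiles:\n")
    print(round(x$delta_quantiles, 4))
  }
  invisible(x)
}

#' @export
plot.hmc_calls <- function(x, ...) {
  if (!nrow(x)) stop("no CpGs to plot")
  d <- density(x$delta)
  plot(d, main = "p_Bis - p_OxBis across tested CpGs",
       xlab = expression(p[Bis] - p[OxBis]), ...)
  abline(v = 0, lty = 2, col = "grey40")
  invisible(x)
}

# Region-averaging contribution rules, applied CpG-wise:
#   significant                      -> contributes delta
#   delta < 0                        -> discarded
#   non-significant, delta > impute_max -> discarded (too large to trust)
#   non-significant, 0 <= delta <= impute_max -> imputed to zero
hmc_contributions <- function(calls, impute_max = 0.10) {
  value <- calls$delta
  ns <- !calls$significant
  keep <- !(calls$delta < 0 | (ns & calls$delta > impute_max))
  value[ns & keep] <- 0
  list(value = value, keep = keep)
}

#' Average 5hmC per region with discard/impute rules
#'
#' Per region, CpG calls contribute to the average as: significant CpGs
#' contribute their `delta`; non-significant CpGs with
#' `0 <= delta <= impute_max` are imputed to zero; non-significant CpGs
#' with `delta > impute_max` and any CpG with `delta < 0` are discarded.
#' The region average is taken over contributing CpGs only. Regions with
#' no contributing CpG are flagged undefined (`NA` average).
#'
#' @param calls An [call_hmc()] result (must include non-significant CpGs).
#' @param regions Interval table.
#' @param impute_max Impute/discard boundary on delta (default 0.10, i.e.
#'   10%); the boundary value itself is imputed to zero.
#'
#' @return `data.frame`: one row per input region with `n_cpg` (tested
#'   CpGs overlapped), `n_contrib`, `avg_hmc` (NA when undefined) and
#'   `defined`.
#' @export
region_average_hmc <- function(calls, regions, impute_max = 0.10) {
  contrib <- hmc_contributions(calls, impute_max)
  hits <- overlap_points_regions(calls$chrom, calls$pos, regions)
  n_cpg <- tabulate(hits$region, nbins = nrow(regions))
  kept <- contrib$keep[hits$point]
  reg_k <- hits$region[kept]
  val_k <- contrib$value[hits$point][kept]
  n_contrib <- tabulate(reg_k, nbins = nrow(regions))
  sums <- numeric(nrow(regions))
  if (length(reg_k)) {
    agg <- rowsum(val_k, reg_k)
    sums[as.integer(rownames(agg))] <- agg[, 1L]
  }
  avg <- ifelse(n_contrib > 0L, sums / n_contrib, NA_real_)
  data.frame(regions[, c("chrom", "start", "end")],
             n_cpg = n_cpg, n_contrib = n_contrib, avg_hmc = avg,
             defined = n_contrib > 0L, stringsAsFactors = FALSE)
}

#' Classify regions as hydroxymethylated
#'
#' A region is hydroxymethylated when it contains at least `min_sig`
#' significantly hydroxymethylated CpGs.
#'
#' @param calls An [call_hmc()] result.
#' @param regions Interval table.
#' @param min_sig Minimum significant CpGs (default 1).
#' @return Logical vector, one per region.
#' @export
classify_hydroxymethylated_region <- function(calls, regions, min_sig = 1L) {
  sig <- calls[calls$significant, , drop = FALSE]
  hits <- overlap_points_regions(sig$chrom, sig$pos, regions)
  tabulate(hits$region, nbins = nrow(regions)) >= min_sig
}

#' Power of the two-sample proportion test
#'
#' Normal-approximation power for detecting `p1` vs `p2` with `n` samples
#' per group at two-sided level `alpha`, via `stats::power.prop.test()`.
#' The degenerate null `p1 == p2` returns `alpha`.
#'
#' @param p1,p2 True proportions, `0 <= p2 <= p1 <= 1`.
#' @param n Coverage (samples per group), >= 2.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
power_two_proportion <- function(p1, p2, n, alpha = 0.05) {
  if (p2 > p1 || p1 > 1 || p2 < 0) stop("need 0 <= p2 <= p1 <= 1")
  if (n < 2) stop("n must be >= 2")
  if (p1 == p2) return(alpha)
  power.prop.test(n = n, p1 = p1, p2 = p2, sig.level = alpha)$power
}

#' Summarise the delta distribution and significant fraction
#'
#' The empirical distribution of `p_Bis - p_OxBis` over all tested CpGs
#' plus the fraction called significantly hydroxymethylated — the
#' genome-wide view of how much 5hmC a sample carries.
#'
#' @param calls An [call_hmc()] result including non-significant CpGs.
#' @param probs Quantile probabilities to report.
#' @return List with `n`, `frac_significant`, `quantiles`, `mean_delta`
#'   and `density` (a `stats::density` object).
#' @export
delta_density_summary <- function(calls,
                                  probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  if (!nrow(calls)) stop("empty call table")
  list(
    n = nrow(calls),
    frac_significant = mean(calls$significant),
    mean_delta = mean(calls$delta),
    quantiles = quantile(calls$delta, probs),
    density = density(calls$delta)
  )
}
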