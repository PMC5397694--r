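# Shared fixtures built in code.

perfect_chem <- function(...) {
  args <- list(e_nonconv = 0, e_overconv = 0, eff_ox = 1, eff_tet = 1,
               eff_bgt = 1)
  args[names(list(...))] <- list(...)
  do.call(chemistry_model, args)
}

# A calls table assembled directly (bypassing the caller) for rule tests.
make_calls <- function(p_value, delta, p_bis = pmax(delta, 0) + 0.3,
                       pos = NULL, alpha = 0.05) {
  n <- length(p_value)
  if (is.null(pos)) pos <- seq_len(n) * 10L - 10L
  out <- data.frame(
    chrom = rep("chr1", n), pos = as.integer(pos),
    n_bis = rep(30L, n), n_oxbis = rep(30L, n),
    p_bis = p_bis, p_oxbis = p_bis - delta,
    delta = delta, p_value = p_value,
    significant = p_value < alpha & delta > 0,
    stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  attr(out, "min_cov") <- 10L
  class(out) <- c("hmc_calls", "data.frame")
  out
}

# Independent rule-by-rule re-implementation of the region-averaging
# discard/impute rules, CpG by CpG, used as a brute-force oracle.
oracle_region_average <- function(calls, regions, impute_max = 0.10) {
  vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    vals <- c()
    for (j in seq_len(nrow(calls))) {
      if (calls$chrom[j] != r$chrom) next
      if (calls$pos[j] < r$start || calls$pos[j] >= r$end) next
      p <- calls$p_value[j]; d <- calls$delta[j]
      sig <- calls$significant[j]
      if (sig) {
        vals <- c(vals, d)
      } else if (d < 0) {
        # discarded
      } else if (d > impute_max) {
        # discarded
      } else {
        vals <- c(vals, 0)
      }
    }
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1))
}

# Spike-in count rows assembled by hand.
spike_rows <- function(state, assay, retained, converted) {
  data.frame(site = seq_along(retained), state = state, assay = assay,
             retained = retained, converted = converted,
             stringsAsFactors = FALSE)
}
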