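#' Detection-p-value filter
#'
#' Keeps probes with a reliable methylation readout, i.e. detection
#' p-value below `threshold` in **all** samples.
#'
#' @param probes A `probe_table` (see [simulate_array_betas()]).
#' @param threshold Detection p-value cut-off (default 0.01).
#' @return The filtered `probe_table`.
#' @export
detection_filter <- function(probes, threshold = 0.01) {
  if (is.null(probes$detp)) stop("probe table has no detection p-values")
  keep <- rowSums(probes$detp < threshold) == ncol(probes$detp)
  out <- probes
  out$beta <- probes$beta[keep, , drop = FALSE]
  out$detp <- probes$detp[keep, , drop = FALSE]
  out$probes <- probes$probes[keep, , drop = FALSE]
  out
}

#' Logit (M-value) transform of beta values
#'
#' `M = log2(beta / (1 - beta))` after clamping beta to
#' `[cap, 1 - cap]` to avoid extreme M-values. Base 2 is the standard
#' M-value convention; set `base` to `exp(1)` for natural-log M-values.
#'
#' @param beta Beta values in `[0, 1]` (vector or matrix).
#' @param cap Clamping bound (default 0.01, so betas are capped at 0.01
#'   and 0.99).
#' @param base Logarithm base.
#' @return M-values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, cap = 0.01, base = 2) {
  b <- pmin(pmax(beta, cap), 1 - cap)
  log(b / (1 - b), base = base)
}

#' @rdname beta_to_m
#' @param m M-values.
#' @return `m_to_beta()`: beta values in `[cap, 1 - cap]`.
#' @export
m_to_beta <- function(m, base = 2) {
  x <- base^m
  x / (1 + x)
}

# Newton inversion of the trigamma function (used by the moments-method
# prior fit). Monotone decreasing on (0, Inf).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderated t contrast on M-values
#'
#' Unpaired two-group contrast per probe with variance moderation: the
#' per-probe residual variance `s^2` (pooled, `d = n1 + n2 - 2` df) is
#' shrunk towards a prior `s0^2` with `d0` prior df,
#' `s2_post = (d0 * s0^2 + d * s^2) / (d0 + d)`, and the moderated t
#' statistic `deltaM / (s_post * sqrt(1/n1 + 1/n2))` is referred to a t
#' distribution on `d0 + d` df. The prior `(d0, s0^2)` is estimated by
#' moment matching on the log residual variances (mean and variance of
#' `log s^2` against the theoretical log-F moments); probes with zero
#' residual variance are excluded from the fit and handled by the prior.
#'
#' @param m Probes x samples matrix of M-values.
#' @param groups Character/factor vector (one per column) with exactly two
#'   levels, e.g. `"Bis"`/`"OxBis"`; the contrast is first level minus
#'   second (alphabetical when character).
#' @param d0,s0_2 Optional forced prior df and variance (e.g. `d0 = Inf`
#'   for pure-prior z-like statistics); estimated when `NULL`.
#'
#' @return List with `table` (`delta_m`, `s2`, `s2_post`, `t_mod`,
#'   `df_total`, `p_value`, `adj_p`) and the prior `d0`, `s0_2`.
#' @export
moderated_t_contrast <- function(m, groups, d0 = NULL, s0_2 = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  i1 <- which(groups == levels(groups)[1L])
  i2 <- which(groups == levels(groups)[2L])
  n1 <- length(i1)
  n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  rss <- rowSums((m[, i1, drop = FALSE] - m1)^2) +
    rowSums((m[, i2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2L
  s2 <- rss / d

  if (is.null(d0) || is.null(s0_2)) {
    pos <- s2 > 0
    if (!any(pos)) {
      d0 <- Inf
      s0_2 <- 0
    } else {
      z <- log(s2[pos])
      ebias <- digamma(d / 2) - log(d / 2)
      vz <- stats::var(z)
      excess <- vz - trigamma(d / 2)
      if (is.na(excess) || excess <= 0) {
        d0 <- Inf
        s0_2 <- exp(mean(z) - ebias)
      } else {
        d0 <- 2 * trigamma_inverse(excess)
        s0_2 <- exp(mean(z) - ebias + digamma(d0 / 2) - log(d0 / 2))
      }
    }
  }

  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d * s2) / (d0 + d)
  delta <- m1 - m2
  denom <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(delta == 0, 0, delta / denom)
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t_mod)) else
    2 * pt(-abs(t_mod), df = df_total)
  p[delta == 0] <- 1
  list(
    table = data.frame(delta_m = delta, s2 = s2, s2_post = s2_post,
                       t_mod = t_mod, df_total = df_total, p_value = p,
                       adj_p = p.adjust(p, method = "BH")),
    d0 = d0, s0_2 = s0_2
  )
}

#' Array-style differential hydroxymethylation calling
#'
#' The full array workflow: detection filtering, capped logit transform of
#' betas to M-values, empirical-Bayes moderated t contrast of Bis versus
#' OxBis, and the significance rule `adjusted p < alpha` with
#' `mean(beta_Bis) - mean(beta_OxBis) > 0`. Set `adjust = "none"` to flag
#' on raw p-values.
#'
#' @param probes A `probe_table`.
#' @param detection_threshold Detection p cut-off (default 0.01).
#' @param cap Beta clamping bound for the M transform (default 0.01).
#' @param alpha Significance level.
#' @param adjust `"BH"` (default) or `"none"`.
#'
#' @return `data.frame` per retained probe: `probe_id`, `delta_beta`,
#'   `delta_m`, `t_mod`, `p_value`, `adj_p`, `significant`; attributes
#'   `d0` and `s0_2` carry the fitted prior.
#' @export
array_hmc <- function(probes, detection_threshold = 0.01, cap = 0.01,
                      alpha = 0.05, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  filt <- detection_filter(probes, detection_threshold)
  if (!nrow(filt$beta)) stop("no probes pass the detection filter")
  m <- beta_to_m(filt$beta, cap = cap)
  fit <- moderated_t_contrast(m, filt$samples$treatment)
  is_bis <- filt$samples$treatment == "Bis"
  delta_beta <- rowMeans(filt$beta[, is_bis, drop = FALSE]) -
    rowMeans(filt$beta[, !is_bis, drop = FALSE])
  p_use <- if (adjust == "BH") fit$table$adj_p else fit$table$p_value
  out <- data.frame(
    probe_id = filt$probes$probe_id,
    delta_beta = delta_beta,
    delta_m = fit$table$delta_m,
    t_mod = fit$table$t_mod,
    p_value = fit$table$p_value,
    adj_p = fit$table$adj_p,
    significant = p_use < alpha & delta_beta > 0,
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- fit$d0
  attr(out, "s0_2") <- fit$s0_2
  out
}
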