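#' Simulate array-style beta values for Bis and OxBis treatments
#'
#' Emulates the input to the array differential workflow: per probe and
#' replicate, the observed beta value is the chemistry-expected retained
#' fraction plus Gaussian measurement noise, clamped to `[0, 1]`. Detection
#' p-values are drawn so that a configured fraction of probe/sample pairs
#' fails the standard `p < 0.01` detection filter.
#'
#' Every CpG of the truth table becomes one probe; probe ids follow the
#' `cg`-prefixed convention.
#'
#' @param truth A [simulate_methylome()] result.
#' @param n_replicates Replicates per treatment (>= 2; two per treatment is
#'   the usual array design).
#' @param noise_sd Standard deviation of the Gaussian beta noise (>= 0).
#' @param detection_fail_rate Fraction of probe/sample pairs whose
#'   detection p-value is drawn above 0.01.
#' @param seed Integer seed.
#'
#' @return An object of class `probe_table`: a list with `beta` and `detp`
#'   (probes x samples matrices), `samples` (treatment/replicate
#'   data.frame) and `probes` (probe_id, chrom, pos, true expected betas).
#' @export
simulate_array_betas <- function(truth, n_replicates = 2, noise_sd = 0.02,
                                 detection_fail_rate = 0, seed = NULL) {
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (detection_fail_rate < 0 || detection_fail_rate > 1) {
    stop("detection_fail_rate must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  chem <- attr(truth, "chemistry")
  if (is.null(chem)) chem <- chemistry_model()
  r <- retention_rates(truth$p_5mc, truth$p_5hmc, chem)
  n_probe <- nrow(truth)
  samples <- data.frame(
    sample = c(paste0("Bis_", seq_len(n_replicates)),
               paste0("OxBis_", seq_len(n_replicates))),
    treatment = rep(c("Bis", "OxBis"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2L),
    stringsAsFactors = FALSE
  )
  mu <- cbind(matrix(r$bis, n_probe, n_replicates),
              matrix(r$oxbis, n_probe, n_replicates))
  beta <- mu
  if (noise_sd > 0) {
    beta <- beta + matrix(rnorm(length(mu), sd = noise_sd), n_probe)
  }
  beta <- pmin(pmax(beta, 0), 1)
  fail <- matrix(runif(length(mu)) < detection_fail_rate, n_probe)
  detp <- matrix(runif(length(mu), 0, 0.01), n_probe)
  detp[fail] <- runif(sum(fail), 0.01, 1)
  colnames(beta) <- colnames(detp) <- samples$sample
  probes <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n_probe)),
    chrom = truth$chrom, pos = truth$pos,
    true_beta_bis = r$bis, true_beta_oxbis = r$oxbis,
    stringsAsFactors = FALSE
  )
  rownames(beta) <- rownames(detp) <- probes$probe_id
  structure(list(beta = beta, detp = detp, samples = samples,
                 probes = probes),
            class = "probe_table")
}

#' @export
print.probe_table <- function(x, ...) {
  cat(sprintf("probe_table: %d probes x %d samples (%s)\n",
              nrow(x$beta), ncol(x$beta),
              paste(x$samples$sample, collapse = ", ")))
  invisible(x)
}
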