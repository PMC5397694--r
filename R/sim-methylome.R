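#' Default per-feature methylation level model
#'
#' Beta-distribution parameters for the true (p_5mC, p_5hmC) landscape by
#' chromatin feature. The shape mirrors what is seen in somatic tissues:
#' enhancers and gene bodies carry the highest 5hmC, CpG islands and active
#' TSSes are hypomethylated and 5hmC-depleted, quiescent chromatin is
#' heavily 5mC-methylated with little 5hmC. Each feature gets a mean and a
#' concentration for the 5hmC beta distribution and for the 5mC fraction of
#' the remaining (non-5hmC) probability mass, which guarantees
#' `p_5mC + p_5hmC <= 1` by construction.
#'
#' @return Named list of per-feature parameter lists with elements
#'   `h_mean`, `h_conc`, `m_mean`, `m_conc`.
#' @export
default_level_model <- function() {
  list(
    TssA  = list(h_mean = 0.02, h_conc = 20, m_mean = 0.10, m_conc = 5),
    TssAFlnk = list(h_mean = 0.12, h_conc = 15, m_mean = 0.50, m_conc = 5),
    Tx    = list(h_mean = 0.15, h_conc = 15, m_mean = 0.80, m_conc = 8),
    Enh   = list(h_mean = 0.25, h_conc = 12, m_mean = 0.60, m_conc = 6),
    CGI   = list(h_mean = 0.02, h_conc = 20, m_mean = 0.08, m_conc = 5),
    Quies = list(h_mean = 0.05, h_conc = 20, m_mean = 0.85, m_conc = 8)
  )
}

#' Simulate a ground-truth methylome
#'
#' Draws per-CpG true methylation (`p_5mC`) and hydroxymethylation
#' (`p_5hmC`) levels from feature-specific beta mixtures, together with
#' genomic positions and feature labels. The result is the ground truth
#' against which callers are evaluated.
#'
#' @param n_cpg Number of CpG sites (>= 1).
#' @param feature_mix Named numeric vector of feature proportions summing
#'   to 1; names must index into `level_model`.
#' @param level_model Per-feature beta parameters, see
#'   [default_level_model()]. A feature's `h_mean`/`h_conc` give the 5hmC
#'   beta distribution; `m_mean`/`m_conc` the 5mC fraction of the remaining
#'   mass.
#' @param chem A [chemistry_model()].
#' @param mean_spacing Mean distance between consecutive CpGs in bases.
#' @param chrom Chromosome name.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A `data.frame` of class `true_methylome` with columns `chrom`,
#'   `pos` (0-based, strictly increasing), `feature`, `p_5mc`, `p_5hmc`,
#'   and attributes `chemistry` and `chrom_len`.
#' @export
simulate_methylome <- function(n_cpg,
                               feature_mix = c(TssA = 0.05, TssAFlnk = 0.05,
                                               Tx = 0.30, Enh = 0.10,
                                               CGI = 0.10, Quies = 0.40),
                               level_model = default_level_model(),
                               chem = chemistry_model(),
                               mean_spacing = 100, chrom = "chr1",
                               seed = NULL) {
  n_cpg <- as.integer(n_cpg)
  if (is.na(n_cpg) || n_cpg < 1L) stop("n_cpg must be >= 1")
  if (is.null(names(feature_mix)) || any(feature_mix < 0) ||
      abs(sum(feature_mix) - 1) > 1e-8) {
    stop("feature_mix must be a named vector of proportions summing to 1")
  }
  missing_feat <- setdiff(names(feature_mix), names(level_model))
  if (length(missing_feat)) {
    stop("no level model for feature(s): ", paste(missing_feat, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)

  # CpGs come in runs of the same feature (chromatin states are segments)
  run_len <- 25L
  n_runs <- ceiling(n_cpg / run_len)
  run_feat <- sample(names(feature_mix), n_runs, replace = TRUE,
                     prob = feature_mix)
  feature <- rep(run_feat, each = run_len)[seq_len(n_cpg)]

  gaps <- 2L + rpois(n_cpg, max(mean_spacing - 2, 1))
  pos <- cumsum(gaps) - gaps[1L]

  p_5hmc <- numeric(n_cpg)
  p_5mc <- numeric(n_cpg)
  for (f in unique(feature)) {
    i <- which(feature == f)
    lm <- level_model[[f]]
    # degenerate means give deterministic levels (e.g. a 5hmC-free landscape)
    h <- if (lm$h_mean == 0) numeric(length(i)) else if (lm$h_mean == 1)
      rep(1, length(i)) else
      rbeta(length(i), lm$h_mean * lm$h_conc, (1 - lm$h_mean) * lm$h_conc)
    m_frac <- rbeta(length(i), lm$m_mean * lm$m_conc,
                    (1 - lm$m_mean) * lm$m_conc)
    p_5hmc[i] <- h
    p_5mc[i] <- m_frac * (1 - h)
  }

  out <- data.frame(chrom = chrom, pos = as.integer(pos), feature = feature,
                    p_5mc = p_5mc, p_5hmc = p_5hmc, stringsAsFactors = FALSE)
  attr(out, "chemistry") <- chem
  attr(out, "chrom_len") <- as.integer(max(pos) + mean_spacing)
  class(out) <- c("true_methylome", "data.frame")
  out
}

#' Construct a ground-truth methylome from explicit levels
#'
#' Companion constructor to [simulate_methylome()] for scripted truths:
#' supply per-CpG true 5mC and 5hmC levels directly.
#'
#' @param p_5mc,p_5hmc Per-CpG true levels; `p_5mc + p_5hmc <= 1`.
#' @param pos Optional 0-based positions (strictly increasing); defaults
#'   to 100-bp spacing.
#' @param chrom Chromosome name.
#' @param feature Optional feature labels.
#' @param chem A [chemistry_model()].
#' @return A `true_methylome` table, as [simulate_methylome()].
#' @export
true_methylome <- function(p_5mc, p_5hmc, pos = NULL, chrom = "chr1",
                           feature = NA_character_,
                           chem = chemistry_model()) {
  n <- max(length(p_5mc), length(p_5hmc))
  p_5mc <- rep_len(p_5mc, n)
  p_5hmc <- rep_len(p_5hmc, n)
  if (any(p_5mc < 0 | p_5hmc < 0 | p_5mc + p_5hmc > 1 + 1e-12)) {
    stop("need p_5mC, p_5hmC >= 0 and p_5mC + p_5hmC <= 1")
  }
  if (is.null(pos)) pos <- seq_len(n) * 100L - 100L
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  out <- data.frame(chrom = chrom, pos = as.integer(pos),
                    feature = rep_len(feature, n),
                    p_5mc = p_5mc, p_5hmc = p_5hmc,
                    stringsAsFactors = FALSE)
  attr(out, "chemistry") <- chem
  attr(out, "chrom_len") <- as.integer(max(pos) + 100L)
  class(out) <- c("true_methylome", "data.frame")
  out
}

#' Simulate paired Bis/OxBis count tables
#'
#' For each CpG the coverage `N` is Poisson with the given mean,
#' independently per treatment (Bis and OxBis are separate libraries), and
#' the retained-cytosine count is `NC ~ Binomial(N, r)` where the retention
#' rate `r` follows the chemistry model: Bis reads 5modC (= 5mC + 5hmC),
#' OxBis reads 5mC plus the unoxidised 5hmC remainder, and unmodified
#' cytosines are retained at the non-conversion error rate.
#'
#' @param truth A [simulate_methylome()] result.
#' @param mean_coverage Mean coverage; scalar or length-2 vector
#'   `c(bis, oxbis)`. Defaults to the 18x/16x means of a typical
#'   whole-genome Bis/OxBis pair.
#' @param seed Integer seed.
#'
#' @return List with elements `bis` and `oxbis`, each a CpG count table
#'   (`chrom`, `pos`, `nc`, `n`) with a `treatment` attribute.
#' @export
simulate_bisoxbis_counts <- function(truth, mean_coverage = c(18, 16),
                                     seed = NULL) {
  if (length(mean_coverage) == 1L) mean_coverage <- rep(mean_coverage, 2L)
  if (any(mean_coverage <= 0)) stop("mean_coverage must be > 0")
  if (!is.null(seed)) set.seed(seed)
  chem <- attr(truth, "chemistry")
  if (is.null(chem)) chem <- chemistry_model()
  r <- retention_rates(truth$p_5mc, truth$p_5hmc, chem)
  n_cpg <- nrow(truth)
  one <- function(rate, mu, treatment) {
    n <- rpois(n_cpg, mu)
    nc <- rbinom(n_cpg, n, rate)
    tab <- data.frame(chrom = truth$chrom, pos = truth$pos, nc = nc, n = n,
                      stringsAsFactors = FALSE)
    attr(tab, "treatment") <- treatment
    tab
  }
  list(bis = one(r$bis, mean_coverage[1L], "Bis"),
       oxbis = one(r$oxbis, mean_coverage[2L], "OxBis"))
}
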