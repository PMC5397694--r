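#' Simulate hMeDIP-style tile counts
#'
#' Generates immunoprecipitation (IP) and input read counts over a
#' fixed-width tiling of the simulated chromosome. Input counts are Poisson
#' around a flat background; IP counts are negative-binomial with mean
#' scaled by `enrichment_fn` evaluated at the average true 5hmC of the
#' CpGs in each tile (tiles without CpGs count as 0 5hmC). Tiles whose
#' enrichment exceeds 1 are recorded as true peak intervals.
#'
#' @param truth A [simulate_methylome()] result.
#' @param tile_width Tile width in bases (default 300).
#' @param n_ip_reps Number of IP replicates.
#' @param background_mean Mean input reads per tile.
#' @param enrichment_fn Function mapping average tile 5hmC in `[0,1]` to an
#'   IP/input mean ratio; default `1 + 20 * h`.
#' @param dispersion Negative-binomial dispersion of IP counts.
#' @param seed Integer seed.
#'
#' @return List with `tiles` (interval columns plus `ip_1..ip_k`, `input`,
#'   `mean_hmc`, `enrichment`) and `true_peaks` (merged intervals where
#'   enrichment > 1).
#' @export
simulate_hmedip <- function(truth, tile_width = 300L, n_ip_reps = 2L,
                            background_mean = 10,
                            enrichment_fn = function(h) 1 + 20 * h,
                            dispersion = 0.01, seed = NULL) {
  tile_width <- as.integer(tile_width)
  if (tile_width <= 0L) stop("tile_width must be > 0")
  if (background_mean <= 0) stop("background_mean must be > 0")
  if (!is.null(seed)) set.seed(seed)
  chrom_len <- attr(truth, "chrom_len")
  tiles <- tile_genome(chrom_len, tile_width, chrom = truth$chrom[1L])
  idx <- findInterval(truth$pos, tiles$start)
  hmc_sum <- tapply(truth$p_5hmc, idx, sum)
  hmc_n <- tapply(truth$p_5hmc, idx, length)
  mean_hmc <- numeric(nrow(tiles))
  mean_hmc[as.integer(names(hmc_sum))] <- hmc_sum / hmc_n
  enr <- enrichment_fn(mean_hmc)
  n_tile <- nrow(tiles)
  for (k in seq_len(n_ip_reps)) {
    tiles[[paste0("ip_", k)]] <- rnbinom(n_tile, mu = background_mean * enr,
                                         size = 1 / dispersion)
  }
  tiles$input <- rpois(n_tile, background_mean)
  tiles$mean_hmc <- mean_hmc
  tiles$enrichment <- enr
  peak_tiles <- tiles[enr > 1, c("chrom", "start", "end"), drop = FALSE]
  true_peaks <- if (nrow(peak_tiles)) merge_intervals(peak_tiles) else
    peak_tiles
  list(tiles = tiles, true_peaks = true_peaks)
}

#' Simulate spike-in control counts
#'
#' Spike-in controls fix the true modification state of every site:
#' `lambda_5mC` is CpG-methylated lambda DNA, `pUC18_5hmC` and `APC_5hmC`
#' are fully hydroxymethylated amplicons. Each control also carries
#' unmodified (non-CpG) cytosines, which is what the bisulphite conversion
#' efficiency is read from. Retained/converted counts are binomial at
#' `depth` per site for each of the Bis, OxBis and TAB assays, with
#' retention probabilities given by the chemistry model:
#'
#' * unmodified: retained with probability `e_nonconv` in every assay;
#' * 5mC: retained `1 - e_overconv` in Bis and OxBis; in TAB retained only
#'   if TET misses it, `(1 - eff_tet) * (1 - e_overconv)`;
#' * 5hmC: retained `1 - e_overconv` in Bis; in OxBis retained only if
#'   oxidation fails, `(1 - eff_ox) * (1 - e_overconv)`; in TAB retained if
#'   glucosylation protects it, `eff_bgt * (1 - e_overconv)` (unprotected
#'   5hmC is assumed oxidised and converted).
#'
#' @param kind One of `"lambda_5mC"`, `"pUC18_5hmC"`, `"APC_5hmC"`.
#' @param n_sites Modified sites per control (an equal number of unmodified
#'   sites is added).
#' @param depth Coverage per site (>= 1).
#' @param chem A [chemistry_model()].
#' @param seed Integer seed.
#'
#' @return `data.frame` with columns `site`, `state`
#'   (`unmodified`/`5mC`/`5hmC`), `assay` (`Bis`/`OxBis`/`TAB`),
#'   `retained`, `converted`.
#' @export
simulate_spikein <- function(kind = c("lambda_5mC", "pUC18_5hmC", "APC_5hmC"),
                             n_sites = 20L, depth = 1000L,
                             chem = chemistry_model(), seed = NULL) {
  kind <- match.arg(kind)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mod_state <- if (kind == "lambda_5mC") "5mC" else "5hmC"
  keep <- 1 - chem$e_overconv
  p_ret <- function(state, assay) {
    switch(state,
      unmodified = chem$e_nonconv,
      "5mC" = switch(assay,
        Bis = keep, OxBis = keep,
        TAB = (1 - chem$eff_tet) * keep),
      "5hmC" = switch(assay,
        Bis = keep,
        OxBis = (1 - chem$eff_ox) * keep,
        TAB = chem$eff_bgt * keep))
  }
  grid <- expand.grid(site = seq_len(2L * n_sites),
                      assay = c("Bis", "OxBis", "TAB"),
                      stringsAsFactors = FALSE)
  grid$state <- ifelse(grid$site <= n_sites, mod_state, "unmodified")
  pr <- mapply(p_ret, grid$state, grid$assay)
  grid$retained <- rbinom(nrow(grid), depth, pr)
  grid$converted <- depth - grid$retained
  attr(grid, "kind") <- kind
  grid[, c("site", "state", "assay", "retained", "converted")]
}

#' Simulate single-molecule amplicon reads
#'
#' Produces a reads x CpGs binary modification matrix whose per-CpG
#' marginal modification levels equal `levels`, while `mosaicity`
#' interpolates the within-read dependence: at 0 CpGs are sampled
#' independently per read; at 1 each read uses one shared latent uniform,
#' which for a region of equal levels gives all-or-none reads. The
#' construction (per read, one shared vs independent uniforms compared to
#' the per-CpG levels) keeps the marginals fixed at every mosaicity.
#'
#' @param levels Per-CpG true modification levels in `[0, 1]` (>= 1 CpG).
#' @param n_reads Number of reads (>= 1).
#' @param mosaicity Dependence parameter in `[0, 1]`; 0 = independent,
#'   1 = all-or-none.
#' @param seed Integer seed.
#'
#' @return Integer matrix (`n_reads` x `length(levels)`) of 0/1 calls.
#' @export
simulate_amplicon_reads <- function(levels, n_reads, mosaicity = 0,
                                    seed = NULL) {
  if (!length(levels) || any(levels < 0 | levels > 1)) {
    stop("levels must be a non-empty vector of probabilities")
  }
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) stop("n_reads must be >= 1")
  if (mosaicity < 0 || mosaicity > 1) stop("mosaicity must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_cpg <- length(levels)
  homogeneous <- runif(n_reads) < mosaicity
  u <- matrix(runif(n_reads * n_cpg), n_reads, n_cpg)
  shared <- runif(n_reads)
  u[homogeneous, ] <- shared[homogeneous]
  m <- matrix(0L, n_reads, n_cpg)
  m[u < rep(levels, each = n_reads)] <- 1L
  m
}
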