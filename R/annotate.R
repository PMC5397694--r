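#' Bin CpG calls by modification level
#'
#' Assigns every tested CpG to a level bin of its 5hmC estimate
#' (`delta = p_Bis - p_OxBis`) or its total-modification readout
#' (`p_Bis`, i.e. 5modC). Bins are left-closed right-open on the supplied
#' edges, the last bin unbounded above, and values below the first edge
#' fall in the first bin, so every CpG lands in exactly one bin.
#'
#' @param calls An [call_hmc()] result.
#' @param variable `"hmc"` (delta) or `"modc"` (p_Bis).
#' @param edges Strictly increasing bin edges on the proportion scale
#'   (default `c(0, 0.1, 0.2, 0.3)`, the usual 0-10/10-20/20-30/>30%
#'   bins).
#' @return Factor of bin labels, one per CpG.
#' @export
bin_calls_by_level <- function(calls, variable = c("hmc", "modc"),
                               edges = c(0, 0.1, 0.2, 0.3)) {
  variable <- match.arg(variable)
  if (!length(edges) || is.unsorted(edges, strictly = TRUE)) {
    stop("edges must be non-empty and strictly increasing")
  }
  x <- if (variable == "hmc") calls$delta else calls$p_bis
  labs <- c(
    if (length(edges) > 1L)
      paste0(100 * edges[-length(edges)], "-", 100 * edges[-1L], "%"),
    paste0(">", 100 * edges[length(edges)], "%")
  )
  idx <- pmax(findInterval(x, edges), 1L)
  factor(labs[idx], levels = labs)
}

#' Observed/expected enrichment of a CpG set in genomic features
#'
#' For each feature, compares the number of set CpGs falling in the
#' feature with the expectation under uniform sampling from the CpG
#' universe, and tests the overlap hypergeometrically (drawing
#' `|cpg_set|` CpGs from the universe with the feature's CpGs as
#' successes). Enrichment p is the upper tail (including the observed
#' count), depletion p the lower tail.
#'
#' @param cpg_set `data.frame` with `chrom`, `pos` — the CpGs of interest
#'   (must be a subset of `all_cpgs`).
#' @param all_cpgs `data.frame` with `chrom`, `pos` — the tested universe.
#' @param features Interval table with feature labels in `name`.
#' @return `data.frame` per feature: `feature`, `n_feature_cpgs`,
#'   `observed`, `expected`, `oe` and `p_enrich`, `p_deplete`. Features
#'   covering no universe CpG are skipped with a warning.
#' @export
observed_expected_enrichment <- function(cpg_set, all_cpgs, features) {
  key_set <- paste(cpg_set$chrom, cpg_set$pos)
  key_all <- paste(all_cpgs$chrom, all_cpgs$pos)
  if (!all(key_set %in% key_all)) {
    stop("cpg_set must be a subset of all_cpgs")
  }
  n_tot <- nrow(all_cpgs)
  n_set <- nrow(cpg_set)
  in_set <- key_all %in% key_set
  feats <- unique(features$name)
  rows <- lapply(feats, function(f) {
    fr <- features[features$name == f, , drop = FALSE]
    hits <- overlap_points_regions(all_cpgs$chrom, all_cpgs$pos, fr)
    in_feat_idx <- unique(hits$point)
    K <- length(in_feat_idx)
    if (K == 0L) {
      warning("feature '", f, "' covers no universe CpG; skipped")
      return(NULL)
    }
    k <- sum(in_set[in_feat_idx])
    expected <- n_set * K / n_tot
    data.frame(
      feature = f, n_feature_cpgs = K, observed = k, expected = expected,
      oe = k / expected,
      p_enrich = phyper(k - 1, K, n_tot - K, n_set, lower.tail = FALSE),
      p_deplete = phyper(k, K, n_tot - K, n_set),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of hydroxymethylated CpGs per region
#'
#' Per region, the number of tested CpGs, the number significantly
#' hydroxymethylated, and their ratio — i.e. how many of a region's CpGs
#' carry detectable 5hmC.
#'
#' @param calls An [call_hmc()] result.
#' @param regions Interval table.
#' @return `data.frame` per region: `n_cpg`, `n_hmc_cpg`, `fraction`
#'   (NA when no tested CpG overlaps the region).
#' @export
region_hmc_fraction <- function(calls, regions) {
  hits <- overlap_points_regions(calls$chrom, calls$pos, regions)
  n_cpg <- tabulate(hits$region, nbins = nrow(regions))
  sig <- calls$significant[hits$point]
  n_sig <- tabulate(hits$region[sig], nbins = nrow(regions))
  data.frame(
    regions[, c("chrom", "start", "end")],
    n_cpg = n_cpg, n_hmc_cpg = n_sig,
    fraction = ifelse(n_cpg > 0L, n_sig / n_cpg, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Contribution of 5hmC to total modification per region
#'
#' Per region, averages the 5hmC level (significant CpGs contribute their
#' delta, non-significant CpGs are assigned zero) and the 5modC level
#' (`p_Bis`), and reports their ratio — the share of a region's total
#' cytosine modification that is hydroxymethylation.
#'
#' @param calls An [call_hmc()] result.
#' @param regions Interval table.
#' @return `data.frame` per region: `avg_hmc`, `avg_modc`, `contribution`
#'   (NA when `avg_modc` is 0 or no CpG overlaps).
#' @export
region_hmc_contribution <- function(calls, regions) {
  hmc <- ifelse(calls$significant, calls$delta, 0)
  hits <- overlap_points_regions(calls$chrom, calls$pos, regions)
  n_cpg <- tabulate(hits$region, nbins = nrow(regions))
  sum_by <- function(v) {
    out <- numeric(nrow(regions))
    if (nrow(hits)) {
      agg <- rowsum(v[hits$point], hits$region)
      out[as.integer(rownames(agg))] <- agg[, 1L]
    }
    out
  }
  avg_hmc <- ifelse(n_cpg > 0L, sum_by(hmc) / n_cpg, NA_real_)
  avg_modc <- ifelse(n_cpg > 0L, sum_by(calls$p_bis) / n_cpg, NA_real_)
  data.frame(
    regions[, c("chrom", "start", "end")],
    n_cpg = n_cpg, avg_hmc = avg_hmc, avg_modc = avg_modc,
    contribution = ifelse(!is.na(avg_modc) & avg_modc > 0,
                          avg_hmc / avg_modc, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Cross-platform overlap of hydroxymethylated regions
#'
#' Classifies each universe region (regions with adequate coverage on both
#' platforms) as called hydroxymethylated by both platforms, by one only,
#' or by neither, and compares the distribution of maximal per-region 5hmC
#' between the `array_only` and `both` classes with a Kruskal-Wallis test
#' — regions the sequencing platform misses are expected to carry less
#' 5hmC.
#'
#' @param wg_called,array_called Logical vectors over the universe
#'   regions: called by the whole-genome / array platform.
#' @param max_hmc Numeric vector: maximal per-region 5hmC (whole-genome
#'   estimate).
#' @return List with `class` (factor `both`/`wg_only`/`array_only`/
#'   `neither`), `counts`, and `kw` (the Kruskal-Wallis `htest` comparing
#'   `max_hmc` between `array_only` and `both`, or NULL with a warning
#'   when a class is empty).
#' @export
platform_overlap <- function(wg_called, array_called, max_hmc) {
  stopifnot(length(wg_called) == length(array_called),
            length(max_hmc) == length(wg_called))
  cls <- ifelse(wg_called & array_called, "both",
                ifelse(wg_called, "wg_only",
                       ifelse(array_called, "array_only", "neither")))
  cls <- factor(cls, levels = c("both", "wg_only", "array_only", "neither"))
  kw <- NULL
  sel <- cls %in% c("both", "array_only")
  if (all(c("both", "array_only") %in% cls[sel])) {
    kw <- kruskal.test(max_hmc[sel], droplevels(cls[sel]))
  } else {
    warning("empty comparison class; Kruskal-Wallis test skipped")
  }
  list(class = cls, counts = table(cls), kw = kw)
}
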