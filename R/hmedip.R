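#' Count extended fragments on genomic tiles
#'
#' Each fragment is extended to `extend` bases from its 5' start and
#' increments every fixed-width tile it overlaps by at least one base —
#' the standard read-extension tiling used for immunoprecipitation
#' enrichment analysis.
#'
#' @param fragments `data.frame` with `chrom`, `start` (0-based 5'
#'   positions; one chromosome per call set is fine, multiple allowed).
#' @param chrom_len Chromosome length (single-chromosome mode) or named
#'   vector of lengths.
#' @param tile_width Tile width (default 300).
#' @param extend Extension length in bases (default 300).
#' @return Interval table with a `count` column covering each chromosome.
#' @export
count_fragments_on_tiles <- function(fragments, chrom_len, tile_width = 300L,
                                     extend = 300L) {
  tile_width <- as.integer(tile_width)
  extend <- as.integer(extend)
  stopifnot(tile_width > 0L, extend > 0L)
  if (is.null(names(chrom_len))) {
    names(chrom_len) <- unique(fragments$chrom)[1L]
  }
  pieces <- lapply(names(chrom_len), function(ch) {
    tiles <- tile_genome(chrom_len[[ch]], tile_width, chrom = ch)
    fs <- fragments$start[fragments$chrom == ch]
    counts <- integer(nrow(tiles))
    if (length(fs)) {
      fe <- pmin(fs + extend, as.integer(chrom_len[[ch]]))
      first <- pmax(fs, 0L) %/% tile_width + 1L
      last <- pmin((fe - 1L) %/% tile_width + 1L, nrow(tiles))
      # difference-array trick: +1 at first tile, -1 after last
      inc <- tabulate(first, nbins = nrow(tiles) + 1L) -
        tabulate(last + 1L, nbins = nrow(tiles) + 1L)
      counts <- cumsum(inc)[seq_len(nrow(tiles))]
    }
    tiles$count <- counts
    tiles
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Remove low-count tiles
#'
#' Drops tiles whose total read count across all samples is below
#' `min_total` (default 20), the usual pre-test filter for tile-based
#' enrichment testing.
#'
#' @param tiles Tile table with count columns.
#' @param count_cols Names of the count columns; defaults to every
#'   numeric column except the coordinates.
#' @param min_total Minimum summed count.
#' @return The filtered tile table.
#' @export
filter_low_tiles <- function(tiles, count_cols = NULL, min_total = 20L) {
  if (is.null(count_cols)) {
    count_cols <- setdiff(names(tiles)[vapply(tiles, is.numeric, TRUE)],
                          c("start", "end", "mean_hmc", "enrichment"))
  }
  if (!length(count_cols)) stop("no count columns found")
  total <- rowSums(as.matrix(tiles[, count_cols, drop = FALSE]))
  tiles[total >= min_total, , drop = FALSE]
}

# Conditional NB exact test for one tile: given the library-size-adjusted
# pair (y1, y2) with common mean under the null, condition on the total and
# compute a two-sided p by doubling the smaller tail (capped at 1).
nb_exact_p <- function(y1, y2, dispersion) {
  t <- y1 + y2
  if (t == 0L) return(1)
  k <- 0:t
  logp <- if (dispersion > 0) {
    size <- 1 / dispersion
    dnbinom(k, size = size, mu = t / 2, log = TRUE) +
      dnbinom(t - k, size = size, mu = t / 2, log = TRUE)
  } else {
    stats::dbinom(k, t, 0.5, log = TRUE)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  lower <- sum(p[k <= y1])
  upper <- sum(p[k >= y1])
  min(1, 2 * min(lower, upper))
}

#' Fixed-dispersion negative-binomial exact test of IP versus input
#'
#' Tests each tile's immunoprecipitation (IP) counts against the input
#' control with a conditional exact negative-binomial test at a fixed
#' dispersion (default 0.01). Library sizes are the plain column sums
#' (no normalisation factors); counts are mean-scaled to a common library
#' size and rounded, the test conditions on the adjusted tile total, and
#' the two-sided p-value doubles the smaller tail (capped at 1). Multiple
#' IP replicates are summed before the contrast. `logFC` is
#' `log2((ip_cpm + prior) / (input_cpm + prior))`; FDR is
#' Benjamini-Hochberg across tiles.
#'
#' @param ip_counts Vector or matrix (tiles x replicates) of IP counts.
#' @param input_counts Vector of input counts.
#' @param dispersion Negative-binomial dispersion (>= 0; 0 gives the
#'   Poisson-limit conditional binomial test).
#' @param lib_sizes Optional length-2 vector `c(ip, input)` of library
#'   sizes; defaults to the column sums (after summing IP replicates).
#' @param prior_count Prior count in the CPM ratios (default 0.5).
#'
#' @return `data.frame` per tile: `ip`, `input`, `logcpm_ip`,
#'   `logcpm_input`, `logfc`, `p_value`, `fdr`.
#' @export
nb_exact_test <- function(ip_counts, input_counts, dispersion = 0.01,
                          lib_sizes = NULL, prior_count = 0.5) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  ip <- if (is.matrix(ip_counts)) rowSums(ip_counts) else ip_counts
  if (length(ip) != length(input_counts)) {
    stop("ip and input count vectors differ in length")
  }
  if (is.null(lib_sizes)) lib_sizes <- c(sum(ip), sum(input_counts))
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  common <- mean(lib_sizes)
  y1 <- as.integer(round(ip * common / lib_sizes[1L]))
  y2 <- as.integer(round(input_counts * common / lib_sizes[2L]))
  # p-value depends only on (y1, y2); compute unique pairs once
  key <- paste(y1, y2)
  uk <- !duplicated(key)
  pu <- mapply(nb_exact_p, y1[uk], y2[uk],
               MoreArgs = list(dispersion = dispersion))
  p <- pu[match(key, key[uk])]
  cpm_ip <- ip / lib_sizes[1L] * 1e6
  cpm_in <- input_counts / lib_sizes[2L] * 1e6
  data.frame(
    ip = ip, input = input_counts,
    logcpm_ip = log2(cpm_ip + prior_count),
    logcpm_input = log2(cpm_in + prior_count),
    logfc = log2((cpm_ip + prior_count) / (cpm_in + prior_count)),
    p_value = p, fdr = p.adjust(p, method = "BH")
  )
}

#' Call enriched tiles
#'
#' A tile is called 5hmC-enriched when `FDR < fdr` and
#' `logFC > min_logfc` (defaults 0.1 and 0).
#'
#' @param test An [nb_exact_test()] result.
#' @param fdr FDR threshold.
#' @param min_logfc logFC threshold (strict).
#' @return Logical vector, one per tile.
#' @export
call_enriched <- function(test, fdr = 0.1, min_logfc = 0) {
  test$fdr < fdr & test$logfc > min_logfc
}

#' Bin tiles by enrichment strength
#'
#' Splits called tiles into low / medium / high enrichment by logFC
#' cut-offs (defaults 1.8 and 2.4); boundary values go to the lower bin.
#'
#' @param test An [nb_exact_test()] result (or any table with `logfc`).
#' @param low_lt,high_gt Cut-offs.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
bin_logfc <- function(test, low_lt = 1.8, high_gt = 2.4) {
  lf <- test$logfc
  factor(ifelse(lf <= low_lt, "low",
                ifelse(lf <= high_gt, "medium", "high")),
         levels = c("low", "medium", "high"))
}

# Build the alternating window/gap segmentation of one chromosome from
# summit positions: windows are summit +/- half_width (merged when they
# touch, clipped at the ends), gaps the complement.
summit_segments <- function(summits, chrom_len, half_width = 150L) {
  w <- merge_intervals(data.frame(
    chrom = summits$chrom,
    start = pmax(0L, summits$pos - half_width),
    end = pmin(as.integer(chrom_len), summits$pos + half_width + 1L),
    stringsAsFactors = FALSE
  ))
  g <- complement_intervals(w$start, w$end, chrom_len)
  seg <- rbind(
    data.frame(start = w$start, end = w$end, label = "window",
               stringsAsFactors = FALSE),
    data.frame(start = g$start, end = g$end, label = "gap",
               stringsAsFactors = FALSE)
  )
  seg <- seg[order(seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  seg$chrom <- w$chrom[1L]
  seg
}

# Mean of per-segment average 5hmC for windows minus gaps, given segment
# boundaries (sorted, tiling [0, chrom_len)) and per-CpG contribution
# values from the discard/impute rules. Segments without contributing
# CpGs are excluded from their class mean.
segment_mean_diff <- function(seg_start, seg_label, pos, value) {
  idx <- findInterval(pos, seg_start)
  n <- tabulate(idx, nbins = length(seg_start))
  sums <- numeric(length(seg_start))
  agg <- rowsum(value, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  avg <- sums / n
  w <- avg[seg_label == "window" & n > 0]
  g <- avg[seg_label == "gap" & n > 0]
  if (!length(w) || !length(g)) return(NA_real_)
  mean(w) - mean(g)
}

#' 5hmC at hMeDIP summit windows versus gaps
#'
#' Expands each peak summit `half_width` bases up- and downstream, takes
#' the complement as gaps, computes the region-average 5hmC (with the
#' discard/impute rules of [region_average_hmc()]) for every window and
#' gap, and compares the two distributions with a Kruskal-Wallis test. A
#' specific antibody should show substantially higher 5hmC in windows.
#'
#' @param summits `data.frame` with `chrom`, `pos` (summit positions).
#' @param calls An [call_hmc()] result.
#' @param chrom_len Chromosome length.
#' @param half_width Window half-width (default 150, i.e. 301-bp windows
#'   clipped at chromosome ends).
#' @return List with `windows` and `gaps` (region-average tables) and
#'   `kw` (Kruskal-Wallis `htest` on the defined averages).
#' @export
summit_gap_hmc <- function(summits, calls, chrom_len, half_width = 150L) {
  seg <- summit_segments(summits, chrom_len, half_width)
  regions <- genomic_intervals(seg$chrom, seg$start, seg$end, seg$label)
  avg <- region_average_hmc(calls, regions)
  avg$label <- seg$label
  windows <- avg[avg$label == "window", , drop = FALSE]
  gaps <- avg[avg$label == "gap", , drop = FALSE]
  vals <- c(windows$avg_hmc[windows$defined], gaps$avg_hmc[gaps$defined])
  grp <- factor(rep(c("window", "gap"),
                    c(sum(windows$defined), sum(gaps$defined))))
  if (nlevels(droplevels(grp)) < 2L) stop("need defined windows and gaps")
  list(windows = windows, gaps = gaps,
       kw = kruskal.test(vals, grp))
}

#' Permutation null for the summit-gap 5hmC difference
#'
#' The observed statistic is the mean of per-window average 5hmC minus the
#' mean of per-gap average 5hmC. The null randomly permutes the order of
#' the alternating window/gap segments along the chromosome (segment
#' lengths and labels preserved, positions reassigned), recomputing the
#' statistic each time. The empirical p-value is
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param summits `data.frame` with `chrom`, `pos`.
#' @param calls An [call_hmc()] result.
#' @param chrom_len Chromosome length.
#' @param n_perm Number of permutations (>= 1; use >= 100 for stable p).
#' @param seed Integer seed.
#' @param half_width Summit window half-width.
#' @return List: `observed`, `null` (length `n_perm`), `p_value`.
#' @export
permutation_null <- function(summits, calls, chrom_len, n_perm = 999L,
                             seed = NULL, half_width = 150L) {
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  seg <- summit_segments(summits, chrom_len, half_width)
  if (nrow(seg) < 2L) stop("degenerate segmentation: need >= 2 segments")
  contrib <- hmc_contributions(calls)
  pos <- calls$pos[contrib$keep]
  value <- contrib$value[contrib$keep]
  widths <- seg$end - seg$start
  observed <- segment_mean_diff(seg$start, seg$label, pos, value)
  total <- sum(widths)
  null <- vapply(seq_len(n_perm), function(i) {
    ord <- sample.int(nrow(seg))
    w <- widths[ord]
    starts <- cumsum(c(0L, w[-length(w)]))
    stopifnot(sum(w) == total)  # length conservation per permutation
    segment_mean_diff(starts, seg$label[ord], pos, value)
  }, numeric(1))
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed, na.rm = TRUE)) / (n_perm + 1))
}

#' Classify hMeDIP peaks by single-base 5hmC support
#'
#' Restricts to peaks whose every overlapped CpG has at least `min_cov`
#' coverage in both the Bis and OxBis count tables, computes each peak's
#' average 5hmC via [region_average_hmc()], and reports the fraction of
#' peaks with average 5hmC > 0 (antibody-specific peaks). A
#' length-preserving random placement of the same peaks gives the
#' expected fraction under no spatial association.
#'
#' @param peaks Interval table of peaks.
#' @param bis,oxbis CpG count tables (used for the coverage eligibility
#'   rule; CpGs absent from either table make a peak ineligible).
#' @param calls An [call_hmc()] result (computed from `bis`/`oxbis` when
#'   NULL).
#' @param min_cov Coverage threshold (default 10).
#' @param chrom_len Chromosome length for random placement.
#' @param n_perm Number of random placements (0 to skip).
#' @param seed Integer seed.
#' @return List: `eligible` (logical per peak), `peak_hmc`
#'   (region-average table over eligible peaks), `fraction_positive`,
#'   `null_fractions`, `p_value` (empirical, when `n_perm > 0`).
#' @export
classify_peaks_by_hmc <- function(peaks, bis, oxbis, calls = NULL,
                                  min_cov = 10L, chrom_len = NULL,
                                  n_perm = 0L, seed = NULL) {
  if (is.null(calls)) calls <- call_hmc(bis, oxbis, min_cov = min_cov)
  key_b <- paste(bis$chrom, bis$pos)
  key_o <- paste(oxbis$chrom, oxbis$pos)
  covered <- bis[bis$n >= min_cov & key_b %in% key_o[oxbis$n >= min_cov], ,
                 drop = FALSE]
  # a peak is eligible iff all its CpGs (union of both tables) pass
  all_pos <- unique(rbind(bis[, c("chrom", "pos")], oxbis[, c("chrom", "pos")]))
  hits_all <- overlap_points_regions(all_pos$chrom, all_pos$pos, peaks)
  hits_cov <- overlap_points_regions(covered$chrom, covered$pos, peaks)
  n_all <- tabulate(hits_all$region, nbins = nrow(peaks))
  n_cov <- tabulate(hits_cov$region, nbins = nrow(peaks))
  eligible <- n_all > 0L & n_all == n_cov
  if (!any(eligible)) stop("no eligible peaks at the coverage threshold")
  pk <- peaks[eligible, , drop = FALSE]
  avg <- region_average_hmc(calls, pk)
  frac_pos <- function(a) {
    def <- a$defined
    if (!any(def)) return(NA_real_)
    mean(a$avg_hmc[def] > 0)
  }
  fraction <- frac_pos(avg)
  null_fracs <- numeric(0)
  p_value <- NA_real_
  if (n_perm > 0L) {
    if (is.null(chrom_len)) stop("chrom_len required for random placement")
    if (!is.null(seed)) set.seed(seed)
    widths <- pk$end - pk$start
    null_fracs <- vapply(seq_len(n_perm), function(i) {
      st <- as.integer(floor(runif(length(widths),
                                   0, chrom_len - widths)))
      frac_pos(region_average_hmc(
        calls, genomic_intervals(pk$chrom, st, st + widths)))
    }, numeric(1))
    p_value <- (1 + sum(null_fracs >= fraction, na.rm = TRUE)) / (n_perm + 1)
  }
  list(eligible = eligible, peak_hmc = avg, fraction_positive = fraction,
       null_fractions = null_fracs, p_value = p_value)
}
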