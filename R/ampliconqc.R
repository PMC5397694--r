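pooled_fraction <- function(counts, state, assay) {
  sel <- counts$state == state & counts$assay == assay
  ret <- sum(counts$retained[sel])
  conv <- sum(counts$converted[sel])
  if (ret + conv == 0L) stop("no coverage for ", state, " sites in ", assay)
  list(retained = ret, converted = conv, total = ret + conv,
       ret_frac = ret / (ret + conv))
}

#' Bisulphite conversion efficiency from unmodified spike-in sites
#'
#' Pools retained/converted counts over unmodified cytosines of a spike-in
#' control and reports the conversion efficiency
#' `converted / (converted + retained)`, its complement (the
#' non-conversion rate, the chemistry's false-positive rate) and an exact
#' binomial confidence interval.
#'
#' @param counts Spike-in count table (see [simulate_spikein()]), already
#'   restricted to one assay or carrying an `assay` column.
#' @param assay Assay to read the efficiency from (default `"Bis"`).
#' @param state Site state to pool over (default `"unmodified"`).
#' @param conf_level Confidence level of the binomial CI.
#' @return List: `efficiency`, `nonconversion_rate`, `conf_int`, `n`.
#' @export
conversion_efficiency <- function(counts, assay = "Bis",
                                  state = "unmodified", conf_level = 0.95) {
  f <- pooled_fraction(counts, state, assay)
  ci <- stats::binom.test(f$converted, f$total,
                          conf.level = conf_level)$conf.int
  list(efficiency = f$converted / f$total,
       nonconversion_rate = f$ret_frac,
       conf_int = as.numeric(ci), n = f$total)
}

#' 5hmC oxidation efficiency of the oxidative bisulphite reaction
#'
#' The fraction of 5hmC spike-in sites converted in OxBis, normalised by
#' the retained (i.e. truly hydroxymethylated) fraction of the same sites
#' in the conventional bisulphite reaction, clipped to `[0, 1]`. The
#' normalisation cancels incomplete modification of the control.
#'
#' @param bis_counts,oxbis_counts Spike-in count tables for the Bis and
#'   OxBis assays (may be the same table carrying both assays).
#' @param state Site state (default `"5hmC"`).
#' @return Efficiency in `[0, 1]`.
#' @export
oxidation_efficiency <- function(bis_counts, oxbis_counts, state = "5hmC") {
  bis <- pooled_fraction(bis_counts, state, "Bis")
  ox <- pooled_fraction(oxbis_counts, state, "OxBis")
  if (bis$ret_frac == 0) stop("no retained signal in Bis: undefined")
  min(1, max(0, (1 - ox$ret_frac) / bis$ret_frac))
}

#' TET-mediated 5mC oxidation efficiency
#'
#' One minus the ratio of retained (mC) signal in TAB to that in Bis at
#' 5mC spike-in sites: efficient TET oxidation leaves almost no 5mC
#' signal in TAB.
#'
#' @param tab_counts,bis_counts Spike-in count tables.
#' @param state Site state (default `"5mC"`).
#' @return Efficiency in `[0, 1]`.
#' @export
tet_oxidation_efficiency <- function(tab_counts, bis_counts, state = "5mC") {
  tab <- pooled_fraction(tab_counts, state, "TAB")
  bis <- pooled_fraction(bis_counts, state, "Bis")
  if (bis$ret_frac == 0) stop("no retained signal in Bis: undefined")
  min(1, max(0, 1 - tab$ret_frac / bis$ret_frac))
}

#' Beta-glucosyltransferase protection efficiency
#'
#' The ratio of retained 5hmC signal in TAB to that in Bis at 5hmC
#' spike-in sites, capped at 1: complete glucosylation protects every
#' 5hmC from TET oxidation, so TAB retains as much as Bis.
#'
#' @param tab_counts,bis_counts Spike-in count tables.
#' @param state Site state (default `"5hmC"`).
#' @return Efficiency in `[0, 1]`.
#' @export
bgt_protection_efficiency <- function(tab_counts, bis_counts,
                                      state = "5hmC") {
  tab <- pooled_fraction(tab_counts, state, "TAB")
  bis <- pooled_fraction(bis_counts, state, "Bis")
  if (bis$ret_frac == 0) stop("no retained signal in Bis: undefined")
  min(1, tab$ret_frac / bis$ret_frac)
}

#' Classify single molecules by per-read modification fraction
#'
#' For each read of a reads x CpGs binary matrix, computes the fraction
#' of modified CpGs and assigns it to one of five classes: exactly 0,
#' (0-10], (10-50], (50-80] and (80-100] percent (fully unmodified reads
#' are their own class; other bins are right-closed). Class frequencies
#' sum to 1 per region.
#'
#' @param reads Binary matrix, reads in rows, CpGs in columns (>= 1 CpG).
#' @param edges Internal bin edges as fractions (default
#'   `c(0, 0.1, 0.5, 0.8, 1)`).
#' @return List: `freq` (named class frequencies), `fractions` (per-read
#'   modified fraction), `mean_modification` (region average).
#' @export
classify_single_molecules <- function(reads,
                                      edges = c(0, 0.1, 0.5, 0.8, 1)) {
  reads <- as.matrix(reads)
  if (ncol(reads) < 1L || nrow(reads) < 1L) {
    stop("need a non-empty reads x CpGs matrix")
  }
  frac <- rowMeans(reads)
  labs <- c("0", paste0(100 * edges[-length(edges)], "-",
                        100 * edges[-1L], "%"))
  cls <- rep(labs[1L], length(frac))
  pos <- frac > 0
  cls[pos] <- labs[-1L][findInterval(frac[pos], edges, left.open = TRUE,
                                     rightmost.closed = TRUE)]
  cls <- factor(cls, levels = labs)
  freq <- setNames(as.numeric(table(cls)) / length(frac), labs)
  list(freq = freq, fractions = frac, mean_modification = mean(frac))
}
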