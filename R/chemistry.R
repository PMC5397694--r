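#' Chemistry error model for bisulphite-based assays
#'
#' Collects the conversion-chemistry parameters shared by all simulated
#' assays. Defaults are the efficiencies printed for the spike-in controls
#' of a deep Bis/OxBis/TAB experiment: 0.42% non-conversion of unmodified
#' cytosine, 99.33% oxidation of 5hmC in the oxidative bisulphite reaction,
#' 98.74% TET-mediated oxidation of 5mC in TAB, and complete
#' beta-glucosyltransferase protection of 5hmC. Over-conversion of modified
#' cytosines defaults to `1 - 0.9830`, the lower end of the reported
#' bisulphite conversion range, applied symmetrically to 5mC and 5hmC.
#'
#' @param e_nonconv Probability an unmodified C is read as C (non-conversion
#'   error).
#' @param e_overconv Probability a modified C is read as T (over-conversion).
#' @param eff_ox Probability a 5hmC is oxidised (hence read as T) in OxBis.
#' @param eff_tet Probability a 5mC is oxidised (hence read as T) in TAB.
#' @param eff_bgt Probability a 5hmC is glucosylated, protecting it (read as
#'   C) in TAB; unprotected 5hmC is assumed oxidised and converted.
#'
#' @return An object of class `chemistry_model` (a named list).
#' @export
chemistry_model <- function(e_nonconv = 0.0042, e_overconv = 1 - 0.9830,
                            eff_ox = 0.9933, eff_tet = 0.9874,
                            eff_bgt = 1.0) {
  cm <- list(e_nonconv = e_nonconv, e_overconv = e_overconv,
             eff_ox = eff_ox, eff_tet = eff_tet, eff_bgt = eff_bgt)
  for (nm in names(cm)) {
    v <- cm[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(nm, " must be a single probability in [0, 1]")
    }
  }
  structure(cm, class = "chemistry_model")
}

#' @export
print.chemistry_model <- function(x, ...) {
  cat("Bisulphite chemistry error model\n")
  cat(sprintf("  non-conversion (unmodified C read as C): %.4f\n", x$e_nonconv))
  cat(sprintf("  over-conversion (modified C read as T):  %.4f\n", x$e_overconv))
  cat(sprintf("  OxBis 5hmC oxidation efficiency:         %.4f\n", x$eff_ox))
  cat(sprintf("  TAB TET 5mC oxidation efficiency:        %.4f\n", x$eff_tet))
  cat(sprintf("  TAB BGT 5hmC protection efficiency:      %.4f\n", x$eff_bgt))
  invisible(x)
}

# Expected retained-cytosine fraction per treatment given true (p5mC, p5hmC).
# Bis reads 5modC = 5mC + 5hmC; OxBis reads 5mC plus the unoxidised 5hmC
# remainder; unmodified C contributes the non-conversion error either way.
retention_rates <- function(p_5mc, p_5hmc, chem) {
  p_un <- 1 - p_5mc - p_5hmc
  keep <- 1 - chem$e_overconv
  list(
    bis = (p_5mc + p_5hmc) * keep + p_un * chem$e_nonconv,
    oxbis = p_5mc * keep + p_5hmc * (1 - chem$eff_ox) + p_un * chem$e_nonconv
  )
}
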