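#' Atomic C:N ratio from weight percentages
#'
#' `(%C / %N) * 1.1666`, converting the weight ratio to an atomic ratio
#' (14.007/12.011 is the mass correction). Values in 2.9-3.6 indicate
#' preserved bone protein; degraded or contaminated collagen drifts outside.
#' Scale-invariant: multiplying both percentages by the same factor leaves
#' the ratio unchanged.
#'
#' @param pct_c,pct_n weight % carbon and nitrogen (vectorised; `NA`
#'   propagates).
#' @return Atomic C:N, unitless.
#' @export
atomic_cn <- function(pct_c, pct_n) {
  if (any(pct_n <= 0, na.rm = TRUE))
    stop("atomic C:N undefined for pct_n <= 0")
  (pct_c / pct_n) * 1.1666
}

#' Delta notation for isotope abundance ratios
#'
#' Per-mil deviation of a sample's isotope abundance ratio from an
#' international standard (V-PDB for carbon, AIR for nitrogen):
#' `(r_sample / r_standard - 1) * 1000`. Zero exactly at the standard and
#' strictly increasing in the sample ratio.
#'
#' @param r_sample,r_standard isotope abundance ratios (vectorised).
#' @return delta value in per mil.
#' @export
delta_ratio <- function(r_sample, r_standard) {
  if (any(r_standard <= 0, na.rm = TRUE))
    stop("r_standard must be > 0")
  (r_sample / r_standard - 1) * 1000
}

#' Protein-survival QC flags for a wet-chemistry record
#'
#' Three conventional screens: atomic C:N outside the preserved-protein range
#' (inclusive endpoints, default 2.9-3.6), collagen yield below the suspect
#' floor (default 1% w/w; yields under 1-2% are generally considered suspect
#' and both endpoints are configurable), and analytical nitrogen mass at or
#' below the mass-spectrometry floor (default 7 ug; `NA` when the mass is
#' unknown).
#'
#' @param cn_atomic atomic C:N (vectorised; `NA` gives an `NA` flag).
#' @param pct_collagen collagen yield, % w/w.
#' @param nitrogen_mass_ug analytical nitrogen mass, micrograms (optional).
#' @param cn_range length-2 inclusive acceptance range for C:N.
#' @param collagen_floor suspect threshold on % collagen.
#' @param nitrogen_floor insufficiency threshold on nitrogen mass, ug.
#' @return A `data.frame` with logical columns `cn_out_of_range`,
#'   `collagen_suspect`, `nitrogen_insufficient`.
#' @export
qc_flags <- function(cn_atomic, pct_collagen, nitrogen_mass_ug = NA_real_,
                     cn_range = c(2.9, 3.6), collagen_floor = 1.0,
                     nitrogen_floor = 7) {
  n <- max(length(cn_atomic), length(pct_collagen), length(nitrogen_mass_ug))
  cn_atomic <- rep_len(cn_atomic, n)
  pct_collagen <- rep_len(pct_collagen, n)
  nitrogen_mass_ug <- rep_len(nitrogen_mass_ug, n)
  data.frame(
    cn_out_of_range = !(cn_atomic >= cn_range[1] & cn_atomic <= cn_range[2]),
    collagen_suspect = pct_collagen < collagen_floor,
    nitrogen_insufficient = nitrogen_mass_ug <= nitrogen_floor)
}
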