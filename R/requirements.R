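# Nutrient requirements: the SID-lysine chain, amino-acid expansion,
# phosphorus/calcium, and log-linear minerals & vitamins. Vectorized.

#' Feed dry-matter intake
#'
#' @param fi Feed intake, kg/d.
#' @param fdm Feed dry-matter fraction, in (0, 1].
#' @return FDMI, kg/d.
#' @export
feed_dry_matter_intake <- function(fi, fdm) {
  stopifnot(fdm > 0, fdm <= 1)
  fdm * fi
}

#' Basal endogenous gastrointestinal lysine losses
#'
#' `1.1 * 4.17e-4 * FDMI` g/d, with the dry-matter intake expressed in
#' grams (the dry-matter fraction applied to feed intake in g/d).
#'
#' @param fdmi_g Feed dry-matter intake, g/d.
#' @return Lysine loss, g/d.
#' @export
git_lysine_loss <- function(fdmi_g) {
  stopifnot(all(fdmi_g >= 0))
  1.1 * 4.17e-4 * fdmi_g
}

#' Integument lysine losses
#'
#' `0.0045 * BW^0.75` g/d (metabolic-weight scaling of skin/hair losses).
#'
#' @param bw Body weight, kg.
#' @return Lysine loss, g/d.
#' @export
integument_lysine_loss <- function(bw) {
  stopifnot(all(bw > 0))
  0.0045 * bw^0.75
}

#' Total SID lysine requirement
#'
#' Maintenance and growth components share the efficiency denominator
#' `0.75 + 0.002 * (Pd_max - 147.7)` (147.7 g/d is the fixed reference
#' maximum deposition, not recomputed per sex):
#' \itemize{
#'   \item `sid_lys1 = (GIT losses + integument losses) / denom`
#'   \item `sid_lys2 = 0.071 * Pd * (1.0547 + 0.002215 * BW) / denom`
#' }
#'
#' @param git,integ Lysine losses, g/d.
#' @param pd Protein deposition, g/d.
#' @param bw Body weight, kg.
#' @param pd_max Sex-specific maximum protein deposition, g/d.
#' @return A list with `sid_lys1`, `sid_lys2` and `total` (their sum),
#'   all g/d.
#' @export
sid_lysine <- function(git, integ, pd, bw, pd_max) {
  denom <- 0.75 + 0.002 * (pd_max - 147.7)
  if (any(denom <= 0))
    stop("non-positive SID-lysine efficiency denominator; check pd_max")
  l1 <- (git + integ) / denom
  l2 <- (0.071 * pd) * (1.0547 + 0.002215 * bw) / denom
  list(sid_lys1 = l1, sid_lys2 = l2, total = l1 + l2)
}

#' Expand SID lysine into the other amino-acid requirements
#'
#' Each essential amino acid (and nitrogen) is a fixed ratio of the total
#' SID lysine requirement.
#'
#' @param sid_lys Total SID lysine, g/d (scalar).
#' @param ratios Named ratio vector, default [amino_acid_ratios()].
#' @return Named numeric vector of requirements, g/d.
#' @export
expand_amino_acids <- function(sid_lys, ratios = amino_acid_ratios()) {
  stopifnot(all(sid_lys >= 0), all(ratios > 0))
  ratios * sid_lys
}

#' Whole-body phosphorus mass
#'
#' Quadratic in whole-body protein mass:
#' `1.1613 + 26.012 * BP + 0.2299 * BP^2` g.
#'
#' @param bp Whole-body protein mass, kg.
#' @return Body phosphorus, g.
#' @export
body_phosphorus_mass <- function(bp) {
  stopifnot(all(bp >= 0))
  1.1613 + 26.012 * bp + 0.2299 * bp^2
}

#' Maximum daily phosphorus retention
#'
#' No retention equation is published; the model operationalizes maximum
#' retention as the daily increment of whole-body phosphorus along the
#' protein trajectory:
#' `body_phosphorus_mass(bp + pd/1000) - body_phosphorus_mass(bp)`.
#'
#' @param bp Whole-body protein mass, kg (start of day).
#' @param pd Protein deposition, g/d.
#' @return Retention, g/d.
#' @export
max_p_retention <- function(bp, pd) {
  stopifnot(all(pd >= 0))
  body_phosphorus_mass(bp + pd / 1000) - body_phosphorus_mass(bp)
}

#' STTD phosphorus requirement
#'
#' `0.85 * (max_p_ret / 0.77 + 0.19 * FDMI + 0.007 * BW)` g/d. The 0.77 is
#' read as a retention-efficiency divisor: division reproduces the
#' published day-130 magnitudes (~5-6 g/d), multiplication would give
#' ~3.5 g/d. Set `multiply = TRUE` for the literal-product reading.
#'
#' @param max_p_ret Maximum phosphorus retention, g/d.
#' @param fdmi_kg Feed dry-matter intake, kg/d.
#' @param bw Body weight, kg.
#' @param multiply If `TRUE`, multiply retention by 0.77 instead of
#'   dividing.
#' @return STTD P, g/d.
#' @export
sttd_phosphorus <- function(max_p_ret, fdmi_kg, bw, multiply = FALSE) {
  stopifnot(all(max_p_ret >= 0), all(fdmi_kg >= 0), all(bw >= 0))
  ret <- if (multiply) max_p_ret * 0.77 else max_p_ret / 0.77
  0.85 * (ret + 0.19 * fdmi_kg + 0.007 * bw)
}

#' Total calcium requirement
#'
#' Fixed ratio to digestible phosphorus: `Ca = 2.15 * STTD_P` g/d.
#'
#' @param sttd_p STTD phosphorus requirement, g/d.
#' @return Calcium, g/d.
#' @export
total_calcium <- function(sttd_p) {
  stopifnot(all(sttd_p >= 0))
  2.15 * sttd_p
}

#' Mineral and vitamin requirements at a body weight
#'
#' Evaluates every fitted log-linear requirement curve
#' `intercept + slope * ln(BW)` at one body weight.
#'
#' @param bw Body weight, kg (scalar).
#' @param coeffs Coefficient table from [nutrient_coefficients()].
#' @return A data.frame with columns `nutrient`, `class`, `units`,
#'   `value` (per-day requirement in the nutrient's printed units).
#' @export
micronutrient_requirements <- function(bw, coeffs = nutrient_coefficients()) {
  stopifnot(length(bw) == 1, bw > 0)
  data.frame(nutrient = coeffs$nutrient, class = coeffs$class,
             units = coeffs$units,
             value = coeffs$intercept + coeffs$slope * log(bw),
             stringsAsFactors = FALSE)
}
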