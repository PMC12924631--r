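# Energy and feed intake: metabolizable energy, ad-libitum feed intake,
# thermal environment, space, maintenance. Vectorized over pigs.

#' Metabolizable energy intake
#'
#' Saturating curve `a * (1 - exp(-exp(b) * BW^c))` kcal/d; strictly
#' increasing in body weight and bounded above by the sex-specific
#' asymptote `a`.
#'
#' @param bw Body weight, kg.
#' @param params A [sex_params()] object.
#' @return MEI, kcal/d.
#' @examples
#' energy_intake(50, sex_params("gilt"))  # ~5918 kcal/d
#' @export
energy_intake <- function(bw, params) {
  k <- params$mei
  k[["a"]] * (1 - exp(-exp(k[["b"]]) * bw^k[["c"]]))
}

#' Ad-libitum feed intake
#'
#' Gilts and barrows follow the published saturating curve
#' `x * (1 - exp(-exp(y) * BW^z))` kg/d. No intake coefficients are
#' published for boars; unless overridden (`boar_fi_coeffs` /
#' `fi_coeffs`), boar intake is derived from the energy account,
#' `FI = MEI / (me_content * (1 - feed_wastage))`, which keeps the feed and
#' energy books consistent.
#'
#' @param bw Body weight, kg.
#' @param params A [sex_params()] object.
#' @param me_content Feed ME content, kcal/kg (used by the fallback).
#' @param feed_wastage Wasted feed fraction (used by the fallback).
#' @return FI, kg/d.
#' @export
feed_intake <- function(bw, params, me_content = 3300, feed_wastage = 0.05) {
  k <- params$fi
  if (is.null(k))
    return(energy_intake(bw, params) / (me_content * (1 - feed_wastage)))
  k[["x"]] * (1 - exp(-exp(k[["y"]]) * bw^k[["z"]]))
}

#' Lower critical temperature
#'
#' `17.9 - 0.0375 * BW` C: the ambient temperature below which the pig
#' spends extra energy on thermogenesis. Heavier pigs tolerate colder air.
#'
#' @param bw Body weight, kg.
#' @return LCT, degrees C.
#' @export
lower_critical_temp <- function(bw) 17.9 - 0.0375 * bw

#' Minimum space allowance for maximum energy intake
#'
#' `0.0336 * BW^0.667` m2 per pig; pens tighter than this threshold
#' depress intake in practice (the model reports the threshold only, no
#' penalty function being published).
#'
#' @param bw Body weight, kg.
#' @return Space, m2 per pig.
#' @export
min_space <- function(bw) 0.0336 * bw^0.667

#' Maximum daily feed intake
#'
#' `(111 * BW^0.803) * (1 + (LCT - T) * 0.025)` g/d, floored at zero.
#' Temperatures below the lower critical temperature raise the ceiling by
#' 2.5% per degree of cold; temperatures above it reduce the ceiling
#' (heat-stress reading, no clamping of the bracket).
#'
#' @param bw Body weight, kg.
#' @param temperature Ambient temperature, C.
#' @return Maximum FI, g/d.
#' @export
max_feed_intake <- function(bw, temperature) {
  pmax(0, (111 * bw^0.803) *
         (1 + (lower_critical_temp(bw) - temperature) * 0.025))
}

#' Maintenance metabolizable energy requirement
#'
#' Standard maintenance is `197 * BW^0.6` kcal/d. Below the lower critical
#' temperature the pig additionally spends
#' `0.07425 * (LCT - T) * StdmME` kcal/d on thermogenesis; at or above LCT
#' this term is clamped to zero (maintenance cannot fall below standard;
#' LCT is the lower bound of the thermoneutral zone). A constant
#' activity/genotype adjustment `adj` is added on top.
#'
#' @param bw Body weight, kg.
#' @param temperature Ambient temperature, C.
#' @param adj Activity/genotype ME adjustment, kcal/d.
#' @return A list with `stdm_me`, `me_therm`, `m_me`
#'   (`= stdm_me + me_therm + adj`), all kcal/d.
#' @export
maintenance_energy <- function(bw, temperature, adj = 0) {
  stdm <- 197 * bw^0.6
  lct <- lower_critical_temp(bw)
  therm <- pmax(0, 0.07425 * (lct - temperature) * stdm)
  list(stdm_me = stdm, me_therm = therm, m_me = stdm + therm + adj)
}
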