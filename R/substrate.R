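#' Default stoichiometric coefficient sets
#'
#' Three labeled sets convert gas flows (L·min⁻¹) into substrate oxidation
#' (g·min⁻¹) and, for the exercise sets, energy expenditure (kcal·min⁻¹),
#' assuming negligible protein oxidation:
#'
#' * `resting` (ventilated-hood, fasting/clamp):
#'   CHOox = 4.55·VCO2 − 3.21·VO2; FATox = 1.67·VO2 − 1.67·VCO2.
#' * `low_intensity` (cycling at light-to-moderate loads):
#'   EE = 0.575·VCO2 + 4.435·VO2; CHOox = 4.344·VCO2 − 3.061·VO2.
#' * `maximal` (near-exhaustion loads, acid-base shift and extra muscle
#'   glycogen): EE = 0.550·VCO2 + 4.471·VO2; CHOox = 4.210·VCO2 − 2.962·VO2.
#'
#' Both exercise sets share FATox = 1.695·VO2 − 1.701·VCO2. The resting set
#' carries no EE coefficients; resting EE uses the Weir-form combination in
#' [resting_ee_kcal_day()].
#'
#' @return A named list of coefficient sets.
#' @export
default_stoichiometry <- function() {
  list(
    resting = list(label = "resting",
                   cho_vco2 = 4.55, cho_vo2 = -3.21,
                   fat_vo2 = 1.67, fat_vco2 = -1.67,
                   ee_vco2 = NA_real_, ee_vo2 = NA_real_),
    low_intensity = list(label = "low_intensity",
                         cho_vco2 = 4.344, cho_vo2 = -3.061,
                         fat_vo2 = 1.695, fat_vco2 = -1.701,
                         ee_vco2 = 0.575, ee_vo2 = 4.435),
    maximal = list(label = "maximal",
                   cho_vco2 = 4.210, cho_vo2 = -2.962,
                   fat_vo2 = 1.695, fat_vco2 = -1.701,
                   ee_vco2 = 0.550, ee_vo2 = 4.471)
  )
}

# Weir-form resting energy expenditure, kcal/min from L/min flows.
# Coefficients configurable through options-free arguments at call sites.
weir_kcal_min <- function(vo2_l, vco2_l, c_vo2 = 3.941, c_vco2 = 1.106) {
  c_vo2 * vo2_l + c_vco2 * vco2_l
}

#' Resting energy expenditure (kcal·day⁻¹)
#'
#' Weir-form linear combination of VO2 and VCO2 (3.941·VO2 + 1.106·VCO2
#' kcal·min⁻¹ with flows in L·min⁻¹), scaled to a day.
#'
#' @param mean_vo2,mean_vco2 gas means in mL·min⁻¹.
#' @param c_vo2,c_vco2 kcal per litre coefficients.
#' @return kcal·day⁻¹.
#' @export
resting_ee_kcal_day <- function(mean_vo2, mean_vco2, c_vo2 = 3.941, c_vco2 = 1.106) {
  1440 * weir_kcal_min(mean_vo2 / 1000, mean_vco2 / 1000, c_vo2, c_vco2)
}

#' Substrate oxidation rates from gas means
#'
#' Applies a labeled stoichiometric set to steady-state (or exercise-stage)
#' gas means. Flows are stored in mL·min⁻¹ and converted to L·min⁻¹ exactly
#' once, here. Negative oxidation rates are preserved (a maximal-exercise
#' RER above 1.695/1.701 yields negative FATox by construction); they are
#' clamped to zero only inside the %EE share computation.
#'
#' @param mean_vo2,mean_vco2 gas means, mL·min⁻¹.
#' @param label coefficient set: `"resting"`, `"low_intensity"` or `"maximal"`.
#' @param mass body mass in kg (for mg·kg⁻¹·min⁻¹ scaling); `NA` to skip.
#' @param stoich coefficient sets as from [default_stoichiometry()].
#' @param e_cho,e_fat energy equivalents, kcal per g oxidized.
#' @return An object of class `substrate_rates` with g·min⁻¹ rates,
#'   mg·kg⁻¹·min⁻¹ rates, EE in kcal·min⁻¹ and the %EE split.
#' @export
substrate_rates <- function(mean_vo2, mean_vco2, label = "resting", mass = NA,
                            stoich = default_stoichiometry(),
                            e_cho = 4.07, e_fat = 9.46) {
  if (!label %in% names(stoich))
    mf_config_error(sprintf("unknown stoichiometry label '%s'", label))
  st <- stoich[[label]]
  vo2 <- mean_vo2 / 1000
  vco2 <- mean_vco2 / 1000
  cho <- st$cho_vco2 * vco2 + st$cho_vo2 * vo2
  fat <- st$fat_vo2 * vo2 + st$fat_vco2 * vco2
  ee <- if (label == "resting") weir_kcal_min(vo2, vco2) else st$ee_vco2 * vco2 + st$ee_vo2 * vo2
  shares <- tryCatch(percent_ee(cho, fat, e_cho, e_fat),
                     metflexr_domain_error = function(e) c(NA_real_, NA_real_))
  structure(
    list(
      label = label,
      choox_g_min = cho, fatox_g_min = fat,
      ee_kcal_min = ee,
      choox_mg_kg_min = if (is_number(mass)) 1000 * cho / mass else NA_real_,
      fatox_mg_kg_min = if (is_number(mass)) 1000 * fat / mass else NA_real_,
      cho_pct_ee = shares[[1L]], fat_pct_ee = shares[[2L]],
      rer = mean_vco2 / mean_vo2
    ),
    class = "substrate_rates"
  )
}

#' @export
print.substrate_rates <- function(x, ...) {
  cat(sprintf(
    "<substrate_rates:%s> CHOox %.3f g/min  FATox %.3f g/min  EE %.2f kcal/min  CHO %.1f%%EE\n",
    x$label, x$choox_g_min, x$fatox_g_min, x$ee_kcal_min, x$cho_pct_ee
  ))
  invisible(x)
}

#' Energy share of carbohydrate vs fat oxidation
#'
#' Converts oxidation rates to energy with the configured equivalents and
#' returns the percentage split. Negative rates are clamped to zero for the
#' share only.
#'
#' @param choox,fatox oxidation rates, g·min⁻¹.
#' @param e_cho,e_fat energy equivalents, kcal·g⁻¹.
#' @return Length-2 numeric `c(cho_pct, fat_pct)` summing to 100.
#' @export
percent_ee <- function(choox, fatox, e_cho = 4.07, e_fat = 9.46) {
  cho_kcal <- max(0, choox) * e_cho
  fat_kcal <- max(0, fatox) * e_fat
  tot <- cho_kcal + fat_kcal
  if (tot <= 0)
    mf_domain_error("both oxidation rates non-positive: energy share undefined")
  c(cho_pct = 100 * cho_kcal / tot, fat_pct = 100 * fat_kcal / tot)
}

#' Metabolic flexibility from fasting to insulin stimulation
#'
#' The clamp ΔRER statistic: insulin-stimulated steady-state RER minus
#' fasting steady-state RER. Positive values indicate the expected
#' insulin-driven shift toward carbohydrate oxidation; values near or below
#' zero indicate metabolic inflexibility.
#'
#' @param fasting,clamp [detect_steady_state()] windows (or any object with
#'   an `rer` field).
#' @return List with `rer_fasting`, `rer_clamp`, `delta_rer_clamp`.
#' @export
metflex_clamp <- function(fasting, clamp) {
  if (is.null(fasting$rer) || is.null(clamp$rer))
    mf_domain_error("both steady-state windows are required for clamp ΔRER")
  list(
    rer_fasting = fasting$rer,
    rer_clamp = clamp$rer,
    delta_rer_clamp = clamp$rer - fasting$rer
  )
}
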