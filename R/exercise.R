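#' Graded-ramp protocol description
#'
#' The default mirrors the maximal cycle-ergometer test: start at 25 W,
#' +25 W every 3 min until volitional exhaustion.
#'
#' @param start_w starting load, watts.
#' @param increment_w per-stage increment, watts.
#' @param stage_s stage duration, seconds.
#' @return Object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(start_w = 25, increment_w = 25, stage_s = 180) {
  if (start_w <= 0 || increment_w <= 0 || stage_s <= 0)
    mf_config_error("ramp protocol values must be positive")
  structure(list(start_w = start_w, increment_w = increment_w, stage_s = stage_s),
            class = "ramp_protocol")
}

#' Average an exercise gas series over 20-s periods
#'
#' Non-overlapping bins aligned to test start; an incomplete trailing bin is
#' dropped. Bin RER is the ratio of bin-mean flows.
#'
#' @param series an exercise-condition [gas_series()].
#' @param bin_s bin length, seconds.
#' @return data.frame with `t_mid`, `t_start`, `t_end`, `vo2`, `vco2`, `rer`.
#' @export
bin_20s <- function(series, bin_s = 20) {
  stopifnot(inherits(series, "gas_series"))
  s <- series$samples
  t0 <- s$t[1L]
  n_bins <- floor((s$t[nrow(s)] - t0) / bin_s)
  if (n_bins < 1L) mf_insufficient_data("exercise series shorter than one bin")
  keep <- s$t < t0 + n_bins * bin_s
  idx <- floor((s$t[keep] - t0) / bin_s) + 1L
  f <- factor(idx, levels = seq_len(n_bins))
  vo2 <- as.numeric(tapply(s$vo2[keep], f, mean))
  vco2 <- as.numeric(tapply(s$vco2[keep], f, mean))
  ok <- !is.na(vo2)
  data.frame(
    t_start = t0 + (seq_len(n_bins) - 1L) * bin_s,
    t_mid = t0 + (seq_len(n_bins) - 0.5) * bin_s,
    t_end = t0 + seq_len(n_bins) * bin_s,
    vo2 = vo2, vco2 = vco2, rer = vco2 / vo2
  )[ok, , drop = FALSE]
}

#' Read an exercise stage log
#'
#' @param path CSV with header `stage_idx,power_w,start_s,end_s`.
#' @return data.frame of stages ordered by `start_s`.
#' @export
read_stages <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  need <- c("stage_idx", "power_w", "start_s", "end_s")
  if (!all(need %in% names(d)))
    mf_parse_error(sprintf("stage CSV %s must have columns %s", path,
                           paste(need, collapse = ",")))
  d[order(d$start_s), , drop = FALSE]
}

#' Summarize one ramp stage from 20-s bins
#'
#' Gas means use the final `tail_s` seconds of the stage (by default the
#' last three 20-s bins), where values are closest to stage steady state.
#'
#' @param bins output of [bin_20s()].
#' @param stage one row of a stage log (`power_w`, `start_s`, `end_s`).
#' @param tail_s seconds at the end of the stage to average over.
#' @return List with `power_w`, `mean_vo2`, `mean_vco2`, `rer`, `n_bins`.
#' @export
stage_summary <- function(bins, stage, tail_s = 60) {
  sel <- bins$t_start >= max(stage$start_s, stage$end_s - tail_s) &
    bins$t_end <= stage$end_s + 1e-9
  if (!any(sel))
    mf_insufficient_data(sprintf("no complete 20-s bin in stage at %g W", stage$power_w))
  vo2 <- mean(bins$vo2[sel]); vco2 <- mean(bins$vco2[sel])
  list(power_w = stage$power_w, mean_vo2 = vo2, mean_vco2 = vco2,
       rer = vco2 / vo2, n_bins = sum(sel))
}

#' Maximal oxygen uptake from binned exercise data
#'
#' VO2max is the highest single 20-s bin VO2, expressed per kg body mass and
#' per kg fat-free mass. Plateau and secondary criteria are out of scope; an
#' `early_terminated` flag can be carried by the caller for tests stopped
#' before volitional exhaustion.
#'
#' @param bins output of [bin_20s()].
#' @param mass body mass, kg.
#' @param ffm fat-free mass, kg.
#' @param stages optional stage log; if given, `max_po_w` is the power of
#'   the last stage with any bin data.
#' @return List with `vo2max_ml_min`, `vo2max_ml_kg_min`,
#'   `vo2max_ml_kgffm_min`, `max_po_w`.
#' @export
vo2max <- function(bins, mass, ffm = NA, stages = NULL) {
  if (nrow(bins) < 1L) mf_insufficient_data("no bins")
  vmax <- max(bins$vo2)
  max_po <- NA_real_
  if (!is.null(stages)) {
    entered <- stages$start_s <= max(bins$t_end)
    if (any(entered)) max_po <- max(stages$power_w[entered])
  }
  list(
    vo2max_ml_min = vmax,
    vo2max_ml_kg_min = vmax / mass,
    vo2max_ml_kgffm_min = if (is_number(ffm)) vmax / ffm else NA_real_,
    max_po_w = max_po
  )
}

#' RER extrema and exercise metabolic flexibility
#'
#' Reports the minimum and maximum 20-s RER over the test and the exercise
#' ΔRER. By the `"stage"` convention (default) ΔRER runs from the
#' low-intensity (25 W) stage mean RER to the maximal stage mean RER; the
#' `"extrema"` convention uses max − min over all bins.
#'
#' @param bins output of [bin_20s()].
#' @param low_stage,max_stage [stage_summary()] results (stage convention).
#' @param convention `"stage"` or `"extrema"`.
#' @return List with `rer_min`, `rer_max`, `rer_low_ex`, `rer_max_ex`,
#'   `delta_rer_ex`.
#' @export
rer_extrema <- function(bins, low_stage = NULL, max_stage = NULL,
                        convention = c("stage", "extrema")) {
  convention <- match.arg(convention)
  if (nrow(bins) < 1L) mf_insufficient_data("no bins")
  rmin <- min(bins$rer); rmax <- max(bins$rer)
  if (convention == "stage") {
    if (is.null(low_stage) || is.null(max_stage))
      mf_config_error("stage convention needs low and maximal stage summaries")
    low <- low_stage$rer; high <- max_stage$rer
  } else {
    low <- rmin; high <- rmax
  }
  list(rer_min = rmin, rer_max = rmax,
       rer_low_ex = low, rer_max_ex = high,
       delta_rer_ex = high - low)
}

#' Substrate oxidation for an exercise stage
#'
#' Delegates to [substrate_rates()] with the `low_intensity` or `maximal`
#' coefficient set.
#'
#' @param stage a [stage_summary()].
#' @param which `"low_intensity"` or `"maximal"`.
#' @param mass body mass, kg.
#' @param stoich coefficient sets.
#' @return A [substrate_rates()] object.
#' @export
stage_substrate <- function(stage, which = c("low_intensity", "maximal"), mass,
                            stoich = default_stoichiometry()) {
  which <- match.arg(which)
  substrate_rates(stage$mean_vo2, stage$mean_vco2, label = which, mass = mass,
                  stoich = stoich)
}

#' Delta exercise efficiency
#'
#' 100 × ΔPO / ΔEE between two submaximal loads, with power converted from
#' watts to kcal·min⁻¹ by the factor 0.014. The bounds represent moderate
#' intensity: 25 to 75 W for women and 25 to 100 W for men. Stage EE uses
#' the low-intensity exercise equation.
#'
#' @param stages list of [stage_summary()] results covering the bounds.
#' @param sex `"male"` or `"female"`.
#' @param w_per_kcal_min watts-to-kcal·min⁻¹ conversion factor.
#' @param bounds_w optional explicit `c(lo, hi)` watt bounds, overriding sex.
#' @param stoich coefficient sets.
#' @return Efficiency in percent.
#' @export
delta_efficiency <- function(stages, sex = c("female", "male"),
                             w_per_kcal_min = 0.014, bounds_w = NULL,
                             stoich = default_stoichiometry()) {
  sex <- match.arg(sex)
  if (is.null(bounds_w))
    bounds_w <- if (sex == "male") c(25, 100) else c(25, 75)
  pw <- vapply(stages, function(s) s$power_w, numeric(1))
  i_lo <- which(abs(pw - bounds_w[1L]) < 1e-9)
  i_hi <- which(abs(pw - bounds_w[2L]) < 1e-9)
  if (!length(i_lo) || !length(i_hi))
    mf_stop("metflexr_not_computable",
            sprintf("missing bound stage (%g or %g W)", bounds_w[1L], bounds_w[2L]))
  ee <- function(s) {
    st <- stoich$low_intensity
    st$ee_vco2 * s$mean_vco2 / 1000 + st$ee_vo2 * s$mean_vo2 / 1000
  }
  d_ee <- ee(stages[[i_hi[1L]]]) - ee(stages[[i_lo[1L]]])
  if (d_ee <= 0)
    mf_stop("metflexr_degenerate_input", "EE does not increase between bound stages")
  100 * (diff(bounds_w) * w_per_kcal_min) / d_ee
}
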