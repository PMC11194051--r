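#' Construct a hyperinsulinemic-euglycemic clamp timeline
#'
#' Bundles the variable glucose-infusion pump log and the bedside plasma
#' glucose samples for one clamp, together with the infusate strength and
#' the euglycemic target. The insulin infusion runs at a fixed rate per m²
#' body surface area (nominally 40 mU·min⁻¹·m⁻²) and is recorded for
#' provenance only; all uptake arithmetic uses the glucose side.
#'
#' @param pump_log data.frame with columns `t_s` (seconds, increasing) and
#'   `rate_ml_h` (pump rate, mL·h⁻¹, held until the next entry).
#' @param glucose_samples data.frame with columns `t_s` and `glucose_mmol_l`.
#' @param glucose_conc_pct infusate glucose concentration, percent (20 = 20 g/100 mL).
#' @param target_glucose euglycemic target, mmol·L⁻¹.
#' @param insulin_rate insulin infusion, mU·min⁻¹·m⁻².
#' @param bsa body surface area, m².
#' @return Object of class `clamp_timeline`.
#' @export
clamp_timeline <- function(pump_log, glucose_samples, glucose_conc_pct = 20,
                           target_glucose = 5.0, insulin_rate = 40, bsa = NA) {
  stopifnot(all(c("t_s", "rate_ml_h") %in% names(pump_log)),
            all(c("t_s", "glucose_mmol_l") %in% names(glucose_samples)))
  if (nrow(pump_log) < 1L) mf_insufficient_data("empty pump log")
  if (any(pump_log$rate_ml_h < 0)) mf_parse_error("negative pump rate")
  if (is.unsorted(pump_log$t_s, strictly = TRUE))
    mf_parse_error("pump log times must be strictly increasing")
  if (nrow(glucose_samples) > 1L && is.unsorted(glucose_samples$t_s, strictly = TRUE))
    mf_parse_error("glucose sample times must be strictly increasing")
  if (glucose_conc_pct <= 0 || glucose_conc_pct > 100)
    mf_config_error("glucose_conc_pct must be in (0, 100]")
  structure(
    list(pump_log = as.data.frame(pump_log),
         glucose_samples = as.data.frame(glucose_samples),
         glucose_conc_pct = glucose_conc_pct,
         target_glucose = target_glucose,
         insulin_rate = insulin_rate, bsa = bsa),
    class = "clamp_timeline"
  )
}

#' @export
print.clamp_timeline <- function(x, ...) {
  cat(sprintf(
    "<clamp_timeline> %d pump entries over %.0f min, %d glucose samples, %g%% infusate, target %.1f mmol/L\n",
    nrow(x$pump_log), diff(range(x$pump_log$t_s)) / 60,
    nrow(x$glucose_samples), x$glucose_conc_pct, x$target_glucose
  ))
  invisible(x)
}

# Time-weighted mean of a right-open step function over [t0, t1].
step_mean <- function(t, v, t0, t1) {
  knots <- sort(unique(c(t0, t1, t[t > t0 & t < t1])))
  vals <- vapply(head(knots, -1L), function(tt) {
    i <- findInterval(tt, t)
    if (i < 1L) v[1L] else v[i]
  }, numeric(1))
  sum(vals * diff(knots)) / (t1 - t0)
}

#' Glucose infusion rate over an interval
#'
#' Time-weighted mean pump rate (mL·h⁻¹, step function held between log
#' entries) converted to mg of glucose per kg per minute: a `pct`% infusate
#' carries `10 × pct` mg·mL⁻¹.
#'
#' @param timeline a [clamp_timeline()].
#' @param mass body mass, kg.
#' @param interval numeric length-2, seconds `(t0, t1)` within the log span.
#' @return GIR in mg·kg⁻¹·min⁻¹.
#' @export
glucose_infusion_rate <- function(timeline, mass, interval) {
  stopifnot(inherits(timeline, "clamp_timeline"), mass > 0)
  p <- timeline$pump_log
  t0 <- interval[[1L]]; t1 <- interval[[2L]]
  if (t1 <= t0) mf_domain_error("interval must have positive length")
  if (t0 < p$t_s[1L] - 1e-9)
    mf_stop("metflexr_range_error", "interval starts before the pump log")
  mean_ml_h <- step_mean(p$t_s, p$rate_ml_h, t0, t1)
  mean_ml_h * (10 * timeline$glucose_conc_pct) / 60 / mass
}

#' Whole-body glucose uptake (M value) from a clamp
#'
#' Partitions the clamp into consecutive `interval_min`-minute intervals
#' from the start of the pump log. An interval is steady when every plasma
#' glucose sample inside it lies within `tolerance_pct` of the target. M for
#' a steady interval is the glucose infusion rate over it; the summary M is
#' the last steady interval (default) or the mean of the last two.
#'
#' @param timeline a [clamp_timeline()].
#' @param mass body mass, kg.
#' @param interval_min interval length, minutes.
#' @param tolerance_pct allowed deviation of glucose from target, percent.
#' @param summary_mode `"last"` or `"mean_last2"`.
#' @return Object of class `clamp_m` with `m_intervals` (data.frame:
#'   `t0_s`, `t1_s`, `gir_mg_kg_min`, `steady`) and `m_value`.
#' @export
m_value <- function(timeline, mass, interval_min = 20, tolerance_pct = 5,
                    summary_mode = c("last", "mean_last2")) {
  summary_mode <- match.arg(summary_mode)
  stopifnot(inherits(timeline, "clamp_timeline"))
  p <- timeline$pump_log
  g <- timeline$glucose_samples
  span0 <- p$t_s[1L]
  span1 <- max(p$t_s[nrow(p)], if (nrow(g)) g$t_s[nrow(g)] else -Inf)
  n_int <- floor((span1 - span0) / (interval_min * 60))
  if (n_int < 1L) mf_insufficient_data("no complete clamp interval")
  tol <- tolerance_pct / 100 * timeline$target_glucose
  rows <- lapply(seq_len(n_int), function(k) {
    t0 <- span0 + (k - 1L) * interval_min * 60
    t1 <- span0 + k * interval_min * 60
    in_int <- g$t_s >= t0 & g$t_s < t1
    steady <- any(in_int) &&
      all(abs(g$glucose_mmol_l[in_int] - timeline$target_glucose) <= tol)
    data.frame(t0_s = t0, t1_s = t1,
               gir_mg_kg_min = glucose_infusion_rate(timeline, mass, c(t0, t1)),
               steady = steady)
  })
  m_intervals <- do.call(rbind, rows)
  st <- which(m_intervals$steady)
  if (!length(st)) mf_stop("metflexr_no_steady_clamp", "no steady 20-min clamp interval")
  m <- if (summary_mode == "last") {
    m_intervals$gir_mg_kg_min[max(st)]
  } else {
    mean(m_intervals$gir_mg_kg_min[tail(st, 2L)])
  }
  structure(list(m_intervals = m_intervals, m_value = m,
                 summary_mode = summary_mode),
            class = "clamp_m")
}

#' @export
print.clamp_m <- function(x, ...) {
  cat(sprintf("<clamp_m> M = %.2f mg/kg/min (%s of %d steady / %d intervals)\n",
              x$m_value, x$summary_mode, sum(x$m_intervals$steady),
              nrow(x$m_intervals)))
  invisible(x)
}

#' Non-oxidative glucose disposal
#'
#' Glucose infusion rate minus carbohydrate oxidation rate, floored at zero
#' (negative values are interpreted as zero); a proxy for glycogen storage.
#'
#' @param gir glucose infusion rate, mg·kg⁻¹·min⁻¹.
#' @param choox carbohydrate oxidation, mg·kg⁻¹·min⁻¹ (clamped to >= 0
#'   before subtraction, mirroring the reporting convention).
#' @return NOGD in mg·kg⁻¹·min⁻¹, always >= 0.
#' @export
nonoxidative_disposal <- function(gir, choox) {
  stopifnot(is.finite(gir), is.finite(choox))
  max(0, gir - max(0, choox))
}

#' Partition carbohydrate oxidation into exogenous vs other sources
#'
#' Oxidation up to the infused glucose is attributed to exogenous glucose;
#' any excess to other carbohydrate sources (endogenous glucose, glycogen,
#' lactate).
#'
#' @param choox carbohydrate oxidation, mg·kg⁻¹·min⁻¹; must be > 0.
#' @param gir glucose infusion rate, mg·kg⁻¹·min⁻¹.
#' @return `c(exogenous, other)` shares summing to 1.
#' @export
partition_choox <- function(choox, gir) {
  if (!is.finite(choox) || choox <= 0)
    mf_domain_error("CHOox partition undefined for non-positive CHOox")
  exo <- min(choox, max(0, gir)) / choox
  c(exogenous = exo, other = 1 - exo)
}

#' Insulin-stimulated change in a blood metabolite
#'
#' @param fasting_value,clamp_value concentrations, mmol·L⁻¹.
#' @return clamp minus fasting.
#' @export
insulin_stim_delta <- function(fasting_value, clamp_value) {
  if (anyNA(c(fasting_value, clamp_value)))
    mf_domain_error("both fasting and clamp values are required")
  clamp_value - fasting_value
}

#' HOMA-IR insulin-resistance index
#'
#' fasting glucose (mmol·L⁻¹) × fasting insulin (mU·L⁻¹) / 22.5. Insulin is
#' supplied in pmol·L⁻¹ and converted with a fixed factor.
#'
#' @param glucose fasting plasma glucose, mmol·L⁻¹.
#' @param insulin_pmol fasting insulin, pmol·L⁻¹.
#' @param pmol_per_mU conversion factor, pmol per mU.
#' @return The dimensionless index.
#' @export
homa_ir <- function(glucose, insulin_pmol, pmol_per_mU = 6.945) {
  if (any(glucose <= 0) || any(insulin_pmol <= 0))
    mf_domain_error("HOMA-IR needs positive glucose and insulin")
  glucose * (insulin_pmol / pmol_per_mU) / 22.5
}

#' Du Bois body surface area
#'
#' Used only to simulate the per-BSA insulin infusion in synthetic clamps.
#'
#' @param height_cm height in cm.
#' @param weight_kg weight in kg.
#' @return BSA in m².
#' @export
bsa_du_bois <- function(height_cm, weight_kg) {
  0.007184 * height_cm^0.725 * weight_kg^0.425
}
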