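#' Construct a breath-by-breath gas-exchange series
#'
#' A `gas_series` holds one condition's breath-by-breath stream of oxygen
#' uptake (VO2) and carbon-dioxide output (VCO2) for one subject, as produced
#' by an automated metabolic cart. Units are fixed: seconds and mL·min⁻¹.
#'
#' @param t numeric vector, seconds from measurement start; strictly increasing.
#' @param vo2 numeric vector, VO2 in mL·min⁻¹; strictly positive.
#' @param vco2 numeric vector, VCO2 in mL·min⁻¹; non-negative.
#' @param condition one of `"fasting"`, `"clamp"`, `"exercise"`.
#' @param subject_id opaque subject identifier.
#' @param start_offset_s seconds of clamp elapsed at series start (clamp
#'   condition only; informational).
#' @return An object of class `gas_series`.
#' @export
gas_series <- function(t, vo2, vco2, condition = c("fasting", "clamp", "exercise"),
                       subject_id = NA_character_, start_offset_s = 0) {
  condition <- match.arg(condition)
  n <- length(t)
  if (n < 1L) mf_insufficient_data("a gas series needs at least one breath")
  if (length(vo2) != n || length(vco2) != n)
    mf_parse_error("t, vo2 and vco2 must have equal length")
  if (anyNA(t) || anyNA(vo2) || anyNA(vco2))
    mf_parse_error("gas series contains missing values")
  if (n > 1L && any(diff(t) <= 0))
    mf_parse_error("breath times must be strictly increasing")
  if (any(vo2 <= 0)) {
    bad <- which(vo2 <= 0)[1L]
    mf_parse_error(sprintf("non-positive VO2 at breath %d", bad))
  }
  if (any(vco2 < 0)) mf_parse_error("negative VCO2 value")
  structure(
    list(
      subject_id = subject_id,
      condition = condition,
      samples = data.frame(t = as.numeric(t), vo2 = as.numeric(vo2),
                           vco2 = as.numeric(vco2)),
      start_offset_s = start_offset_s
    ),
    class = "gas_series"
  )
}

#' @export
print.gas_series <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<gas_series> subject=%s condition=%s breaths=%d span=%.0f s mean RER=%.3f\n",
    x$subject_id, x$condition, nrow(s), diff(range(s$t)) + 0,
    mean(s$vco2 / s$vo2)
  ))
  invisible(x)
}

#' Read a breath-by-breath CSV file
#'
#' Expects the header `t_s,vo2_ml_min,vco2_ml_min` (UTF-8, '.' decimal
#' separator). Rows with non-positive VO2 are rejected with an error naming
#' the offending data row.
#'
#' @param path path to the breath CSV.
#' @inheritParams gas_series
#' @return A validated [gas_series()].
#' @export
read_gas_series <- function(path, condition = c("fasting", "clamp", "exercise"),
                            subject_id = NA_character_, start_offset_s = 0) {
  condition <- match.arg(condition)
  if (!file.exists(path)) mf_parse_error(sprintf("file not found: %s", path))
  d <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  need <- c("t_s", "vo2_ml_min", "vco2_ml_min")
  if (!all(need %in% names(d)))
    mf_parse_error(sprintf("breath CSV %s must have columns %s",
                           path, paste(need, collapse = ",")))
  if (nrow(d) == 0L) mf_insufficient_data(sprintf("empty breath series: %s", path))
  bad <- which(!is.finite(d$vo2_ml_min) | d$vo2_ml_min <= 0)
  if (length(bad))
    mf_parse_error(sprintf("non-positive VO2 in %s at data row %d", path, bad[1L]))
  gas_series(d$t_s, d$vo2_ml_min, d$vco2_ml_min, condition = condition,
             subject_id = subject_id, start_offset_s = start_offset_s)
}

#' Write a gas series back to the breath CSV schema
#'
#' Values are formatted with 17 significant digits so that a write/read
#' cycle reproduces every double bit-exactly.
#'
#' @param series a [gas_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gas_series <- function(series, path) {
  stopifnot(inherits(series, "gas_series"))
  s <- series$samples
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("t_s,vo2_ml_min,vco2_ml_min",
               sprintf("%.17g,%.17g,%.17g", s$t, s$vo2, s$vco2)),
             con, sep = "\n")
  invisible(path)
}

#' Respiratory exchange ratio
#'
#' RER = VCO2 / VO2, the mouth-level proxy for the tissue respiratory
#' quotient (about 0.7 for pure fat oxidation, about 1.0 for pure
#' carbohydrate oxidation).
#'
#' @param vo2 VO2 (any flow unit, must match `vco2`); strictly positive.
#' @param vco2 VCO2, non-negative.
#' @return The dimensionless ratio, vectorized.
#' @export
compute_rer <- function(vo2, vco2) {
  if (any(!is.finite(vo2)) || any(vo2 <= 0))
    mf_domain_error("RER requires VO2 > 0")
  vco2 / vo2
}

#' Percent coefficient of variation
#'
#' 100 × SD / mean with the n−1 (sample) SD, as used in the steady-state
#' criteria for gas flows and RER.
#'
#' @param values numeric vector of at least two sub-bin means, mean != 0.
#' @return CV in percent.
#' @export
rolling_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    mf_insufficient_data("CV needs at least two values")
  m <- mean(values)
  if (m == 0) mf_domain_error("CV undefined for zero mean")
  100 * sd(values) / m
}

#' Steady-state detection parameters
#'
#' Defaults implement the protocol: discard the first 4 min of hood data,
#' then accept a window of at least 4 min in which VO2 and VCO2 vary by
#' <10% CV and/or RER by <5% CV. CVs are computed on non-overlapping 30-s
#' sub-bin means (configurable), not raw breaths.
#'
#' @param discard_s seconds discarded at series start.
#' @param min_window_s minimum qualifying window length, seconds.
#' @param cv_gas_max CV threshold (%) for VO2 and VCO2.
#' @param cv_rer_max CV threshold (%) for RER.
#' @param criterion_mode `"either"` (default: gas or RER criterion suffices),
#'   `"both"`, `"gas_only"` or `"rer_only"`.
#' @param bin_s sub-bin length in seconds for CV computation.
#' @param rer_mode window RER as `"mean_of_ratios"` (mean of sub-bin RER,
#'   default) or `"ratio_of_means"` (mean VCO2 over mean VO2).
#' @return An object of class `steady_state_params`.
#' @export
steady_state_params <- function(discard_s = 240, min_window_s = 240,
                                cv_gas_max = 10, cv_rer_max = 5,
                                criterion_mode = c("either", "both", "gas_only", "rer_only"),
                                bin_s = 30,
                                rer_mode = c("mean_of_ratios", "ratio_of_means")) {
  criterion_mode <- match.arg(criterion_mode)
  rer_mode <- match.arg(rer_mode)
  if (cv_gas_max <= 0 || cv_rer_max <= 0 || bin_s <= 0 || min_window_s <= 0)
    mf_config_error("steady-state thresholds and lengths must be positive")
  if (min_window_s < 2 * bin_s)
    mf_config_error("min_window_s must be at least two sub-bins")
  structure(
    list(discard_s = discard_s, min_window_s = min_window_s,
         cv_gas_max = cv_gas_max, cv_rer_max = cv_rer_max,
         criterion_mode = criterion_mode, bin_s = bin_s, rer_mode = rer_mode),
    class = "steady_state_params"
  )
}

# Sub-bin means after discarding the lead-in. Bins are aligned to discard_s;
# a trailing bin not fully covered by the series span is dropped so all bins
# are equal-width. Bin RER is the mean of breath-level VCO2/VO2 ratios.
gas_subbins <- function(series, discard_s, bin_s) {
  s <- series$samples
  t0 <- s$t[1L] + discard_s
  t_end <- s$t[nrow(s)]
  n_bins <- floor((t_end - t0) / bin_s)
  if (n_bins < 1L) return(NULL)
  keep <- s$t >= t0 & s$t < t0 + n_bins * bin_s
  if (!any(keep)) return(NULL)
  idx <- floor((s$t[keep] - t0) / bin_s) + 1L
  f <- factor(idx, levels = seq_len(n_bins))
  counts <- tabulate(f, nbins = n_bins)
  if (any(counts == 0L)) {
    # a gap left an empty bin: truncate at the first gap
    n_bins <- which(counts == 0L)[1L] - 1L
    if (n_bins < 1L) return(NULL)
    keep <- s$t >= t0 & s$t < t0 + n_bins * bin_s
    idx <- floor((s$t[keep] - t0) / bin_s) + 1L
    f <- factor(idx, levels = seq_len(n_bins))
  }
  data.frame(
    bin = seq_len(n_bins),
    start_s = t0 + (seq_len(n_bins) - 1L) * bin_s,
    end_s = t0 + seq_len(n_bins) * bin_s,
    vo2 = as.numeric(tapply(s$vo2[keep], f, mean)),
    vco2 = as.numeric(tapply(s$vco2[keep], f, mean)),
    rer = as.numeric(tapply(s$vco2[keep] / s$vo2[keep], f, mean))
  )
}

window_diagnostics <- function(bins, i, j, params) {
  vo2 <- bins$vo2[i:j]; vco2 <- bins$vco2[i:j]; rer <- bins$rer[i:j]
  cv_vo2 <- rolling_cv(vo2); cv_vco2 <- rolling_cv(vco2); cv_rer <- rolling_cv(rer)
  gas_ok <- cv_vo2 < params$cv_gas_max && cv_vco2 < params$cv_gas_max
  rer_ok <- cv_rer < params$cv_rer_max
  ok <- switch(params$criterion_mode,
               either = gas_ok || rer_ok,
               both = gas_ok && rer_ok,
               gas_only = gas_ok,
               rer_only = rer_ok)
  list(cv_vo2 = cv_vo2, cv_vco2 = cv_vco2, cv_rer = cv_rer,
       gas_ok = gas_ok, rer_ok = rer_ok, ok = ok)
}

#' Detect the steady-state averaging window of a gas series
#'
#' Discards the lead-in, forms non-overlapping sub-bin means of VO2, VCO2 and
#' RER, and scans all candidate windows of at least `min_window_s`, advancing
#' one sub-bin at a time. The longest qualifying window is returned (earliest
#' wins on ties). A window qualifies when its sub-bin CVs satisfy the gas
#' and/or RER criterion per `criterion_mode`.
#'
#' @param series a [gas_series()] (fasting or clamp condition, typically).
#' @param params a [steady_state_params()].
#' @return An object of class `steady_state_window` with fields `start_s`,
#'   `end_s`, `cv_vo2`, `cv_vco2`, `cv_rer`, `mean_vo2`, `mean_vco2`, `rer`
#'   and `criterion_met` (`"gas"`, `"rer"` or `"both"`).
#' @export
detect_steady_state <- function(series, params = steady_state_params()) {
  stopifnot(inherits(series, "gas_series"))
  bins <- gas_subbins(series, params$discard_s, params$bin_s)
  k_min <- as.integer(ceiling(params$min_window_s / params$bin_s))
  if (is.null(bins) || nrow(bins) < k_min)
    mf_insufficient_data("series too short after discard for the minimum window")
  n <- nrow(bins)
  best <- NULL
  # longest first, earliest first within a length: stop at first hit per length
  for (len in seq(n, k_min)) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      d <- window_diagnostics(bins, i, j, params)
      if (d$ok) {
        best <- list(i = i, j = j, d = d)
        break
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best))
    mf_no_steady_state("no qualifying steady-state window")
  i <- best$i; j <- best$j; d <- best$d
  mean_vo2 <- mean(bins$vo2[i:j]); mean_vco2 <- mean(bins$vco2[i:j])
  rer <- if (params$rer_mode == "mean_of_ratios") mean(bins$rer[i:j]) else mean_vco2 / mean_vo2
  structure(
    list(
      start_s = bins$start_s[i], end_s = bins$end_s[j],
      cv_vo2 = d$cv_vo2, cv_vco2 = d$cv_vco2, cv_rer = d$cv_rer,
      mean_vo2 = mean_vo2, mean_vco2 = mean_vco2, rer = rer,
      criterion_met = if (d$gas_ok && d$rer_ok) "both" else if (d$gas_ok) "gas" else "rer",
      n_bins = j - i + 1L, bin_s = params$bin_s
    ),
    class = "steady_state_window"
  )
}

#' @export
print.steady_state_window <- function(x, ...) {
  cat(sprintf(
    "<steady_state_window> [%.0f, %.0f] s  VO2=%.0f VCO2=%.0f mL/min  RER=%.3f\n  CV%%: VO2 %.2f, VCO2 %.2f, RER %.2f  (criterion: %s)\n",
    x$start_s, x$end_s, x$mean_vo2, x$mean_vco2, x$rer,
    x$cv_vo2, x$cv_vco2, x$cv_rer, x$criterion_met
  ))
  invisible(x)
}
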