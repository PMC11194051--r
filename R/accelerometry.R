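#' Epoch classification cut-points
#'
#' Sedentary and standing are <= 1.5 METs (split by posture), light-intensity
#' activity is the open interval up to 3.0 METs, and moderate-to-vigorous
#' activity is >= 3.0 METs. An optional monotone piecewise-linear
#' MAD (milli-g) to MET mapping covers epochs that carry no device MET value.
#'
#' @param sedentary_met_max inclusive upper MET bound for sedentary/standing.
#' @param lpa_met_max exclusive upper MET bound for light activity.
#' @param mad_to_met optional data.frame `mad_mg`, `met` with increasing
#'   breakpoints for linear interpolation.
#' @return Object of class `cut_points`.
#' @export
cut_points <- function(sedentary_met_max = 1.5, lpa_met_max = 3.0,
                       mad_to_met = NULL) {
  if (!(sedentary_met_max > 0 && sedentary_met_max < lpa_met_max))
    mf_config_error("need 0 < sedentary_met_max < lpa_met_max")
  if (!is.null(mad_to_met)) {
    stopifnot(all(c("mad_mg", "met") %in% names(mad_to_met)))
    if (is.unsorted(mad_to_met$mad_mg, strictly = TRUE) ||
        is.unsorted(mad_to_met$met))
      mf_config_error("mad_to_met mapping must be monotone")
  }
  structure(list(sedentary_met_max = sedentary_met_max,
                 lpa_met_max = lpa_met_max, mad_to_met = mad_to_met),
            class = "cut_points")
}

#' Mean amplitude deviation of a raw tri-axial epoch
#'
#' Mean absolute deviation of the acceleration resultant from its epoch mean,
#' scaled to milli-g. Inputs are in g unless `scale_mg = FALSE`.
#'
#' @param x,y,z numeric vectors of within-epoch samples (g).
#' @param scale_mg multiply by 1000 to report milli-g.
#' @return MAD in milli-g (or g).
#' @export
mad_from_raw <- function(x, y, z, scale_mg = TRUE) {
  n <- length(x)
  if (n < 2L || length(y) != n || length(z) != n)
    mf_insufficient_data("MAD needs >= 2 tri-axial samples")
  r <- sqrt(x^2 + y^2 + z^2)
  m <- mean(abs(r - mean(r)))
  if (scale_mg) 1000 * m else m
}

#' Classify 6-s epochs into activity categories
#'
#' Vectorized over an epoch table. Non-worn epochs are `"nonwear"`; worn
#' epochs at <= 1.5 METs split by posture into `"sedentary"` (sitting/lying)
#' and `"standing"` (upright); then `"lpa"` below 3.0 METs and `"mvpa"` at
#' or above.
#'
#' @param epochs data.frame with columns `met` (or `mad_mg` when a mapping is
#'   configured), `posture` (`"sit"`/`"sitting_lying"` or `"upright"`) and
#'   `worn` (logical).
#' @param cp a [cut_points()].
#' @return Character vector of classes, one per epoch.
#' @export
classify_epoch <- function(epochs, cp = cut_points()) {
  met <- epochs$met
  if (is.null(met)) {
    if (is.null(cp$mad_to_met))
      mf_config_error("epochs carry no MET and no MAD-to-MET mapping is configured")
    met <- stats::approx(cp$mad_to_met$mad_mg, cp$mad_to_met$met,
                         xout = epochs$mad_mg, rule = 2)$y
  }
  worn <- as.logical(epochs$worn)
  out <- rep("nonwear", nrow(epochs))
  low <- worn & met <= cp$sedentary_met_max
  if (any(low & (is.na(epochs$posture) | !nzchar(epochs$posture))))
    mf_parse_error("posture missing for a worn low-MET epoch")
  sitting <- epochs$posture %in% c("sit", "sitting_lying")
  out[low & sitting] <- "sedentary"
  out[low & !sitting] <- "standing"
  out[worn & met > cp$sedentary_met_max & met < cp$lpa_met_max] <- "lpa"
  out[worn & met >= cp$lpa_met_max] <- "mvpa"
  out
}

#' Summarize one day of classified epochs
#'
#' Category hours are epoch counts times 6/3600; steps are summed over worn
#' epochs; a break in sedentary time is a worn sedentary epoch followed by a
#' worn non-sedentary epoch (sit-to-stand transition, no minimum bout). A
#' day is valid with 10-19 h of wear.
#'
#' @param epochs data.frame for one day, sorted by `t_s`, with columns
#'   `t_s`, `met`, `posture`, `steps`, `worn`.
#' @param cp a [cut_points()].
#' @param wear_bounds_h valid wear-time bounds, hours.
#' @param epoch_s epoch length, seconds.
#' @return One-row data.frame (class `day_activity`): `wear_h`, `sed_h`,
#'   `stand_h`, `lpa_h`, `mvpa_h`, `total_pa_h`, `steps`, `breaks`, `valid`.
#' @export
summarize_day <- function(epochs, cp = cut_points(), wear_bounds_h = c(10, 19),
                          epoch_s = 6) {
  if (anyDuplicated(epochs$t_s)) mf_parse_error("duplicate epoch timestamps")
  if (is.unsorted(epochs$t_s)) epochs <- epochs[order(epochs$t_s), , drop = FALSE]
  cls <- classify_epoch(epochs, cp)
  worn <- cls != "nonwear"
  h <- function(what) sum(cls == what) * epoch_s / 3600
  wear_h <- sum(worn) * epoch_s / 3600
  wcls <- cls[worn]
  breaks <- if (length(wcls) > 1L)
    sum(wcls[-length(wcls)] == "sedentary" & wcls[-1L] != "sedentary") else 0L
  out <- data.frame(
    wear_h = wear_h, sed_h = h("sedentary"), stand_h = h("standing"),
    lpa_h = h("lpa"), mvpa_h = h("mvpa"),
    total_pa_h = h("lpa") + h("mvpa"),
    steps = sum(epochs$steps[worn]),
    breaks = as.integer(breaks),
    valid = wear_h >= wear_bounds_h[1L] && wear_h <= wear_bounds_h[2L]
  )
  class(out) <- c("day_activity", class(out))
  out
}

#' Per-subject activity summary over valid days
#'
#' Means of each daily field over valid days; subjects with fewer than
#' `min_days` valid days are excluded (classed condition
#' `metflexr_insufficient_days`).
#'
#' @param days data.frame of [summarize_day()] rows (one per day).
#' @param min_days minimum number of valid days.
#' @return One-row data.frame of means plus `n_valid_days`.
#' @export
subject_summary <- function(days, min_days = 4) {
  v <- days[days$valid, , drop = FALSE]
  if (nrow(v) < min_days)
    mf_stop("metflexr_insufficient_days",
            sprintf("only %d valid days (< %d required)", nrow(v), min_days))
  num <- c("wear_h", "sed_h", "stand_h", "lpa_h", "mvpa_h", "total_pa_h",
           "steps", "breaks")
  out <- as.data.frame(as.list(colMeans(v[num])))
  out$n_valid_days <- nrow(v)
  out
}
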