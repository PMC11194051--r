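# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation paths they check.

# Exhaustive steady-state window search over sub-bin means: all (start, len)
# pairs, direct CV formulas, longest qualifying window, earliest on ties.
oracle_steady_state <- function(bins, params) {
  n <- nrow(bins)
  k_min <- ceiling(params$min_window_s / params$bin_s)
  cv <- function(v) 100 * sd(v) / mean(v)
  best <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i || (j - i + 1) < k_min) next
      cvo <- cv(bins$vo2[i:j]); cvc <- cv(bins$vco2[i:j]); cvr <- cv(bins$rer[i:j])
      gas_ok <- cvo < params$cv_gas_max && cvc < params$cv_gas_max
      rer_ok <- cvr < params$cv_rer_max
      ok <- switch(params$criterion_mode,
                   either = gas_ok || rer_ok, both = gas_ok && rer_ok,
                   gas_only = gas_ok, rer_only = rer_ok)
      if (!ok) next
      len <- j - i + 1
      if (is.null(best) || len > best$len || (len == best$len && i < best$i))
        best <- list(i = i, j = j, len = len)
    }
  }
  best
}

# Build a gas series whose sub-bin means are exactly the given levels:
# breath values are piecewise constant over the realized bin grid.
make_series_from_levels <- function(vo2_levels, rer_levels, bin_s = 30,
                                    breath_gap = 3, condition = "fasting") {
  n_bins <- length(vo2_levels)
  t <- seq(1, n_bins * bin_s + breath_gap, by = breath_gap)
  idx <- pmin(n_bins, floor((t - t[1]) / bin_s) + 1L)
  gas_series(t, vo2_levels[idx], rer_levels[idx] * vo2_levels[idx],
             condition = condition)
}

# Partial correlation through the inverse of the correlation matrix.
oracle_partial_r <- function(x, y, Z) {
  m <- cbind(x, y, Z)
  P <- solve(stats::cor(m))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Auxiliary-regression VIF.
oracle_vif <- function(design, j) {
  r2 <- summary(lm(design[[j]] ~ ., data = design[, -j, drop = FALSE]))$r.squared
  1 / (1 - r2)
}

# A default steady-state params object with no discard, for constructed series.
ss_params_nodiscard <- function(...) {
  steady_state_params(discard_s = 0, ...)
}
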