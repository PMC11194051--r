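#' Synthetic cohort configuration
#'
#' Describes the stated world the generator emulates: 64 sedentary adults
#' with metabolic syndrome (37 women, 27 men), age 58.3 (SD 6.8) years,
#' weight 93.2 (16.1) kg, BMI 31.6 (4.3); daily activity of about 10.0 h
#' sedentary, 1.8 h standing, 2.7 h total PA and 5,149 steps over about 26
#' measurement days; fasting RER around 0.91 with a near-zero mean clamp
#' ΔRER; exercise RER rising from 0.74 at 25 W to 1.12 at maximal load;
#' whole-body glucose uptake (M) with median 2.5 mg·kg⁻¹·min⁻¹; delta
#' exercise efficiency 16.7 (2.5) %.
#'
#' Cross-sectional effects are planted on latent subject traits through
#' `effect_matrix` (columns `outcome`, `exposure`, `beta`): each outcome's
#' latent z-score is a linear combination of the z-scored exposures plus
#' independent noise, so a standardized single-exposure regression recovers
#' `beta` in expectation (exposures are generated mutually independent).
#' Default plants are the significant fasting/clamp associations: sedentary
#' time on fasting RER (+0.35) and clamp ΔRER (−0.41), standing on fasting
#' RER (−0.32), and light-intensity PA on clamp ΔRER (+0.33).
#'
#' @param n number of participants.
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of it.
#' @param n_days accelerometer measurement days per subject.
#' @param female_ratio share of women.
#' @param breath_noise_cv multiplicative breath-level noise CV.
#' @param glucose_noise_sd clamp glucose sample SD, mmol·L⁻¹.
#' @param effect_matrix planted standardized associations; `NULL` for none.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n = 64, seed = 1, n_days = 26, female_ratio = 37 / 64,
                          breath_noise_cv = 0.02, glucose_noise_sd = 0.1,
                          effect_matrix = default_effect_matrix()) {
  if (n < 2) mf_config_error("cohort needs n >= 2")
  if (!is.null(effect_matrix)) {
    stopifnot(all(c("outcome", "exposure", "beta") %in% names(effect_matrix)))
    if (any(abs(effect_matrix$beta) >= 1))
      mf_config_error("planted betas must lie in (-1, 1)")
    ss <- tapply(effect_matrix$beta^2, effect_matrix$outcome, sum)
    if (any(ss >= 1))
      mf_config_error("per-outcome planted beta^2 must sum to < 1")
  }
  structure(
    list(n = n, seed = as.integer(seed), n_days = n_days,
         female_ratio = female_ratio, breath_noise_cv = breath_noise_cv,
         glucose_noise_sd = glucose_noise_sd, effect_matrix = effect_matrix),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_effect_matrix <- function() {
  data.frame(
    outcome = c("rer_fasting", "rer_fasting", "delta_rer_clamp", "delta_rer_clamp"),
    exposure = c("sed_h", "stand_h", "sed_h", "lpa_h"),
    beta = c(0.35, -0.32, -0.41, 0.33)
  )
}

# Deterministic substream seeding: one base seed per subject, offset per
# data type, kept under 2^31.
substream_seed <- function(base_seed, subject_idx, label) {
  offs <- c(traits = 0L, fasting = 1L, clamp_gas = 2L, clamp = 3L,
            ramp = 4L, epochs = 5L)
  (as.integer(base_seed) %% 200000L) * 10000L + subject_idx * 7L + offs[[label]]
}

rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  pmin(hi, pmax(lo, x))
}

# ---- latent subject table -------------------------------------------------

#' Draw the latent subject-level truth table
#'
#' Generates anthropometrics, bloods, activity exposures and the latent
#' physiological outcomes with the planted effect structure, without writing
#' any raw data streams. This is the calibration surface: regressions run on
#' this table recover the planted standardized betas free of measurement
#' noise.
#'
#' @param config a [cohort_config()].
#' @return data.frame with one row per subject (the ground-truth table).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  set.seed(config$seed)
  sex <- ifelse(runif(n) < config$female_ratio, "female", "male")
  age <- rtruncnorm1(n, 58.3, 6.8, 40, 65)
  weight <- ifelse(sex == "male",
                   rtruncnorm1(n, 101.2, 16.5, 70, 150),
                   rtruncnorm1(n, 87.4, 13.1, 60, 130))
  bmi <- rtruncnorm1(n, 31.6, 4.3, 25, 40)
  height_cm <- 100 * sqrt(weight / bmi)
  body_fat_pct <- ifelse(sex == "male",
                         rtruncnorm1(n, 37.2, 7.6, 15, 55),
                         rtruncnorm1(n, 47.4, 4.7, 25, 60))
  ffm <- weight * (1 - body_fat_pct / 100)
  bsa <- bsa_du_bois(height_cm, weight)

  # exposures: mutually independent truncated normals (Table-1 anchors)
  # wear time is the sum of the four categories (10.04 + 1.79 + 1.74 + 0.97
  # = 14.54 h/day), since only worn epochs are classified
  exposures <- data.frame(
    sed_h = rtruncnorm1(n, 10.04, 1.01, 7, 13),
    stand_h = rtruncnorm1(n, 1.79, 0.59, 0.4, 4),
    lpa_h = rtruncnorm1(n, 1.74, 0.44, 0.5, 3.5),
    mvpa_h = rtruncnorm1(n, 0.97, 0.32, 0.2, 2.2),
    steps = rtruncnorm1(n, 5149, 1825, 1500, 12000),
    breaks = rtruncnorm1(n, 29, 8, 10, 55)
  )
  exposures$total_pa_h <- exposures$lpa_h + exposures$mvpa_h
  exposures$wear_h <- exposures$sed_h + exposures$stand_h + exposures$total_pa_h

  # latent outcomes: planted effect structure on z-scores. Because wear time
  # is structurally the sum of the category hours, the wear-adjusted partial
  # coefficient of an exposure is not its marginal loading; each planted
  # value is therefore defined as the partial standardized beta given the
  # recovery covariates (sex, age, and wear for accelerometer exposures).
  # Loadings on the covariate-residualized exposures are solved from the
  # residual covariance so that every single-exposure adjusted regression
  # recovers its planted beta in expectation.
  em <- config$effect_matrix
  sex01 <- as.numeric(sex == "male")
  accel_exposures <- c("sed_h", "stand_h", "lpa_h", "mvpa_h", "total_pa_h",
                       "steps", "breaks")
  resid_exposure <- function(name) {
    x <- exposures[[name]]
    zx <- (x - mean(x)) / sd(x)
    covs <- if (name %in% accel_exposures)
      cbind(sex01, age, exposures$wear_h) else cbind(sex01, age)
    residuals(lm(zx ~ covs))
  }
  outcome_z <- function(outcome) {
    z <- rnorm(n)
    if (is.null(em)) return(z)
    rows <- em[em$outcome == outcome, , drop = FALSE]
    if (!nrow(rows)) return(z)
    R <- vapply(rows$exposure, resid_exposure, numeric(n))
    C <- crossprod(R) / (n - 1)
    # recovered_j = sum_k a_k C[j, k] / C[j, j]  =>  solve M a = beta,
    # M[j, k] = C[j, k] / C[j, j] (division recycles down rows)
    a <- tryCatch(solve(C / diag(C), rows$beta), error = function(e) NULL)
    if (is.null(a) || anyNA(a) || n < 10) {
      # tiny or degenerate cohorts: fall back to marginal loadings
      Z <- vapply(rows$exposure, function(e) {
        x <- exposures[[e]]; (x - mean(x)) / sd(x)
      }, numeric(n))
      planted <- as.numeric(Z %*% rows$beta)
    } else {
      planted <- as.numeric(R %*% a)
    }
    planted + sqrt(max(0, 1 - var(planted))) * z
  }

  # clips only guard the breath-generator domain [0.65, 1.3]; they sit far
  # enough out (> 3.5 SD) not to attenuate the planted associations
  rer_fasting <- pmin(1.28, pmax(0.66, 0.91 + 0.09 * outcome_z("rer_fasting")))
  delta_rer_clamp <- pmin(0.3, pmax(-0.3, 0.00 + 0.05 * outcome_z("delta_rer_clamp")))
  rer_clamp <- pmin(1.29, pmax(0.66, rer_fasting + delta_rer_clamp))
  delta_rer_clamp <- rer_clamp - rer_fasting

  vo2_fasting <- weight * rtruncnorm1(n, 2.58, 0.25, 1.8, 3.4)
  vo2_clamp <- vo2_fasting * rtruncnorm1(n, 1.054, 0.03, 0.95, 1.2)

  m_true <- exp(log(2.5) + 0.51 * outcome_z("m_value_log"))
  vo2max_kg <- ifelse(sex == "male",
                      rtruncnorm1(n, 25.0, 4.9, 16, 40),
                      rtruncnorm1(n, 21.1, 3.7, 14, 35)) +
    0 * outcome_z("vo2max")  # hook kept for planted fitness effects
  efficiency <- rtruncnorm1(n, 16.7 + 2.5 * outcome_z("efficiency"), 0, 11, 24)
  rer_low_ex <- pmin(0.88, pmax(0.66, 0.74 + 0.05 * outcome_z("rer_low_ex")))
  delta_rer_ex <- pmin(0.55, pmax(0.2, 0.39 + 0.07 * outcome_z("delta_rer_ex")))
  rer_max_ex <- rer_low_ex + delta_rer_ex

  # a subject who completed the efficiency-bound stage (75 W women / 100 W
  # men) must have a VO2 ceiling above that stage's requirement; floor the
  # drawn VO2max accordingly (couples low fitness with low efficiency,
  # which is also what the test protocol implies)
  vo2_25 <- 6.45 * weight
  ee_25 <- (0.575 * rer_low_ex + 4.435) * vo2_25 / 1000
  hi_w <- ifelse(sex == "male", 100, 75)
  ee_hi <- ee_25 + (hi_w - 25) * 0.014 * 100 / efficiency
  vo2_req <- 1000 * ee_hi / (0.575 * rer_low_ex + 4.435)
  vo2max_ml_min <- pmax(vo2max_kg * weight, 1.10 * vo2_req)

  glucose_fast <- rtruncnorm1(n, 5.9, 0.4, 4.8, 6.9)
  insulin_pmol <- exp(rnorm(n, log(69.5), 0.56))
  ffa_fast <- rtruncnorm1(n, 0.60, 0.20, 0.15, 1.3)
  ffa_clamp <- pmax(0.02, ffa_fast + rtruncnorm1(n, -0.48, 0.20, -1.1, 0.1))
  lactate_fast <- exp(rnorm(n, log(1.0), 0.25))
  lactate_clamp <- pmax(0.3, lactate_fast + rnorm(n, 0.18, 0.30))

  out <- cbind(
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      sex = sex, age = age, weight_kg = weight, height_cm = height_cm,
      bmi = bmi, body_fat_pct = body_fat_pct, ffm_kg = ffm, bsa_m2 = bsa
    ),
    exposures,
    data.frame(
      rer_fasting = rer_fasting, rer_clamp = rer_clamp,
      delta_rer_clamp = delta_rer_clamp,
      vo2_fasting = vo2_fasting, vo2_clamp = vo2_clamp,
      m_true = m_true,
      vo2max_ml_kg_min = vo2max_ml_min / weight,
      vo2max_ml_min = vo2max_ml_min,
      efficiency_pct = efficiency,
      rer_low_ex = rer_low_ex, rer_max_ex = rer_max_ex,
      delta_rer_ex = delta_rer_ex,
      glucose_fast = glucose_fast, insulin_pmol = insulin_pmol,
      ffa_fast = ffa_fast, ffa_clamp = ffa_clamp,
      lactate_fast = lactate_fast, lactate_clamp = lactate_clamp,
      n_days = config$n_days
    )
  )
  out
}

# ---- raw-stream generators ------------------------------------------------

#' Simulate a breath-by-breath gas series around a true RER
#'
#' Breath times are ~3 s apart with jitter; VO2 and VCO2 carry independent
#' multiplicative noise so that E[VCO2/VO2] equals `true_rer` to first
#' order. An optional unsteady lead-in linearly decays an initial offset in
#' both flows, emulating settling under the hood.
#'
#' @param true_rer planted RER, in [0.65, 1.3].
#' @param true_vo2 planted VO2, mL·min⁻¹.
#' @param duration_s series length, seconds.
#' @param noise_cv multiplicative noise CV (0 = noiseless).
#' @param seed optional seed.
#' @param condition series condition tag.
#' @param lead_in_s lead-in duration with decaying offset (0 = none).
#' @param lead_in_frac initial fractional elevation of both flows.
#' @return A [gas_series()].
#' @export
generate_breaths <- function(true_rer, true_vo2, duration_s = 1200,
                             noise_cv = 0.02, seed = NULL,
                             condition = "fasting",
                             lead_in_s = 0, lead_in_frac = 0.3) {
  if (true_rer < 0.65 || true_rer > 1.3)
    mf_config_error("true_rer outside the physiological band [0.65, 1.3]")
  if (!is.null(seed)) set.seed(seed)
  n_max <- ceiling(duration_s / 2) + 10L
  gaps <- 3 + runif(n_max, -0.8, 0.8)
  t <- cumsum(gaps)
  t <- t[t <= duration_s]
  n <- length(t)
  decay <- if (lead_in_s > 0) pmax(0, 1 - t / lead_in_s) else rep(0, n)
  vo2 <- true_vo2 * (1 + lead_in_frac * decay) * pmax(0.2, 1 + rnorm(n, 0, noise_cv))
  # ratio noise rides on the realized VO2 so E[VCO2/VO2] = true_rer exactly
  # (after the lead-in, whose settling elevates the RER as well)
  vco2 <- true_rer * (1 + lead_in_frac * decay) * vo2 *
    pmax(0.2, 1 + rnorm(n, 0, noise_cv))
  gas_series(t, vo2, vco2, condition = condition)
}

#' Simulate a clamp pump log and glucose samples
#'
#' The pump ramps up over a transient and then settles at the rate implying
#' the planted per-kg uptake `true_m`; after the transient, glucose samples
#' scatter around the 5.0 mmol·L⁻¹ target. The final 25 minutes of pumping
#' are exactly at the settled rate, so the last 20-min interval recovers
#' `true_m` exactly at zero glucose noise.
#'
#' @param true_m planted whole-body glucose uptake, mg·kg⁻¹·min⁻¹.
#' @param mass body mass, kg.
#' @param bsa body surface area, m² (recorded only).
#' @param seed optional seed.
#' @param duration_min clamp length, minutes.
#' @param transient_min settling time, minutes.
#' @param glucose_noise_sd sample noise SD, mmol·L⁻¹.
#' @param glucose_conc_pct infusate strength.
#' @param target_glucose euglycemic target, mmol·L⁻¹.
#' @return A [clamp_timeline()].
#' @export
generate_clamp <- function(true_m, mass, bsa = NA, seed = NULL,
                           duration_min = 120, transient_min = 30,
                           glucose_noise_sd = 0.1, glucose_conc_pct = 20,
                           target_glucose = 5.0) {
  if (true_m <= 0) mf_config_error("true_m must be positive")
  if (!is.null(seed)) set.seed(seed)
  r_final <- true_m * mass * 60 / (10 * glucose_conc_pct)
  t_pump <- seq(0, duration_min * 60 - 1, by = 300)
  frac <- pmin(1, t_pump / (transient_min * 60))
  rate <- r_final * (0.2 + 0.8 * frac)
  mid <- t_pump >= transient_min * 60 & t_pump < (duration_min - 25) * 60
  if (glucose_noise_sd > 0 && any(mid))
    rate[mid] <- rate[mid] * pmax(0.7, 1 + rnorm(sum(mid), 0, 0.03))
  rate[t_pump >= (duration_min - 25) * 60] <- r_final
  t_gluc <- cumsum(runif(ceiling(duration_min / 5), 300, 600))
  t_gluc <- t_gluc[t_gluc < duration_min * 60]
  transient_dev <- pmax(0, 1 - t_gluc / (transient_min * 60)) * 0.8
  gluc <- target_glucose + transient_dev + rnorm(length(t_gluc), 0, glucose_noise_sd)
  clamp_timeline(
    pump_log = data.frame(t_s = t_pump, rate_ml_h = rate),
    glucose_samples = data.frame(t_s = t_gluc, glucose_mmol_l = gluc),
    glucose_conc_pct = glucose_conc_pct, target_glucose = target_glucose,
    bsa = bsa
  )
}

#' Simulate a graded maximal ramp test
#'
#' Stage energy expenditure rises with power at the planted delta
#' efficiency; stage RER rises from the planted low-intensity value toward
#' the planted maximum; stage VO2 follows from the low-intensity EE
#' equation and plateaus at the planted VO2max, which terminates the test.
#' Breath values ramp toward the stage target over the first minute of each
#' stage and hold it for the final two, so stage-tail means equal the
#' planted targets when `noise_cv = 0`.
#'
#' @param true_vo2max planted plateau VO2, mL·min⁻¹.
#' @param efficiency_pct planted delta efficiency, %.
#' @param mass body mass, kg.
#' @param rer_low,rer_max planted 25-W and maximal stage RER.
#' @param protocol a [ramp_protocol()].
#' @param seed optional seed.
#' @param noise_cv breath noise CV.
#' @return List with `series` (a [gas_series()]), `stages` (data.frame) and
#'   `stage_targets` (planted per-stage VO2/RER).
#' @export
generate_ramp <- function(true_vo2max, efficiency_pct, mass,
                          rer_low = 0.74, rer_max = 1.12,
                          protocol = ramp_protocol(), seed = NULL,
                          noise_cv = 0.02) {
  if (!is.null(seed)) set.seed(seed)
  vo2_25 <- 6.45 * mass
  if (true_vo2max <= vo2_25 * 1.15)
    mf_config_error("true_vo2max must exceed the 25-W requirement")
  ee_of <- function(vo2_l, rer) (0.575 * rer + 4.435) * vo2_l
  ee_25 <- ee_of(vo2_25 / 1000, rer_low)
  # stage targets: EE linear in power at the planted efficiency, RER rising
  # with the VO2 fraction of the plateau; fixed-point for the RER/VO2 couple
  stage_power <- function(k) protocol$start_w + (k - 1) * protocol$increment_w
  targets <- list(list(power = 25, vo2 = vo2_25, rer = rer_low))
  k <- 1L
  repeat {
    k <- k + 1L
    p <- stage_power(k)
    ee_k <- ee_25 + (p - protocol$start_w) * 0.014 * 100 / efficiency_pct
    r <- rer_low
    vo2_k <- vo2_25
    for (it in 1:4) {
      fracv <- min(1, max(0, (vo2_k - vo2_25) / (true_vo2max - vo2_25)))
      r <- rer_low + (rer_max - rer_low) * fracv
      vo2_k <- 1000 * ee_k / (0.575 * r + 4.435)
    }
    if (vo2_k >= true_vo2max) {
      targets[[k]] <- list(power = p, vo2 = true_vo2max, rer = rer_max)
      break
    }
    targets[[k]] <- list(power = p, vo2 = vo2_k, rer = r)
    if (k > 40L) break
  }
  n_stages <- length(targets)
  stage_s <- protocol$stage_s
  # breath stream: ramp to the stage target over the first 60 s, hold after
  t_all <- vo2_all <- vco2_all <- numeric(0)
  for (k in seq_len(n_stages)) {
    tg <- targets[[k]]
    prev_vo2 <- if (k == 1L) 0.85 * vo2_25 else targets[[k - 1L]]$vo2
    prev_rer <- if (k == 1L) rer_low else targets[[k - 1L]]$rer
    dur <- if (k == n_stages) max(90, stage_s / 2) else stage_s
    n_b <- ceiling(dur / 2)
    tt <- cumsum(3 + runif(n_b, -0.8, 0.8))
    tt <- tt[tt <= dur]
    f <- pmin(1, tt / min(60, dur / 3))
    vo2_t <- prev_vo2 + (tg$vo2 - prev_vo2) * f
    rer_t <- prev_rer + (tg$rer - prev_rer) * f
    nn <- length(tt)
    vo2_b <- vo2_t * pmax(0.2, 1 + rnorm(nn, 0, noise_cv))
    vco2_b <- rer_t * vo2_b * pmax(0.2, 1 + rnorm(nn, 0, noise_cv))
    off <- (k - 1L) * stage_s
    t_all <- c(t_all, off + tt)
    vo2_all <- c(vo2_all, vo2_b)
    vco2_all <- c(vco2_all, vco2_b)
  }
  stages <- data.frame(
    stage_idx = seq_len(n_stages),
    power_w = vapply(targets, `[[`, numeric(1), "power"),
    start_s = (seq_len(n_stages) - 1L) * stage_s,
    end_s = c(seq_len(n_stages - 1L) * stage_s,
              (n_stages - 1L) * stage_s + max(90, stage_s / 2))
  )
  list(
    series = gas_series(t_all, vo2_all, vco2_all, condition = "exercise"),
    stages = stages,
    stage_targets = data.frame(
      power_w = stages$power_w,
      vo2 = vapply(targets, `[[`, numeric(1), "vo2"),
      rer = vapply(targets, `[[`, numeric(1), "rer")
    )
  )
}

#' Simulate classified 6-s accelerometer epochs
#'
#' Builds each day as alternating sedentary / non-sedentary bouts so that
#' the planted break count is realized by construction, with day-level
#' noise around the planted category hours. Only the wear period is
#' emitted (all epochs `worn = TRUE`); daily category hours therefore sum
#' to wear hours exactly.
#'
#' @param profile list/row with `wear_h`, `sed_h`, `stand_h`, `lpa_h`,
#'   `mvpa_h`, `steps`, `breaks` daily means.
#' @param n_days number of days.
#' @param seed optional seed.
#' @param epoch_s epoch length, seconds.
#' @param day_noise logical; draw day-level variation around the profile.
#' @return data.frame with columns `date`, `t_s`, `mad_mg`, `met`,
#'   `posture`, `steps`, `worn`.
#' @export
generate_epochs <- function(profile, n_days = 26, seed = NULL, epoch_s = 6,
                            day_noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("wear_h", "sed_h", "stand_h", "lpa_h", "mvpa_h", "steps", "breaks")
  profile <- as.list(profile)
  if (!all(need %in% names(profile)))
    mf_config_error("activity profile is missing fields")
  if (profile$sed_h + profile$stand_h + profile$lpa_h + profile$mvpa_h >
      profile$wear_h + 1e-9)
    mf_config_error("profile category hours exceed wear hours")
  days <- lapply(seq_len(n_days), function(d) {
    jitter <- function(x, s, lo, hi) if (day_noise) min(hi, max(lo, x + rnorm(1, 0, s))) else x
    wear <- jitter(profile$wear_h, 0.3, 10.2, 18.8)
    stand <- jitter(profile$stand_h, 0.2, 0.1, wear / 3)
    lpa <- jitter(profile$lpa_h, 0.2, 0.1, wear / 3)
    mvpa <- jitter(profile$mvpa_h, 0.12, 0.05, wear / 4)
    n_wear <- round(wear * 3600 / epoch_s)
    n_stand <- round(stand * 3600 / epoch_s)
    n_lpa <- round(lpa * 3600 / epoch_s)
    n_mvpa <- round(mvpa * 3600 / epoch_s)
    n_sed <- n_wear - n_stand - n_lpa - n_mvpa
    if (n_sed < 1L) mf_config_error("infeasible day: no sedentary epochs left")
    k <- max(1L, round(profile$breaks + if (day_noise) rnorm(1, 0, 3) else 0))
    k <- min(k, n_sed, n_stand + n_lpa + n_mvpa)
    non_total <- n_stand + n_lpa + n_mvpa
    # k sedentary bouts, each followed by a non-sedentary bout => k breaks
    split_counts <- function(total, k) {
      if (k == 1L) return(total)
      cuts <- sort(sample.int(total - 1L, k - 1L))
      diff(c(0L, cuts, total))
    }
    if (k < 1L || non_total == 0L) {
      cls <- rep("sedentary", n_sed)
    } else {
      sed_bouts <- split_counts(n_sed, k)
      non_bouts <- split_counts(non_total, k)
      non_classes <- sample(c(rep("standing", n_stand), rep("lpa", n_lpa),
                              rep("mvpa", n_mvpa)))
      cls <- character(0)
      pos <- 0L
      for (b in seq_len(k)) {
        cls <- c(cls, rep("sedentary", sed_bouts[b]),
                 non_classes[(pos + 1L):(pos + non_bouts[b])])
        pos <- pos + non_bouts[b]
      }
    }
    n <- length(cls)
    met <- numeric(n)
    met[cls == "sedentary"] <- pmin(1.5, pmax(0.8, rnorm(sum(cls == "sedentary"), 1.2, 0.12)))
    met[cls == "standing"] <- pmin(1.5, pmax(0.9, rnorm(sum(cls == "standing"), 1.35, 0.08)))
    met[cls == "lpa"] <- runif(sum(cls == "lpa"), 1.6, 2.9)
    met[cls == "mvpa"] <- pmax(3.0, rnorm(sum(cls == "mvpa"), 3.6, 0.5))
    steps_day <- max(0, round(profile$steps * (if (day_noise) max(0.3, 1 + rnorm(1, 0, 0.15)) else 1)))
    active <- which(cls %in% c("lpa", "mvpa"))
    steps <- integer(n)
    if (length(active) && steps_day > 0) {
      alloc <- as.integer(rmultinom(1, steps_day, rep(1, length(active))))
      steps[active] <- alloc
    }
    data.frame(
      date = sprintf("day%02d", d),
      t_s = 25200 + (seq_len(n) - 1L) * epoch_s,
      mad_mg = round(pmax(1, (met - 1) * 90 + rnorm(n, 10, 3)), 1),
      met = round(met, 2),
      posture = ifelse(cls == "sedentary", "sit", "upright"),
      steps = steps,
      worn = TRUE
    )
  })
  do.call(rbind, days)
}

#' @importFrom stats rmultinom
NULL

# ---- full cohort ----------------------------------------------------------

#' Generate a complete synthetic cohort
#'
#' Draws the latent truth table with [generate_truth()] and, when `dir` is
#' given, writes the full per-subject raw file tree
#' (`fasting.csv`, `clamp_gas.csv`, `pump_log.csv`, `glucose.csv`,
#' `exercise.csv`, `stages.csv`, `epochs.csv`, `subject.json`) plus
#' `ground_truth.csv` at the top level. Deterministic given the seed.
#'
#' @param config a [cohort_config()].
#' @param dir output directory; `NULL` to return the truth table only.
#' @return List with `truth` (data.frame) and `dir`.
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL) {
  truth <- generate_truth(config)
  if (is.null(dir)) return(list(truth = truth, dir = NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(truth))) {
    s <- truth[i, ]
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    fast <- generate_breaths(s$rer_fasting, s$vo2_fasting, duration_s = 1200,
                             noise_cv = config$breath_noise_cv,
                             seed = substream_seed(config$seed, i, "fasting"),
                             condition = "fasting", lead_in_s = 240)
    write_gas_series(fast, file.path(sdir, "fasting.csv"))
    cg <- generate_breaths(s$rer_clamp, s$vo2_clamp, duration_s = 840,
                           noise_cv = config$breath_noise_cv,
                           seed = substream_seed(config$seed, i, "clamp_gas"),
                           condition = "clamp", lead_in_s = 240)
    write_gas_series(cg, file.path(sdir, "clamp_gas.csv"))
    cl <- generate_clamp(s$m_true, s$weight_kg, bsa = s$bsa_m2,
                         seed = substream_seed(config$seed, i, "clamp"),
                         glucose_noise_sd = config$glucose_noise_sd)
    data.table::fwrite(cl$pump_log, file.path(sdir, "pump_log.csv"))
    data.table::fwrite(cl$glucose_samples, file.path(sdir, "glucose.csv"))
    rmp <- generate_ramp(s$vo2max_ml_min, s$efficiency_pct, s$weight_kg,
                         rer_low = s$rer_low_ex, rer_max = s$rer_max_ex,
                         seed = substream_seed(config$seed, i, "ramp"),
                         noise_cv = config$breath_noise_cv)
    write_gas_series(rmp$series, file.path(sdir, "exercise.csv"))
    data.table::fwrite(rmp$stages, file.path(sdir, "stages.csv"))
    ep <- generate_epochs(
      s[c("wear_h", "sed_h", "stand_h", "lpa_h", "mvpa_h", "steps", "breaks")],
      n_days = config$n_days,
      seed = substream_seed(config$seed, i, "epochs")
    )
    data.table::fwrite(ep, file.path(sdir, "epochs.csv"))
    meta <- as.list(s[c("subject_id", "sex", "age", "weight_kg", "height_cm",
                        "bmi", "ffm_kg", "bsa_m2", "glucose_fast",
                        "insulin_pmol", "ffa_fast", "ffa_clamp",
                        "lactate_fast", "lactate_clamp")])
    jsonlite::write_json(meta, file.path(sdir, "subject.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  data.table::fwrite(truth, file.path(dir, "ground_truth.csv"))
  list(truth = truth, dir = dir)
}
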