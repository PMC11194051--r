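#' Process a cohort directory into a per-subject derived table
#'
#' Runs the full measurement pipeline for every subject directory under
#' `dir`: steady-state detection on the fasting and clamp hood series,
#' resting substrate oxidation, clamp M value / non-oxidative glucose
#' disposal / carbohydrate-source partition, graded-test processing
#' (VO2max, exercise ΔRER, stage substrate oxidation, delta efficiency),
#' and accelerometer daily summaries. Failures are per-component: a subject
#' with no fasting steady state keeps their exercise results, with the
#' affected fields set `NA` and a reason-coded row in the exclusion log,
#' mirroring per-analysis n bookkeeping.
#'
#' @param dir cohort directory as written by [generate_cohort()].
#' @param ss_params [steady_state_params()] for hood series.
#' @param cp [cut_points()] for epoch classification.
#' @param min_days minimum valid accelerometer days.
#' @param m_summary_mode passed to [m_value()].
#' @return List with `derived` (one row per subject) and `exclusions`
#'   (`subject_id`, `component`, `reason`).
#' @export
process_cohort <- function(dir, ss_params = steady_state_params(),
                           cp = cut_points(), min_days = 4,
                           m_summary_mode = "last") {
  subjects <- list.dirs(dir, recursive = FALSE)
  if (!length(subjects)) mf_config_error(sprintf("no subject directories in %s", dir))
  excl <- list()
  note <- function(id, component, e) {
    reason <- if (inherits(e, "metflexr_no_steady_state")) "no_steady_state"
    else if (inherits(e, "metflexr_insufficient_days")) "insufficient_valid_days"
    else if (inherits(e, "metflexr_no_steady_clamp")) "no_steady_clamp"
    else if (inherits(e, "metflexr_not_computable")) "missing_bound_stage"
    else if (inherits(e, "metflexr_insufficient_data")) "insufficient_data"
    else "error"
    excl[[length(excl) + 1L]] <<- data.frame(
      subject_id = id, component = component, reason = reason,
      message = conditionMessage(e)
    )
    NULL
  }
  rows <- lapply(subjects, function(sdir) {
    id <- basename(sdir)
    meta <- jsonlite::read_json(file.path(sdir, "subject.json"),
                                simplifyVector = TRUE)
    mass <- meta$weight_kg
    row <- list(subject_id = id, sex = meta$sex, age = meta$age,
                weight_kg = mass, ffm_kg = meta$ffm_kg)

    ss_fast <- tryCatch(
      detect_steady_state(read_gas_series(file.path(sdir, "fasting.csv"),
                                          "fasting", subject_id = id), ss_params),
      metflexr_error = function(e) note(id, "fasting_calorimetry", e))
    ss_clamp <- tryCatch(
      detect_steady_state(read_gas_series(file.path(sdir, "clamp_gas.csv"),
                                          "clamp", subject_id = id), ss_params),
      metflexr_error = function(e) note(id, "clamp_calorimetry", e))
    sub_fast <- if (!is.null(ss_fast))
      substrate_rates(ss_fast$mean_vo2, ss_fast$mean_vco2, "resting", mass)
    sub_clamp <- if (!is.null(ss_clamp))
      substrate_rates(ss_clamp$mean_vo2, ss_clamp$mean_vco2, "resting", mass)
    row$rer_fasting <- if (!is.null(ss_fast)) ss_fast$rer else NA_real_
    row$rer_clamp <- if (!is.null(ss_clamp)) ss_clamp$rer else NA_real_
    row$delta_rer_clamp <- row$rer_clamp - row$rer_fasting
    row$choox_fasting <- if (!is.null(sub_fast)) sub_fast$choox_mg_kg_min else NA_real_
    row$fatox_fasting <- if (!is.null(sub_fast)) sub_fast$fatox_mg_kg_min else NA_real_
    row$ee_fasting_kcal_day <- if (!is.null(ss_fast))
      resting_ee_kcal_day(ss_fast$mean_vo2, ss_fast$mean_vco2) else NA_real_
    row$choox_clamp <- if (!is.null(sub_clamp)) sub_clamp$choox_mg_kg_min else NA_real_
    row$fatox_clamp <- if (!is.null(sub_clamp)) sub_clamp$fatox_mg_kg_min else NA_real_

    m <- tryCatch({
      tl <- clamp_timeline(
        pump_log = data.table::fread(file.path(sdir, "pump_log.csv"), data.table = FALSE),
        glucose_samples = data.table::fread(file.path(sdir, "glucose.csv"), data.table = FALSE)
      )
      m_value(tl, mass, summary_mode = m_summary_mode)
    }, metflexr_error = function(e) note(id, "clamp", e))
    row$m_value <- if (!is.null(m)) m$m_value else NA_real_
    if (!is.null(m) && !is.na(row$choox_clamp)) {
      row$nogd <- nonoxidative_disposal(row$m_value, row$choox_clamp)
      if (row$choox_clamp > 0) {
        pp <- partition_choox(row$choox_clamp, row$m_value)
        row$exo_share <- pp[["exogenous"]]
        row$other_share <- pp[["other"]]
      } else {
        row$exo_share <- NA_real_; row$other_share <- NA_real_
      }
    } else {
      row$nogd <- NA_real_; row$exo_share <- NA_real_; row$other_share <- NA_real_
    }

    ex <- tryCatch({
      series <- read_gas_series(file.path(sdir, "exercise.csv"), "exercise",
                                subject_id = id)
      stages <- read_stages(file.path(sdir, "stages.csv"))
      bins <- bin_20s(series)
      low_stage <- stage_summary(bins, stages[stages$power_w == 25, ][1L, ])
      max_stage <- stage_summary(bins, stages[nrow(stages), ])
      fit <- vo2max(bins, mass, meta$ffm_kg, stages)
      ext <- rer_extrema(bins, low_stage, max_stage)
      eff <- tryCatch({
        sex_arg <- if (identical(meta$sex, "male")) "male" else "female"
        hi_w <- if (sex_arg == "male") 100 else 75
        hi_stage <- stage_summary(bins, stages[stages$power_w == hi_w, ][1L, ])
        delta_efficiency(list(low_stage, hi_stage), sex = sex_arg)
      }, metflexr_error = function(e) note(id, "efficiency", e))
      s_low <- stage_substrate(low_stage, "low_intensity", mass)
      s_max <- stage_substrate(max_stage, "maximal", mass)
      list(fit = fit, ext = ext, eff = eff, s_low = s_low, s_max = s_max)
    }, metflexr_error = function(e) note(id, "exercise", e),
       error = function(e) note(id, "exercise", e))
    if (!is.null(ex)) {
      row$vo2max_ml_kg_min <- ex$fit$vo2max_ml_kg_min
      row$vo2max_ml_kgffm_min <- ex$fit$vo2max_ml_kgffm_min
      row$max_po_w <- ex$fit$max_po_w
      row$rer_low_ex <- ex$ext$rer_low_ex
      row$rer_max_ex <- ex$ext$rer_max_ex
      row$delta_rer_ex <- ex$ext$delta_rer_ex
      row$efficiency_pct <- if (!is.null(ex$eff)) ex$eff else NA_real_
      row$choox_low <- ex$s_low$choox_mg_kg_min
      row$fatox_low <- ex$s_low$fatox_mg_kg_min
      row$ee_low_kcal_min <- ex$s_low$ee_kcal_min
      row$choox_max <- ex$s_max$choox_mg_kg_min
      row$fatox_max <- ex$s_max$fatox_mg_kg_min
      row$ee_max_kcal_min <- ex$s_max$ee_kcal_min
    } else {
      row[c("vo2max_ml_kg_min", "vo2max_ml_kgffm_min", "max_po_w",
            "rer_low_ex", "rer_max_ex", "delta_rer_ex", "efficiency_pct",
            "choox_low", "fatox_low", "ee_low_kcal_min",
            "choox_max", "fatox_max", "ee_max_kcal_min")] <- NA_real_
    }

    act <- tryCatch({
      ep <- data.table::fread(file.path(sdir, "epochs.csv"), data.table = FALSE)
      days <- do.call(rbind, lapply(split(ep, ep$date), summarize_day, cp = cp))
      subject_summary(days, min_days = min_days)
    }, metflexr_error = function(e) note(id, "accelerometry", e))
    if (!is.null(act)) {
      for (nm in names(act)) row[[nm]] <- act[[nm]]
    } else {
      row[c("wear_h", "sed_h", "stand_h", "lpa_h", "mvpa_h", "total_pa_h",
            "steps", "breaks", "n_valid_days")] <- NA_real_
    }

    row$homa_ir <- if (!is.null(meta$glucose_fast) && !is.null(meta$insulin_pmol))
      homa_ir(meta$glucose_fast, meta$insulin_pmol) else NA_real_
    row$ffa_delta <- if (!is.null(meta$ffa_fast))
      insulin_stim_delta(meta$ffa_fast, meta$ffa_clamp) else NA_real_
    row$lactate_delta <- if (!is.null(meta$lactate_fast))
      insulin_stim_delta(meta$lactate_fast, meta$lactate_clamp) else NA_real_
    as.data.frame(row)
  })
  derived <- do.call(rbind, rows)
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(0), component = character(0),
               reason = character(0), message = character(0))
  list(derived = derived, exclusions = exclusions)
}

mf_exposures <- function() {
  data.frame(
    exposure = c("sed_h", "stand_h", "lpa_h", "mvpa_h", "total_pa_h",
                 "steps", "breaks", "vo2max_ml_kg_min", "vo2max_ml_kgffm_min"),
    accelerometer = c(rep(TRUE, 7), FALSE, FALSE)
  )
}

mf_outcome_tables <- function() {
  list(
    table4 = c("rer_fasting", "rer_clamp", "delta_rer_clamp"),
    table5 = c("choox_fasting", "fatox_fasting", "choox_clamp", "fatox_clamp"),
    table6 = c("rer_low_ex", "rer_max_ex", "delta_rer_ex"),
    table7 = c("choox_low", "fatox_low", "choox_max", "fatox_max")
  )
}

#' Run the association stage on a derived table
#'
#' For each outcome table (fasting/clamp metabolic flexibility, resting and
#' clamp substrate oxidation, exercise metabolic flexibility, exercise
#' substrate oxidation) regresses every outcome on every exposure, one at a
#' time, adjusted for sex and age — plus accelerometer wear time for
#' accelerometer exposures — and reports standardized betas with 95% CIs.
#' Also computes the sedentary-time median-split ΔRER contrast.
#'
#' @param derived per-subject table from [process_cohort()].
#' @param out_dir optional directory; if given, writes `table4.csv` ...
#'   `table7.csv` and `results.csv`.
#' @param transform transform policy for [standardized_beta()].
#' @param split_threshold sedentary-time split point (hours); `NULL` for the
#'   cohort median.
#' @return List with `results` (all association rows), `tables` (named list
#'   of wide tables), `median_split`.
#' @export
analyze_cohort <- function(derived, out_dir = NULL, transform = "auto",
                           split_threshold = 10.0) {
  exps <- mf_exposures()
  tabs <- mf_outcome_tables()
  all_rows <- list()
  tables <- list()
  for (tb in names(tabs)) {
    blocks <- list()
    for (oc in tabs[[tb]]) {
      rows <- list()
      for (i in seq_len(nrow(exps))) {
        covs <- if (exps$accelerometer[i]) c("sex", "age", "wear_h") else c("sex", "age")
        res <- tryCatch(
          standardized_beta(oc, exps$exposure[i], covs, derived,
                            transform = transform),
          metflexr_error = function(e) NULL
        )
        cell <- if (is.null(res)) NA_character_ else
          sprintf("%.2f (%.2f, %.2f)", res$std_beta, res$ci_low, res$ci_high)
        if (!is.null(res)) all_rows[[length(all_rows) + 1L]] <- res
        rows[[i]] <- data.frame(
          exposure = exps$exposure[i], beta_ci = cell,
          p = if (is.null(res)) NA_real_ else round(res$p, 3),
          n = if (is.null(res)) NA_integer_ else res$n
        )
      }
      block <- do.call(rbind, rows)
      names(block)[-1L] <- paste0(oc, c("_beta_ci", "_p", "_n"))
      blocks[[oc]] <- block
    }
    tables[[tb]] <- Reduce(function(a, b) merge(a, b, by = "exposure",
                                                all = TRUE, sort = FALSE),
                           blocks)
  }
  results <- do.call(rbind, all_rows)
  split <- tryCatch(
    median_split_compare("sed_h", "delta_rer_clamp", derived,
                         threshold = split_threshold),
    metflexr_error = function(e) NULL
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tb in names(tables))
      if (!is.null(tables[[tb]]))
        data.table::fwrite(tables[[tb]], file.path(out_dir, paste0(tb, ".csv")))
    data.table::fwrite(results, file.path(out_dir, "results.csv"))
  }
  list(results = results, tables = tables, median_split = split)
}

#' Simulate, process and analyze in one call
#'
#' @param config a [cohort_config()].
#' @param dir working directory for the generated cohort tree.
#' @param out_dir optional directory for report tables.
#' @param ... passed to [process_cohort()].
#' @return List with `truth`, `derived`, `exclusions`, `analysis`.
#' @export
run_pipeline <- function(config = cohort_config(), dir = tempfile("cohort"),
                         out_dir = NULL, ...) {
  gen <- generate_cohort(config, dir = dir)
  proc <- process_cohort(dir, ...)
  analysis <- analyze_cohort(proc$derived, out_dir = out_dir)
  list(truth = gen$truth, derived = proc$derived,
       exclusions = proc$exclusions, analysis = analysis)
}
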