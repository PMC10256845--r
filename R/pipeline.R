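#' Validate a pipeline configuration
#'
#' Fails fast (before any computation) if required fields are missing or
#' malformed. Every stochastic stage draws its seed deterministically from the
#' master `seed`, so a config without a seed is rejected.
#'
#' @param config Named list (or path to a JSON file) with at least `out_dir`
#'   and `seed`; optional fields and defaults: `n_subjects` (40), `models`
#'   (all five), `prior_preset_selection` ("default"), `prior_preset_winner`
#'   ("wide"), `max_missing_fraction` (0.25), `k_sd` (2), `threat_period`
#'   (20), `sem_syntax` (aggression MIMIC on the four aggression subscales),
#'   `n_boot` (200), `n_starts` (4).
#' @return Validated config list of class `hex_pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) {
    stop_hex("validation_error", "config must name an explicit master seed")
  }
  if (is.null(config$out_dir)) {
    stop_hex("validation_error", "config must name an output directory")
  }
  defaults <- list(
    n_subjects = 40L, models = .MODELS,
    prior_preset_selection = "default", prior_preset_winner = "wide",
    max_missing_fraction = 0.25, k_sd = 2, threat_period = 20L,
    sem_syntax = paste(
      "agg =~ bpaq_physical + bpaq_verbal + bpaq_anger + bpaq_hostility",
      "agg ~ omega + mu + sigma + epsilon + zeta", sep = "\n"),
    n_boot = 200L, n_starts = 4L
  )
  config <- modifyList(defaults, config)
  if (!all(config$models %in% .MODELS)) {
    stop_hex("validation_error", "unknown model(s): %s",
             paste(setdiff(config$models, .MODELS), collapse = ", "))
  }
  structure(config, class = c("hex_pipeline_config", "list"))
}

#' Validate trial and questionnaire tables
#'
#' Schema, range and alignment checks for externally supplied data: required
#' columns, outcome coding (`u` in 0/1), response labels
#' (`shoot`/`withhold`/`missing`), and subject-ID consistency across tables
#' (subjects present in the trials but absent from the questionnaires are a
#' warning only — they remain usable for task-only analyses).
#'
#' @param trials Trial-level data frame.
#' @param questionnaires Optional subject-by-scale data frame.
#' @return List of class `hex_validation`: `errors` (character), `warnings`
#'   (character), `ok` (no errors).
#' @export
validate_inputs <- function(trials, questionnaires = NULL) {
  errors <- character()
  warnings <- character()
  need <- c("subject", "trial", "opponent", "threat", "u", "response")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    errors <- c(errors, sprintf("trials: missing column '%s'", miss))
  }
  if ("u" %in% names(trials)) {
    bad <- which(!trials$u %in% c(0L, 1L))
    if (length(bad)) {
      errors <- c(errors, sprintf("trials: u out of range {0,1} at row %d",
                                  head(bad, 10)))
    }
  }
  if ("response" %in% names(trials)) {
    bad <- which(!trials$response %in% c("shoot", "withhold", "missing"))
    if (length(bad)) {
      errors <- c(errors,
                  sprintf("trials: invalid response label at row %d",
                          head(bad, 10)))
    }
  }
  if ("threat" %in% names(trials)) {
    if (!all(trials$threat %in% c("high", "low"))) {
      errors <- c(errors, "trials: threat labels must be 'high'/'low'")
    }
  }
  if (!is.null(questionnaires)) {
    if (!"subject" %in% names(questionnaires)) {
      errors <- c(errors, "questionnaires: missing column 'subject'")
    } else if ("subject" %in% names(trials)) {
      only_trials <- setdiff(unique(trials$subject),
                             unique(questionnaires$subject))
      if (length(only_trials)) {
        warnings <- c(warnings, sprintf(
          "subject '%s' has trials but no questionnaires (task-only analyses)",
          only_trials))
      }
      only_q <- setdiff(unique(questionnaires$subject),
                        unique(trials$subject))
      if (length(only_q)) {
        warnings <- c(warnings, sprintf(
          "subject '%s' has questionnaires but no trials", only_q))
      }
    }
  }
  structure(list(errors = errors, warnings = warnings,
                 ok = length(errors) == 0L),
            class = "hex_validation")
}

#' @export
print.hex_validation <- function(x, ...) {
  cat(sprintf("Input validation: %s\n", if (x$ok) "OK" else "FAILED"))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages simulate -> fit all candidate models -> random-effects
#' model selection -> refit the winner with wide priors per threat condition
#' -> exclusions and condition contrasts -> MIMIC SEM of the latent aggression
#' trait on the high-threat learning parameters, writing per-stage CSV/JSON
#' artefacts, a machine-readable run manifest and a human-readable Markdown
#' report into `out_dir`. Identical configs reproduce identical outputs.
#'
#' @param config A `hex_pipeline_config` (or list/path accepted by
#'   [pipeline_config()]).
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `lme`, `bms`, `summaries`, `contrasts`, `sem`, `manifest`).
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) message(sprintf(...))

  # stage 1: simulate
  spec <- population_spec(n_subjects = config$n_subjects,
                          seed = derive_seed(config$seed, 1L),
                          schedule = build_schedule(
                            threat_period = config$threat_period))
  cohort <- generate_cohort(spec)
  write.csv(cohort$trials, file.path(config$out_dir, "trials.csv"),
            row.names = FALSE)
  write.csv(cohort$questionnaires,
            file.path(config$out_dir, "questionnaires.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(config$out_dir, "truth.csv"),
            row.names = FALSE)
  val <- validate_inputs(cohort$trials, cohort$questionnaires)
  if (!val$ok) {
    stop_hex("pipeline_error", "stage simulate: generated data invalid: %s",
             paste(val$errors, collapse = "; "))
  }
  log_line("stage simulate: %d subjects", config$n_subjects)

  # stage 2: per-subject fits of every candidate model
  subjects <- unique(cohort$trials$subject)
  lme <- matrix(NA_real_, length(subjects), length(config$models),
                dimnames = list(subjects, config$models))
  for (s in seq_along(subjects)) {
    sub <- cohort$trials[cohort$trials$subject == subjects[s], ]
    for (m in config$models) {
      fit <- fit_map(sub$u, sub$response, model = m,
                     priors = model_priors(m, config$prior_preset_selection),
                     opponent = sub$opponent, n_starts = config$n_starts,
                     seed = derive_seed(config$seed, 1000L + s))
      lme[s, m] <- fit$log_model_evidence
    }
  }
  write.csv(data.frame(subject = subjects, lme),
            file.path(config$out_dir, "log_evidence.csv"), row.names = FALSE)
  log_line("stage fit: %d subjects x %d models", length(subjects),
           length(config$models))

  # stage 3: model selection
  bms <- random_effects_bms(lme, seed = derive_seed(config$seed, 2L))
  winner <- names(which.max(bms$exceedance_prob))
  jsonlite::write_json(
    list(alpha = bms$alpha, expected_freq = bms$expected_freq,
         exceedance_prob = bms$exceedance_prob, winner = winner),
    file.path(config$out_dir, "bms.json"), auto_unbox = TRUE, digits = NA)
  log_line("stage bms: winner '%s' (xp = %.3f)", winner,
           max(bms$exceedance_prob))

  # stage 4: winner refit with wide priors, per condition; exclusions;
  # high-vs-low contrasts on the learning parameters
  keep_missing <- exclude_missing(cohort$trials, config$max_missing_fraction)
  summaries <- NULL
  for (s in subjects[keep_missing[subjects]]) {
    sub <- cohort$trials[cohort$trials$subject == s, ]
    fits <- fit_by_condition(sub, model = winner,
                             priors = model_priors(
                               winner, config$prior_preset_winner),
                             n_starts = config$n_starts,
                             seed = derive_seed(config$seed, 3L))
    sm <- summarize_conditions(fits)
    sm$subject <- s
    summaries <- rbind(summaries, sm)
  }
  wide_par <- merge(
    summaries[summaries$condition == "high",
              c("subject", "omega", "zeta", "mean_mu2", "mean_sigma2",
                "mean_epsilon")],
    summaries[summaries$condition == "low",
              c("subject", "omega", "zeta", "mean_mu2", "mean_sigma2",
                "mean_epsilon")],
    by = "subject", suffixes = c("_high", "_low"))
  keep_par <- exclude_param_outliers(wide_par, k_sd = config$k_sd)
  wide_par <- wide_par[keep_par[wide_par$subject], , drop = FALSE]
  write.csv(summaries, file.path(config$out_dir, "condition_summaries.csv"),
            row.names = FALSE)
  contrasts <- list()
  par_map <- c(omega = "omega", mu = "mean_mu2", sigma = "mean_sigma2",
               epsilon = "mean_epsilon", zeta = "zeta")
  for (pn in names(par_map)) {
    tt <- paired_t(wide_par[[paste0(par_map[[pn]], "_high")]],
                   wide_par[[paste0(par_map[[pn]], "_low")]])
    contrasts[[pn]] <- list(t = tt$statistic, df = tt$df, p = tt$p_value,
                            bf10 = tt$bf10,
                            significant_both = significant_both(tt$p_value,
                                                                tt$bf10))
  }
  jsonlite::write_json(contrasts, file.path(config$out_dir, "contrasts.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("stage conditions: %d subjects retained", nrow(wide_par))

  # stage 5: MIMIC SEM of the latent trait on high-threat parameters
  sem_data <- merge(cohort$questionnaires, data.frame(
    subject = wide_par$subject, omega = wide_par$omega_high,
    mu = wide_par$mean_mu2_high, sigma = wide_par$mean_sigma2_high,
    epsilon = wide_par$mean_epsilon_high, zeta = wide_par$zeta_high),
    by = "subject")
  model <- sem_model(config$sem_syntax)
  sem_fit <- tryCatch(
    fit_ml_sem(sem_data, model, n_starts = 3L,
               seed = derive_seed(config$seed, 4L)),
    error = function(e) e)
  if (inherits(sem_fit, "error")) {
    stop_hex("pipeline_error", "stage sem: %s", conditionMessage(sem_fit))
  }
  gt <- sem_fit$standardized$gamma_table
  jsonlite::write_json(
    list(chi_square = sem_fit$chi_square, df = sem_fit$df,
         p_value = sem_fit$p_value, cfi = sem_fit$cfi, rmsea = sem_fit$rmsea,
         srmr = sem_fit$srmr, paths = gt),
    file.path(config$out_dir, "sem.json"), auto_unbox = TRUE, digits = NA)
  log_line("stage sem: chi2(%d) = %.2f, CFI = %.3f", sem_fit$df,
           sem_fit$chi_square, sem_fit$cfi)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hexlearn")),
    master_seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, 1L),
                       bms = derive_seed(config$seed, 2L),
                       condition_fits = derive_seed(config$seed, 3L),
                       sem = derive_seed(config$seed, 4L)),
    config = unclass(config),
    n_subjects_retained = nrow(wide_par),
    winner = winner)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- c(
    "# Pipeline report", "",
    sprintf("- Subjects simulated: %d; retained after exclusions: %d",
            config$n_subjects, nrow(wide_par)),
    sprintf("- Model selection winner: **%s** (exceedance probability %.3f)",
            winner, max(bms$exceedance_prob)),
    "", "## High vs low threat contrasts", "",
    "| parameter | t | p | BF10 | significant (both) |",
    "|---|---|---|---|---|",
    vapply(names(contrasts), function(pn) {
      cc <- contrasts[[pn]]
      sprintf("| %s | %.2f | %.3g | %.3g | %s |", pn, cc$t, cc$p, cc$bf10,
              cc$significant_both)
    }, character(1)),
    "", "## SEM (high-threat parameters)", "",
    sprintf("chi2(%d) = %.3f, p = %.3f, CFI = %.3f, RMSEA = %.3f, SRMR = %.3f",
            sem_fit$df, sem_fit$chi_square, sem_fit$p_value, sem_fit$cfi,
            sem_fit$rmsea, sem_fit$srmr))
  writeLines(report, file.path(config$out_dir, "report.md"))

  invisible(list(cohort = cohort, lme = lme, bms = bms, summaries = summaries,
                 retained = wide_par, contrasts = contrasts, sem = sem_fit,
                 manifest = manifest))
}
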