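#' Population specification for synthetic cohorts
#'
#' Describes the generative world for a cohort of learning agents: a bivariate
#' standard-normal latent trait (aggression and psychopathy, correlated 0.639
#' by default), agent parameters as population mean + trait coupling + noise,
#' questionnaire subscales as linear factor indicators of the traits, and
#' completely-at-random missing responses.
#'
#' Parameter defaults state the emulated conditions once: volatility
#' `omega` centred on -3.2 under low threat with a +0.8 shift under high
#' threat (the published direction; magnitude unprinted), between-subject SD
#' 0.7, trait-to-omega coupling -0.3 per trait SD; exploration `zeta`
#' log-normal around 2 with no trait coupling; initial beliefs `mu2_0` and
#' `log sigma2_0` positively coupled to the trait (the indirect route by which
#' mean belief and uncertainty track the trait); 2% missing responses.
#'
#' @param n_subjects Number of agents.
#' @param seed Master seed.
#' @param model Generating observer model (default `"hgf2"`).
#' @param schedule A `hex_schedule` (default: the published 160-trial design).
#' @param trait_cor Correlation between the aggression and psychopathy traits.
#' @param omega_mean_low,omega_cond_effect,omega_sd Population location of
#'   `omega` under low threat, the high-threat shift, and the between-subject
#'   SD.
#' @param coupling_omega,coupling_mu0,coupling_lsigma0,coupling_zeta Trait
#'   couplings (per trait SD) into `omega`, `mu2_0`, `log sigma2_0`, and
#'   `log zeta`.
#' @param zeta_meanlog,zeta_sdlog Log-normal population distribution of
#'   `zeta`.
#' @param missing_rate MCAR missing-response probability.
#' @param counterbalance Alternate the threat-phase assignment across
#'   subjects (even subjects see the schedule's threat labels, odd subjects
#'   the swapped ones). The two condition streams necessarily traverse
#'   slightly different outcome sequences; counterbalancing cancels that
#'   structural asymmetry in group-level condition contrasts (default
#'   `TRUE`).
#' @param bpaq_loadings,srp_loadings Standardised loadings of the four
#'   aggression and four psychopathy subscales on their traits.
#' @return Object of class `hex_population_spec` (a validated list).
#' @export
population_spec <- function(n_subjects = 200L, seed = 1L, model = "hgf2",
                            schedule = build_schedule(),
                            trait_cor = 0.639,
                            omega_mean_low = -3.2, omega_cond_effect = 0.8,
                            omega_sd = 0.7,
                            coupling_omega = -0.3, coupling_mu0 = 0.5,
                            coupling_lsigma0 = 0.3, coupling_zeta = 0,
                            zeta_meanlog = log(2), zeta_sdlog = 0.4,
                            missing_rate = 0.02,
                            counterbalance = TRUE,
                            bpaq_loadings = c(physical = 0.80, verbal = 0.62,
                                              anger = 0.74, hostility = 0.86),
                            srp_loadings = c(ipm = 0.85, ca = 0.75,
                                             els = 0.70, ct = 0.60)) {
  if (omega_sd <= 0 || zeta_sdlog <= 0) {
    stop_hex("specification_error", "population SDs must be > 0")
  }
  if (abs(trait_cor) >= 1) {
    stop_hex("specification_error", "trait correlation must be in (-1, 1)")
  }
  if (any(abs(c(bpaq_loadings, srp_loadings)) >= 1)) {
    stop_hex("specification_error",
             "standardised loadings must have magnitude < 1")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_hex("specification_error", "missing_rate must be in [0, 1)")
  }
  structure(as.list(environment()), class = "hex_population_spec")
}

# simulate one subject whose parameters differ by threat condition: each
# condition's trial subsequence is filtered independently (mirroring how the
# per-condition fits split the data), per-opponent streams preserved
.simulate_subject <- function(schedule, u, model, params_by_cond, seed,
                              missing_rate) {
  out <- data.frame(trial = schedule$trial, opponent = schedule$opponent,
                    threat = schedule$threat, p_gun = schedule$p_gun,
                    u = as.integer(u), p_shoot = NA_real_,
                    response = NA_character_, stringsAsFactors = FALSE)
  for (cc in c("high", "low")) {
    idx <- which(schedule$threat == cc)
    pars <- params_by_cond[[cc]]
    traj <- filter_model(u[idx], model, pars,
                         opponent = schedule$opponent[idx])
    out$p_shoot[idx] <- response_prob(traj$mu1_hat, pars$zeta)
  }
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs), add = TRUE)
  set.seed(seed)
  shoot <- rbinom(nrow(out), 1L, out$p_shoot)
  out$response <- ifelse(shoot == 1L, "shoot", "withhold")
  if (missing_rate > 0) {
    out$response[runif(nrow(out)) < missing_rate] <- "missing"
  }
  out
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Draws latent traits, sets condition-specific agent parameters from the
#' population spec, simulates task responses trial by trial, generates
#' questionnaire subscale scores as `loading * trait + residual` (residual
#' variance `1 - loading^2`, so scores are standardised in the population),
#' and simulates face-judgement responses from a trait-linked hostility bias.
#' Everything is reproducible from the spec's master seed.
#'
#' @param spec A `hex_population_spec`.
#' @param include Which data tables to generate besides the truth table
#'   (dropping `"trials"` or `"hibt"` makes very large cohorts cheap when only
#'   the questionnaire structure is needed).
#' @return Object of class `hex_cohort`: list with data frames `trials`
#'   (tidy: subject, trial, opponent, p_gun, threat, u, response, ...),
#'   `questionnaires`, `hibt` (requested components only, others `NULL`), and
#'   `truth` (all generating parameters and traits, one row per subject).
#' @export
generate_cohort <- function(spec,
                            include = c("trials", "questionnaires", "hibt")) {
  stopifnot(inherits(spec, "hex_population_spec"))
  n <- spec$n_subjects
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs), add = TRUE)

  set.seed(derive_seed(spec$seed, 1L))
  Rt <- matrix(c(1, spec$trait_cor, spec$trait_cor, 1), 2)
  traits <- rmvnorm_chol(n, Rt)
  colnames(traits) <- c("aggression", "psychopathy")

  set.seed(derive_seed(spec$seed, 2L))
  omega_low <- spec$omega_mean_low + spec$coupling_omega * traits[, 1] +
    rnorm(n, 0, spec$omega_sd)
  omega_high <- omega_low + spec$omega_cond_effect
  zeta <- exp(spec$zeta_meanlog + spec$coupling_zeta * traits[, 1] +
                rnorm(n, 0, spec$zeta_sdlog))
  mu2_0 <- spec$coupling_mu0 * traits[, 1]
  sigma2_0 <- exp(spec$coupling_lsigma0 * traits[, 1])

  sched_flip <- spec$schedule
  sched_flip$threat <- ifelse(sched_flip$threat == "high", "low", "high")

  trials <- if ("trials" %in% include) vector("list", n) else NULL
  for (i in if (is.null(trials)) integer() else seq_len(n)) {
    sched_i <- if (spec$counterbalance && i %% 2L == 1L) sched_flip
               else spec$schedule
    u <- sample_outcomes(sched_i, seed = derive_seed(spec$seed, 100L + i))
    pars <- list(
      high = list(omega = omega_high[i], zeta = zeta[i], mu2_0 = mu2_0[i],
                  sigma2_0 = sigma2_0[i]),
      low = list(omega = omega_low[i], zeta = zeta[i], mu2_0 = mu2_0[i],
                 sigma2_0 = sigma2_0[i])
    )
    if (spec$model != "hgf2") {
      # non-HGF generators share zeta; remaining parameters come from the
      # model's prior-mean defaults shifted by the trait coupling on omega
      pars <- lapply(pars, function(p) {
        base <- switch(spec$model,
          rw = list(alpha = unit_sigmoid(-1 + 0.3 * (p$omega + 3))),
          k1 = list(mu_meta = 0.05, beta0 = -2),
          kalman = list(q = exp(p$omega), r_obs = 0.25),
          hgf3 = list(omega2 = p$omega, theta = -6, kappa = 1),
          stop_hex("configuration_error", "unknown model '%s'", spec$model))
        c(base, list(zeta = p$zeta))
      })
    }
    trials[[i]] <- cbind(subject = sprintf("s%03d", i),
                         .simulate_subject(sched_i, u, spec$model, pars,
                                           derive_seed(spec$seed, 200L + i),
                                           spec$missing_rate))
  }
  if (!is.null(trials)) trials <- do.call(rbind, trials)

  set.seed(derive_seed(spec$seed, 3L))
  q_item <- function(lam, trait) lam * trait + rnorm(n, 0, sqrt(1 - lam^2))
  questionnaires <- data.frame(
    subject = sprintf("s%03d", seq_len(n)),
    bpaq_physical = q_item(spec$bpaq_loadings[["physical"]], traits[, 1]),
    bpaq_verbal = q_item(spec$bpaq_loadings[["verbal"]], traits[, 1]),
    bpaq_anger = q_item(spec$bpaq_loadings[["anger"]], traits[, 1]),
    bpaq_hostility = q_item(spec$bpaq_loadings[["hostility"]], traits[, 1]),
    srp_ipm = q_item(spec$srp_loadings[["ipm"]], traits[, 2]),
    srp_ca = q_item(spec$srp_loadings[["ca"]], traits[, 2]),
    srp_els = q_item(spec$srp_loadings[["els"]], traits[, 2]),
    srp_ct = q_item(spec$srp_loadings[["ct"]], traits[, 2]),
    wsap_hostile = q_item(0.30, traits[, 2]),
    spsrq_punishment = q_item(-0.20, traits[, 2]),
    spsrq_reward = q_item(0.15, traits[, 2]),
    risq = q_item(0.25, traits[, 2]),
    stringsAsFactors = FALSE
  )

  hibt <- NULL
  if ("hibt" %in% include) {
    design <- build_hibt_design(seed = derive_seed(spec$seed, 4L))
    hibt <- generate_hibt_responses(0.4 * traits[, 1], design,
                                    seed = derive_seed(spec$seed, 5L))
  }
  if (!"questionnaires" %in% include) questionnaires <- NULL

  truth <- data.frame(subject = sprintf("s%03d", seq_len(n)),
                      trait_aggression = traits[, 1],
                      trait_psychopathy = traits[, 2],
                      omega_high = omega_high, omega_low = omega_low,
                      zeta = zeta, mu2_0 = mu2_0, sigma2_0 = sigma2_0,
                      stringsAsFactors = FALSE)
  structure(list(trials = trials, questionnaires = questionnaires,
                 hibt = hibt, truth = truth, spec = spec),
            class = "hex_cohort")
}

#' @export
print.hex_cohort <- function(x, ...) {
  nt <- if (is.null(x$trials)) 0L else nrow(x$trials) / nrow(x$truth)
  cat(sprintf("Synthetic cohort: %d subjects, %d trials each (model '%s')\n",
              nrow(x$truth), nt, x$spec$model))
  invisible(x)
}

#' Simulate face-judgement (hostile/not-hostile) responses
#'
#' `P(hostile) = logistic(b0_e + b1_e * intensity + bias_i)` with
#' emotion-specific intercepts and slopes; by default the intensity slope
#' orders anger > disgust > fear > joy (joy negative), and neutral faces use
#' an intercept-only rate.
#'
#' @param bias Numeric vector of per-subject hostility biases (log-odds
#'   shift).
#' @param design A `hex_hibt_design`.
#' @param seed Integer seed.
#' @param intercepts,slopes Named numeric vectors per emotion (intensity is
#'   scaled to `[0.2, 1]`).
#' @return Data frame with columns `subject`, `trial`, `emotion`, `intensity`,
#'   `is_practice`, `p_hostile`, `hostile` (0/1).
#' @export
generate_hibt_responses <- function(bias, design, seed = 1L,
                                    intercepts = c(anger = -1.0,
                                                   disgust = -1.6,
                                                   fear = -2.0, joy = -0.6,
                                                   neutral = -1.5),
                                    slopes = c(anger = 4.0, disgust = 3.0,
                                               fear = 2.0, joy = -2.0,
                                               neutral = 0)) {
  stopifnot(inherits(design, "hex_hibt_design"))
  n <- length(bias)
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs), add = TRUE)
  set.seed(seed)
  intensity01 <- ifelse(is.na(design$intensity), 0, design$intensity / 100)
  eta_design <- intercepts[design$emotion] + slopes[design$emotion] * intensity01
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- unit_sigmoid(eta_design + bias[i])
    out[[i]] <- data.frame(subject = sprintf("s%03d", i),
                           trial = design$trial, emotion = design$emotion,
                           intensity = design$intensity,
                           is_practice = design$is_practice,
                           p_hostile = p,
                           hostile = rbinom(length(p), 1L, p),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Default predictor correlation matrix for direct MIMIC cohorts
#'
#' The published standardised path magnitudes imply `B' R B > 1` for
#' independent predictors, so a unit-variance latent requires correlated
#' predictors; this frozen matrix is one admissible choice (positive
#' definite, `B' R B < 1` for the published coefficient pattern).
#'
#' @return A 5x5 correlation matrix over `omega`, `mu`, `sigma`, `epsilon`,
#'   `zeta`.
#' @export
mimic_predictor_corr <- function() {
  nm <- c("omega", "mu", "sigma", "epsilon", "zeta")
  R <- diag(5)
  R[1, 2] <- R[2, 1] <- 0.3    # omega-mu
  R[1, 4] <- R[4, 1] <- 0.3    # omega-epsilon
  R[2, 3] <- R[3, 2] <- -0.3   # mu-sigma
  R[2, 4] <- R[4, 2] <- -0.4   # mu-epsilon
  R[3, 4] <- R[4, 3] <- -0.3   # sigma-epsilon
  dimnames(R) <- list(nm, nm)
  R
}

#' Generate a cohort directly from a MIMIC model
#'
#' Draws the five predictor variables from a multivariate normal with the
#' given correlation matrix, sets the latent trait to
#' `sum(b * x) + residual` with residual variance `1 - b' R b` (so the latent
#' has unit variance and `b` are the true standardised structural
#' coefficients), and generates the four indicators as
#' `loading * trait + residual`.
#'
#' @param n Number of subjects.
#' @param b Named standardised structural coefficients for `omega`, `mu`,
#'   `sigma`, `epsilon`, `zeta` (default: the published aggression-model
#'   pattern).
#' @param loadings Standardised indicator loadings (length 4).
#' @param predictor_corr Predictor correlation matrix (default
#'   [mimic_predictor_corr()]).
#' @param seed Integer seed.
#' @return Data frame with predictors, indicators `ind1..ind4`, and the true
#'   `trait`; the true coefficient vector is kept as attribute `b_true`.
#' @export
generate_mimic_cohort <- function(n, b = c(omega = -0.24, mu = 0.72,
                                           sigma = 0.45, epsilon = 0.78,
                                           zeta = -0.01),
                                  loadings = c(0.80, 0.62, 0.74, 0.86),
                                  predictor_corr = mimic_predictor_corr(),
                                  seed = 1L) {
  R <- as.matrix(predictor_corr)
  stopifnot(length(b) == ncol(R), all(abs(loadings) < 1))
  psi <- 1 - drop(t(b) %*% R %*% b)
  if (psi <= 0) {
    stop_hex("specification_error",
             "coefficients imply non-positive latent residual variance (%.3f)",
             psi)
  }
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs), add = TRUE)
  set.seed(seed)
  X <- rmvnorm_chol(n, R)
  colnames(X) <- colnames(R)
  trait <- drop(X %*% b) + rnorm(n, 0, sqrt(psi))
  inds <- vapply(loadings, function(l) l * trait + rnorm(n, 0, sqrt(1 - l^2)),
                 numeric(n))
  colnames(inds) <- paste0("ind", seq_along(loadings))
  out <- data.frame(X, inds, trait = trait)
  attr(out, "b_true") <- b
  attr(out, "psi_true") <- psi
  out
}

#' Compare pipeline outputs against a cohort's ground truth
#'
#' Collects recovery diagnostics for whichever pipeline outputs are supplied:
#' correlation between true and fitted parameters, the model-selection winner
#' versus the generating model, condition contrasts flagged by the
#' dual-criterion rule versus the true condition effect, and the sign pattern
#' of fitted SEM paths versus the generating couplings.
#'
#' @param cohort A `hex_cohort`.
#' @param fitted_params Optional data frame with `subject` plus fitted
#'   `omega_high`, `omega_low`, `zeta` columns.
#' @param bms Optional `hex_bms` result with the generating model among the
#'   columns.
#' @param condition_tests Optional named list of `hex_test` objects for
#'   high-vs-low contrasts of the learning parameters.
#' @param sem_fit Optional `hex_sem_fit` with a trait regressed on learning
#'   parameters.
#' @return List of class `hex_recovery_report`: per-check entries with
#'   observed values and a logical `pass`.
#' @export
end_to_end_truth_check <- function(cohort, fitted_params = NULL, bms = NULL,
                                   condition_tests = NULL, sem_fit = NULL) {
  stopifnot(inherits(cohort, "hex_cohort"))
  checks <- list()
  truth <- cohort$truth
  if (!is.null(fitted_params)) {
    m <- merge(truth, fitted_params, by = "subject",
               suffixes = c("_true", "_fit"))
    for (par in c("omega_high", "omega_low", "zeta")) {
      tc <- paste0(par, "_true"); fc <- paste0(par, "_fit")
      if (all(c(tc, fc) %in% names(m))) {
        r <- cor(m[[tc]], m[[fc]])
        checks[[paste0("recovery_", par)]] <-
          list(value = r, pass = r >= if (par == "zeta") 0.5 else 0.6)
      }
    }
  }
  if (!is.null(bms)) {
    winner <- names(which.max(bms$exceedance_prob))
    checks$model_identity <- list(value = winner,
                                  pass = identical(winner, cohort$spec$model))
  }
  if (!is.null(condition_tests)) {
    true_effect <- cohort$spec$omega_cond_effect != 0
    flagged <- vapply(condition_tests, function(tt) {
      isTRUE(significant_both(tt$p_value, tt$bf10))
    }, logical(1))
    checks$condition_contrasts <- list(
      value = flagged,
      pass = if (true_effect) any(flagged) else !any(flagged))
  }
  if (!is.null(sem_fit) && !is.null(sem_fit$standardized$gamma_table)) {
    gt <- sem_fit$standardized$gamma_table
    expected_sign <- c(omega = -1, mu = 1, sigma = 1, epsilon = 1)
    hits <- vapply(names(expected_sign), function(pr) {
      row <- gt[gt$predictor == pr, , drop = FALSE]
      nrow(row) == 1 && sign(row$std) == expected_sign[[pr]]
    }, logical(1))
    checks$sem_signs <- list(value = hits, pass = all(hits))
  }
  structure(checks, class = "hex_recovery_report")
}

#' @export
print.hex_recovery_report <- function(x, ...) {
  for (nm in names(x)) {
    v <- x[[nm]]$value
    cat(sprintf("%-24s %s (%s)\n", nm,
                if (x[[nm]]$pass) "PASS" else "FAIL",
                paste(format(v, digits = 3), collapse = ", ")))
  }
  invisible(x)
}
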