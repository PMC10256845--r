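# Per-model estimation-space layout. Free parameters are estimated on an
# unconstrained scale (log / logit for positives and unit-interval rates);
# everything else is a fixed constant configurable through the prior object.
.MODEL_SPEC <- list(
  hgf2 = list(
    est_names = c("omega", "log_zeta"),
    fixed = list(mu2_0 = 0, sigma2_0 = 1),
    to_native = function(est, fixed) {
      c(list(omega = unname(est["omega"]),
             zeta = exp(unname(est["log_zeta"]))), fixed)
    },
    priors = list(
      default = list(mean = c(omega = -3, log_zeta = 0),
                     sd = c(omega = 2, log_zeta = 1)),
      wide = list(mean = c(omega = -3, log_zeta = 0),
                  sd = c(omega = 4, log_zeta = 2))
    )
  ),
  hgf3 = list(
    est_names = c("omega2", "theta", "log_zeta"),
    fixed = list(kappa = 1, mu2_0 = 0, sigma2_0 = 1, mu3_0 = 1, sigma3_0 = 1),
    to_native = function(est, fixed) {
      c(list(omega2 = unname(est["omega2"]), theta = unname(est["theta"]),
             zeta = exp(unname(est["log_zeta"]))), fixed)
    },
    priors = list(
      default = list(mean = c(omega2 = -3, theta = -6, log_zeta = 0),
                     sd = c(omega2 = 2, theta = 2, log_zeta = 1)),
      wide = list(mean = c(omega2 = -3, theta = -6, log_zeta = 0),
                  sd = c(omega2 = 4, theta = 4, log_zeta = 2))
    )
  ),
  rw = list(
    est_names = c("logit_alpha", "log_zeta"),
    fixed = list(v0 = 0.5),
    to_native = function(est, fixed) {
      c(list(alpha = unit_sigmoid(unname(est["logit_alpha"])),
             zeta = exp(unname(est["log_zeta"]))), fixed)
    },
    priors = list(
      default = list(mean = c(logit_alpha = -1, log_zeta = 0),
                     sd = c(logit_alpha = 1, log_zeta = 1)),
      wide = list(mean = c(logit_alpha = -1, log_zeta = 0),
                  sd = c(logit_alpha = 2, log_zeta = 2))
    )
  ),
  k1 = list(
    est_names = c("log_mu_meta", "beta0", "log_zeta"),
    fixed = list(v0 = 0.5),
    to_native = function(est, fixed) {
      c(list(mu_meta = exp(unname(est["log_mu_meta"])),
             beta0 = unname(est["beta0"]),
             zeta = exp(unname(est["log_zeta"]))), fixed)
    },
    priors = list(
      default = list(mean = c(log_mu_meta = -3, beta0 = -2, log_zeta = 0),
                     sd = c(log_mu_meta = 1, beta0 = 1, log_zeta = 1)),
      wide = list(mean = c(log_mu_meta = -3, beta0 = -2, log_zeta = 0),
                  sd = c(log_mu_meta = 2, beta0 = 2, log_zeta = 2))
    )
  ),
  kalman = list(
    est_names = c("log_q", "log_r_obs", "log_zeta"),
    fixed = list(v0 = 0.5, s0 = 1),
    to_native = function(est, fixed) {
      c(list(q = exp(unname(est["log_q"])),
             r_obs = exp(unname(est["log_r_obs"])),
             zeta = exp(unname(est["log_zeta"]))), fixed)
    },
    priors = list(
      default = list(mean = c(log_q = -4, log_r_obs = -1.4, log_zeta = 0),
                     sd = c(log_q = 1.5, log_r_obs = 1, log_zeta = 1)),
      wide = list(mean = c(log_q = -4, log_r_obs = -1.4, log_zeta = 0),
                  sd = c(log_q = 3, log_r_obs = 2, log_zeta = 2))
    )
  )
)

#' Gaussian priors for model fitting
#'
#' Returns the estimation-space Gaussian prior (mean and standard deviation
#' per free parameter) for a model, together with the model's fixed constants.
#' Two presets are available: `"default"` (moderately informative, used during
#' model comparison) and `"wide"` (broader, used to refit the winning model so
#' individual differences are less shrunk). The exact wide-prior values used
#' in the original toolbox analysis are not published; these presets are
#' documented surrogates and fully configurable.
#'
#' @param model Model identifier.
#' @param preset `"default"` or `"wide"`.
#' @param mean,sd Optional named vectors overriding individual prior entries.
#' @param fixed Optional named list overriding fixed constants (e.g.
#'   `mu2_0`).
#' @return Object of class `hex_priors`.
#' @export
model_priors <- function(model, preset = c("default", "wide"),
                         mean = NULL, sd = NULL, fixed = NULL) {
  preset <- match.arg(preset)
  spec <- .MODEL_SPEC[[model]]
  if (is.null(spec)) stop_hex("configuration_error", "unknown model '%s'", model)
  pr <- spec$priors[[preset]]
  if (!is.null(mean)) pr$mean[names(mean)] <- mean
  if (!is.null(sd)) pr$sd[names(sd)] <- sd
  if (any(pr$sd <= 0)) stop_hex("configuration_error", "prior sds must be > 0")
  fx <- spec$fixed
  if (!is.null(fixed)) fx <- modifyList(fx, fixed)
  structure(list(model = model, preset = preset, mean = pr$mean, sd = pr$sd,
                 fixed = fx), class = "hex_priors")
}

#' Encode shoot/withhold/missing responses as 1/0/NA
#'
#' @param response Character vector (`"shoot"`, `"withhold"`, `"missing"`),
#'   or a numeric vector already coded 1/0/NA (returned unchanged).
#' @return Integer vector with `NA` for missing responses.
#' @export
encode_responses <- function(response) {
  if (is.numeric(response)) return(as.integer(response))
  r <- rep(NA_integer_, length(response))
  r[response == "shoot"] <- 1L
  r[response == "withhold"] <- 0L
  bad <- !(response %in% c("shoot", "withhold", "missing", NA))
  if (any(bad)) {
    stop_hex("validation_error", "unknown response label '%s'",
             response[bad][1])
  }
  r
}

#' Negative log joint density of responses and parameters
#'
#' The MAP objective: minus the Bernoulli response log-likelihood under the
#' model's trial-wise shoot probabilities, minus the Gaussian log prior over
#' the estimation-space parameters (normalisation constants included).
#' Missing responses are skipped in the likelihood.
#'
#' @param est Named estimation-space parameter vector.
#' @param u Outcome sequence.
#' @param responses Responses coded 1/0/NA (see [encode_responses()]).
#' @param model Model identifier.
#' @param priors A `hex_priors` object.
#' @param opponent Optional opponent labels (per-opponent belief streams).
#' @param pool_opponents Single pooled stream if `TRUE`.
#' @return Scalar objective value (finite at interior points).
#' @export
neg_log_joint <- function(est, u, responses, model, priors, opponent = NULL,
                          pool_opponents = FALSE) {
  responses <- encode_responses(responses)
  if (length(responses) && all(is.na(responses))) {
    stop_hex("insufficient_data", "all responses missing")
  }
  spec <- .MODEL_SPEC[[model]]
  native <- spec$to_native(est, priors$fixed)
  ll <- 0
  if (length(u)) {
    mu1_hat <- .mu1hat(u, opponent, model, native, pool_opponents)
    p <- response_prob(mu1_hat, native$zeta)
    obs <- !is.na(responses)
    ll <- sum(responses[obs] * log(p[obs]) +
                (1 - responses[obs]) * log1p(-p[obs]))
  }
  lp <- sum(dnorm(est[names(priors$mean)], priors$mean, priors$sd, log = TRUE))
  -(ll + lp)
}

.nearest_pd <- function(h, eps = 1e-8) {
  e <- eigen((h + t(h)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
}

#' Fit a model to one subject by MAP with Laplace model evidence
#'
#' Multi-start quasi-Newton (BFGS) minimisation of [neg_log_joint()] in the
#' unconstrained estimation space; the best optimum is retained. The log model
#' evidence is the Laplace approximation
#' `-obj_min + (d/2) log(2*pi) - 0.5 * log|H|` with `H` the numerical Hessian
#' at the optimum (replaced by the nearest positive-definite matrix, with a
#' flag, if needed).
#'
#' @param u Outcome sequence.
#' @param responses Responses (`"shoot"`/`"withhold"`/`"missing"` or 1/0/NA).
#' @param model Model identifier.
#' @param priors A `hex_priors` object (default: the model's `"default"`
#'   preset).
#' @param opponent Opponent labels for per-opponent belief streams.
#' @param n_starts Number of jittered starts around the prior mean.
#' @param seed Seed controlling the start jitter.
#' @param fix Optional named vector of estimation-space parameters to hold
#'   fixed (excluded from optimisation and from the Laplace dimension).
#' @param pool_opponents Single pooled stream if `TRUE`.
#' @param min_trials Minimum number of non-missing trials required.
#' @return Object of class `hex_fit` with elements `model`, `estimates`
#'   (native space), `est` (estimation space), `log_model_evidence`,
#'   `hessian_log_det`, `n_starts_converged`, `objective`, `flags`, and
#'   `trajectory` (with per-trial `p_shoot`).
#' @export
fit_map <- function(u, responses, model = "hgf2",
                    priors = model_priors(model), opponent = NULL,
                    n_starts = 8L, seed = 1L, fix = NULL,
                    pool_opponents = FALSE, min_trials = 10L) {
  responses <- encode_responses(responses)
  n_obs <- sum(!is.na(responses))
  if (n_obs < min_trials) {
    stop_hex("insufficient_data",
             "only %d non-missing trials (need >= %d)", n_obs, min_trials)
  }
  spec <- .MODEL_SPEC[[model]]
  if (is.null(spec)) stop_hex("configuration_error", "unknown model '%s'", model)
  free <- setdiff(spec$est_names, names(fix))
  if (!length(free)) stop_hex("configuration_error", "no free parameters")

  obj <- function(th) {
    est <- c(setNames(th, free), fix)[spec$est_names]
    names(est) <- spec$est_names
    v <- tryCatch(neg_log_joint(est, u, responses, model, priors,
                                opponent = opponent,
                                pool_opponents = pool_opponents),
                  error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }

  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs), add = TRUE)
  set.seed(seed)
  pm <- priors$mean[free]
  ps <- priors$sd[free]
  starts <- matrix(rep(pm, n_starts), nrow = n_starts, byrow = TRUE)
  if (n_starts > 1) {
    jit <- matrix(rnorm((n_starts - 1) * length(free)), n_starts - 1)
    starts[-1, ] <- starts[-1, , drop = FALSE] + jit * rep(ps, each = n_starts - 1)
  }

  best <- NULL
  n_conv <- 0L
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      optim(starts[i, ], obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || n_conv == 0L) {
    stop_hex("optimization_failure",
             "no start converged for model '%s' (%d starts)", model, n_starts)
  }

  flags <- character()
  h <- tryCatch(optimHess(best$par, obj), error = function(e) NULL)
  if (is.null(h) || !all(is.finite(h))) {
    h <- diag(1, length(free))
    flags <- c(flags, "hessian_failed")
  }
  ev <- eigen((h + t(h)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    h <- .nearest_pd(h)
    flags <- c(flags, "hessian_not_pd")
  }
  log_det_h <- determinant(h, logarithm = TRUE)$modulus[1]
  d <- length(free)
  lme <- -best$value + (d / 2) * log(2 * pi) - 0.5 * log_det_h

  est_full <- c(setNames(best$par, free), fix)[spec$est_names]
  names(est_full) <- spec$est_names
  # flag boundary-like zeta (deterministic responding regime)
  if ("log_zeta" %in% free &&
      est_full["log_zeta"] > priors$mean["log_zeta"] + 3 * priors$sd["log_zeta"]) {
    flags <- c(flags, "zeta_upper_region")
  }
  native <- spec$to_native(est_full, priors$fixed)
  traj <- filter_model(u, model, native, opponent = opponent,
                       pool_opponents = pool_opponents)
  traj$p_shoot <- response_prob(traj$mu1_hat, native$zeta)
  traj$response <- responses

  structure(list(model = model, estimates = native, est = est_full,
                 log_model_evidence = unname(lme),
                 hessian_log_det = unname(log_det_h),
                 n_starts_converged = n_conv, objective = best$value,
                 flags = flags, priors = priors, trajectory = traj,
                 n_trials = length(u), n_obs = n_obs),
            class = "hex_fit")
}

#' @export
print.hex_fit <- function(x, ...) {
  est <- x$estimates[!vapply(x$estimates, is.null, TRUE)]
  est <- est[names(est) %in% c("omega", "omega2", "theta", "kappa", "alpha",
                               "mu_meta", "beta0", "q", "r_obs", "zeta")]
  cat(sprintf("MAP fit, model '%s' (%d/%d trials observed)\n", x$model,
              x$n_obs, x$n_trials))
  cat("  ", paste(sprintf("%s = %.3f", names(est), unlist(est)),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  log model evidence (Laplace): %.2f\n", x$log_model_evidence))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a model separately to the high- and low-threat trials
#'
#' Splits a subject's trial table by threat label (preserving trial order and
#' per-opponent streams) and fits the model independently to each condition,
#' making the fitted parameters condition-specific.
#'
#' @param trials Data frame with columns `u`, `response`, `threat`, and
#'   `opponent` (one subject).
#' @param model Model identifier.
#' @param priors A `hex_priors` object.
#' @param ... Passed to [fit_map()].
#' @return List of class `hex_condition_fits` with elements `high` and `low`.
#' @export
fit_by_condition <- function(trials, model = "hgf2",
                             priors = model_priors(model), ...) {
  stopifnot(all(c("u", "response", "threat") %in% names(trials)))
  conds <- unique(trials$threat)
  if (!all(c("high", "low") %in% conds)) {
    stop_hex("insufficient_data",
             "both threat conditions must be present (found: %s)",
             paste(conds, collapse = ", "))
  }
  fits <- lapply(c(high = "high", low = "low"), function(cc) {
    sub <- trials[trials$threat == cc, , drop = FALSE]
    r <- encode_responses(sub$response)
    if (sum(!is.na(r)) < 10L) {
      stop_hex("insufficient_data",
               "condition '%s' has fewer than 10 non-missing trials", cc)
    }
    fit_map(sub$u, r, model = model, priors = priors,
            opponent = sub$opponent, ...)
  })
  structure(fits, class = "hex_condition_fits")
}

#' Summarise fitted trajectories by threat condition
#'
#' Per condition: the fitted `omega` and `zeta`, and the means over that
#' condition's trials of the second-level belief `mu2`, its variance `sigma2`,
#' and the signed precision-weighted prediction error `epsilon`.
#'
#' @param fits A `hex_condition_fits` object from [fit_by_condition()].
#' @return Data frame with one row per condition and columns `condition`,
#'   `omega`, `zeta`, `mean_mu2`, `mean_sigma2`, `mean_epsilon`.
#' @export
summarize_conditions <- function(fits) {
  stopifnot(inherits(fits, "hex_condition_fits"))
  rows <- lapply(names(fits), function(cc) {
    f <- fits[[cc]]
    tr <- f$trajectory
    data.frame(
      condition = cc,
      omega = if (!is.null(f$estimates$omega)) f$estimates$omega else NA_real_,
      zeta = f$estimates$zeta,
      mean_mu2 = if ("mu2" %in% names(tr)) mean(tr$mu2) else NA_real_,
      mean_sigma2 = if ("sigma2" %in% names(tr)) mean(tr$sigma2) else NA_real_,
      mean_epsilon = if ("epsilon" %in% names(tr)) mean(tr$epsilon) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Inclusion mask by missing-response fraction
#'
#' A subject is excluded iff their fraction of missing responses strictly
#' exceeds `max_missing_fraction` (default 0.25; a sensitivity reanalysis can
#' reinstate subjects by raising it, e.g. to 0.50).
#'
#' @param trials Data frame with columns `subject` and `response`.
#' @param max_missing_fraction Threshold in (0, 1).
#' @return Named logical vector (`TRUE` = keep), one entry per subject.
#' @export
exclude_missing <- function(trials, max_missing_fraction = 0.25) {
  stopifnot(max_missing_fraction > 0, max_missing_fraction < 1,
            all(c("subject", "response") %in% names(trials)))
  miss <- tapply(is.na(encode_responses(trials$response)),
                 trials$subject, mean)
  mask <- miss <= max_missing_fraction
  setNames(as.logical(mask), names(miss))
}

#' Inclusion mask by parameter outlyingness
#'
#' A subject is excluded iff any designated parameter lies outside
#' `mean +/- k_sd * SD`, with mean and SD computed once on the full sample
#' (single pass, no iteration). Zero-variance parameters are skipped with a
#' warning.
#'
#' @param params Data frame with a `subject` column and numeric parameter
#'   columns.
#' @param k_sd Cut-off in standard deviations (default 2).
#' @param columns Parameter columns to screen (default: all numeric columns).
#' @return Named logical vector (`TRUE` = keep).
#' @export
exclude_param_outliers <- function(params, k_sd = 2,
                                   columns = NULL) {
  stopifnot("subject" %in% names(params), k_sd > 0)
  if (nrow(params) < 3) {
    stop_hex("insufficient_data", "need at least 3 subjects")
  }
  if (is.null(columns)) {
    columns <- setdiff(names(params)[vapply(params, is.numeric, TRUE)],
                       "subject")
  }
  keep <- rep(TRUE, nrow(params))
  for (cl in columns) {
    x <- params[[cl]]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("parameter '%s' has zero variance; skipped", cl))
      next
    }
    m <- mean(x)
    keep <- keep & (x >= m - k_sd * s) & (x <= m + k_sd * s)
  }
  setNames(keep, params$subject)
}
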