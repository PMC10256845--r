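#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over subjects' log model evidences (Stephan
#' et al. 2009): posterior assignment weights
#' `g_nk` proportional to `exp(lme_nk + psi(alpha_k) - psi(sum(alpha)))` and
#' concentration updates `alpha_k = alpha0 + sum_n g_nk`, iterated to
#' convergence. Exceedance probabilities (the posterior probability that each
#' model is the most frequent in the population) are estimated by Monte-Carlo
#' sampling from the Dirichlet posterior.
#'
#' @param lme Numeric matrix of log model evidences, subjects in rows, models
#'   in columns (column names label the models).
#' @param alpha0 Prior Dirichlet concentration (default 1: uniform).
#' @param n_mc Number of Monte-Carlo draws for exceedance probabilities.
#' @param seed Seed for the Monte-Carlo step.
#' @param tol Convergence tolerance on `max |delta alpha|`.
#' @param max_iter Iteration cap.
#' @return Object of class `hex_bms`: list with `alpha`, `expected_freq`,
#'   `exceedance_prob`, `g` (subject-by-model assignment weights),
#'   `n_mc_samples`, `converged`, `n_iter`.
#' @export
random_effects_bms <- function(lme, alpha0 = 1, n_mc = 1e5, seed = 1L,
                               tol = 1e-6, max_iter = 1e4) {
  lme <- as.matrix(lme)
  if (!all(is.finite(lme))) stop_hex("validation_error", "lme must be finite")
  K <- ncol(lme)
  if (K < 2) stop_hex("validation_error", "need at least 2 models")
  if (alpha0 <= 0) stop_hex("configuration_error", "alpha0 must be > 0")
  models <- colnames(lme)
  if (is.null(models)) models <- paste0("model", seq_len(K))

  alpha <- rep(alpha0, K)
  converged <- FALSE
  g <- matrix(0, nrow(lme), K)
  for (it in seq_len(max_iter)) {
    w <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- w - apply(w, 1, max)
    g <- exp(w)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged) {
    stop_hex("convergence_error",
             "random-effects BMS did not converge in %d iterations", max_iter)
  }

  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs), add = TRUE)
  set.seed(seed)
  # Dirichlet draws via normalized gammas
  draws <- matrix(rgamma(n_mc * K, shape = rep(alpha, each = n_mc)), n_mc, K)
  winner <- max.col(draws, ties.method = "first")
  xp <- tabulate(winner, nbins = K) / n_mc

  structure(list(alpha = setNames(alpha, models),
                 expected_freq = setNames(alpha / sum(alpha), models),
                 exceedance_prob = setNames(xp, models),
                 g = g, n_mc_samples = as.integer(n_mc),
                 converged = converged, n_iter = it),
            class = "hex_bms")
}

#' @importFrom stats rgamma
#' @export
print.hex_bms <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  tab <- data.frame(alpha = round(x$alpha, 2),
                    expected_freq = round(x$expected_freq, 3),
                    exceedance_prob = round(x$exceedance_prob, 3))
  print(tab)
  invisible(x)
}

#' Fixed-effects model comparison (group log Bayes factors)
#'
#' Sums log evidences over subjects and re-centres the column sums on the best
#' model, giving group log Bayes factors relative to the winner (a diagnostic
#' companion to the random-effects analysis).
#'
#' @param lme Log-evidence matrix, subjects in rows.
#' @return Named numeric vector of log Bayes factors (0 for the best model,
#'   negative elsewhere).
#' @export
fixed_effects_bms <- function(lme) {
  lme <- as.matrix(lme)
  if (!all(is.finite(lme))) stop_hex("validation_error", "lme must be finite")
  s <- colSums(lme)
  s - max(s)
}
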