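#' Specify a structural equation model
#'
#' Small text grammar in the lavaan style, one statement per line or separated
#' by `;`:
#' \itemize{
#'   \item `factor =~ ind1 + ind2 + ind3` — measurement (loadings, all free);
#'   \item `factor ~ x1 + x2` — structural regression of a latent on observed
#'     covariates (MIMIC paths);
#'   \item `f1 ~~ f2` — free covariance between two latents.
#' }
#' Identification follows the unit-latent-variance convention: every latent's
#' (residual) variance is fixed to 1 and all loadings are free. Observed
#' covariates are treated as fixed exogenous variables (their covariance
#' matrix is set to the sample one and not counted as free moments).
#'
#' @param syntax Character scalar (or vector of statements).
#' @return Object of class `hex_sem_model`.
#' @examples
#' sem_model("agg =~ pa + va + an + ho
#'            agg ~ omega + mu + sigma + epsilon + zeta")
#' @export
sem_model <- function(syntax) {
  lines <- unlist(strsplit(paste(syntax, collapse = "\n"), "[\n;]"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  loadings <- list()   # latent -> indicators
  regressions <- list()# latent -> predictors
  covs <- list()       # pairs of latents
  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "=~", fixed = TRUE)[[1]]
      lat <- trimws(parts[1])
      inds <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
      loadings[[lat]] <- c(loadings[[lat]], inds)
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      covs[[length(covs) + 1L]] <- parts
    } else if (grepl("~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "~", fixed = TRUE)[[1]]
      lat <- trimws(parts[1])
      preds <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
      regressions[[lat]] <- c(regressions[[lat]], preds)
    } else {
      stop_hex("configuration_error", "cannot parse model line: '%s'", ln)
    }
  }
  if (!length(loadings)) {
    stop_hex("configuration_error", "model needs at least one '=~' statement")
  }
  latents <- names(loadings)
  indicators <- unique(unlist(loadings))
  predictors <- unique(unlist(regressions))
  if (length(intersect(indicators, predictors))) {
    stop_hex("configuration_error",
             "variables cannot be both indicator and predictor: %s",
             paste(intersect(indicators, predictors), collapse = ", "))
  }
  for (lat in names(regressions)) {
    if (!lat %in% latents) {
      stop_hex("configuration_error", "regression on unknown latent '%s'", lat)
    }
  }
  for (cv in covs) {
    if (!all(cv %in% latents)) {
      stop_hex("configuration_error", "covariance between unknown latents")
    }
  }
  structure(list(latents = latents, loadings = loadings,
                 regressions = regressions, covs = covs,
                 indicators = indicators, predictors = predictors,
                 syntax = paste(lines, collapse = "\n")),
            class = "hex_sem_model")
}

#' @export
print.hex_sem_model <- function(x, ...) {
  cat("SEM specification:\n")
  cat(paste(" ", strsplit(x$syntax, "\n")[[1]], collapse = "\n"), "\n")
  invisible(x)
}

# Parameter bookkeeping: free entries and their positions
.sem_layout <- function(model) {
  p <- length(model$indicators)
  m <- length(model$latents)
  q <- length(model$predictors)
  lam <- do.call(rbind, lapply(seq_along(model$latents), function(j) {
    inds <- model$loadings[[model$latents[j]]]
    cbind(i = match(inds, model$indicators), j = j)
  }))
  gam <- NULL
  if (q > 0) {
    gam <- do.call(rbind, lapply(names(model$regressions), function(lat) {
      preds <- model$regressions[[lat]]
      cbind(j = match(lat, model$latents), k = match(preds, model$predictors))
    }))
  }
  psi <- NULL
  if (length(model$covs)) {
    psi <- do.call(rbind, lapply(model$covs, function(cv) {
      idx <- sort(match(cv, model$latents))
      cbind(j1 = idx[1], j2 = idx[2])
    }))
  }
  n_free <- nrow(lam) + (if (is.null(gam)) 0 else nrow(gam)) + p +
    (if (is.null(psi)) 0 else nrow(psi))
  list(p = p, m = m, q = q, lam = lam, gam = gam, psi = psi, n_free = n_free)
}

# Assemble Lambda, Gamma, Psi, Theta from the unconstrained parameter vector:
# loadings and regressions native, residual variances log, latent covariances
# tanh (they are correlations under unit latent variance)
.sem_matrices <- function(theta, layout) {
  p <- layout$p; m <- layout$m; q <- layout$q
  idx <- 0
  L <- matrix(0, p, m)
  for (r in seq_len(nrow(layout$lam))) {
    idx <- idx + 1
    L[layout$lam[r, "i"], layout$lam[r, "j"]] <- theta[idx]
  }
  G <- matrix(0, m, max(q, 1))
  if (!is.null(layout$gam)) {
    for (r in seq_len(nrow(layout$gam))) {
      idx <- idx + 1
      G[layout$gam[r, "j"], layout$gam[r, "k"]] <- theta[idx]
    }
  }
  Th <- exp(theta[idx + seq_len(p)])
  idx <- idx + p
  Psi <- diag(1, m)
  if (!is.null(layout$psi)) {
    for (r in seq_len(nrow(layout$psi))) {
      idx <- idx + 1
      Psi[layout$psi[r, "j1"], layout$psi[r, "j2"]] <-
        Psi[layout$psi[r, "j2"], layout$psi[r, "j1"]] <- tanh(theta[idx])
    }
  }
  list(L = L, G = G, Th = Th, Psi = Psi)
}

# Model-implied covariance of (indicators, predictors)
.sem_implied <- function(mats, Phi) {
  L <- mats$L
  q <- if (is.null(Phi)) 0 else ncol(Phi)
  cov_eta <- mats$Psi
  if (q > 0) cov_eta <- cov_eta + mats$G[, seq_len(q), drop = FALSE] %*% Phi %*%
      t(mats$G[, seq_len(q), drop = FALSE])
  Syy <- L %*% cov_eta %*% t(L) + diag(mats$Th, length(mats$Th))
  if (q == 0) return(list(Sigma = Syy, cov_eta = cov_eta))
  Syx <- L %*% mats$G[, seq_len(q), drop = FALSE] %*% Phi
  Sigma <- rbind(cbind(Syy, Syx), cbind(t(Syx), Phi))
  list(Sigma = Sigma, cov_eta = cov_eta)
}

# analytic gradient of F_ML: dF = tr[ Sigma^-1 (Sigma - S) Sigma^-1 dSigma ],
# assembled per parameter class (loadings, regressions, log residual
# variances, tanh latent covariances)
.fml_grad <- function(theta, layout, Phi, S) {
  mats <- .sem_matrices(theta, layout)
  imp <- .sem_implied(mats, Phi)
  ch <- tryCatch(chol(imp$Sigma), error = function(e) NULL)
  if (is.null(ch)) return(rep(0, length(theta)))
  Sinv <- chol2inv(ch)
  W <- Sinv - Sinv %*% S %*% Sinv
  p <- layout$p; q <- layout$q
  yi <- seq_len(p)
  Wyy <- W[yi, yi, drop = FALSE]
  L <- mats$L
  C <- imp$cov_eta
  g <- numeric(length(theta))
  idx <- 0
  A <- Wyy %*% L %*% C
  if (q > 0) {
    xi <- p + seq_len(q)
    Wyx <- W[yi, xi, drop = FALSE]
    G <- mats$G[, seq_len(q), drop = FALSE]
    A <- A + Wyx %*% Phi %*% t(G)
  }
  for (r in seq_len(nrow(layout$lam))) {
    idx <- idx + 1
    g[idx] <- 2 * A[layout$lam[r, "i"], layout$lam[r, "j"]]
  }
  if (!is.null(layout$gam)) {
    B <- t(L) %*% (Wyy %*% L %*% G + Wyx) %*% Phi
    for (r in seq_len(nrow(layout$gam))) {
      idx <- idx + 1
      g[idx] <- 2 * B[layout$gam[r, "j"], layout$gam[r, "k"]]
    }
  }
  g[idx + seq_len(p)] <- diag(Wyy) * mats$Th  # chain rule through log
  idx <- idx + p
  if (!is.null(layout$psi)) {
    M <- t(L) %*% Wyy %*% L
    for (r in seq_len(nrow(layout$psi))) {
      idx <- idx + 1
      ps <- mats$Psi[layout$psi[r, "j1"], layout$psi[r, "j2"]]
      g[idx] <- 2 * M[layout$psi[r, "j1"], layout$psi[r, "j2"]] * (1 - ps^2)
    }
  }
  g
}

.fml <- function(Sigma, S, log_det_S) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  log_det <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  log_det + tr - log_det_S - nrow(S)
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimises the ML discrepancy
#' `F_ML = log|Sigma(theta)| + tr(S Sigma(theta)^{-1}) - log|S| - P`
#' over the free parameters (loadings and regressions unconstrained, residual
#' variances on the log scale, latent covariances through tanh). Reported fit
#' statistics: `chi^2 = (n-1) F_ML` with its df and p, CFI against the
#' independence baseline, `RMSEA = sqrt(max(chi2 - df, 0) / (df (n-1)))`, and
#' SRMR over standardised residuals (diagonal included). Variables are
#' z-scored first by default. Residual variances cannot go negative under the
#' log parameterisation; estimates collapsing towards zero are flagged as
#' Heywood cases.
#'
#' @param data Data frame containing all indicators and predictors (complete
#'   cases are used; rows dropped are counted in the result). Alternatively
#'   pass `sample_cov` and `n`.
#' @param model A `hex_sem_model`.
#' @param sample_cov Optional covariance matrix (used instead of `data`).
#' @param n Sample size (required with `sample_cov`).
#' @param standardize Z-score the data first (default `TRUE`; ignored when
#'   `sample_cov` is supplied).
#' @param se Compute standard errors and Wald p-values from the numerical
#'   Hessian (default `TRUE`).
#' @param n_starts Number of optimisation starts (first from deterministic
#'   starting values, the rest jittered).
#' @param seed Seed for start jitter.
#' @param start Optional warm-start parameter vector (as returned in `$par`),
#'   used as the first start instead of the deterministic defaults.
#' @param reltol Relative convergence tolerance of the optimiser (default
#'   `1e-12`; bootstrap refits use `1e-8`, ample for percentile intervals).
#' @return Object of class `hex_sem_fit` with elements `estimates` (matrices
#'   `lambda`, `gamma`, `psi`, `theta`), `standardized` (same, fully
#'   standardised, plus `gamma_table` with SEs/p-values for the structural
#'   paths), `chi_square`, `df`, `p_value`, `cfi`, `rmsea`, `srmr`,
#'   `converged`, `heywood`, `n`, `fml`.
#' @export
fit_ml_sem <- function(data = NULL, model, sample_cov = NULL, n = NULL,
                       standardize = TRUE, se = TRUE, n_starts = 3L,
                       seed = 1L, start = NULL, reltol = 1e-12) {
  stopifnot(inherits(model, "hex_sem_model"))
  vars <- c(model$indicators, model$predictors)
  if (is.null(sample_cov)) {
    stopifnot(!is.null(data))
    miss <- setdiff(vars, names(data))
    if (length(miss)) {
      stop_hex("validation_error", "variables missing from data: %s",
               paste(miss, collapse = ", "))
    }
    X <- as.matrix(data[, vars, drop = FALSE])
    cc <- complete.cases(X)
    X <- X[cc, , drop = FALSE]
    n <- nrow(X)
    if (standardize) X <- scale(X)
    S <- cov(X)
    n_dropped <- sum(!cc)
  } else {
    S <- as.matrix(sample_cov)[vars, vars]
    stopifnot(!is.null(n))
    n_dropped <- 0L
  }
  P <- length(vars)
  if (n <= P) stop_hex("insufficient_data", "n must exceed number of variables")
  log_det_S <- determinant(S, logarithm = TRUE)$modulus[1]
  if (!is.finite(log_det_S)) {
    stop_hex("estimation_error", "sample covariance is singular")
  }

  layout <- .sem_layout(model)
  q <- layout$q
  Phi <- if (q > 0) S[model$predictors, model$predictors, drop = FALSE] else NULL
  df_model <- P * (P + 1) / 2 - layout$n_free - q * (q + 1) / 2
  if (df_model < 0) {
    stop_hex("configuration_error", "model not identified (df = %d)", df_model)
  }

  objective <- function(th) {
    mats <- .sem_matrices(th, layout)
    v <- .fml(.sem_implied(mats, Phi)$Sigma, S, log_det_S)
    if (!is.finite(v) || v < -1e-8) 1e10 else v
  }
  gradient <- function(th) .fml_grad(th, layout, Phi, S)

  # deterministic start: loadings 0.7, regressions 0, residuals 0.5
  start0 <- c(rep(0.7, nrow(layout$lam)),
              rep(0, if (is.null(layout$gam)) 0 else nrow(layout$gam)),
              rep(log(0.5), layout$p),
              rep(0, if (is.null(layout$psi)) 0 else nrow(layout$psi)))
  if (!is.null(start)) {
    stopifnot(length(start) == length(start0))
    start0 <- start
  }
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs), add = TRUE)
  set.seed(seed)
  best <- NULL
  for (i in seq_len(max(1L, n_starts))) {
    st <- if (i == 1) start0 else start0 + rnorm(length(start0), 0, 0.3)
    res <- tryCatch(
      optim(st, objective, gradient, method = "BFGS",
            control = list(maxit = 1000, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || best$value >= 1e9) {
    stop_hex("estimation_error", "SEM optimisation failed to converge")
  }
  converged <- best$convergence == 0 ||
    best$value < 1e-10  # perfect-fit data can trip reltol bookkeeping

  mats <- .sem_matrices(best$par, layout)
  # sign convention: each latent's first indicator loads positively (the
  # solution is invariant to flipping a latent's sign)
  for (j in seq_len(layout$m)) {
    first_ind <- match(model$loadings[[model$latents[j]]][1], model$indicators)
    if (mats$L[first_ind, j] < 0) {
      mats$L[, j] <- -mats$L[, j]
      mats$G[j, ] <- -mats$G[j, ]
      mats$Psi[j, -j] <- -mats$Psi[j, -j]
      mats$Psi[-j, j] <- -mats$Psi[-j, j]
    }
  }
  imp <- .sem_implied(mats, Phi)
  Sigma <- imp$Sigma
  dimnames(Sigma) <- list(vars, vars)
  fml <- max(best$value, 0)
  chi2 <- (n - 1) * fml
  p_val <- if (df_model > 0) pchisq(chi2, df_model, lower.tail = FALSE) else NA_real_

  # independence baseline: diagonal for indicators, saturated x-block
  Sigma_b <- diag(diag(S), P)
  dimnames(Sigma_b) <- dimnames(S)
  if (q > 0) {
    Sigma_b[model$predictors, model$predictors] <- Phi
  }
  fml_b <- .fml(Sigma_b, S, log_det_S)
  df_b <- P * (P + 1) / 2 - layout$p - q * (q + 1) / 2
  chi2_b <- (n - 1) * fml_b
  cfi <- if (df_model > 0) {
    num <- max(chi2 - df_model, 0)
    den <- max(chi2_b - df_b, chi2 - df_model, 0)
    if (den == 0) 1 else 1 - num / den
  } else 1
  rmsea <- if (df_model > 0) sqrt(max(chi2 - df_model, 0) / (df_model * (n - 1)))
           else 0
  d_s <- sqrt(diag(S)); d_sig <- sqrt(diag(Sigma))
  Rres <- S / tcrossprod(d_s) - Sigma / tcrossprod(d_sig)
  srmr <- sqrt(mean(Rres[lower.tri(Rres, diag = TRUE)]^2))

  heywood <- any(mats$Th < 1e-4)

  # standardized solution
  sd_eta <- sqrt(diag(imp$cov_eta))
  sd_y <- sqrt(diag(Sigma)[seq_len(layout$p)])
  L_std <- mats$L * outer(1 / sd_y, sd_eta)
  dimnames(L_std) <- list(model$indicators, model$latents)
  G_std <- NULL
  if (q > 0) {
    sd_x <- sqrt(diag(Phi))
    G_std <- mats$G[, seq_len(q), drop = FALSE] * outer(1 / sd_eta, sd_x)
    dimnames(G_std) <- list(model$latents, model$predictors)
  }
  Psi_std <- diag(1 / sd_eta, layout$m) %*% mats$Psi %*% diag(1 / sd_eta, layout$m)
  dimnames(Psi_std) <- list(model$latents, model$latents)
  Th_std <- mats$Th / diag(Sigma)[seq_len(layout$p)]

  se_vec <- rep(NA_real_, length(best$par))
  if (se) {
    H <- tryCatch(optimHess(best$par, function(th) 0.5 * (n - 1) * objective(th)),
                  error = function(e) NULL)
    if (!is.null(H)) {
      ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
      if (all(ev > 0)) {
        se_vec <- sqrt(pmax(diag(solve((H + t(H)) / 2)), 0))
      }
    }
  }
  # structural-path table (unstandardised Wald tests + standardised estimates)
  gamma_table <- NULL
  if (q > 0 && !is.null(layout$gam)) {
    off <- nrow(layout$lam)
    rows <- lapply(seq_len(nrow(layout$gam)), function(r) {
      j <- layout$gam[r, "j"]; k <- layout$gam[r, "k"]
      est <- mats$G[j, k]; s <- se_vec[off + r]
      z <- if (is.finite(s) && s > 0) est / s else NA_real_
      data.frame(latent = model$latents[j], predictor = model$predictors[k],
                 estimate = est, std = G_std[j, k], se = s, z = z,
                 p_value = if (is.finite(z)) 2 * pnorm(-abs(z)) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    gamma_table <- do.call(rbind, rows)
  }

  dimnames(mats$L) <- list(model$indicators, model$latents)
  if (q > 0) dimnames(mats$G) <- list(model$latents, model$predictors)
  dimnames(mats$Psi) <- list(model$latents, model$latents)

  structure(list(
    model = model,
    estimates = list(lambda = mats$L,
                     gamma = if (q > 0) mats$G else NULL,
                     psi = mats$Psi,
                     theta = setNames(mats$Th, model$indicators),
                     phi = Phi),
    standardized = list(loadings = L_std, gamma = G_std, psi = Psi_std,
                        theta = setNames(Th_std, model$indicators),
                        gamma_table = gamma_table),
    par = best$par, se = se_vec, layout = layout,
    implied = Sigma, sample_cov = S, cov_eta = imp$cov_eta,
    fml = fml, chi_square = chi2, df = df_model, p_value = p_val,
    cfi = cfi, rmsea = rmsea, srmr = srmr,
    baseline_chi_square = chi2_b, baseline_df = df_b,
    converged = converged, heywood = heywood, n = n,
    n_dropped = n_dropped, standardize = standardize),
    class = "hex_sem_fit")
}

#' @export
print.hex_sem_fit <- function(x, ...) {
  cat(sprintf("ML SEM fit (n = %d): chi2(%d) = %.3f, p = %.3f\n", x$n, x$df,
              x$chi_square, x$p_value))
  cat(sprintf("  CFI = %.3f, RMSEA = %.3f, SRMR = %.3f%s%s\n", x$cfi, x$rmsea,
              x$srmr, if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$heywood) " [Heywood]" else ""))
  if (!is.null(x$standardized$gamma_table)) {
    cat("  Structural paths (standardized):\n")
    gt <- x$standardized$gamma_table
    for (r in seq_len(nrow(gt))) {
      cat(sprintf("    %s ~ %s: %.3f (p = %.3g)\n", gt$latent[r],
                  gt$predictor[r], gt$std[r], gt$p_value[r]))
    }
  }
  invisible(x)
}

#' Latent factor scores (regression method)
#'
#' `eta_hat = Cov(eta) Lambda' Sigma_yy^{-1} (y - mean(y))`, computed on the
#' same standardisation used at fit time; scores have mean zero by
#' construction.
#'
#' @param fit A converged `hex_sem_fit`.
#' @param data Data frame containing the model's indicators.
#' @return Numeric matrix, subjects by latents (rows with missing indicators
#'   yield `NA`).
#' @export
factor_scores <- function(fit, data) {
  stopifnot(inherits(fit, "hex_sem_fit"))
  if (!fit$converged) stop_hex("estimation_error", "fit did not converge")
  inds <- fit$model$indicators
  Y <- as.matrix(data[, inds, drop = FALSE])
  p <- length(inds)
  Syy <- fit$implied[seq_len(p), seq_len(p), drop = FALSE]
  ch <- tryCatch(chol(Syy), error = function(e) {
    stop_hex("numerical_error", "implied indicator covariance is singular")
  })
  W <- fit$cov_eta %*% t(fit$estimates$lambda) %*% chol2inv(ch)
  cc <- complete.cases(Y)
  Yc <- Y[cc, , drop = FALSE]
  if (fit$standardize) Yc <- scale(Yc)
  else Yc <- scale(Yc, center = TRUE, scale = FALSE)
  scores <- matrix(NA_real_, nrow(Y), nrow(W))
  scores[cc, ] <- Yc %*% t(W)
  colnames(scores) <- fit$model$latents
  scores
}

#' Fit and rank several candidate structures
#'
#' Fits each model to the same data, reports the fit indices side by side
#' (ranked by CFI), and flags models failing all four conventional good-fit
#' cut-offs (chi-square p > 0.05, CFI > 0.95, RMSEA < 0.05, SRMR < 0.08).
#' Estimation errors in one model do not abort the others.
#'
#' @param data Data frame.
#' @param models Named list of `hex_sem_model` objects.
#' @param ... Passed to [fit_ml_sem()].
#' @return List of class `hex_sem_comparison`: `table` (data frame) and
#'   `fits` (list, `NULL` where estimation failed).
#' @export
compare_structures <- function(data, models, ...) {
  stopifnot(length(models) >= 1)
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  fits <- lapply(models, function(m) {
    tryCatch(fit_ml_sem(data, m, ...), error = function(e) NULL)
  })
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.null(f)) {
      return(data.frame(model = nm, chi_square = NA, df = NA, p_value = NA,
                        cfi = NA, rmsea = NA, srmr = NA, fails_all = NA))
    }
    good <- c(isTRUE(f$p_value > 0.05), f$cfi > 0.95, f$rmsea < 0.05,
              f$srmr < 0.08)
    data.frame(model = nm, chi_square = f$chi_square, df = f$df,
               p_value = f$p_value, cfi = f$cfi, rmsea = f$rmsea,
               srmr = f$srmr, fails_all = !any(good, na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$cfi, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "hex_sem_comparison")
}

#' @export
print.hex_sem_comparison <- function(x, ...) {
  print(x$table, digits = 4)
  invisible(x)
}

#' Nonparametric bootstrap intervals for SEM parameters
#'
#' Resamples subjects with replacement, refits the model, and returns
#' percentile confidence intervals for the standardised structural paths (and
#' loadings). This is the package's second decision criterion alongside the
#' classical p-value, standing in for a posterior credible interval.
#'
#' @param data Data frame.
#' @param model A `hex_sem_model`.
#' @param n_boot Number of bootstrap draws (default 2000).
#' @param level Confidence level.
#' @param seed Seed.
#' @param ... Passed to [fit_ml_sem()] for the refits (`se` is forced off and
#'   each refit warm-starts from the full-sample solution).
#' @return List of class `hex_sem_boot`: `ci` (data frame with lower/upper per
#'   standardised path), `draws` (matrix), `n_failed`.
#' @export
sem_bootstrap <- function(data, model, n_boot = 2000L, level = 0.95,
                          seed = 1L, ...) {
  vars <- c(model$indicators, model$predictors)
  X <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  rs <- .save_rng_state()
  on.exit(.restore_rng_state(rs), add = TRUE)
  set.seed(seed)
  args <- list(...)
  args$se <- FALSE
  if (is.null(args$n_starts)) args$n_starts <- 1L
  if (is.null(args$reltol)) args$reltol <- 1e-8
  if (is.null(args$start)) {
    full <- tryCatch(do.call(fit_ml_sem, c(list(X, model), args)),
                     error = function(e) NULL)
    if (!is.null(full)) args$start <- full$par
  }
  draws <- NULL
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(X), replace = TRUE)
    f <- tryCatch(do.call(fit_ml_sem, c(list(X[idx, , drop = FALSE], model),
                                        args)),
                  error = function(e) NULL)
    if (is.null(f)) { n_failed <- n_failed + 1L; next }
    gt <- f$standardized$gamma_table
    v <- if (!is.null(gt)) setNames(gt$std, paste(gt$latent, gt$predictor,
                                                  sep = "~")) else numeric()
    lam <- f$standardized$loadings
    lv <- setNames(as.vector(lam)[as.vector(lam) != 0],
                   outer(rownames(lam), colnames(lam),
                         function(a, b) paste0(b, "=~", a))[as.vector(lam) != 0])
    draws <- rbind(draws, c(v, lv))
  }
  if (is.null(draws) || nrow(draws) < 10) {
    stop_hex("estimation_error", "too few successful bootstrap refits")
  }
  al <- (1 - level) / 2
  ci <- data.frame(
    parameter = colnames(draws),
    lower = apply(draws, 2, quantile, probs = al),
    upper = apply(draws, 2, quantile, probs = 1 - al),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(ci = ci, draws = draws, n_failed = n_failed, level = level),
            class = "hex_sem_boot")
}
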