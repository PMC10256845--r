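.test_result <- function(method, statistic, df, p_value, bf10 = NA_real_,
                         effect_size = NA_real_, extra = list()) {
  structure(c(list(method = method, statistic = unname(statistic), df = df,
                   p_value = unname(p_value), bf10 = unname(bf10),
                   effect_size = unname(effect_size)), extra),
            class = "hex_test")
}

#' @export
print.hex_test <- function(x, ...) {
  cat(sprintf("%s: stat = %.4g, df = %s, p = %.4g", x$method, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p_value))
  if (is.finite(x$bf10)) cat(sprintf(", BF10 = %.4g", x$bf10))
  if (is.finite(x$effect_size)) cat(sprintf(", effect = %.3f", x$effect_size))
  cat("\n")
  invisible(x)
}

#' Paired t-test with Cohen's d_z and JZS Bayes factor
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @param scale Cauchy prior scale for the Bayes factor.
#' @return A `hex_test` with `statistic` (t), `df`, `p_value` (two-tailed),
#'   `bf10`, and `effect_size` (d_z).
#' @export
paired_t <- function(x, y, scale = sqrt(2) / 2) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  s <- sd(d)
  eps <- 1e-12 * (mean(abs(d)) + 1)
  if (!is.finite(s) || s < eps) {
    # identical inputs: a flat zero effect; a constant nonzero shift with no
    # noise would give an infinite t and is rejected instead
    if (all(abs(d) < eps)) {
      return(.test_result("paired t", 0, n - 1, 1,
                          jzs_bf_ttest(0, n, scale = scale), 0))
    }
    stop_hex("degenerate_data", "zero variance of paired differences")
  }
  t <- mean(d) / (s / sqrt(n))
  p <- 2 * pt(abs(t), n - 1, lower.tail = FALSE)
  bf <- jzs_bf_ttest(t, n, scale = scale)
  .test_result("paired t", t, n - 1, p, bf, mean(d) / s)
}

#' Independent-samples t-test (pooled variance) with Cohen's d and JZS BF
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @param scale Cauchy prior scale for the Bayes factor.
#' @return A `hex_test`.
#' @export
independent_t <- function(x, y, scale = sqrt(2) / 2) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 < 1e-24 * (mean(abs(c(x, y))) + 1)^2) {
    if (mean(x) == mean(y)) {
      return(.test_result("independent t", 0, n1 + n2 - 2, 1,
                          jzs_bf_ttest(0, n1, n2, scale = scale), 0))
    }
    stop_hex("degenerate_data", "zero pooled variance")
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE)
  bf <- jzs_bf_ttest(t, n1, n2, scale = scale)
  .test_result("independent t", t, n1 + n2 - 2, p, bf,
               (mean(x) - mean(y)) / sqrt(sp2))
}

#' JZS (default-prior) Bayes factor for a t statistic
#'
#' Jeffreys-Zellner-Siow Bayes factor for the alternative over the null,
#' computed by numerical integration over the Cauchy(`scale`) prior on the
#' standardised effect (Rouder et al. 2009). For one sample pass `n`; for two
#' samples pass `n` and `n2` (effective sample size `n*n2/(n+n2)`, df
#' `n+n2-2`).
#'
#' @param t Observed t statistic.
#' @param n First (or only) sample size.
#' @param n2 Optional second sample size.
#' @param scale Cauchy prior scale (default `sqrt(2)/2`).
#' @return Scalar `bf10` (> 0).
#' @export
jzs_bf_ttest <- function(t, n, n2 = NULL, scale = sqrt(2) / 2) {
  stopifnot(n >= 2)
  if (is.null(n2)) {
    N <- n; nu <- n - 1
  } else {
    N <- n * n2 / (n + n2); nu <- n + n2 - 2
  }
  r2 <- scale^2
  log_denom <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    lh <- -0.5 * log1p(N * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu)) +
      0.5 * log(r2 / (2 * pi)) - 1.5 * log(g) - r2 / (2 * g)
    exp(lh - log_denom)
  }
  val <- tryCatch(
    integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 0,
              subdivisions = 500L)$value,
    error = function(e) {
      stop_hex("numerical_error", "JZS integration failed: %s",
               conditionMessage(e))
    })
  val
}

# Gauss hypergeometric 2F1 by direct series (z in [0, 1); c > 0 large here,
# so terms decay geometrically in z)
.hyp2f1 <- function(a, b, cc, z, tol = 1e-13, max_terms = 2e5) {
  term <- 1
  s <- 1
  for (k in 0:(max_terms - 1)) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < tol * abs(s)) return(s)
  }
  s
}

# log of the rho-dependent part of the exact density of a sample correlation
.log_r_density_kernel <- function(rho, r, n) {
  (n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r) +
    log(.hyp2f1(0.5, 0.5, n - 0.5, (1 + rho * r) / 2))
}

#' Default-prior Bayes factor for a Pearson correlation
#'
#' Bayes factor for the alternative that the population correlation is nonzero,
#' with a stretched-beta prior on `rho` (`(rho+1)/2 ~ Beta(1/kappa, 1/kappa)`,
#' `kappa = 1/3` giving the conventional "medium" default). Computed by
#' numerical integration of the exact sampling density of `r` against the
#' prior.
#'
#' @param r Observed sample correlation.
#' @param n Sample size (>= 4).
#' @param kappa Prior width (1 = uniform over (-1, 1)).
#' @return Scalar `bf10`.
#' @export
jzs_bf_cor <- function(r, n, kappa = 1 / 3) {
  stopifnot(n >= 4, abs(r) < 1, kappa > 0)
  a <- 1 / kappa
  log_f0 <- .log_r_density_kernel(0, r, n)
  integrand <- function(rho) {
    lk <- vapply(rho, .log_r_density_kernel, numeric(1), r = r, n = n)
    exp(lk - log_f0) * dbeta((rho + 1) / 2, a, a) / 2
  }
  tryCatch(
    integrate(integrand, -1, 1, rel.tol = 1e-8, subdivisions = 500L)$value,
    error = function(e) {
      stop_hex("numerical_error", "correlation BF integration failed: %s",
               conditionMessage(e))
    })
}

#' Pearson correlation test with Bayes factor
#'
#' @param x,y Numeric vectors (n >= 4 after pairwise-complete deletion).
#' @param kappa Prior width for the Bayes factor (see [jzs_bf_cor()]).
#' @return A `hex_test` with `statistic` = r, `df` = n - 2, two-tailed
#'   `p_value` from the t transform, and `bf10`.
#' @export
pearson_cor_test <- function(x, y, kappa = 1 / 3) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 4)
  if (sd(x) == 0 || sd(y) == 0) {
    stop_hex("degenerate_data", "zero variance in correlation input")
  }
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    return(.test_result("pearson correlation", r, n - 2, 0, Inf, r,
                        extra = list(n = n, t = sign(r) * Inf)))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(t), n - 2, lower.tail = FALSE)
  bf <- jzs_bf_cor(r, n, kappa = kappa)
  .test_result("pearson correlation", r, n - 2, p, bf, r,
               extra = list(n = n, t = t))
}

#' 2x2 fully within-subject repeated-measures ANOVA
#'
#' Standard within-subject decomposition for a two-by-two design. With two
#' levels per factor every effect is exactly a paired contrast, so each F
#' equals the square of the corresponding paired t, and the per-effect Bayes
#' factor is the JZS one-sample Bayes factor on the subject-level contrast
#' scores.
#'
#' @param data Long data frame.
#' @param subject,a,b,value Column names for the subject identifier, the two
#'   within factors (2 levels each), and the response.
#' @param scale Cauchy prior scale for the contrast Bayes factors.
#' @return List of class `hex_anova` with one `hex_test` per effect (`A`,
#'   `B`, `AB`), each carrying `ss_effect` and `ss_error`.
#' @export
rm_anova_2x2 <- function(data, subject = "subject", a = "a", b = "b",
                         value = "value", scale = sqrt(2) / 2) {
  stopifnot(all(c(subject, a, b, value) %in% names(data)))
  la <- sort(unique(as.character(data[[a]])))
  lb <- sort(unique(as.character(data[[b]])))
  if (length(la) != 2 || length(lb) != 2) {
    stop_hex("incomplete_design", "both factors must have exactly 2 levels")
  }
  cell <- aggregate(data[[value]],
                    by = list(subject = data[[subject]], a = data[[a]],
                              b = data[[b]]), FUN = mean)
  wide <- matrix(NA_real_, length(unique(cell$subject)), 4)
  subjects <- sort(unique(as.character(cell$subject)))
  combos <- expand.grid(a = la, b = lb, stringsAsFactors = FALSE)
  for (j in seq_len(4)) {
    sub <- cell[cell$a == combos$a[j] & cell$b == combos$b[j], ]
    wide[match(as.character(sub$subject), subjects), j] <- sub$x
  }
  if (anyNA(wide)) {
    stop_hex("incomplete_design", "missing cells in the 2x2 design")
  }
  n <- nrow(wide)
  if (n < 3) stop_hex("incomplete_design", "need n >= 3 subjects")

  # columns: (a1,b1), (a2,b1), (a1,b2), (a2,b2)
  contrasts <- list(
    A = (wide[, 1] + wide[, 3] - wide[, 2] - wide[, 4]) / 2,
    B = (wide[, 1] + wide[, 2] - wide[, 3] - wide[, 4]) / 2,
    AB = wide[, 1] - wide[, 2] - wide[, 3] + wide[, 4]
  )
  scale_ss <- c(A = 1, B = 1, AB = 1 / 4)
  out <- lapply(names(contrasts), function(eff) {
    d <- contrasts[[eff]]
    s <- sd(d)
    if (s == 0) {
      t <- 0; p <- 1; bf <- jzs_bf_ttest(0, n, scale = scale)
      f <- 0
    } else {
      t <- mean(d) / (s / sqrt(n))
      f <- t^2
      p <- pf_upper(f, 1, n - 1)
      bf <- jzs_bf_ttest(t, n, scale = scale)
    }
    .test_result(sprintf("RM-ANOVA effect %s", eff), f, c(1, n - 1), p, bf,
                 extra = list(t = if (s == 0) 0 else t,
                              ss_effect = n * mean(d)^2 * scale_ss[[eff]],
                              ss_error = sum((d - mean(d))^2) * scale_ss[[eff]]))
  })
  structure(setNames(out, names(contrasts)), class = "hex_anova")
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' @export
print.hex_anova <- function(x, ...) {
  for (eff in names(x)) print(x[[eff]])
  invisible(x)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return q-values (monotone, capped at 1), same order as `p`.
#' @export
fdr_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  n <- length(p)
  if (n == 0) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

#' Power of a two-tailed Pearson correlation test (Fisher z)
#'
#' `power = Phi(z_rho * sqrt(n-3) - z_{1-alpha/2}) +
#'  Phi(-z_rho * sqrt(n-3) - z_{1-alpha/2})`, with `z_rho = atanh(rho)`.
#'
#' @param n Sample size (>= 4).
#' @param rho True correlation in (-1, 1).
#' @param alpha Two-tailed significance level.
#' @return Power in `[alpha, 1]`.
#' @examples
#' correlation_power(188, 0.2)  # ~0.787
#' @export
correlation_power <- function(n, rho, alpha = 0.05) {
  stopifnot(n >= 4, abs(rho) < 1, alpha > 0, alpha < 1)
  zr <- atanh(rho) * sqrt(n - 3)
  zc <- qnorm(1 - alpha / 2)
  pnorm(zr - zc) + pnorm(-zr - zc)
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param items Numeric matrix or data frame, subjects in rows, items in
#'   columns (k >= 2 items, >= 3 complete rows).
#' @return Scalar alpha (<= 1).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  stopifnot(k >= 2, nrow(items) >= 3)
  tv <- var(rowSums(items))
  if (!is.finite(tv) || tv == 0) {
    stop_hex("degenerate_data", "zero total-score variance")
  }
  k / (k - 1) * (1 - sum(apply(items, 2, var)) / tv)
}

#' McDonald's omega (total) from a single-factor ML fit
#'
#' Fits a one-factor confirmatory model by maximum likelihood (see
#' [fit_ml_sem()]) on the standardised items and returns
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta)`.
#'
#' When the items share no common factor the one-factor ML solution is only
#' identified up to a ridge (a single item can absorb an arbitrary loading
#' with compensating residual), so omega estimates near zero reliability are
#' unstable; values well below the conventional 0.7 threshold should be read
#' qualitatively.
#'
#' @param items Numeric matrix or data frame of items.
#' @return Scalar omega in `[0, 1]`.
#' @export
mcdonald_omega <- function(items) {
  items <- as.data.frame(items)
  items <- items[complete.cases(items), , drop = FALSE]
  nm <- paste0("it", seq_len(ncol(items)))
  names(items) <- nm
  model <- sem_model(paste("f =~", paste(nm, collapse = " + ")))
  fit <- fit_ml_sem(items, model, se = FALSE)
  if (!fit$converged) stop_hex("estimation_error", "factor fit did not converge")
  lam <- fit$standardized$loadings[, "f"]  # signed: noise loadings cancel
  th <- fit$standardized$theta
  sum(lam)^2 / (sum(lam)^2 + sum(th))
}

#' Principal component analysis on the correlation matrix
#'
#' Eigen-decomposition of the correlation matrix of complete cases. With
#' `n_components = "auto"` (Kaiser rule) all components with eigenvalue > 1
#' are retained.
#'
#' @param x Numeric data frame/matrix (>= 2 variables).
#' @param n_components Integer, or `"auto"`.
#' @return List of class `hex_pca`: `eigenvalues`, `loadings` (eigenvectors),
#'   `scores` (complete cases only), `n_retained`, `n_dropped_rows`.
#' @export
pca_scores <- function(x, n_components = "auto") {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2)
  cc <- complete.cases(x)
  xs <- x[cc, , drop = FALSE]
  sds <- apply(xs, 2, sd)
  if (any(sds == 0)) {
    stop_hex("degenerate_data", "constant column: %s",
             paste(colnames(xs)[sds == 0], collapse = ", "))
  }
  R <- cor(xs)
  e <- eigen(R, symmetric = TRUE)
  k <- if (identical(n_components, "auto")) max(1L, sum(e$values > 1))
       else as.integer(n_components)
  z <- scale(xs)
  scores <- z %*% e$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(e$vectors) <- colnames(x)
  structure(list(eigenvalues = e$values, loadings = e$vectors,
                 scores = scores, n_retained = k,
                 n_dropped_rows = sum(!cc)),
            class = "hex_pca")
}

#' Dual-criterion significance rule
#'
#' The analysis convention that an effect counts as significant only when both
#' the classical and the Bayesian index support it: `p < p_crit` and
#' `bf10 > bf_crit`.
#'
#' @param p_value,bf10 Numeric vectors (recycled).
#' @param p_crit,bf_crit Cut-offs (defaults 0.05 and 3).
#' @return Logical vector.
#' @export
significant_both <- function(p_value, bf10, p_crit = 0.05, bf_crit = 3) {
  p_value < p_crit & bf10 > bf_crit
}
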