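# fast OLS coefficient helper used inside bootstrap loops
.ols_coef <- function(X, y) .lm.fit(X, y)$coefficients

#' Three-variable mediation analysis with bootstrap inference
#'
#' Fits the OLS path model: `a` from `m ~ x`, `b` and the direct effect
#' `c'` from `y ~ x + m`, and the total effect `c` from `y ~ x`. The
#' indirect effect is `a*b`, which for OLS paths equals `c - c'` exactly.
#' Inference on the indirect effect uses a nonparametric bootstrap
#' (participant resampling) percentile confidence interval and two-sided
#' p-value; a Sobel z test is reported alongside for reference.
#'
#' @param x Predictor vector (age in the lifespan analyses).
#' @param m Mediator vector.
#' @param y Outcome vector.
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `mediation_result` with paths `a`, `b`, `c`,
#'   `c_prime`, `indirect`, `ci` (percentile), `p_boot`, `sobel_z`,
#'   `p_sobel`, `n`, `n_boot`.
#' @export
mediate <- function(x, m, y, n_boot = 5000L, seed = 1L, conf = 0.95) {
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("x, m, y must have equal length")
  if (n < 10L) stop("mediation needs at least 10 observations")
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0)
    stop("zero-variance input")

  X1 <- cbind(1, x)
  X2 <- cbind(1, x, m)
  if (qr(X2)$rank < 3L) {
    # mediator exactly collinear with the predictor: paths b and c' are
    # unidentifiable (arises for noiseless synthetic trajectories)
    fa <- stats::lm.fit(X1, m)
    fc <- stats::lm.fit(X1, y)
    return(structure(list(a = unname(fa$coefficients[2]), b = NA_real_,
                          c = unname(fc$coefficients[2]),
                          c_prime = NA_real_, indirect = NA_real_,
                          ci = c(NA_real_, NA_real_), conf = conf,
                          p_boot = NA_real_, sobel_z = NA_real_,
                          p_sobel = NA_real_, n = n, n_boot = n_boot,
                          seed = seed, degenerate = TRUE),
                     class = "mediation_result"))
  }
  fa <- stats::lm.fit(X1, m)
  f2 <- stats::lm.fit(X2, y)
  fc <- stats::lm.fit(X1, y)
  a <- fa$coefficients[2]
  b <- f2$coefficients[3]
  c_prime <- f2$coefficients[2]
  c_tot <- fc$coefficients[2]
  indirect <- a * b

  # Sobel z from the asymptotic path variances
  se2 <- function(fit, X) {
    s2 <- sum(fit$residuals^2) / (length(fit$residuals) - ncol(X))
    diag(chol2inv(chol(crossprod(X)))) * s2
  }
  se_a <- sqrt(se2(fa, X1)[2])
  se_b <- sqrt(se2(f2, X2)[3])
  sobel_z <- indirect / sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  p_sobel <- 2 * stats::pnorm(-abs(sobel_z))

  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]
      ab <- tryCatch({
        a_s <- .ols_coef(cbind(1, xb), m[idx])[2]
        b_s <- .ols_coef(cbind(1, xb, m[idx]), y[idx])[3]
        a_s * b_s
      }, error = function(e) NA_real_)
      ab
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  alpha <- 1 - conf
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 6))
  p_boot <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))

  structure(list(a = unname(a), b = unname(b), c = unname(c_tot),
                 c_prime = unname(c_prime), indirect = unname(indirect),
                 ci = ci, conf = conf, p_boot = p_boot,
                 sobel_z = unname(sobel_z), p_sobel = unname(p_sobel),
                 n = n, n_boot = n_boot, seed = seed, degenerate = FALSE),
            class = "mediation_result")
}

#' Adjust p-values for multiple comparisons
#'
#' Holm step-down by default; Benjamini-Hochberg and Bonferroni
#' selectable. Thin wrapper over [stats::p.adjust()] with input
#' validation.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method `"holm"`, `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p, method = c("holm", "BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Partial correlation of two variables given a covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after OLS
#' regression of each on `z` (with intercept).
#'
#' @param x,y Numeric vectors.
#' @param z Covariate vector (age in the lifespan analyses).
#' @return Scalar partial correlation in [-1, 1], or `NA` when either
#'   variable is an exact affine function of the covariate (zero residual
#'   variance, as for noiseless synthetic trajectories).
#' @export
partial_cor <- function(x, y, z) {
  Z <- cbind(1, z)
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (stats::sd(rx) <= 1e-12 * max(stats::sd(x), 1) ||
      stats::sd(ry) <= 1e-12 * max(stats::sd(y), 1))
    return(NA_real_)
  stats::cor(rx, ry)
}

#' Age-partialled correlation matrices among metrics, per tract
#'
#' For each tract, the symmetric matrix of pairwise partial correlations
#' among the four metrics (iron, myelin, ADC, GFA) with age as the
#' covariate. Conditioning is pairwise on age only, not on the remaining
#' metrics.
#'
#' @param table Collapsed region-metric table holding all four metrics
#'   for each tract.
#' @param participants Participant table supplying ages.
#' @param targets Tract labels (default the three stopping-network
#'   tracts).
#' @param metrics Metric labels (default all four).
#' @return Named list (per tract) of correlation matrices.
#' @export
partial_correlations <- function(table, participants,
                                 targets = tract_labels(),
                                 metrics = c("iron", "myelin", "ADC", "GFA")) {
  out <- lapply(targets, function(tg) {
    sub <- table[table$target == tg, ]
    wide <- lapply(metrics, function(mt) {
      v <- sub[sub$metric == mt, ]
      if (nrow(v) == 0L)
        stop("metric '", mt, "' missing for tract '", tg, "'")
      v$value[match(participants$participant_id, v$participant_id)]
    })
    names(wide) <- metrics
    if (anyNA(unlist(wide)))
      stop("incomplete metric data for tract '", tg, "'")
    M <- diag(1, length(metrics))
    dimnames(M) <- list(metrics, metrics)
    for (i in seq_along(metrics)) for (j in seq_along(metrics)) {
      if (i < j) {
        r <- partial_cor(wide[[i]], wide[[j]], participants$age)
        M[i, j] <- M[j, i] <- r
      }
    }
    M
  })
  names(out) <- targets
  out
}
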