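#' Default candidate polynomial age models
#'
#' Six candidates spanning linear, quadratic and/or cubic age terms, each
#' with an intercept: powers {1}, {2}, {3}, {1,2}, {1,3}, {1,2,3}. The set
#' is configurable wherever it is consumed and is recorded in output
#' metadata.
#'
#' @return List of integer vectors of included age powers.
#' @export
candidate_set <- function() {
  list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(1L, 2L, 3L))
}

#' @keywords internal
candidate_name <- function(powers) {
  paste0("age^{", paste(powers, collapse = ","), "}")
}

# Exact interpolation guard: an RSS this small relative to the response
# scale is numerical noise from an exact fit, not residual variance.
.rss_degenerate <- function(RSS, values) {
  TSS <- sum((values - mean(values))^2)
  RSS <= 1e-12 * max(TSS, 1e-8 * sum(values^2))
}

#' Fit one candidate polynomial age model by OLS
#'
#' Ordinary least squares of `values` on raw (uncentred) powers of age.
#' Ages are scaled by their maximum absolute value for the internal QR
#' solve (conditioning for cubic terms) and coefficients are mapped back
#' to the raw-age basis exactly. The Gaussian concentrated log-likelihood
#' is `-(n/2) * (log(2*pi) + log(RSS/n) + 1)` and
#' `BIC = k*log(n) - 2*loglik` with `k` the number of regression
#' coefficients (the error variance is excluded; the convention is shared
#' by all candidates so it cancels in comparisons). An exact fit
#' (`RSS ~ 0`) yields a `-Inf` BIC sentinel with `degenerate = TRUE`.
#'
#' @param ages Numeric vector of ages (years), finite.
#' @param values Numeric response vector, same length.
#' @param powers Integer vector of included age powers, subset of 1:3;
#'   the intercept is always included.
#' @return Object of class `fit_result`: candidate powers, `coefficients`
#'   on the raw basis (named `(Intercept)`, `age`, `age^2`, `age^3`), `n`,
#'   `k`, `RSS`, `loglik`, `BIC`, `degenerate`, plus `fitted`, `residuals`
#'   and `leverage` for influence diagnostics.
#' @export
fit_candidate <- function(ages, values, powers) {
  powers <- sort(unique(as.integer(powers)))
  if (length(powers) == 0L || !all(powers %in% 1:3))
    stop("`powers` must be a non-empty subset of 1:3")
  if (length(ages) != length(values) || anyNA(ages) || any(!is.finite(ages)))
    stop("ages and values must be finite vectors of equal length")
  n <- length(ages)
  k <- length(powers) + 1L
  if (n <= k) stop("need more observations than coefficients (n > k)")

  s <- max(abs(ages))
  if (s == 0) s <- 1
  X <- outer(ages / s, c(0L, powers), `^`)
  qr_x <- qr(X)
  if (qr_x$rank < k)
    stop("rank-deficient design (ages carry too little variation)")
  coef_z <- qr.coef(qr_x, values)
  fitted <- drop(X %*% coef_z)
  resid <- values - fitted
  RSS <- sum(resid^2)
  h <- rowSums(qr.Q(qr_x)[, seq_len(k), drop = FALSE]^2)

  degenerate <- .rss_degenerate(RSS, values)
  loglik <- if (degenerate) Inf else -(n / 2) * (log(2 * pi) + log(RSS / n) + 1)
  BIC <- if (degenerate) -Inf else k * log(n) - 2 * loglik

  coefs <- coef_z / s^c(0L, powers)
  names(coefs) <- c("(Intercept)",
                    ifelse(powers == 1L, "age", paste0("age^", powers)))
  structure(list(powers = powers, coefficients = coefs, n = n, k = k,
                 RSS = RSS, loglik = loglik, BIC = BIC,
                 degenerate = degenerate, fitted = fitted,
                 residuals = resid, leverage = h,
                 ages = ages, values = values),
            class = "fit_result")
}

#' Cook's distances and influence diagnostics for a fitted candidate
#'
#' `D_i = e_i^2 * h_ii / (k * s^2 * (1 - h_ii)^2)` with `s^2 =
#' RSS / (n - k)`; the exclusion threshold is `4/n` with the current n.
#' For a degenerate (exact-interpolation) fit the residual variance is 0
#' and all distances are defined as 0, so no point is flagged.
#'
#' @param fit A [fit_candidate()] result.
#' @param ages,values Optionally the data the fit was computed on, checked
#'   for consistency.
#' @return List with `cooks` (D_i), `leverage` (h_ii), `threshold` (4/n),
#'   `flagged` (indices with D_i > 4/n) and `degenerate`.
#' @export
cooks_distances <- function(fit, ages = NULL, values = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  if (!is.null(ages) && !isTRUE(all.equal(ages, fit$ages)))
    stop("`ages` differ from the data the fit was computed on")
  if (!is.null(values) && !isTRUE(all.equal(values, fit$values)))
    stop("`values` differ from the data the fit was computed on")
  n <- fit$n; k <- fit$k
  if (n <= k) stop("influence diagnostics need n > k")
  if (fit$degenerate) {
    D <- rep(0, n)
  } else {
    s2 <- fit$RSS / (n - k)
    h <- fit$leverage
    D <- fit$residuals^2 * h / (k * s2 * (1 - h)^2)
  }
  thr <- 4 / n
  list(cooks = D, leverage = fit$leverage, threshold = thr,
       flagged = which(D > thr), degenerate = fit$degenerate)
}

#' @keywords internal
.pick_winner <- function(fits) {
  bic <- vapply(fits, `[[`, numeric(1), "BIC")
  k <- vapply(fits, `[[`, numeric(1), "k")
  order(bic, k)[1]  # lowest BIC; ties (incl. -Inf) to fewest parameters
}

#' Select a lifespan trajectory with influence pruning
#'
#' The full selection procedure: (i) fit every candidate by OLS and take
#' the lowest-BIC model as the pre-prune winner (ties to fewest
#' parameters); (ii) compute Cook's distances on the winner and drop
#' observations with `D_i > 4/n`; (iii) refit every candidate on the
#' reduced data and reselect. One prune-refit pass only. The BIC gap to
#' the runner-up is reported, with a caution flag when it is below 6
#' (weak evidence for the winner).
#'
#' @param ages,values Numeric data vectors.
#' @param candidates List of power sets (default [candidate_set()]).
#' @param ids Optional participant ids aligned with the data (defaults to
#'   indices), used to report exclusions.
#' @param prune Run the Cook's-distance pruning pass (default TRUE).
#' @return Object of class `selection_result`: `pre` (winning
#'   [fit_candidate()] fit on all data), `excluded_ids`, `post` (winner
#'   after pruning), `delta_bic` (runner-up minus winner, post-prune),
#'   `caution` (`delta_bic < 6`), `candidates`, and all post-prune fits
#'   (`fits`).
#' @export
select_trajectory <- function(ages, values, candidates = candidate_set(),
                              ids = NULL, prune = TRUE) {
  if (length(candidates) < 2L) stop("need at least 2 candidate models")
  if (is.null(ids)) ids <- as.character(seq_along(ages))

  fits0 <- lapply(candidates, function(p) fit_candidate(ages, values, p))
  w0 <- .pick_winner(fits0)

  excluded <- character(0)
  keep <- rep(TRUE, length(ages))
  if (prune) {
    infl <- cooks_distances(fits0[[w0]])
    if (length(infl$flagged)) {
      keep[infl$flagged] <- FALSE
      excluded <- ids[infl$flagged]
      max_k <- max(vapply(candidates, length, integer(1))) + 1L
      if (sum(keep) <= max_k)
        stop("pruning would leave too few observations (n <= max k)")
    }
  }

  if (length(excluded)) {
    fits1 <- lapply(candidates, function(p)
      fit_candidate(ages[keep], values[keep], p))
  } else fits1 <- fits0
  w1 <- .pick_winner(fits1)

  bic <- vapply(fits1, `[[`, numeric(1), "BIC")
  others <- sort(bic[-w1])
  delta <- if (is.infinite(bic[w1]) && is.infinite(others[1])) NA_real_
           else others[1] - bic[w1]
  structure(list(pre = fits0[[w0]], excluded_ids = excluded,
                 post = fits1[[w1]], delta_bic = delta,
                 caution = is.na(delta) || delta < 6,
                 candidates = candidates, fits = fits1),
            class = "selection_result")
}

#' Sex and age-by-sex linear models
#'
#' OLS of `value ~ age + sex + age:sex` with two-sided coefficient tests,
#' screening for sex main effects and age-by-sex interactions.
#'
#' @param ages Numeric age vector.
#' @param values Numeric response vector.
#' @param sex Factor or character vector with exactly two levels present.
#' @return `data.frame(term, estimate, se, t, p, degenerate)`; the
#'   `degenerate` flag marks an essentially perfect fit (zero residual
#'   variance), whose p-values are meaningless.
#' @export
fit_sex_models <- function(ages, values, sex) {
  sex <- as.factor(as.character(sex))
  if (nlevels(sex) != 2L)
    stop("both sexes must be present in the data")
  fit <- stats::lm(values ~ ages * sex)
  degen <- .rss_degenerate(sum(stats::residuals(fit)^2), values)
  cf <- suppressWarnings(summary(fit)$coefficients)
  data.frame(term = c("(Intercept)", "age", "sex", "age:sex"),
             estimate = cf[, 1], se = cf[, 2], t = cf[, 3], p = cf[, 4],
             degenerate = degen, row.names = NULL, stringsAsFactors = FALSE)
}
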