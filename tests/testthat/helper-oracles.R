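# Independent brute-force oracles; deliberately scalar and loop-based so
# they share no code path with the implementation they check.

gfa_oracle <- function(psi) {
  n <- length(psi)
  if (all(psi == 0)) return(0)
  num <- 0
  for (p in psi) num <- num + (p - mean(psi))^2
  den <- 0
  for (p in psi) den <- den + p^2
  sqrt(n * num / ((n - 1) * den))
}

adc_oracle <- function(s0, sb, b) {
  acc <- 0
  for (i in seq_along(b)) acc <- acc + (-1 / b[i]) * log(sb[i] / s0)
  acc / length(b)
}

iron_oracle <- function(r2s, qsm) 0.24 * r2s + 98.28 * qsm - 3.83
myelin_oracle <- function(r2s, r1) 0.11 * r2s + 31.87 * r1 - 7.99

# case-deletion Cook's distance: refit without observation i, compare
# fitted values at all points (ages rescaled so the explicit normal
# equations stay well-conditioned; D_i is invariant to column scaling)
cooks_oracle <- function(ages, values, powers) {
  X <- outer(ages / max(abs(ages)), c(0, sort(powers)), `^`)
  n <- length(values); k <- ncol(X)
  beta <- solve(t(X) %*% X, t(X) %*% values)
  fit_all <- X %*% beta
  s2 <- sum((values - fit_all)^2) / (n - k)
  D <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    bi <- solve(t(Xi) %*% Xi, t(Xi) %*% values[-i])
    D[i] <- sum((fit_all - X %*% bi)^2) / (k * s2)
  }
  D
}

# exhaustive model selection with explicit matrix algebra and explicit
# case deletion (one prune pass), for small-n equivalence checks
select_oracle <- function(ages, values, candidates) {
  bic_of <- function(a, v, powers) {
    X <- outer(a / max(abs(a)), c(0, sort(powers)), `^`)
    n <- length(v); k <- ncol(X)
    beta <- solve(t(X) %*% X, t(X) %*% v)
    rss <- sum((v - X %*% beta)^2)
    tss <- sum((v - mean(v))^2)
    if (rss <= 1e-12 * max(tss, 1e-8 * sum(v^2))) return(c(-Inf, k))
    ll <- -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
    c(k * log(n) - 2 * ll, k)
  }
  pick <- function(a, v) {
    tab <- t(vapply(candidates, function(p) bic_of(a, v, p), numeric(2)))
    order(tab[, 1], tab[, 2])[1]
  }
  w0 <- pick(ages, values)
  D <- cooks_oracle(ages, values, candidates[[w0]])
  drop_idx <- which(D > 4 / length(ages))
  keep <- setdiff(seq_along(ages), drop_idx)
  w1 <- pick(ages[keep], values[keep])
  list(pre = w0, excluded = drop_idx, post = w1)
}

# partial correlation from the normalized inverse covariance of
# (x, y, z): -P12 / sqrt(P11 * P22)
pcor_oracle <- function(x, y, z) {
  P <- solve(stats::cov(cbind(x, y, z)))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# two-mask layout on a small grid, for synthesis unit tests
two_mask_layout <- function(labels = c("STN_L", "STN_R")) {
  m1 <- array(FALSE, c(8, 8, 8)); m1[2:3, 2:3, 2:3] <- TRUE
  m2 <- array(FALSE, c(8, 8, 8)); m2[6:7, 6:7, 6:7] <- TRUE
  masks <- list(m1, m2)
  names(masks) <- labels
  structure(list(dim = c(8L, 8L, 8L), voxel_mm = 1, masks = masks),
            class = "phantom_layout")
}

# truth rows for one target/metric on both hemispheres of a cohort
truth_rows <- function(participants, target, metric, values_L, values_R) {
  rbind(
    data.frame(participant_id = participants$participant_id, target = target,
               hemisphere = "L", metric = metric, value = values_L,
               stringsAsFactors = FALSE),
    data.frame(participant_id = participants$participant_id, target = target,
               hemisphere = "R", metric = metric, value = values_R,
               stringsAsFactors = FALSE))
}
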