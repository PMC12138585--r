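test_that("OLS candidate fits reproduce hand-computed coefficients and BIC", {
  # exact interpolation: coefficients recovered, -Inf BIC sentinel + flag
  ages <- c(20, 35, 50, 65, 80)
  f <- fit_candidate(ages, 2 + 3 * ages, powers = 1)
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-10)
  expect_lt(f$RSS, 1e-18)
  expect_true(f$degenerate)
  expect_identical(f$BIC, -Inf)

  # hand OLS on (0,1,2,3) -> (0,1,1,2): intercept 0.1, slope 0.6, RSS 0.2;
  # BIC = 2*ln(4) + 4*(ln(2*pi) + ln(0.05) + 1) = 2.1411679
  g <- fit_candidate(0:3, c(0, 1, 1, 2), powers = 1)
  expect_equal(unname(g$coefficients), c(0.1, 0.6), tolerance = 1e-12)
  expect_equal(g$RSS, 0.2, tolerance = 1e-12)
  expect_equal(g$BIC, 2.1411679, tolerance = 1e-6)
  expect_equal(g$k, 2)
  expect_equal(g$loglik, -(4 / 2) * (log(2 * pi) + log(0.05) + 1),
               tolerance = 1e-12)

  # quadratic truth at cohort scale: all three coefficients to 1e-8
  p <- generate_participants(49, c(21, 83), 27, seed = 31)
  y <- 6.732 + 0.371 * p$age - 0.004 * p$age^2
  h <- fit_candidate(p$age, y, powers = c(1, 2))
  expect_equal(unname(h$coefficients), c(6.732, 0.371, -0.004),
               tolerance = 1e-8)

  expect_error(fit_candidate(rep(50, 10), rnorm(10), 1), "rank-deficient")
  expect_error(fit_candidate(1:3, 1:3, c(1, 2)), "n > k")
  expect_error(fit_candidate(1:10, rnorm(10), integer(0)), "subset")
})

test_that("Cook's distances match case deletion and the hat-trace identity", {
  set.seed(32)
  for (powers in list(1, c(1, 2))) {
    ages <- runif(15, 21, 83)
    y <- 3 + 0.05 * ages + rnorm(15, 0, 0.5)
    f <- fit_candidate(ages, y, powers)
    d <- cooks_distances(f)
    expect_equal(sum(d$leverage), f$k, tolerance = 1e-10)
    expect_true(all(d$leverage >= 0 & d$leverage < 1))
    expect_true(all(d$cooks >= 0))
    expect_equal(d$cooks, cooks_oracle(ages, y, powers), tolerance = 1e-10)
    # independent implementation in stats agrees too
    lmfit <- lm(y ~ poly(ages, max(unlist(powers)), raw = TRUE))
    if (identical(powers, c(1, 2)))
      expect_equal(unname(d$cooks), unname(cooks.distance(lmfit)),
                   tolerance = 1e-8)
  }

  f49 <- fit_candidate(runif(49, 21, 83), rnorm(49), 1)
  d49 <- cooks_distances(f49)
  expect_equal(d49$threshold, 4 / 49)
  expect_equal(round(d49$threshold, 2), 0.08)
})

test_that("selection picks the generating family and prunes gross outliers", {
  p <- generate_participants(49, c(21, 83), 27, seed = 33)

  # zero noise, linear truth: winner {1} before and after, no exclusions
  y0 <- 7.549 - 0.009 * p$age
  s0 <- select_trajectory(p$age, y0, ids = p$participant_id)
  expect_equal(s0$pre$powers, 1L)
  expect_equal(s0$post$powers, 1L)
  expect_length(s0$excluded_ids, 0)

  # contamination: two gross outliers are flagged and pruning restores
  # the linear winner with a slope closer to truth
  spec <- trajectory_spec("IFG", "iron", c(3.858, 0.015), noise_sd = 0.05)
  tt <- generate_region_truth(spec, p, seed = 35)
  bad <- inject_influential(tt, k = 2, offset = 1.5, seed = 36)
  displaced <- attr(bad, "displaced_ids")
  sel <- select_trajectory(p$age, bad$value, ids = p$participant_id)
  expect_true(all(displaced %in% sel$excluded_ids))
  expect_equal(sel$post$powers, 1L)
  err_pre <- abs(sel$pre$coefficients[2] - 0.015)
  err_post <- abs(sel$post$coefficients[2] - 0.015)
  expect_lt(err_post, err_pre)

  # the injected points are exactly the 4/n exceedances of the clean fit
  fit_bad <- fit_candidate(p$age, bad$value, 1)
  flags <- cooks_distances(fit_bad)$flagged
  expect_true(all(match(displaced, p$participant_id) %in% flags))

  expect_error(select_trajectory(p$age, y0, candidates = list(1L)),
               "2 candidate")
})

test_that("selection equals an exhaustive brute-force oracle on small n", {
  cands <- candidate_set()
  for (rep_i in 1:20) {
    set.seed(400 + rep_i)
    n <- sample(9:12, 1)
    ages <- runif(n, 21, 83)
    y <- 5 + 0.05 * ages - 4e-4 * ages^2 + rnorm(n, 0, 0.3)
    got <- select_trajectory(ages, y, candidates = cands)
    want <- select_oracle(ages, y, cands)
    expect_equal(got$pre$powers, cands[[want$pre]])
    expect_equal(as.integer(got$excluded_ids), want$excluded)
    expect_equal(got$post$powers, cands[[want$post]])
  }
})

test_that("BIC respects nesting and is shift-equivariant across candidates", {
  set.seed(36)
  ages <- runif(40, 21, 83)
  y <- 4 + 0.02 * ages + rnorm(40, 0, 0.4)
  cands <- candidate_set()
  fits <- lapply(cands, function(p) fit_candidate(ages, y, p))
  rss <- vapply(fits, `[[`, numeric(1), "RSS")
  # nested candidates: adding powers never increases RSS
  expect_lte(rss[[4]], rss[[1]] + 1e-10)  # {1,2} vs {1}
  expect_lte(rss[[6]], rss[[4]] + 1e-10)  # {1,2,3} vs {1,2}
  # k is penalised by exactly ln(n)
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  ks <- vapply(fits, `[[`, numeric(1), "k")
  bic <- vapply(fits, `[[`, numeric(1), "BIC")
  expect_equal(bic, ks * log(40) - 2 * ll, tolerance = 1e-10)

  # adding a constant shifts only the intercept; Delta-BIC is unchanged
  fits2 <- lapply(cands, function(p) fit_candidate(ages, y + 100, p))
  bic2 <- vapply(fits2, `[[`, numeric(1), "BIC")
  expect_equal(bic - bic[1], bic2 - bic2[1], tolerance = 1e-6)
  expect_equal(fits2[[4]]$coefficients[-1], fits[[4]]$coefficients[-1],
               tolerance = 1e-7)
})

test_that("sex models detect injected interactions and nothing else", {
  p <- generate_participants(60, c(21, 83), 30, seed = 37)

  # identical generating process for both sexes: estimates ~ 0
  y <- 5 + 0.02 * p$age
  tab <- fit_sex_models(p$age, y, p$sex)
  expect_true(tab$degenerate[1])
  expect_lt(abs(tab$estimate[tab$term == "sex"]), 1e-10)
  expect_lt(abs(tab$estimate[tab$term == "age:sex"]), 1e-10)

  # strong injected sex-specific slope: interaction p < 0.001 in >= 95%
  hits <- vapply(1:100, function(i) {
    set.seed(500 + i)
    slope <- ifelse(p$sex == "F", 0.02, 0.06)
    yy <- 5 + slope * p$age + rnorm(60, 0, 0.3)
    fit_sex_models(p$age, yy, p$sex)$p[4] < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(fit_sex_models(p$age, y, rep("F", 60)), "both sexes")
})
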