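test_that("mask means match hand values and a brute-force loop", {
  v <- array(0, c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4))

  m[2, 2, 2] <- TRUE
  v[2, 2, 2] <- 3.14
  expect_equal(aggregate_mask_mean(v, m), 3.14)

  u <- array(7.5, c(4, 4, 4))
  expect_equal(aggregate_mask_mean(u, m), 7.5)

  m3 <- array(FALSE, c(4, 4, 4)); m3[1:3, 1, 1] <- TRUE
  v3 <- array(0, c(4, 4, 4)); v3[1:3, 1, 1] <- c(1, 2, 6)
  expect_equal(aggregate_mask_mean(v3, m3), 3.0)

  set.seed(11)
  vr <- array(rnorm(64), c(4, 4, 4))
  mr <- array(runif(64) < 0.4, c(4, 4, 4))
  acc <- 0; k <- 0
  for (i in seq_len(64)) if (mr[i]) { acc <- acc + vr[i]; k <- k + 1 }
  expect_lt(abs(aggregate_mask_mean(vr, mr) - acc / k), 1e-12)

  expect_error(aggregate_mask_mean(v, array(FALSE, c(4, 4, 4)),
                                   label = "STN_L"), "STN_L")
  expect_error(aggregate_mask_mean(v, array(FALSE, c(2, 2, 2))), "grid")
})

test_that("hemisphere t-tests handle identical, offset and noisy data", {
  p <- generate_participants(30, c(21, 83), 15, seed = 21)
  vals <- 5 + 0.02 * p$age + rnorm(30, 0, 0.1)

  same <- truth_rows(p, "STN", "iron", vals, vals)
  r <- test_hemisphere_difference(same)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_true(r$degenerate)

  off <- truth_rows(p, "STN", "iron", vals, vals + 0.5)
  r2 <- test_hemisphere_difference(off)
  expect_equal(r2$p, 0)
  expect_true(r2$degenerate)
  expect_equal(r2$mean_diff, -0.5)

  set.seed(22)
  noisy <- truth_rows(p, "STN", "iron", vals + rnorm(30, 0, 0.2),
                      vals + rnorm(30, 0, 0.2))
  r3 <- test_hemisphere_difference(noisy)
  expect_false(r3$degenerate)
  expect_true(r3$p >= 0 && r3$p <= 1)
  # matches stats::t.test directly
  L <- noisy$value[noisy$hemisphere == "L"]
  R <- noisy$value[noisy$hemisphere == "R"]
  tt <- t.test(L, R, paired = TRUE)
  expect_equal(r3$t, unname(tt$statistic))
  expect_equal(r3$p, tt$p.value)

  expect_error(test_hemisphere_difference(same[same$hemisphere == "L", ]),
               "hemisphere")
})

test_that("collapsing averages hemispheres and preserves grand means", {
  p <- generate_participants(10, c(21, 83), 5, seed = 23)
  tab <- truth_rows(p, "IFG", "myelin", rep(4, 10), rep(6, 10))
  col <- collapse_hemispheres(tab)
  expect_true(all(col$value == 5))
  expect_true(all(col$hemisphere == "collapsed"))

  same <- truth_rows(p, "IFG", "myelin", rep(3.3, 10), rep(3.3, 10))
  expect_true(all(collapse_hemispheres(same)$value == 3.3))

  set.seed(24)
  noisy <- truth_rows(p, "IFG", "myelin", rnorm(10, 8), rnorm(10, 8))
  col2 <- collapse_hemispheres(noisy)
  expect_equal(mean(col2$value), mean(noisy$value), tolerance = 1e-12)

  broken <- noisy[-1, ]  # drop one L row
  expect_error(collapse_hemispheres(broken), "missing hemisphere")
})

test_that("collapse commutes with mask-mean aggregation", {
  layout <- two_mask_layout(c("IFG_L", "IFG_R"))
  set.seed(25)
  vol <- array(rnorm(512, 10), c(8, 8, 8))
  mean_L <- aggregate_mask_mean(vol, layout$masks[["IFG_L"]])
  mean_R <- aggregate_mask_mean(vol, layout$masks[["IFG_R"]])

  p1 <- generate_participants(2, c(21, 83), 1, seed = 26)
  tab <- truth_rows(p1, "IFG", "iron", rep(mean_L, 2), rep(mean_R, 2))
  col <- collapse_hemispheres(tab)
  # averaging the two mask means equals the mask mean of the voxelwise
  # hemispheric average (masks have equal size)
  both <- layout$masks[["IFG_L"]] | layout$masks[["IFG_R"]]
  expect_equal(col$value[1], aggregate_mask_mean(vol, both),
               tolerance = 1e-12)
})

test_that("region extraction produces the long-format exchange table", {
  p <- generate_participants(3, c(21, 83), 2, seed = 27)
  layout <- two_mask_layout()
  truth <- rbind(
    truth_rows(p, "STN", "iron", 10 + 0.1 * p$age, 11 + 0.1 * p$age),
    truth_rows(p, "STN", "myelin", rep(15, 3), rep(16, 3)))
  vols <- synthesize_qmri_volumes(truth, layout)
  metrics <- extract_region_metrics(
    lapply(vols, function(v) list(iron = compute_iron(v),
                                  myelin = compute_myelin(v))), layout)
  expect_setequal(names(metrics),
                  c("participant_id", "target", "hemisphere", "metric",
                    "value"))
  expect_equal(nrow(metrics), 3 * 2 * 2)  # participants x masks x metrics
  expect_setequal(unique(metrics$hemisphere), c("L", "R"))
  expect_true(all(is.finite(metrics$value)))
})
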