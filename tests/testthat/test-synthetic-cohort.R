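test_that("participant generation matches the cohort design", {
  p <- generate_participants(49, c(21, 83), n_female = 27, seed = 42)
  expect_equal(nrow(p), 49)
  expect_equal(sum(p$sex == "F"), 27)
  expect_false(anyDuplicated(p$participant_id) > 0)
  expect_true(all(p$age >= 21 & p$age <= 83))

  expect_identical(p, generate_participants(49, c(21, 83), 27, seed = 42))
  expect_false(identical(p$age,
                         generate_participants(49, c(21, 83), 27,
                                               seed = 43)$age))

  degen <- generate_participants(2, c(30, 30.0001), 1, seed = 1)
  expect_true(all(abs(degen$age - 30) < 1e-3))

  expect_error(generate_participants(10, c(50, 30)), "invalid age range")
  expect_error(generate_participants(10, c(30, 30)), "invalid age range")
  expect_error(generate_participants(5, c(21, 83), n_female = 6), "n_female")
  expect_error(generate_participants(1, c(21, 83)), ">= 2")
})

test_that("trajectory truth values are polynomial(age) plus Gaussian noise", {
  p <- generate_participants(12, c(21, 83), 6, seed = 3)

  # noiseless linear model evaluates exactly: intercept + slope * age
  spec <- trajectory_spec("STN", "myelin", c(15.353, -0.011))
  tt <- generate_region_truth(spec, p, seed = 1)
  expect_equal(tt$value, 15.353 - 0.011 * p$age, tolerance = 1e-14)
  expect_equal(eval_trajectory(spec, 0), 15.353)

  # constant trajectory
  const <- trajectory_spec("IFG", "iron", 4.2)
  expect_equal(generate_region_truth(const, p, seed = 1)$value, rep(4.2, 12))

  # law of large numbers: 10,000 draws at one age centre on the polynomial
  one <- generate_participants(10000, c(49.999, 50.001), 5000, seed = 8)
  sigma <- 0.5
  noisy <- trajectory_spec("STN", "iron", c(6.732, 0.371, -0.004),
                           noise_sd = sigma)
  draws <- generate_region_truth(noisy, one, seed = 9)$value
  mu <- eval_trajectory(noisy, 50)
  expect_lt(abs(mean(draws) - mu), 4 * sigma / sqrt(10000) + 1e-3)

  expect_error(trajectory_spec("STN", "GFA", c(0.9, 0.01)), "GFA")
  expect_error(trajectory_spec("STN", "ADC", c(1e-4, -1e-5)), "ADC")
  expect_error(trajectory_spec("STN", "iron", c(1, 2), noise_sd = -1),
               "noise_sd")
})

test_that("reference trajectory catalogue covers all 18 target-metric pairs", {
  mods <- reference_trajectories()
  expect_length(mods, 18)
  expect_setequal(
    unique(vapply(mods, `[[`, character(1), "target")),
    stopping_network_targets())
  expect_true(all(vapply(mods, `[[`, numeric(1), "noise_sd") > 0))
  expect_true(all(vapply(reference_trajectories(0), `[[`, numeric(1),
                         "noise_sd") == 0))
  stn <- mods[["STN.iron"]]
  expect_equal(stn$coefficients, c(6.732, 0.371, -0.004, 0))
})

test_that("qMRI phantom synthesis is the exact algebraic inverse", {
  p <- generate_participants(5, c(21, 83), 3, seed = 2)
  layout <- two_mask_layout()
  truth <- rbind(
    truth_rows(p, "STN", "iron", 10 + p$age * 0.1, 12 + p$age * 0.05),
    truth_rows(p, "STN", "myelin", 15 - p$age * 0.01, 14 + p$age * 0.02))

  vols <- synthesize_qmri_volumes(truth, layout, r2star_baseline = 20)
  recovered <- extract_region_metrics(
    lapply(vols, function(v) list(iron = compute_iron(v),
                                  myelin = compute_myelin(v))), layout)
  key <- function(d) paste(d$participant_id, d$hemisphere, d$metric)
  m <- recovered[match(key(truth), key(recovered)), ]
  expect_lt(max(abs(m$value - truth$value)), 1e-10)

  # iron target = model intercept with zero R2* baseline forces QSM = 0
  t2 <- rbind(truth_rows(p, "STN", "iron", rep(-3.83, 5), rep(-3.83, 5)),
              truth_rows(p, "STN", "myelin", rep(8, 5), rep(8, 5)))
  v2 <- synthesize_qmri_volumes(t2, layout, r2star_baseline = 0)
  expect_equal(max(abs(v2[[1]]$QSM[layout$masks[[1]]])), 0)

  # distinct targets in the two masks stay distinct: no bleed
  qsmA <- unique(vols[[1]]$QSM[layout$masks[[1]]])
  qsmB <- unique(vols[[1]]$QSM[layout$masks[[2]]])
  expect_length(qsmA, 1)
  expect_length(qsmB, 1)
  expect_false(isTRUE(all.equal(qsmA, qsmB)))

  # a mask with no truth value is an explicit, named error
  bad <- truth[truth$hemisphere == "L", ]
  expect_error(synthesize_qmri_volumes(bad, layout), "STN_R")
})

test_that("DWI phantom synthesis round-trips ADC through compute_adc", {
  p <- generate_participants(3, c(21, 83), 2, seed = 5)
  layout <- two_mask_layout()

  # two targets spanning the normal white-matter range, ordering preserved
  truth <- truth_rows(p, "STN", "ADC", rep(0.6e-3, 3), rep(1.05e-3, 3))
  dwi <- synthesize_dwi_signals(truth, layout, s0 = 900)
  adc <- compute_adc(dwi[[1]]$S0, dwi[[1]]$shells)
  vL <- adc[layout$masks[[1]]][1]
  vR <- adc[layout$masks[[2]]][1]
  expect_lt(abs(vL - 0.6e-3), 1e-12)
  expect_lt(abs(vR - 1.05e-3), 1e-12)
  expect_lt(vL, vR)

  # ADC target 0 gives S_b = s0 and recovers exactly 0
  t0 <- truth_rows(p, "STN", "ADC", rep(0, 3), rep(0, 3))
  d0 <- synthesize_dwi_signals(t0, layout, s0 = 1000)
  expect_equal(d0[[1]]$shells[["700"]][layout$masks[[1]]][1], 1000)
  a0 <- compute_adc(d0[[1]]$S0, d0[[1]]$shells)
  expect_equal(a0[layout$masks[[1]]][1], 0)

  expect_error(synthesize_dwi_signals(truth, layout, s0 = 0), "s0")
  tneg <- truth_rows(p, "STN", "ADC", rep(-1e-4, 3), rep(1e-3, 3))
  expect_error(synthesize_dwi_signals(tneg, layout), "non-negative")
})

test_that("FOD synthesis inverts the closed-form single-peak GFA", {
  # target 0: unit peak, all amplitudes equal
  expect_equal(peak_amplitude_for_gfa(0, 10), 1)
  # hand case: n = 2, a = 3 gives GFA 2/sqrt(10); the inverse returns a = 3
  expect_equal(peak_amplitude_for_gfa(2 / sqrt(10), 2), 3, tolerance = 1e-12)
  expect_error(peak_amplitude_for_gfa(1, 10), "\\[0, 1\\)")

  # round trip across the GFA range and direction counts
  for (n_dirs in c(2L, 10L, 100L)) {
    for (g in c(0, 0.1, 0.45, 0.85, 0.99)) {
      a <- peak_amplitude_for_gfa(g, n_dirs)
      expect_gte(a, 1)
      got <- compute_gfa(matrix(c(a, rep(1, n_dirs - 1L)), nrow = 1))
      expect_lt(abs(got - g), 1e-9)
    }
  }

  p <- generate_participants(3, c(21, 83), 2, seed = 6)
  layout <- two_mask_layout()
  truth <- truth_rows(p, "STN", "GFA", rep(0.83, 3), rep(0.86, 3))
  fod <- synthesize_fod_samples(truth, layout, n_dirs = 40)
  g <- compute_gfa(fod[[1]]$amplitudes)
  expect_lt(abs(g[layout$masks[[1]]][1] - 0.83), 1e-9)
  expect_lt(abs(g[layout$masks[[2]]][1] - 0.86), 1e-9)
  expect_equal(dim(fod[[1]]$amplitudes), c(8, 8, 8, 40))
  norms <- sqrt(rowSums(fod[[1]]$directions^2))
  expect_equal(norms, rep(1, 40), tolerance = 1e-12)
})

test_that("influential-point injection displaces exactly k recorded ids", {
  p <- generate_participants(20, c(21, 83), 10, seed = 4)
  spec <- trajectory_spec("IFG", "iron", c(4, 0.02), noise_sd = 0.05)
  tt <- generate_region_truth(spec, p, seed = 7)

  same <- inject_influential(tt, k = 0, offset = 100, seed = 1)
  expect_equal(same$value, tt$value)
  expect_length(attr(same, "displaced_ids"), 0)

  out1 <- inject_influential(tt, k = 2, offset = 50, seed = 9)
  out2 <- inject_influential(tt, k = 2, offset = 50, seed = 9)
  expect_identical(attr(out1, "displaced_ids"), attr(out2, "displaced_ids"))
  moved <- out1$participant_id[abs(out1$value - tt$value) > 1]
  expect_setequal(unique(moved), attr(out1, "displaced_ids"))

  expect_error(inject_influential(tt, k = 20, offset = 1), "smaller")
})
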