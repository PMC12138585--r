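#' Define a ground-truth lifespan trajectory
#'
#' A trajectory is a polynomial in age, `value = b0 + b1*age + b2*age^2 +
#' b3*age^3`, plus i.i.d. Gaussian noise. Predicted values over the stated
#' age range must stay inside the metric's physical domain (GFA in [0, 1],
#' ADC > 0).
#'
#' @param target Region or tract label (see [stopping_network_targets()]).
#' @param metric One of `"iron"`, `"myelin"`, `"ADC"`, `"GFA"`.
#' @param coefficients Numeric vector of up to 4 values: intercept and the
#'   coefficients for age powers 1..3 (absent trailing powers are 0).
#' @param noise_sd Residual standard deviation in the metric's units (>= 0).
#' @param age_range Ages over which the physical-domain check is enforced.
#'
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(target, metric, coefficients, noise_sd = 0,
                            age_range = c(21, 83)) {
  metric <- match.arg(metric, c("iron", "myelin", "ADC", "GFA"))
  if (!is.numeric(coefficients) || length(coefficients) < 1L ||
      length(coefficients) > 4L)
    stop("`coefficients` must be the intercept plus up to 3 age-power terms")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  beta <- c(coefficients, rep(0, 4L - length(coefficients)))
  ages <- seq(age_range[1], age_range[2], length.out = 201L)
  pred <- drop(outer(ages, 0:3, `^`) %*% beta)
  if (metric == "GFA" && (min(pred) < 0 || max(pred) > 1))
    stop("GFA trajectory leaves [0, 1] over the age range")
  if (metric == "ADC" && min(pred) <= 0)
    stop("ADC trajectory must stay positive over the age range")
  structure(list(target = target, metric = metric, coefficients = beta,
                 noise_sd = noise_sd, age_range = age_range),
            class = "trajectory_spec")
}

#' Evaluate a trajectory's polynomial mean at given ages
#'
#' @param spec A [trajectory_spec()].
#' @param age Numeric vector of ages in years.
#' @return Numeric vector of noiseless trajectory values.
#' @export
eval_trajectory <- function(spec, age) {
  drop(outer(age, 0:3, `^`) %*% spec$coefficients)
}

#' Reference winning trajectory models for the stopping network
#'
#' The parameterised winning polynomial age models for iron and myelin in
#' the three regions of interest, and for iron, myelin, ADC and GFA in the
#' three tracts, used as the synthetic cohort's ground truth. Each model's
#' default `noise_sd` is 5% of its dynamic range over ages 21--83, a
#' residual spread typical of regional quantitative-MRI means; pass
#' `noise_frac = 0` for exact (noiseless) cohorts.
#'
#' @param noise_frac Residual SD as a fraction of each model's dynamic
#'   range over the age range (default 0.05).
#' @return Named list of [trajectory_spec()] objects; names are
#'   `"<target>.<metric>"`.
#' @export
reference_trajectories <- function(noise_frac = 0.05) {
  spec_tab <- list(
    list("IFG",        "iron",   c(3.858,  0.015)),
    list("IFG",        "myelin", c(7.549, -0.009)),
    list("preSMA",     "iron",   c(4.510, -0.010)),
    list("preSMA",     "myelin", c(8.046,  0.031)),
    list("STN",        "iron",   c(6.732,  0.371, -0.004)),
    list("STN",        "myelin", c(15.353, -0.011)),
    list("IFG-preSMA", "myelin", c(11.856,  0.009)),
    list("STN-IFG",    "myelin", c(11.103,  0.094, -0.001)),
    list("STN-preSMA", "myelin", c(11.961,  0.099, -0.001)),
    list("IFG-preSMA", "iron",   c(3.409,  0.071, -0.001)),
    list("STN-IFG",    "iron",   c(5.159,  0.019)),
    list("STN-preSMA", "iron",   c(4.812,  0.011)),
    list("IFG-preSMA", "ADC",    c(7.96e-4, -3.71e-6, 5.26e-8)),
    list("STN-IFG",    "ADC",    c(7.51e-4, -4.69e-6, 6.38e-8)),
    list("STN-preSMA", "ADC",    c(7.23e-4, -3.41e-6, 4.67e-8)),
    list("IFG-preSMA", "GFA",    c(0.830, -3.90e-5)),
    list("STN-IFG",    "GFA",    c(0.851,  6.03e-5)),
    list("STN-preSMA", "GFA",    c(0.859,  8.84e-5))
  )
  out <- lapply(spec_tab, function(s) {
    spec0 <- trajectory_spec(s[[1]], s[[2]], s[[3]], noise_sd = 0)
    rng <- diff(range(eval_trajectory(spec0, seq(21, 83, length.out = 201L))))
    trajectory_spec(s[[1]], s[[2]], s[[3]], noise_sd = noise_frac * rng)
  })
  names(out) <- vapply(out, function(s) paste(s$target, s$metric, sep = "."),
                       character(1))
  out
}

#' Generate ground-truth regional values for one trajectory
#'
#' Draws `value = polynomial(age) + N(0, noise_sd)` for every participant.
#'
#' @param spec A [trajectory_spec()].
#' @param participants Participant table from [generate_participants()].
#' @param seed Integer seed.
#' @param hemisphere Hemisphere label for the generated rows (`"L"`, `"R"`
#'   or `"collapsed"`).
#' @return A region-metric table: `data.frame(participant_id, target,
#'   hemisphere, metric, value)`.
#' @export
generate_region_truth <- function(spec, participants, seed = 1L,
                                  hemisphere = "collapsed") {
  stopifnot(inherits(spec, "trajectory_spec"))
  mu <- eval_trajectory(spec, participants$age)
  noise <- if (spec$noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(nrow(participants), 0, spec$noise_sd))
  } else rep(0, nrow(participants))
  data.frame(
    participant_id = participants$participant_id,
    target = spec$target,
    hemisphere = hemisphere,
    metric = spec$metric,
    value = mu + noise,
    stringsAsFactors = FALSE
  )
}

#' Generate the full ground-truth table for a cohort
#'
#' Applies every trajectory model to both hemispheres with independent
#' noise draws, giving the long-format table that drives phantom synthesis.
#'
#' @param participants Participant table.
#' @param models Named list of [trajectory_spec()]s
#'   (default [reference_trajectories()]).
#' @param hemispheres Hemisphere labels to generate (default `c("L","R")`).
#' @param seed Integer seed; per-model seeds are derived deterministically.
#' @return Long-format region-metric `data.frame`.
#' @export
cohort_truth <- function(participants, models = reference_trajectories(),
                         hemispheres = c("L", "R"), seed = 1L) {
  pieces <- list()
  k <- 0L
  for (i in seq_along(models)) {
    for (h in hemispheres) {
      k <- k + 1L
      pieces[[k]] <- generate_region_truth(models[[i]], participants,
                                           seed = seed + 7919L * k,
                                           hemisphere = h)
    }
  }
  do.call(rbind, pieces)
}

#' Displace randomly chosen participants' values (influence fixture)
#'
#' Adds `offset` to every row of `k` randomly chosen participants, to test
#' influential-point detection downstream. The displaced ids are recorded
#' in the `"displaced_ids"` attribute.
#'
#' @param table Region-metric table.
#' @param k Number of participants to displace (`k < n`).
#' @param offset Displacement in metric units.
#' @param seed Integer seed.
#' @return The table with displaced values and attribute `displaced_ids`.
#' @export
inject_influential <- function(table, k, offset, seed = 1L) {
  ids <- unique(table$participant_id)
  if (k >= length(ids)) stop("`k` must be smaller than the number of participants")
  chosen <- if (k > 0L) withr::with_seed(seed, sample(ids, k)) else character(0)
  table$value <- table$value + offset * (table$participant_id %in% chosen)
  attr(table, "displaced_ids") <- sort(chosen)
  table
}
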