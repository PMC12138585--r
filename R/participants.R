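#' Generate a synthetic participant table
#'
#' Draws a cohort of participants with ages sampled uniformly over a given
#' range and a fixed number of females, mirroring an adult-lifespan imaging
#' cohort (the default arguments give 49 participants, 27 of them female,
#' aged 21--83).
#'
#' @param n Number of participants (>= 2).
#' @param age_range Numeric length-2 vector `c(min, max)` in years; `min`
#'   must be strictly below `max`.
#' @param n_female Number of participants labelled `"F"`; the remainder are
#'   `"M"`. Defaults to roughly half the cohort.
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#'
#' @return A `data.frame` with columns `participant_id` (unique strings),
#'   `age` (years) and `sex` (`"F"`/`"M"`).
#' @export
generate_participants <- function(n, age_range = c(21, 83),
                                  n_female = round(n / 2), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("`n` must be a single number >= 2")
  n <- as.integer(n)
  if (length(age_range) != 2L || !is.numeric(age_range))
    stop("`age_range` must be a numeric pair")
  if (age_range[1] >= age_range[2])
    stop("invalid age range: min (", age_range[1],
         ") must be strictly less than max (", age_range[2], ")")
  if (n_female > n || n_female < 0)
    stop("`n_female` must be between 0 and n")

  withr::with_seed(seed, {
    age <- stats::runif(n, age_range[1], age_range[2])
    sex <- sample(rep(c("F", "M"), c(n_female, n - n_female)))
  })
  data.frame(
    participant_id = sprintf("sub-%03d", seq_len(n)),
    age = age,
    sex = sex,
    stringsAsFactors = FALSE
  )
}
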