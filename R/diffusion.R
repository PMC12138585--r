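#' Generalised fractional anisotropy from FOD amplitude samples
#'
#' Computes, per voxel, the ratio of the sample standard deviation of the
#' fibre-orientation-distribution amplitudes to their root-mean-square:
#' `GFA = sqrt(n * sum((psi_i - mean)^2) / ((n-1) * sum(psi_i^2)))`,
#' over `n` amplitude samples on a fixed direction set. GFA is
#' dimensionless, lies in [0, 1], and is invariant to rescaling all
#' amplitudes in a voxel.
#'
#' @param amplitudes Either a 4-D array (x, y, z, direction) or a matrix
#'   (voxel x direction) of non-negative FOD amplitude samples.
#' @return Array (3-D input) or vector (matrix input) of GFA values. A
#'   voxel whose amplitudes are all zero yields 0 (the 0/0 case), with one
#'   warning per call.
#' @export
compute_gfa <- function(amplitudes) {
  dims <- dim(amplitudes)
  if (is.null(dims) || length(dims) < 2L)
    stop("`amplitudes` must be a matrix or 4-D array of samples")
  if (length(dims) == 4L) {
    spatial <- dims[1:3]
    A <- matrix(amplitudes, ncol = dims[4])
  } else if (length(dims) == 2L) {
    spatial <- NULL
    A <- amplitudes
  } else stop("`amplitudes` must be a matrix or 4-D array of samples")
  n <- ncol(A)
  if (n < 2L) stop("need at least 2 direction samples")
  if (any(A < 0)) stop("FOD amplitudes must be non-negative")

  mu <- rowMeans(A)
  ss <- rowSums(A^2)
  dev <- rowSums((A - mu)^2)
  zero <- ss == 0
  if (any(zero))
    warning(sum(zero), " voxel(s) with all-zero FOD amplitudes; GFA set to 0")
  denom <- (n - 1) * ss
  g <- sqrt(n * dev / ifelse(zero, 1, denom))
  g[zero] <- 0
  if (is.null(spatial)) g else array(g, spatial)
}

#' Apparent diffusion coefficient from multi-shell signals
#'
#' Computes the equal-weight average of the per-shell log-ratio diffusivity
#' estimates, `ADC = mean_b( -(1/b) * ln(S_b / S_0) )`, over the given
#' b-values (defaults 700, 1000 and 1600 s/mm^2), yielding ADC in mm^2/s.
#'
#' @param S0 Mean b=0 signal volume (all values > 0).
#' @param shells Named list of shell signal volumes; names are the
#'   b-values in s/mm^2 (or supply `b` explicitly).
#' @param b Numeric vector of b-values matching `shells`.
#' @return Array of ADC values (mm^2/s). Shell signals exceeding S0 give
#'   negative per-shell terms; they are permitted but counted in the
#'   `"qc_negative_terms"` attribute of the result.
#' @export
compute_adc <- function(S0, shells, b = as.numeric(names(shells))) {
  if (!is.list(shells) || length(shells) < 1L)
    stop("`shells` must be a non-empty list of signal volumes")
  if (length(b) != length(shells) || any(!is.finite(b)) || any(b <= 0))
    stop("b-values must be positive and match `shells`")
  if (any(S0 <= 0)) stop("all S0 signals must be positive")
  acc <- 0
  qc <- 0L
  for (i in seq_along(shells)) {
    Sb <- shells[[i]]
    if (!identical(dim(Sb), dim(S0)))
      stop("shell volumes must share the S0 grid")
    if (any(Sb <= 0)) stop("all shell signals must be positive")
    qc <- qc + sum(Sb > S0)
    acc <- acc + (-1 / b[i]) * log(Sb / S0)
  }
  out <- acc / length(shells)
  attr(out, "qc_negative_terms") <- qc
  out
}

#' Deterministic approximately uniform unit direction set
#'
#' Fibonacci-sphere point set used as the default FOD sampling directions.
#'
#' @param n Number of directions (>= 2).
#' @return `n` x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n = 100L) {
  if (n < 2L) stop("need at least 2 directions")
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Peak amplitude reaching a target GFA in the single-peak family
#'
#' For amplitude samples `(a, 1, ..., 1)` over `n` directions the GFA has
#' the closed form `(a - 1) / sqrt(a^2 + n - 1)`; this inverts it,
#' returning the `a >= 1` that achieves the target.
#'
#' @param gfa Target GFA in `[0, 1)`.
#' @param n Number of direction samples (>= 2).
#' @return Peak amplitude `a >= 1`.
#' @export
peak_amplitude_for_gfa <- function(gfa, n) {
  if (any(gfa < 0) || any(gfa >= 1))
    stop("target GFA must lie in [0, 1): 1 is unreachable for finite peaks")
  if (n < 2L) stop("need at least 2 directions")
  disc <- gfa^2 * (n - (n - 1) * gfa^2)
  ifelse(gfa == 0, 1, (1 + sqrt(disc)) / (1 - gfa^2))
}

#' Synthesize multi-shell diffusion phantom signals from a truth table
#'
#' Builds mono-exponential signals `S_b = s0 * exp(-b * ADC)` per mask so
#' that [compute_adc()] recovers the mask's ADC target exactly.
#'
#' @param truth Region-metric table with an `ADC` value per mask label.
#' @param layout A [phantom_layout()].
#' @param s0 Baseline b=0 signal (> 0).
#' @param b b-values in s/mm^2.
#' @param background_adc ADC assigned outside all masks (mm^2/s, >= 0).
#' @param labels Mask labels to paint with truth values (default: all
#'   masks of the layout); unpainted masks keep the background.
#' @return Named list per participant: `list(S0 = volume, shells = named
#'   list of shell volumes)`.
#' @export
synthesize_dwi_signals <- function(truth, layout, s0 = 1000,
                                   b = c(700, 1000, 1600),
                                   background_adc = 0.8e-3,
                                   labels = names(layout$masks)) {
  validate_layout(layout)
  if (s0 <= 0) stop("`s0` must be positive")
  tab <- truth[truth$metric == "ADC", , drop = FALSE]
  key <- paste(tab$participant_id, mask_label(tab$target, tab$hemisphere))
  val <- structure(tab$value, names = key)
  if (any(tab$value < 0)) stop("ADC targets must be non-negative")
  ids <- unique(truth$participant_id)

  out <- lapply(ids, function(id) {
    D <- array(background_adc, layout$dim)
    for (label in labels) {
      v <- val[paste(id, label)]
      if (is.na(v))
        stop("truth table has no ADC value for label '", label,
             "' (participant ", id, ")")
      D[layout$masks[[label]]] <- v
    }
    shells <- lapply(b, function(bb) s0 * exp(-bb * D))
    names(shells) <- as.character(b)
    list(S0 = array(s0, layout$dim), shells = shells)
  })
  names(out) <- ids
  out
}

#' Synthesize FOD amplitude phantom samples from a truth table
#'
#' Per voxel the amplitudes are `(a, 1, ..., 1)` with the peak `a` chosen
#' by [peak_amplitude_for_gfa()] so that [compute_gfa()] returns the
#' mask's GFA target.
#'
#' @param truth Region-metric table with a `GFA` value in `[0, 1)` per
#'   mask label.
#' @param layout A [phantom_layout()].
#' @param n_dirs Number of direction samples (>= 2).
#' @param background_gfa GFA outside all masks.
#' @param labels Mask labels to paint with truth values (default: all
#'   masks of the layout); unpainted masks keep the background.
#' @return Named list per participant: `list(amplitudes = 4-D array,
#'   directions = n_dirs x 3 matrix)`.
#' @export
synthesize_fod_samples <- function(truth, layout, n_dirs = 100L,
                                   background_gfa = 0.1,
                                   labels = names(layout$masks)) {
  validate_layout(layout)
  tab <- truth[truth$metric == "GFA", , drop = FALSE]
  key <- paste(tab$participant_id, mask_label(tab$target, tab$hemisphere))
  val <- structure(tab$value, names = key)
  ids <- unique(truth$participant_id)
  dirs <- fibonacci_directions(n_dirs)

  out <- lapply(ids, function(id) {
    peak <- array(peak_amplitude_for_gfa(background_gfa, n_dirs), layout$dim)
    for (label in labels) {
      v <- val[paste(id, label)]
      if (is.na(v))
        stop("truth table has no GFA value for label '", label,
             "' (participant ", id, ")")
      peak[layout$masks[[label]]] <- peak_amplitude_for_gfa(v, n_dirs)
    }
    amps <- array(1, c(layout$dim, n_dirs))
    amps[, , , 1L] <- peak
    list(amplitudes = amps, directions = dirs)
  })
  names(out) <- ids
  out
}
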