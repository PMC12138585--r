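#' Bundle co-registered quantitative MRI contrasts
#'
#' @param R1 Longitudinal relaxation rate volume (1/s).
#' @param R2star Effective transverse relaxation rate volume (1/s).
#' @param QSM Quantitative susceptibility volume (ppm).
#' @return An object of class `qmri_contrasts` (list of the three arrays).
#' @export
qmri_contrasts <- function(R1, R2star, QSM) {
  d <- dim(R1)
  if (!identical(dim(R2star), d) || !identical(dim(QSM), d))
    stop("R1, R2* and QSM volumes must share one grid shape")
  structure(list(R1 = R1, R2star = R2star, QSM = QSM),
            class = "qmri_contrasts")
}

#' Biophysical iron/myelin model coefficients
#'
#' Affine models mapping relaxometry and susceptibility contrasts to tissue
#' iron and myelin concentration:
#' `iron = 0.24*R2* + 98.28*QSM - 3.83` and
#' `myelin = 0.11*R2* + 31.87*R1 - 7.99`. The defaults are the calibrated
#' literature coefficients; both are overridable.
#'
#' @param iron Named numeric vector `c(r2star=, qsm=, intercept=)`.
#' @param myelin Named numeric vector `c(r2star=, r1=, intercept=)`.
#' @return An object of class `biophysical_model`.
#' @export
biophysical_model <- function(iron = c(r2star = 0.24, qsm = 98.28,
                                       intercept = -3.83),
                              myelin = c(r2star = 0.11, r1 = 31.87,
                                         intercept = -7.99)) {
  stopifnot(all(c("r2star", "qsm", "intercept") %in% names(iron)),
            all(c("r2star", "r1", "intercept") %in% names(myelin)))
  structure(list(iron = iron, myelin = myelin), class = "biophysical_model")
}

#' Voxelwise iron concentration map
#'
#' Applies the affine iron model to the R2* and QSM contrasts. Outputs are
#' in model concentration units and are not clamped: negative voxel values
#' are preserved because downstream analyses use regional means, which
#' clamping would bias.
#'
#' @param contrasts A [qmri_contrasts()] object.
#' @param model A [biophysical_model()] (defaults to the calibrated
#'   coefficients).
#' @return Array of iron estimates with the input grid shape.
#' @export
compute_iron <- function(contrasts, model = biophysical_model()) {
  stopifnot(inherits(contrasts, "qmri_contrasts"))
  w <- model$iron
  w[["r2star"]] * contrasts$R2star + w[["qsm"]] * contrasts$QSM +
    w[["intercept"]]
}

#' Voxelwise myelin concentration map
#'
#' Applies the affine myelin model to the R2* and R1 contrasts; see
#' [compute_iron()] for conventions.
#'
#' @inheritParams compute_iron
#' @return Array of myelin estimates with the input grid shape.
#' @export
compute_myelin <- function(contrasts, model = biophysical_model()) {
  stopifnot(inherits(contrasts, "qmri_contrasts"))
  w <- model$myelin
  w[["r2star"]] * contrasts$R2star + w[["r1"]] * contrasts$R1 +
    w[["intercept"]]
}

#' Synthesize quantitative MRI phantom volumes from a truth table
#'
#' Inverts the affine iron/myelin models per mask: R2* is fixed to a
#' configurable baseline (the inversion is otherwise underdetermined:
#' two model equations, three contrasts), then QSM is solved from the
#' mask's iron target and R1 from its myelin target, so that applying
#' [compute_iron()]/[compute_myelin()] and averaging per mask reproduces
#' the truth table exactly.
#'
#' @param truth Region-metric table containing `iron` and `myelin` rows for
#'   every mask label of the layout (labels are `"<target>_<hemisphere>"`).
#' @param layout A [phantom_layout()].
#' @param r2star_baseline R2* value (1/s) assigned inside every mask.
#' @param background Named list of contrast values outside all masks
#'   (`r1` 1/s, `r2star` 1/s, `qsm` ppm).
#' @param model A [biophysical_model()].
#' @return Named list (one element per participant) of [qmri_contrasts()].
#' @export
synthesize_qmri_volumes <- function(truth, layout, r2star_baseline = 20,
                                    background = list(r1 = 0.65,
                                                      r2star = 20,
                                                      qsm = 0),
                                    model = biophysical_model()) {
  validate_layout(layout)
  ids <- unique(truth$participant_id)
  labels <- names(layout$masks)
  wi <- model$iron; wm <- model$myelin
  key <- paste(truth$participant_id, mask_label(truth$target, truth$hemisphere),
               truth$metric)
  val <- structure(truth$value, names = key)

  lookup <- function(id, label, metric) {
    v <- val[paste(id, label, metric)]
    if (is.na(v))
      stop("truth table has no ", metric, " value for label '", label,
           "' (participant ", id, ")")
    unname(v)
  }

  out <- lapply(ids, function(id) {
    R1 <- array(background$r1, layout$dim)
    R2s <- array(background$r2star, layout$dim)
    QSM <- array(background$qsm, layout$dim)
    for (label in labels) {
      m <- layout$masks[[label]]
      iron <- lookup(id, label, "iron")
      myelin <- lookup(id, label, "myelin")
      R2s[m] <- r2star_baseline
      QSM[m] <- (iron - wi[["r2star"]] * r2star_baseline - wi[["intercept"]]) /
        wi[["qsm"]]
      R1[m] <- (myelin - wm[["r2star"]] * r2star_baseline - wm[["intercept"]]) /
        wm[["r1"]]
    }
    qmri_contrasts(R1, R2s, QSM)
  })
  names(out) <- ids
  out
}
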