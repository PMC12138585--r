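#' Mean of a metric volume over a boolean mask
#'
#' @param volume Metric volume (array).
#' @param mask Logical array of the same shape.
#' @param label Optional mask label, used in error messages.
#' @return Scalar arithmetic mean over the mask voxels.
#' @export
aggregate_mask_mean <- function(volume, mask, label = NULL) {
  if (!identical(dim(volume), dim(mask)))
    stop("volume and mask", if (!is.null(label)) paste0(" '", label, "'"),
         " must share one grid")
  if (!any(mask))
    stop("mask", if (!is.null(label)) paste0(" '", label, "'"), " is empty")
  mean(volume[mask])
}

#' Extract per-participant region/tract means for all metrics
#'
#' Applies [aggregate_mask_mean()] to every (mask, metric volume) pair of
#' every participant, producing the long-format region-metric table that
#' is the pipeline's central exchange format.
#'
#' @param volumes Named list per participant; each element is a named list
#'   `metric -> volume` (metrics among `iron`, `myelin`, `ADC`, `GFA`).
#' @param layout A [phantom_layout()]; mask names `"<target>_<hemisphere>"`.
#' @return `data.frame(participant_id, target, hemisphere, metric, value)`.
#' @export
extract_region_metrics <- function(volumes, layout) {
  validate_layout(layout)
  ids <- names(volumes)
  labels <- names(layout$masks)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    vols <- volumes[[i]]
    metrics <- names(vols)
    grid <- expand.grid(label = labels, metric = metrics,
                        stringsAsFactors = FALSE)
    grid$value <- mapply(function(lab, met)
      aggregate_mask_mean(vols[[met]], layout$masks[[lab]], label = lab),
      grid$label, grid$metric)
    parts <- strsplit(grid$label, "_", fixed = TRUE)
    rows[[i]] <- data.frame(
      participant_id = ids[i],
      target = vapply(parts, `[`, character(1), 1L),
      hemisphere = vapply(parts, `[`, character(1), 2L),
      metric = grid$metric,
      value = grid$value,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test left-right hemisphere differences per target and metric
#'
#' Two-sided Student t-test of left versus right hemisphere values across
#' participants, paired within participant by default (hemispheres are
#' repeated measures; set `paired = FALSE` for the independent-samples
#' variant). A zero-variance paired difference is degenerate: it is
#' reported as t = 0, p = 1 when the difference is identically zero, and
#' as p = 0 with `degenerate = TRUE` when it is a nonzero constant.
#'
#' @param table Region-metric table containing `L` and `R` rows.
#' @param paired Use the paired test (default TRUE).
#' @return `data.frame(target, metric, t, p, mean_diff, degenerate)`.
#' @export
test_hemisphere_difference <- function(table, paired = TRUE) {
  combos <- unique(table[table$hemisphere %in% c("L", "R"),
                         c("target", "metric")])
  if (nrow(combos) == 0L) stop("table has no L/R hemisphere rows")
  res <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    tg <- combos$target[i]; mt <- combos$metric[i]
    sub <- table[table$target == tg & table$metric == mt, ]
    L <- sub[sub$hemisphere == "L", ]
    R <- sub[sub$hemisphere == "R", ]
    if (nrow(L) == 0L || nrow(R) == 0L)
      stop("missing hemisphere for target '", tg, "' (", mt, ")")
    R <- R[match(L$participant_id, R$participant_id), ]
    if (anyNA(R$value)) stop("unmatched participants for target '", tg, "'")
    d <- L$value - R$value
    if (paired && stats::sd(d) == 0) {
      degen <- TRUE
      tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      degen <- FALSE
      tt <- stats::t.test(L$value, R$value, paired = paired)
    }
    res[[i]] <- data.frame(target = tg, metric = mt,
                           t = unname(tt$statistic), p = tt$p.value,
                           mean_diff = mean(d), degenerate = degen,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Collapse a region-metric table across hemispheres
#'
#' Per (participant, target, metric), replaces the L and R rows by their
#' mean, labelled `"collapsed"`. Collapsing is an explicit analysis
#' choice; run [test_hemisphere_difference()] alongside to report the
#' hemispheric tests.
#'
#' @param table Region-metric table with both hemispheres present.
#' @return Collapsed region-metric table.
#' @export
collapse_hemispheres <- function(table) {
  lr <- table[table$hemisphere %in% c("L", "R"), ]
  if (nrow(lr) == 0L) stop("table has no L/R hemisphere rows to collapse")
  key <- interaction(lr$participant_id, lr$target, lr$metric, drop = TRUE)
  n_h <- tapply(lr$hemisphere, key, function(h) length(unique(h)))
  if (any(n_h != 2L)) {
    bad <- names(n_h)[n_h != 2L][1]
    stop("missing hemisphere for ", bad)
  }
  agg <- stats::aggregate(value ~ participant_id + target + metric,
                          data = lr, FUN = mean)
  out <- data.frame(participant_id = agg$participant_id,
                    target = agg$target,
                    hemisphere = "collapsed",
                    metric = agg$metric,
                    value = agg$value,
                    stringsAsFactors = FALSE)
  out[order(out$participant_id, out$target, out$metric), ]
}
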