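#' Default pipeline configuration
#'
#' A single nested list drives the whole pipeline; every source of
#' randomness flows from `seed`. Candidate model power sets are stored as
#' comma-separated strings (e.g. `"1,2"`) so the config serialises to
#' YAML and back without type drift.
#'
#' @param n Cohort size.
#' @param age_range Age range in years.
#' @param n_female Number of female participants.
#' @param noise_frac Trajectory residual SD as a fraction of each model's
#'   dynamic range (0 = noiseless).
#' @param seed Master integer seed.
#' @param grid_dim Phantom grid shape.
#' @param cube Mask cube edge (voxels).
#' @param n_dirs FOD direction samples.
#' @param b_values Diffusion b-values (s/mm^2).
#' @param s0 Baseline b=0 signal.
#' @param r2star_baseline In-mask R2* (1/s) for the qMRI inversion.
#' @param candidates Character vector of power sets.
#' @param prune Cook's-distance pruning toggle.
#' @param n_boot Mediation bootstrap resamples.
#' @param p_adjust Multiplicity correction (`"holm"`, `"BH"`,
#'   `"bonferroni"`).
#' @param output_dir Optional directory for written artefacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n = 49L, age_range = c(21, 83), n_female = 27L,
                            noise_frac = 0.05, seed = 1L,
                            grid_dim = c(24L, 24L, 24L), cube = 3L,
                            n_dirs = 100L, b_values = c(700, 1000, 1600),
                            s0 = 1000, r2star_baseline = 20,
                            candidates = c("1", "2", "3", "1,2", "1,3",
                                           "1,2,3"),
                            prune = TRUE, n_boot = 5000L,
                            p_adjust = "holm", output_dir = NULL) {
  structure(list(
    cohort = list(n = as.integer(n), age_range = as.numeric(age_range),
                  n_female = as.integer(n_female)),
    noise_frac = noise_frac,
    seed = as.integer(seed),
    layout = list(grid_dim = as.integer(grid_dim), cube = as.integer(cube)),
    metrics = list(n_dirs = as.integer(n_dirs),
                   b_values = as.numeric(b_values), s0 = s0,
                   r2star_baseline = r2star_baseline),
    selection = list(candidates = candidates, prune = prune),
    associations = list(n_boot = as.integer(n_boot), p_adjust = p_adjust),
    output_dir = output_dir
  ), class = "pipeline_config")
}

#' Save / load a pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly / the config.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, list(
    n = cfg$cohort$n, age_range = cfg$cohort$age_range,
    n_female = cfg$cohort$n_female, noise_frac = cfg$noise_frac,
    seed = cfg$seed, grid_dim = cfg$layout$grid_dim, cube = cfg$layout$cube,
    n_dirs = cfg$metrics$n_dirs, b_values = cfg$metrics$b_values,
    s0 = cfg$metrics$s0, r2star_baseline = cfg$metrics$r2star_baseline,
    candidates = cfg$selection$candidates, prune = cfg$selection$prune,
    n_boot = cfg$associations$n_boot, p_adjust = cfg$associations$p_adjust,
    output_dir = cfg$output_dir))
}

#' @keywords internal
parse_candidates <- function(strings) {
  lapply(strings, function(s) as.integer(strsplit(s, ",")[[1]]))
}

#' @keywords internal
tract_endpoints <- function(tract) {
  strsplit(tract, "-", fixed = TRUE)[[1]]
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the whole synthetic-cohort analysis pipeline
#'
#' Simulate -> biophysical maps -> diffusion metrics -> region extraction
#' -> hemisphere tests and collapsing -> trajectory selection -> sex
#' models -> mediation and partial correlations -> report. Reruns with
#' the same config give identical tables. Any stage failure aborts with
#' the stage name and the offending label.
#'
#' @param config A [pipeline_config()].
#' @param layout Optional [phantom_layout()] override; by default built
#'   from the config.
#' @return A `run_report` list: `selection` table, `selection_results`
#'   (full objects), `hemisphere_tests`, `sex_models`, `mediations`,
#'   `partial_correlations`, `metrics` (collapsed region-metric table),
#'   `truth`, `participants` and a `provenance` block.
#' @export
run_pipeline <- function(config = pipeline_config(), layout = NULL) {
  seed <- config$seed
  models <- reference_trajectories(noise_frac = config$noise_frac)

  participants <- .stage("simulate", generate_participants(
    config$cohort$n, config$cohort$age_range, config$cohort$n_female,
    seed = seed))
  if (is.null(layout))
    layout <- .stage("layout", phantom_layout(config$layout$grid_dim,
                                              cube = config$layout$cube))
  required <- as.vector(outer(stopping_network_targets(), c("L", "R"),
                              mask_label))
  missing <- setdiff(required, names(layout$masks))
  if (length(missing))
    stop("pipeline stage 'layout' failed: layout is missing mask(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  truth <- .stage("simulate", cohort_truth(participants, models,
                                           seed = seed + 1L))

  qmri <- .stage("maps", synthesize_qmri_volumes(
    truth, layout, r2star_baseline = config$metrics$r2star_baseline))
  tract_masks <- as.vector(outer(tract_labels(), c("L", "R"), mask_label))
  dwi <- .stage("dwi-metrics", synthesize_dwi_signals(
    truth, layout, s0 = config$metrics$s0, b = config$metrics$b_values,
    labels = intersect(tract_masks, names(layout$masks))))
  fod <- .stage("dwi-metrics", synthesize_fod_samples(
    truth, layout, n_dirs = config$metrics$n_dirs,
    labels = intersect(tract_masks, names(layout$masks))))

  volumes <- .stage("maps", {
    lapply(stats::setNames(participants$participant_id,
                           participants$participant_id), function(id) {
      list(iron = compute_iron(qmri[[id]]),
           myelin = compute_myelin(qmri[[id]]),
           ADC = compute_adc(dwi[[id]]$S0, dwi[[id]]$shells,
                             b = config$metrics$b_values),
           GFA = compute_gfa(fod[[id]]$amplitudes))
    })
  })

  metrics_lr <- .stage("extract", extract_region_metrics(volumes, layout))
  hemi <- .stage("extract", test_hemisphere_difference(metrics_lr))
  metrics <- .stage("extract", collapse_hemispheres(metrics_lr))

  candidates <- parse_candidates(config$selection$candidates)
  combos <- data.frame(
    target = c(rep(region_labels(), each = 2),
               rep(tract_labels(), each = 4)),
    metric = c(rep(c("iron", "myelin"), 3),
               rep(c("iron", "myelin", "ADC", "GFA"), 3)),
    stringsAsFactors = FALSE)

  sel_results <- vector("list", nrow(combos))
  sex_rows <- vector("list", nrow(combos))
  sel_rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    tg <- combos$target[i]; mt <- combos$metric[i]
    sub <- metrics[metrics$target == tg & metrics$metric == mt, ]
    sub <- sub[match(participants$participant_id, sub$participant_id), ]
    sel <- .stage("fit", select_trajectory(
      participants$age, sub$value, candidates = candidates,
      ids = participants$participant_id, prune = config$selection$prune))
    sel_results[[i]] <- sel
    sel_rows[[i]] <- data.frame(
      target = tg, metric = mt,
      powers = paste(sel$post$powers, collapse = ","),
      formula = format_model(sel$post$coefficients, sel$post$powers,
                             scientific = mt %in% c("ADC", "GFA")),
      bic = sel$post$BIC, delta_bic = sel$delta_bic,
      n_excluded = length(sel$excluded_ids),
      excluded = paste(sel$excluded_ids, collapse = ";"),
      caution = sel$caution, stringsAsFactors = FALSE)
    sx <- .stage("fit", fit_sex_models(participants$age, sub$value,
                                       participants$sex))
    sx <- cbind(target = tg, metric = mt, sx)
    sex_rows[[i]] <- sx
  }
  names(sel_results) <- paste(combos$target, combos$metric, sep = ".")
  selection <- do.call(rbind, sel_rows)
  sex_models <- do.call(rbind, sex_rows)

  assoc <- .stage("associate", {
    age <- participants$age
    get_vals <- function(tg, mt) {
      v <- metrics[metrics$target == tg & metrics$metric == mt, ]
      v$value[match(participants$participant_id, v$participant_id)]
    }
    med_rows <- list(); k <- 0L
    # family 1: does regional chemistry mediate age -> tract diffusion?
    for (tr in tract_labels()) for (md in c("iron", "myelin"))
      for (oc in c("ADC", "GFA")) {
        k <- k + 1L
        m <- mediate(age, get_vals(tr, md), get_vals(tr, oc),
                     n_boot = config$associations$n_boot,
                     seed = seed + 100L + k)
        med_rows[[k]] <- data.frame(
          family = "age_to_diffusion", tract = tr, mediator = md,
          outcome = oc, a = m$a, b = m$b, c = m$c, c_prime = m$c_prime,
          indirect = m$indirect, ci_lo = m$ci[1], ci_hi = m$ci[2],
          p = m$p_boot, stringsAsFactors = FALSE)
      }
    # family 2: does region-level iron/myelin mediate age -> tract levels?
    for (tr in tract_labels()) for (rg in tract_endpoints(tr))
      for (md in c("iron", "myelin")) {
        k <- k + 1L
        m <- mediate(age, get_vals(rg, md), get_vals(tr, md),
                     n_boot = config$associations$n_boot,
                     seed = seed + 100L + k)
        med_rows[[k]] <- data.frame(
          family = "region_to_tract", tract = tr,
          mediator = paste(rg, md), outcome = paste(tr, md),
          a = m$a, b = m$b, c = m$c, c_prime = m$c_prime,
          indirect = m$indirect, ci_lo = m$ci[1], ci_hi = m$ci[2],
          p = m$p_boot, stringsAsFactors = FALSE)
      }
    med <- do.call(rbind, med_rows)
    med$p_adjusted <- NA_real_
    for (fam in unique(med$family)) {
      idx <- med$family == fam & is.finite(med$p)
      if (any(idx))
        med$p_adjusted[idx] <- adjust_pvalues(med$p[idx],
                                              config$associations$p_adjust)
    }
    list(mediations = med,
         partial_correlations = partial_correlations(metrics, participants))
  })

  report <- structure(list(
    selection = selection, selection_results = sel_results,
    hemisphere_tests = hemi, sex_models = sex_models,
    mediations = assoc$mediations,
    partial_correlations = assoc$partial_correlations,
    metrics = metrics, metrics_by_hemisphere = metrics_lr,
    truth = truth, participants = participants,
    provenance = list(seed = seed,
                      config_yaml = yaml::as.yaml(unclass(config)),
                      candidates = config$selection$candidates,
                      version = as.character(utils::packageVersion("stopnet")))
  ), class = "run_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    write_tsv_table(participants, out("participants.tsv"))
    write_tsv_table(truth, out("truth.tsv"))
    write_tsv_table(metrics, out("region_metrics.tsv"))
    write_tsv_table(hemi, out("hemisphere_tests.tsv"))
    write_tsv_table(render_tables(report), out("winning_models.tsv"))
    write_tsv_table(sex_models, out("sex_models.tsv"))
    write_tsv_table(assoc$mediations, out("mediations.tsv"))
    jsonlite::write_json(
      lapply(assoc$partial_correlations, function(m)
        as.data.frame(as.table(m))),
      out("partial_correlations.json"), digits = NA)
  }
  report
}

#' Format a fitted polynomial as a winning-model string
#'
#' Renders `gamma = b0 + b1*x + b2*x^2 + ...` with coefficients at 3
#' decimals, or in compact scientific notation for small-scale metrics
#' (ADC, GFA terms below 0.01 in magnitude).
#'
#' @param coefficients Named coefficient vector (intercept first).
#' @param powers Included age powers.
#' @param scientific Use scientific notation for small coefficients.
#' @return A single formula string such as `"γ=6.732+0.371x-0.004x2"`.
#' @export
format_model <- function(coefficients, powers, scientific = FALSE) {
  fmt1 <- function(v) {
    if (scientific && abs(v) < 0.01 && v != 0) {
      s <- formatC(abs(v), format = "e", digits = 2)
      sub("e([+-])0*(\\d)", "e\\1\\2", s)
    } else sprintf("%.3f", abs(v))
  }
  terms <- fmt1(coefficients[1])
  vars <- c("x", "x2", "x3")
  for (i in seq_along(powers)) {
    v <- coefficients[i + 1L]
    terms <- paste0(terms, if (v < 0) "-" else "+", fmt1(v),
                    vars[powers[i]])
  }
  paste0("γ=", terms)
}

#' Render the winning-model tables of a run report
#'
#' One row per (target, metric): the winning formula string, its BIC and
#' the number of Cook's-distance exclusions.
#'
#' @param report A [run_pipeline()] report (or any list with a
#'   `selection` data.frame).
#' @return `data.frame(target, metric, winning_model, bic, n_excluded)`.
#' @export
render_tables <- function(report) {
  sel <- report$selection
  if (is.null(sel) || nrow(sel) == 0L)
    return(data.frame(target = character(0), metric = character(0),
                      winning_model = character(0), bic = numeric(0),
                      n_excluded = integer(0)))
  data.frame(target = sel$target, metric = sel$metric,
             winning_model = sel$formula, bic = sel$bic,
             n_excluded = sel$n_excluded, stringsAsFactors = FALSE)
}
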