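#' Run replicated trials for every ensemble member
#'
#' The control arm's hazard depends only on the calibrated baseline
#' mutation rate, so its curve is computed once and shared across the
#' ensemble. For each parameter set, the supplemented mutation rate is
#' the baseline rate times the set's dose-response ratio at the
#' supplement selenium level; the supplement arm uses the at-entry
#' switch surface. Each set's replicates are classified by the
#' beneficial/harmful/insignificant rule.
#'
#' @param ensemble tibble from [build_ensemble()].
#' @param constraint the [calibration_constraint()] used to build it.
#' @param onset_params baseline `onset_parameters` (its `mu` must equal
#'   the constraint's target mutation rate).
#' @param design a [trial_design()].
#' @param seed integer seed; each set gets a derived sub-seed.
#' @return `ensemble` with added columns `supplement_ratio`, `label`,
#'   `n_significant`, `mean_hr` and a `trials` list-column of
#'   per-replicate results.
#' @export
run_ensemble_trials <- function(ensemble, constraint, onset_params,
                                design = trial_design(), seed = 1L) {
  stopifnot(inherits(onset_params, "onset_parameters"))
  if (abs(onset_params$mu / constraint$target_mutation_rate - 1) > 1e-9)
    stop("onset_params$mu must equal the calibrated baseline mutation rate",
         call. = FALSE)
  age_max <- design$entry_age_mean + 8 * design$entry_age_sd
  curve_ages <- seq(0, age_max + design$follow_up, by = 0.25)
  control_curve <- onset_hazard(onset_params, curve_ages)

  per_set <- function(i) {
    row <- ensemble[i, ]
    dr <- row$dose_response[[1]]
    ratio <- dr$relative_mutation_rate[
      dr$selenium_mM == design$supplement_selenium]
    if (length(ratio) != 1)
      stop(sprintf(
        "set %d: dose-response grid lacks the supplement level %.3g mM",
        row$set_id, design$supplement_selenium), call. = FALSE)
    supp <- onset_parameters(onset_params$nu, onset_params$mu * ratio,
                             onset_params$beta, onset_params$delta,
                             onset_params$K)
    surface <- onset_switch_surface(onset_params, supp,
                                    age_max = age_max,
                                    tau_max = design$follow_up)
    trials <- run_replicates(design, control_curve, surface,
                             seed = derive_seed(seed,
                                                paste0("set", row$set_id)))
    outcome <- classify_outcome(trials, alpha = design$alpha)
    tibble::tibble(set_id = row$set_id, supplement_ratio = ratio,
                   label = outcome$label,
                   n_significant = outcome$n_significant,
                   mean_hr = outcome$mean_hr, trials = list(trials))
  }
  res <- dplyr::bind_rows(lapply(seq_len(nrow(ensemble)), per_set))
  dplyr::left_join(ensemble, res, by = "set_id")
}

#' Study configuration
#'
#' Everything [run_study()] needs: network source, bounds, calibration,
#' onset parameters, trial design, ensemble size, VOI settings and the
#' master seed. Stages draw their randomness from named substreams of
#' the master seed, so any stage can be re-run in isolation with
#' identical randomness.
#'
#' @param network a `reaction_network`, or a path to an SBML file.
#' @param bounds bounds tibble (defaults to the shared printed range).
#' @param onset_params baseline `onset_parameters`.
#' @param constraint optional [calibration_constraint()]; defaults to one
#'   anchored at the nominal parameter set with
#'   `target_mutation_rate = onset_params$mu`.
#' @param design a [trial_design()].
#' @param n_sets ensemble size.
#' @param train_fraction,class_weight VOI settings.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(network = reference_selenium_network(),
                       bounds = NULL,
                       onset_params = onset_reference_parameters(),
                       constraint = NULL, design = trial_design(),
                       n_sets = 502L, train_fraction = 0.70,
                       class_weight = TRUE, seed = 1L) {
  if (is.character(network)) network <- import_sbml(network)$network
  if (is.null(bounds)) bounds <- default_parameter_bounds(network)
  if (is.null(constraint))
    constraint <- calibration_constraint(
      network, baseline_selenium = design$baseline_selenium,
      target_mutation_rate = onset_params$mu)
  structure(list(network = network, bounds = bounds,
                 onset_params = onset_params, constraint = constraint,
                 design = design, n_sets = as.integer(n_sets),
                 train_fraction = train_fraction,
                 class_weight = class_weight, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(lapply(unclass(config), unclass)), collapse = "")
  h <- 216613626
  for (ch in utf8ToInt(txt))
    h <- (bitwXor(h, ch) * 16777619) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full study: ensemble, trials, classification, VOI
#'
#' Executes the stages in order — constrained ensemble sampling,
#' replicated virtual trials with Cox analysis and outcome labels,
#' stratified split and boosted-tree classification, relative influence,
#' and enrichment under classifier- and threshold-based restriction —
#' and returns a `run_report` carrying every intermediate table.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stage <- "ensemble"
  report <- tryCatch({
    ensemble <- build_ensemble(
      config$network, config$bounds, config$constraint,
      n = config$n_sets, seed = derive_seed(seed, "ensemble"),
      selenium_grid = sort(unique(c(
        seq(1.0, 4.0, by = 0.25), config$design$baseline_selenium,
        config$design$supplement_selenium))))

    stage <- "trials"
    records <- run_ensemble_trials(ensemble, config$constraint,
                                   config$onset_params, config$design,
                                   seed = derive_seed(seed, "trials"))

    stage <- "voi"
    feats <- paste0("log10_", config$network$parameter_names)
    for (k in seq_along(feats))
      records[[feats[k]]] <-
        log10(records[[config$network$parameter_names[k]]])
    records$beneficial <- records$label == "beneficial"
    voi <- tryCatch({
      split <- split_train_test(records, config$train_fraction,
                                seed = derive_seed(seed, "split"))
      model <- train_classifier(split$train, features = feats,
                                class_weight = config$class_weight,
                                seed = derive_seed(seed, "classifier"))
      influence <- relative_influence(model)
      metrics <- test_metrics(model, split$test)
      enr_cls <- enrichment(records, model)
      top <- sub("^log10_", "", influence$parameter[1])
      dir <- if (stats::median(records[[top]][records$beneficial]) <
                 stats::median(records[[top]])) "below" else "above"
      enr_thr <- conditional_threshold_analysis(
        records, top, stats::median(records[[top]]), dir)
      list(model = model, influence = influence, metrics = metrics,
           enrichment_classifier = enr_cls,
           enrichment_threshold = enr_thr,
           threshold_parameter = top, threshold_direction = dir)
    }, error = function(e) {
      ## e.g. too few beneficial sets to stratify at small n_sets
      list(model = NULL, influence = NULL, metrics = NULL,
           enrichment_classifier = NULL, enrichment_threshold = NULL,
           skipped = conditionMessage(e))
    })

    stage <- "summarize"
    counts <- table(factor(records$label,
                           c("beneficial", "harmful", "insignificant")))
    hr_summary <- records |>
      dplyr::group_by(.data$label) |>
      dplyr::summarise(n = dplyr::n(), min_hr = min(.data$mean_hr),
                       median_hr = stats::median(.data$mean_hr),
                       max_hr = max(.data$mean_hr), .groups = "drop")

    structure(list(
      records = records, counts = as.list(counts),
      fractions = as.list(counts / nrow(records)),
      hr_summary = hr_summary,
      influence = voi$influence, metrics = voi$metrics,
      enrichment_classifier = voi$enrichment_classifier,
      enrichment_threshold = voi$enrichment_threshold,
      threshold_parameter = voi$threshold_parameter,
      threshold_direction = voi$threshold_direction,
      model = voi$model, voi_skipped = voi$skipped,
      provenance = list(seed = seed, n_sets = config$n_sets,
                        config_hash = config_hash(config),
                        package_version =
                          as.character(utils::packageVersion("selenotrial")),
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
      class = "run_report")
  }, error = function(e) {
    stop(sprintf("study failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  report
}

#' @export
print.run_report <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<run_report: %d parameter sets>\n", n))
  for (lab in names(x$counts))
    cat(sprintf("  %-13s %4d (%.1f%%)\n", lab, x$counts[[lab]],
                100 * x$fractions[[lab]]))
  if (!is.null(x$influence))
    cat("  top influence:", x$influence$parameter[1],
        sprintf("(%.1f%%)\n", x$influence$relative_influence_pct[1]))
  invisible(x)
}

#' Write a study report to disk
#'
#' CSV tables (ensemble records, per-replicate trial results, influence
#' ranking), a JSON summary, and the dose-response and influence figures.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
render_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  w <- function(name) file.path(out_dir, name)

  rec <- report$records
  flat <- rec[, !vapply(rec, is.list, TRUE)]
  utils::write.csv(flat, w("ensemble_records.csv"), row.names = FALSE)
  paths <- c(paths, w("ensemble_records.csv"))

  if (nrow(rec) > 0 && "trials" %in% names(rec)) {
    trials <- dplyr::bind_rows(
      purrr::map2(rec$set_id, rec$trials,
                  ~ dplyr::bind_cols(tibble::tibble(set_id = .x), .y)))
    utils::write.csv(trials, w("trial_results.csv"), row.names = FALSE)
    paths <- c(paths, w("trial_results.csv"))
  }
  if (!is.null(report$influence)) {
    utils::write.csv(report$influence, w("influence.csv"),
                     row.names = FALSE)
    paths <- c(paths, w("influence.csv"))
  }
  summary_list <- list(
    counts = report$counts, fractions = report$fractions,
    hr_summary = report$hr_summary, metrics = report$metrics,
    enrichment_classifier = report$enrichment_classifier,
    enrichment_threshold = report$enrichment_threshold,
    threshold_parameter = report$threshold_parameter,
    threshold_direction = report$threshold_direction,
    provenance = report$provenance)
  jsonlite::write_json(summary_list, w("summary.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  paths <- c(paths, w("summary.json"))

  if (nrow(rec) > 0 && "dose_response" %in% names(rec)) {
    p1 <- plot_dose_response(rec)
    ggplot2::ggsave(w("dose_response.png"), p1, width = 7, height = 5,
                    dpi = 150)
    paths <- c(paths, w("dose_response.png"))
  }
  if (!is.null(report$influence)) {
    p2 <- plot_influence(report$influence)
    ggplot2::ggsave(w("influence.png"), p2, width = 7, height = 5,
                    dpi = 150)
    paths <- c(paths, w("influence.png"))
  }
  invisible(paths)
}
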