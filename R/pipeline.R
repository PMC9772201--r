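#' Pipeline configuration
#'
#' Serializable description of a full analysis run: the cohort configuration
#' plus analysis toggles. Written to/read from YAML by [run_pipeline()] and
#' the command-line wrapper.
#'
#' @param cohort a [cohort_config()].
#' @param consistency_iters split-half iterations (default 1000).
#' @param run_bayes fit the Bayesian refit and BF01 (default `FALSE`; MCMC).
#' @param bf_widths prior-width grid for the sensitivity table.
#' @param run_ddm fit the per-participant DDM regressions (default `FALSE`).
#' @param power_grid optional sample-size grid; `NULL` skips the power stage.
#' @param power_or focal odds ratio for the power stage (default 0.97).
#' @param power_sims replicates per grid point.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            consistency_iters = 1000L,
                            run_bayes = FALSE,
                            bf_widths = c(0.1, 0.25, 0.5, 1, 2),
                            run_ddm = FALSE,
                            power_grid = NULL, power_or = 0.97,
                            power_sims = 100L) {
  structure(list(cohort = cohort, consistency_iters = consistency_iters,
                 run_bayes = run_bayes, bf_widths = bf_widths,
                 run_ddm = run_ddm, power_grid = power_grid,
                 power_or = power_or, power_sims = power_sims),
            class = "pipeline_config")
}

#' Run the full simulate-score-design-screen-infer pipeline
#'
#' Executes every stage on a synthetic cohort, writing each stage's tabular
#' outputs as CSV and structured results as JSON into `out_dir`, each with a
#' JSON provenance sidecar (seed, config hash). Deterministic given the
#' config seed. A stage failure aborts with an error naming the stage.
#'
#' Stages: item bank; recognition streams + responses; memory exclusions,
#' CR scoring, split-half consistency; ratings, ranking, pairing, trial
#' assembly; choice simulation; screening; conditional mixed models (value
#' model on the low-`|delta mem|` half, memorability model on the
#' low-`|delta value|` half, the two RT models, and the SumMem models); and
#' optionally Bayes factors, power, and the DDM decomposition.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @return a named list of in-memory results (invisible), with a
#'   human-readable `summary` character vector.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cc <- config$cohort
  results <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  bank <- stage("item_bank", make_item_bank(cc))
  streams <- stage("streams", build_streams(
    bank$item_id, cc$n_mem_participants,
    n_targets = min(29L, cc$n_items %/% 4),
    n_fillers = min(109L, cc$n_items - min(29L, cc$n_items %/% 4)),
    min_target_gap = if (cc$n_items >= 138) 61L else max(2L, cc$n_items %/% 4),
    seed = substream_seed(cc$seed, "streams")))
  responses <- stage("recognition", simulate_recognition(bank, streams, cc))
  mem_excl <- stage("memory_exclusions", exclude_memory_participants(responses))
  scores <- stage("item_scores",
                  participant_item_scores(responses, keep = mem_excl$kept))
  mem_table <- stage("memorability", score_memorability(scores))
  consistency <- if (config$consistency_iters >= 1) {
    stage("consistency", split_half_consistency(
      scores, n_iter = config$consistency_iters,
      seed = substream_seed(cc$seed, "consistency")))
  } else NULL

  ratings <- stage("ratings", zscore_ratings(simulate_ratings(
    bank, cc$n_choice_participants, cc$rating_noise_sd,
    seed = substream_seed(cc$seed, "ratings"))))
  ranks <- stage("ranking", rank_items(ratings,
                                       seed = substream_seed(cc$seed, "ranks")))
  pairs <- stage("pairs", build_choice_pairs(ranks))
  mem_z <- stage("mem_z", zscore_memorability(mem_table))
  trials <- stage("trials", assemble_choice_trials(
    pairs, ratings, mem_z, seed = substream_seed(cc$seed, "sides")))
  trials <- stage("choices", simulate_choices(
    trials, cc$choice_params, seed = substream_seed(cc$seed, "choices")))

  screening <- stage("screening", screen_participants(trials))
  kept <- screening$participant_id[screening$kept]
  if (length(kept) < 2) {
    stop("pipeline stage 'screening' failed: fewer than 2 kept participants",
         call. = FALSE)
  }
  kept_trials <- trials[trials$participant_id %in% kept, ]

  models <- stage("inference", list(
    value_choice = fit_mixed_logistic(kept_trials, model_spec(
      "chose_higher_value", "abs_delta_value", split_on = "abs_delta_mem")),
    mem_choice = fit_mixed_logistic(kept_trials, model_spec(
      "chose_more_memorable", "abs_delta_mem", split_on = "abs_delta_value")),
    value_rt = fit_mixed_linear(kept_trials, model_spec(
      "log_rt", "abs_delta_value", split_on = "abs_delta_mem")),
    mem_rt = fit_mixed_linear(kept_trials, model_spec(
      "log_rt", "abs_delta_mem", split_on = "abs_delta_value")),
    summem_choice = fit_mixed_logistic(kept_trials, model_spec(
      "chose_right", c("delta_value", "sum_mem", "delta_value:sum_mem"),
      random_slopes = c("delta_value", "sum_mem")))
  ))

  value_means <- stage("item_means", {
    agg <- aggregate(rating ~ item_id, data = ratings, FUN = mean)
    setNames(agg$rating, agg$item_id)
  })
  mv <- value_means[as.character(mem_table$item_id)]
  correlations <- stage("correlations", item_level_correlations(
    mem_table$cr, unname(mv), labels = c("cr", "mean_value")))

  results <- c(results, list(
    bank = bank, mem_table = mem_table, consistency = consistency,
    mem_exclusions = mem_excl, screening = screening, trials = trials,
    models = models, correlations = correlations))

  if (config$run_bayes) {
    results$bayes <- stage("bayes", fit_bayesian_mixed_logistic(
      kept_trials, model_spec("chose_more_memorable", "abs_delta_mem",
                              split_on = "abs_delta_value"),
      seed = substream_seed(cc$seed, "bayes")))
    results$bf_sensitivity <- stage("bf_sensitivity", bf_prior_sensitivity(
      kept_trials, model_spec("chose_more_memorable", "abs_delta_mem",
                              split_on = "abs_delta_value"),
      widths = config$bf_widths, seed = substream_seed(cc$seed, "bayes")))
  }
  if (!is.null(config$power_grid)) {
    results$power <- stage("power", power_simulation(
      config$power_or, config$power_grid, config$power_sims,
      template = power_template(cc),
      seed = substream_seed(cc$seed, "power")))
  }
  if (config$run_ddm) {
    results$ddm <- stage("ddm", fit_ddm_regression(
      kept_trials, min_trials = min(80L, nrow(kept_trials) %/%
                                      length(kept))))
  }

  results$summary <- pipeline_summary(results)
  if (!is.null(out_dir)) write_pipeline_outputs(results, out_dir)
  invisible(results)
}

pipeline_summary <- function(r) {
  s <- r$screening
  co <- function(m, term) m$coefficients[m$coefficients$term == term, ]
  vc <- co(r$models$value_choice, "abs_delta_value")
  mc <- co(r$models$mem_choice, "abs_delta_mem")
  c(sprintf("items: %d, memorability median CR = %.2f (range %.2f..%.2f)",
            nrow(r$mem_table), median(r$mem_table$cr),
            min(r$mem_table$cr), max(r$mem_table$cr)),
    if (!is.null(r$consistency)) {
      sprintf("split-half consistency: mean rho = %.3f, p = %.4g",
              r$consistency$mean_rho, r$consistency$p_value)
    } else "split-half consistency: skipped",
    sprintf("memory exclusions: %d of %d",
            length(r$mem_exclusions$excluded),
            nrow(r$mem_exclusions$summary)),
    sprintf("screening: %d side-bias, %d fast-RT, %d value-sanity; kept %d of %d",
            sum(s$side_bias_excluded), sum(s$fast_rt_excluded),
            sum(s$value_sanity_excluded), sum(s$kept), nrow(s)),
    sprintf("|dvalue| on choice (low |dmem| half): OR = %.2f [%.2f, %.2f], LRT p = %.3g",
            vc$or, vc$ci_lo, vc$ci_hi, vc$lrt_p),
    sprintf("|dmem| on choice (low |dvalue| half): OR = %.2f [%.2f, %.2f], LRT p = %.3g",
            mc$or, mc$ci_lo, mc$ci_hi, mc$lrt_p),
    sprintf("CR vs mean value: r(%d) = %.3f, p = %.3g",
            r$correlations$df, r$correlations$r, r$correlations$p))
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cc <- results$config$cohort
  sidecar <- list(seed = cc$seed, config_hash = config_hash(results$config))
  wcsv <- function(d, name) {
    utils::write.csv(d, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(sidecar, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE)
  }
  wcsv(as.data.frame(results$bank), "items")
  wcsv(as.data.frame(results$mem_table), "memorability")
  wcsv(as.data.frame(results$screening), "screening")
  wcsv(results$trials, "trials")
  if (!is.null(results$consistency)) {
    jsonlite::write_json(
      c(sidecar, list(mean_rho = results$consistency$mean_rho,
                      p_value = results$consistency$p_value,
                      null_rhos = results$consistency$null_rhos)),
      file.path(out_dir, "consistency.json"), auto_unbox = TRUE, digits = NA)
  }
  fits <- lapply(results$models, function(m) {
    c(list(response = m$spec$response, n_trials = m$n_trials,
           fallback = m$fallback), list(coefficients = m$coefficients))
  })
  jsonlite::write_json(c(sidecar, fits), file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(results$power)) wcsv(as.data.frame(results$power), "power")
  if (!is.null(results$ddm)) {
    wcsv(results$ddm$participants, "ddm_participants")
    jsonlite::write_json(c(sidecar, list(group = results$ddm$group)),
                         file.path(out_dir, "ddm_group.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  yaml::write_yaml(unclass_rec(results$config),
                   file.path(out_dir, "config.yaml"))
  writeLines(results$summary, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}

#' Load externally collected choice trials
#'
#' Reads one or more trial CSVs in the package's interchange schema
#' (`participant_id`, `left_item`, `right_item`, `delta_value`, `delta_mem`,
#' `abs_delta_value`, `abs_delta_mem`, `sum_mem`, `choice`, `rt_ms`),
#' validates the header, and stacks them. Extra columns are preserved.
#'
#' @param paths character vector of CSV paths.
#' @return a validated trial `data.frame`.
#' @export
load_external_trials <- function(paths) {
  need <- c("participant_id", "left_item", "right_item", "delta_value",
            "delta_mem", "abs_delta_value", "abs_delta_mem", "sum_mem",
            "choice", "rt_ms")
  tabs <- lapply(paths, function(p) {
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    missing <- setdiff(need, names(d))
    if (length(missing)) {
      stop_data(basename(p), ": missing required column(s): ",
                paste(missing, collapse = ", "))
    }
    d
  })
  common <- Reduce(intersect, lapply(tabs, names))
  out <- do.call(rbind, lapply(tabs, function(d) d[common]))
  rownames(out) <- NULL
  out
}
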