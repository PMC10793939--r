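#' Pipeline run configuration
#'
#' @param input Path to a canonical abridged CSV, or `NULL` to simulate with
#'   `synthetic`.
#' @param synthetic A [synthetic_config()] used when `input` is `NULL`.
#' @param horizon Forecast horizon in 5-year periods (default 3: three
#'   periods past the last fitted one).
#' @param analysis_periods Periods whose indicator panels are clustered
#'   (default `c(1990, 2010, 2030)`; in-sample, in-sample, out-of-sample
#'   when fitting 1990..2015).
#' @param k Number of clusters, or `"auto"` for the index-battery vote.
#' @param k_range Candidate range when `k = "auto"`.
#' @param standardize Standardise indicators before clustering.
#' @param radix,rules Life-table construction options.
#' @param seed Seed recorded in the manifest and used for simulation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = synthetic_config(),
                       horizon = 3L, analysis_periods = c(1990L, 2010L, 2030L),
                       k = "auto", k_range = 2:8, standardize = TRUE,
                       radix = 1e5, rules = a_rules(), seed = 1L) {
  structure(list(input = input, synthetic = synthetic, horizon = horizon,
                 analysis_periods = as.integer(analysis_periods), k = k,
                 k_range = k_range, standardize = standardize, radix = radix,
                 rules = rules, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts the scalar fields of [run_config()] plus a nested `synthetic`
#' block with [synthetic_config()] fields; unset fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn_args <- y$synthetic %||% list()
  syn <- do.call(synthetic_config, syn_args)
  args <- y[setdiff(names(y), "synthetic")]
  args$synthetic <- syn
  do.call(run_config, args)
}

#' Run the full convergence-club analysis
#'
#' Executes every stage end to end: read or simulate the abridged panel,
#' fill the terminal group, compute in-sample indicator panels, fit and
#' forecast the logit Lee-Carter model per population, compute
#' out-of-sample indicator panels, select or fix k, cluster every analysis
#' period and sex, tabulate transitions, project onto principal components,
#' and run the beta-convergence and coefficient-of-variation analyses.
#' Every artifact is written as CSV under `out_dir` together with a
#' machine-readable JSON manifest (configuration, seed, versions,
#' warnings); the same configuration and seed reproduce the outputs
#' byte-for-byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `panel`,
#'   `indicator_panels`, `k`, `clusters`, `pca`, `convergence`,
#'   `dispersion`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(w); invokeRestart("muffleWarning")
    }), error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("mortclubs_pipeline_error", "error")))
    })
  }

  panel <- stage("input", {
    if (is.null(config$input)) {
      cfg <- config$synthetic
      cfg$seed <- config$seed
      generate_panel(cfg)$panel
    } else {
      read_abridged_csv(config$input)
    }
  })
  panel <- stage("fill_terminal", fill_terminal_group(panel, quiet = TRUE))
  write_abridged_csv(panel, file.path(out_dir, "panel_observed.csv"))

  fitted_periods <- sort(unique(panel$period_start))
  projected <- stage("lee_carter", lc_project_panel(panel, config$horizon))
  forecast_periods <- setdiff(sort(unique(projected$period_start)), fitted_periods)
  write_abridged_csv(
    projected[projected$period_start %in% forecast_periods, ],
    file.path(out_dir, "panel_forecast.csv"))

  analysis <- intersect(config$analysis_periods, unique(projected$period_start))
  panels <- stage("indicators", {
    indicator_panels(projected, periods = analysis,
                     radix = config$radix, rules = config$rules)
  })
  readr::write_csv(panels, file.path(out_dir, "indicator_panels.csv"),
                   progress = FALSE)

  k <- config$k
  ksel <- NULL
  if (identical(k, "auto")) {
    ksel <- stage("select_k", {
      first <- panels[panels$period_start == analysis[1] &
                        panels$sex == sort(unique(panels$sex))[1], ]
      select_k(first, config$k_range, standardize = config$standardize)
    })
    k <- ksel$best_k
    readr::write_csv(ksel$scores, file.path(out_dir, "k_selection.csv"),
                     progress = FALSE)
  }

  clusters <- stage("cluster", cluster_all(panels, k, config$standardize))
  labels <- purrr::map(clusters$solutions, tidy.cluster_solution) |>
    purrr::list_rbind()
  readr::write_csv(labels, file.path(out_dir, "clusters.csv"), progress = FALSE)
  summaries <- purrr::imap(clusters$solutions, function(s, nm) {
    dplyr::mutate(s$summary, period_sex = nm,
                  representative = s$representative[.data$cluster])
  }) |> purrr::list_rbind()
  readr::write_csv(summaries, file.path(out_dir, "cluster_summaries.csv"),
                   progress = FALSE)
  flows <- purrr::imap(clusters$transitions, function(tr, nm) {
    dplyr::mutate(tr$flows, transition = nm)
  }) |> purrr::list_rbind()
  if (length(flows) > 0) {
    readr::write_csv(flows, file.path(out_dir, "transitions.csv"),
                     progress = FALSE)
  }

  pca <- stage("pca", {
    combos <- dplyr::distinct(panels, .data$period_start, .data$sex)
    purrr::pmap(combos, function(period_start, sex) {
      pr <- project_pca(panels[panels$period_start == period_start &
                                 panels$sex == sex, ])
      dplyr::mutate(pr$scores, period_start = period_start, sex = sex,
                    var1 = pr$var_explained[1], var2 = pr$var_explained[2])
    }) |> purrr::list_rbind()
  })
  readr::write_csv(pca, file.path(out_dir, "pca_scores.csv"), progress = FALSE)

  pairs <- purrr::map(seq_len(length(analysis) - 1),
                      \(i) c(analysis[i], analysis[i + 1]))
  convergence <- NULL
  if (length(pairs) > 0 && nrow(dplyr::distinct(panels, .data$country)) >= 10) {
    convergence <- stage("convergence", convergence_report(panels, pairs))
    readr::write_csv(convergence, file.path(out_dir, "beta_convergence.csv"),
                     progress = FALSE)
  }
  dispersion <- stage("dispersion", sigma_dispersion(panels))
  readr::write_csv(dispersion, file.path(out_dir, "sigma_dispersion.csv"),
                   progress = FALSE)

  manifest <- list(
    package = "mortclubs",
    version = as.character(utils::packageVersion("mortclubs")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    input = config$input %||% "synthetic",
    synthetic = if (is.null(config$input)) unclass_config(config$synthetic),
    horizon = config$horizon,
    analysis_periods = analysis,
    k = k, k_auto = identical(config$k, "auto"),
    standardize = config$standardize,
    radix = config$radix,
    a_rules = unclass(config$rules),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(panel = projected, indicator_panels = panels, k = k,
                 k_selection = ksel, clusters = clusters, pca = pca,
                 convergence = convergence, dispersion = dispersion,
                 manifest = manifest))
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$grid <- NULL # implied by the canonical 21-group layout in the CSVs
  out
}
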