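#' Run the county targeting pipeline end to end
#'
#' Orchestrates the full analysis on a set of input tables: practice-share
#' construction and the cropland-density filter, degree-bin temperature and
#' seasonal precipitation features with 20-year normals and 5-year
#' deviations, per-acre obligation measures, honest-forest training with
#' iterative variable selection on the observed wave pair, the out-of-bag
#' calibration test, forecasting of the held-out wave-pair log ratios, mean
#' sequestration per practice, and the bivariate cost-efficiency
#' classification. Every stage logs the number of counties entering and
#' leaving; all randomness flows from `config$seed`, so identical
#' configurations produce identical outputs.
#'
#' @param config a `pipeline_config` from [load_pipeline_config()], or a path
#'   to a YAML configuration.
#' @return A list of class `pipeline_result`: `predictions`,
#'   `classification` (when `classify` is enabled), `calibration`,
#'   `importance`, `selected`, `models`, `log`, and `out_dir` when outputs
#'   were written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- new_stage_log()

  census <- read_input_table(config$paths$census, "census")
  weather <- read_input_table(config$paths$weather, "weather")
  soils <- read_input_table(config$paths$soils, "soils")
  obligations <- read_input_table(config$paths$obligations, "obligations")
  sequestration <- if (isTRUE(config$classify)) {
    read_input_table(config$paths$sequestration, "sequestration")
  }
  geometry <- if (!is.null(config$paths$geometry)) {
    read_input_table(config$paths$geometry, "geometry")
  }
  log$add("read", "counties in census", dplyr::n_distinct(census$county_id))

  result <- run_pipeline_tables(
    census = census, weather = weather, soils = soils,
    obligations = obligations, sequestration = sequestration,
    geometry = geometry, config = config, log = log
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(result$predictions,
                     file.path(config$out_dir, "predictions.csv"))
    if (!is.null(result$classification)) {
      readr::write_csv(result$classification,
                       file.path(config$out_dir, "classification.csv"))
    }
    readr::write_csv(result$calibration,
                     file.path(config$out_dir, "calibration.csv"))
    readr::write_csv(result$importance,
                     file.path(config$out_dir, "importance.csv"))
    readr::write_csv(result$log, file.path(config$out_dir, "stage_log.csv"))
    for (pr in names(result$models)) {
      write_forest_model(result$models[[pr]],
                         file.path(config$out_dir, paste0("forest_", pr)))
    }
    result$out_dir <- config$out_dir
  }
  result
}

new_stage_log <- function() {
  entries <- list()
  add <- function(stage, what, count) {
    entries[[length(entries) + 1]] <<- tibble::tibble(
      stage = stage, what = what, count = as.integer(count)
    )
    message(sprintf("[%s] %s: %d", stage, what, count))
  }
  as_tibble <- function() dplyr::bind_rows(entries)
  list(add = add, as_tibble = as_tibble)
}

#' Run the pipeline on in-memory tables
#'
#' The computational core of [run_pipeline()], taking tibbles instead of
#' file paths. Useful for simulation studies where the synthetic tables
#' never touch disk.
#'
#' @param census,weather,soils,obligations input tables in the documented
#'   dialects (see [table_dialects()]).
#' @param sequestration sequestration scenario table, or `NULL` to skip
#'   classification.
#' @param geometry optional geometry stub for the export join.
#' @param config a `pipeline_config` (paths are ignored here) or a plain
#'   list with the same non-path fields.
#' @param log internal stage log (created if missing).
#' @return See [run_pipeline()].
#' @export
run_pipeline_tables <- function(census, weather, soils, obligations,
                                sequestration = NULL, geometry = NULL,
                                config = NULL, log = NULL) {
  defaults <- pipeline_config_defaults()
  config <- if (is.null(config)) defaults else modifyList(defaults, unclass(config))
  if (is.null(config$seed)) stop("config must set `seed`", call. = FALSE)
  log <- log %||% new_stage_log()
  waves <- as.integer(config$waves)
  train_pair <- waves[1:2]
  predict_pair <- waves[2:3]

  # --- practice shares and county filters -------------------------------
  shares <- practice_shares(census)
  crop_max <- dplyr::distinct(shares, .data$county_id, .data$cropland_max)
  counties <- dplyr::inner_join(
    crop_max, soils[c("county_id", "land_area")], by = "county_id"
  )
  log$add("shares", "counties with usable cropland", nrow(counties))
  if (isTRUE(config$cropland_decile_filter)) {
    kept <- cropland_filter(counties)
    log$add("cropland_filter", "counties dropped (low cropland density)",
            length(attr(kept, "dropped")))
  } else {
    kept <- counties
  }
  shares <- dplyr::semi_join(shares, kept, by = "county_id")
  log$add("cropland_filter", "counties kept", nrow(kept))

  # --- weather features -------------------------------------------------
  texp <- temperature_exposure(weather, config$temperature_index)
  ptot <- precipitation_totals(weather)
  annual <- dplyr::left_join(
    dplyr::select(texp, -"missing_days"),
    dplyr::select(ptot, -"missing_days"),
    by = c("county_id", "year")
  )
  climate_train <- normals_and_deviations(
    annual, train_pair[2], config$normal_window, config$deviation_window
  )
  climate_pred <- normals_and_deviations(
    annual, predict_pair[2], config$normal_window, config$deviation_window
  )
  log$add("climate", "counties with climate features", nrow(climate_train))

  # --- obligations ------------------------------------------------------
  ob_train_years <- seq(config$obligation_years$train[1],
                        config$obligation_years$train[2])
  ob_pred_years <- seq(config$obligation_years$predict[1],
                       config$obligation_years$predict[2])
  oblig_train <- obligation_features(obligations, crop_max, ob_train_years)
  oblig_pred <- obligation_features(obligations, crop_max, ob_pred_years)

  regions <- soils[c("county_id", "region_code")]
  soil_covars <- soils[setdiff(names(soils),
                               c("region_code", "land_area"))]

  # --- per-practice training, calibration, prediction -------------------
  predictions <- list()
  calibrations <- list()
  importances <- list()
  selected <- list()
  models <- list()
  for (pr in config$practices) {
    dm_train <- assemble_design_matrix(
      shares, climate_train, soil_covars, oblig_train, regions,
      wave_pair = train_pair, practice = pr, with_target = TRUE
    )
    log$add(paste0("design_", pr), "training counties", nrow(dm_train))

    fc <- do.call(forest_config, c(
      list(practice = pr, num_trees = config$num_trees,
           seed = config$seed + match(pr, config$practices)),
      config$forest[[pr]] %||% list()
    ))
    it <- iterative_train(dm_train, fc)
    models[[pr]] <- it$model
    selected[[pr]] <- it$selected
    importances[[pr]] <- dplyr::mutate(split_importance(it$model),
                                       practice = pr, .before = 1)
    log$add(paste0("train_", pr), "predictors retained",
            length(it$selected))

    oob <- predict(it$model, dm_train, oob = TRUE)
    cal <- calibration_test(oob$prediction, dm_train$target)
    calibrations[[pr]] <- dplyr::mutate(tidy(cal), practice = pr,
                                        .before = 1)

    dm_pred <- assemble_design_matrix(
      shares, climate_pred, soil_covars, oblig_pred, regions,
      wave_pair = predict_pair, practice = pr, with_target = FALSE
    )
    log$add(paste0("predict_", pr), "forecast counties", nrow(dm_pred))
    pred <- predict(it$model, dm_pred)
    predictions[[pr]] <- tibble::tibble(
      county_id = dm_pred$county_id,
      practice = pr,
      predicted_log_ratio = pred$prediction,
      n_trees = pred$n_trees_used
    )
  }
  predictions <- dplyr::bind_rows(predictions)
  calibration <- dplyr::bind_rows(calibrations)
  importance <- dplyr::bind_rows(importances)

  # --- sequestration and classification ---------------------------------
  classification <- NULL
  if (!is.null(sequestration)) {
    seq_means <- dplyr::bind_rows(lapply(config$practices, function(pr) {
      mean_sequestration(sequestration, pr)
    }))
    seq_means <- dplyr::semi_join(seq_means, kept, by = "county_id")
    classification <- export_classification(
      dplyr::select(predictions, -"n_trees"), seq_means, geometry
    )
    class(classification) <- c("carbontarget_classification",
                               class(classification))
    log$add("classify", "counties classified",
            sum(!is.na(classification$class_code)))
  }

  structure(
    list(
      predictions = predictions,
      classification = classification,
      calibration = calibration,
      importance = importance,
      selected = selected,
      models = models,
      log = log$as_tibble()
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  practices:", paste(names(x$models), collapse = ", "), "\n")
  cat("  forecast rows:", nrow(x$predictions), "\n")
  if (!is.null(x$classification)) {
    cat("  classified counties:",
        sum(!is.na(x$classification$class_code)), "\n")
  }
  invisible(x)
}

#' Plot adoption paths of scenario counties
#'
#' Draws the S-shaped adoption curves traced by [adoption_path()].
#'
#' @param object a [county_scenarios()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_adoption_path <- function(object, ...) {
  path <- adoption_path(object)
  ggplot2::ggplot(
    path,
    ggplot2::aes(x = .data$period, y = .data$share,
                 colour = .data$county_id)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "period", y = "share of producers adopting",
                  colour = "county")
}
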