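#' Input table dialects
#'
#' The pipeline exchanges plain CSV tables with fixed headers. This function
#' documents the dialect of each table kind: required columns, their types
#' and units.
#'
#' @return A named list of schema tibbles `(column, type, unit)`.
#' @export
table_dialects <- function() {
  schema <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble::tibble(column = m[, 1], type = m[, 2], unit = m[, 3])
  }
  list(
    census = schema(
      "county_id", "character", "-",
      "wave_year", "integer", "calendar year",
      "cropland_acres", "double", "acres",
      "cover_crop_acres", "double", "acres",
      "no_till_acres", "double", "acres",
      "conservation_till_acres", "double", "acres"
    ),
    weather = schema(
      "county_id", "character", "-",
      "date", "date", "ISO-8601",
      "tmax", "double", "degrees C",
      "tmin", "double", "degrees C",
      "prcp", "double", "mm"
    ),
    soils = schema(
      "county_id", "character", "-",
      "region_code", "character", "farm resource region",
      "land_area", "double", "acres",
      "clay", "double", "standardized",
      "silt", "double", "standardized",
      "om", "double", "standardized",
      "whc", "double", "standardized"
    ),
    obligations = schema(
      "county_id", "character", "-",
      "year", "integer", "calendar year",
      "total_dollars", "double", "dollars",
      "cover_crop_dollars", "double", "dollars",
      "tillage_dollars", "double", "dollars"
    ),
    sequestration = schema(
      "county_id", "character", "-",
      "cps", "integer", "conservation practice standard",
      "scenario", "character", "-",
      "joint", "logical", "-",
      "seq_tco2e_acre_yr", "double", "t CO2e/acre/yr"
    ),
    geometry = schema(
      "county_id", "character", "-"
    )
  )
}

dialect_col_types <- function(kind) {
  sch <- table_dialects()[[kind]]
  codes <- c(character = "c", integer = "i", double = "d", date = "D",
             logical = "l")
  paste(codes[sch$type], collapse = "")
}

#' Read and validate a pipeline input table
#'
#' Reads a CSV in one of the documented dialects (see [table_dialects()]),
#' checks the header exactly, parses columns with the declared types, and
#' reports unparseable cells with their row numbers. Empty tables are an
#' explicit error.
#'
#' @param path CSV file path.
#' @param kind one of `names(table_dialects())`.
#' @return A typed tibble.
#' @export
read_input_table <- function(path, kind) {
  kind <- match.arg(kind, names(table_dialects()))
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  sch <- table_dialects()[[kind]]
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(header, sch$column)) {
    stop(kind, " table header mismatch.\n  expected: ",
         paste(sch$column, collapse = ", "), "\n  found:    ",
         paste(header, collapse = ", "), call. = FALSE)
  }
  tab <- suppressWarnings(
    readr::read_csv(path, col_types = dialect_col_types(kind),
                    na = c("", "NA"))
  )  # parse problems are re-raised as errors below
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    stop(kind, " table has unparseable cell(s), e.g. row ", probs$row[1],
         " column ", probs$col[1], " (", nrow(probs), " problem(s) total)",
         call. = FALSE)
  }
  if (nrow(tab) == 0) {
    stop(kind, " table is empty: ", path, call. = FALSE)
  }
  tab
}

pipeline_config_defaults <- function() {
  list(
    paths = list(census = NULL, weather = NULL, soils = NULL,
                 obligations = NULL, sequestration = NULL, geometry = NULL),
    waves = c(2012L, 2017L, 2022L),
    practices = c("cover_crop", "reduced_till"),
    temperature_index = "mean",
    normal_window = 20L,
    deviation_window = 5L,
    cropland_decile_filter = TRUE,
    obligation_years = list(train = c(2014L, 2017L),
                            predict = c(2017L, 2022L)),
    num_trees = 2000L,
    forest = list(),
    seed = NULL,
    classify = TRUE,
    out_dir = NULL
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys, fills documented
#' defaults (standard forest parameter sets, season windows, 20-year
#' normals), and checks that every referenced input path exists and that the
#' seed is explicit (no wall-clock seeding).
#'
#' @param path YAML file path.
#' @return A validated config list of class `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, raw)
  if (is.null(cfg$seed)) {
    stop("configuration must set an explicit `seed`", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$waves <- as.integer(cfg$waves)
  if (length(cfg$waves) != 3) {
    stop("`waves` must list three census years (train pair + forecast year)",
         call. = FALSE)
  }
  required_paths <- c("census", "weather", "soils", "obligations",
                      if (isTRUE(cfg$classify)) "sequestration")
  for (nm in required_paths) {
    p <- cfg$paths[[nm]]
    if (is.null(p)) {
      stop("configuration missing input path: paths$", nm, call. = FALSE)
    }
    if (!file.exists(p)) {
      stop("input path does not exist: paths$", nm, " = ", p, call. = FALSE)
    }
  }
  bad_practice <- setdiff(cfg$practices, c("cover_crop", "reduced_till"))
  if (length(bad_practice) > 0) {
    stop("unknown practice(s): ", paste(bad_practice, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' Convenience inverse of [load_pipeline_config()] (used to generate the
#' worked configurations in tests and examples).
#'
#' @param config a config list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
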