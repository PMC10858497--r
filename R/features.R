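#' Practice shares of cropland
#'
#' Converts a wide census table into long per-practice records. No-till and
#' conservation-tillage acres are combined into a single reduced-tillage
#' category (census acreage cannot distinguish switches between them), and
#' each practice's acres are divided by the county's maximum cropland acres
#' across waves, so both waves share one denominator.
#'
#' @param census a data frame with columns `county_id`, `wave_year`,
#'   `cropland_acres`, `cover_crop_acres`, `no_till_acres`,
#'   `conservation_till_acres` (missing cells as `NA`).
#' @return A tibble `(county_id, wave_year, practice, acres, cropland_max,
#'   share, missing)` with `practice` in `{"cover_crop", "reduced_till"}`.
#'   Counties whose `cropland_max` is not positive are excluded and listed in
#'   the `excluded` attribute.
#' @export
practice_shares <- function(census) {
  required <- c("county_id", "wave_year", "cropland_acres",
                "cover_crop_acres", "no_till_acres",
                "conservation_till_acres")
  check_columns(census, required, "census")
  crop_max <- census |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(
      cropland_max = suppressWarnings(max(.data$cropland_acres, na.rm = TRUE))
    )
  crop_max$cropland_max[!is.finite(crop_max$cropland_max)] <- NA_real_
  bad <- crop_max$county_id[is.na(crop_max$cropland_max) |
                              crop_max$cropland_max <= 0]
  if (length(bad) > 0) {
    message("practice_shares: excluding ", length(bad),
            " county/ies with non-positive or missing cropland")
  }
  long <- census |>
    dplyr::mutate(
      cover_crop = .data$cover_crop_acres,
      reduced_till = .data$no_till_acres + .data$conservation_till_acres
    ) |>
    tidyr::pivot_longer(c("cover_crop", "reduced_till"),
                        names_to = "practice", values_to = "acres") |>
    dplyr::select("county_id", "wave_year", "practice", "acres") |>
    dplyr::inner_join(crop_max, by = "county_id") |>
    dplyr::filter(!.data$county_id %in% bad) |>
    dplyr::mutate(
      share = .data$acres / .data$cropland_max,
      missing = is.na(.data$acres)
    )
  attr(long, "excluded") <- bad
  long
}

#' Cropland-density decile filter
#'
#' Counties in the lowest decile of `cropland_max / land_area` carry little
#' agricultural signal and are excluded. The 10th percentile is computed with
#' linear interpolation (`stats::quantile` type 7) and counties with ratio
#' `<=` the cutoff are dropped, so boundary ties fall out with the low
#' decile.
#'
#' @param counties data frame with `county_id`, `cropland_max`, `land_area`
#'   (`land_area > 0`).
#' @return The kept rows, with a `dropped` attribute naming the excluded
#'   counties and the cutoff. With fewer than 10 counties the filter is
#'   skipped with a warning. If all ratios are identical every county is
#'   dropped and the result is flagged pathological.
#' @export
cropland_filter <- function(counties) {
  check_columns(counties, c("county_id", "cropland_max", "land_area"),
                "counties")
  if (any(counties$land_area <= 0)) {
    stop("`land_area` must be positive", call. = FALSE)
  }
  ratio <- counties$cropland_max / counties$land_area
  if (nrow(counties) < 10) {
    warning("fewer than 10 counties; cropland decile filter skipped")
    attr(counties, "dropped") <- character(0)
    return(counties)
  }
  cutoff <- unname(quantile(ratio, 0.1, type = 7, names = FALSE))
  keep <- ratio > cutoff
  out <- counties[keep, , drop = FALSE]
  attr(out, "dropped") <- counties$county_id[!keep]
  attr(out, "cutoff") <- cutoff
  if (!any(keep)) {
    warning("all cropland ratios identical; every county dropped ",
            "(pathological input)")
    attr(out, "pathological") <- TRUE
  }
  out
}

season_of_month <- function(month) {
  dplyr::case_when(
    month <= 2 ~ "pre",
    month <= 8 ~ "grow",
    TRUE ~ "post"
  )
}

temp_bin_labels <- c("tlt0", "t0_10", "t10_20", "t20_30", "tgt30")

#' Degree-bin temperature exposures
#'
#' Counts, per county and year, the days each season spent in five
#' temperature bins: below 0, [0,10), [10,20), [20,30), and 30 or more
#' degrees Celsius (30.0 itself counts as extreme heat). The daily index
#' temperature is the mean of Tmax and Tmin by default (`index = "tmax"`
#' switches to the daily maximum). Seasons: pre (Jan 1 - end Feb), growing
#' (Mar 1 - Aug 31), post (Sep 1 - Dec 31). Days with a missing index
#' temperature are tallied in `missing_days`, never imputed.
#'
#' @param daily data frame with `county_id`, `date` (Date), `tmax`, `tmin`
#'   (degrees C).
#' @param index `"mean"` (default) or `"tmax"`.
#' @return A wide tibble, one row per county-year, columns
#'   `<bin>_<season>` (days) plus `missing_days`.
#' @export
temperature_exposure <- function(daily, index = c("mean", "tmax")) {
  index <- match.arg(index)
  check_columns(daily, c("county_id", "date", "tmax", "tmin"), "daily")
  if (any(daily$tmax < daily$tmin, na.rm = TRUE)) {
    stop("tmax < tmin in daily series", call. = FALSE)
  }
  temp <- if (index == "mean") (daily$tmax + daily$tmin) / 2 else daily$tmax
  d <- tibble::tibble(
    county_id = daily$county_id,
    year = as.integer(format(daily$date, "%Y")),
    season = season_of_month(as.integer(format(daily$date, "%m"))),
    bin = cut(temp, c(-Inf, 0, 10, 20, 30, Inf), right = FALSE,
              labels = temp_bin_labels)
  )
  missing <- d |>
    dplyr::group_by(.data$county_id, .data$year) |>
    dplyr::summarise(missing_days = sum(is.na(.data$bin)), .groups = "drop")
  counts <- d |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::count(.data$county_id, .data$year, .data$season, .data$bin,
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = c("bin", "season"), values_from = "n",
                       names_sep = "_", values_fill = 0L)
  # ensure all 15 columns exist even if a season never occurs in the data
  expected <- as.vector(outer(temp_bin_labels, c("pre", "grow", "post"),
                              paste, sep = "_"))
  for (col in setdiff(expected, names(counts))) counts[[col]] <- 0L
  counts |>
    dplyr::select("county_id", "year", dplyr::all_of(expected)) |>
    dplyr::left_join(missing, by = c("county_id", "year"))
}

#' Seasonal precipitation totals
#'
#' Sums daily precipitation into pre-season (Jan-Feb), growing-season
#' (Mar-Aug) and post-season (Sep-Dec) totals per county and year. Missing
#' days are tallied, never imputed.
#'
#' @param daily data frame with `county_id`, `date`, `prcp` (mm, >= 0).
#' @return A tibble `(county_id, year, prcp_pre, prcp_grow, prcp_post,
#'   missing_days)`.
#' @export
precipitation_totals <- function(daily) {
  check_columns(daily, c("county_id", "date", "prcp"), "daily")
  if (any(daily$prcp < 0, na.rm = TRUE)) {
    stop("negative precipitation", call. = FALSE)
  }
  tibble::tibble(
    county_id = daily$county_id,
    year = as.integer(format(daily$date, "%Y")),
    season = season_of_month(as.integer(format(daily$date, "%m"))),
    prcp = daily$prcp
  ) |>
    dplyr::group_by(.data$county_id, .data$year) |>
    dplyr::summarise(
      prcp_pre = sum(.data$prcp[.data$season == "pre"], na.rm = TRUE),
      prcp_grow = sum(.data$prcp[.data$season == "grow"], na.rm = TRUE),
      prcp_post = sum(.data$prcp[.data$season == "post"], na.rm = TRUE),
      missing_days = sum(is.na(.data$prcp)),
      .groups = "drop"
    )
}

#' Climate normals and recent weather deviations
#'
#' For every exposure/precipitation variable, the climate normal is its mean
#' over the `normal_window` calendar years strictly before `reference_year`,
#' and the weather deviation is the mean of (annual value - normal) over the
#' `deviation_window` years ending at and including `reference_year`.
#' Counties lacking the full history are flagged missing (`NA`) rather than
#' silently averaged over fewer years.
#'
#' @param annual a per county-year table as returned by joining
#'   [temperature_exposure()] and [precipitation_totals()] (all non-key
#'   numeric columns are treated as variables; `missing_days` is ignored).
#' @param reference_year the census year the windows anchor on.
#' @param normal_window years in the normal (default 20).
#' @param deviation_window years in the deviation window (default 5).
#' @return A tibble, one row per county: `normal_<var>` and `dev_<var>`
#'   columns.
#' @export
normals_and_deviations <- function(annual, reference_year,
                                   normal_window = 20L,
                                   deviation_window = 5L) {
  check_columns(annual, c("county_id", "year"), "annual")
  vars <- setdiff(names(annual), c("county_id", "year", "missing_days"))
  normal_years <- seq(reference_year - normal_window, reference_year - 1L)
  dev_years <- seq(reference_year - deviation_window + 1L, reference_year)
  long <- tidyr::pivot_longer(annual[c("county_id", "year", vars)],
                              dplyr::all_of(vars),
                              names_to = "var", values_to = "value")
  norm <- long |>
    dplyr::filter(.data$year %in% normal_years) |>
    dplyr::group_by(.data$county_id, .data$var) |>
    dplyr::summarise(
      normal = ifelse(dplyr::n() == normal_window && !anyNA(.data$value),
                      mean(.data$value), NA_real_),
      .groups = "drop"
    )
  dev <- long |>
    dplyr::filter(.data$year %in% dev_years) |>
    dplyr::group_by(.data$county_id, .data$var) |>
    dplyr::summarise(
      dev_n = dplyr::n(),
      dev_mean = mean(.data$value),
      .groups = "drop"
    ) |>
    dplyr::left_join(norm, by = c("county_id", "var")) |>
    dplyr::mutate(
      deviation = ifelse(.data$dev_n == deviation_window,
                         .data$dev_mean - .data$normal, NA_real_)
    )
  wide_norm <- tidyr::pivot_wider(norm, names_from = "var",
                                  values_from = "normal",
                                  names_prefix = "normal_")
  wide_dev <- tidyr::pivot_wider(
    dev[c("county_id", "var", "deviation")],
    names_from = "var", values_from = "deviation", names_prefix = "dev_"
  )
  dplyr::full_join(wide_norm, wide_dev, by = "county_id")
}

#' Per-acre conservation-program obligation measures
#'
#' Averages each county's annual program obligations over `year_range`,
#' divided by the county's maximum cropland acres: the total across all
#' programs, the cover-crop-practice total, and the tillage-practice total.
#' Missing annual cells are excluded from the mean (with counts recorded);
#' a measure with no observed years is `NA` for that county.
#'
#' @param obligations data frame with `county_id`, `year`, `total_dollars`,
#'   `cover_crop_dollars`, `tillage_dollars`.
#' @param cropland data frame with `county_id`, `cropland_max`.
#' @param year_range integer vector of years to average over.
#' @return A tibble per county: `oblig_total`, `oblig_cover`, `oblig_till`
#'   (dollars/acre/yr) and the corresponding `*_n_years` counts.
#' @export
obligation_features <- function(obligations, cropland, year_range) {
  check_columns(obligations,
                c("county_id", "year", "total_dollars",
                  "cover_crop_dollars", "tillage_dollars"),
                "obligations")
  check_columns(cropland, c("county_id", "cropland_max"), "cropland")
  stopifnot(length(year_range) >= 1)
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  obligations |>
    dplyr::filter(.data$year %in% year_range) |>
    dplyr::inner_join(cropland, by = "county_id") |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(
      oblig_total = mean_or_na(.data$total_dollars / .data$cropland_max),
      oblig_cover = mean_or_na(.data$cover_crop_dollars / .data$cropland_max),
      oblig_till = mean_or_na(.data$tillage_dollars / .data$cropland_max),
      oblig_total_n_years = sum(!is.na(.data$total_dollars)),
      oblig_cover_n_years = sum(!is.na(.data$cover_crop_dollars)),
      oblig_till_n_years = sum(!is.na(.data$tillage_dollars)),
      .groups = "drop"
    )
}

#' Assemble the forecasting design matrix
#'
#' Joins practice shares, climate normals and weather deviations, soils,
#' obligation measures and region indicators into the predictor set for the
#' log-ratio growth target: the lagged adoption share
#' (`y_prev / cropland_max`, raw-acre denominator), log lagged acres, and the
#' growing-condition covariates. Counties with non-positive lagged acres (or,
#' when a target is requested, non-positive current acres) are dropped and
#' logged. Region codes are one-hot encoded.
#'
#' @param shares output of [practice_shares()].
#' @param climate output of [normals_and_deviations()].
#' @param soils data frame `county_id` + numeric soil covariates.
#' @param obligations output of [obligation_features()] (the `*_n_years`
#'   bookkeeping columns are not used as predictors).
#' @param regions data frame `(county_id, region_code)`.
#' @param wave_pair length-2 integer vector `(earlier, later)` census years.
#' @param practice `"cover_crop"` or `"reduced_till"`.
#' @param with_target include the training target `ln(y_t / y_prev)`
#'   (default `TRUE`; set `FALSE` for the prediction-time matrix, where the
#'   later wave's acres are unobserved).
#' @return A tibble keyed by `county_id` with `target` (if requested),
#'   `lagged_share`, `log_lagged_acres` and all feature columns. Attributes:
#'   `manifest` (column roles) and `dropped` (county/reason log).
#' @export
assemble_design_matrix <- function(shares, climate, soils, obligations,
                                   regions, wave_pair, practice,
                                   with_target = TRUE) {
  stopifnot(length(wave_pair) == 2, wave_pair[1] < wave_pair[2])
  practice <- match.arg(practice, c("cover_crop", "reduced_till"))
  check_columns(regions, c("county_id", "region_code"), "regions")

  prev <- shares |>
    dplyr::filter(.data$practice == !!practice,
                  .data$wave_year == wave_pair[1]) |>
    dplyr::select("county_id", y_prev = "acres", "cropland_max")
  cur <- shares |>
    dplyr::filter(.data$practice == !!practice,
                  .data$wave_year == wave_pair[2]) |>
    dplyr::select("county_id", y_t = "acres")
  base <- dplyr::left_join(prev, cur, by = "county_id")

  dropped <- tibble::tibble(county_id = character(0), reason = character(0))
  log_drop <- function(ids, reason) {
    if (length(ids) > 0) {
      dropped <<- dplyr::bind_rows(
        dropped, tibble::tibble(county_id = ids, reason = reason)
      )
    }
  }
  bad_prev <- base$county_id[is.na(base$y_prev) | base$y_prev <= 0]
  log_drop(bad_prev, "lagged acres missing or non-positive")
  base <- base[!base$county_id %in% bad_prev, ]
  if (with_target) {
    bad_cur <- base$county_id[is.na(base$y_t) | base$y_t <= 0]
    log_drop(bad_cur, "current acres missing or non-positive")
    base <- base[!base$county_id %in% bad_cur, ]
  }

  out <- base |>
    dplyr::mutate(
      lagged_share = .data$y_prev / .data$cropland_max,
      log_lagged_acres = log(.data$y_prev)
    )
  if (with_target) {
    out$target <- build_target(out$y_t, out$y_prev)
  }
  out <- dplyr::select(out, -"y_prev", -"y_t", -"cropland_max")

  join_check <- function(left, right, what) {
    miss <- setdiff(left$county_id, right$county_id)
    if (length(miss) > 0) {
      stop("assemble_design_matrix: ", what, " missing for county/ies: ",
           paste(head(miss, 5), collapse = ", "),
           if (length(miss) > 5) " ..." else "", call. = FALSE)
    }
    dplyr::left_join(left, right, by = "county_id")
  }
  out <- join_check(out, climate, "climate features")
  out <- join_check(out, soils, "soil covariates")
  out <- join_check(
    out,
    dplyr::select(obligations, -dplyr::ends_with("_n_years")),
    "obligation measures"
  )
  region_wide <- regions |>
    dplyr::mutate(value = 1L,
                  region_code = paste0("region_", .data$region_code)) |>
    tidyr::pivot_wider(names_from = "region_code", values_from = "value",
                       values_fill = 0L)
  out <- join_check(out, region_wide, "region code")

  feature_cols <- setdiff(names(out), c("county_id", "target"))
  attr(out, "manifest") <- tibble::tibble(
    column = c("county_id", if (with_target) "target", feature_cols),
    role = c("id", if (with_target) "target",
             rep("predictor", length(feature_cols)))
  )
  attr(out, "dropped") <- dropped
  out
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
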