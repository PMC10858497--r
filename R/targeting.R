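#' Mean sequestration per practice from scenario tables
#'
#' Averages per-county sequestration scenario estimates for a practice,
#' excluding scenarios where multiple practices are adopted jointly. The
#' reduced-tillage practice pools scenarios filed under conservation-practice
#' standards 329 (no-till/strip-till) and 345 (reduced till); cover-cropping
#' uses standard 340.
#'
#' @param scenario_table data frame with `county_id`, `cps` (integer CPS
#'   code), `joint` (logical), `seq_tco2e_acre_yr`.
#' @param practice `"cover_crop"` or `"reduced_till"`.
#' @return A tibble `(county_id, practice, mean_seq, n_scenarios)`. Counties
#'   with no eligible scenario are absent (callers treat them as missing).
#' @export
mean_sequestration <- function(scenario_table,
                               practice = c("cover_crop", "reduced_till")) {
  practice <- match.arg(practice)
  check_columns(scenario_table,
                c("county_id", "cps", "joint", "seq_tco2e_acre_yr"),
                "scenario")
  cps_codes <- switch(practice, cover_crop = 340L,
                      reduced_till = c(329L, 345L))
  scenario_table |>
    dplyr::filter(!.data$joint, .data$cps %in% cps_codes,
                  !is.na(.data$seq_tco2e_acre_yr)) |>
    dplyr::group_by(.data$county_id) |>
    dplyr::summarise(
      practice = practice,
      mean_seq = mean(.data$seq_tco2e_acre_yr),
      n_scenarios = dplyr::n(),
      .groups = "drop"
    )
}

#' Tercile assignment
#'
#' Assigns each value to a tercile with breakpoints at the 1/3 and 2/3
#' quantiles (linear interpolation, `stats::quantile` type 7) and
#' right-closed intervals `(-Inf, q1]`, `(q1, q2]`, `(q2, Inf)`. With
#' distinct values, group sizes differ by at most one.
#'
#' @param values numeric vector (at least 3 non-missing values).
#' @return Integer tercile labels 1-3 (`NA` in, `NA` out). If all values are
#'   equal every value lands in tercile 1 and the `pathological` attribute is
#'   set.
#' @export
tercile_assign <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3) stop("need at least 3 values", call. = FALSE)
  q <- quantile(values[ok], c(1 / 3, 2 / 3), type = 7, names = FALSE)
  out <- rep(NA_integer_, length(values))
  out[ok] <- 1L + (values[ok] > q[1]) + (values[ok] > q[2])
  if (q[1] == q[2] && all(values[ok] == values[ok][1])) {
    attr(out, "pathological") <- TRUE
    warning("all values identical; every value assigned tercile 1")
  }
  out
}

#' Adoption-rate interval assignment
#'
#' Counties with a non-positive predicted rate of change form the "negative"
#' interval (a rate of exactly zero is grouped with it so the intervals are
#' exhaustive); positive rates split at the median positive value into
#' low-positive (`<=` median) and high-positive.
#'
#' @param rates numeric predicted log ratios.
#' @return Character labels `"neg"`, `"low_pos"`, `"high_pos"` (`NA` in,
#'   `NA` out).
#' @export
rate_intervals <- function(rates) {
  out <- rep(NA_character_, length(rates))
  ok <- !is.na(rates)
  pos <- ok & rates > 0
  out[ok & rates <= 0] <- "neg"
  if (any(pos)) {
    med <- median(rates[pos])
    out[pos] <- ifelse(rates[pos] <= med, "low_pos", "high_pos")
  }
  out
}

rate_levels <- c("neg", "low_pos", "high_pos")

bivariate_labels <- c(
  "neg.1" = "inefficient",
  "neg.2" = "negative-rate/mid-sequestration",
  "neg.3" = "expensive-additional",
  "low_pos.1" = "low-rate/low-sequestration",
  "low_pos.2" = "low-rate/mid-sequestration",
  "low_pos.3" = "low-rate/high-sequestration",
  "high_pos.1" = "cheap-low-quality",
  "high_pos.2" = "high-rate/mid-sequestration",
  "high_pos.3" = "cost-effective"
)

#' Bivariate cost-efficiency classification
#'
#' Crosses the adoption-rate interval with the sequestration tercile into the
#' nine-class scheme behind the two-way choropleths. Corner classes carry the
#' cost-efficiency reading of the conceptual model: a negative rate with
#' bottom-tercile sequestration is "inefficient"; a high positive rate with
#' bottom-tercile sequestration is "cheap-low-quality" (credits are cheap but
#' largely non-additional); a negative rate with top-tercile sequestration is
#' "expensive-additional"; a high positive rate with top-tercile
#' sequestration is "cost-effective".
#'
#' @param rate_interval character vector of [rate_intervals()] labels.
#' @param seq_tercile integer vector of [tercile_assign()] labels.
#' @return A tibble `(rate_interval, seq_tercile, class_code, class_label)`;
#'   rows with either input missing get `NA` class.
#' @export
bivariate_classify <- function(rate_interval, seq_tercile) {
  stopifnot(length(rate_interval) == length(seq_tercile))
  bad <- !is.na(rate_interval) & !rate_interval %in% rate_levels
  if (any(bad)) {
    stop("unknown rate interval label(s): ",
         paste(unique(rate_interval[bad]), collapse = ", "), call. = FALSE)
  }
  code <- ifelse(
    is.na(rate_interval) | is.na(seq_tercile),
    NA_character_,
    paste(rate_interval, seq_tercile, sep = ".")
  )
  tibble::tibble(
    rate_interval = rate_interval,
    seq_tercile = as.integer(seq_tercile),
    class_code = code,
    class_label = unname(bivariate_labels[code])
  )
}

#' Export the county classification table
#'
#' Joins predicted rates, mean sequestration, intervals, terciles and class
#' labels into one row per county and practice; counties missing either
#' input keep their row with missing markers (the "white" counties of the
#' maps). Optionally joins a geometry stub (any table keyed by `county_id`)
#' for external choropleth rendering and writes the table to CSV.
#'
#' @param rates tibble `(county_id, practice, predicted_log_ratio)`.
#' @param sequestration tibble from [mean_sequestration()] (possibly several
#'   practices bound together).
#' @param geometry optional data frame keyed by `county_id`.
#' @param path optional CSV output path.
#' @return The classification tibble with columns `county_id`, `practice`,
#'   `predicted_log_ratio`, `mean_seq_tco2e_acre_yr`, `rate_interval`,
#'   `seq_tercile`, `class_code`, `class_label`.
#' @export
export_classification <- function(rates, sequestration, geometry = NULL,
                                  path = NULL) {
  check_columns(rates, c("county_id", "practice", "predicted_log_ratio"),
                "rates")
  out <- rates |>
    dplyr::left_join(
      dplyr::select(sequestration, "county_id", "practice", "mean_seq"),
      by = c("county_id", "practice")
    ) |>
    dplyr::group_by(.data$practice) |>
    dplyr::mutate(
      rate_interval = rate_intervals(.data$predicted_log_ratio),
      seq_tercile = tercile_assign_safe(.data$mean_seq)
    ) |>
    dplyr::ungroup()
  cls <- bivariate_classify(out$rate_interval, out$seq_tercile)
  out$class_code <- cls$class_code
  out$class_label <- cls$class_label
  out <- dplyr::rename(out, mean_seq_tco2e_acre_yr = "mean_seq")
  if (!is.null(geometry)) {
    miss <- setdiff(out$county_id, geometry$county_id)
    if (length(miss) > 0) {
      warning("geometry join misses ", length(miss), " county/ies")
    }
    out <- dplyr::left_join(out, geometry, by = "county_id")
  }
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

# tercile_assign that degrades to NA instead of erroring when a practice has
# under 3 defined sequestration means
tercile_assign_safe <- function(values) {
  if (sum(!is.na(values)) < 3) {
    return(rep(NA_integer_, length(values)))
  }
  tercile_assign(values)
}

#' Plot a bivariate classification grid
#'
#' Displays the county counts of each (adoption-rate interval, sequestration
#' tercile) class as a tile grid — the legend of the two-way choropleth.
#'
#' @param object a classification tibble from [export_classification()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.carbontarget_classification <- function(object, ...) {
  plot_classification(object)
}

#' @rdname autoplot.carbontarget_classification
#' @param classification a classification tibble from
#'   [export_classification()].
#' @export
plot_classification <- function(classification) {
  dat <- classification |>
    dplyr::filter(!is.na(.data$class_code)) |>
    dplyr::count(.data$practice, .data$rate_interval, .data$seq_tercile) |>
    dplyr::mutate(
      rate_interval = factor(.data$rate_interval, levels = rate_levels)
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = factor(.data$seq_tercile), y = .data$rate_interval,
                 fill = .data$n)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::facet_wrap(~practice) +
    ggplot2::labs(
      x = "sequestration tercile",
      y = "predicted adoption-rate interval",
      fill = "counties"
    )
}
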