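#' Configuration for the synthetic county panel
#'
#' Returns the generator settings for a synthetic panel with the statistical
#' structure the analysis assumes: a latent Gaussian net-return model drives
#' practice adoption in three census waves (the third held out as ground
#' truth), county climates follow seasonal sinusoids with county-specific
#' parameters, soils correlate with adoption propensity through a stated
#' linear model, program obligations carry structured missingness, and the
#' sequestration table mixes single-practice and joint-practice scenarios.
#'
#' Latent means are `mu = mu_intercept + coef . z + noise` where `z` are the
#' standardized soil/climate covariates; each practice has its own
#' coefficient vector, common time-varying path `L` (one value per wave) and
#' sequestration model. All values can be overridden via `...` (by top-level
#' name).
#'
#' @param n_counties number of counties.
#' @param waves census years; the last wave is generated but held out of the
#'   census table.
#' @param ... top-level overrides, e.g. `n_counties = 50`.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_counties = 500L,
                         waves = c(2012L, 2017L, 2022L), ...) {
  cfg <- list(
    n_counties = as.integer(n_counties),
    waves = as.integer(waves),
    sigma = 1,
    regions = paste0("R", 1:8),
    population_base = 200L,
    population_mean_extra = 400,
    acre_noise_sd = 0.05,
    missing_frac = 0.05,
    missing_mode = "mcar",  # or "small_county" (disclosure-style bias)
    practices = list(
      cover_crop = list(
        mu_intercept = -1.6,
        L = c(0, 0.20, 0.40),
        coef = c(clay = 0.15, silt = 0.05, om = 0.20, whc = 0.10,
                 temp = -0.15, precip = 0.25),
        mu_noise_sd = 0.30,
        trend_coef = c(precip = 0.10, temp = -0.08),
        trend_noise_sd = 0.05,
        seq_base = 0.35,
        seq_coef = c(precip = 0.08, clay = 0.04),
        seq_noise_sd = 0.05,
        seq_jitter_sd = 0.05
      ),
      reduced_till = list(
        mu_intercept = -0.30,
        L = c(0, 0.15, 0.30),
        coef = c(clay = 0.20, silt = 0.10, om = 0.10, whc = 0.15,
                 temp = -0.10, precip = 0.15),
        mu_noise_sd = 0.30,
        trend_coef = c(whc = 0.12, temp = -0.15),
        trend_noise_sd = 0.05,
        seq_base = 0.25,
        seq_coef = c(precip = 0.05, clay = 0.06),
        seq_noise_sd = 0.04,
        seq_jitter_sd = 0.05
      )
    ),
    obligations = list(
      years = 2014L:2022L,
      rate_meanlog = log(12),   # dollars/acre/yr, lognormal across counties
      rate_sdlog = 0.5,
      cover_frac_shape = c(2, 8),
      till_frac_shape = c(2, 6),
      missing_total = 0.02,
      missing_practice = 0.15
    ),
    weather_noise_sd = 1.5,
    precip_shape = 0.7
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown synth_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(cfg, over)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_counties < 2) stop("n_counties must be >= 2", call. = FALSE)
  if (length(cfg$waves) < 2) stop("need at least 2 waves", call. = FALSE)
  sds <- c(cfg$acre_noise_sd, cfg$weather_noise_sd,
           vapply(cfg$practices, `[[`, numeric(1), "mu_noise_sd"),
           vapply(cfg$practices, `[[`, numeric(1), "seq_noise_sd"))
  if (any(sds < 0)) stop("noise scales must be >= 0", call. = FALSE)
  if (cfg$missing_frac < 0 || cfg$missing_frac >= 1) {
    stop("missing_frac must be in [0, 1)", call. = FALSE)
  }
  for (pr in names(cfg$practices)) {
    if (length(cfg$practices[[pr]]$L) != length(cfg$waves)) {
      stop("practice `", pr, "` needs one L value per wave", call. = FALSE)
    }
  }
  invisible(cfg)
}

standardize <- function(x) as.numeric(scale(x))

#' Generate the latent county truth table
#'
#' Draws county geography (land area, cropland, region), standardized soil
#' covariates, county climate-generator parameters, producer populations,
#' and — per practice — the latent mean net return `mu` (a configured linear
#' function of soil/climate covariates plus Gaussian noise) and the true
#' sequestration rate. Deterministic given `seed`.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return A tibble with one row per county; columns include `mu_<practice>`
#'   and `seq_<practice>`.
#' @export
generate_truth <- function(config, seed) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- config$n_counties
  truth <- tibble::tibble(
    county_id = sprintf("C%04d", seq_len(n)),
    region_code = sample(config$regions, n, replace = TRUE),
    land_area = runif(n, 2e5, 6e5),
    population = config$population_base +
      rbinom(n, size = 4 * round(config$population_mean_extra), prob = 0.25),
    clay = rnorm(n),
    silt = rnorm(n),
    om = rnorm(n),
    whc = rnorm(n),
    tbar = runif(n, 6, 18),          # annual mean temperature, degrees C
    tamp = runif(n, 8, 14),          # seasonal amplitude
    trange = runif(n, 8, 12),        # diurnal range
    precip_daily = runif(n, 1.5, 4.5),  # mean daily precipitation, mm
    wet_prob = runif(n, 0.2, 0.45)
  )
  truth$cropland_base <- truth$land_area * runif(n, 0.05, 0.8)
  z <- list(
    clay = truth$clay, silt = truth$silt, om = truth$om, whc = truth$whc,
    temp = standardize(truth$tbar), precip = standardize(truth$precip_daily)
  )
  for (pr in names(config$practices)) {
    p <- config$practices[[pr]]
    lin <- p$mu_intercept
    for (nm in names(p$coef)) lin <- lin + p$coef[[nm]] * z[[nm]]
    truth[[paste0("mu_", pr)]] <- lin + rnorm(n, 0, p$mu_noise_sd)
    # county-specific drift in the time-varying return component: local
    # price/cost trends differ between counties, so some counties dis-adopt
    trend <- 0
    for (nm in names(p$trend_coef)) trend <- trend + p$trend_coef[[nm]] * z[[nm]]
    truth[[paste0("trend_", pr)]] <- trend + rnorm(n, 0, p$trend_noise_sd)
    seq_lin <- p$seq_base
    for (nm in names(p$seq_coef)) seq_lin <- seq_lin + p$seq_coef[[nm]] * z[[nm]]
    truth[[paste0("seq_", pr)]] <-
      pmax(seq_lin + rnorm(n, 0, p$seq_noise_sd), 0.02)
  }
  truth
}

#' Effective per-county time-varying path for a practice
#'
#' The common path `L` plus the county's drift: period `w` adds
#' `(w - 1) * trend` to the county's net returns.
#'
#' @param truth a [generate_truth()] table.
#' @param config the [synth_config()] used.
#' @param practice practice name.
#' @return A matrix (counties by waves) of effective L values.
#' @export
effective_L <- function(truth, config, practice) {
  p <- config$practices[[practice]]
  outer(truth[[paste0("trend_", practice)]], seq_along(p$L) - 1) +
    matrix(p$L, nrow(truth), length(p$L), byrow = TRUE)
}

#' Generate daily weather series
#'
#' Daily Tmax/Tmin follow a county-specific seasonal sinusoid (peak in
#' mid-July) plus independent Gaussian noise, re-ordered so `tmax >= tmin`
#' always holds; precipitation is an intermittent gamma process (wet days
#' Bernoulli, amounts gamma). No spatial correlation beyond the shared
#' seasonal form.
#'
#' @param truth a [generate_truth()] table.
#' @param years contiguous integer years.
#' @param seed integer seed.
#' @param config a [synth_config()].
#' @return A tibble `(county_id, date, tmax, tmin, prcp)`.
#' @export
generate_weather <- function(truth, years, seed, config = synth_config()) {
  stopifnot(all(diff(years) == 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  n_days <- length(dates)
  n <- nrow(truth)
  seasonal <- -cos(2 * pi * (doy - 15) / 365.25)  # peak mid-July
  idx <- rep(seq_len(n), each = n_days)
  tmean <- truth$tbar[idx] + truth$tamp[idx] * rep(seasonal, n)
  half_range <- truth$trange[idx] / 2
  noise_sd <- config$weather_noise_sd
  t_hi <- tmean + half_range + rnorm(n * n_days, 0, noise_sd)
  t_lo <- tmean - half_range + rnorm(n * n_days, 0, noise_sd)
  wet <- runif(n * n_days) < truth$wet_prob[idx]
  amt_mean <- truth$precip_daily[idx] / truth$wet_prob[idx]
  shape <- config$precip_shape
  prcp <- ifelse(wet, rgamma(n * n_days, shape = shape,
                             rate = shape / amt_mean), 0)
  tibble::tibble(
    county_id = truth$county_id[idx],
    date = rep(dates, n),
    tmax = pmax(t_hi, t_lo),
    tmin = pmin(t_hi, t_lo),
    prcp = prcp
  )
}

#' Generate census practice-acreage tables
#'
#' For every wave, the number of adopting producers is drawn
#' `Binomial(population, Phi((mu + L_eff) / sigma))` per practice, where
#' `L_eff` is the common path plus the county's drift (see [effective_L()]);
#' acres are
#' the adopter share times the wave's cropland acres with multiplicative
#' lognormal noise. A configured fraction of county-wave practice cells is
#' set missing in the census table (completely at random by default, or
#' biased toward small counties with `missing_mode = "small_county"`). The
#' final wave is withheld from the census and returned separately as ground
#' truth.
#'
#' @param truth a [generate_truth()] table.
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return A list: `census` (observed waves, with missingness, in the
#'   census-table dialect) and `holdout` (all waves, complete, with true
#'   shares and acres).
#' @export
generate_census_tables <- function(truth, config, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- nrow(truth)
  waves <- config$waves
  practices <- names(config$practices)
  rows <- list()
  for (w in seq_along(waves)) {
    cropland_w <- truth$cropland_base * exp(rnorm(n, 0, config$acre_noise_sd))
    row <- tibble::tibble(
      county_id = truth$county_id,
      wave_year = waves[w],
      cropland_acres = cropland_w
    )
    for (pr in practices) {
      p <- config$practices[[pr]]
      L_eff <- p$L[w] + (w - 1) * truth[[paste0("trend_", pr)]]
      share_true <- adoption_share(truth[[paste0("mu_", pr)]], L_eff,
                                   config$sigma)
      adopters <- rbinom(n, truth$population, share_true)
      share_emp <- adopters / truth$population
      acres <- share_emp * cropland_w * exp(rnorm(n, 0, config$acre_noise_sd))
      row[[paste0(pr, "_share_true")]] <- share_true
      row[[paste0(pr, "_share_emp")]] <- share_emp
      row[[paste0(pr, "_acres")]] <- acres
    }
    rows[[w]] <- row
  }
  full <- dplyr::bind_rows(rows)

  observed <- full[full$wave_year %in% waves[-length(waves)], ]
  census <- tibble::tibble(
    county_id = observed$county_id,
    wave_year = observed$wave_year,
    cropland_acres = observed$cropland_acres,
    cover_crop_acres = observed$cover_crop_acres,
    no_till_acres = NA_real_,
    conservation_till_acres = NA_real_
  )
  # split reduced-till acres into its two census components
  till_frac <- runif(nrow(observed), 0.55, 0.8)
  census$no_till_acres <- observed$reduced_till_acres * till_frac
  census$conservation_till_acres <- observed$reduced_till_acres *
    (1 - till_frac)

  for (col in c("cover_crop_acres", "no_till_acres",
                "conservation_till_acres")) {
    miss_prob <- if (identical(config$missing_mode, "small_county")) {
      pop <- truth$population[match(census$county_id, truth$county_id)]
      config$missing_frac * 2 * (1 - (rank(pop) - 0.5) / length(pop))
    } else {
      config$missing_frac
    }
    census[[col]][runif(nrow(census)) < miss_prob] <- NA_real_
  }
  list(census = census, holdout = full)
}

#' Generate obligations and sequestration scenario tables
#'
#' Obligations: per county and year, a lognormal per-acre total-program rate
#' times cropland, split into cover-crop and tillage practice components;
#' practice-specific cells go missing at a higher rate than totals
#' (mimicking disclosure suppression). Sequestration: per county, two
#' single-practice scenarios per practice (cover-crop standard 340:
#' legume / non-legume variants; reduced tillage: standards 329 and 345),
#' jittered around the county's true rate, plus a joint-adoption row per
#' county flagged `joint = TRUE` which downstream averaging must exclude.
#'
#' @param truth a [generate_truth()] table.
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return A list: `obligations`, `sequestration`.
#' @export
generate_program_tables <- function(truth, config, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  ob <- config$obligations
  n <- nrow(truth)
  grid <- tidyr::expand_grid(county_id = truth$county_id, year = ob$years)
  cropland <- truth$cropland_base[match(grid$county_id, truth$county_id)]
  rate <- exp(rnorm(nrow(grid), ob$rate_meanlog, ob$rate_sdlog))
  total <- rate * cropland / 1e3  # thousands of dollars scale kept in dollars
  cover_frac <- rbeta(nrow(grid), ob$cover_frac_shape[1],
                      ob$cover_frac_shape[2])
  till_frac <- rbeta(nrow(grid), ob$till_frac_shape[1], ob$till_frac_shape[2])
  obligations <- tibble::tibble(
    county_id = grid$county_id,
    year = grid$year,
    total_dollars = total,
    cover_crop_dollars = total * cover_frac,
    tillage_dollars = total * till_frac
  )
  obligations$total_dollars[runif(nrow(grid)) < ob$missing_total] <- NA_real_
  obligations$cover_crop_dollars[runif(nrow(grid)) < ob$missing_practice] <-
    NA_real_
  obligations$tillage_dollars[runif(nrow(grid)) < ob$missing_practice] <-
    NA_real_

  jitter1 <- function(x, sd) pmax(x * exp(rnorm(length(x), 0, sd)), 0.01)
  pc <- config$practices$cover_crop
  pt <- config$practices$reduced_till
  sequestration <- dplyr::bind_rows(
    tibble::tibble(county_id = truth$county_id, cps = 340L,
                   scenario = "legume cover crop, 50% N reduction",
                   joint = FALSE,
                   seq_tco2e_acre_yr = jitter1(truth$seq_cover_crop,
                                               pc$seq_jitter_sd)),
    tibble::tibble(county_id = truth$county_id, cps = 340L,
                   scenario = "non-legume cover crop, 25% N reduction",
                   joint = FALSE,
                   seq_tco2e_acre_yr = jitter1(truth$seq_cover_crop,
                                               pc$seq_jitter_sd)),
    tibble::tibble(county_id = truth$county_id, cps = 329L,
                   scenario = "intensive till to no-till/strip-till",
                   joint = FALSE,
                   seq_tco2e_acre_yr = jitter1(truth$seq_reduced_till,
                                               pt$seq_jitter_sd)),
    tibble::tibble(county_id = truth$county_id, cps = 345L,
                   scenario = "intensive till to reduced till",
                   joint = FALSE,
                   seq_tco2e_acre_yr = jitter1(truth$seq_reduced_till,
                                               pt$seq_jitter_sd)),
    tibble::tibble(county_id = truth$county_id, cps = 340L,
                   scenario = "cover crop jointly with no-till",
                   joint = TRUE,
                   seq_tco2e_acre_yr = jitter1(
                     truth$seq_cover_crop + truth$seq_reduced_till, 0.1))
  )
  list(obligations = obligations,
       sequestration = dplyr::arrange(sequestration, .data$county_id,
                                      .data$cps, .data$scenario))
}

#' Write a complete synthetic fixture bundle
#'
#' Generates every table of the synthetic study — census (with the final
#' wave withheld), daily weather spanning the 20-year normal window before
#' the first wave through the final wave, soils/region/land-area, program
#' obligations, sequestration scenarios, a geometry stub, and the truth
#' table — and writes them as CSVs plus a `manifest.json` recording the
#' seed and a hash of the configuration. Regenerating with the same config
#' and seed reproduces byte-identical files.
#'
#' @param config a [synth_config()].
#' @param seed integer master seed (sub-seeds are derived per table).
#' @param out_dir output directory.
#' @return Invisibly, a named list of file paths plus the in-memory tables.
#' @export
write_fixture_bundle <- function(config, seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  tables <- generate_bundle_tables(config, seed)
  paths <- list(
    census = file.path(out_dir, "census.csv"),
    weather = file.path(out_dir, "weather.csv"),
    soils = file.path(out_dir, "soils.csv"),
    obligations = file.path(out_dir, "obligations.csv"),
    sequestration = file.path(out_dir, "sequestration.csv"),
    geometry = file.path(out_dir, "geometry.csv"),
    truth = file.path(out_dir, "truth.csv")
  )
  for (nm in names(paths)) readr::write_csv(tables[[nm]], paths[[nm]])
  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    n_counties = config$n_counties,
    waves = config$waves,
    files = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, list(tables = tables,
                          manifest = file.path(out_dir, "manifest.json"))))
}

#' Generate all bundle tables in memory
#'
#' The in-memory counterpart of [write_fixture_bundle()]; used by tests and
#' simulation studies that do not need files on disk.
#'
#' @inheritParams write_fixture_bundle
#' @param weather_years optional integer years for the weather table
#'   (default: 20 years before the first wave through the last wave).
#' @return A named list of tibbles: `census`, `weather`, `soils`,
#'   `obligations`, `sequestration`, `geometry`, `truth`.
#' @export
generate_bundle_tables <- function(config, seed, weather_years = NULL) {
  stopifnot(inherits(config, "synth_config"))
  seed <- as.integer(seed)
  truth <- generate_truth(config, seed)
  weather_years <- weather_years %||%
    seq(min(config$waves) - 20L, max(config$waves))
  weather <- generate_weather(truth, weather_years, seed + 1L, config)
  cen <- generate_census_tables(truth, config, seed + 2L)
  prog <- generate_program_tables(truth, config, seed + 3L)

  soils <- truth[c("county_id", "region_code", "land_area",
                   "clay", "silt", "om", "whc")]
  geometry <- truth["county_id"]

  holdout_wide <- cen$holdout |>
    dplyr::select("county_id", "wave_year",
                  dplyr::ends_with("_acres"), dplyr::ends_with("_share_emp"),
                  dplyr::ends_with("_share_true")) |>
    tidyr::pivot_wider(names_from = "wave_year",
                       values_from = -c("county_id", "wave_year"),
                       names_sep = "_")
  truth_out <- dplyr::left_join(truth, holdout_wide, by = "county_id")

  list(census = cen$census, weather = weather, soils = soils,
       obligations = prog$obligations, sequestration = prog$sequestration,
       geometry = geometry, truth = truth_out)
}

#' True held-out log ratios from a truth table
#'
#' Recomputes `ln(y_final / y_previous)` per county and practice from the
#' truth table alone, for comparison against forest forecasts.
#'
#' @param truth_table the `truth` tibble from [generate_bundle_tables()].
#' @param config the [synth_config()] used.
#' @return A tibble `(county_id, practice, true_log_ratio)`.
#' @export
true_holdout_log_ratio <- function(truth_table, config) {
  waves <- config$waves
  w_prev <- waves[length(waves) - 1]
  w_last <- waves[length(waves)]
  purrr::map_dfr(names(config$practices), function(pr) {
    y_prev <- truth_table[[paste0(pr, "_acres_", w_prev)]]
    y_last <- truth_table[[paste0(pr, "_acres_", w_last)]]
    ok <- y_prev > 0 & y_last > 0
    tibble::tibble(
      county_id = truth_table$county_id[ok],
      practice = pr,
      true_log_ratio = log(y_last[ok] / y_prev[ok])
    )
  })
}

#' Compact forest-study fixture
#'
#' Builds the design matrix used for the forest property studies: the
#' training log-ratio target for the observed wave pair with a compact
#' predictor set (lagged adoption share, log lagged acres, soil covariates,
#' the county-level climate summaries the seasonal exposure features proxy,
#' per-acre obligation measures, and region indicators — about twenty
#' predictors for 500 counties), plus the held-out final-wave log ratios.
#' Counties with a missing or non-positive acreage cell in any involved wave
#' are dropped, so the same counties appear in both tables.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (drives truth, census and obligations draws).
#' @return A list: `design` (design-matrix tibble per practice, list-named),
#'   `truth_lr` (tibble of held-out true log ratios), `truth` (full truth
#'   table).
#' @export
forest_study_fixture <- function(config = synth_config(), seed = 1L) {
  seed <- as.integer(seed)
  truth <- generate_truth(config, seed)
  cen <- generate_census_tables(truth, config, seed + 2L)
  prog <- generate_program_tables(truth, config, seed + 3L)
  crop_max <- tibble::tibble(county_id = truth$county_id,
                             cropland_max = truth$cropland_base)
  oblig <- obligation_features(prog$obligations, crop_max,
                               seq(config$obligations$years[1],
                                   min(config$waves[2],
                                       max(config$obligations$years))))
  oblig_pred <- obligation_features(prog$obligations, crop_max,
                                    seq(config$waves[2],
                                        max(config$obligations$years)))
  waves <- config$waves
  region_wide <- truth["county_id"]
  for (r in config$regions[-1]) {
    region_wide[[paste0("region_", r)]] <-
      as.numeric(truth$region_code == r)
  }
  covars <- tibble::tibble(
    county_id = truth$county_id,
    clay = truth$clay, silt = truth$silt, om = truth$om, whc = truth$whc,
    climate_temp = truth$tbar, climate_precip = truth$precip_daily
  )
  design <- list()
  design_predict <- list()
  add_covars <- function(dm, ob) {
    dm <- dplyr::left_join(dm, covars, by = "county_id")
    dm <- dplyr::left_join(
      dm, dplyr::select(ob, -dplyr::ends_with("_n_years")),
      by = "county_id"
    )
    dplyr::left_join(dm, region_wide, by = "county_id")
  }
  for (pr in names(config$practices)) {
    acre_col <- function(w) {
      h <- cen$holdout[cen$holdout$wave_year == waves[w], ]
      h[[paste0(pr, "_acres")]][match(truth$county_id, h$county_id)]
    }
    y1 <- acre_col(1)
    y2 <- acre_col(2)
    ok <- !is.na(y1) & !is.na(y2) & y1 > 0 & y2 > 0
    dm <- tibble::tibble(
      county_id = truth$county_id[ok],
      target = build_target(y2[ok], y1[ok]),
      lagged_share = y1[ok] / truth$cropland_base[ok],
      log_lagged_acres = log(y1[ok])
    )
    design[[pr]] <- add_covars(dm, oblig)
    ok2 <- !is.na(y2) & y2 > 0
    dmp <- tibble::tibble(
      county_id = truth$county_id[ok2],
      lagged_share = y2[ok2] / truth$cropland_base[ok2],
      log_lagged_acres = log(y2[ok2])
    )
    design_predict[[pr]] <- add_covars(dmp, oblig_pred)
  }
  list(design = design,
       design_predict = design_predict,
       truth_lr = true_holdout_log_ratio(
         dplyr::left_join(
           truth,
           holdout_acres_wide(cen$holdout), by = "county_id"
         ), config),
       truth = truth)
}

holdout_acres_wide <- function(holdout) {
  holdout |>
    dplyr::select("county_id", "wave_year", dplyr::ends_with("_acres")) |>
    tidyr::pivot_wider(names_from = "wave_year",
                       values_from = -c("county_id", "wave_year"),
                       names_sep = "_")
}
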