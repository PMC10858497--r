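make_census <- function() {
  tibble::tibble(
    county_id = rep(c("X", "Y"), each = 2),
    wave_year = rep(c(2012L, 2017L), 2),
    cropland_acres = c(100, 120, 200, 180),
    cover_crop_acres = c(10, 12, NA, 20),
    no_till_acres = c(20, 30, 50, 60),
    conservation_till_acres = c(5, 10, 30, 20)
  )
}

test_that("practice shares use the max-cropland denominator and combine tillage", {
  sh <- practice_shares(make_census())
  x17 <- sh[sh$county_id == "X" & sh$wave_year == 2017, ]
  # denominator is max(100, 120) = 120 for both waves of county X
  expect_equal(unique(sh$cropland_max[sh$county_id == "X"]), 120)
  expect_equal(x17$share[x17$practice == "reduced_till"], 40 / 120)
  # reduced till = no-till + conservation tillage
  y12 <- sh[sh$county_id == "Y" & sh$wave_year == 2012, ]
  expect_equal(y12$acres[y12$practice == "reduced_till"], 80)
  expect_equal(y12$share[y12$practice == "reduced_till"], 80 / 200)
  expect_true(y12$missing[y12$practice == "cover_crop"])
})

test_that("worked arithmetic: no-till 50 + cons-till 30 over cropland 200 is 0.40", {
  cen <- tibble::tibble(
    county_id = "Z", wave_year = 2012L, cropland_acres = 200,
    cover_crop_acres = 5, no_till_acres = 50, conservation_till_acres = 30
  )
  sh <- practice_shares(cen)
  expect_equal(sh$share[sh$practice == "reduced_till"], 0.40)
})

test_that("counties without positive cropland are excluded with a log entry", {
  cen <- make_census()
  cen$cropland_acres[cen$county_id == "Y"] <- 0
  expect_message(sh <- practice_shares(cen), "excluding")
  expect_false("Y" %in% sh$county_id)
  expect_equal(attr(sh, "excluded"), "Y")
})

test_that("cropland decile filter matches a brute-force percentile", {
  withr::with_seed(19, {
    counties <- tibble::tibble(
      county_id = sprintf("C%03d", 1:100),
      cropland_max = runif(100, 1, 100),
      land_area = 100
    )
  })
  kept <- cropland_filter(counties)
  expect_equal(nrow(kept), 90)
  ratio <- counties$cropland_max / counties$land_area
  cutoff <- quantile(ratio, 0.1, type = 7)
  expect_setequal(kept$county_id, counties$county_id[ratio > cutoff])
  # a ratio above the median is always kept
  expect_true(all(counties$county_id[ratio > median(ratio)] %in%
                    kept$county_id))
})

test_that("cropland filter documents its pathological and small-n edges", {
  same <- tibble::tibble(county_id = letters[1:12], cropland_max = 5,
                         land_area = 10)
  expect_warning(kept <- cropland_filter(same), "pathological|identical")
  expect_equal(nrow(kept), 0)
  few <- tibble::tibble(county_id = letters[1:5],
                        cropland_max = 1:5, land_area = 10)
  expect_warning(kept2 <- cropland_filter(few), "skipped")
  expect_equal(nrow(kept2), 5)
})

test_that("temperature exposure bins match an exhaustive per-day oracle", {
  withr::with_seed(23, {
    days <- seq(as.Date("2015-01-01"), as.Date("2016-12-31"), by = "day")
    daily <- tibble::tibble(
      county_id = "W",
      date = days,
      tmin = runif(length(days), -20, 25)
    )
    daily$tmax <- daily$tmin + runif(length(days), 0, 15)
  })
  got <- temperature_exposure(daily)
  # brute force: classify every day independently
  tm <- (daily$tmax + daily$tmin) / 2
  season <- ifelse(format(daily$date, "%m") %in% c("01", "02"), "pre",
                   ifelse(format(daily$date, "%m") %in%
                            sprintf("%02d", 3:8), "grow", "post"))
  bin <- cut(tm, c(-Inf, 0, 10, 20, 30, Inf), right = FALSE,
             labels = c("tlt0", "t0_10", "t10_20", "t20_30", "tgt30"))
  year <- format(daily$date, "%Y")
  for (yr in c("2015", "2016")) {
    row <- got[got$year == as.integer(yr), ]
    for (b in levels(bin)) {
      for (s in c("pre", "grow", "post")) {
        expect_equal(row[[paste0(b, "_", s)]],
                     sum(bin == b & season == s & year == yr),
                     info = paste(yr, b, s))
      }
    }
    # seasons conserve the calendar (2016 is a leap year)
    expect_equal(sum(unlist(row[grep("^t", names(row))])),
                 if (yr == "2016") 366 else 365)
  }
})

test_that("a day at exactly 30 degrees counts as extreme heat", {
  daily <- tibble::tibble(
    county_id = "B", date = as.Date("2015-07-01"), tmax = 35, tmin = 25
  )
  got <- temperature_exposure(daily)
  expect_equal(got$tgt30_grow, 1L)
  expect_equal(got$t20_30_grow, 0L)
})

test_that("cold pre-season days land in the below-zero bin", {
  daily <- tibble::tibble(
    county_id = "C",
    date = seq(as.Date("2015-01-01"), as.Date("2015-02-28"), by = "day"),
    tmax = -3, tmin = -7
  )
  got <- temperature_exposure(daily)
  expect_equal(got$tlt0_pre, 59L)
  expect_equal(sum(unlist(got[grep("^t", names(got))])), 59L)
})

test_that("missing days are tallied, never imputed", {
  daily <- tibble::tibble(
    county_id = "D",
    date = as.Date("2015-06-01") + 0:9,
    tmax = c(NA, rep(20, 9)), tmin = c(NA, rep(10, 9))
  )
  got <- temperature_exposure(daily)
  expect_equal(got$missing_days, 1L)
  expect_equal(got$t10_20_grow, 9L)
  expect_error(
    temperature_exposure(tibble::tibble(
      county_id = "E", date = as.Date("2015-01-01"), tmax = 1, tmin = 5
    )),
    "tmax"
  )
})

test_that("precipitation totals follow the season calendar", {
  days <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  uniform <- tibble::tibble(county_id = "P", date = days, prcp = 1)
  got <- precipitation_totals(uniform)
  expect_equal(c(got$prcp_pre, got$prcp_grow, got$prcp_post),
               c(59, 184, 122))
  zero <- tibble::tibble(county_id = "P", date = days, prcp = 0)
  expect_equal(unlist(precipitation_totals(zero)[c("prcp_pre", "prcp_grow",
                                                   "prcp_post")],
                      use.names = FALSE), c(0, 0, 0))
  sep1 <- tibble::tibble(county_id = "P", date = as.Date("2015-09-01"),
                         prcp = 10)
  expect_equal(precipitation_totals(sep1)$prcp_post, 10)
})

test_that("normals and deviations use the documented windows", {
  # constant series: deviations exactly zero
  years <- 1997:2017
  ann <- tibble::tibble(county_id = "N", year = years, v = 5)
  nd <- normals_and_deviations(ann, 2017)
  expect_equal(nd$normal_v, 5)
  expect_equal(nd$dev_v, 0)
  # shifting the deviation window by a constant c gives deviation c
  ann2 <- ann
  ann2$v[ann2$year >= 2013] <- 5 + 2
  nd2 <- normals_and_deviations(ann2, 2017)
  expect_equal(nd2$normal_v, mean(ann2$v[ann2$year %in% 1997:2016]))
  expect_equal(nd2$dev_v, mean(ann2$v[ann2$year %in% 2013:2017]) -
                 nd2$normal_v)
  # trend series against brute force
  ann3 <- tibble::tibble(county_id = "N", year = 1990:2017,
                         v = 0.3 * (1990:2017 - 1990))
  nd3 <- normals_and_deviations(ann3, 2017)
  normal_bf <- mean(ann3$v[ann3$year %in% 1997:2016])
  expect_equal(nd3$normal_v, normal_bf)
  expect_equal(nd3$dev_v, mean(ann3$v[ann3$year %in% 2013:2017]) - normal_bf)
  # insufficient history flags the county-variable missing
  short <- tibble::tibble(county_id = "S", year = 2010:2017, v = 1)
  nd4 <- normals_and_deviations(short, 2017)
  expect_true(is.na(nd4$normal_v))
  expect_true(is.na(nd4$dev_v))
})

test_that("obligation features average per-acre dollars over observed years", {
  ob <- tibble::tibble(
    county_id = "O", year = c(2014L, 2015L),
    total_dollars = c(100, 200),
    cover_crop_dollars = c(NA, NA),
    tillage_dollars = c(50, NA)
  )
  crop <- tibble::tibble(county_id = "O", cropland_max = 1000)
  f <- obligation_features(ob, crop, 2014:2015)
  expect_equal(f$oblig_total, 0.15)
  expect_true(is.na(f$oblig_cover))
  expect_equal(f$oblig_till, 0.05)   # single observed year
  expect_equal(f$oblig_till_n_years, 1L)
})

test_that("obligation features equal a brute-force group-by mean", {
  withr::with_seed(29, {
    ob <- tidyr::expand_grid(county_id = c("a", "b", "c"),
                             year = 2014:2017)
    ob$total_dollars <- runif(nrow(ob), 0, 1000)
    ob$cover_crop_dollars <- runif(nrow(ob), 0, 300)
    ob$tillage_dollars <- runif(nrow(ob), 0, 300)
    ob$total_dollars[sample(nrow(ob), 3)] <- NA
    crop <- tibble::tibble(county_id = c("a", "b", "c"),
                           cropland_max = c(500, 800, 1200))
  })
  f <- obligation_features(ob, crop, 2014:2017)
  for (cid in c("a", "b", "c")) {
    rows <- ob[ob$county_id == cid, ]
    cm <- crop$cropland_max[crop$county_id == cid]
    expect_equal(f$oblig_total[f$county_id == cid],
                 mean(rows$total_dollars / cm, na.rm = TRUE))
  }
})

test_that("the design matrix assembles the lagged predictors and drops bad rows", {
  shares <- tibble::tibble(
    county_id = rep(c("X", "Y", "Z"), each = 2),
    wave_year = rep(c(2012L, 2017L), 3),
    practice = "cover_crop",
    acres = c(100, 150, 0, 10, 50, NA),
    cropland_max = rep(c(400, 300, 200), each = 2),
    share = NA, missing = FALSE
  )
  climate <- tibble::tibble(county_id = c("X", "Y", "Z"), normal_v = 1,
                            dev_v = 0)
  soils <- tibble::tibble(county_id = c("X", "Y", "Z"), clay = 0)
  oblig <- tibble::tibble(county_id = c("X", "Y", "Z"), oblig_total = 1,
                          oblig_total_n_years = 4L)
  regions <- tibble::tibble(county_id = c("X", "Y", "Z"),
                            region_code = c("R1", "R2", "R1"))
  dm <- assemble_design_matrix(shares, climate, soils, oblig, regions,
                               c(2012, 2017), "cover_crop")
  # Y dropped (zero lagged acres), Z dropped (missing current acres)
  expect_equal(dm$county_id, "X")
  expect_equal(dm$lagged_share, 100 / 400)
  expect_equal(dm$log_lagged_acres, log(100))
  expect_equal(dm$target, log(150 / 100))
  dropped <- attr(dm, "dropped")
  expect_setequal(dropped$county_id, c("Y", "Z"))
  expect_true(all(c("region_R1", "region_R2") %in% names(dm)))
  expect_false("oblig_total_n_years" %in% names(dm))
  manifest <- attr(dm, "manifest")
  expect_setequal(manifest$column, names(dm))
  # prediction-time matrix keeps Z (no target needed) but still drops Y
  dmp <- assemble_design_matrix(shares, climate, soils, oblig, regions,
                                c(2012, 2017), "cover_crop",
                                with_target = FALSE)
  expect_setequal(dmp$county_id, c("X", "Z"))
  expect_false("target" %in% names(dmp))
})

test_that("design-matrix joins fail loudly on missing counties", {
  shares <- tibble::tibble(
    county_id = c("X", "X"), wave_year = c(2012L, 2017L),
    practice = "cover_crop", acres = c(10, 12), cropland_max = 100,
    share = 0.1, missing = FALSE
  )
  climate <- tibble::tibble(county_id = "other", normal_v = 1)
  soils <- tibble::tibble(county_id = "X", clay = 0)
  oblig <- tibble::tibble(county_id = "X", oblig_total = 1)
  regions <- tibble::tibble(county_id = "X", region_code = "R1")
  expect_error(
    assemble_design_matrix(shares, climate, soils, oblig, regions,
                           c(2012, 2017), "cover_crop"),
    "climate.*X"
  )
})

test_that("design-matrix row count matches brute-force bookkeeping on a fixture", {
  cfg <- synth_config(n_counties = 60)
  tabs <- generate_bundle_tables(cfg, 55, weather_years = 1992:2017)
  shares <- practice_shares(tabs$census)
  texp <- temperature_exposure(tabs$weather)
  ptot <- precipitation_totals(tabs$weather)
  annual <- dplyr::left_join(dplyr::select(texp, -missing_days),
                             dplyr::select(ptot, -missing_days),
                             by = c("county_id", "year"))
  climate <- normals_and_deviations(annual, 2017)
  crop <- dplyr::distinct(shares, county_id, cropland_max)
  oblig <- obligation_features(tabs$obligations, crop, 2014:2017)
  soils <- tabs$soils[c("county_id", "clay", "silt", "om", "whc")]
  regions <- tabs$soils[c("county_id", "region_code")]
  dm <- assemble_design_matrix(shares, climate, soils, oblig, regions,
                               c(2012, 2017), "cover_crop")
  cc <- shares[shares$practice == "cover_crop", ]
  wide <- tidyr::pivot_wider(cc[c("county_id", "wave_year", "acres")],
                             names_from = wave_year, values_from = acres)
  expected_n <- sum(!is.na(wide$`2012`) & wide$`2012` > 0 &
                      !is.na(wide$`2017`) & wide$`2017` > 0)
  expect_equal(nrow(dm), expected_n)
})
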