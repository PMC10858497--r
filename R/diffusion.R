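#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; the worked-example bookkeeping
#' (shares to whole percents, dollars to cents) needs ties rounded away from
#' zero so that e.g. a cost of $0.625 prints as $0.63.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded with ties away from zero.
#' @examples
#' round_half_away(0.625, 2)  # 0.63, where round() gives 0.62
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Build a table of county adoption scenarios
#'
#' A scenario couples a county's latent net-return distribution with its
#' producer population and per-adopter sequestration rate. Producers' net
#' returns to adopting a conservation practice in period `t` are
#' `r_i + L[t]`, with the time-invariant component `r_i ~ Normal(mu, sigma)`
#' and a common time-varying path `L`. A producer adopts while the net return
#' is positive.
#'
#' @param county_id character or factor; unique county identifiers.
#' @param mu mean of the time-invariant net return, dollars.
#' @param sigma standard deviation of net returns, dollars (default 1).
#' @param population number of producers in the county (integer, >= 1).
#' @param seq_rate tons CO2e sequestered per adopting producer.
#' @param L_path numeric vector of the common time-varying return component,
#'   one element per period, or a list of such vectors (one per county).
#' @return A tibble with one row per county and a list-column `L_path`.
#' @examples
#' county_scenarios(c("A", "B"), mu = c(-2/3, -2), population = 1000,
#'                  seq_rate = 1, L_path = c(0, 2/3, 4/3))
#' @export
county_scenarios <- function(county_id, mu, sigma = 1, population = 1000L,
                             seq_rate = 1, L_path = c(0, 2 / 3, 4 / 3)) {
  if (anyDuplicated(county_id)) {
    stop("`county_id` must be unique", call. = FALSE)
  }
  if (any(sigma < 0)) stop("`sigma` must be >= 0", call. = FALSE)
  if (any(seq_rate < 0)) stop("`seq_rate` must be >= 0", call. = FALSE)
  if (any(population < 1)) stop("`population` must be >= 1", call. = FALSE)
  if (!is.list(L_path)) L_path <- list(L_path)
  if (any(lengths(L_path) == 0) ||
      !all(vapply(L_path, function(l) all(is.finite(l)), logical(1)))) {
    stop("each `L_path` must be non-empty and finite", call. = FALSE)
  }
  tibble::tibble(
    county_id = as.character(county_id),
    mu = mu,
    sigma = sigma,
    population = as.integer(population),
    seq_rate = seq_rate,
    L_path = L_path
  )
}

#' Specify a payment-for-practice program
#'
#' @param incentive dollars paid per enrolled adopter (>= 0).
#' @param fixed_cost fixed dollars per county to establish the program (>= 0).
#' @param window integer pair `(start, end)` of 1-based period indices into
#'   each county's `L_path`; producers adopting between `start` and `end` are
#'   compensated.
#' @return An object of class `program_spec`.
#' @examples
#' program_spec(incentive = 0.25, fixed_cost = 50, window = c(2, 3))
#' @export
program_spec <- function(incentive, fixed_cost, window) {
  stopifnot(length(incentive) == 1, length(fixed_cost) == 1,
            length(window) == 2)
  if (incentive < 0) stop("`incentive` must be >= 0", call. = FALSE)
  if (fixed_cost < 0) stop("`fixed_cost` must be >= 0", call. = FALSE)
  window <- as.integer(window)
  if (window[1] >= window[2]) {
    stop("`window` must satisfy start < end", call. = FALSE)
  }
  structure(
    list(incentive = incentive, fixed_cost = fixed_cost, window = window),
    class = "program_spec"
  )
}

#' @export
print.program_spec <- function(x, ...) {
  cat(sprintf(
    "<program_spec> incentive $%.2f/enrollee, fixed cost $%.2f/county, window periods %d-%d\n",
    x$incentive, x$fixed_cost, x$window[1], x$window[2]
  ))
  invisible(x)
}

#' Fraction of producers adopting in a period
#'
#' Under the Gaussian threshold model the fraction of a county's producers
#' with positive net returns in a period is `Phi((mu + L) / sigma)`. With
#' `sigma = 0` the distribution is degenerate and the share is 0 or 1
#' according to the sign of `mu + L`.
#'
#' @param mu mean time-invariant net return.
#' @param L time-varying return component for the period.
#' @param sigma standard deviation of net returns (>= 0).
#' @return Adoption share(s) in `[0, 1]`; vectorized over all arguments.
#' @examples
#' adoption_share(-2/3, 2/3)   # one half
#' adoption_share(-2, 0)       # roughly two percent
#' @export
adoption_share <- function(mu, L, sigma = 1) {
  if (any(sigma < 0)) stop("`sigma` must be >= 0", call. = FALSE)
  n <- max(length(mu), length(L), length(sigma))
  mu <- rep_len(mu, n)
  L <- rep_len(L, n)
  sigma <- rep_len(sigma, n)
  out <- numeric(n)
  deg <- sigma == 0
  out[deg] <- as.numeric(mu[deg] + L[deg] > 0)
  out[!deg] <- pnorm((mu[!deg] + L[!deg]) / sigma[!deg])
  out
}

#' Adoption path over all periods
#'
#' Evaluates [adoption_share()] at every element of each county's `L_path`.
#'
#' @param scenarios a tibble from [county_scenarios()].
#' @return A tibble with one row per county and period: `county_id`,
#'   `period` (1-based), `L`, `share`.
#' @export
adoption_path <- function(scenarios) {
  purrr::pmap_dfr(
    scenarios[c("county_id", "mu", "sigma", "L_path")],
    function(county_id, mu, sigma, L_path) {
      tibble::tibble(
        county_id = county_id,
        period = seq_along(L_path),
        L = L_path,
        share = adoption_share(mu, L_path, sigma)
      )
    }
  )
}

round_share <- function(share, rounding) {
  if (rounding == "nearest_percent") round_half_away(share, 2) else share
}

#' Program outcomes with additionality decomposition
#'
#' Computes, per county, the baseline adoption shares at the program window's
#' start and end, the share adopting once the incentive is added to final-
#' period returns, and the decomposition of enrollees into additional
#' adopters (induced by the incentive) and non-additional adopters (who would
#' have adopted anyway). The administrator cannot observe counterfactuals, so
#' every enrollee earns `seq_rate` credits while only additional adopters
#' sequester additional tons.
#'
#' Counts are shares times population; under `rounding = "nearest_percent"`
#' each share is first rounded to the nearest whole percent (ties away from
#' zero), which reproduces the standard worked example on a 1000-producer
#' county. Negative computed shares (possible when `L` declines over the
#' window by more than the incentive effect) are clamped to zero and flagged
#' in `share_clamped` rather than raising an error.
#'
#' @param scenarios a tibble from [county_scenarios()].
#' @param program a [program_spec()].
#' @param rounding `"exact"` (default) or `"nearest_percent"`.
#' @return A tibble, one row per county, with shares, counts, `total_cost`
#'   (dollars), `credits` and `additional_tons` (tons CO2e), and a
#'   `share_clamped` flag.
#' @examples
#' sc <- county_scenarios(c("A", "B"), mu = c(-2/3, -2), population = 1000,
#'                        seq_rate = 1)
#' program_outcome(sc, program_spec(0.25, 50, c(2, 3)), "nearest_percent")
#' @export
program_outcome <- function(scenarios, program,
                            rounding = c("exact", "nearest_percent")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(program, "program_spec"))
  w <- program$window
  purrr::pmap_dfr(
    scenarios[c("county_id", "mu", "sigma", "population", "seq_rate",
                "L_path")],
    function(county_id, mu, sigma, population, seq_rate, L_path) {
      if (w[2] > length(L_path)) {
        stop("program window outside L_path for county ", county_id,
             call. = FALSE)
      }
      s_start <- adoption_share(mu, L_path[w[1]], sigma)
      s_end <- adoption_share(mu, L_path[w[2]], sigma)
      s_prog <- adoption_share(mu, L_path[w[2]] + program$incentive, sigma)

      enrollee <- s_prog - s_start
      nonadd <- s_end - s_start
      add <- s_prog - s_end
      clamped <- any(c(enrollee, nonadd, add) < 0)
      enrollee <- max(enrollee, 0)
      nonadd <- max(nonadd, 0)
      add <- max(add, 0)

      n_enr <- round_share(enrollee, rounding) * population
      n_add <- round_share(add, rounding) * population
      n_non <- round_share(nonadd, rounding) * population

      total_cost <- program$incentive * n_enr + program$fixed_cost
      tibble::tibble(
        county_id = county_id,
        population = population,
        seq_rate = seq_rate,
        share_baseline_start = s_start,
        share_baseline_end = s_end,
        share_with_program = s_prog,
        enrollee_share = enrollee,
        additional_share = add,
        nonadditional_share = nonadd,
        enrollee_count = n_enr,
        additional_count = n_add,
        nonadditional_count = n_non,
        total_cost = total_cost,
        credits = n_enr * seq_rate,
        additional_tons = n_add * seq_rate,
        share_clamped = clamped
      )
    }
  )
}

#' Average-cost and credit-quality metrics
#'
#' Adds the program administrator's average-cost metrics to a
#' [program_outcome()] table: cost per enrollee, cost per credited ton
#' (`ac_per_credit`), cost per additional ton sequestered
#' (`ac_per_additional_ton`), and credit quality (additional tons per dollar
#' of credits sold at average cost, i.e. `additional_tons / total_cost`).
#' Metrics with a zero denominator are returned as `NA` and named in the
#' `undefined_metrics` column.
#'
#' @param outcomes a tibble from [program_outcome()].
#' @param program the [program_spec()] used (kept for interface symmetry;
#'   costs are already folded into `total_cost`).
#' @return `outcomes` with columns `ac_per_enrollee`, `ac_per_credit`,
#'   `ac_per_additional_ton`, `quality`, `undefined_metrics` appended.
#' @export
cost_metrics <- function(outcomes, program = NULL) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- dplyr::mutate(
    outcomes,
    ac_per_enrollee = safe_div(.data$total_cost, .data$enrollee_count),
    ac_per_credit = safe_div(.data$total_cost, .data$credits),
    ac_per_additional_ton = safe_div(.data$total_cost, .data$additional_tons),
    quality = safe_div(.data$additional_tons, .data$total_cost)
  )
  und <- apply(
    is.na(out[c("ac_per_enrollee", "ac_per_credit", "ac_per_additional_ton",
                "quality")]),
    1L,
    function(m) paste(c("ac_per_enrollee", "ac_per_credit",
                        "ac_per_additional_ton", "quality")[m],
                      collapse = ",")
  )
  out$undefined_metrics <- und
  if (any(nzchar(und))) {
    message("cost_metrics: undefined metrics (zero denominator) for ",
            sum(nzchar(und)), " county/ies; returned as NA")
  }
  out
}

#' Monte-Carlo agent simulation of a program
#'
#' Draws `n_draws` producer-level time-invariant returns from
#' `Normal(mu, sigma)` and applies the adoption and enrollment rules producer
#' by producer, giving an empirical counterpart to the closed-form
#' [program_outcome()]. Useful as a simulation check of the analytic shares.
#'
#' @param scenario a single-row tibble from [county_scenarios()].
#' @param program a [program_spec()].
#' @param n_draws number of simulated producers (>= 1).
#' @param seed integer seed; the simulation is reproducible given the seed.
#' @return A one-row tibble shaped like [program_outcome()] (exact-share
#'   bookkeeping; counts are empirical shares times `population`).
#' @export
simulate_agents <- function(scenario, program, n_draws, seed) {
  stopifnot(nrow(scenario) == 1, n_draws >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  w <- program$window
  L_path <- scenario$L_path[[1]]
  r <- rnorm(n_draws, scenario$mu, scenario$sigma)

  adopt_start <- r + L_path[w[1]] > 0
  adopt_end <- r + L_path[w[2]] > 0
  adopt_prog <- r + L_path[w[2]] + program$incentive > 0

  s_start <- mean(adopt_start)
  s_end <- mean(adopt_end)
  s_prog <- mean(adopt_prog)
  enrollee <- mean(adopt_prog & !adopt_start)
  nonadd <- mean(adopt_end & !adopt_start)
  add <- mean(adopt_prog & !adopt_end)

  population <- scenario$population
  n_enr <- enrollee * population
  n_add <- add * population
  n_non <- nonadd * population
  total_cost <- program$incentive * n_enr + program$fixed_cost
  tibble::tibble(
    county_id = scenario$county_id,
    population = population,
    seq_rate = scenario$seq_rate,
    share_baseline_start = s_start,
    share_baseline_end = s_end,
    share_with_program = s_prog,
    enrollee_share = enrollee,
    additional_share = add,
    nonadditional_share = nonadd,
    enrollee_count = n_enr,
    additional_count = n_add,
    nonadditional_count = n_non,
    total_cost = total_cost,
    credits = n_enr * scenario$seq_rate,
    additional_tons = n_add * scenario$seq_rate,
    share_clamped = FALSE
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Rank counties by a cost-efficiency metric
#'
#' Runs [program_outcome()] and [cost_metrics()] for every scenario and
#' orders counties by the chosen metric: ascending average cost per credit or
#' per additional ton, or descending credit quality. Undefined (NA) metrics
#' sort last; ties break by `county_id` (stable).
#'
#' @param scenarios a tibble from [county_scenarios()].
#' @param program a [program_spec()].
#' @param metric one of `"per_credit"`, `"per_additional_ton"`, `"quality"`.
#' @param rounding passed to [program_outcome()].
#' @return The metrics tibble, ordered, with a `rank` column.
#' @export
rank_counties <- function(scenarios, program,
                          metric = c("per_credit", "per_additional_ton",
                                     "quality"),
                          rounding = c("exact", "nearest_percent")) {
  metric <- match.arg(metric)
  rounding <- match.arg(rounding)
  out <- cost_metrics(program_outcome(scenarios, program, rounding), program)
  key <- switch(metric,
    per_credit = out$ac_per_credit,
    per_additional_ton = out$ac_per_additional_ton,
    quality = -out$quality
  )
  ord <- order(is.na(key), key, out$county_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' The five-county worked example
#'
#' Scenario table for the standard illustration of the threshold model:
#' county A (`mu = -2/3`) and county B (`mu = -2`), each in low (1 t/adopter)
#' and high (2 t/adopter) sequestration versions, plus the intermediate
#' `B_mid` (1.5 t/adopter); `sigma = 1`, `L = (0, 2/3, 4/3)`, 1000 producers.
#'
#' @return A [county_scenarios()] tibble with five rows.
#' @export
worked_example_counties <- function() {
  county_scenarios(
    county_id = c("A_low", "A_high", "B_low", "B_high", "B_mid"),
    mu = c(-2 / 3, -2 / 3, -2, -2, -2),
    sigma = 1,
    population = 1000L,
    seq_rate = c(1, 2, 1, 2, 1.5),
    L_path = c(0, 2 / 3, 4 / 3)
  )
}

#' Worked-example report of the conceptual model
#'
#' Runs the five-county worked example through [program_outcome()] and
#' [cost_metrics()] with the standard program (incentive $0.25 paid for
#' adoption between periods 2 and 3, fixed cost $50) under nearest-percent
#' rounding, and reports every quantity of the numerical illustration:
#' adoption shares, enrollee/additional/non-additional counts, credits,
#' additional tons, and the average-cost and quality metrics.
#'
#' @return A tibble with one row per county version.
#' @examples
#' worked_example_report()
#' @export
worked_example_report <- function() {
  program <- program_spec(incentive = 0.25, fixed_cost = 50, window = c(2, 3))
  cost_metrics(
    program_outcome(worked_example_counties(), program, "nearest_percent"),
    program
  )
}
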