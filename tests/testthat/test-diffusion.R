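test_that("adoption_share matches the Gaussian threshold closed form", {
  # worked-example anchors: half of county A adopts at L = 2/3, county B
  # moves from ~2% to just over 9%
  expect_equal(adoption_share(-2 / 3, 2 / 3), 0.5)
  expect_equal(adoption_share(-2, 0), pnorm(-2), tolerance = 1e-12)
  expect_equal(round(adoption_share(-2, 0), 4), 0.0228)
  expect_equal(round(adoption_share(-2, 2 / 3), 4), 0.0912)
  expect_equal(adoption_share(-5, 1e9), 1)
  # vectorization over mu
  expect_equal(adoption_share(c(-2 / 3, -2), 2 / 3),
               pnorm(c(0, -4 / 3)))
})

test_that("adoption_share handles the degenerate sigma = 0 distribution", {
  expect_equal(adoption_share(-1, 2, sigma = 0), 1)
  expect_equal(adoption_share(-1, 0.5, sigma = 0), 0)
  expect_error(adoption_share(0, 0, sigma = -1), "sigma")
})

test_that("adoption_share is monotone in mu and L and CDF-symmetric", {
  grid <- expand.grid(mu = seq(-3, 3, by = 0.5), L = seq(-2, 2, by = 0.5))
  s <- adoption_share(grid$mu, grid$L)
  s_sym <- adoption_share(-grid$mu, -grid$L)
  expect_equal(s + s_sym, rep(1, nrow(grid)), tolerance = 1e-12)
  expect_true(all(diff(adoption_share(seq(-3, 3, by = 0.1), 0)) > 0))
  expect_true(all(diff(adoption_share(-1, seq(-3, 3, by = 0.1))) > 0))
})

test_that("adoption_path traces the S-curve for the worked counties", {
  sc <- county_scenarios(c("A", "B"), mu = c(-2 / 3, -2))
  path <- adoption_path(sc)
  a <- path$share[path$county_id == "A"]
  b <- path$share[path$county_id == "B"]
  expect_equal(round(a, 4), c(0.2525, 0.5, 0.7475))
  # adoption grows by ~7 then ~16 percentage points in county B
  expect_equal(diff(b), c(0.06846, 0.16128), tolerance = 1e-4)
  flat <- adoption_path(county_scenarios("C", -1, L_path = c(1, 1, 1)))
  expect_equal(flat$share, rep(pnorm(0), 3))
})

test_that("program_outcome reproduces the worked-example enrollment split", {
  sc <- county_scenarios(c("A", "B"), mu = c(-2 / 3, -2), population = 1000)
  out <- program_outcome(sc, worked_program(), "nearest_percent")
  a <- out[out$county_id == "A", ]
  b <- out[out$county_id == "B", ]
  expect_equal(a$enrollee_count, 320)
  expect_equal(a$additional_count, 70)
  expect_equal(a$nonadditional_count, 250)
  expect_equal(b$enrollee_count, 250)
  expect_equal(b$nonadditional_share, 0.16128, tolerance = 1e-4)
  expect_equal(b$additional_share, 0.0859, tolerance = 1e-3)
  expect_equal(round(b$nonadditional_share, 2), 0.16)
  expect_equal(round(b$additional_share, 2), 0.09)
})

test_that("enrollee share decomposes exactly into additional + non-additional", {
  withr::with_seed(11, {
    sc <- county_scenarios(
      sprintf("C%02d", 1:40),
      mu = runif(40, -3, 1),
      population = 500,
      seq_rate = runif(40, 0.1, 2),
      L_path = c(0, 0.5, 1)
    )
  })
  out <- program_outcome(sc, worked_program(), "exact")
  expect_equal(out$enrollee_share,
               out$additional_share + out$nonadditional_share,
               tolerance = 1e-12)
  expect_true(all(out$credits >= out$additional_tons))
  expect_true(all(out$enrollee_share >= 0 & out$enrollee_share <= 1))
})

test_that("a zero incentive produces no additional adoption", {
  sc <- county_scenarios("A", -2 / 3)
  out <- program_outcome(sc, program_spec(0, 50, c(2, 3)))
  expect_equal(out$additional_share, 0)
  expect_equal(out$enrollee_share,
               out$share_baseline_end - out$share_baseline_start)
})

test_that("declining return paths clamp negative shares and flag them", {
  sc <- county_scenarios("D", mu = 0, L_path = c(0, 0, -2))
  out <- program_outcome(sc, program_spec(0.1, 10, c(2, 3)))
  expect_true(out$share_clamped)
  expect_equal(out$enrollee_share, 0)
  expect_equal(out$nonadditional_share, 0)
})

test_that("cost_metrics reproduces the worked-example dollar figures", {
  out <- cost_metrics(program_outcome(
    county_scenarios(c("A", "B"), mu = c(-2 / 3, -2), population = 1000),
    worked_program(), "nearest_percent"
  ))
  a <- out[out$county_id == "A", ]
  b <- out[out$county_id == "B", ]
  expect_equal(a$ac_per_enrollee, 130 / 320)   # prints as $0.41
  expect_equal(a$ac_per_additional_ton, 130 / 70, tolerance = 1e-12)
  expect_equal(b$ac_per_enrollee, 0.45)
  expect_equal(b$ac_per_additional_ton, 1.25)
})

test_that("cost metrics are linear in the sequestration rate", {
  sc1 <- county_scenarios("A", -2 / 3, seq_rate = 1, population = 1000)
  sc2 <- county_scenarios("A", -2 / 3, seq_rate = 2, population = 1000)
  m1 <- cost_metrics(program_outcome(sc1, worked_program()))
  m2 <- cost_metrics(program_outcome(sc2, worked_program()))
  expect_equal(m2$ac_per_credit, m1$ac_per_credit / 2)
  expect_equal(m2$ac_per_additional_ton, m1$ac_per_additional_ton / 2)
  expect_equal(m2$ac_per_enrollee, m1$ac_per_enrollee)
})

test_that("cost metrics are invariant to joint population/fixed-cost scaling", {
  base <- county_scenarios("A", -2 / 3, population = 1000)
  scaled <- county_scenarios("A", -2 / 3, population = 10000)
  m1 <- cost_metrics(program_outcome(base, program_spec(0.25, 50, c(2, 3))))
  m2 <- cost_metrics(program_outcome(scaled,
                                     program_spec(0.25, 500, c(2, 3))))
  for (col in c("ac_per_enrollee", "ac_per_credit", "ac_per_additional_ton",
                "quality")) {
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-12)
  }
})

test_that("undefined cost metrics are NA with an explanatory flag", {
  sc <- county_scenarios("Z", mu = -30)   # nobody adopts or enrolls
  expect_message(
    m <- cost_metrics(program_outcome(sc, worked_program(),
                                      "nearest_percent")),
    "undefined"
  )
  expect_true(is.na(m$ac_per_enrollee))
  expect_match(m$undefined_metrics, "ac_per_enrollee")
})

test_that("simulate_agents converges to the closed form within binomial error", {
  sc <- county_scenarios("A", -2 / 3, population = 1000)
  closed <- program_outcome(sc, worked_program(), "exact")
  n <- 1e6
  sim <- simulate_agents(sc, worked_program(), n_draws = n, seed = 101)
  for (col in c("share_baseline_start", "share_baseline_end",
                "share_with_program", "enrollee_share", "additional_share",
                "nonadditional_share")) {
    p <- closed[[col]]
    expect_lt(abs(sim[[col]] - p), 4 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("simulate_agents is reproducible and handles degenerate cases", {
  sc <- county_scenarios("A", -2 / 3)
  s1 <- simulate_agents(sc, worked_program(), 1000, seed = 5)
  s2 <- simulate_agents(sc, worked_program(), 1000, seed = 5)
  expect_identical(s1, s2)
  one <- simulate_agents(sc, worked_program(), 1, seed = 5)
  expect_true(all(unlist(one[grep("share", names(one))]) %in% c(0, 1)))
  # sigma = 0 with mu + L_end + P > 0 > mu + L_end: every non-adopter enrolls
  deg <- county_scenarios("D", mu = -1.4, sigma = 0)
  out <- simulate_agents(deg, worked_program(), 100, seed = 5)
  expect_equal(out$additional_share, 1)
  expect_equal(out$share_baseline_end, 0)
})

test_that("rank_counties orders by average cost per credit and per ton", {
  sc <- worked_example_counties()
  sc4 <- sc[sc$county_id != "B_mid", ]
  per_credit <- rank_counties(sc4, worked_program(), "per_credit",
                              "nearest_percent")
  expect_equal(per_credit$county_id,
               c("A_high", "B_high", "A_low", "B_low"))
  per_ton <- rank_counties(sc4, worked_program(), "per_additional_ton",
                           "nearest_percent")
  expect_equal(per_ton$county_id, c("B_high", "A_high", "B_low", "A_low"))
  # the mid-sequestration county undercuts the high-sequestration A
  all5 <- rank_counties(sc, worked_program(), "per_additional_ton",
                        "nearest_percent")
  expect_lt(which(all5$county_id == "B_mid"),
            which(all5$county_id == "A_high"))
  qual <- rank_counties(sc4, worked_program(), "quality", "nearest_percent")
  expect_equal(qual$quality, sort(qual$quality, decreasing = TRUE))
})

test_that("undefined metrics rank last", {
  sc <- county_scenarios(c("ok", "dead"), mu = c(-2 / 3, -30),
                         population = 1000)
  suppressMessages(
    r <- rank_counties(sc, worked_program(), "per_credit")
  )
  expect_equal(r$county_id, c("ok", "dead"))
})

test_that("scenario and program constructors validate their invariants", {
  expect_error(county_scenarios(c("A", "A"), mu = c(0, 0)), "unique")
  expect_error(county_scenarios("A", 0, sigma = -1), "sigma")
  expect_error(county_scenarios("A", 0, L_path = numeric(0)), "L_path")
  expect_error(program_spec(-1, 0, c(1, 2)), "incentive")
  expect_error(program_spec(1, 0, c(2, 2)), "window")
  expect_error(
    program_outcome(county_scenarios("A", 0, L_path = c(0, 1)),
                    program_spec(0.1, 1, c(2, 3))),
    "window"
  )
})
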