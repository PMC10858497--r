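# Shared fixtures, generated in code at test time.

# Small synthetic study: enough counties for the pipeline but cheap. Forest
# node sizes are overridden because the practice defaults assume ~500
# training counties.
small_synth_config <- function(n_counties = 120L) {
  synth_config(n_counties = n_counties)
}

small_forest_overrides <- list(
  cover_crop = list(min_node_size = 3, sample_fraction = 0.5),
  reduced_till = list(min_node_size = 3, sample_fraction = 0.5)
)

# Step-function regression fixture: y depends on x1 only, through a single
# threshold at 0. The conditional means (2 and -1) are known exactly.
step_fixture <- function(n = 500, p = 5, noise_sd = 0, seed = 42) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(X) <- paste0("x", seq_len(p))
    X$target <- ifelse(X$x1 > 0, 2, -1) + rnorm(n, 0, noise_sd)
    X$county_id <- sprintf("S%04d", seq_len(n))
    X
  })
}

# The five-county worked example and its standard program.
worked_program <- function() program_spec(0.25, 50, c(2, 3))
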