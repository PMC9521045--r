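# Shared fixtures and independent oracles for the test suite.

# Small synthetic worlds are expensive enough to be worth caching per run.
.pop_cache <- new.env(parent = emptyenv())

cached_population <- function(key, config) {
  if (!exists(key, envir = .pop_cache)) {
    assign(key, generate_population(config), envir = .pop_cache)
  }
  get(key, envir = .pop_cache)
}

small_config <- function(seed = 101, noise = 1.5, ...) {
  synthetic_config(n_herds = 8, years = 2007:2012, herd_size_mean = 14,
                   milk_noise_sd = noise, rng_seed = seed, ...)
}

# Enumeration oracle for the lower weighted median: smallest value whose
# cumulative normalized weight of values <= it reaches one half.
oracle_weighted_median <- function(values, weights) {
  w <- weights / sum(weights)
  cands <- sort(unique(values))
  for (x in cands) {
    if (sum(w[values <= x]) >= 0.5) return(x)
  }
  stop("unreachable")
}

# Minimal stand-in for an lmm_fit when only the OLS design is needed by the
# non-nested tests (spec + retained terms).
ols_stub <- function(outcome, terms, forced = character(0),
                     group = "herd") {
  list(spec = model_spec(outcome, terms, forced = forced, group = group),
       terms = terms)
}

# Stage chain used by end-to-end scenarios: everything in run_pipeline()
# up to and including the analysis table, without models.
build_analysis_table <- function(pop, filters = filter_config()) {
  fits <- suppressWarnings(fit_lactations(pop$test_days))
  span <- seq(min(pop$test_days$year), max(pop$test_days$year))
  w <- partition_lactation_weights(pop$test_days, fits)
  hlcc <- aggregate_hlcc(fits, w, span)
  ind <- compute_economic_indicators(pop$accounting, pop$national_price)
  merged <- merge_sources(ind, hlcc, pop$performance)
  apply_filters(merged, filters)
}
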