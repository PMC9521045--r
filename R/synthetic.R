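#' Configuration for the synthetic herd generator
#'
#' Defines the world the generator emulates: Dutch dairy herds with monthly
#' test-day recording, MilkBot-shaped lactations with parity-specific
#' parameters, lactations spanning calendar years, and herd-year economics
#' whose income over feed cost (IOFC) follows a known linear model in the
#' standardized herd covariates, so that every downstream stage can be
#' validated against ground truth.
#'
#' Defaults follow published herd-level medians: primiparous magnitude
#' around 35 kg/day, time to peak near 30 days, persistency near 358 days;
#' multiparous 47.7 kg/day, 22.1 days and 240 days. Economic coefficients
#' default to herd-level effect sizes of realistic magnitude (EUR per SD of
#' each covariate), a herd random-intercept SD of 200 EUR and a residual SD
#' of 100 EUR. The national milk price series contains a dip in the second
#' year of the span, emulating the 2009 milk price crisis, so the forced
#' year effect is exercised.
#'
#' @param n_herds number of herds.
#' @param years inclusive calendar-year range covered by test-day recording;
#'   must span at least 4 years so that edge-year exclusion leaves usable
#'   years. Accounting and performance tables cover the inner years only.
#' @param herd_size_mean mean number of cows per herd.
#' @param parity_mix fraction of primiparous cows, in \[0, 1\].
#' @param test_interval_days mean spacing of milk weighings (the 4-6-week
#'   recording scheme; exact frequency is an assumption, hence exposed).
#' @param milk_noise_sd additive Gaussian test-day noise, kg/day, truncated
#'   at zero.
#' @param straddle_fraction fraction of lactations whose test days straddle
#'   a calendar-year boundary.
#' @param curve_params list with elements \code{primiparous} and
#'   \code{multiparous}, each a named vector \code{c(a=, b=, d=)} of MilkBot
#'   parameter medians.
#' @param curve_cv list with elements \code{herd} and \code{cow}, each a
#'   named vector of lognormal dispersion (sdlog) for \code{a}, \code{b},
#'   \code{d} at herd and cow level.
#' @param delivery_share fraction of the summed 305-day production that
#'   reaches the factory, calibrated so delivered milk per cow present is
#'   near 7,200 kg/year.
#' @param econ list with \code{intercept} (EUR), \code{coefficients} (named
#'   EUR-per-SD effects on IOFC-cow), \code{year_effects} (EUR offsets
#'   recycled over the inner years, dip in the second year), \code{herd_sd}
#'   and \code{residual_sd} (EUR).
#' @param prop_organic,prop_direct_seller fractions of herds flagged organic
#'   or direct-selling (excluded downstream by the editing cascade).
#' @param rng_seed integer seed; identical configs and seeds regenerate
#'   byte-identical tables.
#' @return A validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_herds = 50,
                             years = 2007:2016,
                             herd_size_mean = 85,
                             parity_mix = 0.35,
                             test_interval_days = 35,
                             milk_noise_sd = 1.5,
                             straddle_fraction = 0.7,
                             curve_params = list(
                               primiparous = c(a = 35, b = 29.6,
                                               d = log(2) / 358),
                               multiparous = c(a = 47.7, b = 22.1,
                                               d = log(2) / 240)),
                             curve_cv = list(
                               herd = c(a = 0.08, b = 0.015, d = 0.15),
                               cow = c(a = 0.12, b = 0.10, d = 0.20)),
                             delivery_share = 0.83,
                             econ = list(
                               intercept = 2437,
                               coefficients = c(
                                 magnitude1 = 48, time_to_peak1 = 0,
                                 persistency1 = 13, magnitude2 = 154,
                                 time_to_peak2 = -4.4, persistency2 = 69,
                                 herd_size = -16, scc = -23,
                                 herd_intensity = -15, calving_interval = -22,
                                 relative_milk_price = 146),
                               year_effects = c(0, -586, -222, 85, -241,
                                                130, 195, -482),
                               herd_sd = 200, residual_sd = 100),
                             prop_organic = 0.02,
                             prop_direct_seller = 0.02,
                             rng_seed = 1L) {
  years <- sort(as.integer(years))
  if (n_herds < 1) stop("invalid config: n_herds must be positive")
  if (length(years) < 4 || !all(diff(years) == 1L)) {
    stop("invalid config: years must be >= 4 consecutive calendar years")
  }
  if (parity_mix < 0 || parity_mix > 1) {
    stop("invalid config: parity_mix must lie in [0, 1]")
  }
  if (herd_size_mean <= 0 || test_interval_days <= 0) {
    stop("invalid config: counts and intervals must be positive")
  }
  if (milk_noise_sd < 0 || econ$herd_sd < 0 || econ$residual_sd < 0) {
    stop("invalid config: variances must be nonnegative")
  }
  if (straddle_fraction < 0 || straddle_fraction > 1) {
    stop("invalid config: straddle_fraction must lie in [0, 1]")
  }
  structure(list(
    n_herds = as.integer(n_herds), years = years,
    herd_size_mean = herd_size_mean, parity_mix = parity_mix,
    test_interval_days = test_interval_days, milk_noise_sd = milk_noise_sd,
    delivery_share = delivery_share,
    straddle_fraction = straddle_fraction, curve_params = curve_params,
    curve_cv = curve_cv, econ = econ, prop_organic = prop_organic,
    prop_direct_seller = prop_direct_seller,
    rng_seed = as.integer(rng_seed)), class = "synthetic_config")
}

#' National raw milk price series for a year span
#'
#' Year-indexed price series (EUR/100 kg) around a base level with a dip in
#' the second year of the span, emulating the 2009 price crisis.
#'
#' @param years integer vector of calendar years.
#' @param base base price, EUR/100 kg.
#' @return data frame with columns \code{year}, \code{price}.
#' @export
national_price_series <- function(years, base = 33) {
  pattern <- c(1.5, -6.5, -2.5, 3.5, -0.5, 4, 5, -2.5)
  offs <- rep_len(pattern, length(years))
  data.frame(year = as.integer(years), price = base + offs)
}

.truncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Generate a synthetic herd population with ground truth
#'
#' Produces the four input tables of the analysis pipeline -- test-day
#' records, herd-year accounting, herd-year performance and a national milk
#' price series -- together with the ground truth used to generate them.
#'
#' Each cow carries one lactation with true MilkBot parameters drawn
#' lognormally around parity-group medians with herd- and cow-level
#' dispersion. Weighings start at DIM 5-14 and recur every
#' \code{test_interval_days} plus uniform jitter of 7 days until a dry-off
#' DIM drawn from 280-420; test-day milk is the MilkBot evaluation plus
#' truncated Gaussian noise. A configurable fraction of lactations is placed
#' so its weighings straddle a calendar-year boundary. Accounting satisfies
#' the identity milk revenue minus summed feed components equals IOFC-cow
#' times herd size by construction, with IOFC-cow following the configured
#' linear model in the standardized covariates plus herd intercept plus
#' residual.
#'
#' @param config a [synthetic_config()].
#' @return list with elements \code{test_days}, \code{accounting},
#'   \code{performance}, \code{national_price} (data frames) and
#'   \code{truth}: a list with \code{lactations} (true parameters per
#'   lactation), \code{herd_intercepts}, \code{coefficients},
#'   \code{year_effects}, \code{hlcc} (true weighted-median HLCC per
#'   herd-year-parity from the true parameters), and \code{analysis_inputs}
#'   (the standardized covariates actually used to generate IOFC).
#' @export
generate_population <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  set.seed(config$rng_seed)
  years <- config$years
  inner <- years[-c(1L, length(years))]
  H <- config$n_herds

  ## ---- herd level ----
  herd_id <- sprintf("H%04d", seq_len(H))
  size0 <- pmax(8, round(stats::rnorm(H, config$herd_size_mean,
                                      0.35 * config$herd_size_mean)))
  growth <- stats::rnorm(H, 0.03, 0.04)
  hectares <- pmax(5, size0 * stats::rnorm(H, 0.56, 0.08))
  soil <- ifelse(stats::runif(H) < 0.4, "sand", "other")
  milking <- ifelse(stats::runif(H) < 0.2, "automatic", "conventional")
  successor <- ifelse(stats::runif(H) < 0.5, "yes", "no")
  outsourced <- ifelse(stats::runif(H) < 0.2, "yes", "no")
  organic <- stats::runif(H) < config$prop_organic
  direct_seller <- stats::runif(H) < config$prop_direct_seller
  equity <- .truncnorm(H, 0.45, 0.28, -0.5, 0.95)
  assets <- size0 * exp(stats::rnorm(H, log(25000), 0.25))
  liabilities <- assets * (1 - equity)
  herd_mult <- lapply(c(a = "a", b = "b", d = "d"), function(p) {
    exp(stats::rnorm(H, 0, config$curve_cv$herd[[p]]))
  })
  premium_h <- stats::rnorm(H, 2.5, 1.8)
  u_h <- stats::rnorm(H, 0, config$econ$herd_sd)

  ## ---- lactation level (all years in span) ----
  hy <- expand.grid(h = seq_len(H), year = years, KEEP.OUT.ATTRS = FALSE)
  hy$size <- round(size0[hy$h] * (1 + growth[hy$h])^(hy$year - years[1]))
  hy$size <- pmax(8, hy$size)
  lac_h <- rep(hy$h, hy$size)
  lac_year <- rep(hy$year, hy$size)
  n_lact <- length(lac_h)
  cow_seq <- stats::ave(lac_h, paste(lac_h, lac_year), FUN = seq_along)
  cow_id <- sprintf("%sC%d_%03d", herd_id[lac_h], lac_year, cow_seq)
  lact_id <- paste0(cow_id, "L")

  primi <- stats::runif(n_lact) < config$parity_mix
  parity <- ifelse(primi, 1L, sample(2:5, n_lact, replace = TRUE))
  pg <- ifelse(primi, "primiparous", "multiparous")

  pmed <- function(p) ifelse(primi, config$curve_params$primiparous[[p]],
                             config$curve_params$multiparous[[p]])
  draw <- function(p) {
    pmed(p) * herd_mult[[p]][lac_h] *
      exp(stats::rnorm(n_lact, 0, config$curve_cv$cow[[p]]))
  }
  a_true <- draw("a"); b_true <- draw("b"); d_true <- draw("d")

  straddle <- stats::runif(n_lact) < config$straddle_fraction
  doy <- ifelse(straddle,
                sample(230:350, n_lact, replace = TRUE),
                sample(5:60, n_lact, replace = TRUE))
  dryoff <- round(stats::runif(n_lact, 280, 420))
  dryoff <- ifelse(straddle, dryoff, pmin(dryoff, 290))
  calving <- as.Date(sprintf("%d-01-01", lac_year)) + (doy - 1)

  ## ---- test-day schedule (matrix of DIMs, masked at dry-off) ----
  iv <- config$test_interval_days
  max_tests <- ceiling((420 - 5) / max(iv - 7, 1)) + 2L
  first_dim <- sample(5:14, n_lact, replace = TRUE)
  gaps <- matrix(iv + stats::runif(n_lact * (max_tests - 1), -7, 7),
                 nrow = n_lact)
  dims <- cbind(first_dim,
                first_dim + t(apply(gaps, 1, cumsum)))
  dims <- round(dims)
  keep <- sweep(dims, 1, dryoff, `<=`)

  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  li <- idx[, 1]
  td_dim <- dims[idx]
  td_date <- calving[li] + td_dim
  td_year <- as.integer(format(td_date, "%Y"))
  mu <- milkbot_yield(td_dim, a_true[li], b_true[li], d_true[li])
  noise <- if (config$milk_noise_sd > 0) {
    stats::rnorm(length(td_dim), 0, config$milk_noise_sd)
  } else 0
  td_milk <- pmax(0, mu + noise)

  test_days <- data.frame(
    herd = herd_id[lac_h[li]], cow = cow_id[li], lactation = lact_id[li],
    parity = parity[li], calving_date = calving[li], test_date = td_date,
    year = td_year, dim = td_dim, milk = td_milk, stringsAsFactors = FALSE)

  lact_truth <- data.frame(
    herd = herd_id[lac_h], cow = cow_id, lactation = lact_id,
    parity = parity, parity_group = pg, calving_year = lac_year,
    a = a_true, b = b_true, d = d_true,
    persistency = log(2) / d_true, straddle = straddle,
    stringsAsFactors = FALSE)

  ## ---- true HLCC from true parameters ----
  last_dim <- tapply(test_days$dim, test_days$lactation, max)
  fits_true <- lact_truth[c("herd", "cow", "lactation", "parity_group",
                            "a", "b", "d", "persistency")]
  fits_true$complete <-
    unname(last_dim[fits_true$lactation]) >= 240
  w_true <- partition_lactation_weights(test_days, fits_true)
  hlcc_true <- aggregate_hlcc(fits_true, w_true, years)
  hlcc_wide <- pivot_hlcc(hlcc_true)

  ## ---- performance table (inner years) ----
  m305 <- milkbot_m305(a_true, b_true, d_true)
  key <- paste(herd_id[lac_h], lac_year, sep = "|")
  hm305_all <- tapply(m305, key, mean)
  milk_sum <- tapply(m305, key, sum)

  perf <- expand.grid(h = seq_len(H), year = inner, KEEP.OUT.ATTRS = FALSE)
  perf <- perf[order(perf$h, perf$year), ]
  pkey <- paste(herd_id[perf$h], perf$year, sep = "|")
  performance <- data.frame(
    herd = herd_id[perf$h], year = perf$year,
    hm305 = unname(hm305_all[pkey]),
    scc = exp(stats::rnorm(nrow(perf), log(190), 0.28)),
    calving_interval = stats::rnorm(nrow(perf), 414, 23),
    age_days = stats::rnorm(nrow(perf), 1716, 160),
    stringsAsFactors = FALSE)

  ## ---- accounting table (inner years) ----
  np <- national_price_series(years)
  acc <- performance[c("herd", "year")]
  acc$h <- perf$h
  acc$herd_size <- hy$size[match(paste(acc$h, acc$year),
                                 paste(hy$h, hy$year))]
  produced <- unname(milk_sum[pkey]) * 1.08 *
    exp(stats::rnorm(nrow(acc), 0, 0.01))
  # not all produced milk reaches the factory (calf milk, discard, dry
  # cows in the herd count); share calibrated so delivered milk per cow
  # present sits near 7,200 kg/year
  acc$milk_delivered <- produced * config$delivery_share
  acc$hectares <- hectares[acc$h]
  premium_hy <- premium_h[acc$h] + stats::rnorm(nrow(acc), 0, 0.8)
  price_y <- np$price[match(acc$year, np$year)]
  acc$milk_revenue <- (price_y + premium_hy) / 100 * acc$milk_delivered

  ## covariates on the generating scale (standardized over inner herd-years)
  cov_raw <- data.frame(
    herd = acc$herd, year = acc$year,
    herd_size = acc$herd_size,
    scc = performance$scc,
    herd_intensity = acc$milk_delivered / acc$hectares,
    calving_interval = performance$calving_interval,
    relative_milk_price = premium_hy,
    stringsAsFactors = FALSE)
  cov_raw <- merge(cov_raw, hlcc_wide, by = c("herd", "year"), all.x = TRUE)
  cov_raw <- cov_raw[order(match(paste(cov_raw$herd, cov_raw$year),
                                 paste(acc$herd, acc$year))), ]
  beta <- config$econ$coefficients
  zmat <- sapply(names(beta), function(v) {
    x <- cov_raw[[v]]
    z <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
    z[is.na(z)] <- 0
    z
  })
  year_eff <- rep_len(config$econ$year_effects, length(inner))
  names(year_eff) <- inner
  iofc_cow <- config$econ$intercept +
    year_eff[as.character(acc$year)] +
    drop(zmat %*% beta) + u_h[acc$h] +
    stats::rnorm(nrow(acc), 0, config$econ$residual_sd)

  feed_total <- acc$milk_revenue - iofc_cow * acc$herd_size
  shares <- c(concentrates = 0.55, roughage = 0.25, wet_byproducts = 0.12,
              minerals = 0.05, vitamins = 0.03)
  share_noise <- matrix(exp(stats::rnorm(nrow(acc) * 5, 0, 0.15)),
                        ncol = 5)
  share_mat <- sweep(share_noise, 2, shares, `*`)
  share_mat <- share_mat / rowSums(share_mat)
  accounting <- data.frame(
    herd = acc$herd, year = acc$year,
    milk_revenue = acc$milk_revenue,
    feed_concentrates = feed_total * share_mat[, 1],
    feed_roughage = feed_total * share_mat[, 2],
    feed_wet_byproducts = feed_total * share_mat[, 3],
    feed_minerals = feed_total * share_mat[, 4],
    feed_vitamins = feed_total * share_mat[, 5],
    assets = assets[acc$h], liabilities = liabilities[acc$h],
    herd_size = acc$herd_size, hectares = acc$hectares,
    milk_delivered = acc$milk_delivered,
    soil_type = soil[acc$h], milking_system = milking[acc$h],
    successor = successor[acc$h], outsourced_rearing = outsourced[acc$h],
    organic = organic[acc$h], direct_seller = direct_seller[acc$h],
    stringsAsFactors = FALSE)

  truth <- list(
    lactations = lact_truth,
    herd_intercepts = stats::setNames(u_h, herd_id),
    coefficients = beta,
    intercept = config$econ$intercept,
    year_effects = year_eff,
    hlcc = hlcc_true,
    analysis_inputs = data.frame(cov_raw, iofc_cow = iofc_cow,
                                 stringsAsFactors = FALSE))

  list(test_days = test_days, accounting = accounting,
       performance = performance, national_price = np, truth = truth)
}

#' Write a generated population to CSV files plus a ground-truth sidecar
#'
#' @param population output of [generate_population()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(test_days = file.path(dir, "test_days.csv"),
             accounting = file.path(dir, "accounting.csv"),
             performance = file.path(dir, "performance.csv"),
             national_price = file.path(dir, "national_price.csv"),
             truth = file.path(dir, "ground_truth.json"))
  for (nm in names(paths)[1:4]) {
    utils::write.csv(population[[nm]], paths[[nm]], row.names = FALSE)
  }
  jsonlite::write_json(population$truth, paths[["truth"]],
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Hand-built straddling-lactation fixture
#'
#' A small deterministic test-day table for exercising the year-partitioning
#' rule: one primiparous lactation calving in late summer of the first year
#' with exactly 5 weighings in that year and 3 in the next, plus filler
#' lactations with known test-day counts so the cell totals n and m are
#' known by construction. Milk values are noise-free MilkBot evaluations.
#'
#' @param year first calendar year (default 2008).
#' @return test-day data frame with attributes \code{n} (total primiparous
#'   test days in \code{year}), \code{m} (same for \code{year + 1}) and
#'   \code{straddle_lactation} (the id of the straddling lactation).
#' @export
generate_straddle_fixture <- function(year = 2008) {
  mk <- function(herd, cow, parity, calving, dims, pars) {
    calving <- as.Date(calving)
    dates <- calving + dims
    data.frame(
      herd = herd, cow = cow, lactation = paste0(cow, "L"),
      parity = parity, calving_date = calving, test_date = dates,
      year = as.integer(format(dates, "%Y")), dim = dims,
      milk = milkbot_yield(dims, pars[1], pars[2], pars[3]),
      stringsAsFactors = FALSE)
  }
  y1 <- sprintf("%d-01-10", year)
  ys <- sprintf("%d-08-01", year)
  y2 <- sprintf("%d-01-05", year + 1)
  ym <- sprintf("%d-02-01", year)
  fix <- rbind(
    # straddler: 5 weighings in `year` (DIM 14..150), 3 in `year`+1
    mk("H1", "A", 1L, ys, c(14, 49, 84, 119, 150, 185, 220, 255),
       c(35, 29.6, 0.0019)),
    # filler primiparous fully inside `year`: 10 weighings
    mk("H1", "B", 1L, y1, seq(10, 325, by = 35), c(33, 28, 0.0021)),
    # filler primiparous fully inside `year`+1: 10 weighings
    mk("H1", "C", 1L, y2, seq(10, 325, by = 35), c(36, 31, 0.0018)),
    # one multiparous lactation to exercise parity grouping: 9 weighings
    mk("H1", "D", 3L, ym, seq(10, 290, by = 35), c(48, 22, 0.0029)))
  structure(fix, n = 15L, m = 13L, straddle_lactation = "AL")
}
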