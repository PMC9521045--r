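test_that("weighted_median follows the lower cumulative-weight convention", {
  expect_equal(weighted_median(34.8, 1), 34.8)
  expect_equal(weighted_median(c(30, 35, 40), c(0.2, 0.3, 0.5)), 35)
  # boundary: cumulative weight reaches exactly 0.5 at the lower value
  expect_equal(weighted_median(c(10, 20), c(0.5, 0.5)), 10)
  expect_error(weighted_median(numeric(0), numeric(0)), "empty")
  expect_error(weighted_median(c(1, 2), c(0, 0)), "zero")
  expect_error(weighted_median(c(1, 2), c(-1, 2)), "nonnegative")
})

test_that("weighted_median equals the enumeration oracle on small cells", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:8, 1)
    v <- round(runif(n, 20, 60), 2)
    w <- runif(n, 0.1, 5)
    expect_identical(weighted_median(v, w), oracle_weighted_median(v, w))
  }
})

test_that("partition weights reproduce the 5/n and 3/m worked example", {
  fix <- generate_straddle_fixture(2008)
  fits <- suppressWarnings(fit_lactations(fix))
  w <- partition_lactation_weights(fix, fits)
  s <- w[w$lactation == attr(fix, "straddle_lactation"), ]
  expect_equal(s$weight[s$year == 2008], 5 / attr(fix, "n"))
  expect_equal(s$weight[s$year == 2009], 3 / attr(fix, "m"))
  # a lactation alone in its herd-year-parity cell has weight 1
  multi <- w[w$parity_group == "multiparous", ]
  expect_equal(multi$weight, 1)
})

test_that("weights sum to one in every herd-year-parity cell", {
  pop <- cached_population("small1", small_config())
  fits <- suppressWarnings(fit_lactations(pop$test_days))
  w <- partition_lactation_weights(pop$test_days, fits)
  sums <- tapply(w$weight, paste(w$herd, w$year, w$parity_group), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("aggregation drops the first and last calendar year of the span", {
  pop <- cached_population("small1", small_config())  # years 2007:2012
  fits <- suppressWarnings(fit_lactations(pop$test_days))
  w <- partition_lactation_weights(pop$test_days, fits)
  hlcc <- aggregate_hlcc(fits, w, 2007:2012)
  expect_setequal(unique(hlcc$year), 2008:2011)
})

test_that("constant inputs aggregate to themselves; noise-free fits match truth", {
  fix <- generate_straddle_fixture(2008)
  # constant parameters: the weighted median must return them exactly
  fits <- data.frame(lactation = unique(fix$lactation),
                     a = 40, b = 25, persistency = 300, complete = TRUE)
  w <- partition_lactation_weights(fix, fits)
  h <- aggregate_hlcc(fits, w, 2007:2010)
  expect_true(all(h$magnitude == 40 & h$time_to_peak == 25 &
                    h$persistency == 300))

  # noise-free world: HLCC from fitted curves equals HLCC from the true
  # parameters via the independent oracle, up to optimizer precision
  pop <- cached_population("small0", small_config(noise = 0))
  fits <- fit_lactations(pop$test_days)
  w <- partition_lactation_weights(pop$test_days, fits)
  hlcc <- aggregate_hlcc(fits, w, 2007:2012)
  tr <- pop$truth$lactations
  wt <- merge(w, tr[c("lactation", "a")], by = "lactation")
  wt <- merge(wt, fits[c("lactation", "complete")], by = "lactation")
  wt <- wt[wt$complete & wt$year %in% 2008:2011, ]
  for (cell in split(wt, paste(wt$herd, wt$year, wt$parity_group))) {
    expected <- oracle_weighted_median(cell$a, cell$weight)
    got <- hlcc$magnitude[hlcc$herd == cell$herd[1] &
                            hlcc$year == cell$year[1] &
                            hlcc$parity_group == cell$parity_group[1]]
    expect_equal(got, expected, tolerance = 1e-6)
  }
})

test_that("aggregation is permutation invariant and shift equivariant", {
  pop <- cached_population("small1", small_config())
  fits <- suppressWarnings(fit_lactations(pop$test_days))
  w <- partition_lactation_weights(pop$test_days, fits)
  h1 <- aggregate_hlcc(fits, w, 2007:2012)
  set.seed(8)
  h2 <- aggregate_hlcc(fits[sample(nrow(fits)), ], w[sample(nrow(w)), ],
                       2007:2012)
  expect_equal(h1, h2)
  # +1 kg/day to every magnitude moves every herd magnitude by exactly +1
  fits_up <- fits
  fits_up$a <- fits_up$a + 1
  h3 <- aggregate_hlcc(fits_up, w, 2007:2012)
  expect_equal(h3$magnitude, h1$magnitude + 1)
})

test_that("HLCC values lie within the range of contributing lactations", {
  pop <- cached_population("small1", small_config())
  fits <- suppressWarnings(fit_lactations(pop$test_days))
  w <- partition_lactation_weights(pop$test_days, fits)
  hlcc <- aggregate_hlcc(fits, w, 2007:2012)
  cf <- fits[fits$complete, ]
  for (i in sample(nrow(hlcc), 20)) {
    cell <- w[w$herd == hlcc$herd[i] & w$year == hlcc$year[i] &
                w$parity_group == hlcc$parity_group[i], ]
    vals <- cf$a[match(cell$lactation, cf$lactation)]
    vals <- vals[!is.na(vals)]
    expect_gte(hlcc$magnitude[i], min(vals))
    expect_lte(hlcc$magnitude[i], max(vals))
  }
})

test_that("pivot_hlcc spreads parity groups into suffixed columns", {
  h <- data.frame(herd = c("H1", "H1"), year = 2010,
                  parity_group = c("primiparous", "multiparous"),
                  magnitude = c(35, 48), time_to_peak = c(30, 22),
                  persistency = c(350, 240), n_lactations = c(4L, 9L))
  wide <- pivot_hlcc(h)
  expect_equal(nrow(wide), 1L)
  expect_equal(wide$magnitude1, 35)
  expect_equal(wide$magnitude2, 48)
  expect_equal(wide$persistency2, 240)
})
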