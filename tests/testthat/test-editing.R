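make_hlcc_long <- function(herds, years) {
  g <- expand.grid(herd = herds, year = years,
                   parity_group = c("primiparous", "multiparous"),
                   stringsAsFactors = FALSE)
  g$magnitude <- ifelse(g$parity_group == "primiparous", 35, 48)
  g$time_to_peak <- ifelse(g$parity_group == "primiparous", 30, 22)
  g$persistency <- ifelse(g$parity_group == "primiparous", 350, 240)
  g$n_lactations <- 5L
  g
}

test_that("merge_sources inner-joins on herd-year with pivoted HLCC", {
  econ <- data.frame(herd = paste0("H", 1:10), year = 2010, iofc_cow = 2000)
  perf <- data.frame(herd = paste0("H", 4:12), year = 2010, hm305 = 8700)
  hl <- make_hlcc_long(paste0("H", 1:8), 2010)
  m <- merge_sources(econ, hl, perf)
  expect_setequal(m$herd, paste0("H", 4:8))  # 10 & 9 & 8 -> 5 in common
  expect_true(all(c("magnitude1", "magnitude2", "persistency1",
                    "persistency2", "time_to_peak1",
                    "time_to_peak2") %in% names(m)))
  expect_equal(m$magnitude2, rep(48, 5))

  # disjoint herds: empty result, full schema
  perf2 <- data.frame(herd = "Z9", year = 2010, hm305 = 8700)
  m0 <- merge_sources(econ, hl, perf2)
  expect_equal(nrow(m0), 0L)
  expect_true(all(c("iofc_cow", "hm305", "magnitude1") %in% names(m0)))

  # duplicate keys are an integrity error
  econ_dup <- rbind(econ, econ[1, ])
  expect_error(merge_sources(econ_dup, hl, perf), "integrity")
})

editing_fixture <- function() {
  herds <- sprintf("H%02d", 1:30)
  d <- expand.grid(herd = herds, year = 2008:2014,
                   stringsAsFactors = FALSE)   # 210 rows
  d <- d[order(d$herd, d$year), ]
  d$herd_size <- 100
  d$direct_seller <- FALSE
  d$organic <- FALSE
  d$iofc_cow <- 2000
  d$iofc_milk <- 32
  d$scc <- 190
  d$hm305 <- 8700
  rownames(d) <- NULL
  # 3 organic herd-years
  d$organic[c(10, 50, 90)] <- TRUE
  # 2 extremely small herds
  d$herd_size[c(25, 60)] <- c(3, 4)
  # 4 outliers, one per screened variable, in distinct clean rows
  d$iofc_cow[100] <- 99999
  d$iofc_milk[120] <- 500
  d$scc[140] <- 9000
  d$hm305[160] <- 40000
  # 1 missing value
  d$scc[180] <- NA
  d
}

test_that("the editing cascade reports exact per-step exclusion counts", {
  d <- editing_fixture()
  cfg <- filter_config(outlier_variables = c("iofc_cow", "iofc_milk",
                                             "scc", "hm305"))
  res <- apply_filters(d, cfg)
  expect_equal(res$audit$step,
               c("non_consecutive_years", "direct_seller_or_organic",
                 "small_herds", "percentile_outliers", "missing_values"))
  expect_equal(res$audit$excluded, c(0L, 3L, 2L, 4L, 1L))
  expect_equal(nrow(res$data), nrow(d) - 10L)
  # audit arithmetic reconciles
  expect_equal(res$audit$remaining,
               nrow(d) - cumsum(res$audit$excluded))
  expect_true(all(diff(res$audit$remaining) <= 0))
})

test_that("a herd with non-consecutive years loses those records", {
  d <- editing_fixture()
  keep <- !(d$herd == "H01" & d$year %in% c(2009, 2011, 2012, 2013, 2014))
  d <- d[keep, ]  # H01 now has {2008, 2010}: two isolated years
  cfg <- filter_config(outlier_variables = c("iofc_cow", "iofc_milk",
                                             "scc", "hm305"))
  res <- apply_filters(d, cfg)
  expect_equal(res$audit$excluded[1], 2L)
  expect_false(any(res$data$herd == "H01"))
})

test_that("a clean table passes unchanged with all-zero counts", {
  herds <- sprintf("H%02d", 1:30)
  d <- expand.grid(herd = herds, year = 2008:2014,
                   stringsAsFactors = FALSE)
  d <- d[order(d$herd, d$year), ]
  d$herd_size <- 100; d$direct_seller <- FALSE; d$organic <- FALSE
  d$iofc_cow <- 2000; d$iofc_milk <- 32; d$scc <- 190; d$hm305 <- 8700
  rownames(d) <- NULL
  cfg <- filter_config(outlier_variables = c("iofc_cow", "iofc_milk",
                                             "scc", "hm305"))
  res <- apply_filters(d, cfg)
  expect_equal(res$audit$excluded, rep(0L, 5))
  expect_equal(res$data, d, ignore_attr = TRUE)
})

test_that("unknown outlier variables are a config error", {
  d <- editing_fixture()
  expect_error(apply_filters(d, filter_config(outlier_variables = "nope")),
               "unknown outlier variable")
})

test_that("re-running the cascade is a no-op outside percentile steps", {
  # percentile steps recompute their cutoffs on the edited table and may
  # re-trim; their removals can in turn strand a year of a herd, so only
  # the value-based (non-percentile, non-run) steps are strictly idempotent
  pop <- cached_population("small1", small_config())
  res <- build_analysis_table(pop)
  res2 <- apply_filters(res$data, filter_config())
  a2 <- res2$audit
  expect_equal(a2$excluded[a2$step == "direct_seller_or_organic"], 0L)
  expect_equal(a2$excluded[a2$step == "missing_values"], 0L)
})

test_that("filter_config validates percentile bounds", {
  expect_error(filter_config(outlier_lower = 0.6, outlier_upper = 0.5),
               "lower < upper")
  expect_error(filter_config(small_herd_percentile = 1.5), "\\[0, 1\\]")
})
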