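# simulate a small herd-year panel with known fixed effects
sim_panel <- function(n_herds = 40, n_per = 8, beta = c(x1 = 50, x2 = -20),
                      herd_sd = 30, resid_sd = 20, year_eff = 0,
                      seed = 1) {
  set.seed(seed)
  n <- n_herds * n_per
  d <- data.frame(herd = rep(sprintf("H%02d", 1:n_herds), each = n_per),
                  year = rep(seq_len(n_per), n_herds))
  for (v in names(beta)) d[[v]] <- rnorm(n)
  u <- rnorm(n_herds, 0, herd_sd)
  d$y <- as.matrix(d[names(beta)]) %*% beta + u[as.integer(factor(d$herd))] +
    year_eff * d$year + rnorm(n, 0, resid_sd)
  d$y <- drop(d$y)
  d
}

test_that("standardization centres, scales, and round-trips", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  s <- standardize_continuous(d, c("a", "b"))
  expect_equal(mean(s$data$a), 0)
  expect_equal(sd(s$data$a), 1)
  # idempotence
  s2 <- standardize_continuous(s$data, c("a", "b"))
  expect_equal(s2$data$a, s$data$a, tolerance = 1e-12)
  # round trip
  back <- unstandardize_continuous(s$data, s$scaling)
  expect_equal(back$a, d$a, tolerance = 1e-10)
  expect_equal(back$b, d$b, tolerance = 1e-10)
  expect_error(standardize_continuous(data.frame(a = rep(1, 5)), "a"),
               "degenerate")
})

test_that("VIF matches the closed form and flags collinearity", {
  set.seed(4)
  n <- 200
  x1 <- rnorm(n)
  e <- residuals(lm(rnorm(n) ~ x1))      # exactly orthogonal to x1
  x1s <- (x1 - mean(x1)) / sd(x1)
  es <- (e - mean(e)) / sd(e)
  # orthogonal pair: both VIF 1
  v0 <- compute_vif(data.frame(x1 = x1s, x2 = es), c("x1", "x2"))
  expect_equal(unname(v0), c(1, 1), tolerance = 1e-10)
  # sample correlation exactly 0.9 by construction
  x2 <- 0.9 * x1s + sqrt(1 - 0.81) * es
  v <- compute_vif(data.frame(x1 = x1s, x2 = x2), c("x1", "x2"))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-6)
  expect_equal(unname(v[1]), 5.263, tolerance = 1e-3)
  # duplicated column: infinite VIF, not an error
  vd <- compute_vif(data.frame(x1 = x1s, x2 = x1s), c("x1", "x2"))
  expect_true(all(is.infinite(vd)))
})

test_that("fit_lmm recovers known coefficients and variance components", {
  d <- sim_panel(n_herds = 60, n_per = 10, seed = 11)
  sp <- model_spec("y", c("x1", "x2"))
  fit <- fit_lmm(sp, d, reml = TRUE)
  cf <- fit$coefficients
  expect_lt(abs(cf$beta[cf$term == "x1"] - 50),
            3 * cf$se[cf$term == "x1"])
  expect_lt(abs(cf$beta[cf$term == "x2"] + 20),
            3 * cf$se[cf$term == "x2"])
  expect_lt(abs(sqrt(fit$varcomp["herd"]) - 30), 10)
  expect_lt(abs(sqrt(fit$varcomp["residual"]) - 20), 3)
  expect_error(fit_lmm(sp, d[d$herd == "H01", ]), "unidentifiable")
  d_na <- d; d_na$x1[1] <- NA
  expect_error(fit_lmm(sp, d_na), "missing")
})

test_that("null effects stay within 3 SE at nominal rates", {
  hits <- 0L; total <- 0L
  for (r in 1:60) {
    d <- sim_panel(n_herds = 20, n_per = 5, beta = c(x1 = 0, x2 = 0),
                   seed = 100 + r)
    fit <- fit_lmm(model_spec("y", c("x1", "x2")), d)
    cf <- fit$coefficients[fit$coefficients$term %in% c("x1", "x2"), ]
    hits <- hits + sum(abs(cf$beta) < 3 * cf$se)
    total <- total + nrow(cf)
  }
  expect_gte(hits / total, 0.97)
})

test_that("zero herd variance is recovered near the boundary", {
  vr <- sapply(1:11, function(r) {
    d <- sim_panel(n_herds = 30, n_per = 8, herd_sd = 0, seed = 200 + r)
    fit <- fit_lmm(model_spec("y", c("x1", "x2")), d)
    fit$varcomp["herd"] / fit$varcomp["residual"]
  })
  expect_lte(median(vr), 0.05)
})

test_that("backward selection drops noise at the AIC-implied rate and
           never drops forced terms", {
  removed <- logical(30)
  for (r in 1:30) {
    d <- sim_panel(n_herds = 25, n_per = 8, beta = c(x1 = 50, x2 = -20),
                   year_eff = 0, seed = 300 + r)
    d$noise <- rnorm(nrow(d))
    sel <- backward_select_aic(model_spec("y", c("x1", "x2", "noise")), d)
    removed[r] <- !("noise" %in% sel$fit$terms)
    # forced year survives even with zero simulated year effect
    expect_true(any(grepl("year", sel$fit$coefficients$term)))
    expect_true(all(c("x1", "x2") %in% sel$fit$terms))
    # AIC of the selected model never exceeds the full model's
    full_aic <- sel$trace$aic[1]
    expect_lte(min(sel$trace$aic), full_aic + 1e-9)
  }
  # AIC keeps a pure-noise term iff its chi-square(1) stat exceeds 2,
  # i.e. drops it with probability ~P(chisq < 2) = 0.843
  expect_gte(mean(removed), 0.70)
  expect_lte(mean(removed), 0.97)
})

test_that("R2 decomposition recovers simulated variance shares (2,1,1)", {
  # 500 herds x 10 obs: enough groups that the herd-variance estimate's
  # own sampling noise stays well inside the 0.03 band
  set.seed(17)
  n_herds <- 500; n_per <- 10
  d <- data.frame(herd = rep(sprintf("H%03d", 1:n_herds), each = n_per))
  d$x <- rnorm(nrow(d))
  u <- rnorm(n_herds, 0, 1)
  d$y <- sqrt(2) * d$x + u[as.integer(factor(d$herd))] + rnorm(nrow(d))
  sp <- model_spec("y", "x", forced = character(0))
  fit <- fit_lmm(sp, d, reml = TRUE)
  r2 <- r2_decomposition(fit, d)
  expect_equal(r2$marginal, 0.50, tolerance = 0.03)
  expect_equal(r2$conditional, 0.75, tolerance = 0.03)
  expect_lte(r2$marginal, r2$conditional)
  # a zero-effect term explains (almost) nothing
  d$z <- rnorm(nrow(d))
  fit2 <- fit_lmm(model_spec("y", c("x", "z"), forced = character(0)), d,
                  reml = TRUE)
  r22 <- r2_decomposition(fit2, d)
  expect_lte(r22$part[["z"]], 0.01)
  expect_gt(r22$part[["x"]], 0.4)
})

test_that("intercept-only fixed part has zero marginal R2", {
  d <- sim_panel(seed = 23)
  sp <- model_spec("y", character(0), forced = character(0))
  fit <- fit_lmm(sp, d, terms = character(0), reml = TRUE)
  r2 <- r2_decomposition(fit, d)
  expect_equal(r2$marginal, 0)
  expect_gt(r2$conditional, 0)
})

test_that("standardizing predictors leaves R2 unchanged", {
  d <- sim_panel(seed = 29)
  sp <- model_spec("y", c("x1", "x2"))
  f1 <- fit_lmm(sp, d, reml = TRUE)
  r1 <- r2_decomposition(f1, d)
  s <- standardize_continuous(d, c("x1", "x2"))
  f2 <- fit_lmm(sp, s$data, reml = TRUE)
  r2 <- r2_decomposition(f2, s$data)
  expect_equal(r1$marginal, r2$marginal, tolerance = 1e-6)
  expect_equal(r1$conditional, r2$conditional, tolerance = 1e-6)
})

test_that("model_spec guards its invariants", {
  expect_error(model_spec("y", c("x", "y")), "outcome")
  expect_error(model_spec("y", "x", group = c("a", "b")), "one grouping")
})
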