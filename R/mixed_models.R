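#' Standardize continuous variables
#'
#' Replaces each listed column by (x - mean)/SD computed over the table, so
#' that regression coefficients are comparable across predictors (EUR per
#' SD). Means and SDs are retained for back-transformation; the outcome and
#' categorical columns are left untouched.
#'
#' @param data data frame.
#' @param variables character vector of numeric column names.
#' @return list with \code{data} (standardized table) and \code{scaling}
#'   (data frame \code{variable}, \code{mean}, \code{sd}).
#' @export
standardize_continuous <- function(data, variables) {
  scaling <- data.frame(variable = variables,
                        mean = NA_real_, sd = NA_real_,
                        stringsAsFactors = FALSE)
  for (i in seq_along(variables)) {
    v <- variables[i]
    x <- data[[v]]
    if (!is.numeric(x)) stop("variable `", v, "` is not numeric")
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("degenerate variable `", v, "`: zero or undefined SD")
    }
    data[[v]] <- (x - m) / s
    scaling$mean[i] <- m
    scaling$sd[i] <- s
  }
  list(data = data, scaling = scaling)
}

#' Undo a standardization
#'
#' @param data standardized data frame.
#' @param scaling scaling record from [standardize_continuous()].
#' @return data frame on the original scale.
#' @export
unstandardize_continuous <- function(data, scaling) {
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$variable[i]
    data[[v]] <- data[[v]] * scaling$sd[i] + scaling$mean[i]
  }
  data
}

#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R2_j), where R2_j is from the ordinary least-squares
#' regression of column j on all other listed columns. Exact collinearity is
#' reported as an infinite VIF rather than an error.
#'
#' @param data data frame containing the columns.
#' @param variables at least two numeric column names.
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(data, variables) {
  if (length(variables) < 2) stop("need at least two variables for VIF")
  X <- as.matrix(data[variables])
  if (!is.numeric(X)) stop("VIF variables must be numeric")
  vapply(seq_along(variables), function(j) {
    y <- X[, j]
    others <- X[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) -> v
  stats::setNames(v, variables)
}

#' Specification of one linear mixed model
#'
#' Fixed-effect candidates plus forced terms (the calendar-year factor is
#' always forced, to absorb market-level price effects), a single random
#' intercept grouping (herd), and the outcome. Backward selection may drop
#' candidates but never forced terms.
#'
#' @param outcome outcome column name (e.g. \code{"iofc_cow"}).
#' @param candidates character vector of candidate fixed-effect column
#'   names; categorical columns are entered as factors.
#' @param forced forced fixed-effect terms, default \code{"year"}.
#' @param group random-intercept grouping column, default \code{"herd"}.
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(outcome, candidates, forced = "year",
                       group = "herd") {
  if (outcome %in% c(candidates, forced)) {
    stop("outcome must not appear among the predictors")
  }
  if (length(group) != 1L) stop("exactly one grouping factor is required")
  structure(list(outcome = outcome, candidates = candidates,
                 forced = forced, group = group), class = "model_spec")
}

.lmm_formula <- function(spec, terms) {
  rhs <- c(vapply(spec$forced, function(t) paste0("factor(", t, ")"), ""),
           terms)
  if (length(rhs) == 0L) rhs <- "1"
  stats::as.formula(paste(
    spec$outcome, "~", paste(rhs, collapse = " + "),
    "+ (1 |", spec$group, ")"))
}

#' Fit a random-intercept linear mixed model
#'
#' Fits \code{outcome ~ forced + terms + (1 | group)} with \pkg{lme4}.
#' Maximum likelihood (\code{REML = FALSE}) is used inside model selection
#' so AIC values are comparable across fixed-effect sets; the final reported
#' model is refit by REML. Fixed-effect p-values are Wald z.
#'
#' @param spec a [model_spec()].
#' @param data analysis table; used columns must be complete.
#' @param terms candidate terms to include (default: all of
#'   \code{spec$candidates}).
#' @param reml logical, REML or ML estimation.
#' @return object of class \code{lmm_fit}: list with \code{model} (the
#'   merMod), \code{coefficients} (term, beta, se, z, p), \code{varcomp}
#'   (herd and residual variances), \code{aic}, \code{logLik},
#'   \code{fitted_fixed} (fixed-effect predictions per row), \code{terms},
#'   \code{spec}, \code{converged}.
#' @export
fit_lmm <- function(spec, data, terms = spec$candidates, reml = FALSE) {
  if (length(unique(data[[spec$group]])) < 2L) {
    stop("random intercept unidentifiable: need at least 2 groups")
  }
  used <- unique(c(spec$outcome, spec$forced, terms, spec$group))
  if (anyNA(data[used])) stop("missing values in model columns")
  fml <- .lmm_formula(spec, terms)
  fit <- lme4::lmer(fml, data = data, REML = reml,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  cf <- as.data.frame(summary(fit)$coefficients)
  names(cf) <- c("beta", "se", "z")
  coefficients <- data.frame(term = rownames(cf), beta = cf$beta,
                             se = cf$se, z = cf$z,
                             p = 2 * stats::pnorm(-abs(cf$z)),
                             stringsAsFactors = FALSE)
  rownames(coefficients) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  herd_var <- vc$vcov[vc$grp == spec$group]
  resid_var <- vc$vcov[vc$grp == "Residual"]
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(
    model = fit, coefficients = coefficients,
    varcomp = c(herd = herd_var, residual = resid_var),
    aic = stats::AIC(fit), logLik = as.numeric(stats::logLik(fit)),
    fitted_fixed = unname(stats::predict(fit, re.form = NA)),
    terms = terms, spec = spec, reml = reml,
    converged = is.null(msgs) || length(msgs) == 0L
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model: %s (%s)\n", deparse(.lmm_formula(
    x$spec, x$terms)), if (x$reml) "REML" else "ML"))
  print(x$coefficients, digits = 3)
  cat(sprintf("Variance components: herd %.2f, residual %.2f; AIC %.1f\n",
              x$varcomp["herd"], x$varcomp["residual"], x$aic))
  invisible(x)
}

#' Backward model selection by AIC with forced terms
#'
#' Starting from the full candidate set, repeatedly refits (by ML) with each
#' single candidate term removed and drops the term whose removal lowers AIC
#' the most; stops when no removal lowers AIC. AIC ties are broken by
#' dropping the term with the larger Wald p-value. Forced terms (year) are
#' never considered for removal. The selected model is refit by REML for
#' reporting.
#'
#' @param spec a [model_spec()].
#' @param data analysis table.
#' @return list with \code{fit} (REML [fit_lmm()] of the selected terms) and
#'   \code{trace} (data frame of steps: term dropped, AIC before/after).
#' @export
backward_select_aic <- function(spec, data) {
  terms <- spec$candidates
  current <- fit_lmm(spec, data, terms, reml = FALSE)
  trace <- data.frame(step = 0L, dropped = NA_character_,
                      aic = current$aic, stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(terms) == 0L) break
    cand_fits <- lapply(terms, function(t) {
      fit_lmm(spec, data, setdiff(terms, t), reml = FALSE)
    })
    aics <- vapply(cand_fits, `[[`, numeric(1), "aic")
    best <- min(aics)
    if (best >= current$aic - 1e-9) break
    winners <- which(abs(aics - best) < 1e-9)
    if (length(winners) > 1L) {
      # tie: drop the least significant term
      pvals <- vapply(terms[winners], function(t) {
        rows <- grepl(t, current$coefficients$term, fixed = TRUE)
        if (!any(rows)) 1 else min(current$coefficients$p[rows])
      }, numeric(1))
      winner <- winners[which.max(pvals)]
    } else winner <- winners
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = terms[winner],
                                     aic = aics[winner],
                                     stringsAsFactors = FALSE))
    terms <- setdiff(terms, terms[winner])
    current <- cand_fits[[winner]]
  }
  list(fit = fit_lmm(spec, data, terms, reml = TRUE), trace = trace)
}

#' Marginal, conditional and part R-squared of a mixed model
#'
#' Variance-explained decomposition for random-intercept models: with
#' \eqn{\sigma^2_f} the variance of the fixed-effect predictions,
#' \eqn{\tau^2} the herd-intercept variance and \eqn{\sigma^2_e} the
#' residual variance, the marginal R2 is
#' \eqn{\sigma^2_f / (\sigma^2_f + \tau^2 + \sigma^2_e)} and the conditional
#' R2 is \eqn{(\sigma^2_f + \tau^2)} over the same denominator. The part R2
#' of a term group is the drop in marginal R2 when the model is refit
#' without that group (floored at zero); the forced year factor is treated
#' as one group.
#'
#' @param fit an [fit_lmm()] result.
#' @param data the table the model was fit on.
#' @return list of class \code{r2_decomposition} with \code{marginal},
#'   \code{conditional} and \code{part} (named numeric vector per term
#'   group).
#' @export
r2_decomposition <- function(fit, data) {
  spec <- fit$spec
  var_f <- stats::var(fit$fitted_fixed)
  tau2 <- unname(fit$varcomp["herd"])
  sig2 <- unname(fit$varcomp["residual"])
  denom <- var_f + tau2 + sig2
  if (denom <= 0) stop("zero total variance")
  marginal <- var_f / denom
  conditional <- (var_f + tau2) / denom

  marg_of <- function(terms, forced = spec$forced) {
    s <- spec
    s$forced <- forced
    f <- fit_lmm(s, data, terms, reml = fit$reml)
    vf <- stats::var(f$fitted_fixed)
    vf / (vf + unname(f$varcomp["herd"]) + unname(f$varcomp["residual"]))
  }
  groups <- c(stats::setNames(as.list(spec$forced), spec$forced),
              stats::setNames(as.list(fit$terms), fit$terms))
  part <- vapply(names(groups), function(g) {
    if (g %in% spec$forced) {
      m <- marg_of(fit$terms, forced = setdiff(spec$forced, g))
    } else {
      m <- marg_of(setdiff(fit$terms, g))
    }
    max(0, marginal - m)
  }, numeric(1))
  structure(list(marginal = marginal, conditional = conditional,
                 part = part), class = "r2_decomposition")
}

#' @export
print.r2_decomposition <- function(x, ...) {
  cat(sprintf("R2: marginal %.3f, conditional %.3f\n",
              x$marginal, x$conditional))
  cat("Part R2 by term group:\n")
  print(round(x$part, 4))
  invisible(x)
}
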