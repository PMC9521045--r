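# Cox and J tests for comparing two non-nested regressions of the same
# outcome. Convention: direction "A-B" tests the null that model B's
# regressors cannot improve model A; rejection means B adds information
# beyond A.

.ols_design <- function(spec, data, terms) {
  rhs <- c(vapply(spec$forced, function(t) paste0("factor(", t, ")"), ""),
           terms)
  if (length(rhs) == 0L) rhs <- "1"
  fml <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  stats::model.matrix(fml, data = data)
}

.ols_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  list(fitted = y - fit$residuals, residuals = fit$residuals,
       rank = fit$rank)
}

.residual_on <- function(X, v) {
  stats::lm.fit(X, v)$residuals
}

.check_distinct <- function(XA, XB) {
  # degenerate when the two design column spaces coincide
  rA <- qr(XA)$rank
  if (qr(cbind(XA, XB))$rank == rA && qr(XB)$rank == rA) {
    stop("degenerate comparison: the two models span the same design space")
  }
}

#' J test for non-nested models (one direction)
#'
#' Direction "A-B": model A's regression is augmented with model B's fitted
#' values as one extra covariate and that coefficient is tested against
#' zero; a significant coefficient means B's regressors improve A. In
#' \code{"ols"} mode both models are refit as fixed-effects-only
#' least-squares regressions (the classical Davidson-MacKinnon J test, with
#' a t-distributed statistic); in \code{"lmm"} mode the augmentation happens
#' inside model A's mixed model, with B's fixed-effect predictions as the
#' extra covariate and a Wald z statistic.
#'
#' @param fit_A,fit_B [fit_lmm()] results sharing outcome and rows.
#' @param data the analysis table both models were fit on.
#' @param mode \code{"lmm"} (augmentation inside the mixed model, pipeline
#'   default) or \code{"ols"} (classical fixed-effects-only J test).
#' @param direction label for the result, default built from the fits.
#' @return list of class \code{nonnested_result} with \code{test},
#'   \code{direction}, \code{estimate}, \code{se}, \code{statistic},
#'   \code{p}.
#' @export
j_test <- function(fit_A, fit_B, data, mode = c("lmm", "ols"),
                   direction = "A-B") {
  mode <- match.arg(mode)
  spec_A <- fit_A$spec; spec_B <- fit_B$spec
  if (spec_A$outcome != spec_B$outcome) stop("outcomes differ")
  y <- data[[spec_A$outcome]]
  XA <- .ols_design(spec_A, data, fit_A$terms)
  XB <- .ols_design(spec_B, data, fit_B$terms)
  .check_distinct(XA, XB)

  if (mode == "ols") {
    fB <- .ols_fit(XB, y)$fitted
    resid_aug <- .residual_on(XA, fB)
    if (sum(resid_aug^2) < 1e-10 * sum(fB^2)) {
      stop("degenerate comparison: rival fitted values collinear with model A")
    }
    Xaug <- cbind(XA, rival = fB)
    fit <- stats::lm.fit(Xaug, y)
    n <- length(y); k <- fit$rank
    sigma2 <- sum(fit$residuals^2) / (n - k)
    XtXinv <- chol2inv(chol(crossprod(Xaug)))
    est <- fit$coefficients[["rival"]]
    se <- sqrt(sigma2 * XtXinv[ncol(Xaug), ncol(Xaug)])
    stat <- est / se
    p <- 2 * stats::pt(-abs(stat), df = n - k)
  } else {
    fB <- fit_B$fitted_fixed
    resid_aug <- .residual_on(XA, fB)
    if (sum(resid_aug^2) < 1e-10 * sum(fB^2)) {
      stop("degenerate comparison: rival fitted values collinear with model A")
    }
    d2 <- data
    d2[[".rival_fit"]] <- fB
    aug <- fit_lmm(spec_A, d2, c(fit_A$terms, ".rival_fit"),
                   reml = fit_A$reml)
    row <- aug$coefficients[aug$coefficients$term == ".rival_fit", ]
    est <- row$beta; se <- row$se; stat <- row$z; p <- row$p
  }
  structure(list(test = "j", direction = direction, estimate = unname(est),
                 se = unname(se), statistic = unname(stat), p = unname(p)),
            class = "nonnested_result")
}

#' Cox test for non-nested models (one direction)
#'
#' Pesaran's operational form of Cox's centred likelihood-ratio statistic,
#' computed on fixed-effects-only least-squares refits of both models. With
#' residual variances \eqn{\hat\sigma^2_A = RSS_A/n} and
#' \eqn{\hat\sigma^2_B = RSS_B/n}, and \eqn{M_B} the residual-maker of B's
#' design, \eqn{\hat\sigma^2_{BA} = \hat\sigma^2_A +
#' \|M_B \hat y_A\|^2 / n}; the estimate is
#' \eqn{c = (n/2)\,\log(\hat\sigma^2_B / \hat\sigma^2_{BA})}, its variance
#' \eqn{\hat\sigma^2_A\, \hat y_A' M_B M_A M_B \hat y_A / \hat\sigma^4_{BA}},
#' and the statistic is standard normal under the null that B's regressors
#' cannot improve A. A large negative statistic rejects that null.
#'
#' @inheritParams j_test
#' @return list of class \code{nonnested_result}.
#' @export
cox_test <- function(fit_A, fit_B, data, direction = "A-B") {
  spec_A <- fit_A$spec; spec_B <- fit_B$spec
  if (spec_A$outcome != spec_B$outcome) stop("outcomes differ")
  y <- data[[spec_A$outcome]]
  XA <- .ols_design(spec_A, data, fit_A$terms)
  XB <- .ols_design(spec_B, data, fit_B$terms)
  .check_distinct(XA, XB)
  n <- length(y)

  olsA <- .ols_fit(XA, y)
  olsB <- .ols_fit(XB, y)
  s2A <- sum(olsA$residuals^2) / n
  s2B <- sum(olsB$residuals^2) / n
  fA <- olsA$fitted
  MB_fA <- .residual_on(XB, fA)
  s2BA <- s2A + sum(MB_fA^2) / n
  est <- (n / 2) * log(s2B / s2BA)
  MA_MB_fA <- .residual_on(XA, MB_fA)
  MB_MA_MB_fA <- .residual_on(XB, MA_MB_fA)
  v <- s2A * sum(MB_fA * MB_MA_MB_fA) / s2BA^2
  se <- sqrt(v)
  stat <- est / se
  structure(list(test = "cox", direction = direction, estimate = est,
                 se = se, statistic = stat,
                 p = 2 * stats::pnorm(-abs(stat))),
            class = "nonnested_result")
}

#' @export
print.nonnested_result <- function(x, ...) {
  cat(sprintf("%s test, direction %s: estimate %.3g (SE %.3g), z = %.2f, p = %.4g\n",
              toupper(x$test), x$direction, x$estimate, x$se, x$statistic,
              x$p))
  invisible(x)
}

#' Verdict from a pair of non-nested test directions
#'
#' Direction "A-B" carries the null that B's regressors cannot improve model
#' A. If both directions reject, each model adds information the other
#' lacks: no difference. If only "B-A" rejects (A improves B but B does not
#' improve A), A is the better model, and vice versa. If neither rejects,
#' the test is uninformative.
#'
#' @param p_ab p-value of direction "A-B".
#' @param p_ba p-value of direction "B-A".
#' @param alpha significance level, default 0.05.
#' @param labels model names \code{c(A, B)} used in the verdict string.
#' @return character verdict.
#' @export
interpret_comparison <- function(p_ab, p_ba, alpha = 0.05,
                                 labels = c("A", "B")) {
  stopifnot(p_ab >= 0, p_ab <= 1, p_ba >= 0, p_ba <= 1)
  rej_ab <- p_ab < alpha   # B improves A
  rej_ba <- p_ba < alpha   # A improves B
  if (rej_ab && rej_ba) return("No difference")
  if (rej_ba) return(sprintf("%s is better than %s", labels[1], labels[2]))
  if (rej_ab) return(sprintf("%s is better than %s", labels[2], labels[1]))
  "Neither model informative"
}

#' Run Cox and J tests in both directions and interpret
#'
#' @param fit_A,fit_B [fit_lmm()] results of the two rival models.
#' @param data analysis table.
#' @param alpha significance level for the verdicts.
#' @param labels model names \code{c(A, B)}.
#' @param j_mode mode passed to [j_test()].
#' @return data frame with one row per test x direction: \code{test},
#'   \code{outcome}, \code{direction}, \code{estimate}, \code{se},
#'   \code{statistic}, \code{p}, \code{interpretation} (on the first row of
#'   each test).
#' @export
compare_models <- function(fit_A, fit_B, data, alpha = 0.05,
                           labels = c("A", "B"), j_mode = "lmm") {
  dir_ab <- paste(labels, collapse = "-")
  dir_ba <- paste(rev(labels), collapse = "-")
  res <- list(
    cox_test(fit_A, fit_B, data, direction = dir_ab),
    cox_test(fit_B, fit_A, data, direction = dir_ba),
    j_test(fit_A, fit_B, data, mode = j_mode, direction = dir_ab),
    j_test(fit_B, fit_A, data, mode = j_mode, direction = dir_ba))
  out <- do.call(rbind, lapply(res, function(r) {
    data.frame(test = r$test, outcome = fit_A$spec$outcome,
               direction = r$direction, estimate = r$estimate, se = r$se,
               statistic = r$statistic, p = r$p, stringsAsFactors = FALSE)
  }))
  out$interpretation <- NA_character_
  out$interpretation[1] <- interpret_comparison(out$p[1], out$p[2], alpha,
                                                labels)
  out$interpretation[3] <- interpret_comparison(out$p[3], out$p[4], alpha,
                                                labels)
  out
}
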