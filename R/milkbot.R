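#' MilkBot lactation curve yield
#'
#' Evaluates the simplified MilkBot lactation curve
#' \deqn{Y(t) = a \left(1 - \tfrac{1}{2} e^{-t/b}\right) e^{-d t}}
#' where \code{a} is the magnitude (scale) of production in kg/day, \code{b}
#' the ramp in days (reported downstream as time to peak yield), and \code{d}
#' the decay rate in 1/day. The offset parameter of the full four-parameter
#' MilkBot family is fixed at zero: it is practically undetectable without
#' daily weighings in very early lactation.
#'
#' @param t days in milk (DIM), numeric vector, \code{t >= 0}.
#' @param a magnitude, kg/day, \code{a > 0}.
#' @param b ramp, days, \code{b > 0}.
#' @param d decay, 1/day, \code{d >= 0}.
#' @return Predicted milk yield in kg/day, same length as the longest input.
#' @examples
#' milkbot_yield(0, a = 40, b = 20, d = 0.002)   # a/2 at calving
#' milkbot_yield(100, a = 40, b = 20, d = 0.002)
#' @export
milkbot_yield <- function(t, a, b, d) {
  if (any(!is.finite(a)) || any(a <= 0)) stop("magnitude `a` must be positive")
  if (any(!is.finite(b)) || any(b <= 0)) stop("ramp `b` must be positive")
  if (any(d < 0)) stop("decay `d` must be nonnegative")
  if (any(t < 0)) stop("days in milk `t` must be nonnegative")
  a * (1 - 0.5 * exp(-t / b)) * exp(-d * t)
}

#' Persistency from the decay rate
#'
#' Persistency is the half-life of post-peak milk decline: the time, in days,
#' for production to drop by half after the peak. For exponential decay at
#' rate \code{d} this is \code{log(2)/d}; the familiar printed constant 0.693
#' is the 3-decimal rounding of \code{log(2)}, which is used at full
#' precision here.
#'
#' @param d decay rate in 1/day, strictly positive (vectorised).
#' @return Persistency in days.
#' @export
persistency_from_decay <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("decay `d` must be strictly positive for a finite persistency")
  }
  log(2) / d
}

# Bounds and starting values for the bounded least-squares fit. a0 = 2*max
# uses Y(0) = a/2; bounds bracket the biological range.
.milkbot_bounds <- list(
  lower = c(a = 1e-6, b = 1e-3, d = 0),
  upper = c(a = 150, b = 100, d = 0.05)
)

.milkbot_rss <- function(par, dim, milk) {
  sum((milk - par[1] * (1 - 0.5 * exp(-dim / par[2])) * exp(-par[3] * dim))^2)
}

.milkbot_rss_grad <- function(par, dim, milk) {
  e <- exp(-dim / par[2])
  g <- 1 - 0.5 * e
  h <- exp(-par[3] * dim)
  f <- par[1] * g * h
  r <- milk - f
  c(-2 * sum(r * g * h),
    -2 * sum(r * par[1] * h * (-0.5 * e * dim / par[2]^2)),
    -2 * sum(r * (-dim) * f))
}

#' Fit the MilkBot curve to one lactation
#'
#' Bounded nonlinear least squares of milk weighings on days in milk, with
#' \code{a in (0, 150]}, \code{b in (0, 100]}, \code{d in [0, 0.05]}. The
#' primary optimiser is \code{nls} (port algorithm); on failure an
#' \code{optim} L-BFGS-B fallback is used and the fit is flagged. At least 4
#' weighings are required to fit 3 parameters with one residual degree of
#' freedom.
#'
#' @param dim days in milk of the weighings, strictly positive and increasing.
#' @param milk milk yields in kg/day.
#' @param parity_group \code{"primiparous"} or \code{"multiparous"}
#'   (bookkeeping only; does not affect the fit).
#' @param min_points minimum number of weighings (default 4).
#' @return An object of class \code{lactation_fit}: a list with elements
#'   \code{a}, \code{b}, \code{d}, \code{persistency}, \code{n_points},
#'   \code{rss}, \code{converged}, \code{parity_group}.
#' @export
fit_lactation <- function(dim, milk, parity_group = "multiparous",
                          min_points = 4L) {
  if (length(dim) != length(milk)) stop("`dim` and `milk` lengths differ")
  if (length(dim) < min_points) {
    stop("insufficient data: need at least ", min_points, " weighings, got ",
         length(dim))
  }
  if (any(dim <= 0)) stop("days in milk must be strictly positive")
  if (is.unsorted(dim, strictly = TRUE)) {
    stop("days in milk must be strictly increasing")
  }
  if (all(milk <= 0)) stop("degenerate data: all milk yields are zero")

  start <- c(a = min(2 * max(milk), 150), b = 21, d = 0.003)
  lo <- .milkbot_bounds$lower
  up <- .milkbot_bounds$upper

  run_lbfgsb <- function(p0) {
    o <- try(stats::optim(p0, .milkbot_rss, .milkbot_rss_grad,
                          dim = dim, milk = milk,
                          method = "L-BFGS-B", lower = lo, upper = up,
                          control = list(factr = 1e4, pgtol = 1e-10,
                                         maxit = 500)),
             silent = TRUE)
    if (inherits(o, "try-error")) NULL
    else list(par = o$par, rss = o$value, converged = o$convergence == 0L)
  }
  fit <- run_lbfgsb(start)
  if (!is.null(fit)) {
    # L-BFGS-B can stall in the flat a-b valley; restarts from the found
    # optimum (fresh Hessian approximation) reliably finish the descent
    for (i in 1:5) {
      polish <- run_lbfgsb(fit$par)
      if (is.null(polish) || polish$rss > fit$rss * (1 - 1e-10)) break
      fit <- polish
    }
  }
  if (is.null(fit) || !fit$converged) {
    # retry from a peak-informed start; keep the better optimum
    alt <- run_lbfgsb(c(a = min(1.1 * max(milk), 150), b = 25,
                        d = 0.002))
    if (!is.null(alt) &&
        (is.null(fit) || alt$rss < fit$rss)) fit <- alt
  }
  if (is.null(fit)) {
    # derivative-free last resort
    o <- stats::optim(start, .milkbot_rss, dim = dim, milk = milk,
                      method = "Nelder-Mead", control = list(maxit = 1000))
    par <- pmin(pmax(o$par, lo), up)
    fit <- list(par = par, rss = .milkbot_rss(par, dim, milk),
                converged = FALSE)
  }

  par <- fit$par
  structure(list(
    a = unname(par[1]), b = unname(par[2]), d = unname(par[3]),
    persistency = if (par[3] > 0) log(2) / unname(par[3]) else Inf,
    n_points = length(dim), rss = fit$rss, converged = fit$converged,
    parity_group = parity_group
  ), class = "lactation_fit")
}

#' @export
print.lactation_fit <- function(x, ...) {
  cat(sprintf(
    "MilkBot fit (%s): a = %.2f kg/d, b = %.2f d, d = %.5f /d, P = %.0f d\n",
    x$parity_group, x$a, x$b, x$d, x$persistency))
  cat(sprintf("  n = %d weighings, RSS = %.3f kg^2, converged: %s\n",
              x$n_points, x$rss, x$converged))
  invisible(x)
}

#' Fit MilkBot curves for every lactation in a test-day table
#'
#' Splits a test-day table by lactation, fits each complete set of weighings,
#' and returns one row per lactation with parameters and diagnostics.
#' Lactations with fewer than \code{min_points} weighings are skipped.
#' A lactation is flagged complete when its last weighing is at or beyond
#' \code{complete_dim} days in milk.
#'
#' @param test_days data frame with columns \code{herd}, \code{cow},
#'   \code{lactation}, \code{parity}, \code{dim}, \code{milk}.
#' @param min_points minimum weighings per lactation (default 4).
#' @param complete_dim DIM threshold for the completeness flag (default 240).
#' @return data frame with columns \code{herd}, \code{cow}, \code{lactation},
#'   \code{parity_group}, \code{a}, \code{b}, \code{d}, \code{persistency},
#'   \code{n_points}, \code{rss}, \code{converged}, \code{complete}.
#' @export
fit_lactations <- function(test_days, min_points = 4L, complete_dim = 240) {
  stopifnot(all(c("herd", "cow", "lactation", "parity", "dim", "milk") %in%
                  names(test_days)))
  ord <- order(test_days$lactation, test_days$dim)
  lact <- test_days$lactation[ord]
  dim_v <- test_days$dim[ord]
  milk_v <- test_days$milk[ord]
  split_idx <- split(seq_along(lact), lact)
  fits <- lapply(split_idx, function(idx) {
    if (length(idx) < min_points) return(NULL)
    tryCatch(fit_lactation(dim_v[idx], milk_v[idx],
                           min_points = min_points),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  idx1 <- vapply(split_idx[ok], `[`, integer(1), 1L)  # first row per lactation
  f <- fits[ok]
  out <- data.frame(
    herd = test_days$herd[ord][idx1],
    cow = test_days$cow[ord][idx1],
    lactation = names(split_idx)[ok],
    parity_group = parity_group(test_days$parity[ord][idx1]),
    a = vapply(f, `[[`, numeric(1), "a"),
    b = vapply(f, `[[`, numeric(1), "b"),
    d = vapply(f, `[[`, numeric(1), "d"),
    persistency = vapply(f, `[[`, numeric(1), "persistency"),
    n_points = vapply(f, `[[`, integer(1), "n_points"),
    rss = vapply(f, `[[`, numeric(1), "rss"),
    converged = vapply(f, `[[`, logical(1), "converged"),
    complete = vapply(split_idx[ok], function(i) max(dim_v[i]), 0) >=
      complete_dim,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Parity group label
#'
#' First-lactation cows are primiparous; all later parities multiparous.
#'
#' @param parity integer parity (1, 2, ...), vectorised.
#' @return character vector, \code{"primiparous"} or \code{"multiparous"}.
#' @export
parity_group <- function(parity) {
  ifelse(parity <= 1L, "primiparous", "multiparous")
}

#' Cumulative 305-day milk yield of a MilkBot curve
#'
#' Closed-form integral of the simplified MilkBot curve from 0 to 305 days,
#' used to derive a 305-day production (M305) consistent with a parameter
#' set.
#'
#' @inheritParams milkbot_yield
#' @param horizon upper limit of integration in days (default 305).
#' @return Cumulative yield in kg.
#' @export
milkbot_m305 <- function(a, b, d, horizon = 305) {
  # int_0^T a (1 - e^{-t/b}/2) e^{-dt} dt
  r <- d + 1 / b
  term1 <- ifelse(d > 0, (1 - exp(-d * horizon)) / d, horizon)
  a * (term1 - 0.5 * (1 - exp(-r * horizon)) / r)
}
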