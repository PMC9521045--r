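#' Filter configuration for the data-editing cascade
#'
#' The editing cascade removes, in order: herd-years outside runs of
#' consecutive years, direct-selling and organic herds (their milk prices
#' differ too much from conventional herds), extremely small herds (below a
#' herd-size percentile), percentile outliers on a list of analysis
#' variables, and records with missing values in those variables. The
#' outlier percentile cutoffs are configurable (default outside the
#' \[0.5th, 99.5th\] percentile); percentiles are recomputed on the table as
#' it stands when the step runs.
#'
#' @param min_consecutive_years minimum run of consecutive years a herd must
#'   have for its records (within such runs) to be retained (default 2).
#' @param exclude_direct_sellers,exclude_organic logical flags.
#' @param small_herd_percentile herd-size percentile below which herd-years
#'   are dropped (default 0.01).
#' @param outlier_variables character vector of column names screened for
#'   outliers and missing values.
#' @param outlier_lower,outlier_upper percentile cutoffs for the outlier
#'   screen, \code{0 <= lower < upper <= 1}.
#' @return list of class \code{filter_config}.
#' @export
filter_config <- function(min_consecutive_years = 2L,
                          exclude_direct_sellers = TRUE,
                          exclude_organic = TRUE,
                          small_herd_percentile = 0.01,
                          outlier_variables = c(
                            "iofc_cow", "iofc_milk", "herd_intensity",
                            "equity_ratio", "hm305", "relative_milk_price",
                            "scc", "calving_interval", "persistency1",
                            "persistency2", "age_days"),
                          outlier_lower = 0.005,
                          outlier_upper = 0.995) {
  if (outlier_lower < 0 || outlier_upper > 1 ||
      outlier_lower >= outlier_upper) {
    stop("invalid filter config: need 0 <= lower < upper <= 1")
  }
  if (small_herd_percentile < 0 || small_herd_percentile > 1) {
    stop("invalid filter config: small_herd_percentile must lie in [0, 1]")
  }
  structure(list(
    min_consecutive_years = as.integer(min_consecutive_years),
    exclude_direct_sellers = exclude_direct_sellers,
    exclude_organic = exclude_organic,
    small_herd_percentile = small_herd_percentile,
    outlier_variables = outlier_variables,
    outlier_lower = outlier_lower, outlier_upper = outlier_upper),
    class = "filter_config")
}

#' Merge economics, HLCC and performance into one herd-year table
#'
#' Inner join on (herd, year) of the three sources, with the HLCC table
#' pivoted so both parity groups' magnitude, time to peak and persistency
#' appear as columns. Duplicate (herd, year) keys in any source are an
#' integrity error.
#'
#' @param economics economic-indicator table (see
#'   [compute_economic_indicators()]).
#' @param hlcc herd-year HLCC table (see [aggregate_hlcc()]), long format
#'   with a \code{parity_group} column, or already pivoted wide.
#' @param performance herd-year performance table (\code{hm305}, \code{scc},
#'   \code{calving_interval}, \code{age_days}).
#' @return merged data frame, one row per herd-year present in all three
#'   sources.
#' @export
merge_sources <- function(economics, hlcc, performance) {
  if ("parity_group" %in% names(hlcc)) hlcc <- pivot_hlcc(hlcc)
  for (nm in c("economics", "hlcc", "performance")) {
    tab <- get(nm)
    if (anyDuplicated(tab[c("herd", "year")])) {
      stop("integrity error: duplicate (herd, year) keys in ", nm)
    }
  }
  out <- merge(economics, hlcc, by = c("herd", "year"))
  out <- merge(out, performance, by = c("herd", "year"))
  out <- out[order(out$herd, out$year), ]
  rownames(out) <- NULL
  out
}

# herd-years lying within a run of >= k consecutive years, per herd
.in_consecutive_run <- function(herd, year, k) {
  keep <- logical(length(herd))
  for (h in unique(herd)) {
    idx <- which(herd == h)
    yrs <- sort(unique(year[idx]))
    runs <- split(yrs, cumsum(c(1, diff(yrs) != 1)))
    good <- unlist(runs[vapply(runs, length, 0L) >= k], use.names = FALSE)
    keep[idx] <- year[idx] %in% good
  }
  keep
}

#' Apply the data-editing cascade
#'
#' Runs the ordered exclusion steps of [filter_config()] on a merged
#' herd-year table and returns the retained analysis table together with an
#' audit log giving, per step, the number of records excluded and remaining.
#' The audit arithmetic always reconciles: remaining counts are
#' non-increasing and the final count equals the input minus the summed
#' exclusions.
#'
#' @param merged merged herd-year table from [merge_sources()].
#' @param config a [filter_config()].
#' @return list with \code{data} (the analysis table) and \code{audit} (data
#'   frame with columns \code{step}, \code{excluded}, \code{remaining}).
#' @export
apply_filters <- function(merged, config = filter_config()) {
  unknown <- setdiff(config$outlier_variables, names(merged))
  if (length(unknown)) {
    stop("config error: unknown outlier variable(s): ",
         paste(unknown, collapse = ", "))
  }
  audit <- data.frame(step = character(), excluded = integer(),
                      remaining = integer(), stringsAsFactors = FALSE)
  log_step <- function(name, before, after) {
    rbind(audit, data.frame(step = name, excluded = before - after,
                            remaining = after, stringsAsFactors = FALSE))
  }
  d <- merged

  n0 <- nrow(d)
  d <- d[.in_consecutive_run(d$herd, d$year, config$min_consecutive_years), ]
  audit <- log_step("non_consecutive_years", n0, nrow(d))

  n0 <- nrow(d)
  drop <- rep(FALSE, nrow(d))
  if (config$exclude_direct_sellers && "direct_seller" %in% names(d)) {
    drop <- drop | d$direct_seller %in% c(TRUE, "TRUE", "yes")
  }
  if (config$exclude_organic && "organic" %in% names(d)) {
    drop <- drop | d$organic %in% c(TRUE, "TRUE", "yes")
  }
  d <- d[!drop, ]
  audit <- log_step("direct_seller_or_organic", n0, nrow(d))

  n0 <- nrow(d)
  if (nrow(d) > 0) {
    cut <- stats::quantile(d$herd_size, config$small_herd_percentile,
                           na.rm = TRUE, names = FALSE)
    d <- d[is.na(d$herd_size) | d$herd_size >= cut, ]
  }
  audit <- log_step("small_herds", n0, nrow(d))

  n0 <- nrow(d)
  if (nrow(d) > 0) {
    out_mask <- rep(FALSE, nrow(d))
    for (v in config$outlier_variables) {
      x <- d[[v]]
      if (all(is.na(x))) next
      qs <- stats::quantile(x, c(config$outlier_lower, config$outlier_upper),
                            na.rm = TRUE, names = FALSE)
      out_mask <- out_mask | (!is.na(x) & (x < qs[1] | x > qs[2]))
    }
    d <- d[!out_mask, ]
  }
  audit <- log_step("percentile_outliers", n0, nrow(d))

  n0 <- nrow(d)
  has_na <- Reduce(`|`, lapply(config$outlier_variables,
                               function(v) is.na(d[[v]])))
  if (length(has_na)) d <- d[!has_na, ]
  audit <- log_step("missing_values", n0, nrow(d))

  rownames(d) <- NULL
  list(data = d, audit = audit)
}
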