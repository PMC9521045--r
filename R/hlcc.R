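#' Lower weighted median
#'
#' After normalising the weights and sorting by value, returns the smallest
#' value whose cumulative weight reaches 0.5. This lower-median convention
#' (no interpolation) is deterministic and directly checkable against an
#' enumeration oracle.
#'
#' @param values numeric vector, at least one element.
#' @param weights nonnegative weights, same length; must not sum to zero.
#' @return One element of \code{values}.
#' @export
weighted_median <- function(values, weights) {
  if (length(values) == 0L) stop("weighted_median of empty input")
  if (length(values) != length(weights)) stop("values/weights length mismatch")
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero")
  o <- order(values)
  cw <- cumsum(weights[o]) / s
  values[o][which(cw >= 0.5)[1]]
}

#' Partition lactations across calendar years by test-day counts
#'
#' A lactation that spans calendar years belongs to each year it touches with
#' a weight proportional to its number of test-day records in that year: a
#' lactation with 5 weighings in one year out of n total weighings in its
#' herd-year-parity cell contributes weight 5/n there. Weights are normalised
#' within each herd x calendar-year x parity-group cell, so they sum to 1
#' per cell. Calendar-year assignment follows the test date, not the calving
#' date. Lactations present in \code{fits} but without any test-day record
#' are dropped with a message.
#'
#' @param test_days test-day table with columns \code{herd}, \code{cow},
#'   \code{lactation}, \code{parity}, \code{year} (calendar year of the test
#'   date), \code{dim}, \code{milk}.
#' @param fits per-lactation fit table (see [fit_lactations()]); only its
#'   lactations receive weights.
#' @return data frame with one row per lactation x year touched: \code{herd},
#'   \code{cow}, \code{lactation}, \code{parity_group}, \code{year},
#'   \code{test_days_in_year}, \code{weight}.
#' @export
partition_lactation_weights <- function(test_days, fits) {
  stopifnot(all(c("herd", "lactation", "parity", "year") %in% names(test_days)))
  missing_td <- setdiff(fits$lactation, test_days$lactation)
  if (length(missing_td)) {
    message(length(missing_td),
            " lactation(s) in fits have no test-day records; excluded")
  }
  td <- test_days[test_days$lactation %in% fits$lactation, ]
  if (nrow(td) == 0L) {
    return(data.frame(herd = character(), cow = character(),
                      lactation = character(), parity_group = character(),
                      year = integer(), test_days_in_year = integer(),
                      weight = numeric()))
  }
  td$parity_group <- parity_group(td$parity)
  key <- paste(td$lactation, td$year, sep = "\r")
  first <- !duplicated(key)
  counts <- data.frame(td[first, c("herd", "cow", "lactation",
                                   "parity_group", "year")],
                       stringsAsFactors = FALSE)
  tab <- table(key)
  counts$test_days_in_year <- as.integer(tab[key[first]])
  cell <- paste(counts$herd, counts$year, counts$parity_group, sep = "\r")
  cell_total <- rowsum(counts$test_days_in_year, cell)
  counts$weight <- counts$test_days_in_year /
    cell_total[match(cell, rownames(cell_total)), 1]
  out <- counts[order(counts$herd, counts$year, counts$parity_group,
                      counts$lactation), ]
  rownames(out) <- NULL
  out[c("herd", "cow", "lactation", "parity_group", "year",
        "test_days_in_year", "weight")]
}

#' Aggregate lactation curve characteristics to herd-year level
#'
#' Weighted median (lower convention) of magnitude, time to peak yield and
#' persistency over the complete lactations contributing to each herd x
#' calendar year x parity-group cell, using test-day-count weights from
#' [partition_lactation_weights()]. Herd-level values for the first and last
#' calendar year of the input span are excluded: lactations touching those
#' years are systematically truncated at the span edges, so their cells are
#' not trustworthy.
#'
#' @param fits per-lactation fit table with a logical \code{complete} column.
#' @param weights lactation-year weight table.
#' @param year_span integer vector of calendar years covered by the input
#'   (e.g. \code{2007:2016}); its first and last year are dropped.
#' @return data frame keyed by (\code{herd}, \code{year},
#'   \code{parity_group}) with \code{magnitude}, \code{time_to_peak},
#'   \code{persistency}, \code{n_lactations}.
#' @export
aggregate_hlcc <- function(fits, weights, year_span) {
  stopifnot(all(c("lactation", "a", "b", "persistency", "complete") %in%
                  names(fits)))
  year_span <- sort(unique(as.integer(year_span)))
  keep_years <- year_span[-c(1L, length(year_span))]

  complete_fits <- fits[fits$complete, ]
  w <- merge(weights,
             complete_fits[c("lactation", "a", "b", "persistency")],
             by = "lactation")
  w <- w[w$year %in% keep_years, ]
  if (nrow(w) == 0L) {
    return(data.frame(herd = character(), year = integer(),
                      parity_group = character(), magnitude = numeric(),
                      time_to_peak = numeric(), persistency = numeric(),
                      n_lactations = integer()))
  }
  cells <- split(w, interaction(w$herd, w$year, w$parity_group, drop = TRUE))
  rows <- lapply(cells, function(cw) {
    data.frame(
      herd = cw$herd[1], year = cw$year[1], parity_group = cw$parity_group[1],
      magnitude = weighted_median(cw$a, cw$weight),
      time_to_peak = weighted_median(cw$b, cw$weight),
      persistency = weighted_median(cw$persistency, cw$weight),
      n_lactations = nrow(cw), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$herd, out$year, out$parity_group), ]
  rownames(out) <- NULL
  out
}

#' Pivot herd-year HLCC to one row per herd-year
#'
#' Spreads the two parity groups into suffixed columns
#' (\code{magnitude1}/\code{time_to_peak1}/\code{persistency1} for
#' primiparous, \code{*2} for multiparous), the layout used by the analysis
#' table.
#'
#' @param hlcc output of [aggregate_hlcc()].
#' @return data frame keyed by (\code{herd}, \code{year}) with six HLCC
#'   columns; herd-years missing either parity group get \code{NA} there.
#' @export
pivot_hlcc <- function(hlcc) {
  suffix <- ifelse(hlcc$parity_group == "primiparous", "1", "2")
  pieces <- lapply(c("1", "2"), function(s) {
    h <- hlcc[suffix == s, c("herd", "year", "magnitude", "time_to_peak",
                             "persistency")]
    names(h)[3:5] <- paste0(c("magnitude", "time_to_peak", "persistency"), s)
    h
  })
  out <- merge(pieces[[1]], pieces[[2]], by = c("herd", "year"), all = TRUE)
  out[order(out$herd, out$year), ]
}
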