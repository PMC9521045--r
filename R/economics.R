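#' Income over feed cost
#'
#' IOFC is total milk revenue minus total feed cost, the standard partial
#' profitability measure when only milk revenue and feed cost are observed.
#' Feed cost is the sum of the annual costs for concentrates, vitamins,
#' minerals, wet by-products and roughage. Two scalings are returned: per
#' cow-year and per 100 kg of milk delivered to the factory.
#'
#' @param milk_revenue total annual milk revenue, EUR.
#' @param feed_components numeric vector (or matrix with one row per record)
#'   of feed cost components, EUR.
#' @param herd_size number of cows present, > 0.
#' @param milk_delivered kg of milk delivered to the factory, > 0.
#' @return list with \code{iofc_cow} (EUR/cow), \code{iofc_milk}
#'   (EUR/100 kg) and \code{total_feed_cost} (EUR).
#' @export
compute_iofc <- function(milk_revenue, feed_components, herd_size,
                         milk_delivered) {
  if (any(herd_size <= 0)) stop("herd_size must be positive")
  if (any(milk_delivered <= 0)) stop("milk_delivered must be positive")
  feed <- if (is.matrix(feed_components)) rowSums(feed_components)
          else sum(feed_components)
  margin <- milk_revenue - feed
  list(iofc_cow = margin / herd_size,
       iofc_milk = 100 * margin / milk_delivered,
       total_feed_cost = feed)
}

#' Herd milk price and relative milk price
#'
#' The herd milk price is revenue per 100 kg delivered; the relative milk
#' price is its difference from the national raw milk price of the same
#' year, isolating the herd's price premium (e.g. milk components) from the
#' market level.
#'
#' @param milk_revenue total annual milk revenue, EUR.
#' @param milk_delivered kg delivered, > 0.
#' @param national_price national raw milk price, EUR/100 kg.
#' @return list with \code{herd_milk_price} and \code{relative_milk_price},
#'   both EUR/100 kg.
#' @export
compute_price_indicators <- function(milk_revenue, milk_delivered,
                                     national_price) {
  if (any(milk_delivered <= 0)) stop("milk_delivered must be positive")
  price <- 100 * milk_revenue / milk_delivered
  list(herd_milk_price = price,
       relative_milk_price = price - national_price)
}

#' Structural herd indicators
#'
#' Equity ratio (assets minus liabilities over assets, a leverage measure),
#' expansion rate (relative herd-size growth per year, computed against the
#' nearest available earlier year and divided by the year gap) and herd
#' intensity (kg milk per hectare).
#'
#' @param assets total assets, EUR, > 0.
#' @param liabilities total liabilities, EUR.
#' @param sizes_by_year named numeric vector mapping calendar year (as name)
#'   to herd size.
#' @param year reference (current) year; must be present in
#'   \code{sizes_by_year}.
#' @param milk kg of milk (delivered) in the reference year.
#' @param hectares farm land, ha, > 0.
#' @return list with \code{equity_ratio}, \code{expansion_rate} (NA when no
#'   earlier year exists) and \code{herd_intensity}.
#' @export
compute_structural_indicators <- function(assets, liabilities, sizes_by_year,
                                          year, milk, hectares) {
  if (any(assets <= 0)) stop("assets must be positive")
  if (any(hectares <= 0)) stop("hectares must be positive")
  yrs <- as.integer(names(sizes_by_year))
  if (!(year %in% yrs)) stop("reference year absent from sizes_by_year")
  m_size <- sizes_by_year[[as.character(year)]]
  prior <- yrs[yrs < year]
  if (length(prior) == 0L) {
    expansion <- NA_real_
  } else {
    n_year <- max(prior)
    n_size <- sizes_by_year[[as.character(n_year)]]
    expansion <- ((m_size - n_size) / n_size) / (year - n_year)
  }
  list(equity_ratio = (assets - liabilities) / assets,
       expansion_rate = expansion,
       herd_intensity = milk / hectares)
}

#' Economic indicators for a herd-year accounting table
#'
#' Table-level wrapper applying [compute_iofc()],
#' [compute_price_indicators()] and [compute_structural_indicators()] to
#' every herd-year accounting record, joined with the national milk price
#' series.
#'
#' @param accounting data frame with columns \code{herd}, \code{year},
#'   \code{milk_revenue}, the five feed component columns
#'   (\code{feed_concentrates}, \code{feed_vitamins}, \code{feed_minerals},
#'   \code{feed_wet_byproducts}, \code{feed_roughage}), \code{assets},
#'   \code{liabilities}, \code{herd_size}, \code{hectares},
#'   \code{milk_delivered}, plus any categorical herd traits (carried
#'   through).
#' @param national_price data frame with columns \code{year}, \code{price}
#'   (EUR/100 kg).
#' @return data frame keyed by (\code{herd}, \code{year}) with
#'   \code{iofc_cow}, \code{iofc_milk}, \code{total_feed_cost},
#'   \code{herd_milk_price}, \code{relative_milk_price},
#'   \code{equity_ratio}, \code{expansion_rate}, \code{herd_intensity},
#'   \code{herd_size} and the carried-through categorical columns.
#' @export
compute_economic_indicators <- function(accounting, national_price) {
  feed_cols <- c("feed_concentrates", "feed_vitamins", "feed_minerals",
                 "feed_wet_byproducts", "feed_roughage")
  stopifnot(all(feed_cols %in% names(accounting)))
  acc <- merge(accounting, national_price, by = "year")
  acc <- acc[order(acc$herd, acc$year), ]

  iofc <- compute_iofc(acc$milk_revenue,
                       as.matrix(acc[feed_cols]),
                       acc$herd_size, acc$milk_delivered)
  prices <- compute_price_indicators(acc$milk_revenue, acc$milk_delivered,
                                     acc$price)

  # expansion rate needs each herd's size history
  expansion <- rep(NA_real_, nrow(acc))
  for (h in unique(acc$herd)) {
    idx <- which(acc$herd == h)
    sizes <- stats::setNames(acc$herd_size[idx], acc$year[idx])
    yrs <- acc$year[idx]
    for (k in seq_along(idx)) {
      prior <- yrs[yrs < yrs[k]]
      if (length(prior)) {
        n_year <- max(prior)
        gap <- yrs[k] - n_year
        n_size <- sizes[[as.character(n_year)]]
        expansion[idx[k]] <- ((acc$herd_size[idx[k]] - n_size) / n_size) / gap
      }
    }
  }

  carry <- setdiff(names(accounting),
                   c("milk_revenue", feed_cols, "assets", "liabilities",
                     "hectares", "milk_delivered"))
  out <- data.frame(
    acc[carry],
    iofc_cow = iofc$iofc_cow, iofc_milk = iofc$iofc_milk,
    total_feed_cost = iofc$total_feed_cost,
    herd_milk_price = prices$herd_milk_price,
    relative_milk_price = prices$relative_milk_price,
    equity_ratio = (acc$assets - acc$liabilities) / acc$assets,
    expansion_rate = expansion,
    herd_intensity = acc$milk_delivered / acc$hectares,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
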