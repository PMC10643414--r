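#' Identify market participants from pairwise fishing-hours records
#'
#' Applies the hours-threshold rule to a table of (buyer flag, seller EEZ,
#' year, fishing hours) records: a flag state is a buyer if in at least one
#' year it fishes for more hours than the threshold in at least one coastal
#' state's waters; a coastal state is a seller if in at least one year some
#' foreign flag exceeds the threshold in its waters. The comparison is
#' strict (`hours > threshold`). The default threshold of 2,420 hours is
#' the one that keeps every coastal state with a publicly known access
#' agreement inside the African market; doubling it is the standard
#' robustness variant.
#'
#' @param hours A data.frame with columns `buyer_flag`, `seller_eez`,
#'   `year`, `hours` (all hours `>= 0`).
#' @param threshold Fishing-hours threshold, `> 0`.
#' @return A list with character vectors `sellers` and `buyers` (sorted,
#'   unique). Empty records give empty sets with a warning.
#' @export
identify_participants <- function(hours, threshold = 2420) {
  check_positive(threshold, "threshold")
  req <- c("buyer_flag", "seller_eez", "year", "hours")
  if (!all(req %in% names(hours)))
    stop("`hours` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(hours) == 0L) {
    warning("empty hours table: no participants identified")
    return(list(sellers = character(0), buyers = character(0)))
  }
  if (any(hours$hours < 0)) stop("hours must be >= 0", call. = FALSE)
  # foreign effort only: a flag fishing its own waters is not buying access
  rec <- hours[hours$buyer_flag != hours$seller_eez & hours$hours > threshold, ]
  list(
    sellers = sort(unique(rec$seller_eez)),
    buyers = sort(unique(rec$buyer_flag))
  )
}

#' Classify vessels as distant-water fishing (DWF) vessels
#'
#' A vessel is DWF if strictly more than half of its fishing hours occur
#' outside the EEZ of its flag state. An exact 50/50 split is not DWF, and
#' vessels with zero recorded hours are classified non-DWF with a warning.
#' A buying country's true fleet capacity is the summed gross tonnage of
#' its DWF vessels (see the `tonnage` attribute).
#'
#' @param vessels A data.frame with columns `vessel_id`, `flag`,
#'   `hours_inside`, `hours_outside`, `gross_tonnage`.
#' @return The input data.frame with a logical `dwf` column appended, and a
#'   named numeric attribute `"tonnage"` giving per-flag summed DWF gross
#'   tonnage.
#' @export
classify_dwf <- function(vessels) {
  req <- c("vessel_id", "flag", "hours_inside", "hours_outside",
           "gross_tonnage")
  if (!all(req %in% names(vessels)))
    stop("`vessels` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(vessels$hours_inside < 0) || any(vessels$hours_outside < 0))
    stop("hours must be >= 0", call. = FALSE)
  check_positive(vessels$gross_tonnage, "gross_tonnage")
  total <- vessels$hours_inside + vessels$hours_outside
  if (any(total == 0))
    warning("vessels with zero recorded hours classified non-DWF")
  vessels$dwf <- vessels$hours_outside > vessels$hours_inside & total > 0
  dwf <- vessels[vessels$dwf, ]
  tonnage <- c(tapply(dwf$gross_tonnage, dwf$flag, sum))
  attr(vessels, "tonnage") <- tonnage[!is.na(tonnage)]
  vessels
}

#' Capacity-weighted country growth parameter
#'
#' A country's intrinsic growth parameter is the average of its stocks'
#' growth parameters weighted by each stock's carrying capacity:
#' `sum(g*k) / sum(k)`.
#'
#' @param stock_g Per-stock growth parameters (1/year), `> 0`.
#' @param stock_k Per-stock carrying capacities (tons), `> 0`, same length.
#' @return The weighted-average growth parameter.
#' @export
weighted_growth <- function(stock_g, stock_k) {
  if (length(stock_g) == 0L || length(stock_g) != length(stock_k))
    stop("`stock_g` and `stock_k` must be non-empty and equal length",
         call. = FALSE)
  check_positive(stock_g, "stock_g")
  check_positive(stock_k, "stock_k")
  sum(stock_g * stock_k) / sum(stock_k)
}

#' Normalize endowments to shares
#'
#' Converts raw biomass (tons) or gross tonnage into shares of the
#' side total. The last share is set by complement so the shares sum to 1
#' exactly in floating point.
#'
#' @param values Non-negative endowments with positive sum.
#' @return Shares summing to exactly 1; names preserved.
#' @export
normalize_shares <- function(values) {
  if (any(!is.finite(values)) || any(values < 0))
    stop("`values` must be finite and >= 0", call. = FALSE)
  total <- sum(values)
  if (total <= 0) stop("sum of `values` must be > 0", call. = FALSE)
  shares <- values / total
  n <- length(shares)
  if (n > 1L) shares[n] <- 1 - sum(shares[-n])
  shares
}

#' Rescale one country's model share under a biomass perturbation
#'
#' When a single country's biomass is counterfactually changed, its model
#' share scales in proportion, `share * new/base`, while all other
#' countries' shares are left untouched — so the model's total true biomass
#' departs from 1 under perturbation. This is the perturbation used to
#' trace out access policy functions.
#'
#' @param base_share Status quo share of the country, `> 0`.
#' @param base_value Status quo biomass (tons), `> 0`.
#' @param new_value Perturbed biomass (tons), `> 0`. Vectorized.
#' @return The perturbed share(s).
#' @export
rescale_share <- function(base_share, base_value, new_value) {
  check_positive(base_share, "base_share")
  check_positive(base_value, "base_value")
  check_positive(new_value, "new_value")
  base_share * (new_value / base_value)
}

#' Anchors converting model units to physical units
#'
#' The market is solved in dimensionless share units; converting its
#' outputs to tons and 2020 USD requires one quantity anchor and one fee
#' anchor: an equilibrium total access quantity known in both model units
#' and tons/year, and an equilibrium access fee known in both model units
#' and USD/ton. Both conversions are linear through the origin. Profits,
#' which are fee units times quantity units, are converted by the product
#' of the two factors.
#'
#' @param qty_units Equilibrium total access quantity, model units, `> 0`.
#' @param qty_tons The same quantity in tons/year, `> 0`.
#' @param fee_units Equilibrium access fee, model units, `> 0`.
#' @param fee_usd The same fee in USD/ton, `> 0`.
#' @return An object of class `unit_scales`.
#' @examples
#' sc <- unit_scales(0.935, 283640 / 0.115, 0.961, 128.20)
#' qty_units_to_tons(0.935, sc) / 1e6  # ~2.47 million tons
#' @export
unit_scales <- function(qty_units, qty_tons, fee_units, fee_usd) {
  check_positive(qty_units, "qty_units")
  check_positive(qty_tons, "qty_tons")
  check_positive(fee_units, "fee_units")
  check_positive(fee_usd, "fee_usd")
  structure(list(qty_units = qty_units, qty_tons = qty_tons,
                 fee_units = fee_units, fee_usd = fee_usd),
            class = "unit_scales")
}

#' @export
print.unit_scales <- function(x, ...) {
  cat(sprintf(
    "<unit_scales> %.4g qty units = %.4g tons/yr; %.4g fee units = $%.2f/ton\n",
    x$qty_units, x$qty_tons, x$fee_units, x$fee_usd))
  invisible(x)
}

#' Convert between model units and physical units
#'
#' Linear-through-origin conversions defined by a [unit_scales()] anchor
#' set. `profit_units_to_usd()` applies both factors, since model profit is
#' denominated in fee units times quantity units.
#'
#' @param q_units,q_tons,p_units,p_usd,profit_units Values to convert.
#'   Vectorized.
#' @param scales A [unit_scales()] object.
#' @return The converted value(s).
#' @export
qty_units_to_tons <- function(q_units, scales) {
  stopifnot(inherits(scales, "unit_scales"))
  q_units * scales$qty_tons / scales$qty_units
}

#' @rdname qty_units_to_tons
#' @export
tons_to_qty_units <- function(q_tons, scales) {
  stopifnot(inherits(scales, "unit_scales"))
  q_tons * scales$qty_units / scales$qty_tons
}

#' @rdname qty_units_to_tons
#' @export
fee_units_to_usd <- function(p_units, scales) {
  stopifnot(inherits(scales, "unit_scales"))
  p_units * scales$fee_usd / scales$fee_units
}

#' @rdname qty_units_to_tons
#' @export
usd_to_fee_units <- function(p_usd, scales) {
  stopifnot(inherits(scales, "unit_scales"))
  p_usd * scales$fee_units / scales$fee_usd
}

#' @rdname qty_units_to_tons
#' @export
profit_units_to_usd <- function(profit_units, scales) {
  stopifnot(inherits(scales, "unit_scales"))
  profit_units * (scales$fee_usd / scales$fee_units) *
    (scales$qty_tons / scales$qty_units)
}

#' Build a model-ready market from seller and buyer tables
#'
#' Calibrates each selling country's stock from its mean annual total catch
#' (carrying capacity via [k_from_catch()], biomass via
#' [biomass_from_depletion()]), normalizes biomass and gross tonnage into
#' shares, and returns an object ready for [solve_nash()] and the scenario
#' runners.
#'
#' @param sellers data.frame with columns `id`, `catch_tons`, `growth_g`,
#'   and optionally per-country `depletion` and `phi` (falling back to the
#'   arguments below). An optional `access_tons` column records observed
#'   access catch (used by the PNA-style workflow).
#' @param buyers data.frame with columns `id`, `gross_tonnage`.
#' @inheritParams cost_fn
#' @param depletion Assumed depletion `b/bmsy` applied to every stock
#'   lacking its own `depletion` column (default 0.8, partially depleted).
#' @param phi Pella-Tomlinson shape parameter default (0.188: maximum
#'   growth at 40% of carrying capacity).
#' @return An object of class `access_market`: list with `sellers`
#'   (calibrated data.frame: `id, catch_tons, growth_g, phi, depletion, k,
#'   b, bmsy, share`), `buyers` (`id, gross_tonnage, share`), and `params`.
#' @export
build_market <- function(sellers, buyers, params = market_params(),
                         depletion = 0.8, phi = 0.188) {
  params <- as_market_params(params)
  req_s <- c("id", "catch_tons", "growth_g")
  if (!all(req_s %in% names(sellers)))
    stop("`sellers` must have columns ", paste(req_s, collapse = ", "),
         call. = FALSE)
  req_b <- c("id", "gross_tonnage")
  if (!all(req_b %in% names(buyers)))
    stop("`buyers` must have columns ", paste(req_b, collapse = ", "),
         call. = FALSE)
  bad_s <- which(!is.finite(sellers$catch_tons) | sellers$catch_tons <= 0 |
                   !is.finite(sellers$growth_g) | sellers$growth_g <= 0)
  if (length(bad_s))
    stop("non-positive catch or growth for seller row(s): ",
         paste(sellers$id[bad_s], collapse = ", "), call. = FALSE)
  bad_b <- which(!is.finite(buyers$gross_tonnage) | buyers$gross_tonnage <= 0)
  if (length(bad_b))
    stop("non-positive gross tonnage for buyer row(s): ",
         paste(buyers$id[bad_b], collapse = ", "), call. = FALSE)
  if (anyDuplicated(sellers$id) || anyDuplicated(buyers$id))
    stop("duplicate ids in seller or buyer table", call. = FALSE)

  s <- sellers
  s$phi <- if ("phi" %in% names(sellers)) sellers$phi else phi
  s$depletion <- if ("depletion" %in% names(sellers)) sellers$depletion else depletion
  s$k <- k_from_catch(s$catch_tons, s$growth_g, s$phi, s$depletion)
  s$bmsy <- bmsy_from_k(s$k, s$phi)
  s$b <- biomass_from_depletion(s$k, s$phi, s$depletion)
  s$share <- normalize_shares(s$b)

  b <- buyers
  b$share <- normalize_shares(b$gross_tonnage)

  structure(list(sellers = s, buyers = b, params = params),
            class = "access_market")
}

#' @export
print.access_market <- function(x, ...) {
  cat(sprintf(
    "<access_market> %d sellers (total biomass %.4g Mt, total catch %.4g Mt/yr), %d buyers (total GT %.4g)\n",
    nrow(x$sellers), sum(x$sellers$b) / 1e6, sum(x$sellers$catch_tons) / 1e6,
    nrow(x$buyers), sum(x$buyers$gross_tonnage)))
  invisible(x)
}
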