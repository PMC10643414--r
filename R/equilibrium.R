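#' Steady-state biomass where the total-catch policy meets the growth curve
#'
#' A country's counterfactual equilibrium biomass is the stable
#' intersection of its total catch policy function with its
#' Pella-Tomlinson growth curve: below it growth exceeds harvest (biomass
#' rises), above it harvest exceeds growth (biomass falls). The difference
#' `growth - total_policy` is scanned over the policy grid (clipped to the
#' country's carrying capacity) for sign changes from positive to
#' negative, and the unique stable crossing is refined by bisection on the
#' interpolated curves. No stable crossing, or more than one, is an error
#' (with the offending curve values reported), never a silent choice.
#'
#' @param policy A [policy_function()] with its non-access component
#'   attached.
#' @param g,k,phi Pella-Tomlinson parameters of the country's stock.
#' @param country,scenario Labels for the returned record (default from
#'   `policy`).
#' @param tol Bisection tolerance as a fraction of `k` (default 1e-6).
#' @return A one-row data.frame: `country, scenario, biomass, access_catch,
#'   nonaccess_catch, total_catch, growth_at_b` (tons and tons/year).
#' @export
find_equilibrium_biomass <- function(policy, g, k, phi = 0.188,
                                     country = policy$country,
                                     scenario = policy$scenario,
                                     tol = 1e-6) {
  stopifnot(inherits(policy, "policy_function"))
  if (is.na(policy$nonaccess_slope))
    stop("policy needs a non-access slope before equilibrium search",
         call. = FALSE)
  lo <- min(policy$biomass)
  hi <- min(max(policy$biomass), k)
  if (lo >= hi)
    stop("policy grid does not overlap the stock's biomass range (0, k]",
         call. = FALSE)

  xs <- policy$biomass[policy$biomass <= hi]
  if (length(xs) == 0L || max(xs) < hi) xs <- c(xs, hi)
  diff_fn <- function(b) pt_growth(b, g, k, phi) - eval_policy(policy, b, "total")
  d <- diff_fn(xs)

  zero_band <- 1e-9 * max(abs(pt_growth(bmsy_from_k(k, phi), g, k, phi)), 1)
  sgn <- ifelse(abs(d) <= zero_band, 0L, ifelse(d > 0, 1L, -1L))

  # stable crossings: last strictly-positive point before a
  # strictly-negative one, with only zeros in between
  crossings <- list()
  i <- 1L
  while (i < length(xs)) {
    if (sgn[i] == 1L) {
      j <- i + 1L
      while (j <= length(xs) && sgn[j] == 0L) j <- j + 1L
      if (j <= length(xs) && sgn[j] == -1L)
        crossings[[length(crossings) + 1L]] <- c(i, j)
      i <- j
    } else i <- i + 1L
  }
  # an exact zero at the first grid point followed by negatives also counts
  if (length(crossings) == 0L && sgn[1] == 0L && any(sgn == -1L)) {
    j <- which(sgn == -1L)[1]
    if (all(sgn[seq_len(j - 1L)] == 0L))
      crossings[[1L]] <- c(1L, j)
  }

  if (length(crossings) == 0L) {
    stop(sprintf(
      "no stable growth/policy crossing for %s [%s] on [%.4g, %.4g]; growth - policy spans [%.4g, %.4g]",
      country, scenario, xs[1], xs[length(xs)], min(d), max(d)),
      call. = FALSE)
  }
  if (length(crossings) > 1L) {
    locs <- vapply(crossings, function(cr) mean(xs[cr]), numeric(1))
    stop(sprintf(
      "multiple stable growth/policy crossings for %s [%s] near biomass: %s",
      country, scenario, paste(signif(locs, 6), collapse = ", ")),
      call. = FALSE)
  }

  cr <- crossings[[1L]]
  b_star <- stats::uniroot(diff_fn, c(xs[cr[1]], xs[cr[2]]),
                           tol = tol * k)$root
  acc <- eval_policy(policy, b_star, "access")
  nonacc <- eval_policy(policy, b_star, "nonaccess")
  data.frame(
    country = country, scenario = scenario, biomass = b_star,
    access_catch = acc, nonaccess_catch = nonacc,
    total_catch = acc + nonacc,
    growth_at_b = pt_growth(b_star, g, k, phi),
    stringsAsFactors = FALSE
  )
}

#' Percent change of a counterfactual relative to a reference
#'
#' `100 * (counterfactual - reference) / reference`. Not symmetric under
#' swapping the arguments.
#'
#' @param reference Reference value(s), nonzero.
#' @param counterfactual Counterfactual value(s).
#' @return Percent change(s).
#' @examples
#' percent_change(100, 116)  # 16
#' @export
percent_change <- function(reference, counterfactual) {
  if (any(reference == 0))
    stop("percent change undefined for a zero reference", call. = FALSE)
  100 * (counterfactual - reference) / reference
}

#' Scenario summary table
#'
#' Aggregates per-country equilibria and converts the market solution's fee
#' and profits into physical units, mirroring a standard
#' status-quo/counterfactual comparison table: access, non-access and total
#' catch (tons/year), biomass (tons), access fee (USD/ton), seller and
#' buyer profit (USD/year), with percent differences against an optional
#' reference scenario.
#'
#' @param equilibria data.frame of per-country equilibrium rows
#'   (from [find_equilibrium_biomass()]), one scenario only.
#' @param solution The scenario's [solve_nash()] solution (model units).
#' @param scales [unit_scales()] anchors.
#' @param reference Optional `scenario_result` to difference against.
#' @param name Scenario name (default from `equilibria`).
#' @return An object of class `scenario_result` with elements `name`,
#'   `equilibria`, `solution`, `scales`, `aggregates` (named numeric) and,
#'   when a reference is given, `comparison` (data.frame with reference,
#'   counterfactual, difference and percent difference per aggregate).
#' @export
summarize_scenario <- function(equilibria, solution, scales,
                               reference = NULL, name = NULL) {
  if (length(unique(equilibria$scenario)) != 1L)
    stop("`equilibria` mixes scenarios", call. = FALSE)
  name <- name %||% equilibria$scenario[1]
  stopifnot(inherits(solution, "nash_market"),
            inherits(scales, "unit_scales"))

  aggregates <- c(
    access_catch_tons = sum(equilibria$access_catch),
    nonaccess_catch_tons = sum(equilibria$nonaccess_catch),
    total_catch_tons = sum(equilibria$total_catch),
    biomass_tons = sum(equilibria$biomass),
    fee_usd_per_ton = fee_units_to_usd(solution$price, scales),
    seller_profit_usd = profit_units_to_usd(sum(solution$sellers$profit), scales),
    buyer_profit_usd = profit_units_to_usd(sum(solution$buyers$profit), scales)
  )

  comparison <- NULL
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "scenario_result"))
    ref <- reference$aggregates[names(aggregates)]
    comparison <- data.frame(
      quantity = names(aggregates),
      reference = unname(ref),
      counterfactual = unname(aggregates),
      difference = unname(aggregates - ref),
      pct_difference = unname(percent_change(ref, aggregates)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }

  structure(list(name = name, equilibria = equilibria, solution = solution,
                 scales = scales, aggregates = aggregates,
                 comparison = comparison),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: %d countries\n", x$name,
              nrow(x$equilibria)))
  a <- x$aggregates
  cat(sprintf("  access %.2f Mt, non-access %.2f Mt, total %.2f Mt, biomass %.2f Mt\n",
              a["access_catch_tons"] / 1e6, a["nonaccess_catch_tons"] / 1e6,
              a["total_catch_tons"] / 1e6, a["biomass_tons"] / 1e6))
  cat(sprintf("  fee $%.2f/ton, seller profit $%.2fM/yr, buyer profit $%.2fM/yr\n",
              a["fee_usd_per_ton"], a["seller_profit_usd"] / 1e6,
              a["buyer_profit_usd"] / 1e6))
  if (!is.null(x$comparison)) {
    cat("  vs reference:\n")
    cmp <- x$comparison
    for (r in seq_len(nrow(cmp)))
      cat(sprintf("    %-22s %+.4g (%+.0f%%)\n", cmp$quantity[r],
                  cmp$difference[r], cmp$pct_difference[r]))
  }
  invisible(x)
}
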