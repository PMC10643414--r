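# Build unit scales from a solved status quo market and anchor data.
# Either the total access quantity in tons is known directly, or it is
# inferred from one anchor buyer whose annual purchase in tons is known
# (total = purchase / that buyer's equilibrium purchase share).
make_scales <- function(solution, anchors) {
  if (is.null(anchors$fee_usd))
    stop("`anchors` must supply fee_usd (USD per ton)", call. = FALSE)
  qty_tons <- anchors$qty_tons
  if (is.null(qty_tons)) {
    if (is.null(anchors$buyer_id) || is.null(anchors$purchase_tons))
      stop("`anchors` must supply qty_tons, or buyer_id + purchase_tons",
           call. = FALSE)
    j <- match(anchors$buyer_id, solution$buyers$id)
    if (is.na(j)) stop("anchor buyer not in market: ", anchors$buyer_id,
                       call. = FALSE)
    purchase_share <- solution$buyers$q[j] / solution$quantity
    qty_tons <- anchors$purchase_tons / purchase_share
  }
  unit_scales(qty_units = solution$quantity, qty_tons = qty_tons,
              fee_units = solution$price, fee_usd = anchors$fee_usd)
}

attach_slopes <- function(policies, slopes) {
  for (id in names(policies)) policies[[id]]$nonaccess_slope <- slopes[[id]]
  policies
}

solve_country_equilibria <- function(policies, sellers, scenario) {
  rows <- lapply(seq_len(nrow(sellers)), function(i) {
    find_equilibrium_biomass(policies[[sellers$id[i]]],
                             g = sellers$growth_g[i], k = sellers$k[i],
                             phi = sellers$phi[i],
                             country = sellers$id[i], scenario = scenario)
  })
  do.call(rbind, rows)
}

#' Status quo scenario: every country sells access individually
#'
#' Solves the Nash equilibrium with all selling countries reporting
#' individually, anchors the unit conversion on the solved market, derives
#' each country's access policy function by grid perturbation, fits linear
#' non-access policies so that access plus non-access catch reproduces the
#' observed total catch at the calibrated biomass, and finds each
#' country's steady-state biomass. By construction the status quo
#' equilibrium biomass recovers the calibrated biomass (up to grid and
#' solver tolerance), which serves as the pipeline's self-consistency
#' check.
#'
#' @param market An [build_market()] object.
#' @param anchors List with `fee_usd` (observed average access fee, USD/ton)
#'   and either `qty_tons` (observed total access catch, tons/year) or
#'   `buyer_id` plus `purchase_tons` (one anchor buyer's known annual
#'   purchase, from which the total is inferred via its equilibrium
#'   purchase share).
#' @param grid_pct Policy-grid step, % of carrying capacity.
#' @param q_star_tons Optional per-country equilibrium access catch
#'   (tons/year) used for the non-access slopes in place of the solved
#'   market's own allocation (the coalition-as-status-quo workflow uses
#'   this).
#' @return A `scenario_result` with extra elements `market`, `policies`,
#'   `q_star_tons` and `nonaccess_slopes`.
#' @export
run_status_quo <- function(market, anchors, grid_pct = 1,
                           q_star_tons = NULL) {
  stopifnot(inherits(market, "access_market"))
  s <- market$sellers
  sol <- solve_nash(stats::setNames(s$share, s$id),
                    stats::setNames(market$buyers$share, market$buyers$id),
                    market$params)
  scales <- make_scales(sol, anchors)

  q_star <- q_star_tons %||%
    stats::setNames(qty_units_to_tons(sol$sellers$q, scales), s$id)
  slopes <- stats::setNames(
    fit_nonaccess_policy(s$catch_tons, unname(q_star[s$id]), s$b), s$id)
  if (any(slopes < 0)) {
    warning("negative non-access slope(s) repaired for: ",
            paste(names(slopes)[slopes < 0], collapse = ", "))
    slopes <- repair_negative_slope(slopes)
  }

  policies <- lapply(s$id, function(id)
    derive_access_policy(market, id, sol, scales, grid_pct))
  names(policies) <- s$id
  policies <- attach_slopes(policies, slopes)

  eq <- solve_country_equilibria(policies, s, "status_quo")
  # price the summary at the emergent (recovered) shares so that every
  # scenario, this one included, is summarized by the same rule
  emergent <- stats::setNames(eq$biomass[match(s$id, eq$country)] / sum(s$b),
                              s$id)
  sol_final <- solve_nash(emergent,
                          stats::setNames(market$buyers$share,
                                          market$buyers$id),
                          market$params)
  out <- summarize_scenario(eq, sol_final, scales, name = "status_quo")
  out$market <- market
  out$policies <- policies
  out$q_star_tons <- q_star
  out$nonaccess_slopes <- slopes
  out
}

#' Continental coalition scenario: all sellers merge into one
#'
#' All selling countries report as a single seller. Coalition access
#' policy functions are derived on the merged biomass grid and apportioned
#' to countries by their status quo true biomass shares; non-access
#' policies are held fixed at their status quo lines. Each country's new
#' steady-state biomass is the intersection of its (rotated) total-catch
#' policy with its unchanged growth curve. The coalition's true biomass
#' share — total coalition equilibrium biomass over total status quo
#' biomass — is an output of this procedure, and the final market solve at
#' that emergent share prices the coalition equilibrium.
#'
#' @param market An [build_market()] object.
#' @param status_quo The [run_status_quo()] result for the same market
#'   (supplies anchors, apportionment shares and non-access slopes).
#' @param grid_pct Policy-grid step, % of summed carrying capacity.
#' @return A `scenario_result` (reference = status quo) with extra elements
#'   `coalition_true_share` and `coalition_policy`.
#' @export
run_continental <- function(market, status_quo, grid_pct = 1) {
  stopifnot(inherits(market, "access_market"),
            inherits(status_quo, "scenario_result"))
  s <- market$sellers
  scales <- status_quo$scales

  policies <- derive_coalition_access_policy(market, status_quo$solution,
                                             scales, grid_pct = grid_pct)
  coalition_pf <- attr(policies, "coalition")
  policies <- attach_slopes(policies, status_quo$nonaccess_slopes)

  eq <- solve_country_equilibria(policies, s, "coalition")
  coalition_share <- sum(eq$biomass) / sum(s$b)

  sol <- solve_nash(c(coalition = coalition_share),
                    stats::setNames(market$buyers$share, market$buyers$id),
                    market$params)

  out <- summarize_scenario(eq, sol, scales, reference = status_quo,
                            name = "coalition")
  out$market <- market
  out$policies <- policies
  out$coalition_policy <- coalition_pf
  out$coalition_true_share <- coalition_share
  out
}

#' Assign each selling country to a single regional coalition
#'
#' Regional Economic Communities overlap, so countries are mapped to
#' exactly one region by iterating over the communities in ascending order
#' of selling-country membership (ties broken alphabetically and flagged):
#' all not-yet-assigned members of the smallest community are assigned to
#' it, then the next smallest, and so on. Explicit overrides reassign
#' individual countries afterwards, excluded communities are dropped
#' before iterating, and any country in no community becomes its own
#' singleton region (it sells access individually).
#'
#' @param membership Named list: region label -> character vector of member
#'   selling countries.
#' @param exclude Region labels to drop before assignment.
#' @param reassign Named character vector country -> region applied after
#'   the iterative rule.
#' @param countries Optional character vector of all selling countries;
#'   any not covered by `membership` get singleton regions.
#' @return Named character vector country -> region, with attribute
#'   `"ties"` (TRUE if any ascending-size tie was broken alphabetically).
#' @export
assign_regions <- function(membership, exclude = character(),
                           reassign = character(), countries = NULL) {
  membership <- membership[setdiff(names(membership), exclude)]
  sizes <- vapply(membership, length, integer(1))
  ord <- order(sizes, names(membership))
  ties <- anyDuplicated(sizes) > 0L

  assigned <- character(0)
  for (region in names(membership)[ord]) {
    new <- setdiff(membership[[region]], names(assigned))
    assigned <- c(assigned, stats::setNames(rep(region, length(new)), new))
  }
  if (length(reassign)) {
    if (!all(names(reassign) %in% names(assigned)))
      stop("reassign refers to unknown countries: ",
           paste(setdiff(names(reassign), names(assigned)), collapse = ", "),
           call. = FALSE)
    assigned[names(reassign)] <- reassign
  }
  if (!is.null(countries)) {
    solo <- setdiff(countries, names(assigned))
    assigned <- c(assigned, stats::setNames(solo, solo))
  }
  attr(assigned, "ties") <- ties
  assigned
}

#' Regional coalition scenario
#'
#' Identical to the continental scenario except one seller reports per
#' region. Policy functions are derived per region and apportioned within
#' the region by each country's share of regional status quo biomass;
#' non-access policies stay at their status quo lines. The final market
#' solve uses each region's emergent share (regional equilibrium biomass
#' over total status quo biomass). With all-singleton regions the scenario
#' reproduces the status quo; with a single region it reproduces the
#' continental coalition.
#'
#' @inheritParams run_continental
#' @param region_map Named character vector country -> region
#'   (see [assign_regions()]).
#' @return A `scenario_result` (reference = status quo) with extra element
#'   `region_shares` (emergent per-region true shares).
#' @export
run_regional <- function(market, region_map, status_quo, grid_pct = 1) {
  stopifnot(inherits(market, "access_market"),
            inherits(status_quo, "scenario_result"))
  s <- market$sellers
  scales <- status_quo$scales

  policies <- derive_regional_access_policy(market, region_map,
                                            status_quo$solution, scales,
                                            grid_pct = grid_pct)
  policies <- attach_slopes(policies, status_quo$nonaccess_slopes)

  eq <- solve_country_equilibria(policies, s, "regional")

  region_of <- region_map[s$id]
  eq_by_region <- tapply(eq$biomass[match(s$id, eq$country)], region_of, sum)
  region_shares <- eq_by_region / sum(s$b)
  sol <- solve_nash(stats::setNames(as.numeric(region_shares),
                                    names(region_shares)),
                    stats::setNames(market$buyers$share, market$buyers$id),
                    market$params)

  out <- summarize_scenario(eq, sol, scales, reference = status_quo,
                            name = "regional")
  out$market <- market
  out$policies <- policies
  out$region_shares <- region_shares
  out
}

#' PNA-style market: coalition as status quo, dissolution as counterfactual
#'
#' For a market that already operates as a cartel (the Parties to the
#' Nauru Agreement), the observed state is the coalition and the
#' counterfactual is its members selling access individually. The unit
#' anchors come from the coalition: the observed access fee and the
#' observed access catch (a configurable fraction of foreign catch, since
#' access-specific catch data do not exist). The coalition's equilibrium
#' access quantity is apportioned to members by true biomass share to fit
#' non-access slopes; a member whose apportioned access exceeds its
#' observed total catch gets a negative slope, which is repaired with the
#' mean slope of the other members.
#'
#' @param sellers Seller table as in [build_market()], with an additional
#'   `foreign_catch_tons` column (observed foreign catch in each member's
#'   waters).
#' @param buyers Buyer table as in [build_market()].
#' @inheritParams build_market
#' @param access_fraction Fraction of foreign catch treated as access
#'   catch, in (0, 1] (default 1).
#' @param fee_usd Observed coalition access fee (USD/ton; 307 for the PNA).
#' @param grid_pct Policy-grid step.
#' @return List with `coalition` and `individual` `scenario_result`s; the
#'   `individual` element carries the comparison against the coalition.
#' @export
run_pna <- function(sellers, buyers, params = market_params(),
                    access_fraction = 1, depletion = 0.8, fee_usd = 307,
                    grid_pct = 1) {
  if (!"foreign_catch_tons" %in% names(sellers))
    stop("`sellers` needs a foreign_catch_tons column", call. = FALSE)
  if (access_fraction <= 0 || access_fraction > 1)
    stop("`access_fraction` must be in (0, 1]", call. = FALSE)
  market <- build_market(sellers, buyers, params, depletion = depletion)
  s <- market$sellers

  # coalition is the observed state: single seller, anchored on observed
  # fee and access catch
  sol_c <- solve_nash(c(coalition = 1),
                      stats::setNames(market$buyers$share, market$buyers$id),
                      params)
  access_tons_total <- access_fraction * sum(s$foreign_catch_tons)
  scales <- unit_scales(sol_c$quantity, access_tons_total, sol_c$price,
                        fee_usd)

  w <- s$b / sum(s$b)
  q_star <- stats::setNames(w * access_tons_total, s$id)
  slopes <- stats::setNames(
    fit_nonaccess_policy(s$catch_tons, unname(q_star), s$b), s$id)
  repaired <- names(slopes)[slopes < 0]
  if (length(repaired)) slopes <- repair_negative_slope(slopes)

  pol_c <- derive_coalition_access_policy(market, sol_c, scales,
                                          grid_pct = grid_pct)
  pol_c <- attach_slopes(pol_c, slopes)
  eq_c <- solve_country_equilibria(pol_c, s, "coalition")
  share_c <- sum(eq_c$biomass) / sum(s$b)
  sol_c_final <- solve_nash(c(coalition = share_c),
                            stats::setNames(market$buyers$share,
                                            market$buyers$id), params)
  res_c <- summarize_scenario(eq_c, sol_c_final, scales, name = "coalition")
  res_c$market <- market
  res_c$policies <- pol_c
  res_c$nonaccess_slopes <- slopes
  res_c$repaired <- repaired
  res_c$coalition_true_share <- share_c

  # counterfactual: members sell individually
  sol_i <- solve_nash(stats::setNames(s$share, s$id),
                      stats::setNames(market$buyers$share, market$buyers$id),
                      params)
  pol_i <- lapply(s$id, function(id)
    derive_access_policy(market, id, sol_i, scales, grid_pct))
  names(pol_i) <- s$id
  pol_i <- attach_slopes(pol_i, slopes)
  eq_i <- solve_country_equilibria(pol_i, s, "individual")
  res_i <- summarize_scenario(eq_i, sol_i, scales, reference = res_c,
                              name = "individual")
  res_i$market <- market
  res_i$policies <- pol_i

  list(coalition = res_c, individual = res_i)
}

#' Robustness sweep over elasticities and depletion
#'
#' Re-runs the status quo and continental coalition scenarios for every
#' combination of the supplied elasticity and depletion values and
#' tabulates the coalition-vs-status-quo aggregate changes. Invalid
#' combinations (eta <= 0 or epsilon <= 1) are skipped with a warning.
#' Sweeping the participant-identification threshold happens upstream, by
#' rebuilding the tables with [identify_participants()] at a different
#' threshold.
#'
#' @param sellers,buyers Tables as in [build_market()].
#' @param anchors As in [run_status_quo()].
#' @param eta,epsilon,depletion Numeric vectors of values to cross.
#' @param grid_pct Policy-grid step.
#' @return data.frame with one row per grid point: the parameters, status
#'   quo and coalition aggregates, and percent differences.
#' @export
sweep_scenarios <- function(sellers, buyers, anchors,
                            eta = 1, epsilon = 2, depletion = 0.8,
                            grid_pct = 1) {
  grid <- expand.grid(eta = eta, epsilon = epsilon, depletion = depletion,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    p <- grid[r, ]
    if (p$eta <= 0 || p$epsilon <= 1) {
      warning(sprintf("skipping invalid grid point eta=%g, epsilon=%g",
                      p$eta, p$epsilon))
      next
    }
    market <- build_market(sellers, buyers, market_params(p$eta, p$epsilon),
                           depletion = p$depletion)
    sq <- run_status_quo(market, anchors, grid_pct = grid_pct)
    co <- run_continental(market, sq, grid_pct = grid_pct)
    cmp <- co$comparison
    rows[[r]] <- data.frame(
      eta = p$eta, epsilon = p$epsilon, depletion = p$depletion,
      B_hat_sq = sq$solution$B_hat, B_hat_co = co$solution$B_hat,
      fee_sq = sq$aggregates[["fee_usd_per_ton"]],
      fee_co = co$aggregates[["fee_usd_per_ton"]],
      access_sq = sq$aggregates[["access_catch_tons"]],
      access_co = co$aggregates[["access_catch_tons"]],
      seller_profit_sq = sq$aggregates[["seller_profit_usd"]],
      seller_profit_co = co$aggregates[["seller_profit_usd"]],
      biomass_sq = sq$aggregates[["biomass_tons"]],
      biomass_co = co$aggregates[["biomass_tons"]],
      pct_fee = cmp$pct_difference[cmp$quantity == "fee_usd_per_ton"],
      pct_access = cmp$pct_difference[cmp$quantity == "access_catch_tons"],
      pct_seller_profit = cmp$pct_difference[cmp$quantity == "seller_profit_usd"],
      pct_biomass = cmp$pct_difference[cmp$quantity == "biomass_tons"]
    )
  }
  do.call(rbind, rows)
}
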