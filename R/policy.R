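# Vectorized safeguarded-Newton solver for one side's best-response roots.
# Each agent's first-order condition has a single sign change on
# (~0, true value]; Newton iterates are kept inside a shrinking bisection
# bracket so convergence is guaranteed. Used inside the fixed-point sweeps
# where scalar uniroot calls would dominate run time; agrees with
# seller_best_response()/buyer_best_response() to solver tolerance.
vec_best_response <- function(true_vals, others, params, side = c("seller", "buyer"),
                              tol = 1e-13, max_newton = 80L) {
  side <- match.arg(side)
  eta <- params$eta
  eps <- params$epsilon
  n <- length(true_vals)

  out <- if (side == "seller") {
    true_vals * ((eps - 1) / eps)^eta
  } else {
    true_vals * (eta / (eta + 1))^eps
  }
  solve_idx <- which(others > 0)
  if (length(solve_idx) == 0L) return(out)

  lo <- 1e-12 * true_vals[solve_idx]
  hi <- true_vals[solve_idx]
  x <- 0.5 * (lo + hi)
  tv <- true_vals[solve_idx]
  ot <- others[solve_idx]
  sub_f <- if (side == "seller") {
    function(x) seller_br_residual(x, tv, ot, eta, eps)
  } else {
    function(x) buyer_br_residual(x, tv, ot, eta, eps)
  }
  sub_fp <- if (side == "seller") {
    function(x) eps * (eta + 1) / eta * x^(1 / eta) + tv^(1 / eta) * (1 - eps) +
      ot * (eps + eta) / eta * x^(1 / eta - 1)
  } else {
    function(x) (eta + 1) * (eps + 1) / eps * x^(1 / eps) - eta * tv^(1 / eps) +
      ot * (eps + eta) / eps * x^(1 / eps - 1)
  }

  for (it in seq_len(max_newton)) {
    fx <- sub_f(x)
    # tighten brackets: residual is < 0 below the root, > 0 above
    below <- fx < 0
    lo[below] <- x[below]
    hi[!below] <- x[!below]
    step <- fx / sub_fp(x)
    x_new <- x - step
    bad <- !is.finite(x_new) | x_new <= lo | x_new >= hi
    x_new[bad] <- 0.5 * (lo[bad] + hi[bad])
    if (max(abs(x_new - x) / tv) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  out[solve_idx] <- x
  out
}

# Solve one side's Nash reports with the vectorized solver; optional warm
# start. Same fixed point as solve_side() in oligopoly.R, much faster for
# repeated calls on policy grids.
solve_side_fast <- function(true_vals, params, side, tol = 1e-10,
                            max_iter = 10000, init = NULL) {
  reports <- init %||% true_vals
  for (iter in seq_len(max_iter)) {
    others <- sum(reports) - reports
    new_reports <- vec_best_response(true_vals, others, params, side)
    delta <- max(abs(new_reports - reports) /
                   pmax(abs(reports), .Machine$double.eps))
    reports <- new_reports
    if (delta < tol)
      return(list(reports = reports, iterations = iter, converged = TRUE))
  }
  stop(sprintf("%s-side fixed point did not converge in %d iterations",
               side, max_iter), call. = FALSE)
}

#' Tabulated harvest policy function for one country
#'
#' A policy function maps a country's biomass to the catch it allows at
#' that biomass: `access` (foreign catch under access agreements, traced
#' out numerically by perturbing biomass and re-solving the market),
#' `nonaccess` (domestic plus unauthorized catch, a line through the
#' origin), and their sum `total`. Access values are defined on the grid
#' and evaluated between grid points by linear interpolation; evaluation
#' outside the grid is an error. The non-access line is evaluable
#' everywhere.
#'
#' @param country Country label.
#' @param scenario Scenario label.
#' @param biomass Ascending biomass grid (tons).
#' @param access Access catch at each grid point (tons/year), `>= 0`.
#' @param nonaccess_slope Slope of the non-access line (catch per ton of
#'   biomass, `>= 0`), or `NA` if not yet attached.
#' @return An object of class `policy_function`.
#' @seealso [eval_policy()], [fit_nonaccess_policy()]
#' @export
policy_function <- function(country, scenario, biomass, access,
                            nonaccess_slope = NA_real_) {
  if (is.unsorted(biomass, strictly = TRUE))
    stop("`biomass` grid must be strictly ascending", call. = FALSE)
  if (length(access) != length(biomass))
    stop("`access` must match the grid length", call. = FALSE)
  if (any(access < -1e-12))
    stop("access catch must be >= 0", call. = FALSE)
  if (!is.na(nonaccess_slope) && nonaccess_slope < 0)
    stop("non-access slope must be >= 0 (see repair_negative_slope)",
         call. = FALSE)
  structure(list(country = country, scenario = scenario,
                 biomass = biomass, access = pmax(access, 0),
                 nonaccess_slope = nonaccess_slope),
            class = "policy_function")
}

#' @export
print.policy_function <- function(x, ...) {
  cat(sprintf(
    "<policy_function> %s [%s]: %d grid points on [%.4g, %.4g] tons; non-access slope %s\n",
    x$country, x$scenario, length(x$biomass), min(x$biomass), max(x$biomass),
    if (is.na(x$nonaccess_slope)) "unset" else sprintf("%.4g", x$nonaccess_slope)))
  invisible(x)
}

#' @export
as.data.frame.policy_function <- function(x, ...) {
  nonacc <- if (is.na(x$nonaccess_slope)) NA_real_ else
    x$nonaccess_slope * x$biomass
  data.frame(country = x$country, scenario = x$scenario,
             biomass_tons = x$biomass, access_tons = x$access,
             nonaccess_tons = nonacc, total_tons = x$access + nonacc,
             stringsAsFactors = FALSE)
}

#' Evaluate a policy function at arbitrary biomass
#'
#' @param policy A [policy_function()].
#' @param b Biomass values (tons). For `what = "access"` or `"total"`, must
#'   lie within the tabulated grid (no extrapolation).
#' @param what One of `"access"`, `"nonaccess"`, `"total"`.
#' @return Catch (tons/year) at each `b`.
#' @export
eval_policy <- function(policy, b, what = c("total", "access", "nonaccess")) {
  what <- match.arg(what)
  stopifnot(inherits(policy, "policy_function"))
  if (what == "nonaccess") {
    if (is.na(policy$nonaccess_slope))
      stop("policy has no non-access component", call. = FALSE)
    return(policy$nonaccess_slope * b)
  }
  rng <- range(policy$biomass)
  if (any(b < rng[1] - 1e-9 * rng[2]) || any(b > rng[2] * (1 + 1e-12)))
    stop(sprintf(
      "biomass outside the tabulated grid [%.6g, %.6g]; extrapolation is not allowed",
      rng[1], rng[2]), call. = FALSE)
  acc <- stats::approx(policy$biomass, policy$access, xout = b,
                       rule = 1, ties = "ordered")$y
  # tolerate the hairline-outside points admitted above
  edge <- is.na(acc)
  if (any(edge))
    acc[edge] <- policy$access[ifelse(b[edge] <= rng[1], 1L,
                                      length(policy$access))]
  if (what == "access") return(acc)
  if (is.na(policy$nonaccess_slope))
    stop("policy has no non-access component; cannot evaluate total",
         call. = FALSE)
  acc + policy$nonaccess_slope * b
}

#' Linear non-access policy from observed catch
#'
#' Non-access catch (domestic plus unauthorized foreign catch) is modelled
#' as linear in biomass through the origin, with slope
#' `(h - q_star) / b_true`: at the status quo biomass the access and
#' non-access components sum exactly to the observed total catch `h`. A
#' negative slope (equilibrium access catch exceeding observed total catch)
#' is returned as-is; callers repair it across countries with
#' [repair_negative_slope()].
#'
#' @param h Observed mean annual total catch (tons/year).
#' @param q_star Equilibrium access catch in the reference scenario
#'   (tons/year).
#' @param b_true Status quo biomass (tons), `> 0`.
#' @return The slope (possibly negative) of the non-access line.
#' @export
fit_nonaccess_policy <- function(h, q_star, b_true) {
  check_positive(b_true, "b_true")
  if (any(h < 0) || any(q_star < 0))
    stop("`h` and `q_star` must be >= 0", call. = FALSE)
  (h - q_star) / b_true
}

#' Replace negative non-access slopes by the mean of the others
#'
#' A country whose equilibrium access catch exceeds its observed total
#' catch would get a negative (impossible) non-access policy; its slope is
#' replaced by the arithmetic mean of the remaining countries' non-negative
#' slopes. Non-negative slopes are untouched.
#'
#' @param slopes Named or unnamed numeric vector of non-access slopes.
#' @return The repaired vector.
#' @export
repair_negative_slope <- function(slopes) {
  neg <- slopes < 0
  if (!any(neg)) return(slopes)
  if (all(neg))
    stop("all non-access slopes are negative; market cannot be repaired",
         call. = FALSE)
  slopes[neg] <- mean(slopes[!neg])
  slopes
}

# Shared machinery: re-solve the seller side over a biomass grid for one
# perturbed selling entity and return total access quantity in tons.
# `entity_shares` is the model-unit share vector of all selling entities,
# `entity_idx` the one being perturbed, `base_tons` its status quo biomass
# in tons. The buyer side is report-invariant to seller perturbations, so
# T_hat is fixed at the base solution's value.
perturb_entity_grid <- function(entity_shares, entity_idx, base_tons,
                                grid_tons, T_hat, params, scales,
                                tol = 1e-10) {
  q_tons <- numeric(length(grid_tons))
  entity_access_tons <- numeric(length(grid_tons))
  init <- NULL
  for (gi in seq_along(grid_tons)) {
    shares <- entity_shares
    shares[entity_idx] <- rescale_share(entity_shares[entity_idx],
                                        base_tons, grid_tons[gi])
    if (length(shares) == 1L) {
      reports <- vec_best_response(shares, 0, params, "seller")
    } else {
      sol <- solve_side_fast(shares, params, "seller", tol = tol, init = init)
      reports <- sol$reports
      init <- reports
    }
    B_hat <- sum(reports)
    Q <- clearing_quantity(B_hat, T_hat, params)
    q_tons[gi] <- qty_units_to_tons(Q, scales)
    entity_access_tons[gi] <- reports[entity_idx] / B_hat * q_tons[gi]
  }
  list(total_tons = q_tons, entity_tons = entity_access_tons)
}

#' Status quo access policy function of one country
#'
#' Replaces the country's biomass with each value of a grid running from 1%
#' to 100% of its carrying capacity in steps of `grid_pct`% (its model
#' share rescaled in proportion, all other countries untouched), re-solves
#' the Nash equilibrium at each point, converts the equilibrium total
#' access quantity to tons, and assigns the country its reported share of
#' the total. Buyer reports are invariant to seller-side perturbations and
#' are held at the base solution's values.
#'
#' @param market An [build_market()] object.
#' @param country Seller id to perturb.
#' @param solution The base [solve_nash()] solution for `market`.
#' @param scales [unit_scales()] anchors.
#' @param grid_pct Grid step as a percentage of carrying capacity
#'   (default 1).
#' @return A [policy_function()] (access component only) on the country's
#'   biomass grid.
#' @export
derive_access_policy <- function(market, country, solution, scales,
                                 grid_pct = 1) {
  stopifnot(inherits(market, "access_market"),
            inherits(solution, "nash_market"))
  i <- match(country, market$sellers$id)
  if (is.na(i)) stop("unknown seller: ", country, call. = FALSE)
  k_i <- market$sellers$k[i]
  grid <- seq(grid_pct, 100, by = grid_pct) / 100 * k_i
  res <- perturb_entity_grid(
    entity_shares = market$sellers$share, entity_idx = i,
    base_tons = market$sellers$b[i], grid_tons = grid,
    T_hat = solution$T_hat, params = market$params, scales = scales
  )
  policy_function(country, "status_quo", grid, res$entity_tons)
}

#' Coalition access policy functions (all sellers merged)
#'
#' Merges every selling country into a single seller whose biomass runs
#' from 1% to 100% of the summed carrying capacity, re-solves the
#' (monopoly-supply) equilibrium at each grid point, and apportions the
#' total access quantity to countries in proportion to their status quo
#' true biomass shares. Country policies are expressed on each country's
#' own biomass axis (its apportioned slice of the coalition grid).
#'
#' @inheritParams derive_access_policy
#' @param apportion_shares Optional apportionment weights (defaults to the
#'   countries' shares of summed status quo biomass).
#' @return Named list of [policy_function()] objects, one per country, plus
#'   an attribute `"coalition"` holding the aggregate policy.
#' @export
derive_coalition_access_policy <- function(market, solution, scales,
                                           apportion_shares = NULL,
                                           grid_pct = 1) {
  stopifnot(inherits(market, "access_market"),
            inherits(solution, "nash_market"))
  s <- market$sellers
  b_total <- sum(s$b)
  K_total <- sum(s$k)
  weights <- apportion_shares %||% (s$b / b_total)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("apportion_shares must sum to 1", call. = FALSE)
  grid <- seq(grid_pct, 100, by = grid_pct) / 100 * K_total
  res <- perturb_entity_grid(
    entity_shares = sum(s$share), entity_idx = 1L, base_tons = b_total,
    grid_tons = grid, T_hat = solution$T_hat, params = market$params,
    scales = scales
  )
  out <- lapply(seq_len(nrow(s)), function(i) {
    policy_function(s$id[i], "coalition",
                    biomass = weights[i] * grid,
                    access = weights[i] * res$total_tons)
  })
  names(out) <- s$id
  attr(out, "coalition") <- policy_function("coalition", "coalition",
                                            grid, res$total_tons)
  out
}

#' Regional coalition access policy functions
#'
#' One seller per region reports to the market. Each region's biomass is
#' perturbed over a grid from 1% to 100% of the regional carrying capacity
#' (other regions held at their status quo values), the equilibrium
#' re-solved, and the region's access quantity apportioned to its member
#' countries in proportion to their share of regional status quo biomass.
#' A map assigning every seller to exactly one region is required. With
#' every region a singleton this reproduces the status quo policies; with
#' one region containing all sellers it reproduces the continental
#' coalition policies.
#'
#' @inheritParams derive_access_policy
#' @param region_map Named character vector mapping seller id to region
#'   label.
#' @return Named list of per-country [policy_function()] objects with a
#'   `"regions"` attribute holding the per-region aggregate policies.
#' @export
derive_regional_access_policy <- function(market, region_map, solution,
                                          scales, grid_pct = 1) {
  stopifnot(inherits(market, "access_market"),
            inherits(solution, "nash_market"))
  s <- market$sellers
  unmapped <- setdiff(s$id, names(region_map))
  if (length(unmapped))
    stop("sellers not assigned to a region: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  region_of <- region_map[s$id]
  regions <- unique(unname(region_of))

  reg_share <- tapply(s$share, region_of, sum)[regions]
  reg_b <- tapply(s$b, region_of, sum)[regions]
  reg_k <- tapply(s$k, region_of, sum)[regions]

  country_pf <- vector("list", nrow(s))
  names(country_pf) <- s$id
  region_pf <- vector("list", length(regions))
  names(region_pf) <- regions

  for (r in seq_along(regions)) {
    grid <- seq(grid_pct, 100, by = grid_pct) / 100 * reg_k[r]
    res <- perturb_entity_grid(
      entity_shares = unname(reg_share), entity_idx = r,
      base_tons = unname(reg_b[r]), grid_tons = grid,
      T_hat = solution$T_hat, params = market$params, scales = scales
    )
    region_pf[[r]] <- policy_function(regions[r], "regional", grid,
                                      res$entity_tons)
    members <- which(region_of == regions[r])
    for (i in members) {
      w <- s$b[i] / reg_b[r]
      country_pf[[i]] <- policy_function(
        s$id[i], "regional", biomass = w * grid,
        access = w * res$entity_tons)
    }
  }
  attr(country_pf, "regions") <- region_pf
  country_pf
}
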