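#' Seller opportunity cost per unit biomass
#'
#' Constant-elasticity opportunity (shadow) cost of supplying fishing access:
#' `c(z) = eta/(eta+1) * z^((eta+1)/eta)`, where `z = q/b` is access quantity
#' supplied per unit of true biomass. The function is convex and strictly
#' increasing, so the marginal shadow cost `z^(1/eta)` rises with supply
#' intensity: the more of its stock a country sells off, the more future
#' growth it foregoes per additional ton.
#'
#' @param z Supply intensity (access quantity / true biomass), `z >= 0`.
#'   Vectorized.
#' @param params A [market_params()] object.
#' @return Opportunity cost per unit biomass (model units).
#' @examples
#' cost_fn(1, market_params(eta = 1))  # 0.5
#' @export
cost_fn <- function(z, params = market_params()) {
  params <- as_market_params(params)
  if (any(!is.finite(z)) || any(z < 0))
    stop("`z` must be finite and >= 0", call. = FALSE)
  eta <- params$eta
  eta / (eta + 1) * z^((eta + 1) / eta)
}

#' Buyer fishing profit per unit fleet tonnage
#'
#' Constant-elasticity fishing profit (dockside revenue net of fuel, labour
#' and capital cost, gross of permit fees):
#' `v(z) = epsilon/(epsilon-1) * z^((epsilon-1)/epsilon)` with `z = q/t`, the
#' catch per unit of distant-water gross tonnage. Concave and strictly
#' increasing: additional permits are worth progressively less to a fleet of
#' fixed capacity.
#'
#' @param z Catch intensity (permits purchased / true tonnage), `z >= 0`.
#'   Vectorized.
#' @inheritParams cost_fn
#' @return Fishing profit per unit tonnage (model units).
#' @examples
#' value_fn(9, market_params(epsilon = 2))  # 6
#' @export
value_fn <- function(z, params = market_params()) {
  params <- as_market_params(params)
  if (any(!is.finite(z)) || any(z < 0))
    stop("`z` must be finite and >= 0", call. = FALSE)
  eps <- params$epsilon
  eps / (eps - 1) * z^((eps - 1) / eps)
}

#' Market-clearing access fee and quantity
#'
#' Given total reported biomass `B_hat` and total reported tonnage `T_hat`,
#' the clearing mechanism equates marginal opportunity cost and marginal
#' fishing profit, which with constant elasticities has the closed form
#' fee `p = B_hat^(-1/(eps+eta)) * T_hat^(1/(eps+eta))` and total quantity
#' `Q = B_hat^(eps/(eps+eta)) * T_hat^(eta/(eps+eta))`. The fee falls with
#' reported supply and rises with reported demand; the quantity rises with
#' both. Conditional on reports the mechanism is surplus-maximizing, which
#' is exactly why strategic under-reporting moves the outcome away from the
#' full-information optimum.
#'
#' @param B_hat Total reported biomass (model/share units), `> 0`. Vectorized.
#' @param T_hat Total reported gross tonnage (model/share units), `> 0`.
#' @inheritParams cost_fn
#' @return The clearing access fee (resp. total access quantity) in model
#'   units.
#' @examples
#' clearing_price(1, 1)     # 1: symmetric anchor
#' clearing_quantity(1, 1)  # 1
#' @export
clearing_price <- function(B_hat, T_hat, params = market_params()) {
  params <- as_market_params(params)
  check_positive(B_hat, "B_hat")
  check_positive(T_hat, "T_hat")
  ee <- params$epsilon + params$eta
  B_hat^(-1 / ee) * T_hat^(1 / ee)
}

#' @rdname clearing_price
#' @export
clearing_quantity <- function(B_hat, T_hat, params = market_params()) {
  params <- as_market_params(params)
  check_positive(B_hat, "B_hat")
  check_positive(T_hat, "T_hat")
  ee <- params$epsilon + params$eta
  B_hat^(params$epsilon / ee) * T_hat^(params$eta / ee)
}

#' Seller and buyer profit at a cleared market
#'
#' Seller profit is permit revenue minus the opportunity cost of foregone
#' stock growth, `p*q - b * c(q/b)`; buyer profit is fishing profit minus
#' permit cost, `t * v(q/t) - p*q`. Both are in model units
#' (fee units x quantity units); see [profit_units_to_usd()] for conversion.
#'
#' @param b_true,t_true True endowment (biomass or gross tonnage, `> 0`).
#' @param q Quantity allocated to the agent, `>= 0`.
#' @param price Clearing access fee.
#' @inheritParams cost_fn
#' @return Profit in model units. Vectorized over `b_true`/`t_true` and `q`.
#' @export
seller_profit <- function(b_true, q, price, params = market_params()) {
  params <- as_market_params(params)
  check_positive(b_true, "b_true")
  if (any(q < 0)) stop("`q` must be >= 0", call. = FALSE)
  price * q - b_true * cost_fn(q / b_true, params)
}

#' @rdname seller_profit
#' @export
buyer_profit <- function(t_true, q, price, params = market_params()) {
  params <- as_market_params(params)
  check_positive(t_true, "t_true")
  if (any(q < 0)) stop("`q` must be >= 0", call. = FALSE)
  t_true * value_fn(q / t_true, params) - price * q
}

#' Equilibrium report as a fraction of the true endowment
#'
#' At a Nash equilibrium, an agent's report relative to its true value is a
#' closed-form function of its realized share of total reports. For a seller
#' holding reported-biomass share `sigma`,
#' `b_hat/b = (1 - sigma/(epsilon + eta*(1-sigma)))^eta`; for a buyer holding
#' reported-tonnage share `s`,
#' `t_hat/t = (1 + s/(epsilon*(1-s) + eta))^(-epsilon)`. Both ratios lie in
#' (0, 1] and decrease in the share: the larger the slice of the market an
#' agent controls, the more it under-reports. A vanishing share recovers
#' truthful price-taking behaviour; a monopolist seller at `eta = 1`,
#' `epsilon = 2` reports exactly half its true biomass.
#'
#' @param sigma,s Share of total reported biomass (resp. tonnage), in
#'   `[0, 1]`. Vectorized.
#' @inheritParams cost_fn
#' @return Report/true ratio in (0, 1].
#' @examples
#' report_ratio_seller(1)    # 0.5 at the defaults
#' report_ratio_buyer(1)     # 0.25
#' @export
report_ratio_seller <- function(sigma, params = market_params()) {
  params <- as_market_params(params)
  if (any(!is.finite(sigma)) || any(sigma < 0) || any(sigma > 1))
    stop("`sigma` must lie in [0, 1]", call. = FALSE)
  eta <- params$eta
  eps <- params$epsilon
  (1 - sigma / (eps + eta * (1 - sigma)))^eta
}

#' @rdname report_ratio_seller
#' @export
report_ratio_buyer <- function(s, params = market_params()) {
  params <- as_market_params(params)
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("`s` must lie in [0, 1]", call. = FALSE)
  eta <- params$eta
  eps <- params$epsilon
  (1 + s / (eps * (1 - s) + eta))^(-eps)
}

# Best-response residual for a seller: the polynomial whose root in
# (0, b_true] is the profit-maximizing report given the rivals' summed
# reports. Negative at 0+ (for b_others > 0), positive at b_true.
seller_br_residual <- function(b_hat, b_true, b_others, eta, eps) {
  eps * b_hat^((eta + 1) / eta) +
    b_true^(1 / eta) * (1 - eps) * b_hat +
    b_others * (eps + eta) * b_hat^(1 / eta) -
    b_true^(1 / eta) * b_others * (eps + eta)
}

buyer_br_residual <- function(t_hat, t_true, t_others, eta, eps) {
  (eta + 1) * t_hat^((eps + 1) / eps) -
    eta * t_true^(1 / eps) * t_hat +
    t_others * (eps + eta) * t_hat^(1 / eps) -
    t_true^(1 / eps) * t_others * (eps + eta)
}

#' Best-response report of a single seller or buyer
#'
#' Solves the first-order condition of the agent's profit maximization for
#' its report, holding the summed reports of its rivals fixed. The condition
#' is a polynomial in the report with a unique economically relevant root in
#' `(0, true value]`; it is bracketed there and solved with [stats::uniroot()].
#' With no rivals the root is available in closed form:
#' `b_hat = b * ((epsilon-1)/epsilon)^eta` for a monopolist seller and
#' `t_hat = t * (eta/(eta+1))^epsilon` for a monopsonist buyer. As rivals'
#' reports grow large the agent's share vanishes and the report tends to the
#' true value.
#'
#' @param b_true,t_true The agent's true endowment, `> 0`.
#' @param b_others,t_others Sum of the rival agents' reports, `>= 0`.
#' @inheritParams cost_fn
#' @param tol Relative root tolerance passed to the solver.
#' @return The best-response report, a scalar in `(0, true value]`.
#' @examples
#' seller_best_response(1, 0)  # 0.5 at the defaults
#' buyer_best_response(1, 0)   # 0.25
#' @export
seller_best_response <- function(b_true, b_others, params = market_params(),
                                 tol = 1e-12) {
  params <- as_market_params(params)
  check_positive(b_true, "b_true")
  if (!is.finite(b_others) || b_others < 0)
    stop("`b_others` must be finite and >= 0", call. = FALSE)
  eta <- params$eta
  eps <- params$epsilon
  if (b_others == 0) return(b_true * ((eps - 1) / eps)^eta)

  lower <- 1e-12 * b_true
  f <- function(x) seller_br_residual(x, b_true, b_others, eta, eps)
  f_lo <- f(lower)
  f_hi <- f(b_true)
  if (f_lo > 0 || f_hi < 0)
    stop(sprintf(
      "seller best response: no sign change on (%.3e, %.3e] for b_true=%g, b_others=%g",
      lower, b_true, b_true, b_others), call. = FALSE)
  stats::uniroot(f, c(lower, b_true), tol = tol * b_true)$root
}

#' @rdname seller_best_response
#' @export
buyer_best_response <- function(t_true, t_others, params = market_params(),
                                tol = 1e-12) {
  params <- as_market_params(params)
  check_positive(t_true, "t_true")
  if (!is.finite(t_others) || t_others < 0)
    stop("`t_others` must be finite and >= 0", call. = FALSE)
  eta <- params$eta
  eps <- params$epsilon
  if (t_others == 0) return(t_true * (eta / (eta + 1))^eps)

  lower <- 1e-12 * t_true
  f <- function(x) buyer_br_residual(x, t_true, t_others, eta, eps)
  f_lo <- f(lower)
  f_hi <- f(t_true)
  if (f_lo > 0 || f_hi < 0)
    stop(sprintf(
      "buyer best response: no sign change on (%.3e, %.3e] for t_true=%g, t_others=%g",
      lower, t_true, t_true, t_others), call. = FALSE)
  stats::uniroot(f, c(lower, t_true), tol = tol * t_true)$root
}

# Solve one side's Nash reports by synchronous best-response iteration.
# `br` is seller_best_response or buyer_best_response. Reports on one side
# depend only on same-side rivals, so the two sides can be solved
# independently; the cross-side link enters only through clearing.
solve_side <- function(true_vals, params, br, tol, max_iter) {
  reports <- true_vals  # truthful start
  damping_on <- FALSE
  prev_step <- NULL
  for (iter in seq_len(max_iter)) {
    total <- sum(reports)
    new_reports <- vapply(
      seq_along(true_vals),
      function(i) br(true_vals[i], total - reports[i], params),
      numeric(1)
    )
    step <- new_reports - reports
    if (damping_on) new_reports <- reports + 0.5 * step
    delta <- max(abs(step) / pmax(abs(reports), .Machine$double.eps))
    # engage damping if successive steps point in opposite directions
    if (!damping_on && !is.null(prev_step) &&
        sum(step * prev_step) < 0 && delta > tol) {
      damping_on <- TRUE
    }
    prev_step <- step
    reports <- new_reports
    if (delta < tol) {
      return(list(reports = reports, iterations = iter, converged = TRUE))
    }
  }
  list(reports = reports, iterations = max_iter, converged = FALSE)
}

#' Nash equilibrium of the bilateral access market
#'
#' Finds the report profile at which no seller or buyer can raise its own
#' profit by changing its report unilaterally, then clears the market at
#' those reports. The solver iterates synchronous best responses (every
#' agent responds to the previous round's rival sums), starting from
#' truthful reports, with a 0.5 damping factor engaged only if oscillation
#' is detected. Because an agent's first-order condition involves only
#' same-side rivals, the seller and buyer subgames are solved independently.
#'
#' @param b_true Numeric vector of sellers' true biomass (share or model
#'   units), all `> 0`. Names, if present, label the sellers.
#' @param t_true Numeric vector of buyers' true gross tonnage, all `> 0`.
#' @inheritParams cost_fn
#' @param tol Relative convergence tolerance on the report vector.
#' @param max_iter Maximum best-response sweeps per side.
#'
#' @return An object of class `nash_market`: a list with
#'   \describe{
#'     \item{params}{the `market_params` used}
#'     \item{sellers}{data.frame `id, b_true, b_report, share, q, profit`}
#'     \item{buyers}{data.frame `id, t_true, t_report, share, q, profit`}
#'     \item{B_hat, T_hat}{summed reports}
#'     \item{price, quantity}{clearing fee and total access quantity}
#'     \item{iterations, converged}{solver diagnostics per side}
#'   }
#' @examples
#' m <- solve_nash(b_true = c(0.3, 0.7), t_true = c(0.5, 0.5))
#' m$price
#' @export
solve_nash <- function(b_true, t_true, params = market_params(),
                       tol = 1e-10, max_iter = 10000) {
  params <- as_market_params(params)
  if (length(b_true) < 1L || length(t_true) < 1L)
    stop("need at least one seller and one buyer", call. = FALSE)
  check_positive(b_true, "b_true")
  check_positive(t_true, "t_true")

  s_ids <- names(b_true) %||% paste0("S", seq_along(b_true))
  b_ids <- names(t_true) %||% paste0("B", seq_along(t_true))

  sell <- solve_side(unname(b_true), params, seller_best_response, tol, max_iter)
  buy <- solve_side(unname(t_true), params, buyer_best_response, tol, max_iter)
  if (!sell$converged || !buy$converged)
    stop(sprintf(
      "Nash fixed point did not converge within %d iterations (seller side: %s after %d, buyer side: %s after %d)",
      max_iter, sell$converged, sell$iterations, buy$converged, buy$iterations),
      call. = FALSE)

  B_hat <- sum(sell$reports)
  T_hat <- sum(buy$reports)
  price <- clearing_price(B_hat, T_hat, params)
  quantity <- clearing_quantity(B_hat, T_hat, params)

  sigma <- sell$reports / B_hat
  s <- buy$reports / T_hat
  q_i <- sigma * quantity
  q_j <- s * quantity

  sellers <- data.frame(
    id = s_ids, b_true = unname(b_true), b_report = sell$reports,
    share = sigma, q = q_i,
    profit = seller_profit(unname(b_true), q_i, price, params),
    stringsAsFactors = FALSE
  )
  buyers <- data.frame(
    id = b_ids, t_true = unname(t_true), t_report = buy$reports,
    share = s, q = q_j,
    profit = buyer_profit(unname(t_true), q_j, price, params),
    stringsAsFactors = FALSE
  )

  structure(list(
    params = params, sellers = sellers, buyers = buyers,
    B_hat = B_hat, T_hat = T_hat, price = price, quantity = quantity,
    iterations = c(seller = sell$iterations, buyer = buy$iterations),
    converged = TRUE
  ), class = "nash_market")
}

#' @export
print.nash_market <- function(x, ...) {
  cat(sprintf(
    "<nash_market> %d sellers, %d buyers | fee p = %.6g, quantity Q = %.6g (model units)\n",
    nrow(x$sellers), nrow(x$buyers), x$price, x$quantity))
  cat(sprintf("  B_hat = %.6g (of %.6g true), T_hat = %.6g (of %.6g true)\n",
              x$B_hat, sum(x$sellers$b_true), x$T_hat, sum(x$buyers$t_true)))
  invisible(x)
}
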