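#' Elasticity parameters of the access market
#'
#' Bundles the two constant elasticities that govern curvature of the
#' seller-side opportunity-cost function and the buyer-side fishing-profit
#' function. `eta` is the seller cost elasticity (must be positive) and
#' `epsilon` the buyer value elasticity (must exceed 1 so that marginal
#' fishing profit is decreasing). The defaults, `eta = 1` and `epsilon = 2`,
#' are one unit above each parameter's lower bound.
#'
#' @param eta Seller cost elasticity, dimensionless, `eta > 0`.
#' @param epsilon Buyer value elasticity, dimensionless, `epsilon > 1`.
#'
#' @return An object of class `market_params`: a list with elements `eta`
#'   and `epsilon`.
#' @examples
#' market_params()            # eta = 1, epsilon = 2
#' market_params(0.5, 1.5)
#' @export
market_params <- function(eta = 1, epsilon = 2) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0)
    stop("`eta` must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 1)
    stop("`epsilon` must be a single finite number > 1", call. = FALSE)
  structure(list(eta = eta, epsilon = epsilon), class = "market_params")
}

as_market_params <- function(params) {
  if (inherits(params, "market_params")) return(params)
  if (is.list(params) && all(c("eta", "epsilon") %in% names(params)))
    return(market_params(params$eta, params$epsilon))
  stop("`params` must be a market_params object", call. = FALSE)
}

#' @export
print.market_params <- function(x, ...) {
  cat(sprintf("<market_params> eta = %g, epsilon = %g\n", x$eta, x$epsilon))
  invisible(x)
}
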