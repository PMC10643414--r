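# Independent oracles used across the suite. These evaluate the agents'
# objectives directly from the closed-form clearing rules, without going
# through the package's best-response or fixed-point code paths.

# Seller i's profit as a function of its own report, rivals' summed
# reports fixed, buyer side summarized by T_hat.
oracle_seller_profit <- function(b_hat, b_true, b_others, T_hat, params) {
  B <- b_hat + b_others
  p <- clearing_price(B, T_hat, params)
  Q <- clearing_quantity(B, T_hat, params)
  q <- b_hat / B * Q
  p * q - b_true * cost_fn(q / b_true, params)
}

oracle_buyer_profit <- function(t_hat, t_true, t_others, B_hat, params) {
  T_ <- t_hat + t_others
  p <- clearing_price(B_hat, T_, params)
  Q <- clearing_quantity(B_hat, T_, params)
  q <- t_hat / T_ * Q
  t_true * value_fn(q / t_true, params) - p * q
}

# Grid-search best response: maximize the objective over n points in
# (0, true value].
grid_best_report <- function(objective, true_val, others, other_total,
                             params, n = 10000) {
  grid <- seq_len(n) / n * true_val
  vals <- objective(grid, true_val, others, other_total, params)
  grid[which.max(vals)]
}

# Numerically solve the marginal-value = marginal-cost crossing that the
# closed-form clearing rules must satisfy: (Q/B)^(1/eta) = (Q/T)^(-1/eps).
oracle_clearing <- function(B, T_, params) {
  f <- function(Q) (Q / B)^(1 / params$eta) - (Q / T_)^(-1 / params$epsilon)
  Q <- uniroot(f, c(1e-12, 1e6), tol = 1e-14)$root
  list(price = (Q / B)^(1 / params$eta), quantity = Q)
}

# A tiny calibrated market used by several files.
toy_market <- function(n_sellers = 3, n_buyers = 3, seed = 11,
                       params = market_params()) {
  syn <- gen_market(synth_spec(n_sellers = n_sellers, n_buyers = n_buyers,
                               seed = seed))
  list(market = build_market(syn$sellers, syn$buyers, params),
       anchors = syn$anchors, tables = syn)
}
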