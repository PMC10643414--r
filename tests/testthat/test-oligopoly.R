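test_that("cost and value functions match closed forms and integrals of marginals", {
  p <- market_params(eta = 1, epsilon = 2)
  expect_identical(cost_fn(0, p), 0)
  expect_equal(cost_fn(1, p), 0.5)
  expect_equal(cost_fn(4, p), 8)
  expect_identical(value_fn(0, p), 0)
  expect_equal(value_fn(1, p), 2)
  expect_equal(value_fn(9, p), 6)

  # cross-check against numerical integration of the marginals
  for (pp in list(p, market_params(0.5, 1.5), market_params(1.5, 2.5))) {
    expect_equal(cost_fn(4, pp),
                 integrate(function(z) z^(1 / pp$eta), 0, 4,
                           rel.tol = 1e-10)$value, tolerance = 1e-8)
    expect_equal(value_fn(9, pp),
                 integrate(function(z) z^(-1 / pp$epsilon), 0, 9,
                           rel.tol = 1e-10)$value, tolerance = 1e-8)
  }
  expect_error(cost_fn(-1, p), "z")
  expect_error(value_fn(-1, p), "z")
})

test_that("cost is convex increasing, value concave increasing", {
  p <- market_params(0.7, 1.8)
  z <- seq(0.01, 5, length.out = 200)
  cz <- cost_fn(z, p)
  vz <- value_fn(z, p)
  expect_true(all(diff(cz) > 0))
  expect_true(all(diff(vz) > 0))
  expect_true(all(diff(diff(cz)) > 0))  # convex
  expect_true(all(diff(diff(vz)) < 0))  # concave
})

test_that("clearing price and quantity match the marginal-condition oracle", {
  p <- market_params(1, 2)
  expect_equal(clearing_price(1, 1, p), 1)
  expect_equal(clearing_quantity(1, 1, p), 1)

  or <- oracle_clearing(0.6, 1, p)
  expect_equal(clearing_price(0.6, 1, p), or$price, tolerance = 1e-8)
  expect_equal(clearing_quantity(0.6, 1, p), or$quantity, tolerance = 1e-8)

  # swapped-argument symmetry of the closed form
  for (bt in list(c(0.3, 1.4), c(2, 5), c(0.1, 0.9))) {
    expect_equal(clearing_price(bt[1], bt[2], p) * clearing_price(bt[2], bt[1], p),
                 1, tolerance = 1e-12)
  }
  expect_error(clearing_price(0, 1, p), "B_hat")
  expect_error(clearing_quantity(1, -2, p), "T_hat")
})

test_that("first-order consistency: marginal value = marginal cost = price", {
  set.seed(42)
  for (i in 1:20) {
    p <- market_params(runif(1, 0.3, 2), runif(1, 1.2, 3))
    B <- runif(1, 0.1, 5)
    T_ <- runif(1, 0.1, 5)
    Q <- clearing_quantity(B, T_, p)
    price <- clearing_price(B, T_, p)
    expect_equal((Q / B)^(1 / p$eta), price, tolerance = 1e-10)
    expect_equal((Q / T_)^(-1 / p$epsilon), price, tolerance = 1e-10)
  }
})

test_that("profit functions evaluate the objectives term by term", {
  p <- market_params(1, 2)
  # truthful monopoly seller: B_hat = b = 1 facing T_hat = 1
  expect_equal(seller_profit(1, 1, 1, p), 1 - cost_fn(1, p))
  expect_equal(seller_profit(1, 1, 1, p), 0.5)
  # truthful monopsonist
  expect_equal(buyer_profit(1, 1, 1, p), 2 - 1)
  expect_equal(seller_profit(2, 0, 1.3, p), 0)
  expect_equal(buyer_profit(2, 0, 1.3, p), 0)
  expect_error(seller_profit(0, 1, 1, p), "b_true")
  expect_error(buyer_profit(-1, 1, 1, p), "t_true")
})

test_that("report ratios match closed forms and are monotone in the share", {
  p <- market_params(1, 2)
  expect_equal(report_ratio_seller(1, p), 0.5)
  expect_equal(report_ratio_seller(0, p), 1)
  expect_equal(report_ratio_seller(0.5, p), 0.8)
  expect_equal(report_ratio_buyer(0, p), 1)
  expect_equal(report_ratio_buyer(1, p), 0.25)

  s_grid <- seq(0, 1, by = 0.01)
  for (pp in list(p, market_params(0.5, 1.5), market_params(1.5, 2.5))) {
    rs <- report_ratio_seller(s_grid, pp)
    rb <- report_ratio_buyer(s_grid, pp)
    expect_true(all(diff(rs) < 0))
    expect_true(all(diff(rb) < 0))
    expect_true(all(rs > 0 & rs <= 1))
    expect_true(all(rb > 0 & rb <= 1))
  }
  expect_error(report_ratio_seller(1.2, p), "sigma")
  expect_error(report_ratio_buyer(-0.1, p), "s")
})

test_that("best responses match monopoly closed forms and vanishing-share limits", {
  p <- market_params(1, 2)
  expect_equal(seller_best_response(1, 0, p), 0.5)
  expect_equal(buyer_best_response(1, 0, p), 0.25)
  # huge rival reports drive the report to the true value
  expect_equal(seller_best_response(1, 1e9, p), 1, tolerance = 1e-4)
  expect_equal(buyer_best_response(1, 1e9, p), 1, tolerance = 1e-4)
  # interior case: root of 2 b^2 + 2 b^... verified against grid search
  br <- seller_best_response(1, 1, p)
  grid_br <- grid_best_report(
    function(bh, bt, bo, T_, pp) oracle_seller_profit(bh, bt, bo, T_, pp),
    1, 1, 1, p)
  expect_equal(br, grid_br, tolerance = 2e-4)
})

test_that("best responses maximize the agents' objectives (grid oracle, varied elasticities)", {
  set.seed(7)
  for (rep in 1:6) {
    p <- market_params(runif(1, 0.4, 1.6), runif(1, 1.3, 2.6))
    b_true <- runif(1, 0.2, 2)
    b_others <- runif(1, 0, 3)
    T_hat <- runif(1, 0.3, 2)
    br <- seller_best_response(b_true, b_others, p)
    grid <- seq_len(10000) / 10000 * b_true
    prof <- oracle_seller_profit(grid, b_true, b_others, T_hat, p)
    expect_gte(oracle_seller_profit(br, b_true, b_others, T_hat, p),
               max(prof) - 1e-9)

    t_true <- runif(1, 0.2, 2)
    t_others <- runif(1, 0, 3)
    B_hat <- runif(1, 0.3, 2)
    tr <- buyer_best_response(t_true, t_others, p)
    proft <- oracle_buyer_profit(grid / b_true * t_true, t_true, t_others,
                                 B_hat, p)
    expect_gte(oracle_buyer_profit(tr, t_true, t_others, B_hat, p),
               max(proft) - 1e-9)
  }
})

test_that("report-share relation is consistent with the best-response roots across a share grid", {
  for (p in list(market_params(1, 2), market_params(0.5, 2.5),
                 market_params(1.5, 1.5))) {
    for (sigma in seq(0.05, 0.95, by = 0.1)) {
      b_true <- 1.7
      b_hat <- b_true * report_ratio_seller(sigma, p)
      b_others <- b_hat * (1 - sigma) / sigma
      expect_equal(seller_best_response(b_true, b_others, p), b_hat,
                   tolerance = 1e-8)
      t_true <- 0.9
      t_hat <- t_true * report_ratio_buyer(sigma, p)
      t_others <- t_hat * (1 - sigma) / sigma
      expect_equal(buyer_best_response(t_true, t_others, p), t_hat,
                   tolerance = 1e-8)
    }
  }
})

test_that("solve_nash reproduces the 1x1 closed form and clears the market", {
  p <- market_params(1, 2)
  m <- solve_nash(c(s = 1), c(b = 1), p)
  expect_equal(m$sellers$b_report, 0.5)
  expect_equal(m$buyers$t_report, 0.25)
  expect_equal(m$price, clearing_price(0.5, 0.25, p))
  expect_equal(m$quantity, clearing_quantity(0.5, 0.25, p))
  expect_equal(sum(m$sellers$q), m$quantity)
  expect_equal(sum(m$buyers$q), m$quantity)
})

test_that("symmetric markets solve the scalar share equations", {
  p <- market_params(1, 2)
  for (nm in list(c(2, 3), c(4, 2), c(5, 5))) {
    n <- nm[1]; mth <- nm[2]
    m <- solve_nash(rep(1 / n, n), rep(1 / mth, mth), p)
    # symmetric equilibrium: every share is 1/n (1/m), so each report
    # satisfies the report-ratio relation at that share
    expect_equal(m$sellers$b_report,
                 rep(report_ratio_seller(1 / n, p) / n, n), tolerance = 1e-9)
    expect_equal(m$buyers$t_report,
                 rep(report_ratio_buyer(1 / mth, p) / mth, mth),
                 tolerance = 1e-9)
  }
})

test_that("reports approach truth in the competitive (many-agent) limit", {
  p <- market_params(1, 2)
  m <- solve_nash(rep(1 / 400, 400), rep(1 / 400, 400), p)
  expect_equal(m$B_hat, 1, tolerance = 5e-3)
  expect_equal(m$T_hat, 1, tolerance = 5e-3)
})

test_that("Nash solution: underreporting, share relation, and grid-oracle optimality", {
  set.seed(99)
  for (rep in 1:4) {
    n <- sample(2:5, 1); mth <- sample(2:5, 1)
    p <- market_params(runif(1, 0.5, 1.5), runif(1, 1.4, 2.5))
    b <- runif(n, 0.1, 2)
    t <- runif(mth, 0.1, 2)
    m <- solve_nash(b, t, p)
    # underreporting: reports in (0, true]
    expect_true(all(m$sellers$b_report > 0 & m$sellers$b_report <= b))
    expect_true(all(m$buyers$t_report > 0 & m$buyers$t_report <= t))
    # closed-form share relation at realized shares
    expect_equal(m$sellers$b_report / b,
                 report_ratio_seller(m$sellers$share, p), tolerance = 1e-8)
    expect_equal(m$buyers$t_report / t,
                 report_ratio_buyer(m$buyers$share, p), tolerance = 1e-8)
    # every agent's report maximizes its objective on a 10,000-point grid
    for (i in seq_len(n)) {
      grid <- seq_len(10000) / 10000 * b[i]
      prof <- oracle_seller_profit(grid, b[i], m$B_hat - m$sellers$b_report[i],
                                   m$T_hat, p)
      expect_gte(oracle_seller_profit(m$sellers$b_report[i], b[i],
                                      m$B_hat - m$sellers$b_report[i],
                                      m$T_hat, p),
                 max(prof) - 1e-9)
    }
    for (j in seq_len(mth)) {
      grid <- seq_len(10000) / 10000 * t[j]
      prof <- oracle_buyer_profit(grid, t[j], m$T_hat - m$buyers$t_report[j],
                                  m$B_hat, p)
      expect_gte(oracle_buyer_profit(m$buyers$t_report[j], t[j],
                                     m$T_hat - m$buyers$t_report[j],
                                     m$B_hat, p),
                 max(prof) - 1e-9)
    }
  }
})

test_that("profit at the Nash report is at least profit at the truthful report", {
  p <- market_params(1, 2)
  m <- solve_nash(c(0.6, 0.4), c(0.7, 0.3), p)
  for (i in 1:2) {
    rivals <- m$B_hat - m$sellers$b_report[i]
    expect_gte(oracle_seller_profit(m$sellers$b_report[i], m$sellers$b_true[i],
                                    rivals, m$T_hat, p),
               oracle_seller_profit(m$sellers$b_true[i], m$sellers$b_true[i],
                                    rivals, m$T_hat, p))
  }
})

test_that("the same fixed point is reached from multiple initializations", {
  p <- market_params(0.8, 2.2)
  b <- c(0.5, 0.3, 0.2)
  ref <- solve_nash(b, c(0.6, 0.4), p)$sellers$b_report
  set.seed(3)
  for (rep in 1:5) {
    init <- runif(3, 0.01, 1) * b
    alt <- fishbloc:::solve_side_fast(b, p, "seller", init = init)$reports
    expect_equal(alt, ref, tolerance = 1e-8)
  }
})

test_that("buyer equilibrium reports are invariant to the seller side", {
  p <- market_params(1, 2)
  t <- c(0.5, 0.3, 0.2)
  r1 <- solve_nash(c(1), t, p)$buyers$t_report
  r2 <- solve_nash(runif(7, 0.01, 0.4), t, p)$buyers$t_report
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("merging sellers lowers reports and quantity, raises the fee and joint profit", {
  set.seed(17)
  p <- market_params(1, 2)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    b <- runif(n, 0.1, 1)
    t <- runif(3, 0.2, 0.8)
    pre <- solve_nash(b, t, p)
    idx <- sample(n, sample(2:n, 1))
    b_merged <- c(sum(b[idx]), b[-idx])
    post <- solve_nash(b_merged, t, p)
    expect_lte(post$B_hat, pre$B_hat + 1e-10)
    expect_gte(post$price, pre$price - 1e-10)
    expect_lte(post$quantity, pre$quantity + 1e-10)
    expect_gte(post$sellers$profit[1], sum(pre$sellers$profit[idx]) - 1e-10)
  }
})

test_that("truthful reports maximize total surplus at the cleared quantity", {
  set.seed(5)
  for (rep in 1:5) {
    p <- market_params(runif(1, 0.5, 1.5), runif(1, 1.4, 2.6))
    B <- runif(1, 0.5, 3)
    T_ <- runif(1, 0.5, 3)
    Q_star <- clearing_quantity(B, T_, p)
    surplus <- function(Q) T_ * value_fn(Q / T_, p) - B * cost_fn(Q / B, p)
    opt <- optimize(surplus, c(1e-9, 10 * Q_star), maximum = TRUE,
                    tol = 1e-12)
    expect_equal(Q_star, opt$maximum, tolerance = 1e-6)
  }
})

test_that("degenerate and invalid market inputs are rejected", {
  p <- market_params()
  expect_error(solve_nash(numeric(0), 1, p), "at least one")
  expect_error(solve_nash(c(1, -1), 1, p), "b_true")
  expect_error(market_params(0, 2), "eta")
  expect_error(market_params(1, 1), "epsilon")
})
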