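test_that("status quo equilibria recover the calibrated biomass", {
  tm <- toy_market(4, 4, seed = 41)
  sq <- run_status_quo(tm$market, tm$anchors)
  b_cal <- tm$market$sellers$b[match(sq$equilibria$country,
                                     tm$market$sellers$id)]
  grid_step <- 0.01 * tm$market$sellers$k
  expect_true(all(abs(sq$equilibria$biomass - b_cal) < grid_step))
  # the anchored fee converts back to the anchor value
  expect_equal(sq$aggregates[["fee_usd_per_ton"]], tm$anchors$fee_usd,
               tolerance = 1e-4)
})

test_that("the full-size 32x33 market runs end to end and recovers its calibration", {
  syn <- gen_market(synth_spec(seed = 42))
  mkt <- build_market(syn$sellers, syn$buyers)
  sq <- run_status_quo(mkt, syn$anchors, grid_pct = 2)
  expect_equal(nrow(sq$equilibria), 32L)
  b_cal <- mkt$sellers$b[match(sq$equilibria$country, mkt$sellers$id)]
  expect_true(all(abs(sq$equilibria$biomass - b_cal) < 0.02 * mkt$sellers$k))
  # model-unit quantities are reported alongside converted tons
  expect_true(is.finite(sq$solution$quantity))
  expect_equal(qty_units_to_tons(sq$solution$quantity, sq$scales),
               syn$anchors$qty_tons, tolerance = 1e-6)
  co <- run_continental(mkt, sq, grid_pct = 2)
  cmp <- setNames(co$comparison$pct_difference, co$comparison$quantity)
  expect_lt(cmp[["access_catch_tons"]], 0)
  expect_gt(cmp[["biomass_tons"]], 0)
})

test_that("the coalition restricts access, raises the fee, and benefits sellers", {
  tm <- toy_market(5, 4, seed = 43)
  sq <- run_status_quo(tm$market, tm$anchors)
  co <- run_continental(tm$market, sq)
  cmp <- setNames(co$comparison$pct_difference, co$comparison$quantity)
  expect_lt(cmp[["access_catch_tons"]], 0)
  expect_gt(cmp[["fee_usd_per_ton"]], 0)
  expect_gt(cmp[["seller_profit_usd"]], 0)
  expect_lt(cmp[["buyer_profit_usd"]], 0)
  expect_gt(cmp[["biomass_tons"]], 0)
  # every single country gains biomass
  b_sq <- sq$equilibria$biomass[match(co$equilibria$country,
                                      sq$equilibria$country)]
  expect_true(all(co$equilibria$biomass >= b_sq))
  # the coalition's true share is an emergent output above 1
  expect_gt(co$coalition_true_share, 1)
  # single seller's equilibrium report ratio is the monopoly ratio
  expect_equal(co$solution$B_hat / co$coalition_true_share,
               report_ratio_seller(1, tm$market$params), tolerance = 1e-9)
})

test_that("a 40% lower report moves fee and quantity by the closed-form ratios", {
  p <- market_params(1, 2)
  fee_ratio <- clearing_price(0.6, 1, p) / clearing_price(1, 1, p)
  qty_ratio <- clearing_quantity(0.6, 1, p) / clearing_quantity(1, 1, p)
  expect_equal(fee_ratio, 0.6^(-1 / 3), tolerance = 1e-12)
  expect_equal(qty_ratio, 0.6^(2 / 3), tolerance = 1e-12)
  expect_equal(round(100 * (fee_ratio - 1)), 19)
  expect_equal(round(100 * (qty_ratio - 1)), -29)
})

test_that("region assignment follows the ascending-size rule with overrides", {
  mem <- list(A = c("x", "y"), B = c("y", "z", "w"))
  got <- assign_regions(mem)
  expect_equal(got[c("x", "y", "z", "w")],
               c(x = "A", y = "A", z = "B", w = "B"), ignore_attr = TRUE)
  # singleton fallback for countries in no community
  got2 <- assign_regions(mem, countries = c("x", "y", "z", "w", "solo"))
  expect_equal(unname(got2["solo"]), "solo")
  # exclusion and reassignment
  got3 <- assign_regions(mem, exclude = "A", reassign = c(z = "C"),
                         countries = c("x", "y", "z", "w"))
  expect_equal(unname(got3[c("y", "z", "x")]), c("B", "C", "x"))
  expect_error(assign_regions(mem, reassign = c(missing = "B")), "unknown")
})

test_that("overlapping communities resolve exactly as a brute-force rule replay", {
  mem <- list(
    CEN = c("c1", "c2", "c3", "c4"),
    EST = c("e1", "e2", "c2"),
    SUD = c("s1", "e1")
  )
  got <- assign_regions(mem)
  # replay: ascending sizes SUD(2) < EST(3) < CEN(4)
  manual <- c(s1 = "SUD", e1 = "SUD", e2 = "EST", c2 = "EST",
              c1 = "CEN", c3 = "CEN", c4 = "CEN")
  expect_equal(got[names(manual)], manual, ignore_attr = TRUE)
  expect_true(is.logical(attr(got, "ties")))
})

test_that("scenario nesting: singleton regions reproduce the status quo", {
  tm <- toy_market(4, 3, seed = 47)
  sq <- run_status_quo(tm$market, tm$anchors)
  singles <- setNames(tm$market$sellers$id, tm$market$sellers$id)
  rg <- run_regional(tm$market, singles, sq)
  expect_equal(rg$equilibria$biomass, sq$equilibria$biomass,
               tolerance = 1e-9)
  expect_equal(rg$equilibria$access_catch, sq$equilibria$access_catch,
               tolerance = 1e-9)
  expect_equal(rg$solution$price, sq$solution$price, tolerance = 1e-9)
  expect_equal(rg$solution$quantity, sq$solution$quantity, tolerance = 1e-9)
  expect_equal(unname(rg$aggregates), unname(sq$aggregates),
               tolerance = 1e-9)
})

test_that("scenario nesting: one region reproduces the continental coalition", {
  tm <- toy_market(4, 3, seed = 47)
  sq <- run_status_quo(tm$market, tm$anchors)
  co <- run_continental(tm$market, sq)
  allone <- setNames(rep("ALL", 4), tm$market$sellers$id)
  rg <- run_regional(tm$market, allone, sq)
  expect_equal(rg$equilibria$biomass, co$equilibria$biomass,
               tolerance = 1e-9)
  expect_equal(rg$solution$price, co$solution$price, tolerance = 1e-9)
  expect_equal(unname(rg$aggregates), unname(co$aggregates),
               tolerance = 1e-9)
  # intermediate coarsening: the aggregate report ratio (reported biomass
  # over emergent true biomass share) sits between status quo and coalition
  report_ratio <- function(res, b_true_total) {
    res$solution$B_hat / (sum(res$equilibria$biomass) / b_true_total)
  }
  bt <- sum(tm$market$sellers$b)
  rmap <- setNames(c("R1", "R1", "R2", "R2"), tm$market$sellers$id)
  rg2 <- run_regional(tm$market, rmap, sq)
  expect_lt(report_ratio(rg2, bt), report_ratio(sq, bt) + 1e-9)
  expect_gt(report_ratio(rg2, bt), report_ratio(co, bt) - 1e-9)
})

test_that("PNA-style dissolution lowers members' biomass and triggers slope repair", {
  # healthy stocks (depletion 1.3), access-heavy PNA-like market; the
  # low-growth member holds a biomass share large enough that its
  # apportioned access exceeds its observed total catch
  sellers <- data.frame(
    id = c(sprintf("P%d", 1:8), "SOL"),
    catch_tons = rep(1e5, 9),
    growth_g = c(rep(0.3, 8), 0.15),
    foreign_catch_tons = 0.65 * rep(1e5, 9))
  syn <- gen_market(synth_spec(n_sellers = 2, n_buyers = 6, seed = 53))
  res <- run_pna(sellers, syn$buyers, access_fraction = 1, fee_usd = 307,
                 depletion = 1.3)
  expect_identical(res$coalition$repaired, "SOL")
  expect_true(all(res$coalition$nonaccess_slopes >= 0))
  # dissolution lowers every member's biomass
  b_co <- res$coalition$equilibria$biomass
  b_in <- res$individual$equilibria$biomass[
    match(res$coalition$equilibria$country,
          res$individual$equilibria$country)]
  expect_true(all(b_in < b_co))
  cmp <- setNames(res$individual$comparison$pct_difference,
                  res$individual$comparison$quantity)
  expect_lt(cmp[["biomass_tons"]], 0)
  expect_lt(cmp[["seller_profit_usd"]], 0)

  # halving the access fraction changes q*, hence the slopes, and removes
  # the need for repair
  res2 <- run_pna(sellers, syn$buyers, access_fraction = 0.5, fee_usd = 307,
                  depletion = 1.3)
  expect_length(res2$coalition$repaired, 0)
  expect_false(isTRUE(all.equal(res2$coalition$nonaccess_slopes,
                                res$coalition$nonaccess_slopes)))
  expect_error(run_pna(sellers, syn$buyers, access_fraction = 0),
               "access_fraction")
  expect_error(run_pna(syn$sellers, syn$buyers), "foreign_catch_tons")
})

test_that("a single-point sweep equals a direct run and invalid points are skipped", {
  tm <- toy_market(3, 3, seed = 59)
  sw <- sweep_scenarios(tm$tables$sellers, tm$tables$buyers, tm$anchors,
                        eta = 1, epsilon = 2, depletion = 0.8)
  sq <- run_status_quo(tm$market, tm$anchors)
  co <- run_continental(tm$market, sq)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$fee_sq, sq$aggregates[["fee_usd_per_ton"]])
  expect_equal(sw$biomass_co, co$aggregates[["biomass_tons"]])
  expect_warning(
    sw2 <- sweep_scenarios(tm$tables$sellers, tm$tables$buyers, tm$anchors,
                           eta = c(-1, 1), epsilon = 2, depletion = 0.8),
    "invalid")
  expect_equal(nrow(sw2), 1L)
})
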