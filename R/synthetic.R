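#' Specification for a synthetic access market
#'
#' Collects the knobs of the synthetic-data generator. The defaults emulate
#' the structure of the African access market: 32 heterogeneous selling
#' countries and 33 heterogeneous buying countries with right-skewed
#' (log-normal) catch and tonnage distributions, country-level growth
#' parameters, stocks at depletion 0.8, an EU-like anchor buyer holding
#' 11.5% of access purchases with a known annual purchase in tons, an
#' observed average access fee of $128.20/ton, and total access catch
#' around one fifth of total catch.
#'
#' @param n_sellers,n_buyers Participant counts, `>= 1`.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param catch_meanlog,catch_sdlog Log-normal parameters for mean annual
#'   total catch (tons/year). The defaults put the median country near
#'   150,000 t/yr with a heavy right tail, so a continent of 32 totals
#'   roughly 10 million t/yr.
#' @param growth_range Uniform bounds for the intrinsic growth parameter g
#'   (1/year).
#' @param tonnage_meanlog,tonnage_sdlog Log-normal parameters for
#'   distant-water-fleet gross tonnage.
#' @param anchor_buyer_share Anchor buyer's share of true tonnage, in
#'   (0, 1) (default 0.115).
#' @param anchor_fee_usd Observed average access fee (USD/ton).
#' @param access_catch_frac Total access catch as a fraction of total
#'   observed catch, used to size the quantity anchor (default 0.21).
#' @param depletion Assumed depletion b/bmsy (default 0.8).
#' @param phi Pella-Tomlinson shape (default 0.188).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_sellers = 32, n_buyers = 33, seed = 1,
                       catch_meanlog = log(1.5e5), catch_sdlog = 1.2,
                       growth_range = c(0.15, 0.45),
                       tonnage_meanlog = log(8e4), tonnage_sdlog = 1.1,
                       anchor_buyer_share = 0.115, anchor_fee_usd = 128.20,
                       access_catch_frac = 0.21,
                       depletion = 0.8, phi = 0.188) {
  stopifnot(n_sellers >= 1, n_buyers >= 1,
            catch_sdlog > 0, tonnage_sdlog > 0,
            length(growth_range) == 2, all(growth_range > 0),
            anchor_buyer_share > 0, anchor_buyer_share < 1,
            anchor_fee_usd > 0, access_catch_frac > 0, access_catch_frac < 1)
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate synthetic seller and buyer tables
#'
#' Draws right-skewed endowments: seller catch and buyer gross tonnage are
#' log-normal, growth parameters uniform. When there are at least two
#' buyers, the first buyer is the anchor (id `"ANCHOR"`) and its tonnage is
#' set so its true tonnage share equals `anchor_buyer_share`. The returned
#' `anchors` element carries everything [run_status_quo()] needs: the
#' anchor buyer id, its annual purchase in tons (the anchor share of total
#' access catch, itself `access_catch_frac` of total catch), and the fee
#' anchor.
#'
#' @param spec A [synth_spec()].
#' @return List with `sellers` (id, catch_tons, growth_g), `buyers`
#'   (id, gross_tonnage) and `anchors` (fee_usd, qty_tons, buyer_id,
#'   purchase_tons).
#' @export
gen_market <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  sellers <- data.frame(
    id = sprintf("S%02d", seq_len(spec$n_sellers)),
    catch_tons = stats::rlnorm(spec$n_sellers, spec$catch_meanlog,
                               spec$catch_sdlog),
    growth_g = stats::runif(spec$n_sellers, spec$growth_range[1],
                            spec$growth_range[2]),
    stringsAsFactors = FALSE
  )
  n_other <- if (spec$n_buyers > 1) spec$n_buyers - 1L else spec$n_buyers
  other_gt <- stats::rlnorm(n_other, spec$tonnage_meanlog, spec$tonnage_sdlog)
  if (spec$n_buyers > 1) {
    anchor_gt <- spec$anchor_buyer_share / (1 - spec$anchor_buyer_share) *
      sum(other_gt)
    buyers <- data.frame(
      id = c("ANCHOR", sprintf("F%02d", seq_len(n_other))),
      gross_tonnage = c(anchor_gt, other_gt),
      stringsAsFactors = FALSE
    )
  } else {
    buyers <- data.frame(id = "F01", gross_tonnage = other_gt,
                         stringsAsFactors = FALSE)
  }
  qty_tons <- spec$access_catch_frac * sum(sellers$catch_tons)
  anchors <- list(
    fee_usd = spec$anchor_fee_usd,
    qty_tons = qty_tons,
    buyer_id = if (spec$n_buyers > 1) "ANCHOR" else buyers$id[1],
    purchase_tons = spec$anchor_buyer_share * qty_tons
  )
  list(sellers = sellers, buyers = buyers, anchors = anchors)
}

#' Generate synthetic fishing-hours and vessel tables with planted truth
#'
#' Fabricates the two ingestion tables used by participant identification
#' and DWF classification, together with the answer key: which flags
#' should come out as buyers, which coastal states as sellers, and which
#' vessels are distant-water. Hours records span several years and mix
#' above- and below-threshold pairs; vessels mix majority-inside and
#' majority-outside effort.
#'
#' @param n_flags,n_eez,n_years Table dimensions.
#' @param threshold Hours threshold the planted truth is built against.
#' @param seed Integer seed.
#' @return List with `hours`, `vessels` data.frames and `truth` (list
#'   `buyers`, `sellers`, `dwf_vessels`, `threshold`).
#' @export
gen_hours <- function(n_flags = 4, n_eez = 3, n_years = 2,
                      threshold = 2420, seed = 1) {
  stopifnot(n_flags >= 1, n_eez >= 1, n_years >= 1, threshold > 0)
  set.seed(seed)
  flags <- sprintf("FLAG%02d", seq_len(n_flags))
  eezs <- sprintf("EEZ%02d", seq_len(n_eez))
  years <- 2016L + seq_len(n_years) - 1L
  grid <- expand.grid(buyer_flag = flags, seller_eez = eezs, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # roughly half the pairs active in any year; active pairs clear the
  # threshold by a wide margin, inactive ones stay well below
  active <- stats::runif(nrow(grid)) < 0.5
  grid$hours <- ifelse(active,
                       threshold * stats::runif(nrow(grid), 1.2, 4),
                       threshold * stats::runif(nrow(grid), 0, 0.8))
  over <- grid[grid$hours > threshold, ]
  truth_buyers <- sort(unique(over$buyer_flag))
  truth_sellers <- sort(unique(over$seller_eez))

  n_vessels <- 5L * n_flags
  vessels <- data.frame(
    vessel_id = sprintf("V%03d", seq_len(n_vessels)),
    flag = rep(flags, each = 5L),
    stringsAsFactors = FALSE
  )
  dwf <- stats::runif(n_vessels) < 0.5
  base <- stats::runif(n_vessels, 500, 5000)
  vessels$hours_inside <- ifelse(dwf, base * stats::runif(n_vessels, 0.1, 0.9),
                                 base)
  vessels$hours_outside <- ifelse(dwf, base, base * stats::runif(n_vessels, 0.1, 0.9))
  vessels$gross_tonnage <- stats::rlnorm(n_vessels, log(1500), 0.8)

  list(hours = grid, vessels = vessels,
       truth = list(buyers = truth_buyers, sellers = truth_sellers,
                    dwf_vessels = vessels$vessel_id[dwf],
                    threshold = threshold))
}

#' Worked-example fixture: a median-biomass seller in a 32-country market
#'
#' A fixed small fixture pinning the share-rescaling arithmetic: one
#' selling country (Madagascar-like) with true biomass 2,213,411 tons and
#' true biomass share 0.0189, embedded in a market whose remaining
#' countries jointly hold the complementary share 0.9811.
#'
#' @return List with `b_true_tons`, `share`, `rest_share`, and a
#'   `perturbed(new_tons)` function returning the rescaled share and the
#'   model's total true biomass under the perturbation.
#' @examples
#' fx <- worked_example_fixture()
#' fx$perturbed(3458613)$share        # ~0.0295
#' fx$perturbed(3458613)$model_total  # ~1.0106
#' @export
worked_example_fixture <- function() {
  b_true <- 2213411
  share <- 0.0189
  list(
    b_true_tons = b_true,
    share = share,
    rest_share = 1 - share,
    perturbed = function(new_tons) {
      new_share <- rescale_share(share, b_true, new_tons)
      list(share = new_share, model_total = (1 - share) + new_share)
    }
  )
}
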