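#' Pella-Tomlinson biomass at maximum sustainable yield
#'
#' `bmsy = k / (phi + 1)^(1/phi)`, where `k` is carrying capacity and `phi`
#' the shape parameter of the surplus-production curve. The default shape
#' used throughout the package, `phi = 0.188`, places maximum growth at 40%
#' of carrying capacity; `phi = 1` recovers the logistic (Schaefer) model
#' with its maximum at `k/2`.
#'
#' @param k Carrying capacity (tons), `> 0`. Vectorized.
#' @param phi Shape parameter, `> 0`.
#' @return Biomass at MSY (tons), strictly between 0 and `k`.
#' @examples
#' bmsy_from_k(1, 0.188)  # ~0.400
#' bmsy_from_k(1, 1)      # 0.5
#' @export
bmsy_from_k <- function(k, phi = 0.188) {
  check_positive(k, "k")
  check_positive(phi, "phi")
  k / (phi + 1)^(1 / phi)
}

#' Pella-Tomlinson surplus production
#'
#' Annual growth of the stock at biomass `b`:
#' `growth = (phi+1)/phi * g * b * (1 - (b/k)^phi)`. Zero at `b = 0` and at
#' carrying capacity, with a single interior maximum at [bmsy_from_k()].
#' At a steady state this growth equals the annual harvest.
#'
#' @param b Biomass (tons), in `[0, k]`. Vectorized.
#' @param g Intrinsic growth parameter (1/year), `> 0`.
#' @inheritParams bmsy_from_k
#' @return Surplus production (tons/year).
#' @export
pt_growth <- function(b, g, k, phi = 0.188) {
  check_positive(g, "g")
  check_positive(k, "k")
  check_positive(phi, "phi")
  if (any(!is.finite(b)) || any(b < 0) || any(b > k * (1 + 1e-12)))
    stop("`b` must lie in [0, k]", call. = FALSE)
  (phi + 1) / phi * g * b * (1 - (b / k)^phi)
}

#' Biomass at a given depletion level
#'
#' Depletion is defined relative to MSY: `d = b / bmsy`, so
#' `b = d * k / (phi+1)^(1/phi)`. `d = 0.8` describes a partially depleted
#' stock; `d = 1` puts the stock exactly at bmsy. `d` may exceed 1 (healthy
#' stocks) but must stay below `(phi+1)^(1/phi)` so that `b < k`.
#'
#' @inheritParams bmsy_from_k
#' @param d Depletion `b/bmsy`, with `0 <= d < (phi+1)^(1/phi)`. Vectorized.
#' @return Biomass (tons); satisfies `b / bmsy_from_k(k, phi) == d`.
#' @export
biomass_from_depletion <- function(k, phi = 0.188, d = 0.8) {
  check_positive(k, "k")
  check_positive(phi, "phi")
  dmax <- (phi + 1)^(1 / phi)
  if (any(!is.finite(d)) || any(d < 0) || any(d >= dmax))
    stop(sprintf("`d` must lie in [0, %.4g) so that b < k", dmax),
         call. = FALSE)
  d * k / (phi + 1)^(1 / phi)
}

#' Carrying capacity calibrated from observed equilibrium catch
#'
#' Treats the observed mean annual total catch `h` as the steady-state
#' harvest of a Pella-Tomlinson stock held at depletion `d`, and solves the
#' equilibrium condition `h = pt_growth(b)` with `b = d*k/(phi+1)^(1/phi)`
#' for the carrying capacity:
#' `k = h/(g*d) * phi * (phi+1)^(1/phi) / (phi + 1 - d^phi)`.
#' At `d = 0.8` the leading factor `1/d` is the familiar 1.25. The
#' calibration is exact by construction: plugging the implied biomass back
#' into [pt_growth()] returns `h`.
#'
#' @param h Mean annual total catch (tons/year), `> 0`. Vectorized.
#' @param g Intrinsic growth parameter (1/year), `> 0`.
#' @inheritParams biomass_from_depletion
#' @return Carrying capacity `k` (tons).
#' @export
k_from_catch <- function(h, g, phi = 0.188, d = 0.8) {
  check_positive(h, "h")
  check_positive(g, "g")
  check_positive(phi, "phi")
  dmax <- (phi + 1)^(1 / phi)
  if (any(!is.finite(d)) || any(d <= 0) || any(d >= dmax))
    stop(sprintf("`d` must lie in (0, %.4g)", dmax), call. = FALSE)
  h / (g * d) * phi * (phi + 1)^(1 / phi) / (phi + 1 - d^phi)
}
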