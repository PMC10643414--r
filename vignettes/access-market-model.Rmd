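---
title: "The fishbloc access-market model: mechanics, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fishbloc access-market model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishbloc)
```

## The market mechanism

`fishbloc` models the international market for fishing access as a bilateral
oligopoly in the Hendricks–McAfee tradition: a small number of coastal
states (sellers) and distant-water fishing nations (buyers) simultaneously
submit *reports* of their endowments — biomass b̂ and fleet gross tonnage
t̂ — to a clearing mechanism that is efficient *conditional on the reports*.
Market power is exercised entirely through strategic under-reporting; the
report is a modelling device for bargaining leverage, not a claim about
actual negotiation tactics.

With constant elasticities, the seller's opportunity cost of supplying
access is $b \cdot c(q/b)$ with $c(z)=\frac{\eta}{\eta+1}z^{(\eta+1)/\eta}$
(convex: the more of its stock a country sells off, the more future growth
it foregoes per ton), and the buyer's fishing profit is $t \cdot v(q/t)$
with $v(z)=\frac{\epsilon}{\epsilon-1}z^{(\epsilon-1)/\epsilon}$ (concave:
permits are worth less to a fleet already fishing near capacity). Equating
marginal cost and marginal value yields the closed-form clearing rules
implemented in `clearing_price()` and `clearing_quantity()`, and each
agent's first-order condition is a polynomial in its own report whose
unique economically relevant root lies in $(0, \text{true value}]$
(`seller_best_response()`, `buyer_best_response()`).

**Elasticity defaults.** $\eta = 1$, $\epsilon = 2$ — each one unit above
its admissible lower bound ($\eta > 0$, $\epsilon > 1$). Both are
dimensionless curvature parameters; robustness runs use
$\eta \in \{0.5, 1.5\}$ and $\epsilon \in \{1.5, 2.5\}$, and
`sweep_scenarios()` crosses these grids automatically.

## Solving for the Nash equilibrium

The literature this model comes from does not prescribe a fixed-point
scheme, so the package makes one explicit and documents it:

* synchronous best-response iteration — every agent responds to the
  previous round's rival report sums;
* truthful reports as the starting point;
* relative tolerance $10^{-10}$ on the report vector, at most 10,000
  sweeps;
* a damping factor of 0.5 engaged only when successive update steps point
  in opposite directions (oscillation), which in practice never triggers at
  the default elasticities.

Reports on one side depend only on same-side rivals (the rival side enters
the objective only through the clearing functions, which drop out of the
first-order condition), so the seller and buyer subgames are solved
independently. The test suite verifies this numerically rather than
assuming it, and also confirms that the fixed point is reached from random
initializations and that every equilibrium report maximizes its agent's
profit against a 10,000-point brute-force grid.

Two root-finding paths coexist deliberately. The exported best responses
bracket the first-order polynomial on $(10^{-12}\,b,\ b]$ and call
`uniroot()`; the policy-function machinery, which re-solves the seller side
thousands of times, uses a vectorized safeguarded-Newton iteration on the
same polynomials (Newton steps confined to a shrinking bisection bracket,
so convergence is guaranteed). Tests pin cold-start agreement between the
two paths.

## Biology and calibration

Each selling country carries one aggregate Pella-Tomlinson stock —
deliberately coarse; modelling individual stocks within a country is out of
scope. Growth is
$\frac{\phi+1}{\phi}\,g\,b\,(1-(b/k)^\phi)$, with $\phi = 0.188$ for all
countries so that maximum growth occurs at 40% of carrying capacity
(`bmsy_from_k()`); $\phi$ is overridable per stock. Because biomass
estimates are largely unavailable for the stocks of interest, biomass is
pinned by an assumed depletion $d = b/b_{MSY}$, default 0.8 (partially
depleted), with 0.6 and 0.4 as pessimistic variants and 1.3 for healthy
(Pacific tuna) stocks. Carrying capacity then follows from treating the
observed mean annual total catch $h$ as a steady-state harvest:
`k_from_catch()` inverts the equilibrium condition in closed form, for any
admissible $d$, and the calibration is exact by construction —
`pt_growth()` at the implied biomass returns $h$ to machine precision. The
closed form is stated in the source only for $d = 0.8$; the general-$d$
version implemented here reproduces it exactly at $d = 0.8$ (a unit test).

The market is solved in dimensionless share units: biomass and tonnage are
normalized by `normalize_shares()` (last share set by complement, so the
side sums to 1 exactly). Converting model outputs back to tons and USD uses
two linear-through-origin anchors (`unit_scales()`): one equilibrium
quantity known in both model units and tons/year, and one equilibrium fee
known in both model units and USD/ton. In the African-market configuration
the quantity anchor comes from one transparent buyer — the EU publishes its
access agreements — whose known annual purchase divided by its equilibrium
purchase share gives the market total; profit, being fee × quantity units,
converts by the product of the two factors.

Participant identification applies a strict hours-threshold rule
(`identify_participants()`, default 2,420 h) to pairwise flag-by-EEZ
fishing-hours tables, and fleet capacity sums gross tonnage over
distant-water vessels, defined as fishing strictly more than half their
hours outside their flag state's EEZ (`classify_dwf()`; an exact 50/50 tie
is *not* distant-water, reading "more than half" strictly).

## Policy functions

A country's access policy function answers: at a given stock size, how much
access catch would the market equilibrium allocate to it? It is traced
numerically: replace the country's biomass with each value of a grid,
rescale its model share in proportion (`rescale_share()` — other countries'
shares untouched, so the model's total "true" biomass departs from 1),
re-solve the Nash equilibrium, and record the country's share of the
converted total quantity. Between grid points the tabulated curve is
evaluated by linear interpolation; extrapolation beyond the grid is an
error rather than a guess.

Grid choices, made once and used everywhere:

* start at 1% of the relevant carrying capacity ("near-zero"), step 1%
  (`grid_pct` is configurable);
* the grid ceiling is the relevant *carrying capacity* — the country's own
  $k$ in the status quo, the summed $k$ for the continental cartel, the
  regional summed $k$ for regional cartels. A biomass-based ceiling would
  be too short: a coalition's equilibrium biomass exceeds the status quo
  biomass, and evaluating the policy there would require forbidden
  extrapolation. Using carrying capacity uniformly also makes the nesting
  identities exact: singleton regions reproduce the status quo curves, and
  a single all-country region reproduces the continental curves, to
  machine precision.

Buyer-side reports are analytically invariant to seller perturbations, so
they are computed once per run; the invariance is verified in the test
suite rather than assumed.

Non-access catch (domestic plus unauthorized foreign) is modelled as linear
in biomass through the origin — access policies come out close to linear,
the linear form needs only one free parameter, and a zero-biomass stock
supports zero catch. The slope $(h - q^*)/b$ makes access plus non-access
reproduce the observed catch exactly at the calibrated biomass. A country
whose equilibrium access catch exceeds its observed total catch would get
a negative slope; `repair_negative_slope()` replaces it with the mean slope
of the other countries. Non-access policies are held fixed across
scenarios: whether cartelization would pivot them up (less deterrence of
illegal fishing) or down (more) is a behavioural question the model
deliberately does not answer, and the sign of the resulting bias is
documented rather than modelled.

## Equilibrium biomass

Counterfactual biomass is the *stable* intersection of the total-catch
policy with the growth curve: growth exceeds harvest below it, harvest
exceeds growth above it. The solver scans the policy grid (clipped to
$k$) for sign changes of growth-minus-policy from positive to negative
(values within $10^{-9}$ of scale count as zero, which matters because the
status quo difference is exactly zero at the calibrated biomass), then
bisects the interpolated curves to a tolerance of $10^{-6} k$. Zero stable
crossings, or more than one, raise an error that names the country and
reports the curve range — never a silent tie-break. Transient dynamics
between the old and new steady states are out of scope; all comparisons
are across steady states.

The status quo run doubles as the pipeline's regression test: each
country's recovered equilibrium biomass must equal its calibrated biomass
to within one grid step, and the test suite enforces this on twenty seeded
synthetic markets.

## Scenarios

* **Status quo** (`run_status_quo()`): all sellers individual. Anchors the
  unit scales, fits non-access slopes, derives policies, recovers
  equilibria. Its summary is priced by one extra Nash solve at the
  emergent (recovered) shares so that every scenario is summarized by the
  same rule; this leaves the anchored fee unchanged to about $10^{-6}$
  relative.
* **Continental coalition** (`run_continental()`): one merged seller.
  Total access is apportioned to countries in proportion to status quo
  true biomass (reported shares no longer exist for individual members).
  The coalition's true biomass share — its equilibrium biomass over the
  status quo total — is an *output* of the policy/growth intersections,
  never an input, and the final solve at that share prices the coalition.
* **Regional coalitions** (`run_regional()`): one seller per region, with
  within-region apportionment by regional biomass share. The
  `assign_regions()` rule maps countries that belong to several overlapping
  communities to exactly one: iterate communities in ascending size order,
  assigning not-yet-assigned members; ties in size are broken
  alphabetically and flagged; explicit overrides handle reassignments and
  exclusions; countries in no community sell individually as singletons.
* **Cartel dissolution** (`run_pna()`): the observed state is the
  coalition, the counterfactual is individual selling; anchors come from
  the coalition's observed fee and access catch (a configurable fraction
  of foreign catch, since access-specific catch records do not exist), and
  apportioned access that exceeds a member's observed catch triggers the
  slope repair.
* **Robustness** (`sweep_scenarios()`): full re-runs over grids of
  $\eta$, $\epsilon$ and depletion; the hours-threshold variant is a
  rebuild of the input tables upstream.

## The synthetic-data generator

`gen_market()` emulates the *structure* of the real inputs — log-normal
(right-skewed) catch and tonnage so that a few countries dominate each
side, uniform growth parameters in a realistic 0.15–0.45/yr band, a
median-country catch near 150,000 t/yr so a 32-country continent totals
roughly 10 Mt/yr, an anchor buyer holding 11.5% of tonnage, a $128.20/ton
fee anchor, and access catch near 21% of total catch. `gen_hours()`
fabricates hours and vessel tables with a planted answer key so
identification and classification are testable end-to-end. What the
generator does **not** emulate: the actual country-level endowments of any
real market, spatial fishing patterns, or multi-stock structure within
countries. Passing tests on synthetic markets therefore validate the
*machinery and its comparative statics* (the directions: cartels cut
access catch, raise fees, raise seller profit and biomass), not the
magnitudes of any particular published table, which require the deposited
study data.

## Numerical choices and degenerate inputs

* Best-response brackets: $(10^{-12}\,\text{true},\ \text{true}]$; a
  missing sign change is an error naming the inputs.
* Fixed point: relative $10^{-10}$, max 10,000 sweeps; non-convergence is
  an error with per-side iteration counts, never a silent partial result.
* Equilibrium bisection: $10^{-6} k$; zero-band $10^{-9}$ of the growth
  scale.
* Monopoly/monopsony (single-agent sides) use the closed-form report and
  are fully supported — the coalition scenario requires them.
* Shares sum to exactly 1 by setting the last share as the complement.
* A DWF tie at exactly half the hours is non-DWF; a vessel with zero
  recorded hours is non-DWF with a warning; an empty hours table yields
  empty participant sets with a warning, not an error.

## Problem sizes

The shipped tests run the full pipeline on synthetic markets of 2–8
sellers for the policy-and-equilibrium stages (where each policy function
costs ~100 market re-solves), the 27-point elasticity–depletion sweep on a
5×5 market, and single Nash solves up to 400 agents a side; these sizes
exercise every code path while keeping the default suite to a few minutes.
The full 32×33 configuration runs in well under a minute per scenario via
the vectorized solver.

## Known limitations

* One aggregate stock per country; no age structure, no transboundary
  movement, no species detail.
* Steady-state comparisons only; no adjustment-path welfare.
* Non-access policies are exogenous lines; behavioural responses of
  domestic and illegal fishing to cartelization are assumptions, not
  results.
* At depletion 0.8 the calibrated catch sits at ~97.5% of MSY. A country
  whose non-access slope has been repaired (apportioned access above
  observed catch) can then have a total policy above its growth curve at
  every biomass — no steady state exists and the equilibrium solver
  errors. This is a structural feature of near-MSY calibration, not a
  solver failure; with healthy stocks (depletion 1.3) the same repair
  admits a stable crossing, and that is the configuration the repair tests
  use.
* Coalition formation itself — who joins, side payments, enforcement — is
  out of scope, as are auction-style selling mechanisms.
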