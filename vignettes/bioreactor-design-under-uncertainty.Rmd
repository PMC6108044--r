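---
title: "Hollow-fiber bioreactor design under uncertainty: models, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hollow-fiber bioreactor design under uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemodesign)
```

This vignette is the package's account of its science: the coupled
model it scores, the methods layered on top of it, the parameters that
matter, the numerical choices behind the solvers, and what the test
suite does and does not demonstrate.

## The system

A dual hollow-fiber bioreactor grows red blood cells (RBC) from
hematopoietic progenitors seeded in a 3-D scaffold. Two interleaved
fiber sets thread the scaffold: polymeric set A perfuses nutrients
(glucose, oxygen) and clears lactate; ceramic set B runs a closed
recycle loop for the expensive growth factors (GFs) erythropoietin
(EPO) and stem cell factor (SCF) and harvests product cells through its
membrane. A design decision fixes the number of parallel reactors, the
fiber counts and types, the reactor geometry, the per-fiber flow, the
feed concentrations, the seeding density and the culture horizon
(default 30 days). The objective is cost per transfusion unit of RBC,
taken as 2×10^12 cells (configurable; the count is a convention, not a
measurement).

## Cell kinetics

The default model is a linear compartment chain HSC → progenitor →
RBC. The Gran/Leuk lineages are pooled into the progenitor compartment
(the main-text biology does not pin down the full branching graph; the
four-type split is retained for metabolic bookkeeping, with the pooled
compartment reported 50/50). Each compartment obeys

$$\frac{dN_c}{dt} = \beta_c(G)\,N_c - \kappa_c N_c - \delta_c N_c
  + A_{c-1}\,\kappa_{c-1}\,N_{c-1},$$

where $\beta_c(G) = \beta_{\max}\,G^{n}/(\theta^{n}+G^{n})$ is a
Hill-type response to the compartment's driving growth factor (SCF for
HSC, EPO for progenitors; default $n=1$, a Monod form — the Hill
exponent is exposed because published hematopoiesis models use both
saturating and switch-like variants), $\kappa$ is the differentiation
rate into the next compartment, $\delta$ the death rate, and $A \ge 1$
the amplification (progeny per differentiating cell, applied to the
flux *into* the receiving compartment).

Integration is explicit Euler at `dt = 0.01` day. The scheme is
first-order (verified empirically: halving `dt` halves the error
against a fine-step reference) and exactly conservative in the
bookkeeping sense: differentiation outflow of one compartment equals
the unamplified inflow of the next at every step, and with
$\delta = 0$ the cumulative amplified inflow into RBC equals harvested
plus standing RBC to within floating-point rounding — a closure the
test suite asserts at `1e-10` relative. A step-size guard rejects
`rate * dt > 0.5`; the guard is applied to each compartment's own
turnover rate $\beta+\kappa+\delta$ rather than to the realized
relative change, because a near-empty compartment receiving inflow
legitimately multiplies its density in one step. Densities that
undershoot zero in extreme parameter corners are clamped at zero with a
warning rather than aborting, so robustness scans can visit those
corners.

### The alternative ("suspension culture") preset

Model uncertainty is probed by swapping the kinetics preset. The
alternative preset represents a pessimistic 2-D suspension-culture
bound: identical structure, proliferation and nutrient demands, but the
erythroid amplification `amp_prog` attenuated to 85%. The attenuation
acts linearly on output (fewer RBC per differentiating progenitor)
while leaving cell numbers — and hence nutrient delivery and waste
clearance needs — essentially unchanged. That is precisely the regime
in which a model exchange should raise the cost per unit by an
order-10% amount *without* moving the transport-side design decisions,
which is what the acceptance suite checks. Attenuating proliferation
instead would compound exponentially over a 30-day campaign and
represent a different (catastrophic) scenario, not a bounding model.

## Krogh-cylinder transport

Each fiber set is assumed to tile the cross-section evenly, so one
fiber of a set serves a concentric annulus of radius
$R_k = \sqrt{A/(\pi n)}$ with no flux at $R_k$ (the sets tile
independently; species on set B are unaffected by set A's geometry and
feeds — a superposition the tests assert). Within a day the transport
is treated as quasi-steady: diffusion across millimetre annuli
equilibrates in minutes while the cell populations evolve over days.

Per species and day the solver composes:

1. **Axial lumen balance** (plug flow of the cross-section-averaged
   Poiseuille stream): $dC/dz = -e(z)/Q$, trapezoid-integrated on a
   uniform grid of 101 points, clamped at zero with a starvation flag
   and exact accounting of the realized extraction.
2. **Membrane resistance**, lumped into a permeability: the wall
   concentration is the lumen mean minus (area flux)/permeability.
3. **Radial annulus profile.** For constant volumetric uptake $q_0$
   the closed form
   $C(r) = C_w + \frac{q_0}{4D}(r^2 - R_o^2)
   - \frac{q_0 R_k^2}{2D}\ln(r/R_o)$
   with truncation at zero and an anoxic flag. A Michaelis–Menten
   variant solves $\frac{1}{r}\frac{d}{dr}(rD\frac{dC}{dr}) =
   \frac{V\rho\,C}{K_m + C}$ by second-order finite volumes (Picard
   linearization, tridiagonal solves); the half-cell at the no-flux
   boundary is discretized as a half control volume, which is what
   keeps the scheme second-order there. Both agree with an independent
   two-point BVP oracle to 1e-6 relative on random parameter draws.
4. **Limited fraction** $\varphi$: the volume-weighted fraction of the
   annulus below a critical concentration (above a toxicity ceiling
   for lactate, the produced species, which reuses the same machinery
   with the sign flipped).

The local uptake depends on the local concentration and vice versa;
that fixed point is iterated with 0.5 damping (up to 20 rounds,
tolerance 1e-4 of feed) because the anoxic truncation makes the
undamped iteration oscillate at high cell density.

Proliferation is attenuated by the nutrient-limited volume:
$\beta \to \beta\,(1 - \max(\varphi_{O_2}, \varphi_{Glc}))$ — cells in
starved scaffold do not proliferate.

## Harvest and cost

Product cells exit through set-B membranes at
`rate = J_cells * area * (rho_RBC / rho_ref)` with
`rho_ref = 1e6 cells/mL`. `J_cells` is the single most consequential
uncertain parameter in the default configuration: the default regime
is deliberately harvest-limited (standing RBC density is set by the
balance of production against trans-membrane flux), consistent with the
experimental observation that cells are impeded from crossing ceramic
fibers. This is why the univariate scan ranks `j_cells` first and why
the robust counterpart hedges with more ceramic fibers.

Growth factors decay with half-life $\tau$ (`C(t) = C_0 2^{-t/\tau}`)
and are topped up to the feed level daily; the replaced mass times the
unit price is the GF cost, which dominates the consumables. The daily
effective concentration seen by the cells is the decay average
$C_{feed}\,\tau/\ln 2\,(1 - 2^{-1/\tau})$. Cost decomposes exactly
into EPO + SCF + media + materials, and every extensive quantity is
linear in the reactor count, so cost per unit is invariant under pure
parallelization (asserted to 1e-10).

## Parameter registry and defaults

All 30 uncertain parameters live in one registry
(`default_registry()`) with nominal value, unit, group and uncertainty
class: `measured_box` for the six material properties (diffusivities,
membrane permeability; ±10% boxes) and `level_set` (50/90/110/150%
levels) for the rest. The nominal values are documented placeholders at
literature-plausible orders of magnitude — each `description` says so —
and none of the package's validity checks depend on their exact values.
Choices worth explaining:

* `vmax_o2 = 1e-17 mol/cell/s`: erythroid cells are largely
  glycolytic; with this uptake a moderately dense culture is near the
  oxygen-limitation boundary, so the oxygen constraint is active but
  not hopeless — the regime where design actually matters. The default
  grid therefore includes the 2x-atmospheric oxygen feed (0.4 mol/m³)
  as a design option.
* `j_cells = 2e5 cells/cm²/day` puts the default designs in the
  harvest-limited regime discussed above.
* Ceramic fibers are priced well above polymeric ones (0.20 vs 0.05
  USD amortized per campaign): specialty ceramic hollow fibers are the
  expensive component, and this is what makes the ceramic-fiber count
  an interior optimum that the robust counterpart can move.
* GF prices and half-lives are set so that a 30-day campaign's cost is
  GF-decay-dominated, the qualitative structure the cost model is
  meant to capture.

Dollar figures produced with these placeholders are internally
consistent but not literature values; all acceptance checks on the
optimizer are therefore directional or structural (ordering,
invariance, monotonicity), never dollar targets.

## Superstructure optimization

The design space is a declared grid (`design_grid()`); the search is
exhaustive enumeration in deterministic lexicographic order, which is
exact *on the declared grid* and needs no algebraic structure from the
evaluator. Ties resolve to the lexicographically smallest design by
construction (strict-improvement search in lexicographic order).
Optional pruning takes a user-supplied lower bound and must — and is
tested to — reproduce the exhaustive answer exactly. Two-level nested
grid refinement (`refine_grid()`, factor 5) is available for
continuous variables. The default grid is kept under 100 designs so a
full optimization runs in well under a minute; a general mixed-integer
nonlinear solver is out of scope by design — exactness on a declared
grid is easier to audit than a claimed global optimum on a continuous
relaxation.

## Robust counterpart

Uncertainty is an independent per-parameter box (no correlation
structure is claimed anywhere); the robust problem minimizes the
worst-case objective over designs that are feasible under every probed
realization (constraint-wise worst case, the standard static
counterpart). `vertex_enum` evaluates all extreme-multiplier
combinations plus the nominal point — exact whenever the response is
coordinatewise monotone, which holds for the flux/half-life
uncertainties used in the default fixtures — and is capped at 12
parameters (2^k growth); beyond that, `coordinate_probe` picks each
parameter's adverse extreme independently, a conservative heuristic
that never reports below the nominal evaluation. Chance constraints
are deliberately out of scope: the worst case is the analysis of
record.

On the default fixture the mechanism is visible and physical: with the
trans-membrane flux halved in the worst case, designs with fewer than
20 ceramic fibers become oxygen-infeasible (standing RBC accumulates)
and the robust optimum moves from 16 to 28 ceramic fibers.

## Sensitivity analysis

Because the design variables are discrete, shadow prices are
meaningless here; and a full variance-based global analysis at ~300 s
per optimization is out of budget (the package's `scan_budget()`
reproduces that arithmetic: 435 parameter pairs at four levels is
24.2 CPU-days). The package instead implements one- and two-at-a-time
elementary effects *of the optimizer output*:
$\Delta = (f^*_{perturbed} - f^*_{nominal})/f^*_{nominal}$ at levels
{0.5, 0.9, 1.1, 1.5}, flagged at $|\Delta| \ge 10\%$, and
$S_{ij} = \Delta_{ij} - \Delta_i - \Delta_j$ per level pair, flagged at
$|S_{ij}| > 15\%$ (aggregation over level pairs by the maximum, the
most conservative choice). $S_{ij}$ is exactly zero for any
linear-in-parameters response — the built-in linear toy fixture checks
this to machine precision, and the multiplicative toy pins the hand
value $S = 0.25$ at (1.5, 1.5). Infeasible perturbations are recorded
as such, never dropped. Full 435-pair scans are supported; the test
suite exercises reduced parameter sets so it runs in seconds.

## Explicit-geometry cross-section solver

The Krogh assumption — evenly spaced, non-interacting fibers — is
stress-tested by solving $D\,\nabla^2 C = q(C)$ on real cross-section
geometries with arbitrary fiber placement. Numerical choices:

* 5-point finite differences on a uniform Cartesian grid, assembled
  sparse and solved directly (`Matrix`); a direct solve is
  deterministic and exact, where a point-iterative relaxation sweep in
  interpreted R would be orders of magnitude slower.
* Fiber walls (Dirichlet) use Shortley–Weller fractional-spacing
  stencils — plain rasterization would cap the scheme at first order.
* The circular no-flux reactor wall uses a ghost closure derived from
  the boundary condition itself: through each exterior ghost the
  radial profile is modelled as $c_0 + c_2 s^2 + c_3 s^3$ in the wall
  distance $s$ (no linear term, because the normal flux vanishes),
  fitted through three interior samples at $s = -h, -2h, -3h$ obtained
  by quadratic least-squares interpolation. The closure error is
  $O(h^4)$ *before* the $1/h$ flux amplification at the wall — this
  matters: any $O(h^2)$ ghost-value error acts as a spurious wall flux
  and demotes the whole field to first order. With it, the solver
  converges at second order to the single-fiber Krogh analytic
  solution (error ratios ≈ 4 per halving of `h`; asserted in the
  acceptance suite).
* Nonlinear uptake is solved by damped Newton iteration with step
  halving; the hard anoxic cut-off of constant uptake is an
  obstacle-type problem and is regularized as Michaelis–Menten uptake
  with a half-saturation of 1e-3 of the wall concentration — the
  reaction interface this smears is far thinner than a grid cell.

The validity check mirrors the qualitative finding that motivates
keeping the Krogh model: at matched fiber density (0.2 fibers/mm², in
the reactor's 0.15–0.25 range) and a moderately limited regime
(`q0 = 4e-4 mol/m³/s`, hypoxic-proliferation threshold 0.08 mol/m³,
where the Krogh limited fraction is ≈ 0.5 and well-conditioned), the
gap between the evenly spaced explicit solution and the Krogh
prediction (≈ 0.01) is an order of magnitude smaller than the spread of
the explicit solution across ten random placements (≈ 0.1–0.3).
Placement uncertainty, not the Krogh reduction, dominates — so
placement variability is best handled as parameter uncertainty, which
is exactly what the robust module does. The deep-anoxia regime is
deliberately avoided in this comparison: there the zeroth-order Krogh
profile is flat near $R_k$ and its limited fraction is an
ill-conditioned function of the threshold, so the comparison would
measure threshold conditioning rather than geometric validity.

## Market and labor analysis

`npv()` is the plain discounted sum $\sum_t R_t/(1+i)^t$. The
rare-blood market is built from three segments — current US rare-blood
usage uplifted for availability and scaled by the First-World/US
population ratio (6.25), one shortage-day's worth of the total
transfusion market at the affected hospital fraction, and a military
demand — summed exactly before any display rounding. Scenario payouts
use declared conventions: year-end flows, development outlays in years
1..`dev_years` not success-weighted, revenues in the remaining years
weighted by the clinical-success probability, discounted at 11%. These
conventions are configurable because the printed payouts in the source
analyses are not exactly recoverable under any single standard
convention; under the declared defaults the $225-price scenario lands
within the ±25% bracket the tests assert. The labor model is the
fabrication/culture activity table with the 8-hour person-day rule
(`person_days = days × hours/8`), closing to 22.8125 person-days and
69 timeline days; one operator cycles two parallel bioreactors every
48 days, i.e. ⌊365/48⌋ = 7 duplicate experiments per operator-year,
and a five-factor corner-point characterization campaign is 2⁵ = 32
runs.

## Problem sizes and determinism

The shipped configurations are sized for interactive use: campaign
simulation ≈ 0.1 s; the 96-point default grid optimizes in ≈ 12 s; the
robust fixture (10 designs × 5 vertex realizations) in ≈ 40 s;
cross-section solves at `h = R/60` in ≈ 2 s each. Every stochastic
path (layout sampling) requires an explicit seed and restores the
global RNG state; everything else is deterministic, and rerunning any
subcommand with identical inputs reproduces identical outputs.

## What the tests do and do not show

The synthetic defaults emulate the *structure* of the real problem —
GF-cost-dominated consumables, harvest-limited product flux, an active
oxygen constraint, fiber-count/geometry trade-offs — with placeholder
magnitudes. Passing tests therefore demonstrate correctness of the
solvers against independent oracles, exactness of the printed
arithmetic (market, budgets, labor), and the directional/structural
claims (robustness ordering, model-exchange stability, Krogh
validity). They do not validate the placeholder nominals against a real
bioreactor, do not cover transient transport, pressure-driven
trans-membrane flow, delay or cell-cycle-structured kinetics, or
correlated uncertainty sets — all declared out of scope. Dollar outputs
should be read as internally consistent model quantities, not
price predictions.
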