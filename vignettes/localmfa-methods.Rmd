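---
title: "Local INST-MFA: models, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local INST-MFA: models, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
labeling model, the three local flux estimators, the synthetic study
conditions, and the numerical and design choices that were genuinely open.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The labeling model

A network is a set of metabolites (each with a count of labelable atoms
and a pool size, in arbitrary concentration units) and reactions with
signed stoichiometry and 1-based atom-transition maps. Time is in minutes
and fluxes in pool-units·min⁻¹ throughout; experimental units such as
mmol·gDW⁻¹·h⁻¹ are a linear rescaling left to the user. Reversible
reactions carry two nonnegative flux values (forward and backward), since
the backward flux is itself an estimation target. Source metabolites hold
a fixed mass isotopomer distribution (MID) — the fully labeled nutrient —
instead of dynamics.

For every non-source metabolite $Z$ with pool $P_Z$ the MID vector obeys

$$\frac{d\,\mathrm{MID}_Z}{dt} \;=\; \frac{1}{P_Z}\Big[\sum_{j \in
\mathrm{prod}(Z)} v_j\,\mathrm{MID}^{(j)}_{\to Z}(t)\;-\;\Big(\sum_{c \in
\mathrm{cons}(Z)} v_c\Big)\,\mathrm{MID}_Z\Big],$$

where the transferred MID of a producing reaction follows the atom map: a
unimolecular conversion passes the substrate MID through, a condensation
contributes the convolution of its substrate MIDs, and a cleavage
contributes the marginal MID of the inherited atom subset. At steady
state production equals consumption, so each MID stays normalized; the
simulator (`simulate_labeling`) integrates the assembled system with
lsoda at relative tolerance $10^{-8}$ and absolute $10^{-10}$, reflecting
the wide spread of labeling time scales across pools.

**The MID-level closure.** The state is one MID per metabolite (dimension
$\sum_Z (n_Z+1)$), not the full isotopomer distribution. A cleavage then
needs the marginal labeling of an atom *subset*, which a MID determines
only under the assumption that, within each mass class, all positional
isotopomers are equally likely (hypergeometric thinning,
`mid_marginal`). This is exact for exchangeable positions and an
approximation otherwise; with at most two atoms per metabolite in the
packaged scenarios the error is negligible, and the estimators use the
same closure as the simulator, so comparisons are internally consistent.
Tracking full isotopomer vectors ($2^n$ states) would remove the
approximation at exponential cost and is intentionally out of scope, as
is the elementary-metabolite-unit decomposition used by global methods.

## Sampling grids and measurement noise

The dense reference grid is logarithmic,
$t_i = 10^{(i-1)\log_{10}(H+1)/(n-1)} - 1$, which for $n = 161$ points
over a 15-minute horizon places the second sample about one second after
label introduction and the second-to-last about sixteen seconds before
the end. Measurement datasets are index-even subsamples (always keeping
the first and last grid point) of 6, 11, 21 or 81 points. Measurement
error is independent Gaussian noise per MID fraction with a default
standard deviation of 0.01 (absolute) — the magnitude against which a
0.01 enrichment difference is invisible — followed by clipping to
$[0,1]$ and renormalization of each (metabolite, time) MID.
Renormalization projects out the common noise mode: for a balanced
two-class MID the effective standard deviation is $0.01/\sqrt2$, which is
what the tests assert. Whether noise should perturb enrichments or each
fraction independently is not determined by the study design;
per-fraction noise was chosen.

## The three estimators

**KFP.** The unlabeled fraction of a product pool follows
$u(t) = \rho + (1-\rho)\,c_0 + (1-\rho)c_1\frac{k}{k-a}e^{-at} +
C\,e^{-kt}$ for a substrate unlabeled fraction $c_0 + c_1 e^{-at}$ (the
complement of a reversed-exponential-decay enrichment input), with
$u(0)=1$ fixing $C$ and a confluent limit at $k \to a$; instant labeling
reduces it to $\rho + (1-\rho)e^{-kt}$. `kfp_estimate` fits $(k, \rho)$
by bounded Levenberg–Marquardt on the closed form (no integration); the
analytic solution is pinned against numeric integration of the motif ODE
in the tests. The flux through the pool is $k P$; it equals a reaction
flux only for sole-producer products, which is how benchmark eligibility
is derived. Estimates with the rate at its bound are flagged
non-converged rather than hidden.

**NSMFRA.** The junction ODE is linear in the branch inputs; the fit runs
over all mass classes simultaneously, with the branch inputs supplied as
fitted analytic curves, interpolated MID series, or (for a condensation
branch) the convolution of two substrate inputs. Without the junction
pool size only the flux ratio and the turnover are identifiable — the
package returns exactly those, and absolute $v_1, v_2$ only when $P_Z$ is
given. Pointwise-identical branch inputs are rejected as unidentifiable,
and a branch estimated at (effectively) zero flux is flagged as a
boundary solution. Mass classes are unweighted in the objective; a
variance-weighted option was considered and left out because the default
noise model is homoscedastic per fraction.

**Subsystem estimation.** A subsystem is a reaction subset; every
metabolite feeding it from outside must carry a fitted input function.
Internal metabolites whose producers and consumers all lie inside the
subsystem contribute steady-state balance rows, and the flux space is
parameterized by the free fluxes of the reduced row echelon form of that
stoichiometry — for the fully coupled pair this collapses to a single
free flux automatically. The objective is the summed squared difference
between simulated and measured MID fractions over the internal
metabolites, minimized by multi-start bounded Levenberg–Marquardt (first
start at unit flux, further starts log-uniform in $[10^{-2}, 10^2]$,
bounds $[0, 10^3]$); dependent fluxes driven negative are penalized.
Because every subsystem the planner builds here is feed-forward, the
internal MIDs satisfy linear ODEs with known forcing and are solved
metabolite-by-metabolite with an exact update for piecewise-linear
forcing on a 4-fold refined grid — about 25× faster than stiff
integration, agreeing with it to ~10⁻⁵, and smooth in the fluxes (which
the finite-difference Jacobian of the optimizer needs; the optimizer's
difference step is likewise set above the solver noise). Cyclic
subsystems fall back to lsoda.

**Enrichment inputs for multi-atom metabolites.** Input functions are
fitted to the mean labeled fraction. For a multi-atom input the MID is
reconstructed binomially (independent, equally enriched positions) —
exact when the condensation substrates are equally enriched, and a close
approximation in the packaged network where the two branches feeding the
condensation are parallel paths from the same precursor.

## Input-function fitting and model selection

Three kinds are registered — the 4-parameter logistic
$A + (K-A)/(1+e^{-r(t-t_0)})$, the 7-parameter double logistic
$A + B_1/(1+e^{-r_1(t-t_{01})}) + B_2/(1+e^{-r_2(t-t_{02})})$, and the
3-parameter reversed exponential decay $b + (P-b)(1-e^{-kt})$ — with
levels bounded in $[0, 1.2]$, rates in $(0, 100]$ and centers in
$[-H, 2H]$; the registry is extensible. The exact functional forms are
this package's choice of the canonical parameterizations; any monotone
reparameterization satisfying the same invariants would do. Fitting is
by global-best particle swarm
optimization (swarm 30, 200 iterations, inertia 0.72,
cognitive = social = 1.49, 10 independent starts by default — standard
literature values, all configurable). PSO is the sole optimizer, as in
the procedure this reimplements; it reaches SSE below $10^{-13}$ on
noiseless self-fits, so no derivative polish is applied. Rates pinned at
the upper bound mark step-like fits and are flagged.

`select_input` fits each kind and selects by SSE, with two provisions.
First, when the double logistic is fitted after the logistic, the best
logistic solution (second term off) is injected into the swarm, so
$SSE_{dl} \le SSE_{log}$ holds by construction. Second, because of that
guarantee, raw minimum-SSE selection would always return the double
logistic; selection therefore applies a parsimony margin: a higher-arity
kind is preferred only if it reduces the SSE by more than 10%
(relative), chosen a priori from the sampling fluctuation of a noisy SSE
($\sqrt{2/(n-p)} \approx 30\%$ at $n = 21$), so sub-fluctuation gains
never promote the richer model. A known consequence, measured
systematically during development and documented rather than tuned away:
with both models optimized well, the double logistic genuinely reduces
the SSE by far more than 10% for most smooth one-wave enrichment curves
on the dense log grid (the 4-parameter logistic's model error exceeds the
noise floor there). The often-reported outcome that the logistic wins
almost everywhere arises when the 7-parameter optimization is run without
the injected start and under-converges — a failure mode this
implementation removes by design. What survives robustly is the
qualitative signature: the junction metabolite fed by two delayed paths
is the pool where the double logistic's advantage is largest and most
consistent. Six-point datasets cannot determine the 7-parameter kind; it
is dropped from selection there rather than fitted under-determined.

## Whole-process Monte-Carlo sensitivity

Confidence intervals come from re-estimating on data with freshly drawn
noise. Unlike the estimation-only scheme (which keeps the original input
fits, provided here as `refit_inputs = FALSE`), the default repeats the
*entire* process — input fitting and estimation — per replicate, so
input-fit uncertainty propagates into the intervals; the default is 100
replicates. Intervals are empirical quantiles taken as order statistics
(type 1) at level 0.95 by default, with the median as point summary —
the level and estimator are this package's choice, since the procedure
being reimplemented names neither. Replicate seeds are drawn once from
the master seed, so serial and forked-parallel execution agree
bit-for-bit. Coupled-flux inference (`infer_coupled_fluxes`) derives a
poorly identified flux from well-identified ones preferring, in order: a
full-coupling proportionality with a single known flux, a single node
balance whose other flows are known (this reproduces the printed balance
at the reversible node exactly), and only then a general least-squares
derivation — the general solution is not unique when the known fluxes
are themselves mutually coupled, so the method's actual two rules take
precedence. Intervals for inferred fluxes are obtained by applying the
same linear combination to every replicate.

## The synthetic study conditions

`build_synthetic_scenario()` is deterministic: 17 one-atom metabolites
(including the fully labeled source `S_out`) plus the two-atom `H`,
19 reactions with the single reversible exchange `r6 (C ⇌ D)`, the
condensation `r12 (I + J → H)` and two cleavages of `H`, the fully
coupled pair `r3`/`r7` (through the sole intermediate `G`), the node
balance `v₈ + v₆ᵇ = v₇ + v₆ᶠ` at `D`, converging pairs `r4`/`r9` (at `E`)
and `r17`/`r18` (at `O`), and a 15-minute horizon. The topology is
feed-forward apart from the local `C ⇌ D` exchange, so each pool's
enrichment is a single sigmoid wave except at `O`, whose two feeding
paths (`…→P→F` fast, `…→M→Q→N` slow) have distinct delays — the
double-logistic use case. True fluxes are O(1) pool-units·min⁻¹ and
pools are chosen so turnover times spread over ≈0.15–4 minutes, leaving
the slow pools (`O`, `N`, `Q`, `K`) visibly short of isotopic steady
state at the horizon. Tests assert these structural constraints, not the
incidental flux/pool values, which are otherwise free.

`build_small_difference_scenario()` emulates the failure regime of a
nitrogen-labeling experiment on a whole-plant model: a chain
`S_in → R → P → sink` at flux 0.01 with a slow reactant pool
(τ ≈ 627 min, so enrichment only reaches ≈0.4 over the 320-minute
horizon) and a fast product pool (τ = 5 min), giving a maximal
reactant–product enrichment gap of ≈0.008 — below the 0.01 measurement
noise. The builder simulates the chain, stores the achieved gap and
maximal enrichment, and flags whether the gap lies in the intended band
[0.005, 0.01]; shrinking the product pool a thousand-fold collapses the
gap far below the band and the flag reports it. The horizon is 320
minutes, matching the equidistant 81-point sampling design (4-minute
spacing).

## What the benchmark shows — and limits of the emulation

`run_benchmark` simulates once on the dense grid, subsamples to each
time-point count, and runs the whole-process Monte Carlo per (method,
count) cell, with motif eligibility derived from stoichiometry
(sole-producer products for KFP; two-producer junctions for NSMFRA;
single-reaction, junction and reversible-cluster subsystems for the
subsystem method). The patterns the test suite verifies at reduced
problem sizes (25 replicates for interval widths, 100 for input-fit
spread — sizes chosen to keep the default test run brief):

* input-fit spread (pointwise IQR of 100 refits) shrinks from 6 to 11
  time points, and subsystem CI widths are non-increasing across
  6 → 11 → 21 → 81 for well-conditioned reactions;
* KFP matches the truth with tight intervals for near-source reactions —
  tighter at 6 points than the subsystem method's — but is confidently
  wrong (truth outside a narrow interval) for delayed reactions, where
  the reversed-exponential input model cannot represent the lagged
  enrichment onset;
* the reversible-exchange cluster (`r6`, `r7`) is weakly identified by
  direct fitting and is repaired by the coupling relations;
* on the small-difference scenario the subsystem intervals span orders
  of magnitude and the KFP point estimate is biased several-fold low.

Known limitations, measured during development and left as findings
rather than engineered away: (i) with many time points the whole-process
intervals shrink below the systematic bias contributed by analytic
input-function misfit on fast pools (≈2–4%), so truth-in-interval
coverage is *not* monotone in the number of time points — it rises from
6 to 21 points and degrades again at 81; (ii) on the compliant
small-difference chain KFP's model is exactly correct (the reactant's
enrichment is exactly in the reversed-exponential family) and its rate is
unidentifiable upward at the achievable gap, so KFP fails there by bias
and interval explosion, not by the narrow-but-wrong interval seen on
full-scale plant-model simulations; reproducing the latter exactly would
require the external whole-plant model and is out of scope. The
simulator also emulates neither natural-abundance correction, MS
fragment structure, nor compartment-specific transport — real datasets
carry all three.
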