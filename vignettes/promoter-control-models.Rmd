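---
title: "Dissecting kinetic versus thermodynamic promoter control at a dual-promoter locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting kinetic versus thermodynamic promoter control at a dual-promoter locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The system and the question

The *Bacillus subtilis* sporulation master regulator Spo0A autoregulates its
own transcription. The *spo0A* locus is transcribed from two promoters — an
upstream vegetative promoter Pv read by sigma-A RNA polymerase holoenzyme and
a downstream sporulation promoter Ps read by sigma-H holoenzyme — and carries
three binding sites (0A boxes 0A1–0A3) for the phosphorylated regulator
0A~P between them. A fourth site, 0A4, overlaps the Ps −10 element and
cannot be perturbed without destroying the promoter, so it is outside the
model's scope. Two kinds of measurements inform the model: gel-shift (EMSA)
titrations that give the fraction of DNA fragments bound by 0A~P as a
function of its concentration for each subset of intact boxes, and
beta-galactosidase reporter time courses (hourly, 2–9 h after the onset of
starvation) for a panel of 24 strains — 3 promoter cohorts (both promoters,
Pv only, Ps only) crossed with all 8 subsets of intact boxes.

The question the models answer is *where* 0A~P acts on each promoter: on
the equilibrium probability that RNAP occupies the promoter (thermodynamic
control of recruitment) or on the maximum initiation rate after recruitment
(kinetic control). `spo0Areg` implements both mechanisms for each promoter,
all four combinations, the fitting machinery to decide between them, and
the downstream analyses of the winning fit.

# The binding model

Each 0A box binds N molecules of 0A~P as one cooperative event. At
mass-action equilibrium the bound fraction of a single box is

$$ f(c) = \frac{c^N}{K_h^N + c^N}, $$

so $K_h$ is the concentration at which the box is occupied with 50%
probability and a lower $K_h$ means higher affinity
(`fraction_bound_single()`). For fragments carrying several boxes the
package uses the equivalent statistical-thermodynamic form: each
configuration $s \in \{0,1\}^k$ has weight
$\prod_i (c/K_{h,i})^{N s_i} \prod_{i<j} e^{-\varepsilon_{ij} s_i s_j}$,
and the EMSA observable is the probability that at least one box is bound
(`fraction_bound_multi()`) — any occupied state shifts the band. Energies
are dimensionless (units of $k_BT$) and negative $\varepsilon$ is
attractive. In vitro the interaction energies are fixed at zero: the
multi-box EMSA curves are predicted from single-box constants alone, which
is the minimal model consistent with the assay.

`fit_kh()` estimates $K_h$ per box by least squares on untransformed
bound fractions (they are bounded in [0,1] with roughly homoscedastic
noise in the measured range, so no logit transform is applied), using the
concentrations exactly as measured. Replicate uncertainty is propagated by
a parametric bootstrap (`augment_dataset()`): each augmented dataset
redraws every (subset, concentration) point from a normal law with the
replicate mean and SD truncated to [0,1], and the 2.5/97.5 percentiles
over 1,000 refits give the 95% CI. Points with a single replicate fall
back to a configurable relative SD (default 5%). A nonparametric replicate
bootstrap would be the alternative; with duplicate gels it has only three
distinguishable resamples per point, so the parametric form was chosen.
`select_cooperativity()` refits the curves for candidate stoichiometries
(default 1–6) and picks the lowest summed squared error, breaking ties
toward the smaller N (parsimony). On steep titrations this recovers a
tetramer and a dimer fit is many-fold worse.

# The promoter model

The effective transcription rate is the occupancy-weighted sum of maximum
initiation rates over promoter-bound configurations,

$$ v_\mathrm{eff} = \sum_{\alpha} v_{\max,\alpha} \, P_\alpha . $$

Box configurations are 3-bit strings ("000"–"111", digits = 0A1, 0A2, 0A3;
boxes mutated out of a strain are forced unbound). In vivo, configuration
weights use the same product form as the EMSA model with the cooperativity
exponent `n0a` and fitted interaction energies (`config_weight()`,
`box_occupancy()`). `n0a` defaults to the EMSA stoichiometry N; the two
exponents are kept as separate fields so an in-vivo value differing from
the in-vitro one can be explored.

**Kinetic control.** Binding does not affect RNAP recruitment; it rescales
the maximum initiation rate per configuration through ratios
$\rho(s) \ge 0$ with $\rho(\text{"000"}) = 1$. Only the product of the
RNAP-bound probability and the basal rate is identifiable from reporter
data, so that product is carried as one per-timepoint activity scale
$A(p,t)$ (reporter units/h); this reparameterization removes a
structurally unidentifiable direction rather than pretending to resolve
recruitment and initiation separately. Then
$v_\mathrm{eff} = A(p,t) \sum_s P(s)\rho(p,s)$.

**Thermodynamic control.** Initiation rates are uniform but bound 0A~P
interacts with promoter-bound RNAP through per-box energies $\eta$. The
joint partition function over (box configuration, RNAP state) uses weights
$W(s)\,(R(p,t) \prod_i e^{-\eta_i s_i})^r$ where $R(t)$ is the RNAP
occupancy ratio $[\mathrm{RNAP}]/K_P$, and
$v_\mathrm{eff} = v_{\max} P(\text{RNAP bound})$.

**Dual promoters.** For PvPs strains the partition function runs over the
box configuration and the RNAP state of each thermodynamically controlled
promoter, with each bound RNAP coupling to the boxes through its own
$\eta$ terms and *no* RNAP–RNAP interaction term — the additivity of the
measured panel argues against interference between an elongating RNAP
from Pv and an initiating one at Ps, so no such parameter is introduced.
A corollary the package exploits heavily in tests: under purely kinetic
control the dual rate is *exactly* the sum of the two single-promoter
rates, while thermodynamic coupling breaks additivity.

Scenario tags are two letters, (Pv, Ps), each "K" or "T". RNAP time
dependence is nonparametric — one free activity value per promoter per
timepoint on the fixed 2–9 h hourly grid — because the rising RNAP
activity is a *result* of the analysis, not a constraint; no smoothness or
monotonicity penalty is applied by default. Whether the thermodynamic
$v_{\max}$ scale should itself be time-varying is unknowable from the
data; here all time dependence lives in $A$ under every scenario.

`veff_enumerate()` recomputes any rate by brute-force enumeration of every
joint (box, RNAP) state with no algebraic shortcuts; the closed forms must
match it to 1e−12, which the test suite checks on a thousand randomized
instances.

# Fitting and model selection

The objective is the sum of three per-cohort mean squared *relative*
residuals over 8 strains × 8 timepoints each ($E = E_v + E_s + E_{vs}$,
192 observations), computed against replicate means; relative residuals
weight the dim early Ps points and the bright late points equally and make
the objective invariant to the arbitrary Miller-unit scale. EMSA-derived
constants enter as constraints: the in-vivo half-saturations are
$\lambda K_{h,i}^{vitro}$ with one global fitted scale $\lambda > 0$,
preserving the relative box affinities (the in-vivo environment can shift
the absolute scale, not the ordering).

Free parameters per scenario: the three interaction energies, $\lambda$,
and per promoter either 8 activities + 7 ratios (kinetic) or 8 occupancy
ratios + 1 rate scale + 3 RNAP energies (thermodynamic). Scenarios
therefore differ modestly in parameter count (34, 31, 31, 28); ranking is
by error with a parameter-count tiebreak, and BIC (computed from the
summed squared relative residuals under a Gaussian relative-error
likelihood, with the honest per-scenario count) guards the nested
interaction-energy comparisons (`bic()`, `fit_constrained_interactions()`).

`fit_scenario()` minimizes the objective by multi-start bounded
quasi-Newton search (L-BFGS-B) over a compiled objective: 20 independent
starts by default (one data-informed start — activities from the box-free
strain's curve, ratios from late-time activity ratios — plus seeded random
restarts), a short exploration stage from every start and a
polish-to-convergence stage on the best few. Bounds: $\rho \in [0,5]$,
$\varepsilon \in [-10,5]$, $\lambda \in [0.01,100]$, $A$ up to five times
the data maximum, $\log R \in [-9, 9]$. The fit is deterministic given its
seed, reports the full per-restart error trace, and flags parameters that
end on a bound.

# The synthetic study

`default_truth()` fixes the generator's conditions once: tetrameric
binding ($N = N_{0A} = 4$) with $K_h$ = 0.4/0.6/0.2 µM for 0A1/0A2/0A3
(affinity order 0A3 > 0A1 > 0A2); purely kinetic control with Pv ratios
all repressive (0A1 strongest) and Ps ratios of mixed sign — 0A3 alone
activating (1.5), 0A2 repressing (0.55), the 2+3 combination repressive
(0.5) despite 0A3, and the all-bound configuration at 0.284 so that full
repression of Ps is 71.6%; attractive couplings
$\varepsilon_{12}, \varepsilon_{13}, \varepsilon_{23} = -1.0, -1.5, -2.5\,k_BT$
(strongest between 0A2 and 0A3, magnitudes of order one $k_BT$ as typical
for protein–DNA cooperativity); RNAP activities rising 1.4-fold (Pv, 100
to 140) and 10.8-fold (Ps, 20 to 216) over 2–9 h; and $\lambda = 1$. The
0A~P input is a logistic stand-in, $c_{\max} = 1$ µM, midpoint 4 h, rate
1/h, sampled hourly — a monotone sigmoidal rise with the right scale
relative to the $K_h$ values, replacing the phosphorelay-model trajectory
that is outside scope (any measured series can be supplied as a CSV).

Noise is multiplicative log-normal on activities (reporter noise scales
with signal; default CV 5%, 3 replicates, mean-corrected so replicate
means are unbiased) and additive truncated-Gaussian on EMSA fractions
(default SD 0.02, duplicate gels). Every dataset is byte-reproducible
given its seed.

What the generator does *not* emulate: day-to-day batch effects,
growth-stage autocorrelation within a time course, gel-specific
systematic errors, partial band shifts, or any 0A4 contribution. Passing
recovery tests therefore shows the inference machinery is correct and
well-conditioned at realistic noise, not that real measurements satisfy
the model's assumptions.

# Numerical choices and degenerate inputs

Configuration weights are computed relative to the all-unbound state, so
partition sums start at 1 and cannot vanish; zero concentration gives the
reference state probability 1 exactly. Zero measured activities are
rejected (the relative residual is undefined) rather than patched.
Optimizer finite-difference probes just outside the box constraints are
clamped inside the compiled objective. Parameters pinned to zero for
nested fits are removed from the search vector entirely (R's L-BFGS-B
cannot differentiate along a zero-width box). The saturation threshold for
`saturation_time()` is 0.99 — "saturated" is not defined numerically by
the source analyses, so it is a configurable default — and the
strength/freeze reference times (9 h and 2 h) are likewise arguments. The
shared-sigma fit is the best rank-1 approximation (SVD) with the shape
normalized to its first timepoint; an 8-point free shape mirrors the
nonparametric treatment of RNAP activity.

Cohort-level collapse caveats: with boxes saturated and one RNAP pool per
promoter, single-promoter strains collapse exactly onto 1 under the
endpoint/none normalization; dual-promoter strains mix two RNAP time
shapes and collapse exactly only when those shapes coincide — the package
tests both statements rather than the looser "everything collapses".

# Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the test suite run the full
24-strain, 8-timepoint design: EMSA fits with 1,000 augmented datasets;
scenario fits with 20 restarts; recovery and model-selection experiments
over 10 independent noise seeds. These sizes match the study design while
keeping a complete run of the workflow in the low minutes on one core.

# Known limitations

* The in-vivo cooperativity exponent is taken equal to the EMSA
  stoichiometry by default; if the oligomeric species differs on
  chromosomal DNA, $\lambda$ absorbs part of the discrepancy and the
  fitted energies shift accordingly.
* Scenario parameter counts are reconstructed from the model structure,
  not from a published parameter table; BIC uses the honest counts.
* The bootstrap CIs quantify replicate noise only, not gel-to-gel
  systematic error.
* Mixed control of a single promoter (binding affecting recruitment *and*
  initiation simultaneously) is not among the four scenarios, consistent
  with the additivity of the data that motivates purely kinetic control.
* The optimizer is a multi-start local method; the two-stage restart
  scheme makes the global optimum reproducible on the synthetic design,
  but pathological landscapes could in principle require more restarts
  (`n_restarts`, `maxit_explore` are tunable).
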