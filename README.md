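# spo0Areg

Biophysical models of transcriptional autoregulation at the *Bacillus
subtilis* *spo0A* locus — and, more generally, of any locus where a
dual-promoter gene is controlled by multiple transcription-factor binding
sites. The package is written for systems biologists who want to decide,
from reporter time courses and in-vitro binding titrations, **which step of
transcription a regulator acts on**: the equilibrium recruitment of RNA
polymerase (thermodynamic control) or the post-recruitment initiation rate
(kinetic control).

## The models

**Binding.** Each 0A box binds N molecules of phosphorylated Spo0A (0A~P)
cooperatively; the single-box bound fraction is the Hill-type mass-action
form `f(c) = c^N / (Kh^N + c^N)`, with `Kh` the concentration of
half-maximal occupancy. Multi-box fragments are handled by a
statistical-thermodynamic partition function with per-configuration weights
`prod_i (c/Kh_i)^(N s_i) * prod_{i<j} exp(-eps_ij)^(s_i s_j)`; the EMSA
observable is the probability that at least one box is bound.

**Transcription.** The effective transcription rate is the
occupancy-weighted sum of maximum initiation rates over promoter-bound
configurations, `veff = sum_a vmax_a * P_a`. Four scenarios — kinetic or
thermodynamic control for each of the two promoters (tags KK, KT, TK, TT)
— are fitted to a 24-strain reporter panel (3 promoter cohorts x 8 box
subsets, hourly activities over 2–9 h) under EMSA-derived binding
constraints, by multi-start bounded optimization of a per-cohort relative
squared-error objective (compiled core, 20 restarts, deterministic given a
seed). Purely kinetic control makes dual-promoter activity exactly the sum
of the single-promoter activities; that additivity is the observable
fingerprint that separates the scenarios.

**Downstream analyses.** Data collapses (additivity ratio and
endpoint/none normalization), per-subset repression/activation strengths,
box-occupancy saturation times, decomposition of RNAP-holoenzyme dynamics
from 0A~P effects, BIC-based nesting tests for the box–box interaction
energies, and shared-sigma joint fits of box-free promoter pairs.

A synthetic-data module generates EMSA titrations and the full 24-strain
panel with the study's qualitative structure (tetrameric binding, affinity
ordering 0A3 < 0A1 < 0A2, mostly repressive boxes with 0A3 activating Ps,
attractive couplings strongest between 0A2 and 0A3, RNAP activities rising
1.4-fold on Pv and 10.8-fold on Ps), so the entire pipeline is testable
offline.

## Worked example

```r
library(spo0Areg)

truth <- default_truth()                      # the study's ground truth
emsa  <- gen_emsa_dataset(truth, sd = 0.02, seed = 1)
panel <- gen_activity_panel(truth, cv = 0.05, seed = 1)

# 1. in-vitro binding: stoichiometry, then per-box Kh with bootstrap CIs
select_cooperativity(emsa, 1:6)$errors
#>       1       2       3       4       5       6
#> 0.78200 0.16500 0.02320 0.00509 0.02080 0.04380
fit_kh(emsa, 4, n_augment = 1000, seed = 1)
#> <kh_fit> N=4  total SSE=0.005092
#>   0A1: Kh = 0.3969 uM  [0.3834, 0.4119]
#>   0A2: Kh = 0.6095 uM  [0.595, 0.6253]
#>   0A3: Kh = 0.2001 uM  [0.1894, 0.2103]
```

The tetramer (N = 4) beats the dimer ~32-fold in summed squared error, and
the half-saturation constants come back within a few percent of the
generating values with 0A3 the strongest box.

```r
# 2. fit all four control scenarios and rank them
con  <- list(kh = c("0A1" = 0.3969, "0A2" = 0.6095, "0A3" = 0.2001), n = 4)
fits <- lapply(c("KK","TT","TK","KT"), function(sc)
  fit_scenario(panel, con, truth$sig, sc, n_restarts = 20, seed = 1))
compare_scenarios(fits)$ranking
#>   scenario           E  k        bic
#> 1       KK 0.001850571 34 -1240.2928
#> 2       TK 0.002302681 31 -1214.0980
#> 3       KT 0.023216167 31  -770.4292
#> 4       TT 0.023871882 28  -780.8541
```

Purely kinetic control (KK) attains the lowest error — the panel is
additive, which thermodynamic coupling cannot reproduce. The fitted
couplings are all attractive with the 0A2–0A3 pair strongest
(eps = −1.1, −1.17, −2.66 kT), and pinning any of them to zero worsens
BIC.

```r
# 3. what the boxes do, once saturated (RNAP frozen at its 2 h level)
st <- regulation_strength(fits[[1]], truth$sig, t_ref = 9, t_freeze = 2)
subset(st, boxes == "123")
#>   cohort boxes strength_pct
#>     PvPs   123       -66.30
#>       Pv   123       -65.41
#>       Ps   123       -70.82
```

With all boxes bound the sporulation promoter is repressed ~71% (the
generating initiation-rate ratio is 0.284, i.e. −71.6%), and the
dual-promoter strength lies between the two single-promoter strengths. The
RNAP-dynamics decomposition (`rnap_contribution()`) attributes the
remaining rise in expression to the holoenzymes: freezing RNAP at its 2 h
level leaves Ps at 1/10.9 of its dynamic prediction by 9 h, Pv at 1/1.4.

The same pipeline runs as a numbered workflow in `analysis/01_simulate.R`
through `analysis/04_regulatory_analysis.R`, writing tidy tables under
`results/`.

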