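---
title: "Methods: modelling a leaky bundle sheath and mapping its mutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling a leaky bundle sheath and mapping its mutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4leak)
```

This vignette explains the models and estimators the package implements,
the defaults and why they were chosen, what the synthetic-data generators
do and do not emulate, and the numerical decisions a maintainer would want
to know about.

## The forward C₄ flux model

C₄ photosynthesis is modelled as two coupled compartments. The mesophyll
fixes CO₂ through PEP carboxylase,

$$V_p = \min\!\left(\frac{C_m\,V_{pmax}}{C_m + K_p},\; V_{pr}\right),$$

and delivers it to the bundle sheath, from which it leaks back
diffusively at rate $L = g_{bs}(C_{bs} - C_m)$. At steady state the leaf
balance gives $L = V_p - A - R_m$, which is the mass-balance invariant
every returned state satisfies to $10^{-9}$ relative. In the bundle
sheath, net fixation follows either Rubisco CO₂/O₂ kinetics
(enzyme-limited),

$$A = \frac{V_{cmax}\,(C_{bs} - \gamma^{*} O_{bs})}{C_{bs} + K_c(1 + O_{bs}/K_o)} - R_d,$$

or the ATP budget of electron transport (light-limited), where total
electron transport $J_t$ is the smaller root of the non-rectangular
hyperbola $\theta J_t^2 - (I_2 + J_{max})J_t + I_2 J_{max} = 0$ with
$I_2 = I\cdot\text{absorptance}\cdot(1-f)/2$, a fraction $x$ of $J_t$
drives the C₄ cycle ($V_p = x J_t / 2$) and the remainder supports
bundle-sheath carboxylation with capacity $(1-x)J_t/3$. Substituting the
mass balance into either bundle-sheath expression yields a quadratic in
$A$; the model takes its smaller root, which is the physical branch
(the larger root corresponds to a negative-pressure bundle sheath).
`assimilation()` evaluates both limitations and returns the smaller rate.

Assumptions worth stating: infinite mesophyll conductance (intercellular
and mesophyll CO₂ identical), no temperature dependence of the kinetic
constants, no triose-phosphate limitation, and a NADP-ME-type bundle
sheath that is PSII-poor by default (`alpha = 0`, so bundle-sheath O₂
stays at the mesophyll value). Partial pressures use the convention
1 µmol mol⁻¹ ≡ 1 µbar at 1 bar total pressure; CO₂ quantities are in
µbar, O₂ in mbar, and conductance is mol m⁻² s⁻¹ bar⁻¹ internally,
reported as mmol m⁻² s⁻¹ bar⁻¹ where leaf estimates are quoted.

### Parameters and defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| `vcmax` | 20.5 | µmol m⁻² s⁻¹ | measured wildtype in-vitro Rubisco activity |
| `vpmax` | 167 | µmol m⁻² s⁻¹ | measured wildtype PEPC activity |
| `vpr` | 80 | µmol m⁻² s⁻¹ | standard PEP-regeneration cap |
| `kp` | 80 | µbar | standard PEPC Michaelis constant |
| `kc`, `ko` | 650, 450 | µbar, mbar | canonical C₄-model Rubisco constants |
| `gamma_star` | 0.000193 | – | canonical Rubisco specificity term |
| `gbs` | 0.0028 | mol m⁻² s⁻¹ bar⁻¹ | wildtype initial-slope estimate |
| `rd`, `rm` | 1.0, 0.5·rd | µmol m⁻² s⁻¹ | standard assumption, unmeasured |
| `om` | 210 | mbar | 21 % O₂ |
| `jmax`, `theta` | 400, 0.7 | µmol m⁻² s⁻¹, – | typical C₄ light response |
| `f_spectral`, `absorptance` | 0.15, 0.85 | – | standard leaf optics |
| `x_partition` | 0.4 | – | canonical C₄ electron-transport split |

All of these are exposed rather than hard-coded, because the model
predictions of interest (the effect of doubling `gbs`) should be
reproducible under any defensible parameterisation.

### Numerical choices

* Root selection is always the smaller quadratic root; a zero
  discriminant returns the double root; a negative discriminant raises a
  model-infeasibility error rather than clamping (round-off at tangency,
  below $10^{-12}$ relative, is treated as zero).
* Negative net assimilation is meaningful (dark respiration) and never
  clamped.
* The independent check used in the tests solves the same compartment
  balance by bisection on the physical branch ($C_{bs} \ge 0$, i.e.
  $A < V_p - R_m + g_{bs} C_m$) to $10^{-10}$ and agrees with the
  closed forms to $10^{-6}$ relative over randomly drawn physiological
  parameter sets.

## Inverse analyses

**Bundle-sheath conductance.** With PEPC inhibited (DCDP-fed leaves),
CO₂ enters the bundle sheath only by diffusion, and the initial slope of
the CO₂ response approximates $g_{bs}$. The estimator is an ordinary
least-squares line over the points with $C_i \le 100$ µbar (the measured
grid places four points there), with a free intercept because inhibition
leaves residual fixation. Units: a slope in µmol m⁻² s⁻¹ µbar⁻¹ equals
mol m⁻² s⁻¹ bar⁻¹, reported ×1000 in mmol.

A known, documented limitation: the method reads low whenever
bundle-sheath Rubisco partially limits the inhibited flux. Linearising
the inhibited balance gives an apparent slope of roughly
$g_{bs}\,k/(g_{bs}+k)$ with $k = V_{cmax}/(\gamma^*O + K_c(1+O/K_o))
\approx 0.021$ mol m⁻² s⁻¹ bar⁻¹ at 21 % O₂, so the bias grows with the
true conductance: about −12 % at 2.8 and −27 % at 7.4 mmol m⁻² s⁻¹
bar⁻¹ under the default parameter set (the tests record these). Ranking
and the roughly two-fold wildtype/mutant contrast are preserved
(rank correlation > 0.99 across the 1–10 mmol range).

**Leakiness from ¹³C discrimination.** The simplest linear relation
$\Delta = a + (b_4 - a + c\,\phi)\,C_i/C_a$ with $a = 4.3$,
$b_4 = -5.7$, $c = 27.2$ ‰ is used forward and inverted exactly
(round-trip to $10^{-12}$). The default aggregator inverts each leaf's
observation and reports the mean with its standard error, matching
per-plant replication; the alternative regresses $\Delta - a$ on
$C_i/C_a$ through the origin and maps the slope to $\phi$ — the two
coincide when all leaves share one $C_i/C_a$. The full ternary-corrected
discrimination model (boundary layer, respiratory and photorespiratory
fractionations) is out of scope; the simple relation is what the
leaf-level comparison uses.

**Bundle-sheath CO₂.** From leaf-level quantities,
$V_p = (A + R_m)/(1-\phi)$, $L = \phi V_p$, and
$C_{bs} = C_m + L/g_{bs}$, with $R_m = 0.5 R_d$, $R_d = 1$ µmol m⁻² s⁻¹
and $C_m = C_i$ (infinite mesophyll conductance) by default. With the
published wildtype inputs these defaults reproduce the reference value
to 0.1 %, and the result moves under ±2 % for $R_d$ anywhere in [0, 2].
The analogous mutant computation gives ≈1513 µbar, noticeably below the
published 1693 µbar; that number is not recoverable from the published
genotype means under any $R_d$ in [0, 2] and most likely reflects
unpublished per-leaf rates measured under the isotope conditions
(2 % O₂, 1500 µmol quanta). The defaults were not tuned toward it; the
mutant value is instead characterised by the robust properties that it
falls below 2000 µbar and below half the wildtype value.

**Quantum yield** is the OLS slope of assimilation on incident
irradiance over 0–200 µmol quanta m⁻² s⁻¹, the measured low-light
window. **Group comparisons** default to Welch's t-test (group sizes and
variances differ between genotypes); one-way ANOVA is provided and its
two-group F equals the pooled t².

## Mapping-by-sequencing

The filter cascade applies, in order: (1) an alignment-artifact filter
removing variants with mutant-pool allele frequency ≤ 0.3; (2) mutant
pool depth ≥ 10 reads and genotype quality ≥ 30; (3) fixation in the
mutant pool (frequency 1, tested as the integer identity
alt-count = depth by default, with a configurable epsilon for sampling
noise); (4) azygous-pool frequency ≤ 0.5; (5) absence from the wildtype
pool (the operational meaning of "induced"). The artifact and depth/GQ
filters act on the mutant pool by default — the locus search is driven by
the mutant pool — but the artifact filter can be extended to all pools.
An audit vector reports removals per stage, and records with undefined
frequency (zero depth) at a required stage are dropped with reason
`no_coverage`. The cascade is idempotent and order-stable.

The allele-frequency landscape averages mutant-pool frequencies in
non-overlapping windows (1 Mb in the drivers) and reports the peak
window set, ties included. "Typical linkage pattern" is operationalised
as this peak criterion: at 50× pool depth, a marker a few Mb from the
causal locus occasionally samples to frequency exactly 1.0 and ties the
causal window, so localization is judged on whether the reported tie set
intersects the causal neighbourhood (in repeated simulations ~97 % of
runs localise to within 2 Mb this way).

Effect classification maps a SNP through a minimal gene model
(strand-aware concatenated CDS, 1-based inclusive intervals as in
GFF/VCF; internal offsets are handled in one place and cross-checked in
tests). The reference and mutant codons are translated with the standard
genetic code; stop gains are `nonsense`, UTR and intron positions are
non-candidates, and positions within 2 bp of an exon edge are `splice`.
The test oracle retranslates the whole mutated CDS and compares.

Mendelian expectations are enumerated, not sampled: conditioning on the
recessive phenotype fixes the causal allele in the mutant pool
(frequency 1); the azygous class mixes 1 homozygous-wildtype : 2
heterozygous segregants, giving exactly 1/3 (comfortably under the 0.5
screening bound); unlinked heterozygous induced sites sit at 1/2 in
every F₂-derived pool and at 0 in the wildtype pool.

## What the generators emulate — and what they do not

`simulate_gas_exchange`, `simulate_dcdp_curve` and
`simulate_discrimination` add iid Gaussian noise to forward-model
curves, with the true curve retained as an attribute; DCDP feeding is
emulated by forcing PEP carboxylation to zero (`vpmax = vpr = 0`). They
do not emulate instrument drift, leaf-to-leaf parameter variation, or
stomatal dynamics, so passing recovery tests shows estimator
correctness under the model, not robustness to biological heterogeneity.

`simulate_bc1f2_pools` implements the cross as heterozygous-F1-selfed
(monohybrid 1:2:1 segregation, matching the observed 25 % recessive
fraction), with all induced mutations carried on one chromosome pair and
Haldane (no-interference) recombination; positions are uniform, the
mutation spectrum is 80 % G:C→A:T as expected for NMU. Pools of 45
(mutant) and 54 (azygous) individuals are drawn from the phenotype
classes of a 300-plant population, a separate 50-plant wildtype pool
carries no induced alleles, and reads are sampled depth ~ Poisson(50),
alt ~ Binomial(depth, pool frequency). Genotype quality is synthesized
as `GQ = min(99, round(4.3·depth))` — a labelled plumbing surrogate, not
a caller likelihood, sufficient to exercise the GQ filter. A
misclassification-rate parameter exists for imperfect phenotyping but
defaults to 0, as no rate was reported. Read-level artifacts (the very
thing the 0.3 filter targets in real data), multi-allelic sites, indels
and background polymorphisms are not simulated.

All generators are deterministic given their seed.

## Problem sizes in the test suite

The suite keeps simulations small enough to run in well under a minute:
100 random parameter draws for the oracle-equivalence property, 200
simulated isotope experiments for the calibration check, 100 simulated
crosses for segregation coverage, 20 crosses for filter retention, 10
for landscape localization, and 250 random SNPs per strand for the
translation oracle. These sizes were chosen so that Monte-Carlo error is
small relative to each assertion's tolerance.

## Known limitations

* The initial-slope $g_{bs}$ estimator's conductance-dependent low bias
  (above): at mutant-level conductance the default-model bias reaches
  ~−27 %, outside the 25 % band that holds at wildtype conductance.
* The enzyme-limited defaults cap assimilation near $V_{cmax} - R_d$,
  so with the measured in-vitro $V_{cmax}$ the modelled wildtype ceiling
  (~19 µmol m⁻² s⁻¹) sits below the measured light-saturated rate
  (30.2): in-vitro activity underestimates in-vivo capacity, and users
  comparing against leaf data should calibrate `vcmax` accordingly.
* At C_i = 0 an inhibited leaf does not respire at exactly $-R_d$:
  bundle-sheath Rubisco refixes part of the respiratory CO₂. The exact
  $-R_d$ limit requires `vcmax = 0` as well.
* Single-locus, single-chromosome recessive designs only; no epistasis,
  no multi-locus phenotypes, no reference-bias or alignment artifacts in
  the simulated pools.
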