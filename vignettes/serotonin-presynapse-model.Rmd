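---
title: "A genotype-aware kinetic model of the serotonin presynapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A genotype-aware kinetic model of the serotonin presynapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serodyn)
```

## The model

serodyn tracks eight molecular species of presynaptic serotonin metabolism —
serum tryptophan, tryptophan available for synthesis, the cellular
tryptophan pool, 5-HTP, free cellular 5-HT, vesicular 5-HT, extracellular
5-HT and 5-HIAA — through eight coupled ordinary differential equations.
Transport and enzymatic steps (tryptophan transporter, TPH2, AADC, VMAT,
SERT, MAOA) are Michaelis–Menten fluxes; pool exchange, vesicular leak,
exocytosis and all removal processes are first-order mass-action fluxes.
The simulated experiment is a single 100 µM bolus of serum tryptophan at
time zero with every other species at zero, followed for three hours. Every
non-removal flux transfers mass between two tracked species, so the
derivatives sum to exactly minus the four removal fluxes; this conservation
identity is asserted to 1e-10 µM/h in the test suite and used as a running
audit of whole trajectories (`massAudit()`, closing the input to 0.1%).

The model deliberately omits autoreceptor and glial feedback, postsynaptic
receptors, stimulus-driven release patterns and dietary tryptophan input;
it is a response-to-one-bolus model, not a steady-state synapse model.

### Fixed parameters

All fixed constants live in `modelParameters()` with units documented per
field: Michaelis constants (µM) and fixed maximal rates (µM/h) for the
transporter, AADC and VMAT, and first-order constants (1/h) for everything
else. Two published ambiguities are carried as explicit switches rather
than silent choices:

* **Pool leakage substrate.** The published rate-law table makes the
  reverse pool flux proportional to free tryptophan, not to the pool
  itself. The literal form is the default (`pool_reverse_substrate =
  "trp"`); it reproduces the observed slow post-depletion decline of the
  pool. The mass-balance-intuitive alternative (`"trp_pool"`) is one
  argument away.
* **Exocytosis order.** The rate-law table defines release as first-order
  in vesicular serotonin with k = 20 1/h (the default); the accompanying
  prose reads like a constant 20 µM/h flux. `release_kinetics =
  "zero_order"` selects the constant-flux reading.

The constants printed with units µM/h for the pool-exchange pair are
treated as first-order constants in 1/h: the rate law V = k[S] forces that
dimension.

5-HIAA removal is first-order with k = 1 1/h, consistent with the measured
disappearance constant (~0.8 1/h) the source model cites.

## From genotype to maximal rates

Five regulatory variants drive the three genotype-dependent maximal rates.
Each allele carries a normalised expression effect (reference allele = 1,
shipped in `inst/extdata/variant_effects.tsv`, overridable): the three TPH2
SNVs (G of rs11178998 = 3, A of rs4290270 = 0.7, A of rs7305115 = 1.7), the
5-HTTLPR S allele = 0.3, and the MAOA uVNTR grouped into low- (3R, 5R,
effect 0.2) and high-expression (3.5R, 4R, reference) classes. The rare 2R
allele has no established effect and is rejected unless the user supplies
one. The per-gene correction is

* TPH2: additive, averaged over the three loci, C = mean(a1 + a2) — the
  average keeps three loci from outweighing the single-locus genes;
* SERT: dominant, the lower-expression allele masks the other, so LS and
  SS both give C = 0.6 and LL gives C = 2;
* MAOA: additive, a1 + a2, with hemizygous males counted as homozygotes
  (C = 2a) — the X-linked dosage convention of the source study, applied
  without a dosage-compensation alternative.

The maximal rate is then Vmax = E_NX · C · kcat · scale, with E_NX = NX/1000
µM from brain-stem expression (TPH2 46.2 NX, SLC6A4 11.2, MAOA 18.6) and
hourly turnover numbers kcat (TPH2 5.03 /s, MAOA 18.6 /s, SERT 198.4 /s
back-derived from transporter rates).

### The frozen scale calibration

The literal product E_NX · C · kcat, with the reference homozygote at
C = 2, is internally consistent for TPH2: it yields the published baseline
5-HTP mean with no adjustment, so `scale_tph2 = 1`. For SERT and MAOA it is
not: taken literally it puts the SERT maximal rate near 16,000 µM/h, which
pins extracellular serotonin at ~2 nM instead of the published ~70 nM
baseline, and analogously overshoots degradation. The per-genotype maximal
rates actually used by the source study are not published, so the absolute
scale of these two rates is under-determined by the printed material. The
package therefore fixes two dimensionless multipliers once —
`scale_sert = 0.01219` and `scale_maoa = 0.03667` — by rooting, over the
exact Hardy–Weinberg genotype-class distribution (not a sampled cohort),
the expected extracellular-5-HT mean at 70.5 nM and the 5-HIAA/fc5-HT
ratio at 0.67. Rooting MAOA on the 5-HIAA point value instead pushes the
ratio outside its band, because fc5-HT is an emergent quantity the ratio is
more sensitive to; with the ratio rooted, 5-HIAA still lands well inside
its reported spread. These defaults are frozen; `vmaxScale(1, 1, 1)`
recovers the literal law, and all relative genotype effects are unaffected
by the choice since the multipliers are per-gene constants.

## Simulation and summaries

`simulateIndividual()` integrates with lsoda (stiff-capable, adaptive) and
reports the solution on a fixed grid, 0 to 3 h every 0.01 h (301 points).
The 0.01 is an output grid, not an integration step — a stiff solver
chooses its own internal steps. Tolerances default to rtol 1e-8 / atol
1e-12, at which the species means are tolerance-independent to at least six
significant digits; agreement with a fixed-step explicit RK4 integration at
dt = 1e-4 h is ~1e-9 relative on species means when both are compared on
the shared output grid. Solver undershoots below zero are clipped at
-1e-9 µM; anything more negative is treated as an integration failure.
Per-individual summaries are plain arithmetic means over all grid rows,
t = 0 included (`include_t0 = FALSE` excludes it; the effect is at most
1/301 of a species' range). `simulateCohort()` caches integrations per
distinct maximal-rate triple, so a cohort costs one solve per genotype
class.

The three-hour horizon matters: all species except the tryptophan pool are
more than 99% cleared by then, but the slowest clearance processes — the
AADC first-order slope Vmax/Km = 2.5 1/h for 5-HTP and the 1 1/h removal of
5-HIAA — still leave residues of order 0.1 µM at the horizon. "Reached
zero" holds at the resolution of a concentration plot, not at the µM⁻³
level, and longer horizons would only dilute the means toward those decay
tails.

## The synthetic cohort generator

No individual genotype data ship with the package; `sampleCohort()` draws
cohorts under Hardy–Weinberg equilibrium at the published allele
frequencies (e.g. L = 0.58, uVNTR 4R = 0.685) with the published sex ratio
(65.7% female), one allele draw per chromosome — so males get a single
uVNTR allele. What it emulates is a population in HWE at those marginal
frequencies; what it does not emulate is linkage disequilibrium between the
three physically linked TPH2 SNVs (no haplotype frequencies are published;
loci are drawn independently, and `cohortSpec()` accepts per-locus
frequency overrides but no haplotype input), nor any genotype-phenotype
ascertainment structure of a real clinical sample. Tests passing on these
cohorts therefore validate the pipeline's behaviour under HWE sampling
variation, not the reproduction of any particular patient group — which is
also why group-difference results on synthetic cohorts (e.g. the injected
uVNTR frequency shift exercised in the test suite) demonstrate sensitivity
of the battery, not clinical effect sizes.

## Statistics

Two-group comparisons of per-individual species means use the two-sided
Mann–Whitney U test (exact null distribution when both groups have at most
8 untied observations, normal approximation with tie correction and no
continuity correction otherwise — ties do occur, since identical genotypes
give identical means). Three or more groups use Kruskal–Wallis with tie
correction followed by Dunn's post hoc z tests on pooled ranks,
Bonferroni-multiplied by the number of pairs and capped at 1. Cohen's d is
computed on the raw species means with the pooled n−1 standard deviation,
and post hoc power uses the two-sided normal approximation
Φ(|d|√(n₁n₂/(n₁+n₂)) − z₀.₉₇₅) (+ the opposite tail), with a noncentral-t
variant available. Dunn's test is implemented in the package (no installed
dependency provides it) and is cross-checked in the tests against an
independent transcription of the published rank formula.

## Numerical and degenerate-input choices

* Negative inputs, non-positive Michaelis constants, empty samples, zero
  pooled SD, unknown alleles, missing loci and malformed genotype cells are
  hard errors with located messages (row/column for table input).
* A male uVNTR cell must be a single allele; two alleles for a male is an
  error, never silently averaged.
* Monomorphic genotype counts make the HWE chi-square 0 by construction
  rather than 0/0.
* Allele order within an unordered genotype pair never affects any result.
* Cohort sampling restores the caller's RNG state when a seed is supplied;
  identical specs and seeds give byte-identical cohorts.

## Problem sizes in the shipped checks

The test suite and the acceptance script use a 140-individual cohort for
baseline reproduction (the published validation-cohort size), 80 per group
for the injected-difference demonstration, 1000 replicate count draws for
the HWE-test calibration, 10⁵ individuals for allele-frequency convergence,
and five random maximal-rate triples for the stiff-vs-explicit oracle;
these sizes give sampling errors comfortably below the tolerances they are
tested against.

## Known limitations

* The absolute SERT and MAOA rate scales are calibrated, not derived; only
  their relative genotype effects are mechanistic.
* No linkage disequilibrium between TPH2 SNVs; HWE sampling treats loci
  independently.
* mRNA expression effects are taken as proportional protein-activity
  effects; post-transcriptional and post-translational regulation (TPH2
  RNA editing, SERT trafficking) is outside the model.
* One bolus, one compartment, no feedback: concentrations after the bolus
  response decays are not interpretable as resting-state levels.
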