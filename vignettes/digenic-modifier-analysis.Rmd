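---
title: "Modelling digenic mtDNA–nuclear modifier inheritance with mtdigenic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling digenic mtDNA–nuclear modifier inheritance with mtdigenic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdigenic)
library(dplyr)
```

## The scientific problem

Reversible infantile respiratory chain deficiency (RIRCD) is a mitochondrial
myopathy of early infancy that recovers spontaneously. Every patient carries
the same homoplasmic mt-tRNA^Glu^ variant, yet only a minority of carriers —
roughly a third within carrier families — ever develop symptoms. The working
model implemented here is digenic inheritance: disease manifests when the
homoplasmic mtDNA variant co-occurs with a heterozygous damaging allele in
one of six nuclear genes that interact with mt-tRNA^Glu^ (`EARS2`, `TRMU`,
`QRSL1`, `GOT2`, `GLS`, `MSS51`). The package provides the full quantitative
chain behind that model: qualifying-variant filtering, pedigree-stratified
allele-burden comparison, carrier-frequency and penetrance arithmetic, a
residue-composition/expression correlation, and two small assay models (qPCR
mtDNA copy number; proteome regulation thresholds), together with seeded
simulators that generate every input the chain consumes.

## Variant classification and rarity

A variant qualifies as potentially pathogenic when its consequence is
truncating (splice site, frameshift, stop gain/loss), or when it is missense
and simultaneously (i) predicted damaging by an upstream in-silico consensus,
(ii) at an evolutionarily conserved residue and (iii) inside a known InterPro
domain. The conservation and domain requirements can be waived individually
(`filter_config()`), because different annotation pipelines differ in how
aggressively they call these flags. The consensus itself is consumed as a
single precomputed boolean: running annotation tools is out of scope, which
keeps the package free of external databases.

Rarity is a strict MAF cutoff, default `maf_threshold = 0.005`. The choice is
deliberately permissive: the rarest published modifier alleles in this panel
sit below 0.002, so 0.005 contains them with margin, while anything common
enough to approach 0.5% is no longer plausibly a high-penetrance modifier. A
missing MAF is treated as 0 (a novel allele passes) with a warning — the
rare-disease convention, since absence from a population database is itself
evidence of rarity.

One allele in the panel is deliberately *not* rare: the common `TRMU`
p.Ala10Ser-like allele (MAF ≈ 0.097) is a functional modifier that burden
counting must retain. The pipeline therefore separates the *discovery* gate
(0.005) from the *burden panel* gate (default 0.1): discovery filtering finds
rare co-segregating alleles, while allele counting includes every damaging
panel allele below the laxer gate.

## Allele burden in pedigrees

Each person's burden is the sum of their damaging panel allele counts plus
one if they carry the homoplasmic mtDNA variant. Counting homoplasmy as a
single allele (not two, despite being effectively "homozygous") is the
convention that makes the typical digenic patient score 2 — mtDNA variant
plus one heterozygous nuclear allele — and reproduces the scale of published
per-group means (≈2.3 affected vs ≈1.3 unaffected carriers vs ≈0.7
population controls).

Group means are compared with a two-sided pooled-variance Student's t-test by
default, because that is the test named in the source analyses; Welch and a
seeded label-permutation test are options. The permutation p-value uses the
add-one estimator `(1 + #{|Δ_perm| ≥ |Δ_obs|}) / (1 + n_perm)`, which is
never exactly zero. Relatives are treated as independent observations — a
simplification the source shares; kinship-adjusted tests are a stated
non-goal. Degenerate inputs resolve explicitly: equal means with zero
variance give t = 0, p = 1; unequal means with zero pooled variance give the
smallest representable positive p with a warning rather than a silent NaN.

`simulate_burden_power()` wraps the comparison in a Monte-Carlo loop: counts
are drawn per individual as binomial panel sums, the affected group receives
Poisson-distributed extra alleles, and the rejection rate at α is reported
with its binomial standard error. At `effect = 0` this measures type-I error;
on the default panel at group sizes (22, 12) the t-test is calibrated to
within Monte-Carlo error of the nominal 5%.

## Digenic risk arithmetic

Three aggregation rules convert per-variant MAFs into a carrier frequency:

* `additive` — `sum(p)`, clamped at 1. This is the published convention for
  cumulative carrier frequencies (0.0135 for the `EARS2` alleles; 0.32
  panel-wide), and is what identifies the panel-wide cumulative MAF with the
  predicted penetrance among mtDNA carriers (32%).
* `at_least_one_allele` — `1 − prod((1 − p)²)`, the exact probability that a
  diploid individual carries at least one allele across independent sites.
* `hardy_weinberg_het` — `1 − prod(1 − 2p(1 − p))`, heterozygous carriers
  only.

These differ materially: for rare alleles the exact diploid probability is
close to *twice* the additive MAF sum (each person samples two alleles). The
additive rule is nonetheless the default for penetrance prediction because it
is the stated method of the arithmetic being reproduced; the package keeps
the exact alternatives available rather than adjudicating. Co-occurrence is
the product of the mtDNA carrier frequency (equal to allele frequency under
homoplasmy) and the nuclear carrier frequency, under independence of the two
genomes — e.g. `1e-4 × 0.0135 = 1.35e-6`. Prevalence is co-occurrence of
mtDNA carriage with penetrance; expected cases are prevalence × population
size, with the reference population (66 M, a UK-scale figure) a configurable
default, not policy. Display rounding ("1 in 30,000") is a separate
formatting layer (`format_one_in()`); the arithmetic itself is never rounded.
Headline expected-case counts in the pipeline report follow the
one-significant-figure prevalence, matching how such figures are quoted.

## Residue composition and expression

`composition_table()` counts glutamate and glutamine residues (the amino
acids handled by the mt-tRNA^Glu^/mt-tRNA^Gln^ machinery) in the 13
mtDNA-encoded proteins and correlates their fraction (or absolute count)
with a per-gene expression-change metric, Pearson by default with the
two-sided p from the t distribution on n − 2 df. Both the metric column and
the predictor are configurable because the exact published choice for the
corresponding figure is not stated; the package makes no claim to reproduce
the published r = 0.61677 exactly, and instead verifies the machinery on
exact oracles and on simulated composition-coupled expression.

**The packaged FASTA is synthetic.** No human reference sequences ship with
the package: `inst/extdata/mt_proteins_synthetic.fasta` is generated by
`simulate_mt_proteome()` (seed 1) with the real chain lengths of the 13
subunits and E+Q contents that emulate the real qualitative pattern —
complex I (ND) subunits enriched, ND5 carrying the highest absolute count —
over a hydrophobic membrane-protein-like background. Conclusions about the
real proteome should be drawn with the real sequences substituted via the
`fasta` argument; results on the fixture demonstrate the machinery, not
human biology.

## Assay models

mtDNA copy number per diploid cell follows `2 × 2^ΔCt` with
`ΔCt = Ct(nuclear reference) − Ct(mitochondrial target)`: equal Cts mean two
mtDNA copies per cell, and each cycle is a two-fold abundance step.
Replicates are averaged at the ΔCt level before exponentiation (the
geometric-mean convention for exponential data); arithmetic copy-level
averaging is available by flag, and the choice is recorded in the output so
downstream fold changes are interpretable. Standard-curve fitting is out of
scope — the final quantity uses only ΔCt.

Proteome regulation thresholds are mean ± 2 SD of all quantified proteins'
log2 ratios (sample SD, n − 1; a median/MAD robust variant is non-default).
A protein is called regulated only if it passes the ratio cutoff *and* an
ANOVA p ≤ 0.05 *and* was quantified with unique peptides in all replicates —
the same conjunctive gate as the source's label-free analysis. Back-solving
the published cutoffs (−2.2, 0.98) gives mean −0.61 and SD 0.795, which the
assay simulator uses as its default ratio distribution; whether the published
cutoffs derive from exactly that distribution is unverifiable without the
deposited raw data, so only the procedure is claimed.

## What the simulators emulate — and what they do not

`simulate_cohort()` generates nuclear families ascertained through a
homoplasmic maternal founder: every founder mother carries the mtDNA variant
(families enter the study *because* of it), all her children inherit it
(homoplasmic mtDNA passes maternally without segregation), and fathers never
carry it. Setting `freq_mt = 0` removes carriers entirely. Nuclear alleles
are drawn binomially at panel MAFs in founders and transmitted Mendelianly.
Affection follows a three-parameter penetrance model: π_digenic = 0.9 for
mtDNA carriers with ≥ 1 modifier allele, π_mt_only = 0.01, π_background =
0.001. The source implies π_mt_only ≈ 0 and high π_digenic but quantifies
neither; these defaults encode "almost fully penetrant digenic state, near-0
otherwise" and are free parameters, chosen once. With them, penetrance among
simulated carriers equals the panel carrier frequency times π_digenic (plus
a negligible remainder) — the 0.32-scale the additive arithmetic predicts,
up to the additive-vs-exact carrier-frequency gap discussed above.

Population controls (`simulate_control_genotypes()`, default n = 1,044 to
match the published control panel) draw genotypes independently per variant;
mtDNA carrier status is `FALSE` by default or drawn at `freq_mt` for
frequency-recovery checks. Expression tables are linear in the E+Q fraction
plus Gaussian noise; the default slope 18 with noise SD 0.35 puts the
population correlation near 0.6 over the 13 proteins given the fixture's
composition spread (SD ≈ 0.0148), via r = βσ_x / √(β²σ_x² + σ²). The qPCR
simulator places group ΔCt at (control 5, affected 3) — patients at one
quarter of control copy number, the scale of the published depletion — and
the proteome simulator draws 1,600 ratios from N(−0.61, 0.795²) with 20
injected outliers per tail at 4 SD.

What passing tests on these simulators do *not* show: robustness to
population stratification, linkage disequilibrium between panel sites,
genotyping error, ascertainment bias beyond the maternal-founder rule,
relatedness-induced variance inflation in the t-test, or any feature of real
expression/proteomics noise beyond Gaussianity. The simulators are designed
to make the *arithmetic and inference machinery* testable, not to be a
population-genetics forward simulator.

## Numerical and design choices

* **Randomness.** One root seed; each component derives an independent
  substream via a small integer LCG-style mix (`derive_seed()`), so
  regenerating one table never perturbs another. Identical config + seed
  gives byte-identical outputs; unseeded simulation is an error.
* **Ties and degeneracies.** Zero-carrier variants are excluded from
  segregation with a logged count; unknown-affection carriers force a
  variant to `shared` (warning) rather than guessing; zero-variance inputs
  to the correlation error naming the degenerate side.
* **Problem sizes.** Test and acceptance runs use the study-scale design
  (19 families, 1,044 controls, group sizes 22/12, 1,000 null simulations,
  10,000-draw threshold recovery, 1,600-protein tables) — small enough to run
  in seconds, large enough for 3-SE Monte-Carlo bands to be meaningful.
* **Interface.** Every user-facing function takes a data frame first and
  returns a tibble; fitted objects (`burden_comparison`, `eq_correlation`)
  have `tidy()`/`glance()` methods and plots come from `plot_*()` /
  `autoplot()`. The pipeline is driven from R via `run_pipeline()`, which
  writes a JSON/TSV/markdown bundle whose markdown numbers are copied from
  the JSON fields.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "rircd_run")

tidy(res$burden$affected_vs_unaffected)
glance(res$burden$affected_vs_unaffected)
res$digenic$risk
tidy(res$composition$correlation)

plot_burden(res$burden$table)
autoplot(res$composition$correlation)
plot_protein_ratios(res$assays$flagged, res$assays$thresholds)
```

## Known limitations

The additive carrier-frequency convention understates the exact diploid
carrier probability by up to two-fold for rare alleles; it is kept as the
default because it is the convention of the arithmetic being modelled, and
the exact methods are one argument away. Penetrance parameters are
educated defaults, not estimates; ascertainment correction is a non-goal.
The composition fixture is synthetic (see above). The burden test ignores
family structure. Heteroplasmy is out of scope — the model cohort is
homoplasmic, so carrier frequency and allele frequency coincide.
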