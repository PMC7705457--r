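# mtdigenic

Digenic-modifier analysis for homoplasmic mitochondrial DNA disease, in R.

## The problem

Reversible infantile respiratory chain deficiency (RIRCD) is an infant-onset
mitochondrial myopathy that recovers spontaneously after about six months.
All patients carry the same homoplasmic mt-tRNA^Glu^ variant, but only a
minority of carriers — roughly a third within carrier families — ever become
ill. The leading explanation is **digenic inheritance**: disease requires
the mtDNA variant *plus* a heterozygous damaging allele in one of six
nuclear genes that service mt-tRNA^Glu^ (`EARS2`, `TRMU`, `QRSL1`, `GOT2`,
`GLS`, `MSS51`).

`mtdigenic` implements the quantitative machinery of that model for anyone
studying reduced-penetrance mtDNA disease:

* **Variant filtering** — a variant qualifies if truncating (splice site,
  frameshift, stop gain/loss) or damaging missense (in-silico consensus +
  conservation + InterPro domain), with a strict rarity cutoff
  (MAF < 0.005 by default), then partitioned by segregation with affection
  status (affected-only / unaffected-only / shared).
* **Pedigree burden** — per-person cumulative damaging allele counts
  (nuclear panel alleles + 1 for the homoplasmic mtDNA variant), compared
  across groups by pooled t, Welch t or a seeded permutation test; a
  Monte-Carlo power/type-I-error harness at the study design size.
* **Digenic risk arithmetic** — carrier frequency from MAF lists (additive
  `Σp`, exact diploid `1 − Π(1−p)²`, or Hardy-Weinberg heterozygote),
  co-occurrence `f_mt × f_nuclear`, predicted penetrance among mtDNA
  carriers, prevalence, expected cases, and carrier-count MAF estimation.
* **Composition vs expression** — Glu+Gln residue content of the 13
  mtDNA-encoded proteins correlated with per-gene expression change
  (Pearson/Spearman, t-distribution p on n−2 df).
* **Assay models** — qPCR mtDNA copy number `2 × 2^ΔCt` with
  `ΔCt = Ct(nuclear) − Ct(mito)`, and proteome regulation calls at
  mean ± 2 SD of the log2-ratio distribution gated by ANOVA p ≤ 0.05 and
  unique-peptide quantification.
* **Seeded simulators** — maternally ascertained pedigrees with Mendelian
  nuclear transmission, population control genotypes, composition-coupled
  expression, Ct and proteome tables, all byte-reproducible from one root
  seed.

All functions are tibble-in/tibble-out and pipe-friendly; fitted objects
have `tidy()`/`glance()` methods and `plot_*()`/`autoplot()` graphics.

Note: the packaged 13-protein FASTA is a **synthetic stand-in** (real chain
lengths, emulated Glu+Gln enrichment; see `?mt_proteome_fasta`) — substitute
real sequences via the `fasta` argument for biological conclusions.

## Worked example

```r
library(mtdigenic)

cfg <- simulation_config(seed = 1)   # study-scale defaults: 19 families,
                                     # 1,044 controls, panel MAFs as published
res <- run_pipeline(cfg, out_dir = "rircd_run")

res$burden$affected_vs_unaffected
#> <burden_comparison> student_t
#>   affected: n = 19, mean = 2.421 (sd 0.769)
#>   unaffected: n = 38, mean = 1.132 (sd 0.529)
#>   t = 7.432, df = 55.00, p = 7.4e-10

res$digenic$risk
#> # A tibble: 1 x 8
#>   freq_mt carrier_freq_nuclear co_occurrence predicted_penetrance
#>    0.0001                 0.32      0.000032                 0.32
#>   predicted_prevalence expected_cases population_size prevalence_one_in
#>               0.000032           2112        66000000 1 in 3e+04

res$composition$correlation
#> <eq_correlation> pearson r = 0.74443, p = 0.00352, n = 13 (fraction_target vs log2fc)

res$assays$thresholds
#> # A tibble: 1 x 4
#>   mean_log2 sd_log2 lower upper
#>      -0.618   0.937 -2.49  1.26
```

Reading these numbers: simulated affected carriers average ~2.4 qualifying
alleles against ~1.1 in unaffected carriers — the one-extra-allele
separation the digenic model predicts. The risk table is exact arithmetic
on the published frequencies: a 0.0001-frequency mtDNA variant times a 0.32
panel-wide cumulative modifier frequency gives a 3.2 × 10⁻⁵ chance of
carrying both, i.e. the predicted prevalence among newborns, about 1 in
30,000. The correlation is the recovered composition–expression coupling on
one simulated expression table, and the proteome thresholds are mean ± 2 SD
of the simulated log2-ratio distribution.

The headline published probabilities come straight from the arithmetic
functions:

```r
co_occurrence_probability(1e-4, 0.0135)   # 1.35e-06  (mtDNA x EARS2)
co_occurrence_probability(1e-4, 0.09695)  # 9.695e-06 (~1e-5, mtDNA x TRMU)
predicted_prevalence(1e-4, 0.30)          # 3e-05     (0.003%, ~1/30,000)
maf_from_carrier_counts(11, 358916)       # 3.06e-05  (biobank carrier MAF)
```

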