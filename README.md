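# prmepi

Case-control SNP association and SNP-SNP interaction (epistasis) analysis
for persistent respiratory morbidity (PRM) after paediatric acute
respiratory failure, over a fixed 14-SNP surfactant-protein panel
(*SFTPA1*, *SFTPA2*, *SFTPB*, *SFTPC*, *SFTPD*).

## What it does

* **Data model and I/O** — minor-allele dosage matrices (0/1/2/NA) from
  TSV or biallelic VCF (via `vcfR`), validated against the bundled panel;
  cohort tables with outcome status and clinical covariates.
* **QC** — per-group allele counts, missingness, and a conditional exact
  Hardy-Weinberg equilibrium test (chi-square fallback available).
* **Carrier-model screen** — univariate logistic regression of each SNP's
  carrier indicator on case status (candidates at p < 0.1), then
  multivariate backward elimination at 0.05 with obliged covariates;
  demographic comparisons use a chi-square(Yates)/Fisher switching rule.
* **Epistasis sweep** — for every 1-, 2- and 3-SNP subset and every
  additive/dominant/silent effect-type assignment (2/8/26 types;
  28/728/9464 tests on the panel), partitions multi-locus genotypes into
  a selected group vs complement, estimates a Mantel-Haenszel odds ratio
  stratified by sex x race x median-split age with a
  Robins-Breslow-Greenland CI, computes a covariate-adjusted logistic
  Wald p, and applies Benjamini-Hochberg FDR control per model order.
* **Synthetic cohorts** — a seeded generator whose defaults are the study
  conditions (n = 155, prevalence 0.425, infant demographics,
  literature-informed minor-allele frequencies), with planted single-SNP
  or epistatic effects, optional LD and missingness; used for power and
  type-I-error studies.

Notation: an effect type such as `a1d2` assigns an additive contrast to
the first SNP of a subset and a dominant contrast to the second; under
the default (`paper_literal`) convention its selected group at two loci is
{AABb, aaBb} against the 7 remaining genotypes.

## Worked example

Simulate a cohort with a planted `a1d2` interaction between rs1130866
(*SFTPB*) and rs1124 (*SFTPC*) at odds ratio 3, then run the two-SNP
sweep:

```r
library(prmepi)

spec <- simulation_spec(
  n_subjects = 600, seed = 42,
  effects = list(list(snps = c("rs1130866", "rs1124"),
                      labels = c("a", "d"), log_or = log(3))))
sim <- simulate_cohort(spec)
m2 <- run_model(2, sim$genotypes, sim$cohort)
head(m2[, c("snp1", "snp2", "effect_type", "or_mh", "or_mh_low",
            "or_mh_high", "p_adj", "fdr_q", "significant_fdr")],
     5)
```

```
      snp1      snp2 effect_type     or_mh or_mh_low or_mh_high        p_adj
 rs1130866    rs1124        a1d2 2.6290844 1.8220262  3.7936253 1.917537e-07
 rs1965708 rs1130866        a1d2 0.4605901 0.2953746  0.7182176 2.361490e-04
 rs1965708    rs1124        d1d2 2.2720841 1.4300824  3.6098383 3.200939e-04
 rs1059047 rs1130866          a2 1.8104700 1.2644595  2.5922552 4.243546e-04
 rs1136450 rs1130866          a2 1.8104700 1.2644595  2.5922552 4.243546e-04
        fdr_q significant_fdr
 0.0001395967            TRUE
 0.0106527625            TRUE
 0.0106527625            TRUE
 0.0106527625            TRUE
 0.0106527625            TRUE
```

The planted interaction is the top hit, with the Mantel-Haenszel odds
ratio recovering the planted effect and surviving FDR control.  The
end-to-end pipeline (cohort summary, QC, screen, sweeps at orders 1-3,
manifest and log) is one call:

```r
cfg <- list(sim_spec = simulation_spec(n_subjects = 155, seed = 1),
            obliged_covariates = "culture_positive")
res <- run_pipeline(cfg, "results/run1")
```

## Analysis workflow

Numbered drivers under `analysis/` reproduce a full study run on
simulated data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # null + planted cohorts at study scale
Rscript analysis/02_qc_screen.R   # cohort summary, QC, carrier screen
Rscript analysis/03_epistasis.R   # order 1-3 sweeps via run_pipeline()
Rscript analysis/04_power.R       # power / familywise error study
```

## Documentation

See `vignettes/methods.Rmd` for the statistical methods, the design
decisions (exact HWE test, Yates correction default, `paper_literal` vs
`orthogonal` partition conventions, stratification scheme, FDR families)
and the generator's realism and limits.
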