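# reefcross

Quantitative genetics of selective breeding for coral heat tolerance.

`reefcross` models a breeding experiment in which corals from a
heat-experienced population ("PG", hot origin) and a heat-naive population
("IO", cool origin) are crossed in a dam × sire design, their larvae are
exposed to ambient and elevated temperatures, and the survivors of each
family × temperature pool are sequenced at thousands of biallelic loci.
The package covers the full path from raw count tables (or a built-in
forward simulator) to heritability estimates, SNP–survival associations,
heat-selection scans and Gene Ontology enrichment.

## Modules

- **Simulation** (`simulate_experiment()`, `population_model()`,
  `make_cross_design()`, `simulate_family_survival()`,
  `emit_read_counts()`): diverged source allele frequencies, Mendelian
  inheritance, genotype-dependent heat mortality on the logit scale, and
  pooled read-count sampling with sequencing error. All randomness flows
  from one master seed.
- **Genotyping** (`call_parent_genotype()`, `call_pooled_maf()`,
  `designate_minor_alleles()`, `filter_genotype_data()`): threshold-based
  parental genotype scores (error filter at a 5% read fraction, 5×
  coverage floor) and pooled minor-allele frequencies (50× floor) on a
  single global minor-allele axis per locus.
- **Phenotype statistics** (`relative_survival()`, `origin_effect_model()`,
  `variance_explained()`, `survival_index()`, `field_survival_summary()`):
  ambient-standardized survival, origin × temperature models with Tukey
  contrasts, partial eta-squared effect sizes, dam-relative paternal
  survival indices, and field-deployment summaries.
- **Heritability** (`estimate_heritability()`): a compiled Gibbs sampler
  for the Gaussian sire–dam variance-component model; additive variance
  via the paternal half-sib identity `V_A = 4 V_sire`, heritability with
  and without the maternal component, 95% credible intervals and
  effective sample sizes.
- **Association** (`scan_survival_association()`, `score_parents()`,
  `cluster_paternal_genotypes()`): per-locus binomial regression of hot
  survival on ambient pool frequency with an origin covariate, |R| ≥ 0.5
  "strong" classification, Bonferroni adjustment, beneficial-allele
  scoring of parents and clustering of paternal genotypes.
- **Selection** (`scan_selection()`, `summarize_selection()`,
  `hybrid_shift_pca()`): ambient-versus-hot allele-frequency shift tests
  on library-size-normalized counts, per-origin summaries, fixation
  contrasts, and a PCA of hybrid pools at strongly responding loci.
- **Enrichment** (`fisher_enrichment()`, `genes_from_loci()`): one-sided
  Fisher (hypergeometric tail) GO-term tests against a background of
  genes containing tested SNPs, with a minimum-background rule and
  optional true-path propagation.
- **Pipeline and I/O** (`run_pipeline()`, `stage_*()`,
  `default_run_config()`): schema-validated TSV/CSV interchange, byte-
  stable writers, a minimal GT-only VCF export, YAML run configuration,
  and a CLI wrapper (`inst/cli/reefcross.R`) with subcommands
  `simulate genotype phenostats assoc select enrich run`.

## Quick start

```r
library(reefcross)

# full synthetic experiment -> artifact directory
res <- run_pipeline(default_run_config(), "artifacts", seed = 1)

# or stage by stage
sim  <- simulate_experiment(seed = 1)
rel  <- relative_survival(sim$survival)
plates <- relative_survival(sim$plates)
h36  <- plates[plates$temperature == 36, ]
fit  <- estimate_heritability(h36$rel_survival, h36$sire_id, h36$dam_id)
print(fit)
```

From a shell:

```sh
Rscript inst/cli/reefcross.R run --seed 1 --out-dir artifacts
```

Exit codes: 0 success, 2 usage error, 1 stage failure.

## Testing

```r
testthat::test_dir("tests/testthat", package = "reefcross",
                   load_package = "installed")
```

The suite contains fast unit tests per module plus a statistical
acceptance suite (planted-signal recovery, heritability coverage,
Mendelian consistency of pooled frequencies, selection-scan ordering and
enrichment oracles) that takes several minutes.

See the vignette in `vignettes/` for the statistical model, the design
rationale behind the simulator defaults, and known limitations of
per-locus tests on crossed designs.
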