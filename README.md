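# cfscreen

Extended non-invasive prenatal testing (NIPT-PLUS) from binned
maternal-plasma cell-free DNA read counts, for people who build or study
cfDNA screening pipelines: simulation, calling and
screening-versus-diagnostic concordance in one R package.

Plasma cfDNA is a mixture of maternal DNA and a placental ("fetal")
fraction ff. The package implements the screening mathematics end to end:

- **Normalisation** — equal-read genome windows, relative read numbers
  `r_i = c_i / mean(c)`, and least-squares GC correction (iterated
  multiplicative removal of the fitted linear GC effect).
- **Aneuploidy calling** — per-chromosome corrected read fractions
  standardised against a euploid reference panel,
  `z_c = (x_c − μ_c)/σ_c`, positive at `|z| ≥ 3`, with a finite-panel
  calibration of σ so the 3-SD rule keeps its nominal normal tail; a
  decision table over chrX dosage and the chrY read share calls the sex
  karyotypes (45,X; 47,XXX; 47,XXY; 47,XYY).
- **CNV calling** — least-squares (quadratic-cost) changepoint
  segmentation, grow-then-prune binary splitting with a dynamic threshold
  `|mean − 1| ≥ z_t·σ̂/√L`, sizing in Mb and fetal/maternal origin
  attribution from the expected deviations `ff/2` vs `(1−ff)/2 … 1/2`.
- **Fetal fraction** — chrY-based estimation
  `(y − background)/(male_ref − background)` and a seqFF-style ridge
  regression on short-fragment (100–150 bp) enrichment, combined, with a
  3.5% lower detection limit.
- **Concordance** — an ISCN-style microarray result parser
  (`arr[GRCh37] 21q11.2q22.3(15,016,486_48,093,361)×3`, mosaic `×2–3`
  ranges), call matching by chromosome/karyotype/reciprocal overlap, and
  sensitivity / PPV / miss-rate tables with Wilson confidence intervals.
- **Simulation** — a maternal-plasma cohort generator with separate
  maternal, placental and fetal compartments on a reduced (1/20-scale,
  50-kb-bin) genome, negative-binomial counts, GC bias, fragment-length
  mixtures and scenario mixes covering trisomies, rare autosomal trisomies,
  sex-chromosome aneuploidies, fetal/maternal CNVs, mosaics and confined
  placental mosaicism — so every claim in the test suite is checked against
  generated truth.

The methods vignette (`vignettes/cfdna-screening-methods.Rmd`) documents
the models, parameter defaults and design decisions.

## Worked example

Simulate a trisomy-21 pregnancy (male fetus, ff = 0.18), screen it against
a euploid panel, and compare the screening calls with the rendered
diagnostic finding:

```r
library(cfscreen)

genome <- synthetic_genome()
config <- run_config()

y_cal       <- calibrate_y_reference(genome, n = 30, seed = 2)
seqff_model <- train_seqff(simulate_seqff_calibration(n = 50, genome = genome, seed = 3))
panel       <- build_panel(lapply(1:25, function(i)
  normalize_bintable(simulate_sample(sim_sample_spec(
    sample_id = i, fetal_sex = "female", fetal_fraction = 0.15,
    seed = child_seed(4, i)), genome)$bins)))

spec   <- scenario_sample_spec("t21", "demo", genome, ff = 0.18,
                               fetal_sex = "male", seed = 47)
sample <- simulate_sample(spec, genome)
calls  <- screen_sample(sample, panel, seqff_model, y_cal, config)
```

The fetal fraction is recovered by both routes and combined
(`ff_y = 0.177`, `ff_seqff = 0.180`, combined `0.179`, above the 3.5%
limit), and chromosome 21 crosses the 3-SD threshold:

```
  chromosome        z    call
1      chr21 4.771003 trisomy
```

The diagnostic truth renders as `arr[GRCh37] 21(1_2,400,000)×3`
(whole chr21 on the reduced genome), and matching classifies the pair:

```
  category class           detail
1      T21    TP              T21
2      SCA    TN
3      CNV    FP  chr4 dup 1.45Mb
4      CNV    FP chr14 dup 1.25Mb
5      CNV    FP chr18 del 0.25Mb
```

— a true-positive T21, plus the handful of sub-Mb noise segments a
per-segment 3-SD rule admits (see the vignette; `segmentation_config(
multiplicity_adjust = TRUE)` trades them against small-event sensitivity).

Reproducing a published comparison table from its packaged counts:

```r
rep3 <- build_report(fixture = read_fixture(cfscreen_fixture("aneuploidy_ppv_counts.tsv")))
rep3$metrics[, c("label", "n_screen_positive", "n_confirmed", "ppv")]
#>   label n_screen_positive n_confirmed   ppv
#> 1   T21                31          28 90.32
#> 2   T18                 8           7 87.50
#> 3   T13                 4           1 25.00
#> 4   SCA                45          40 88.89
#> 5   RAT                 8           4 50.00
```

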