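# otuSD

Whole-community toxicant sensitivity from 16S rRNA amplicon dose-response
experiments.

Conventional soil ecotoxicology measures the response of one test species or
one function to a toxicant. `otuSD` instead treats every operational
taxonomic unit (OTU) in an amplicon survey as a test organism: it fits a
dose-response curve to each OTU's absolute abundance across a spiking
series, extracts a per-OTU toxicity value (EC20), and assembles those values
into an *OTU sensitivity distribution* (OSD) — the microbial analogue of a
species sensitivity distribution — from which community-protective hazardous
concentrations (HCx) are derived. A parallel branch computes ECx values for
functional endpoints such as substrate-induced nitrification. The package is
aimed at microbial ecotoxicologists deriving soil quality thresholds for
metals and nanomaterials (e.g. Ag⁺, AgNPs, Ag₂S-NPs) from sequencing data.

## The method

**Preprocessing.** Read counts (OTUs × samples) are cleaned of singletons
and doubletons, rarefied to a common depth (default 9,000 reads, without
replacement), and converted to absolute, genome-equivalent abundance by
combining each sample's qPCR total 16S load *T(s)* with per-OTU 16S gene
copy numbers *CN(i)*:

    A(i,s) = T(s) · r(i,s) / CN(i)

where *r(i,s)* is the read relative abundance. An OTU enters curve fitting
for a treatment only if it is present in ≥ 6 of that treatment's samples
(shared controls count toward every arm).

**Dose-response models.** Each eligible OTU is fitted with the
four-parameter log-logistic model

    y = c + (d − c) / (1 + (x/e)^b)

and the five-parameter Brain–Cousens hormesis model

    y = c + (d − c + f·x) / (1 + (x/e)^b)

which allows low-dose stimulation (*f* > 0). A fit is accepted only when
(1) *b* > 0 (inhibition), (2) *e* is below the maximum spiking
concentration, and (3) R² > 0.65. If both models are accepted the hormesis
model is used, giving conservative EC20s; hormesis significance (Wald
t-interval on *f*) is reported as metadata. The EC20 is the dose reducing
the fitted upper-asymptote response by 20% (a span-referenced mode is also
available).

**Sensitivity distribution.** Per treatment, accepted EC20s are fitted by
maximum likelihood to a Burr Type III distribution,
F(x) = (1 + (b/x)^c)^(−k), and HCx values — the concentration affecting x%
of OTUs — are its quantiles. 95% confidence intervals come from a
nonparametric bootstrap over EC20 records; treatments are compared by CI
overlap.

**Functional endpoint.** Net nitrate production over 28 d
(NO₃⁻ at t=28 minus t=0), normalized to the control mean, is run through
the same fitting machinery to give EC10/EC20/EC50 with delta-method CIs
(hormesis is used there only when significant).

A synthetic-community generator with known ground truth
(`generateTruth()` / `simulateObserved()` / `simulateNitrification()`)
backs every parameter-recovery claim in the test suite.

## Worked example

```r
library(otuSD)

truth <- generateTruth(nOtus = 120, seed = 5,
    classProportions = c(insensitive = 0.3, loglogistic = 0.6, hormetic = 0.1),
    ec50Meanlog = log(15), ec50Sdlog = 0.8, abundSdlog = 1)
obs <- simulateObserved(truth, depth = 20000)
res <- runOsdPipeline(list(output_dir = tempfile(), n_boot = 200, seed = 7),
                      otu_experiment = obs)
#> 0 low-count OTUs removed (total count <= 2); 120 retained
#> [Ag] 120 eligible OTUs, 88 fitted with an EC20

head(res$ec20s[, 1:5], 3)
#>     otu_id treatment      ec20 model_used hormesis_significant
#> 1 OTU_0001        Ag 31.656814  hormesis5                FALSE
#> 2 OTU_0003        Ag  9.495582  hormesis5                 TRUE
#> 3 OTU_0004        Ag  5.067096  hormesis5                FALSE

res$hc[, c("protection_percent", "value", "ci_low", "ci_high", "n_ec20")]
#>   protection_percent     value     ci_low   ci_high n_ec20
#> 1                  5  1.402208  0.6459616  2.714019     88
#> 2                 10  2.500822  1.4519774  3.904811     88
#> 3                 20  4.562574  3.1387605  6.202679     88
#> 4                 80 26.966878 20.8643608 35.667054     88
```

Of 120 simulated OTUs, 88 produced an accepted dose-response curve and an
EC20. The HC table reads: 95% of OTUs are protected below
1.40 mg Ag kg⁻¹ (HC5, bootstrap 95% CI 0.65–2.71), 80% below
4.56 mg kg⁻¹ (HC20), while only the most tolerant 20% of OTUs withstand
concentrations above 27 mg kg⁻¹ (HC80). Treatments run side by side get
per-level significance letters from CI overlap.

A file-based interface with the same stages (`simulate`, `preprocess`,
`fit-otus`, `osd`, `nitrif`, `pipeline`) is available as a thin script:

```sh
Rscript inst/scripts/otusd-cli.R simulate --out-dir sim --n-otus 200 --seed 1
```

## Vignette

`vignettes/otu-sensitivity-methods.Rmd` documents the models, the
acceptance rules, every tunable constant with its default and units, the
synthetic generator's noise model, numerical choices, and known
limitations.
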