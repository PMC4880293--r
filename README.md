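# dyadHMM

Inference of DNA methylation maintenance, de novo methylation and
Tet-mediated hydroxylation dynamics at CpG dyads from hairpin bisulfite
(BS) and oxidative bisulfite (oxBS) sequencing counts.

## The problem

In dividing cells (mouse ESCs shifted from serum/LIF into 2i medium are
the canonical system) DNA methylation is progressively lost.  Oxidation
of 5-methylcytosine (5mC) to 5-hydroxymethylcytosine (5hmC) is suspected
to drive part of this loss by hiding hemimethylated CpGs from the
Dnmt1/Uhrf1 maintenance machinery.  Hairpin sequencing reads both
strands of one molecule, so the strand-resolved state of each CpG dyad
is observable; splitting the sample into a BS arm (5mC and 5hmC both
read C) and an oxBS arm (only 5mC reads C) makes 5hmC quantifiable.

`dyadHMM` models the dyad as a nine-state discrete-time hidden Markov
chain over `{u, m, h}^2` with one step per cell division,

```
P(t) = D · M(t) · H(t)
```

— replication dilution `D`, methylation `M` with maintenance efficiency
μ_m(t), de novo efficiency μ_d(t) (total efficiency on hemimethylated
dyads λ(t) = μ_m + μ_d − μ_m·μ_d) and a non-recognition probability `p`
for hemi-hydroxylated dyads, and per-strand hydroxylation `H` with
efficiency η(t).  Efficiencies are linear in the division index,
giving a seven-parameter vector estimated by maximum likelihood from
BS/oxBS read-pair counts (`TT/TC/CT/CC`) observed through explicit
conversion-error channels.  The package provides
observed-Fisher-information standard errors, Wald tests on the
efficiency slopes (including the joint 2-df test on the time
coefficients of λ), leave-one-timepoint-out cross-validation of linear
versus constant efficiencies, a synthetic hairpin data generator, and a
small command line (`inst/cli/dyadhmm`).

## Worked example

Simulate a demethylating locus under the package's default study
conditions (days 0/1/3/6, 10^4 read pairs per day and treatment, ground
truth μ_m = 0.8, μ_d = 0.3 − 0.02 t, η = 0.05 + 0.03 t, p = 1) and run
the full pipeline:

```r
library(dyadHMM)

cfg <- simulation_config(seed = 42)
ds  <- generate_dataset(cfg)

pi0 <- estimate_initial_distribution(ds, starts = 20, seed = 1)
fit <- fit_efficiencies(ds, pi0$pi0, starts = 20, seed = 1)
print(fit)
#> Dyad HMM efficiency fit (linear efficiencies, t_max = 6)
#>                estimate     sd ci_lower ci_upper note
#> mu_m_intercept   0.7947 0.0101   0.7750   0.8145
#> mu_m_slope      -0.0045 0.0035  -0.0113   0.0024
#> mu_d_intercept   0.2978 0.0093   0.2795   0.3161
#> mu_d_slope      -0.0185 0.0019  -0.0222  -0.0147
#> eta_intercept    0.0422 0.0058   0.0309   0.0535
#> eta_slope        0.0314 0.0019   0.0277   0.0350
#> p                0.9893 0.0341   0.9224   1.0000
#> -log L2: 72181.33  | converged starts: 19 / 20
```

Every interval covers its generating value: maintenance is flat near
0.8, de novo declines by ~0.02 per division, hydroxylation rises by
~0.03, and the non-recognition probability is pushed to 1 — the regime
in which 5hmC accumulation passively dilutes methylation.  The slope
tests and the model comparison agree that the dynamics are genuinely
time-dependent:

```r
wald_slope_test(fit, "eta")
#> Wald test, H0: eta_slope = 0
#> z statistic: 16.89546
#> p-value: < 2.22e-16 -> reject at alpha = 0.01

loocv_compare(ds, pi0 = pi0$pi0, starts = 10, seed = 1)$improvement
#>            kl bhattacharyya
#>         0.982         0.982   # linear beats constant on held-out days

round(predict_timecourse(fit)[, c("day", "fully_methylated",
  "hemimethylated", "unmethylated", "hydroxylated_total", "lambda")], 3)
#>   day fully_methylated hemimethylated unmethylated hydroxylated_total lambda
#> 1   0            0.705          0.088        0.058              0.148     NA
#> 2   1            0.586          0.152        0.056              0.207  0.849
#> 3   3            0.413          0.164        0.128              0.295  0.834
#> 4   6            0.216          0.150        0.245              0.390  0.811
```

The timecourse table gives the fitted hidden-state summaries per day:
loss of fully methylated dyads, transient hemimethylation, and the
growing fraction of dyads carrying at least one 5hmC.

The same pipeline runs from the shell on TSV count tables:

```sh
Rscript inst/cli/dyadhmm simulate --config sim.yaml --out simdir --seed 42
Rscript inst/cli/dyadhmm fit --counts simdir/counts.tsv \
    --errors simdir/conversion.tsv --out fitdir --starts 20 --seed 1
Rscript inst/cli/dyadhmm loocv --counts simdir/counts.tsv \
    --errors simdir/conversion.tsv --out cvdir --seed 1
```

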