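---
title: "Modelling CpG dyad methylation and hydroxylation dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CpG dyad methylation and hydroxylation dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadHMM)
```

## The model

A palindromic CpG dyad carries one cytosine per strand, each unmethylated
(`u`), methylated (`m`, 5mC) or hydroxylated (`h`, 5hmC).  The dyad state
is the ordered pair of strand marks, giving nine hidden states in the
fixed canonical order `uu, um, mu, uh, hu, mm, mh, hm, hh` (grouped by
number of modified strands so matrices read naturally).  The state
evolves as a discrete-time Markov chain with one step per cell division;
each step is the product of three event matrices,

$$P(t) = D \cdot M(t) \cdot H(t),$$

applied strictly in that order:

* **Replication dilution** $D$: one strand, chosen with probability 0.5,
  is replaced by a newly synthesized unmodified strand.  Averaging over
  daughter cells, `mm` moves to `um` or `mu` with probability 0.5 each,
  `hh` to `uh`/`hu`, and so on.  $D$ is parameter-free and identical for
  every division; no time dependence is modelled.
* **Methylation** $M(t)$: on `uu`, two independent de novo events with
  probability $\mu_d(t)$ each.  On hemimethylated dyads the unmodified
  strand is methylated with the total efficiency
  $\lambda(t) = \mu_m(t) + \mu_d(t) - \mu_m(t)\mu_d(t)$ — maintenance
  acts first, de novo catches its failures.  On `uh`/`hu` the hydroxyl
  group escapes the maintenance machinery with probability $p$, leaving
  only de novo; with probability $1-p$ the dyad is handled as
  hemimethylated, so the transition probability to `mh`/`hm` is
  $p\,\mu_d + (1-p)\,\lambda$.  States `mm`, `mh`, `hm`, `hh` have no
  unmodified target cytosine and are untouched.
* **Hydroxylation** $H(t)$: each methylated strand is oxidized to `h`
  independently with probability $\eta(t)$.  Because $H$ follows $M$, a
  cytosine can pass `u` → `m` → `h` within one cycle.

Each efficiency is linear in the division index,
$f(t) = \beta_0 + \beta_1 t$, yielding seven free parameters (three
intercept/slope pairs plus $p$).  The efficiency of the $t$-th cycle is
evaluated at integer $t \ge 1$, the first cycle being $t = 1$.  With one
division per day (the default `divisions_per_day = 1`, matching a 24 h
cycle time) observation days index divisions directly; other regimes are
configurable.

Oxidized states beyond 5hmC (5fC/5caC) and replication-independent
(active) demethylation are deliberately outside the model, as is any
dependence between neighbouring CpGs.  When $\eta = 0$ the per-strand
5hmC level obeys an exact halving law, $\ell(t) = \ell(0)/2^t$, because
no event other than replication touches an `h` strand — the package's
tests verify this as a matrix identity.

## Observations and conversion errors

Hairpin sequencing reads both strands of one molecule, so the observable
is the read pair over `{T, C}` in the canonical order
`TT, TC, CT, CC`.  Under bisulfite treatment (BS) an unmodified C
converts to T with probability $c$ and 5mC/5hmC are retained as C with
probabilities $d$ and $e$; under oxidative bisulfite (oxBS) 5hmC is
instead converted to T with probability $f$.  The two strands pass
through independent channels, so each 9×4 emission matrix factorizes
over strands.  Profiles are per treatment and may vary by day and locus;
they are estimated from the unmodified C, 5mC and 5hmC controls built
into the hairpin linker as unconverted/total tallies
(`estimate_conversion_errors()`).  Miscalls other than conversion
failure are not modelled separately — they are absorbed into
$c, d, e, f$.

The generator's default profiles ($c = 0.995$, $d = 0.98$, $e = 0.95$
for BS; $c = 0.995$, $d = 0.98$, $f = 0.93$ for oxBS) are typical of
deep hairpin-linker control measurements: sub-percent failure to convert
unmodified C, a few percent loss of 5mC, and a somewhat noisier 5hmC
channel, oxBS being the harder chemistry.

## Inference

Both treatments observe the same hidden chain through different
emissions.  The initial distribution $\pi(0)$ is estimated from day-0
counts by maximizing
$L_1(\pi(0)) = \prod_j \pi_{bs}(j,0)^{n_{bs}(j,0)}\,\pi_{ox}(j,0)^{n_{ox}(j,0)}$
on the 9-simplex.  Because $\log L_1$ is concave in $\pi(0)$ (the log of
a linear map), the package uses multi-start EM rather than a generic
box-constrained optimizer: EM ascends monotonically and reaches boundary
optima, which a log-barrier method cannot.  Day-0 data carry only
$3 + 3$ observable degrees of freedom against 8 free parameters, so the
maximizer is generically a face, not a point; all starts reach the same
likelihood but possibly different vectors, and the spread among
likelihood-equivalent optima is reported as a non-identifiability
diagnostic.  An optional strand-symmetry constraint
($\pi_{um} = \pi_{mu}$ etc., `symmetric = TRUE`) restores generic
identifiability; it is off by default so that hemimethylated states are
reported separately.

Given $\pi(0)$, the seven-parameter vector is estimated by minimizing
$-\log L_2$ over all post-day-0 timepoints, treating counts at distinct
days as independent (measurements sample a vanishing fraction of a large
pool).  The constraint $f(t) \in [0,1]$ for all fitted $t$ is, by
linearity, equivalent to requiring it at $t = 1$ and $t = t_{\max}$, so
each pair is reparameterized by its endpoint values
$(f(1), f(t_{\max})) \in [0,1]^2$, a bijection for $t_{\max} > 1$ that
turns the problem into a pure box constraint solved with L-BFGS-B.
Defaults: 20 uniform starts in the box (seeded), objective tolerance
near $10^{-9}$ (`factr = 100`), ties between starts broken by objective
then lexicographic parameter order.  A likelihood of zero for an
observed category maps to a large finite penalty so the optimizer can
back away from degenerate regions.

Uncertainty comes from the observed Fisher information: the numerical
Hessian (central differences via `pracma::hessian`) of $-\log L_2$ at
the optimum over the free natural parameters, inverted for the
asymptotic covariance.  A singular information matrix falls back to the
pseudo-inverse and is flagged; parameters whose efficiency touches 0 or
1 within $10^{-4}$ at either end of the fitted range are flagged as
boundary-pinned, and $p$'s confidence interval is truncated to
$[0,1]$.  Slope hypotheses ($H_0: \beta_1 = 0$) use the normal Wald
statistic at the 1% level.  Because $\lambda(t)$ is quadratic in $t$
with coefficients
$\lambda_1 = a_1 + b_1 - a_0 b_1 - a_1 b_0$ and
$\lambda_2 = -a_1 b_1$ (where $(a_0, a_1)$ and $(b_0, b_1)$ are the
maintenance and de novo pairs), the joint hypothesis
$\lambda_1 = \lambda_2 = 0$ is tested with a 2-df chi-square statistic
whose covariance comes from the delta method at the optimum.

## Cross-validation

To guard against overfitting from the linearity assumption,
`loocv_compare()` holds out each post-day-0 timepoint in turn (the
timepoints are the only exchangeable blocks), refits the linear and the
constant (slopes fixed to zero) model on the remaining days with
$\pi(0)$ held fixed from day 0, and scores the held-out day's empirical
read-pair distributions with $\mathrm{KL}(\text{empirical}\,\|\,
\text{predicted})$ — predicted probabilities smoothed additively by
$10^{-12}$ — and the Bhattacharyya distance, summed over the two
treatments.  Training folds are fitted with the box constraints enforced
up to the full data's $t_{\max}$, not the fold's, so the extrapolated
efficiencies remain valid probabilities at the held-out day.  The
headline number is the relative improvement
$(\text{constant} - \text{linear})/\text{constant}$; positive values
favour the linear model.

## The synthetic-data generator

`simulation_config()` fixes the study conditions the package is
validated under: observation days 0, 1, 3, 6 with one division per day;
$10^4$ read pairs per day and treatment; ground-truth efficiencies
$\mu_m = 0.8$, $\mu_d = 0.3 - 0.02t$, $\eta = 0.05 + 0.03t$, $p = 1$ (a
locus with steady maintenance, declining de novo activity and rising
hydroxylation, the regime the model was built to resolve); and an
initial distribution dominated by `mm` (0.70) with a small 5hmC
fraction, as expected for a methylated locus under serum/LIF before the
shift to 2i medium.  Dyads are i.i.d. — no lineage correlation — and the
BS and oxBS pools are disjoint samples of the same hidden chain,
mirroring the split of hairpin-ligated DNA into the two treatments.
Reads are emitted through the same conversion channels the likelihood
assumes.

What the generator does *not* emulate: PCR duplicates and
amplification bias, read-level quality and alignment artifacts,
cell-cycle desynchronization (every dyad divides exactly once per day),
lineage correlation between sampled molecules, and locus heterogeneity
within aggregated repeat families.  Passing recovery tests therefore
demonstrate correctness of the inference machinery under the model's own
assumptions, not robustness to these real-data effects.

## Validation design and problem sizes

The test suite validates the chain against two independent oracles: an
event-level one-step simulator (uniform strand replacement, sequential
maintenance/de novo draws, per-strand hydroxylation) whose empirical
frequencies must match every transition row within total variation 0.01
at $10^5$ dyads, and a separate 4-state u/m-only implementation that
must reproduce the full model's methylation estimates to $10^{-6}$ when
hydroxylation is switched off (both fits then use a tightened
`factr = 1` so the comparison is limited by the optima, not the
stopping rule).  Parameter recovery uses 50 simulated replicates at the
study conditions (confidence-interval coverage and a 0.05 absolute
error band on every efficiency at every division), Wald calibration 100
constant-efficiency replicates, and the cross-validation contrast 20
replicates per regime.  Recovery-style simulations supply the
generator's true $\pi(0)$ to the efficiency fit: day-0 counts leave
$\pi(0)$ under-determined (see above), and conditioning on the known
initial state isolates the estimator under test.  `scripts/acceptance.R`
re-runs the same battery at moderately reduced replicate counts and
writes the measured quantities as JSON.

## Limitations

* $\pi(0)$ is not point-identified from day-0 marginals; downstream
  efficiency estimates inherit this ambiguity when $\pi(0)$ must be
  estimated.  Use `symmetric = TRUE`, or inspect the reported spread.
* Efficiencies are linear in $t$; strongly non-monotone enzyme dynamics
  will be projected onto the nearest linear trend (the LOOCV comparison
  flags when even linearity overfits).
* A fit that pushes $p$ or an efficiency to its bound has a
  non-standard sampling distribution there; intervals are truncated and
  flagged rather than corrected.
* With low 5hmC levels, $p$ is weakly identified — its likelihood
  contribution vanishes with the mass on `uh`/`hu`.
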