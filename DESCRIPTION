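Package: dyadHMM
Title: Hidden Markov Modelling of CpG Dyad Methylation and Hydroxylation
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the fate of 5-methylcytosine (5mC) and
    5-hydroxymethylcytosine (5hmC) at palindromic CpG dyads across cell
    divisions with a nine-state discrete-time hidden Markov model.  Hidden
    dyad states evolve through replication-coupled dilution, maintenance
    and de novo methylation, and Tet-mediated hydroxylation; observations
    are strand-resolved hairpin bisulfite (BS) and oxidative bisulfite
    (oxBS) read-pair counts with explicit conversion-error channels.
    Provides maximum-likelihood estimation of the initial dyad-state
    distribution and of time-linear enzymatic efficiency functions,
    observed-Fisher-information standard errors and confidence intervals,
    Wald tests on efficiency slopes, leave-one-out cross-validation for
    linear-versus-constant model comparison, a synthetic hairpin BS/oxBS
    data generator, and TSV-based input/output with a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
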