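# Synthetic hairpin BS/oxBS data generator.
#
# Dyads are simulated i.i.d. (sampled cells are unlikely to share a
# recent ancestor, matching the independence assumption of the
# likelihood), and the BS and oxBS pools are disjoint samples of the same
# hidden chain, mirroring the split of the hairpin-ligated DNA into the
# two treatments.

#' Configuration for the synthetic-data generator
#'
#' The defaults emulate the study conditions the package is designed
#' for: a methylated locus in serum/LIF shifted into 2i medium, observed
#' at days 0, 1, 3 and 6 with one division per day, deep coverage
#' (10,000 read pairs per day and treatment) and realistic
#' hairpin-linker conversion error rates.
#'
#' @param model Ground-truth [efficiency_model()].  Default: constant
#'   maintenance 0.8, declining de novo `0.3 - 0.02 t`, rising
#'   hydroxylation `0.05 + 0.03 t`, full non-recognition `p = 1`.
#' @param pi0 Ground-truth initial distribution.  Default: a
#'   predominantly methylated locus with a small 5hmC fraction.
#' @param days Observation days (must include 0 for initial-distribution
#'   estimation downstream).
#' @param coverage Read pairs per day and treatment: a scalar, or a data
#'   frame with columns `day`, `treatment`, `coverage`.
#' @param profiles Conversion profiles as accepted by
#'   [observation_dataset()]; the default has small BS/oxBS conversion
#'   errors typical of hairpin-linker controls.
#' @param n_cpg Number of CpG positions per locus (per-CpG mode: one
#'   count table per position sharing the ground truth).
#' @param divisions_per_day Divisions per observation day.
#' @param seed Integer seed; identical configurations and seeds yield
#'   identical counts.
#' @param locus Locus label.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(model = efficiency_model(
                                mu_m = c(0.8, 0), mu_d = c(0.3, -0.02),
                                eta = c(0.05, 0.03), p = 1
                              ),
                              pi0 = c(
                                uu = 0.06, um = 0.04, mu = 0.04,
                                uh = 0.01, hu = 0.01, mm = 0.70,
                                mh = 0.05, hm = 0.05, hh = 0.04
                              ),
                              days = c(0, 1, 3, 6), coverage = 10000,
                              profiles = list(
                                bs = conversion_profile("bs", c = 0.995, d = 0.98, e = 0.95),
                                ox = conversion_profile("ox", c = 0.995, d = 0.98, f = 0.93)
                              ),
                              n_cpg = 1L, divisions_per_day = 1L,
                              seed = NULL, locus = "synthetic") {
  stopifnot(inherits(model, "efficiency_model"))
  pi0 <- as_hidden_distribution(pi0)
  if (any(days < 0 | days != round(days))) stop("days must be nonnegative integers")
  days <- sort(unique(days))
  if (is.data.frame(coverage)) {
    if (!all(c("day", "treatment", "coverage") %in% names(coverage))) {
      stop("coverage data frame needs columns day, treatment, coverage")
    }
  } else {
    if (!is.numeric(coverage) || length(coverage) != 1L || coverage < 0) {
      stop("`coverage` must be a nonnegative scalar or a data frame")
    }
  }
  structure(
    list(
      model = model, pi0 = pi0, days = days, coverage = coverage,
      profiles = .normalize_profiles(profiles), n_cpg = as.integer(n_cpg),
      divisions_per_day = as.integer(divisions_per_day),
      seed = seed, locus = locus
    ),
    class = "simulation_config"
  )
}

.coverage_for <- function(config, day, treatment) {
  cov <- config$coverage
  if (is.data.frame(cov)) {
    hit <- cov[cov$day == day & cov$treatment == treatment, "coverage"]
    if (!length(hit)) 0 else hit[1L]
  } else {
    cov
  }
}

# Advance a pool of dyads (state counts, length 9) through one division.
.step_pool <- function(state_counts, P) {
  out <- numeric(9L)
  for (i in which(state_counts > 0)) {
    out <- out + stats::rmultinom(1L, state_counts[i], P[i, ])[, 1L]
  }
  out
}

#' Simulate hidden dyad pools over the observation days
#'
#' Draws one independent pool of dyads per treatment from `pi0`,
#' propagates each dyad by sampling transitions from `P(1), P(2), ...`
#' and records the pool's state counts at every observation day.  The
#' pool size per treatment is the maximum coverage requested for that
#' treatment; [simulate_reads()] subsamples per day.
#'
#' @param config A [simulation_config()].
#' @return List with elements `bs` and `ox`, each a `days x 9` matrix of
#'   hidden-state counts (rows named by day).
#' @export
simulate_hidden_states <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  dpd <- config$divisions_per_day
  t_obs <- config$days * dpd
  out <- list()
  for (tr in c("bs", "ox")) {
    size <- max(vapply(config$days, function(d) .coverage_for(config, d, tr), numeric(1)))
    pool <- stats::rmultinom(1L, size, config$pi0)[, 1L]
    rec <- matrix(0, length(config$days), 9L,
      dimnames = list(config$days, DYAD_STATES)
    )
    t_now <- 0L
    for (di in seq_along(config$days)) {
      while (t_now < t_obs[di]) {
        t_now <- t_now + 1L
        pool <- .step_pool(pool, transition_matrix(t_now, config$model))
      }
      rec[di, ] <- pool
    }
    out[[tr]] <- rec
  }
  out
}

#' Convert hidden dyad pools to observed read-pair counts
#'
#' Each dyad emits a read pair through the treatment's conversion
#' channels; per day, `coverage` dyads are subsampled from the pool
#' without replacement before emission.
#'
#' @param hidden Output of [simulate_hidden_states()].
#' @param config The same [simulation_config()].
#' @return Data frame with columns `day`, `treatment`, `TT`, `TC`, `CT`,
#'   `CC`; days with zero coverage are omitted.
#' @export
simulate_reads <- function(hidden, config) {
  stopifnot(inherits(config, "simulation_config"))
  # temporary dataset to reuse the profile lookup
  proto <- structure(list(profiles = config$profiles), class = "observation_dataset")
  rows <- list()
  for (tr in c("bs", "ox")) {
    rec <- hidden[[tr]]
    for (di in seq_along(config$days)) {
      day <- config$days[di]
      n_want <- .coverage_for(config, day, tr)
      if (n_want <= 0) next
      pool <- rec[di, ]
      if (sum(pool) > n_want) {
        # subsample dyads without replacement
        drawn <- sample(rep.int(seq_len(9L), pool), n_want)
        pool <- tabulate(drawn, nbins = 9L)
      }
      E <- emission_matrix(get_profile(proto, day, tr))
      counts <- numeric(4L)
      for (i in which(pool > 0)) {
        counts <- counts + stats::rmultinom(1L, pool[i], E[i, ])[, 1L]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        day = day, treatment = tr,
        TT = counts[1L], TC = counts[2L], CT = counts[3L], CC = counts[4L]
      )
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic hairpin BS/oxBS dataset
#'
#' Composes [simulate_hidden_states()] and [simulate_reads()] under the
#' configuration's seed.  In per-CpG mode (`n_cpg > 1`) each position is
#' simulated independently from the shared ground truth.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; if given, writes `counts.tsv`,
#'   `conversion.tsv` and a `truth.yaml` sidecar recording the
#'   ground-truth parameters.
#' @return A single [observation_dataset()] (`n_cpg = 1`) or a list of
#'   one per CpG position, each with the ground truth attached as
#'   `attr(, "ground_truth")`.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  truth <- list(
    efficiencies = list(
      mu_m = config$model$mu_m, mu_d = config$model$mu_d,
      eta = config$model$eta, p = config$model$p
    ),
    pi0 = as.list(config$pi0),
    days = config$days, divisions_per_day = config$divisions_per_day
  )
  make_one <- function(pos) {
    counts <- simulate_reads(simulate_hidden_states(config), config)
    ds <- observation_dataset(counts,
      profiles = config$profiles, locus = config$locus,
      cpg_position = pos, divisions_per_day = config$divisions_per_day
    )
    attr(ds, "ground_truth") <- truth
    ds
  }
  datasets <- if (config$n_cpg > 1L) {
    stats::setNames(
      lapply(seq_len(config$n_cpg), function(i) make_one(as.character(i))),
      paste0(config$locus, ":", seq_len(config$n_cpg))
    )
  } else {
    make_one("aggregate")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_counts(datasets, file.path(out_dir, "counts.tsv"))
    prof <- cbind(locus = config$locus, config$profiles)
    write_conversion_errors(prof, file.path(out_dir, "conversion.tsv"))
    yaml::write_yaml(truth, file.path(out_dir, "truth.yaml"))
  }
  datasets
}
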