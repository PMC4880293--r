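# Leave-one-out cross-validation: linear versus constant efficiencies.
#
# Observation timepoints are the only exchangeable blocks in this design,
# so each post-day-0 day is held out in turn.  The initial distribution
# stays fixed (estimated once from day-0 data, or supplied); both models
# are refit on the remaining days and scored on the held-out day's
# empirical read-pair distributions.

.kl_divergence <- function(empirical, predicted, smooth = 1e-12) {
  predicted <- predicted + smooth
  pos <- empirical > 0
  sum(empirical[pos] * log(empirical[pos] / predicted[pos]))
}

.bhattacharyya <- function(empirical, predicted) {
  -log(sum(sqrt(empirical * predicted)))
}

#' Cross-validated comparison of linear and constant efficiency models
#'
#' For each held-out post-day-0 timepoint, fits the linear model (slopes
#' free) and the constant model (slopes fixed to zero) on the remaining
#' timepoints, predicts the held-out observable distributions for both
#' treatments, and scores the prediction with the Kullback-Leibler
#' divergence `KL(empirical || predicted)` (predicted probabilities
#' smoothed additively by 1e-12) and the Bhattacharyya distance
#' `-log sum_j sqrt(empirical_j * predicted_j)`, summed over the two
#' treatments.  Reports per-fold values and the relative improvement
#' `(constant - linear) / constant` of the totals for each divergence.
#'
#' @param data An [observation_dataset()] with at least 3 post-day-0
#'   timepoints.
#' @param pi0 Initial distribution; `NULL` (default) estimates it once
#'   from day-0 data and keeps it fixed across folds.
#' @param starts,seed Passed to [fit_efficiencies()] for each fold.
#' @return An object of class `"dyad_loocv"`: `folds` (per-fold, per-model
#'   divergences), `totals` and `improvement` (relative improvement per
#'   divergence; positive favours the linear model).
#' @export
loocv_compare <- function(data, pi0 = NULL, starts = 10L, seed = NULL) {
  stopifnot(inherits(data, "observation_dataset"))
  days <- setdiff(data$days, 0)
  if (length(days) < 3L) {
    stop("LOOCV needs at least 3 post-day-0 timepoints, got ", length(days))
  }
  if (is.null(pi0)) {
    pi0 <- estimate_initial_distribution(data, seed = seed)$pi0
  }
  pi0 <- as_hidden_distribution(pi0)
  dpd <- data$divisions_per_day
  t_max <- max(days) * dpd

  folds <- list()
  for (i in seq_along(days)) {
    held <- days[i]
    train <- observation_dataset(
      data$counts[!(data$counts$day %in% held) | data$counts$day == 0, , drop = FALSE],
      profiles = data$profiles, locus = data$locus,
      cpg_position = data$cpg_position, divisions_per_day = dpd
    )
    for (model_kind in c("constant", "linear")) {
      fit <- fit_efficiencies(train, pi0,
        starts = starts,
        seed = if (is.null(seed)) NULL else seed + i,
        trend = model_kind, t_max = t_max, compute_fim = FALSE
      )
      pi_held <- propagate(pi0, fit$model, held * dpd, clamp = TRUE)
      kl <- 0
      bh <- 0
      for (tr in c("bs", "ox")) {
        n <- counts_for(data, held, tr)
        if (is.null(n) || sum(n) == 0) next
        emp <- n / sum(n)
        pred <- observable_distribution(pi_held, get_profile(data, held, tr))
        kl <- kl + .kl_divergence(emp, pred)
        bh <- bh + .bhattacharyya(emp, pred)
      }
      folds[[length(folds) + 1L]] <- data.frame(
        day = held, model = model_kind, kl = kl, bhattacharyya = bh
      )
    }
  }
  folds <- do.call(rbind, folds)
  totals <- stats::aggregate(folds[c("kl", "bhattacharyya")],
    by = list(model = folds$model), FUN = sum
  )
  tot <- function(model, col) totals[totals$model == model, col]
  improvement <- c(
    kl = (tot("constant", "kl") - tot("linear", "kl")) / tot("constant", "kl"),
    bhattacharyya = (tot("constant", "bhattacharyya") - tot("linear", "bhattacharyya")) /
      tot("constant", "bhattacharyya")
  )
  structure(
    list(folds = folds, totals = totals, improvement = improvement, pi0 = pi0),
    class = "dyad_loocv"
  )
}

#' @export
print.dyad_loocv <- function(x, digits = 4, ...) {
  cat("Leave-one-timepoint-out comparison, linear vs constant efficiencies\n")
  print(round_df(x$folds, digits))
  cat("relative improvement of the linear model ((constant - linear)/constant):\n")
  print(round(x$improvement, digits))
  invisible(x)
}
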