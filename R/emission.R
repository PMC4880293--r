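# Emission model: from hidden dyad states to hairpin read pairs.
#
# Bisulfite chemistry reads an unmodified C as T (conversion to uracil)
# and 5mC as C.  5hmC reads as C under plain bisulfite (BS) but as T under
# oxidative bisulfite (oxBS), where it is first oxidized to 5fC.  Each
# channel has a per-experiment success probability estimated from control
# cytosines embedded in the hairpin linker:
#   c - unmodified C correctly converted (read T), both treatments
#   d - 5mC correctly retained (read C), both treatments
#   e - 5hmC retained as C, BS only
#   f - 5hmC converted to T, oxBS only

#' Conversion-probability profile for one treatment
#'
#' @param treatment `"bs"` or `"ox"`.
#' @param c Probability that an unmodified cytosine is correctly converted
#'   (read as T).
#' @param d Probability that a 5mC is correctly retained (read as C).
#' @param e BS only: probability that a 5hmC is retained as C.
#' @param f oxBS only: probability that a 5hmC is converted to T.
#' @param day Optional timepoint label; profiles may differ between
#'   treatments and over time.
#' @return An object of class `"conversion_profile"`.
#' @export
conversion_profile <- function(treatment = c("bs", "ox"), c = 1, d = 1,
                               e = NULL, f = NULL, day = NA) {
  treatment <- match.arg(treatment)
  .check_prob(c, "c")
  .check_prob(d, "d")
  if (treatment == "bs") {
    if (is.null(e)) stop("BS profile requires `e` (5hmC retained as C)", call. = FALSE)
    .check_prob(e, "e")
    f <- NULL
  } else {
    if (is.null(f)) stop("oxBS profile requires `f` (5hmC converted to T)", call. = FALSE)
    .check_prob(f, "f")
    e <- NULL
  }
  structure(
    list(treatment = treatment, c = c, d = d, e = e, f = f, day = day),
    class = "conversion_profile"
  )
}

#' Per-strand read distribution of a cytosine mark
#'
#' @param mark One of `"u"`, `"m"`, `"h"`.
#' @param profile A [conversion_profile()].
#' @return Named numeric `c(T = , C = )`.
#' @export
strand_emission <- function(mark, profile) {
  stopifnot(inherits(profile, "conversion_profile"))
  mark <- match.arg(mark, c("u", "m", "h"))
  pr_C <- switch(mark,
    u = 1 - profile$c,
    m = profile$d,
    h = if (profile$treatment == "bs") profile$e else 1 - profile$f
  )
  c(T = 1 - pr_C, C = pr_C)
}

#' Emission matrix of a treatment
#'
#' The two strands of a hairpin molecule are read through independent
#' conversion channels, so the dyad emission probability factorizes:
#' `E[(s1, s2), (r1, r2)] = P(r1 | s1) * P(r2 | s2)`.
#'
#' @param profile A [conversion_profile()].
#' @return A 9 x 4 row-stochastic matrix, rows in canonical dyad-state
#'   order, columns `TT, TC, CT, CC`.
#' @export
emission_matrix <- function(profile) {
  per_mark <- vapply(c("u", "m", "h"), strand_emission,
    numeric(2),
    profile = profile
  ) # 2 x 3, rows T/C
  E <- matrix(0, 9, 4, dimnames = list(DYAD_STATES, OBS_STATES))
  reads <- matrix(unlist(strsplit(OBS_STATES, "")), ncol = 2, byrow = TRUE)
  for (i in 1:9) {
    for (j in 1:4) {
      E[i, j] <- per_mark[reads[j, 1], .STATE_MARKS[i, 1]] *
        per_mark[reads[j, 2], .STATE_MARKS[i, 2]]
    }
  }
  E
}

#' Distribution over observable read pairs
#'
#' Computes `pi_obs(t) = pi(t) %*% E` for one treatment.
#'
#' @param pi Hidden-state distribution (see [as_hidden_distribution()]).
#' @param profile A [conversion_profile()].
#' @return Named numeric vector over `TT, TC, CT, CC` summing to 1.
#' @export
observable_distribution <- function(pi, profile) {
  pi <- as_hidden_distribution(pi)
  out <- as.vector(pi %*% emission_matrix(profile))
  names(out) <- OBS_STATES
  out
}

#' Estimate conversion probabilities from hairpin-linker controls
#'
#' The hairpin linker carries unmodified C, 5mC and 5hmC at known
#' positions; the per-channel error rate is the number of control bases
#' read in the wrong channel divided by the total analyzed.  Tallies are
#' given as (unconverted, total), where "unconverted" means read as C.
#'
#' @param control_counts Data frame with columns `base` (one of `"C"`,
#'   `"mC"`, `"hmC"`), `unconverted` (count read as C) and `total`.
#' @param treatment `"bs"` or `"ox"`.
#' @param day Optional timepoint label.
#' @return A [conversion_profile()].  `c = 1 - unconverted/total` for C
#'   controls; `d = unconverted/total` for 5mC controls (retention is the
#'   desired outcome); `e = unconverted/total` (BS) or
#'   `f = 1 - unconverted/total` (oxBS) for 5hmC controls.
#' @export
estimate_conversion_errors <- function(control_counts, treatment = c("bs", "ox"),
                                       day = NA) {
  treatment <- match.arg(treatment)
  need <- c("base", "unconverted", "total")
  if (!is.data.frame(control_counts) || !all(need %in% names(control_counts))) {
    stop("`control_counts` must have columns base, unconverted, total")
  }
  rate <- function(base) {
    row <- control_counts[control_counts$base == base, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("need exactly one tally row for control base '", base, "'", call. = FALSE)
    }
    if (row$total <= 0) stop("zero total for control base '", base, "'", call. = FALSE)
    if (row$unconverted < 0 || row$unconverted > row$total) {
      stop("invalid tally for control base '", base, "'", call. = FALSE)
    }
    row$unconverted / row$total
  }
  if (treatment == "bs") {
    conversion_profile("bs",
      c = 1 - rate("C"), d = rate("mC"), e = rate("hmC"),
      day = day
    )
  } else {
    conversion_profile("ox",
      c = 1 - rate("C"), d = rate("mC"), f = 1 - rate("hmC"),
      day = day
    )
  }
}
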