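# State space and transition structure of the dyad chain.
#
# A CpG dyad carries one mark per strand, u (unmethylated), m (5mC) or
# h (5hmC).  The chain state is the ordered pair (upper, lower).  One time
# step corresponds to one cell division and factorizes into three events
# applied in order: replication (D), methylation (M), hydroxylation (H).

# Canonical ordering used for every vector/matrix index in the package:
# grouped by number of modified strands.
DYAD_STATES <- c("uu", "um", "mu", "uh", "hu", "mm", "mh", "hm", "hh")
OBS_STATES <- c("TT", "TC", "CT", "CC")

# per-state strand marks, rows in canonical order
.STATE_MARKS <- matrix(unlist(strsplit(DYAD_STATES, "")),
  ncol = 2, byrow = TRUE,
  dimnames = list(DYAD_STATES, c("upper", "lower"))
)

# index permutations induced by exchanging the two strands
.STATE_SWAP <- c(1L, 3L, 2L, 5L, 4L, 6L, 8L, 7L, 9L)
.OBS_SWAP <- c(1L, 3L, 2L, 4L)

# number of hydroxylated strands per state, canonical order
.H_COUNT <- rowSums(.STATE_MARKS == "h")
.M_COUNT <- rowSums(.STATE_MARKS == "m")

#' Dyad and observable state labels
#'
#' The nine hidden dyad states `(upper, lower)` with strand marks in
#' `{u, m, h}`, and the four observable hairpin read pairs over `{T, C}`,
#' in the canonical orders used for all vectors and matrices in the
#' package.
#'
#' @return Character vector of state labels.
#' @export
dyad_states <- function() DYAD_STATES

#' @rdname dyad_states
#' @export
observable_states <- function() OBS_STATES

#' Exchange the two strands of a dyad state
#'
#' Maps each state `(s1, s2)` to `(s2, s1)`.  Strand exchange is a
#' bijection of the state set, and all transition and emission matrices in
#' the model are invariant under applying it simultaneously to rows and
#' columns.
#'
#' @param state Character vector of state labels, or integer indices into
#'   [dyad_states()].
#' @return Same type as the input, strand-swapped.
#' @export
swap_state <- function(state) {
  if (is.numeric(state)) {
    return(.STATE_SWAP[state])
  }
  idx <- match(state, DYAD_STATES)
  if (anyNA(idx)) stop("unknown dyad state: ", paste(state[is.na(idx)], collapse = ", "))
  DYAD_STATES[.STATE_SWAP[idx]]
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single probability in [0, 1], got ",
      deparse(x),
      call. = FALSE
    )
  }
  x
}

#' Replication-dilution transition matrix
#'
#' With each division one strand of the dyad is replaced by a newly
#' synthesized, unmodified strand.  Averaging over the two daughter cells,
#' from state `(s1, s2)` the chain moves to `(s1, u)` or `(u, s2)` with
#' probability 0.5 each.  The matrix is parameter-free and identical for
#' every division.
#'
#' @return A 9 x 9 row-stochastic matrix in canonical state order.
#' @export
division_matrix <- function() {
  D <- matrix(0, 9, 9, dimnames = list(DYAD_STATES, DYAD_STATES))
  for (i in 1:9) {
    keep_upper <- paste0(.STATE_MARKS[i, 1], "u") # lower strand replaced
    keep_lower <- paste0("u", .STATE_MARKS[i, 2]) # upper strand replaced
    D[i, keep_upper] <- D[i, keep_upper] + 0.5
    D[i, keep_lower] <- D[i, keep_lower] + 0.5
  }
  D
}

#' Methylation transition matrix
#'
#' Applies maintenance and de novo methylation after replication.  An
#' unmethylated dyad `(uu)` can gain methyl groups only through two
#' independent de novo events (each `mu_d`).  On a hemimethylated dyad the
#' unmodified cytosine is methylated with total efficiency
#' `lambda = mu_m + mu_d - mu_m * mu_d` (maintenance first, de novo as
#' fallback).  On `(uh)`/`(hu)` the hydroxyl group escapes recognition by
#' the maintenance machinery with probability `p`, in which case only de
#' novo methylation applies; with probability `1 - p` the dyad is treated
#' as hemimethylated.  States `(mm)`, `(mh)`, `(hm)` and `(hh)` carry no
#' unmodified cytosine that the Dnmts act on and have self-loops only.
#'
#' @param mu_m Maintenance methylation probability.
#' @param mu_d De novo methylation probability.
#' @param p Probability that a hemi-hydroxylated dyad is not recognized by
#'   the maintenance machinery.
#' @return A 9 x 9 row-stochastic matrix in canonical state order.
#' @export
methylation_matrix <- function(mu_m, mu_d, p) {
  .check_prob(mu_m, "mu_m")
  .check_prob(mu_d, "mu_d")
  .check_prob(p, "p")
  lambda <- mu_m + mu_d - mu_m * mu_d
  M <- diag(9)
  dimnames(M) <- list(DYAD_STATES, DYAD_STATES)
  # (uu): two independent de novo events
  M["uu", ] <- 0
  M["uu", "uu"] <- (1 - mu_d)^2
  M["uu", "um"] <- (1 - mu_d) * mu_d
  M["uu", "mu"] <- mu_d * (1 - mu_d)
  M["uu", "mm"] <- mu_d^2
  # hemimethylated: maintenance or de novo on the unmodified strand
  M["um", "um"] <- 1 - lambda
  M["um", "mm"] <- lambda
  M["mu", "mu"] <- 1 - lambda
  M["mu", "mm"] <- lambda
  # hemi-hydroxylated: maintenance blocked with probability p
  gain <- p * mu_d + (1 - p) * lambda
  M["uh", "uh"] <- 1 - gain
  M["uh", "mh"] <- gain
  M["hu", "hu"] <- 1 - gain
  M["hu", "hm"] <- gain
  M
}

#' Hydroxylation transition matrix
#'
#' Each methylated strand is oxidized to 5hmC independently with
#' probability `eta`; unmodified and already hydroxylated strands are
#' unchanged.
#'
#' @param eta Hydroxylation probability per methylated strand.
#' @return A 9 x 9 row-stochastic matrix in canonical state order.
#' @export
hydroxylation_matrix <- function(eta) {
  .check_prob(eta, "eta")
  # per-strand channel: u -> u, m -> {m: 1 - eta, h: eta}, h -> h
  marks <- c("u", "m", "h")
  K <- diag(3)
  dimnames(K) <- list(marks, marks)
  K["m", "m"] <- 1 - eta
  K["m", "h"] <- eta
  H <- matrix(0, 9, 9, dimnames = list(DYAD_STATES, DYAD_STATES))
  for (i in 1:9) {
    for (j in 1:9) {
      H[i, j] <- K[.STATE_MARKS[i, 1], .STATE_MARKS[j, 1]] *
        K[.STATE_MARKS[i, 2], .STATE_MARKS[j, 2]]
    }
  }
  H
}

#' One-division transition matrix of the dyad chain
#'
#' The combined transition matrix for the `t`-th division cycle,
#' `P(t) = D %*% M(mu_m(t), mu_d(t), p) %*% H(eta(t))`.  Hydroxylation is
#' applied after methylation, so within one cycle a cytosine can go from
#' u to m and on to h.
#'
#' @param t Division index (>= 1) at which the efficiency functions are
#'   evaluated.
#' @param model An [efficiency_model()].
#' @param clamp If `TRUE`, efficiency values a small numerical distance
#'   outside \[0, 1\] are clamped instead of raising an error (used when
#'   extrapolating a fitted model beyond its fitted range).
#' @return A 9 x 9 row-stochastic matrix in canonical state order.
#' @export
transition_matrix <- function(t, model, clamp = FALSE) {
  e <- evaluate_efficiencies(model, t, clamp = clamp)
  division_matrix() %*% methylation_matrix(e$mu_m, e$mu_d, e$p) %*%
    hydroxylation_matrix(e$eta)
}

#' Propagate a hidden-state distribution over divisions
#'
#' Computes `pi(t) = pi(0) %*% P(1) %*% ... %*% P(t)` for the row vector
#' of hidden-state probabilities.
#'
#' @param pi0 Initial distribution over the nine dyad states (see
#'   [as_hidden_distribution()]).
#' @param model An [efficiency_model()].
#' @param t Number of divisions (>= 0); `t = 0` returns `pi0` unchanged.
#' @param clamp Passed to [transition_matrix()].
#' @return Named numeric vector of length 9 summing to 1.
#' @export
propagate <- function(pi0, model, t, clamp = FALSE) {
  pi_t <- as_hidden_distribution(pi0)
  if (t < 0 || t != round(t)) stop("`t` must be a nonnegative integer")
  for (k in seq_len(t)) {
    pi_t <- as.vector(pi_t %*% transition_matrix(k, model, clamp = clamp))
  }
  names(pi_t) <- DYAD_STATES
  pi_t
}

#' Validate a hidden-state distribution
#'
#' Checks that `x` is a length-9 nonnegative vector summing to 1 (within
#' 1e-6) over the canonical dyad states and returns it renormalized to sum
#' exactly to 1.  Accepts an unnamed vector in canonical order, a named
#' vector in any order, or the result of [estimate_initial_distribution()].
#'
#' @param x Distribution to validate.
#' @return Named numeric vector of length 9.
#' @export
as_hidden_distribution <- function(x) {
  if (inherits(x, "dyad_pi0_fit")) x <- x$pi0
  if (!is.numeric(x) || length(x) != 9L) {
    stop("a hidden distribution must be a numeric vector of length 9")
  }
  if (!is.null(names(x))) {
    idx <- match(DYAD_STATES, names(x))
    if (anyNA(idx)) stop("hidden distribution names must be the nine dyad states")
    x <- x[idx]
  }
  if (any(x < -1e-12)) stop("hidden distribution has negative entries")
  x[x < 0] <- 0
  s <- sum(x)
  if (abs(s - 1) > 1e-6) stop("hidden distribution must sum to 1 (got ", format(s), ")")
  x <- x / s
  names(x) <- DYAD_STATES
  x
}

# ---- fast internal kernels -------------------------------------------
# Unnamed, unchecked versions of the matrix builders, used in likelihood
# loops.  State indices follow the canonical order
# uu=1 um=2 mu=3 uh=4 hu=5 mm=6 mh=7 hm=8 hh=9.

.D_MAT_CACHE <- new.env(parent = emptyenv())

.D_fast <- function() {
  if (is.null(.D_MAT_CACHE$D)) {
    D <- division_matrix()
    dimnames(D) <- NULL
    .D_MAT_CACHE$D <- D
  }
  .D_MAT_CACHE$D
}

.M_fast <- function(mu_m, mu_d, p) {
  lambda <- mu_m + mu_d - mu_m * mu_d
  gain <- p * mu_d + (1 - p) * lambda
  M <- diag(9)
  M[1L, 1L] <- (1 - mu_d)^2
  M[1L, 2L] <- M[1L, 3L] <- mu_d * (1 - mu_d)
  M[1L, 6L] <- mu_d^2
  M[2L, 2L] <- M[3L, 3L] <- 1 - lambda
  M[2L, 6L] <- M[3L, 6L] <- lambda
  M[4L, 4L] <- M[5L, 5L] <- 1 - gain
  M[4L, 7L] <- M[5L, 8L] <- gain
  M
}

.H_fast <- function(eta) {
  H <- diag(9)
  H[2L, 2L] <- H[3L, 3L] <- H[7L, 7L] <- H[8L, 8L] <- 1 - eta
  H[2L, 4L] <- H[3L, 5L] <- H[7L, 9L] <- H[8L, 9L] <- eta
  H[6L, 6L] <- (1 - eta)^2
  H[6L, 7L] <- H[6L, 8L] <- eta * (1 - eta)
  H[6L, 9L] <- eta^2
  H
}

# linear efficiency with clamping; NA signals a real constraint violation
.eff_at <- function(pair, t, clamp) {
  x <- pair[1L] + pair[2L] * t
  if (x < 0 || x > 1) {
    if (!clamp && (x < -1e-9 || x > 1 + 1e-9)) {
      return(NA_real_)
    }
    x <- min(max(x, 0), 1)
  }
  x
}

#' Summary levels of a hidden-state distribution
#'
#' Collapses a dyad-state distribution into the quantities usually plotted
#' for hairpin data: fully methylated (`mm`), hemimethylated (`um` + `mu`),
#' unmethylated (`uu`), total hydroxylated (any state containing at least
#' one h) and the per-strand 5hmC and 5mC levels.
#'
#' @param pi Hidden-state distribution (see [as_hidden_distribution()]).
#' @return Named numeric vector of summary levels.
#' @export
summarize_hidden <- function(pi) {
  pi <- as_hidden_distribution(pi)
  c(
    fully_methylated = unname(pi["mm"]),
    hemimethylated = unname(pi["um"] + pi["mu"]),
    unmethylated = unname(pi["uu"]),
    hydroxylated_total = sum(pi[.H_COUNT > 0]),
    h_per_strand = sum(pi * .H_COUNT) / 2,
    m_per_strand = sum(pi * .M_COUNT) / 2
  )
}
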