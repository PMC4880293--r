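# Maximum-likelihood estimation of the seven-parameter efficiency vector.
#
# The feasible region "intercept + slope * t in [0, 1] for all fitted
# division indices t" is, by linearity, exactly the set where the
# efficiency lies in [0, 1] at t = 1 and t = t_max.  Each intercept/slope
# pair is therefore reparameterized by its values q1 = f(1) and
# q2 = f(t_max), turning the constrained problem into a box-constrained
# one on [0, 1]^k solved by L-BFGS-B from multiple uniform starts.

.PAR_NAMES <- c(
  "mu_m_intercept", "mu_m_slope", "mu_d_intercept", "mu_d_slope",
  "eta_intercept", "eta_slope", "p"
)

# Parameter layout given the trend and fixed settings.
.par_layout <- function(trend, fixed, t_max) {
  pairs <- c("mu_m", "mu_d", "eta")
  layout <- list()
  for (nm in pairs) {
    if (nm %in% names(fixed)) {
      v <- fixed[[nm]]
      if (length(v) == 1L) v <- c(v, 0)
      layout[[nm]] <- list(mode = "fixed", value = unname(v))
    } else if (trend == "constant" || t_max < 2) {
      layout[[nm]] <- list(mode = "constant")
    } else {
      layout[[nm]] <- list(mode = "linear")
    }
  }
  layout$p <- if ("p" %in% names(fixed)) {
    list(mode = "fixed", value = unname(fixed$p))
  } else {
    list(mode = "free")
  }
  layout
}

.n_free_q <- function(layout) {
  k <- 0L
  for (nm in c("mu_m", "mu_d", "eta")) {
    k <- k + switch(layout[[nm]]$mode, linear = 2L, constant = 1L, fixed = 0L)
  }
  k + (layout$p$mode == "free")
}

# Map a box point q in [0, 1]^k to an efficiency model.
.q_to_model <- function(q, layout, t_max) {
  i <- 0L
  pair <- function(nm) {
    l <- layout[[nm]]
    if (l$mode == "fixed") {
      return(l$value)
    }
    if (l$mode == "constant") {
      i <<- i + 1L
      return(c(q[i], 0))
    }
    q1 <- q[i + 1L]
    q2 <- q[i + 2L]
    i <<- i + 2L
    slope <- (q2 - q1) / (t_max - 1)
    c(q1 - slope, slope)
  }
  mu_m <- pair("mu_m")
  mu_d <- pair("mu_d")
  eta <- pair("eta")
  p <- if (layout$p$mode == "fixed") layout$p$value else q[i + 1L]
  efficiency_model(mu_m = mu_m, mu_d = mu_d, eta = eta, p = min(max(p, 0), 1))
}

# Free natural-parameter names (for the FIM) given a layout.
.free_natural <- function(layout) {
  out <- character(0)
  for (nm in c("mu_m", "mu_d", "eta")) {
    out <- c(out, switch(layout[[nm]]$mode,
      linear = paste0(nm, c("_intercept", "_slope")),
      constant = paste0(nm, "_intercept"),
      fixed = character(0)
    ))
  }
  if (layout$p$mode == "free") out <- c(out, "p")
  out
}

# Fast dynamics negative log-likelihood closure: emission matrices and
# counts are precomputed, only propagation runs per evaluation.
.make_dynamics_nll <- function(data, pi0, t_max) {
  days <- setdiff(data$days, 0)
  dpd <- data$divisions_per_day
  obs <- list()
  for (d in days) {
    for (tr in c("bs", "ox")) {
      n <- counts_for(data, d, tr)
      if (is.null(n) || sum(n) == 0) next
      obs[[length(obs) + 1L]] <- list(
        t = d * dpd, n = n,
        E = emission_matrix(get_profile(data, d, tr))
      )
    }
  }
  if (!length(obs)) stop("no positive post-day-0 counts to fit")
  function(model, clamp = FALSE) {
    pis <- .propagate_table(pi0, model, t_max, clamp = clamp)
    nll <- 0
    for (o in obs) {
      pred <- as.vector(pis[o$t + 1L, ] %*% o$E)
      pos <- o$n > 0
      if (any(pos & pred <= 0)) {
        return(Inf)
      }
      nll <- nll - sum(o$n[pos] * log(pred[pos]))
    }
    nll
  }
}

#' Fit the enzymatic efficiency functions by maximum likelihood
#'
#' Minimizes the dynamics negative log-likelihood `-log L2(v)` over the
#' seven-parameter vector `v` (intercept and slope of `mu_m(t)`,
#' `mu_d(t)`, `eta(t)`, plus `p`) under the constraint that every
#' efficiency lies in \[0, 1\] at all fitted division indices, using
#' L-BFGS-B from multiple random starting points.  Ties between starts
#' are broken by objective value, then lexicographic parameter order.
#'
#' @param data An [observation_dataset()] with counts at days > 0.
#' @param pi0 Initial hidden-state distribution, typically from
#'   [estimate_initial_distribution()].
#' @param starts Number of random starting points.
#' @param seed Optional integer seed for the starting points.
#' @param trend `"linear"` (default; slopes free) or `"constant"`
#'   (slopes fixed to zero).
#' @param fixed Named list fixing parameters: entries `mu_m`, `mu_d`,
#'   `eta` as `c(intercept, slope)` (or a scalar for a constant value)
#'   and/or scalar `p`.
#' @param t_max Largest division index the constraints and propagation
#'   cover; defaults to the last observation day times
#'   `divisions_per_day`.  Set it higher when the fitted model must be
#'   valid beyond the data (e.g. cross-validation prediction).
#' @param compute_fim If `TRUE` (default), attach [observed_fim()]
#'   results (standard deviations and confidence intervals).
#' @param level Confidence level for the intervals.
#' @param control Passed to [stats::optim()]; defaults
#'   `list(factr = 1e2, maxit = 1000)` give an objective tolerance near
#'   1e-9.
#' @return An object of class `"dyad_fit"`; see [print.dyad_fit()].
#'   Key elements: `model` (the fitted [efficiency_model()]), `nll` and
#'   `logLik`, `pi0`, `fim` (see [observed_fim()]), `starts` (per-start
#'   trace) and `convergence` (0 = converged).
#' @export
fit_efficiencies <- function(data, pi0, starts = 20L, seed = NULL,
                             trend = c("linear", "constant"),
                             fixed = list(), t_max = NULL,
                             compute_fim = TRUE, level = 0.95,
                             control = list()) {
  stopifnot(inherits(data, "observation_dataset"))
  trend <- match.arg(trend)
  pi0 <- as_hidden_distribution(pi0)
  days <- setdiff(data$days, 0)
  if (!length(days)) stop("dataset has no post-day-0 counts")
  dpd <- data$divisions_per_day
  if (is.null(t_max)) t_max <- max(days) * dpd
  if (t_max < max(days) * dpd) stop("`t_max` must cover the last observation day")
  if (trend == "linear" && t_max < 2) {
    warning("only one division index observed; slopes are unidentifiable, fitting constant efficiencies")
    trend <- "constant"
  }

  layout <- .par_layout(trend, fixed, t_max)
  k <- .n_free_q(layout)
  nll_fun <- .make_dynamics_nll(data, pi0, t_max)
  big <- 1e12
  objective <- function(q) {
    v <- nll_fun(.q_to_model(q, layout, t_max))
    if (!is.finite(v)) big else v
  }

  control <- utils::modifyList(list(factr = 1e2, maxit = 1000L), control)
  if (!is.null(seed)) set.seed(seed)
  if (k == 0L) stop("all parameters fixed; nothing to fit")
  start_mat <- matrix(stats::runif(starts * k), nrow = starts, ncol = k)

  fits <- vector("list", starts)
  for (s in seq_len(starts)) {
    fits[[s]] <- tryCatch(
      stats::optim(start_mat[s, ], objective,
        method = "L-BFGS-B",
        lower = rep(0, k), upper = rep(1, k), control = control
      ),
      error = function(e) list(par = start_mat[s, ], value = Inf, convergence = 99L, message = conditionMessage(e))
    )
  }
  values <- vapply(fits, `[[`, numeric(1), "value")
  if (all(!is.finite(values) | values >= big)) {
    stop("all optimization starts failed; per-start values: ", paste(format(values), collapse = ", "))
  }
  pars <- do.call(rbind, lapply(fits, `[[`, "par"))
  ord <- do.call(order, c(list(round(values, 9)), as.data.frame(pars)))
  best <- ord[1L]

  model <- .q_to_model(fits[[best]]$par, layout, t_max)
  trace <- data.frame(
    start = seq_len(starts), objective = values,
    convergence = vapply(fits, `[[`, numeric(1), "convergence")
  )
  fit <- structure(
    list(
      model = model, pi0 = pi0, nll = values[best], logLik = -values[best],
      data = data, t_max = t_max, trend = trend, layout = layout,
      starts = trace, convergence = fits[[best]]$convergence,
      level = level, fim = NULL
    ),
    class = "dyad_fit"
  )
  if (compute_fim) fit$fim <- observed_fim(fit, level = level)
  fit
}

#' Observed Fisher information, standard deviations and confidence intervals
#'
#' Computes the negative Hessian of the dynamics log-likelihood at the
#' fitted parameters (the observed Fisher information matrix over the
#' free parameters), inverts it for the asymptotic covariance, and
#' derives normal-approximation confidence intervals.  A singular
#' information matrix is handled with a pseudo-inverse and flagged;
#' parameters pinned at a box boundary are flagged and `p`'s interval is
#' truncated to \[0, 1\].
#'
#' @param fit A `"dyad_fit"` from [fit_efficiencies()].
#' @param level Confidence level (default taken from the fit).
#' @return List with `fim`, `cov` (over the free parameters), `sd` and
#'   `ci` (over all seven parameters, `NA` for fixed ones), `free`
#'   (free parameter names), `singular`, `boundary` and `unreliable`
#'   flags.
#' @export
observed_fim <- function(fit, level = NULL) {
  stopifnot(inherits(fit, "dyad_fit"))
  if (is.null(level)) level <- fit$level
  layout <- fit$layout
  free <- .free_natural(layout)
  est_all <- coef(fit$model)
  theta0 <- est_all[free]
  nll_fun <- .make_dynamics_nll(fit$data, fit$pi0, fit$t_max)

  theta_to_model <- function(theta) {
    g <- function(nm) {
      l <- layout[[nm]]
      if (l$mode == "fixed") {
        return(l$value)
      }
      if (l$mode == "constant") {
        return(c(theta[[paste0(nm, "_intercept")]], 0))
      }
      c(theta[[paste0(nm, "_intercept")]], theta[[paste0(nm, "_slope")]])
    }
    p <- if (layout$p$mode == "fixed") layout$p$value else theta[["p"]]
    efficiency_model(
      mu_m = g("mu_m"), mu_d = g("mu_d"), eta = g("eta"),
      p = min(max(p, 0), 1)
    )
  }
  f <- function(theta) {
    names(theta) <- free
    v <- nll_fun(theta_to_model(theta), clamp = TRUE)
    if (!is.finite(v)) 1e12 else v
  }
  H <- pracma::hessian(f, theta0)
  dimnames(H) <- list(free, free)
  H <- (H + t(H)) / 2
  singular <- FALSE
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov)) || any(diag(cov) < -1e-8)) {
    cov <- pracma::pinv(H)
    singular <- TRUE
  }
  dimnames(cov) <- list(free, free)
  vars <- diag(cov)
  unreliable_free <- vars < -1e-8
  vars[vars < 0] <- 0

  sd <- stats::setNames(rep(NA_real_, length(.PAR_NAMES)), .PAR_NAMES)
  sd[free] <- sqrt(vars)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = est_all - z * sd, upper = est_all + z * sd)
  ci["p", ] <- pmin(pmax(ci["p", ], 0), 1)

  # boundary diagnostics: efficiency at 0/1 at the ends of the fitted
  # range, or p at 0/1
  boundary <- stats::setNames(rep(FALSE, length(.PAR_NAMES)), .PAR_NAMES)
  for (nm in c("mu_m", "mu_d", "eta")) {
    pair <- fit$model[[nm]]
    ends <- pair[1] + pair[2] * c(1, fit$t_max)
    if (any(ends < 1e-4 | ends > 1 - 1e-4)) {
      boundary[paste0(nm, c("_intercept", "_slope"))] <- TRUE
    }
  }
  if (est_all["p"] < 1e-4 || est_all["p"] > 1 - 1e-4) boundary["p"] <- TRUE
  unreliable <- stats::setNames(rep(FALSE, length(.PAR_NAMES)), .PAR_NAMES)
  unreliable[free] <- unreliable_free
  if (singular) unreliable <- unreliable | boundary

  list(
    fim = H, cov = cov, sd = sd, ci = ci, free = free, level = level,
    singular = singular, boundary = boundary, unreliable = unreliable
  )
}

#' @export
coef.dyad_fit <- function(object, ...) coef(object$model)

#' @export
logLik.dyad_fit <- function(object, ...) {
  structure(object$logLik,
    df = length(.free_natural(object$layout)),
    class = "logLik"
  )
}

#' @describeIn fit_efficiencies Print a coefficient table with standard
#'   deviations and confidence intervals.
#' @param x,digits,... Print method arguments.
#' @export
print.dyad_fit <- function(x, digits = 4, ...) {
  cat("Dyad HMM efficiency fit (", x$trend, " efficiencies, t_max = ",
    x$t_max, ")\n",
    sep = ""
  )
  est <- coef(x)
  tab <- data.frame(estimate = est)
  if (!is.null(x$fim)) {
    tab$sd <- x$fim$sd
    tab$ci_lower <- x$fim$ci[, "lower"]
    tab$ci_upper <- x$fim$ci[, "upper"]
    tab$note <- ifelse(x$fim$boundary, "boundary", "")
  }
  print(round_df(tab, digits))
  cat("-log L2:", format(x$nll), " | converged starts:",
    sum(x$starts$convergence == 0), "/", nrow(x$starts), "\n")
  if (!is.null(x$fim) && x$fim$singular) {
    cat("note: observed information singular; pseudo-inverse used\n")
  }
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
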