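# Shared multi-start bounded minimizer of a negative mean log-likelihood.
# Quasi-random (latin hypercube) start points plus the box midpoint;
# L-BFGS-B within the variant's bounds. Deterministic given `seed`.
multistart_optim <- function(objective, info, n_starts, seed) {
  d <- length(info$free)
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(max(n_starts - 1L, 1L), d)
  starts <- rbind(u, matrix(0.5, 1, d))
  # keep starts off hard bounds so finite-difference gradients stay inside
  span <- info$upper - info$lower
  starts <- sweep(sweep(starts * 0.98 + 0.01, 2, span, `*`), 2, info$lower, `+`)
  best <- NULL
  n_fail <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = info$lower, upper = info$upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best$n_failed_starts <- n_fail
  best
}

#' Fit one model variant to one session by maximum normalized likelihood
#'
#' Maximizes the session's normalized likelihood `Z` (equivalently minimizes
#' the negative mean log per-trial likelihood) over the variant's free
#' parameters, by multi-start bounded optimization. Initial model states are
#' fixed (Q values 0.5, `Beta(1, 1)` posteriors) and never fitted. Bounds:
#' learning/forgetting rates in `[0, 1]`, `k1`, `k2` in `[0, 2]`, `beta` in
#' `[0, 50]`, `G` in `[1e-3, 1e3]`, `k` in `[0, 5]`, `phi` in `[-20, 20]`.
#'
#' @inheritParams run_model_forward
#' @param n_starts Number of optimizer starts (quasi-random within bounds).
#' @param seed Integer seed controlling the start points; refits with the
#'   same seed are identical.
#' @return An object of class `bq_fit`: `variant`, named `par`, fitted `Z`
#'   and `logZ`, `n_trials`, the per-trial `trajectory` from
#'   [run_model_forward()] at the optimum, `params` (full parameter object)
#'   and `convergence` info.
#' @export
fit_session <- function(session, variant, n_starts = 20, seed = 1) {
  check_session_frame(session)
  info <- variant_info(variant)
  ci <- session_choice_int(session)
  rw <- as.integer(session$reward)
  objective <- function(th) {
    p <- forward_probs(ci, rw, info, info$assemble(th))
    z <- ifelse(ci == 1L, p, 1 - p)
    -mean(log(pmin(pmax(z, PROB_CLAMP[1]), PROB_CLAMP[2])))
  }
  best <- multistart_optim(objective, info, n_starts, seed)
  par <- stats::setNames(best$par, info$free)
  params <- info$assemble(best$par)
  structure(list(
    variant = variant, par = par, params = params,
    Z = exp(-best$value), logZ = -best$value, n_trials = length(ci),
    trajectory = run_model_forward(session, variant, params),
    convergence = list(code = best$convergence,
                       n_failed_starts = best$n_failed_starts)),
    class = "bq_fit")
}

#' @export
print.bq_fit <- function(x, ...) {
  cat("Model fit:", x$variant, "\n")
  cat("  trials:", x$n_trials, "  normalized likelihood Z:",
      format(x$Z, digits = 4), "\n")
  cat("  parameters:\n")
  print(round(x$par, 4))
  invisible(x)
}

split_sessions <- function(sessions) {
  split(sessions, factor(sessions$session_id,
                         levels = unique(sessions$session_id)))
}

#' Fit one shared parameter vector to a group of sessions
#'
#' Maximizes the mean over sessions of the per-session log normalized
#' likelihood (each session weighted equally regardless of length). This is
#' the training step of the cross-validation model comparison.
#'
#' @param sessions Session data frame, possibly containing several
#'   `session_id`s.
#' @inheritParams fit_session
#' @return A `bq_fit`-like object of class `bq_group_fit` with the shared
#'   `par`, the mean `logZ`, and per-session normalized likelihoods
#'   `session_Z`.
#' @export
fit_group <- function(sessions, variant, n_starts = 20, seed = 1) {
  info <- variant_info(variant)
  per <- lapply(split_sessions(sessions), function(s) {
    check_session_frame(s)
    list(ci = session_choice_int(s), rw = as.integer(s$reward))
  })
  stopifnot(length(per) >= 1L)
  objective <- function(th) {
    params <- info$assemble(th)
    -mean(vapply(per, function(d) {
      p <- forward_probs(d$ci, d$rw, info, params)
      z <- ifelse(d$ci == 1L, p, 1 - p)
      mean(log(pmin(pmax(z, PROB_CLAMP[1]), PROB_CLAMP[2])))
    }, numeric(1)))
  }
  best <- multistart_optim(objective, info, n_starts, seed)
  params <- info$assemble(best$par)
  session_Z <- vapply(names(per), function(sid) {
    normalized_likelihood(sessions[sessions$session_id == sid, ],
                          variant, params)$Z
  }, numeric(1))
  structure(list(
    variant = variant, par = stats::setNames(best$par, info$free),
    params = params, logZ = -best$value, Z = exp(-best$value),
    session_Z = session_Z, n_sessions = length(per),
    convergence = list(code = best$convergence,
                       n_failed_starts = best$n_failed_starts)),
    class = "bq_group_fit")
}

#' Fit each session of a collection separately
#'
#' Convenience wrapper running [fit_session()] on every `session_id`.
#'
#' @inheritParams fit_group
#' @return Named list of `bq_fit` objects, one per session.
#' @export
fit_sessions <- function(sessions, variant, n_starts = 20, seed = 1) {
  lapply(split_sessions(sessions), fit_session, variant = variant,
         n_starts = n_starts, seed = seed)
}
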