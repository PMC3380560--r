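# Experience label of one trial: optimality of the choice crossed with the
# reward outcome. These four labels condition the next trial's behavior.
experience_labels <- function(optimal, reward) {
  paste0(ifelse(optimal, "Opt", "NonOpt"),
         ifelse(reward == 1, "-Rew", "-NonRew"))
}

window_indices <- function(n_block, window, n_window) {
  if (window == "first") seq_len(n_window) else (n_block - n_window + 1L):n_block
}

#' Experience-conditional optimal-choice probability
#'
#' For the first or last `n_window` trials of each block, computes the
#' probability of an optimal choice conditioned on the experience of the one
#' (or two) preceding trials. An experience is one of four types: optimal or
#' non-optimal choice, rewarded or not (`Opt-Rew`, `NonOpt-Rew`,
#' `Opt-NonRew`, `NonOpt-NonRew`). Conditioning trials must lie inside the
#' same block and window as the conditioned trial; the unconditional
#' optimal-choice probability of the window is reported under the key
#' `"Choice0"`. Blocks shorter than `2 * n_window` trials are excluded so
#' the two windows never overlap. When both windows are requested, each
#' conditional cell is additionally compared between windows across sessions
#' with a two-sample Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param sessions Session data frame.
#' @param window `"first"`, `"last"`, or both (default) to analyse the first
#'   and/or last `n_window` trials of each block.
#' @param depth 1 or 2 preceding trials to condition on.
#' @param n_window Window length in trials.
#' @return List with `per_session` (per session/window/experience-key counts
#'   and probabilities; empty cells carry `n = 0` and `NA` probability),
#'   `summary` (across-session mean, SE and pooled probability per cell,
#'   with empty cells flagged), and `tests` (per-key Mann-Whitney p-values
#'   between windows, or `NULL` if a single window was requested).
#' @export
conditional_optimal_choice <- function(sessions, window = c("first", "last"),
                                       depth = 1, n_window = 10) {
  window <- match.arg(window, c("first", "last"), several.ok = TRUE)
  stopifnot(depth %in% c(1, 2))
  sessions <- add_optimal(sessions)
  per <- list()
  for (sid in unique(sessions$session_id)) {
    s <- sessions[sessions$session_id == sid, ]
    for (w in window) {
      num <- list(); den <- list()
      bump <- function(key, opt) {
        den[[key]] <<- (den[[key]] %||% 0) + 1
        num[[key]] <<- (num[[key]] %||% 0) + opt
      }
      for (blk in split(s, s$block)) {
        nb <- nrow(blk)
        if (nb < 2 * n_window) next
        idx <- window_indices(nb, w, n_window)
        exps <- experience_labels(blk$optimal[idx], blk$reward[idx])
        opts <- as.numeric(blk$optimal[idx])
        for (j in seq_along(idx)) bump("Choice0", opts[j])
        if (depth == 1) {
          for (j in 2:length(idx)) bump(exps[j - 1], opts[j])
        } else {
          for (j in 3:length(idx))
            bump(paste(exps[j - 2], exps[j - 1], sep = " > "), opts[j])
        }
      }
      keys <- conditional_keys(depth)
      per[[paste(sid, w)]] <- data.frame(
        session_id = sid, window = w, key = keys,
        n = vapply(keys, function(k) den[[k]] %||% 0, numeric(1)),
        p = vapply(keys, function(k)
          if (is.null(den[[k]])) NA_real_ else num[[k]] / den[[k]],
          numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, c(per, make.row.names = FALSE))
  summ <- do.call(rbind, lapply(split(per, list(per$window, per$key)),
    function(d) {
      ok <- !is.na(d$p)
      data.frame(window = d$window[1], key = d$key[1],
                 n_sessions = sum(ok), n_trials = sum(d$n),
                 mean_p = if (any(ok)) mean(d$p[ok]) else NA_real_,
                 se_p = if (sum(ok) > 1) sd(d$p[ok]) / sqrt(sum(ok)) else NA_real_,
                 pooled_p = if (sum(d$n) > 0)
                   sum(d$p[ok] * d$n[ok]) / sum(d$n[ok]) else NA_real_,
                 empty = !any(ok), stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  tests <- NULL
  if (length(window) == 2L) {
    tests <- do.call(rbind, lapply(unique(per$key), function(k) {
      a <- per$p[per$key == k & per$window == "first"]
      b <- per$p[per$key == k & per$window == "last"]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      p <- if (length(a) > 0 && length(b) > 0 &&
               (length(unique(c(a, b))) > 1))
        suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
      else NA_real_
      data.frame(key = k, p_value = p, stringsAsFactors = FALSE)
    }))
  }
  list(per_session = per, summary = summ, tests = tests)
}

conditional_keys <- function(depth) {
  base <- c("Opt-Rew", "NonOpt-Rew", "Opt-NonRew", "NonOpt-NonRew")
  if (depth == 1) c("Choice0", base)
  else c("Choice0", as.vector(outer(base, base,
                                    function(a, b) paste(a, b, sep = " > "))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Blockwise re-fitted learning rates of the forgetting Q-learning model
#'
#' For each block, the FQ learning rate is re-optimized separately on the
#' first and last `n_window` trials, keeping every other parameter frozen at
#' the session-level fit. The value trajectory entering each window is
#' propagated from trial 1 with the session-fit parameters; only within the
#' evaluated window do updates use the candidate learning rate. Blocks
#' shorter than `2 * n_window` trials are excluded. Estimates within `tol`
#' of the `[0, 1]` boundary (e.g. from windows with constant choices and
#' rewards) are flagged.
#'
#' @param sessions Session data frame.
#' @param fits Optional named list of per-session FQ [fit_session()] results
#'   (names = session ids); fitted internally when `NULL`.
#' @param n_window Window length in trials.
#' @param tol Distance from a bound at which an estimate is flagged.
#' @param ... Passed to [fit_sessions()] when fitting internally.
#' @return Data frame: `session_id`, `block`, `n_trials`, `alpha_first`,
#'   `alpha_last`, `at_bound_first`, `at_bound_last`.
#' @export
blockwise_fq_learning_rates <- function(sessions, fits = NULL,
                                        n_window = 10, tol = 1e-3, ...) {
  if (is.null(fits)) fits <- fit_sessions(sessions, "FQ", ...)
  out <- list()
  for (sid in unique(sessions$session_id)) {
    s <- sessions[sessions$session_id == sid, ]
    fit <- fits[[sid]]
    if (is.null(fit) || fit$variant != "FQ")
      stop("need an FQ fit for session ", sid)
    pp <- fit$params
    ci <- session_choice_int(s)
    rw <- as.integer(s$reward)
    fwd <- q_forward_cpp(ci, rw, pp$alpha1, pp$alpha2, pp$k1, pp$k2, pp$beta)
    window_loglik <- function(a, idx) {
      qL <- fwd$q_left[idx[1]]; qR <- fwd$q_right[idx[1]]
      ll <- 0
      for (t in idx) {
        p <- 1 / (1 + exp(-pp$beta * (qL - qR)))
        z <- if (ci[t] == 1L) p else 1 - p
        ll <- ll + log(min(max(z, PROB_CLAMP[1]), PROB_CLAMP[2]))
        target <- pp$k1 * rw[t] - pp$k2 * (1 - rw[t])
        if (ci[t] == 1L) {
          qL <- (1 - a) * qL + a * target; qR <- (1 - a) * qR
        } else {
          qR <- (1 - a) * qR + a * target; qL <- (1 - a) * qL
        }
      }
      ll
    }
    fit_window <- function(idx) {
      opt <- optimize(function(a) -window_loglik(a, idx),
                      interval = c(0, 1), tol = 1e-6)
      cand <- c(opt$minimum, 0, 1)
      vals <- vapply(cand, function(a) -window_loglik(a, idx), numeric(1))
      a_hat <- cand[which.min(vals)]
      c(alpha = a_hat, at_bound = as.numeric(a_hat < tol || a_hat > 1 - tol))
    }
    for (b in unique(s$block)) {
      gidx <- which(s$block == b)
      if (length(gidx) < 2 * n_window) next
      first <- fit_window(gidx[seq_len(n_window)])
      last <- fit_window(tail(gidx, n_window))
      out[[paste(sid, b)]] <- data.frame(
        session_id = sid, block = b, n_trials = length(gidx),
        alpha_first = first[["alpha"]], alpha_last = last[["alpha"]],
        at_bound_first = first[["at_bound"]] == 1,
        at_bound_last = last[["at_bound"]] == 1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Blockwise effective learning rates of a Bayesian Q-learning fit
#'
#' Averages the per-trial effective learning rate over the first and last
#' `n_window` trials of each block, using one session-level parameter set
#' throughout (the effective rate varies across trials because the
#' posterior's concentration does, not because any parameter changes).
#' Blocks shorter than `2 * n_window` trials are excluded.
#'
#' By default the concentration-driven rate `1/(x+y+1)` is averaged; for
#' `k = 1` it equals the realized outcome-dependent rate on every trial,
#' while for the asymmetric model (`k = 0`) the realized rate is structurally
#' zero on non-reward trials, so its window means confound uncertainty with
#' reward rate (`rate = "realized"` is available for that reading).
#'
#' @param sessions Session data frame.
#' @param fits Optional named list of per-session Bayesian-variant
#'   [fit_session()] results; fitted internally as `"asymmetricBQ"` when
#'   `NULL`.
#' @param rate Which per-trial rate to average (see Details).
#' @inheritParams blockwise_fq_learning_rates
#' @return Data frame: `session_id`, `block`, `n_trials`, `ea_first`,
#'   `ea_last`.
#' @export
blockwise_effective_learning_rates <- function(sessions, fits = NULL,
                                               n_window = 10,
                                               rate = c("concentration",
                                                        "realized"), ...) {
  rate <- match.arg(rate)
  if (is.null(fits)) fits <- fit_sessions(sessions, "asymmetricBQ", ...)
  col <- if (rate == "concentration") "ea_conc" else "ea"
  out <- list()
  for (sid in unique(sessions$session_id)) {
    s <- sessions[sessions$session_id == sid, ]
    fit <- fits[[sid]]
    if (is.null(fit) || !(col %in% names(fit$trajectory)))
      stop("need a Bayesian-variant fit for session ", sid)
    ea <- fit$trajectory[[col]]
    for (b in unique(s$block)) {
      gidx <- which(s$block == b)
      if (length(gidx) < 2 * n_window) next
      out[[paste(sid, b)]] <- data.frame(
        session_id = sid, block = b, n_trials = length(gidx),
        ea_first = mean(ea[gidx[seq_len(n_window)]]),
        ea_last = mean(ea[tail(gidx, n_window)]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Regression of the effective learning rate on action-value mean and SD
#'
#' Ordinary least squares of the per-trial effective learning rate on an
#' intercept plus the chosen action's posterior mean and standard deviation,
#' with coefficient t-tests at `threshold`. Plain correlations of the
#' effective rate with the mean and with the SD are reported alongside.
#' Exactly collinear or constant regressors are flagged and the entry's
#' coefficients set to `NA` rather than silently solved.
#'
#' The concentration-driven rate is regressed by default (see
#' [blockwise_effective_learning_rates()] for why the realized rate is
#' uninformative at `k = 0`).
#'
#' @param fit A Bayesian-variant [fit_session()] result (its trajectory must
#'   carry the rate column, `mu_chosen` and `sd_chosen`).
#' @param threshold Two-sided significance level for the coefficient tests.
#' @param rate Which per-trial rate to regress.
#' @return One-row data frame: coefficients (`coef_mu`, `coef_sd`), their
#'   p-values and significance flags, correlations (`cor_mu`, `cor_sd`) and
#'   a `degenerate` flag.
#' @export
learning_rate_regression <- function(fit, threshold = 0.01,
                                     rate = c("concentration", "realized")) {
  rate <- match.arg(rate)
  col <- if (rate == "concentration") "ea_conc" else "ea"
  traj <- fit$trajectory
  stopifnot(all(c(col, "mu_chosen", "sd_chosen") %in% names(traj)))
  mu <- traj$mu_chosen; sdev <- traj$sd_chosen; ea <- traj[[col]]
  degenerate <- sd(mu) < 1e-12 || sd(sdev) < 1e-12 ||
    abs(cor(mu, sdev)) > 1 - 1e-10 || sd(ea) < 1e-12
  if (degenerate) {
    return(data.frame(coef_mu = NA_real_, coef_sd = NA_real_,
                      p_mu = NA_real_, p_sd = NA_real_,
                      sig_mu = NA, sig_sd = NA,
                      cor_mu = NA_real_, cor_sd = NA_real_,
                      degenerate = TRUE))
  }
  m <- lm(ea ~ mu + sdev)
  cf <- summary(m)$coefficients
  data.frame(
    coef_mu = cf["mu", "Estimate"], coef_sd = cf["sdev", "Estimate"],
    p_mu = cf["mu", "Pr(>|t|)"], p_sd = cf["sdev", "Pr(>|t|)"],
    sig_mu = cf["mu", "Pr(>|t|)"] < threshold,
    sig_sd = cf["sdev", "Pr(>|t|)"] < threshold,
    cor_mu = cor(ea, mu), cor_sd = cor(ea, sdev),
    degenerate = FALSE)
}

#' Per-session learning-rate regressions over a cohort
#'
#' Runs [learning_rate_regression()] on each session's fit and counts the
#' sessions with significant mean and SD coefficients.
#'
#' @param fits Named list of Bayesian-variant [fit_session()] results.
#' @inheritParams learning_rate_regression
#' @return List with `report` (one row per session) and `counts`
#'   (`n_sessions`, `n_sig_mu`, `n_sig_sd`, `n_pos_cor_sd`, mean
#'   correlations).
#' @export
learning_rate_regressions <- function(fits, threshold = 0.01,
                                      rate = c("concentration",
                                               "realized")) {
  rate <- match.arg(rate)
  rows <- lapply(fits, learning_rate_regression, threshold = threshold,
                 rate = rate)
  report <- do.call(rbind, c(rows, make.row.names = FALSE))
  report <- cbind(session_id = names(fits), report)
  ok <- !report$degenerate
  counts <- list(
    n_sessions = nrow(report),
    n_degenerate = sum(!ok),
    n_sig_mu = sum(report$sig_mu[ok]),
    n_sig_sd = sum(report$sig_sd[ok]),
    n_pos_cor_sd = sum(report$cor_sd[ok] > 0),
    n_neg_cor_mu = sum(report$cor_mu[ok] < 0),
    mean_cor_mu = mean(report$cor_mu[ok]),
    mean_cor_sd = mean(report$cor_sd[ok]))
  list(report = report, counts = counts)
}

#' Paired model-comparison table from cross-validation scores
#'
#' Summarizes held-out normalized likelihoods per variant (mean and SE over
#' sessions) and runs paired t-tests between designated variant pairs, with
#' win counts (number of sessions where the first variant's held-out `Z`
#' exceeds the second's; ties count one half each).
#'
#' @param cv A [cross_validate()] result.
#' @param pairs List of length-2 character vectors of variants to test.
#'   Defaults to the canonical comparisons among those present: best
#'   Bayesian vs best standard (`asymmetricBQ` vs `FQ`), the uncertainty
#'   bonus (`asymmetricBQ` vs `asymmetricBQ_phi0`), and the learning-rate
#'   mechanism (`asymmetricBQ_phi0` vs `FQ`).
#' @return List with `summary` (per-variant mean/SE of held-out `Z`) and
#'   `tests` (one row per pair: mean difference, paired-t p-value — `NA` and
#'   flagged when the difference is constant — and win counts).
#' @export
model_comparison_report <- function(cv, pairs = NULL) {
  stopifnot(inherits(cv, "bq_cv"))
  sc <- cv$scores
  if (is.null(pairs)) {
    canonical <- list(c("asymmetricBQ", "FQ"),
                      c("asymmetricBQ", "asymmetricBQ_phi0"),
                      c("asymmetricBQ_phi0", "FQ"))
    pairs <- Filter(function(p) all(p %in% cv$variants), canonical)
    if (length(pairs) == 0L && length(cv$variants) >= 2L)
      pairs <- utils::combn(cv$variants, 2, simplify = FALSE)
  }
  summ <- do.call(rbind, lapply(split(sc, sc$variant), function(d)
    data.frame(variant = d$variant[1], n = nrow(d), mean_Z = mean(d$Z),
               se_Z = sd(d$Z) / sqrt(nrow(d)), stringsAsFactors = FALSE)))
  summ <- summ[order(-summ$mean_Z), ]
  rownames(summ) <- NULL
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    ids <- unique(sc$session_id)
    a <- sc$Z[match(paste(ids, pr[1]), paste(sc$session_id, sc$variant))]
    b <- sc$Z[match(paste(ids, pr[2]), paste(sc$session_id, sc$variant))]
    keep <- complete.cases(a, b)
    a <- a[keep]; b <- b[keep]
    d <- a - b
    constant <- sd(d) < 1e-15
    pv <- if (constant) NA_real_ else t.test(a, b, paired = TRUE)$p.value
    data.frame(variant_a = pr[1], variant_b = pr[2], n = length(d),
               mean_diff = mean(d), p_value = pv, constant_diff = constant,
               wins_a = sum(d > 0) + 0.5 * sum(d == 0),
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests)
}

#' Distribution of the fitted uncertainty-bonus parameter
#'
#' Summarizes per-session fitted `phi` values (histogram bins, median) and
#' tests the median against zero. The default test is the one-sample
#' Wilcoxon signed-rank test; `method = "two_sample_vs_zero"` instead runs a
#' two-sample rank-sum test of the fitted values against an equal-length
#' zero sample (an alternative reading of applying a Mann-Whitney U-test to
#' a one-sample location question).
#'
#' @param phi Numeric vector of fitted `phi` values, or a named list of
#'   Bayesian-variant [fit_session()] results from which `phi` is extracted.
#' @param method Location test to run (see Details).
#' @param breaks Passed to [graphics::hist()] for binning (no plot drawn).
#' @return List with `phi`, `median`, `p_value`, `method` and `histogram`
#'   (bin breaks and counts).
#' @export
phi_distribution_report <- function(phi,
                                    method = c("signed_rank",
                                               "two_sample_vs_zero"),
                                    breaks = "Sturges") {
  method <- match.arg(method)
  if (is.list(phi) && !is.numeric(phi))
    phi <- vapply(phi, function(f) unname(f$par["phi"]), numeric(1))
  stopifnot(is.numeric(phi), length(phi) >= 2L)
  p_value <- if (all(phi == 0)) {
    1  # no evidence of a non-zero location by convention
  } else if (method == "signed_rank") {
    suppressWarnings(wilcox.test(phi, mu = 0, exact = FALSE)$p.value)
  } else {
    suppressWarnings(wilcox.test(phi, rep(0, length(phi)),
                                 exact = FALSE)$p.value)
  }
  h <- graphics::hist(phi, breaks = breaks, plot = FALSE)
  list(phi = phi, median = stats::median(phi), p_value = p_value,
       method = method,
       histogram = data.frame(mid = h$mids, count = h$counts))
}
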