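session_choice_int <- function(session) {
  ch <- session$choice
  if (!all(ch %in% c("L", "R"))) stop("session choices must be \"L\" or \"R\"")
  as.integer(ch == "L")
}

check_session_frame <- function(session) {
  need <- c("choice", "reward")
  if (!is.data.frame(session) || !all(need %in% names(session)))
    stop("session must be a data frame with at least columns choice, reward")
  if (nrow(session) == 0L) stop("session has no trials")
  if (!all(session$reward %in% c(0, 1))) stop("rewards must be 0 or 1")
  invisible(session)
}

#' Run a model forward over an observed session
#'
#' Replays a model variant trial by trial over a session's observed choices
#' and rewards. On each trial the left-choice probability is computed from
#' the model state *before* that trial's choice and reward are observed, and
#' the state is then updated with the observation. For Bayesian variants the
#' within-trial order is: prediction (forgetting) step on both actions,
#' choice probability, conjugate update of the chosen action; the effective
#' learning rate is evaluated on the chosen action's post-prediction pair.
#'
#' @param session Data frame with columns `choice` (`"L"`/`"R"`) and
#'   `reward` (0/1), one row per trial.
#' @param variant One of [model_variants()].
#' @param params A [q_params()] or [bq_params()] object matching the
#'   variant's family (use [variant_params()] to build one that respects the
#'   variant's constraints).
#' @return A data frame with one row per trial: `trial`, `p_left` and, for
#'   standard variants, pre-update `q_left`, `q_right`; for Bayesian
#'   variants, post-prediction `mu_left`, `sd_left`, `mu_right`, `sd_right`,
#'   `mu_chosen`, `sd_chosen`, the realized effective learning rate `ea`
#'   (outcome dependent: `1/(x+y+1)` after reward, `k/(x+y+k)` after
#'   non-reward) and the concentration-driven rate `ea_conc = 1/(x+y+1)`
#'   (the rate a reward would produce; for `k = 1` the two coincide on every
#'   trial, and for `k = 0` `ea` degenerates to zero on non-reward trials
#'   while `ea_conc` keeps tracking the posterior uncertainty). The final
#'   posterior hyperparameters are attached as attribute `final_state` for
#'   Bayesian variants.
#' @export
run_model_forward <- function(session, variant, params) {
  check_session_frame(session)
  info <- variant_info(variant)
  ci <- session_choice_int(session)
  rw <- as.integer(session$reward)
  if (info$family == "q") {
    if (!inherits(params, "q_params"))
      stop("variant ", variant, " needs q_params")
    out <- q_forward_cpp(ci, rw, params$alpha1, params$alpha2,
                         params$k1, params$k2, params$beta)
    data.frame(trial = seq_along(ci), p_left = out$p_left,
               q_left = out$q_left, q_right = out$q_right)
  } else {
    if (!inherits(params, "bq_params"))
      stop("variant ", variant, " needs bq_params")
    out <- bq_forward_cpp(ci, rw, params$G, params$k, params$beta,
                          params$phi)
    traj <- data.frame(
      trial = seq_along(ci), p_left = out$p_left,
      mu_left = out$mu_left, sd_left = out$sd_left,
      mu_right = out$mu_right, sd_right = out$sd_right,
      mu_chosen = ifelse(ci == 1L, out$mu_left, out$mu_right),
      sd_chosen = ifelse(ci == 1L, out$sd_left, out$sd_right),
      ea = out$ea, ea_conc = out$ea_conc)
    attr(traj, "final_state") <- list(
      left = beta_pair(out$x_left, out$y_left),
      right = beta_pair(out$x_right, out$y_right))
    traj
  }
}
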