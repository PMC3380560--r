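#' Specify one synthetic rat for cohort generation
#'
#' @param rat_id Label for the synthetic animal.
#' @param variant Generating model variant, one of [model_variants()].
#' @param params Named list/vector of the variant's free parameters (passed
#'   to [variant_params()]).
#' @param n_sessions Number of sessions to simulate for this rat.
#' @param n_blocks Blocks scheduled per session.
#' @return A `rat_spec` list.
#' @export
rat_spec <- function(rat_id, variant, params, n_sessions = 26,
                     n_blocks = 14) {
  stopifnot(n_sessions >= 1, n_blocks >= 6)
  structure(list(rat_id = rat_id, variant = variant,
                 params = as.list(params), n_sessions = n_sessions,
                 n_blocks = n_blocks),
            class = "rat_spec")
}

#' Default generating agent of the synthetic cohort
#'
#' The cohort's reference agent is an asymmetric Bayesian Q-learner (`k = 0`)
#' with an uncertainty-seeking choice policy: `G = 5`, `beta = 40`,
#' `phi = 3.5`. The uncertainty bonus sits at the clearly positive value the
#' models are meant to detect; `G` and `beta` were calibrated once, by pilot
#' simulation, so that the closed-loop agent reaches the 80% block-change
#' criterion after a few tens of trials (mean block length near 37 trials
#' over 14-block sessions). Strong forgetting plus a sharp soft-max is the
#' only corner of this model family where an uncertainty-seeking agent still
#' exploits well enough to end blocks: the bonus `phi * sd` pulls toward the
#' rarely chosen (uncertain) option, so block completion requires the mean
#' term to dominate.
#'
#' @return Named numeric vector of free parameters.
#' @export
default_bq_agent <- function() {
  c(G = 5, beta = 40, phi = 3.5)
}

#' Generate a reproducible cohort of synthetic sessions
#'
#' Simulates every session of every [rat_spec()] in `config` with
#' deterministic per-session seeds derived from `seed`, and returns both the
#' pooled trial log and a manifest of the true generating parameters (for
#' parameter-recovery studies).
#'
#' @param config List of [rat_spec()] objects.
#' @param seed Master integer seed.
#' @param max_trials Per-session trial cap passed to [run_session()].
#' @return List with `sessions` (pooled session data frame) and `manifest`
#'   (data frame: `rat_id`, `session_id`, `seed`, `variant`, `params` as a
#'   JSON string, `truncated`).
#' @export
generate_cohort <- function(config, seed, max_trials = 5000) {
  if (inherits(config, "rat_spec")) config <- list(config)
  stopifnot(length(config) >= 1L, is.numeric(seed))
  total <- sum(vapply(config, function(r) r$n_sessions, numeric(1)))
  set.seed(as.integer(seed))
  session_seeds <- sample.int(2147483646L, total)
  sessions <- vector("list", total)
  manifest <- vector("list", total)
  i <- 0L
  for (r in config) {
    params <- variant_params(r$variant, r$params)
    agent <- make_agent(r$variant, params)
    for (j in seq_len(r$n_sessions)) {
      i <- i + 1L
      sid <- paste0(r$rat_id, "_s", j)
      sess <- run_session(agent, make_schedule(r$n_blocks),
                          seed = session_seeds[i], max_trials = max_trials,
                          session_id = sid, rat_id = r$rat_id)
      sessions[[i]] <- sess
      manifest[[i]] <- data.frame(
        rat_id = r$rat_id, session_id = sid, seed = session_seeds[i],
        variant = r$variant,
        params = as.character(jsonlite::toJSON(r$params, auto_unbox = TRUE)),
        truncated = attr(sess, "truncated"), stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  if (anyDuplicated(manifest$session_id))
    stop("duplicate session ids in cohort config")
  list(sessions = do.call(rbind, sessions), manifest = manifest)
}
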