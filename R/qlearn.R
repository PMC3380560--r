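#' Initial state of a standard Q-learning model
#'
#' Both action values start at 0.5, the average reward probability across the
#' task's six reward-probability settings.
#'
#' @return A list with elements `qL` and `qR`.
#' @export
q_init <- function() {
  list(qL = 0.5, qR = 0.5)
}

check_choice <- function(action) {
  if (!(is.character(action) && length(action) == 1L && action %in% c("L", "R")))
    stop("action must be \"L\" or \"R\"")
  invisible(action)
}

check_reward <- function(reward) {
  if (!(is.numeric(reward) && length(reward) == 1L && reward %in% c(0, 1)))
    stop("reward must be 0 or 1")
  invisible(reward)
}

#' One value update of a standard Q-learning model
#'
#' The chosen option's value moves at rate `alpha1` toward the reinforcement
#' target `k1 * r - k2 * (1 - r)`; the unchosen option's value decays toward
#' zero at rate `alpha2`:
#' \deqn{Q_{chosen} \leftarrow (1-\alpha_1) Q_{chosen} + \alpha_1 (k_1 r - k_2 (1-r))}
#' \deqn{Q_{unchosen} \leftarrow (1-\alpha_2) Q_{unchosen}}
#'
#' @param state List with `qL`, `qR` (see [q_init()]).
#' @param params A [q_params()] object.
#' @param action `"L"` or `"R"`, the chosen option.
#' @param reward 0 or 1.
#' @return Updated state list.
#' @export
q_step <- function(state, params, action, reward) {
  stopifnot(inherits(params, "q_params"),
            is.finite(state$qL), is.finite(state$qR))
  check_choice(action)
  check_reward(reward)
  target <- params$k1 * reward - params$k2 * (1 - reward)
  if (action == "L") {
    state$qL <- (1 - params$alpha1) * state$qL + params$alpha1 * target
    state$qR <- (1 - params$alpha2) * state$qR
  } else {
    state$qR <- (1 - params$alpha1) * state$qR + params$alpha1 * target
    state$qL <- (1 - params$alpha2) * state$qL
  }
  state
}

#' Soft-max left-choice probability of a standard Q-learning model
#'
#' \deqn{P(L) = 1 / (1 + \exp(-\beta (Q_L - Q_R)))}
#'
#' @inheritParams q_step
#' @return Probability of choosing left, in `(0, 1)`.
#' @export
q_choice_prob <- function(state, params) {
  stopifnot(inherits(params, "q_params"),
            is.finite(state$qL), is.finite(state$qR))
  1 / (1 + exp(-params$beta * (state$qL - state$qR)))
}
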