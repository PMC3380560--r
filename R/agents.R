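#' Construct a simulated agent for closed-loop task simulation
#'
#' Wraps a model variant and parameter set as a stateful agent usable by
#' [run_session()]. The contract per trial is: call `$prob()` once (for
#' Bayesian variants this performs the prediction/forgetting step on both
#' actions and returns the left-choice probability), then `$update(choice,
#' reward)` once with the observed outcome. `$reset()` returns the agent to
#' its initial state (Q values 0.5, or `Beta(1, 1)` posteriors).
#'
#' @param variant One of [model_variants()].
#' @param params Matching [q_params()] or [bq_params()] object.
#' @return A list of closures `prob`, `update`, `reset`, plus `variant` and
#'   `params`.
#' @examples
#' ag <- make_agent("asymmetricBQ", bq_params(G = 20, beta = 7, phi = 3.5))
#' ag$prob()
#' ag$update("L", 1)
#' @export
make_agent <- function(variant, params) {
  info <- variant_info(variant)
  if (info$family == "q") {
    stopifnot(inherits(params, "q_params"))
    state <- q_init()
    list(
      variant = variant, params = params,
      reset = function() state <<- q_init(),
      prob = function() q_choice_prob(state, params),
      update = function(choice, reward) {
        state <<- q_step(state, params, choice, reward)
        invisible(NULL)
      })
  } else {
    stopifnot(inherits(params, "bq_params"))
    state <- bq_init()
    list(
      variant = variant, params = params,
      reset = function() state <<- bq_init(),
      prob = function() {
        state$left <<- bq_predict(state$left, params$G)
        state$right <<- bq_predict(state$right, params$G)
        bq_choice_prob(state, params)
      },
      update = function(choice, reward) {
        check_choice(choice)
        if (choice == "L") {
          state$left <<- bq_update(state$left, reward, params$k)
        } else {
          state$right <<- bq_update(state$right, reward, params$k)
        }
        invisible(NULL)
      })
  }
}
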