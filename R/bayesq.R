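#' Hyperparameters of a beta-distributed action value
#'
#' A `beta_pair` holds the `(x, y)` hyperparameters of the `Beta(x, y)`
#' posterior over one action's reward probability.
#'
#' @param x,y Positive beta hyperparameters.
#' @return An object of class `beta_pair`.
#' @examples
#' p <- beta_pair(2, 1)
#' pair_mean(p)  # 2/3
#' @export
beta_pair <- function(x, y) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x > 0,
            is.numeric(y), length(y) == 1L, is.finite(y), y > 0)
  structure(list(x = x, y = y), class = "beta_pair")
}

#' @rdname beta_pair
#' @param pair A `beta_pair`.
#' @export
pair_mean <- function(pair) pair$x / (pair$x + pair$y)

#' @rdname beta_pair
#' @export
pair_var <- function(pair) {
  s <- pair$x + pair$y
  pair$x * pair$y / (s * s * (s + 1))
}

#' @rdname beta_pair
#' @export
pair_sd <- function(pair) sqrt(pair_var(pair))

#' Initial state of a Bayesian Q-learning model
#'
#' Both actions start at the uniform `Beta(1, 1)` prior (mean 0.5).
#'
#' @return A list with `beta_pair` elements `left` and `right`.
#' @export
bq_init <- function() {
  list(left = beta_pair(1, 1), right = beta_pair(1, 1))
}

#' Forgetting transition kernel of the Bayesian Q-learning model
#'
#' Given the previous action value `q_prev`, the kernel is the beta
#' distribution `Beta(1 + G * q_prev, 1 + G * (1 - q_prev))`. Its mode equals
#' `q_prev`, so the posterior's peak is retained while its variance inflates;
#' small `G` inflates the variance strongly (the `G -> 0` limit is the uniform
#' `Beta(1, 1)` regardless of `q_prev`).
#'
#' @param q_prev Previous action value, strictly inside `(0, 1)`.
#' @param G Kernel concentration, `> 0`.
#' @return A [beta_pair()] describing the kernel.
#' @examples
#' transition_kernel(0.3, 10)  # Beta(4, 8), mode 0.3
#' @export
transition_kernel <- function(q_prev, G) {
  stopifnot(is.numeric(q_prev), length(q_prev) == 1L,
            is.numeric(G), length(G) == 1L, G > 0, is.finite(G))
  if (!(q_prev > 0 && q_prev < 1)) stop("q_prev must lie strictly in (0, 1)")
  beta_pair(1 + G * q_prev, 1 + G * (1 - q_prev))
}

#' Match a beta distribution to a mean and variance
#'
#' Solves for `(x, y)` such that `Beta(x, y)` has the given mean and
#' variance: with `c = mean * (1 - mean) / variance - 1`,
#' `x = mean * c` and `y = (1 - mean) * c`.
#'
#' @param mean Target mean, strictly inside `(0, 1)`.
#' @param variance Target variance, in `(0, mean * (1 - mean))`.
#' @return A [beta_pair()].
#' @examples
#' moment_match(0.5, 1/12)  # Beta(1, 1)
#' @export
moment_match <- function(mean, variance) {
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(variance), length(variance) == 1L)
  if (!(mean > 0 && mean < 1)) stop("mean must lie strictly in (0, 1)")
  if (variance <= 0) stop("variance must be positive")
  if (variance >= mean * (1 - mean))
    stop("infeasible moments: variance must be below mean * (1 - mean)")
  conc <- mean * (1 - mean) / variance - 1
  beta_pair(max(mean * conc, 1e-6), max((1 - mean) * conc, 1e-6))
}

#' Prediction (forgetting) step of the Bayesian Q-learning model
#'
#' Propagates the posterior one trial forward through the forgetting kernel
#' ([transition_kernel()]) and re-approximates the resulting mixture as a beta
#' distribution by moment matching. The first two moments of the mixture are
#' analytic: with prior moments `m = E[q']` and `m2 = E[q'^2]`,
#' \deqn{E[q] = (1 + G m) / (2 + G)}
#' \deqn{E[q^2] = (2 + 3 G m + G^2 m2) / ((2 + G)(3 + G))}
#' The predicted mean contracts toward 0.5 by the factor `G / (2 + G)`.
#' `G = Inf` returns the prior unchanged (point-mass kernel, no forgetting).
#'
#' @param prior A [beta_pair()].
#' @param G Kernel concentration, `> 0` (may be `Inf`).
#' @return The moment-matched predicted [beta_pair()].
#' @export
bq_predict <- function(prior, G) {
  stopifnot(inherits(prior, "beta_pair"),
            is.numeric(G), length(G) == 1L, G > 0)
  if (!is.finite(G)) return(prior)
  s <- prior$x + prior$y
  m <- prior$x / s
  m2 <- prior$x * (prior$x + 1) / (s * (s + 1))
  new_m <- (1 + G * m) / (2 + G)
  new_m2 <- (2 + 3 * G * m + G * G * m2) / ((2 + G) * (3 + G))
  v <- new_m2 - new_m * new_m
  if (!(v > 0 && v < new_m * (1 - new_m)))
    stop("degenerate predicted moments (variance outside the feasible range)")
  moment_match(new_m, v)
}

#' Posterior update of the chosen action's value distribution
#'
#' Conjugate update of the predicted beta distribution with one outcome:
#' reward increments `x` by 1; non-reward increments `y` by `k`, the relative
#' reinforcement strength of non-rewards (`k = 1` strict Bayes, `k = 0`
#' ignores non-rewards). The unchosen action's distribution is never passed
#' through this update; it keeps its predicted distribution.
#'
#' @param predicted A [beta_pair()] after the prediction step.
#' @param reward 0 or 1.
#' @param k Non-reward reinforcement strength, `>= 0`.
#' @return Updated [beta_pair()].
#' @export
bq_update <- function(predicted, reward, k) {
  stopifnot(inherits(predicted, "beta_pair"),
            is.numeric(k), length(k) == 1L, k >= 0)
  check_reward(reward)
  if (reward == 1) return(beta_pair(predicted$x + 1, predicted$y))
  if (k == 0) return(predicted)
  beta_pair(predicted$x, predicted$y + k)
}

#' Effective learning rate of the Bayesian posterior update
#'
#' The fraction of the prediction error by which the posterior mean moves
#' after one outcome, `(mean_after - mean_before) / (reward - mean_before)`,
#' evaluated on the post-prediction-step pair. Closed forms: reward
#' `1 / (x + y + 1)`; non-reward `k / (x + y + k)`. It is not a free
#' parameter: a flat (uncertain) posterior yields a high rate, a sharply
#' peaked one a low rate.
#'
#' @inheritParams bq_update
#' @return Effective learning rate in `[0, 1)`.
#' @examples
#' effective_learning_rate(beta_pair(1, 1), reward = 1, k = 0)  # 1/3
#' @export
effective_learning_rate <- function(predicted, reward, k) {
  stopifnot(inherits(predicted, "beta_pair"),
            is.numeric(k), length(k) == 1L, k >= 0)
  check_reward(reward)
  s <- predicted$x + predicted$y
  if (reward == 1) 1 / (s + 1) else k / (s + k)
}

#' Soft-max left-choice probability with an uncertainty bonus
#'
#' Each action is scored by the weighted sum of its posterior mean and
#' standard deviation, `mu + phi * sigma`, and the scores enter a soft-max:
#' \deqn{P(L) = 1/(1 + \exp(-\beta[(\mu_L + \phi\sigma_L) - (\mu_R + \phi\sigma_R)]))}
#' Positive `phi` favors the more uncertain option (exploration bonus),
#' negative `phi` the less uncertain one.
#'
#' @param state List with `beta_pair` elements `left` and `right`
#'   (see [bq_init()]).
#' @param params A [bq_params()] object.
#' @return Probability of choosing left, in `(0, 1)`.
#' @export
bq_choice_prob <- function(state, params) {
  stopifnot(inherits(params, "bq_params"),
            inherits(state$left, "beta_pair"),
            inherits(state$right, "beta_pair"))
  uL <- pair_mean(state$left) + params$phi * pair_sd(state$left)
  uR <- pair_mean(state$right) + params$phi * pair_sd(state$right)
  1 / (1 + exp(-params$beta * (uL - uR)))
}
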