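#' Parameters of the standard Q-learning family
#'
#' Constructs a validated parameter set for the standard (mean-tracking)
#' Q-learning models. The chosen option's value moves toward a reinforcement
#' target of `k1` after a reward and `-k2` after a non-reward, at rate
#' `alpha1`; the unchosen option's value decays toward zero at rate `alpha2`.
#'
#' @param alpha1 Learning rate of the chosen option, in `[0, 1]`.
#' @param alpha2 Forgetting rate of the unchosen option, in `[0, 1]`.
#' @param k1 Reinforcement strength of a reward outcome, `>= 0`.
#' @param k2 Reinforcement strength of a non-reward outcome, `>= 0`.
#' @param beta Inverse temperature of the soft-max choice rule, `>= 0`.
#' @return An object of class `q_params`.
#' @examples
#' q_params(alpha1 = 0.3, alpha2 = 0.3, k1 = 1, k2 = 0.3, beta = 5)
#' @export
q_params <- function(alpha1, alpha2 = 0, k1 = 1, k2 = 0, beta = 1) {
  stopifnot(
    is.numeric(alpha1), length(alpha1) == 1L, alpha1 >= 0, alpha1 <= 1,
    is.numeric(alpha2), length(alpha2) == 1L, alpha2 >= 0, alpha2 <= 1,
    is.numeric(k1), length(k1) == 1L, k1 >= 0,
    is.numeric(k2), length(k2) == 1L, k2 >= 0,
    is.numeric(beta), length(beta) == 1L, beta >= 0
  )
  structure(list(alpha1 = alpha1, alpha2 = alpha2, k1 = k1, k2 = k2,
                 beta = beta),
            class = "q_params")
}

#' Parameters of the Bayesian Q-learning family
#'
#' Constructs a validated parameter set for the Bayesian Q-learning models,
#' which track a beta-distributed posterior over each action's reward
#' probability.
#'
#' @param G Concentration of the per-trial forgetting (transition) kernel,
#'   `> 0`. Small `G` inflates the posterior variance strongly each trial;
#'   `G = Inf` disables forgetting (stationary-world Bayes). May be `Inf`.
#' @param k Relative reinforcement strength of non-reward outcomes, `>= 0`.
#'   `k = 1` is strict Bayesian updating; `k = 0` ignores non-rewards.
#' @param beta Inverse temperature of the soft-max choice rule, `>= 0`.
#' @param phi Weight on the posterior standard deviation in the choice rule.
#'   Positive values are uncertainty seeking (exploration bonus), negative
#'   values uncertainty averse.
#' @return An object of class `bq_params`.
#' @examples
#' bq_params(G = 20, k = 0, beta = 7, phi = 3.5)
#' @export
bq_params <- function(G, k = 0, beta = 1, phi = 0) {
  stopifnot(
    is.numeric(G), length(G) == 1L, G > 0,
    is.numeric(k), length(k) == 1L, k >= 0,
    is.numeric(beta), length(beta) == 1L, beta >= 0,
    is.numeric(phi), length(phi) == 1L, is.finite(phi)
  )
  structure(list(G = G, k = k, beta = beta, phi = phi), class = "bq_params")
}

#' Model variants
#'
#' The six model variants: three standard Q-learning models (`"Q"` original,
#' `"FQ"` forgetting, `"dFQ"` differential-forgetting) and four Bayesian
#' Q-learning models (`"originalBQ"` with strict Bayes `k = 1`,
#' `"asymmetricBQ"` with `k = 0`, its uncertainty-blind restriction
#' `"asymmetricBQ_phi0"` with `phi = 0`, and `"generalizedBQ"` with `k` free).
#'
#' @return Character vector of variant names.
#' @export
model_variants <- function() {
  c("Q", "FQ", "dFQ",
    "originalBQ", "asymmetricBQ", "asymmetricBQ_phi0", "generalizedBQ")
}

# Registry of per-variant free parameters, bounds and constraint assembly.
# Bounds are artifact choices for the bounded optimizer.
variant_info <- function(variant) {
  b <- list(alpha = c(0, 1), kk = c(0, 2), beta = c(0, 50),
            G = c(1e-3, 1e3), k = c(0, 5), phi = c(-20, 20))
  switch(variant,
    Q = list(
      family = "q", free = c("alpha1", "k1", "beta"),
      lower = c(b$alpha[1], b$kk[1], b$beta[1]),
      upper = c(b$alpha[2], b$kk[2], b$beta[2]),
      assemble = function(th) q_params(alpha1 = th[1], alpha2 = 0,
                                       k1 = th[2], k2 = 0, beta = th[3])),
    FQ = list(
      family = "q", free = c("alpha1", "k1", "k2", "beta"),
      lower = c(b$alpha[1], b$kk[1], b$kk[1], b$beta[1]),
      upper = c(b$alpha[2], b$kk[2], b$kk[2], b$beta[2]),
      assemble = function(th) q_params(alpha1 = th[1], alpha2 = th[1],
                                       k1 = th[2], k2 = th[3], beta = th[4])),
    dFQ = list(
      family = "q", free = c("alpha1", "alpha2", "k1", "k2", "beta"),
      lower = c(b$alpha[1], b$alpha[1], b$kk[1], b$kk[1], b$beta[1]),
      upper = c(b$alpha[2], b$alpha[2], b$kk[2], b$kk[2], b$beta[2]),
      assemble = function(th) q_params(alpha1 = th[1], alpha2 = th[2],
                                       k1 = th[3], k2 = th[4], beta = th[5])),
    originalBQ = list(
      family = "bq", free = c("G", "beta", "phi"),
      lower = c(b$G[1], b$beta[1], b$phi[1]),
      upper = c(b$G[2], b$beta[2], b$phi[2]),
      assemble = function(th) bq_params(G = th[1], k = 1, beta = th[2],
                                        phi = th[3])),
    asymmetricBQ = list(
      family = "bq", free = c("G", "beta", "phi"),
      lower = c(b$G[1], b$beta[1], b$phi[1]),
      upper = c(b$G[2], b$beta[2], b$phi[2]),
      assemble = function(th) bq_params(G = th[1], k = 0, beta = th[2],
                                        phi = th[3])),
    asymmetricBQ_phi0 = list(
      family = "bq", free = c("G", "beta"),
      lower = c(b$G[1], b$beta[1]),
      upper = c(b$G[2], b$beta[2]),
      assemble = function(th) bq_params(G = th[1], k = 0, beta = th[2],
                                        phi = 0)),
    generalizedBQ = list(
      family = "bq", free = c("G", "k", "beta", "phi"),
      lower = c(b$G[1], b$k[1], b$beta[1], b$phi[1]),
      upper = c(b$G[2], b$k[2], b$beta[2], b$phi[2]),
      assemble = function(th) bq_params(G = th[1], k = th[2], beta = th[3],
                                        phi = th[4])),
    stop("unknown model variant: ", variant)
  )
}

#' Assemble a full parameter object for a variant from named values
#'
#' Fills in the variant's fixed constraints (e.g. `k = 0` for
#' `"asymmetricBQ"`, `alpha2 = alpha1` for `"FQ"`) around the variant's free
#' parameters.
#'
#' @param variant One of [model_variants()].
#' @param values Named numeric vector or list giving the variant's free
#'   parameters.
#' @return A `q_params` or `bq_params` object.
#' @examples
#' variant_params("asymmetricBQ", c(G = 20, beta = 7, phi = 3.5))
#' @export
variant_params <- function(variant, values) {
  info <- variant_info(variant)
  values <- unlist(values)
  missing <- setdiff(info$free, names(values))
  if (length(missing) > 0L) {
    stop("missing free parameters for ", variant, ": ",
         paste(missing, collapse = ", "))
  }
  info$assemble(as.numeric(values[info$free]))
}
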