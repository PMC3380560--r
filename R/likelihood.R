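PROB_CLAMP <- c(1e-10, 1 - 1e-10)

forward_probs <- function(ci, rw, info, params) {
  if (info$family == "q") {
    q_forward_cpp(ci, rw, params$alpha1, params$alpha2, params$k1,
                  params$k2, params$beta)$p_left
  } else {
    bq_forward_cpp(ci, rw, params$G, params$k, params$beta, params$phi)$p_left
  }
}

#' Normalized likelihood of a model on a session
#'
#' The normalized likelihood is the geometric mean of the per-trial choice
#' likelihoods,
#' \deqn{Z = \left(\prod_{t=1}^N z(t)\right)^{1/N}, \quad
#'       z(t) = \begin{cases} P(a(t)=L) & a(t)=L \\ 1-P(a(t)=L) & a(t)=R \end{cases}}
#' with `P` the model's predicted left-choice probability from
#' [run_model_forward()]. `Z` is a per-trial-scaled fit score in `(0, 1]`; a
#' coin-flipping model scores exactly 0.5. Per-trial likelihoods are clamped
#' to `[1e-10, 1 - 1e-10]` before taking logs; the number of clamped trials
#' is reported.
#'
#' @inheritParams run_model_forward
#' @return List with `Z`, `logZ`, per-trial `z`, `n` and `n_clamped`.
#' @export
normalized_likelihood <- function(session, variant, params) {
  check_session_frame(session)
  info <- variant_info(variant)
  ci <- session_choice_int(session)
  rw <- as.integer(session$reward)
  p <- forward_probs(ci, rw, info, params)
  z <- ifelse(ci == 1L, p, 1 - p)
  zc <- pmin(pmax(z, PROB_CLAMP[1]), PROB_CLAMP[2])
  logZ <- mean(log(zc))
  list(Z = exp(logZ), logZ = logZ, z = z, n = length(z),
       n_clamped = sum(z != zc))
}
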