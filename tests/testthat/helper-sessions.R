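# Shared fixture builders. Heavy cohorts are built once per test run and
# cached so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Minimal single-block session frame from explicit choices/rewards.
toy_session <- function(choice, reward, pL = 2 / 3, pR = 1 / 3,
                        session_id = "toy") {
  data.frame(session_id = session_id, rat_id = NA_character_,
             trial = seq_along(choice), block = 1L, pL = pL, pR = pR,
             choice = choice, reward = as.integer(reward),
             stringsAsFactors = FALSE)
}

# Random choice/reward sequence (no task structure; for model-path tests).
random_toy_session <- function(n, seed, session_id = "rnd") {
  set.seed(seed)
  toy_session(sample(c("L", "R"), n, replace = TRUE),
              rbinom(n, 1, 0.5), session_id = session_id)
}

# Session frame built from blocks of explicit per-block choices.
# `blocks` is a list of data.frames with columns choice, reward, pL, pR.
stack_blocks <- function(blocks, session_id = "stacked") {
  rows <- lapply(seq_along(blocks), function(b) {
    blk <- blocks[[b]]
    data.frame(session_id = session_id, rat_id = NA_character_,
               trial = NA_integer_, block = b, pL = blk$pL, pR = blk$pR,
               choice = blk$choice, reward = as.integer(blk$reward),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$trial <- seq_len(nrow(out))
  out
}

default_bq_cohort <- function(n_sessions = 12, seed = 401) {
  fixture(paste0("bq_cohort_", n_sessions, "_", seed), {
    generate_cohort(rat_spec("bq", "asymmetricBQ", default_bq_agent(),
                             n_sessions = n_sessions, n_blocks = 14),
                    seed = seed)
  })
}

fq_agent_params <- function() {
  c(alpha1 = 0.3, k1 = 1, k2 = 0.3, beta = 5)
}
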