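#' The six reward-probability settings of the free-choice task
#'
#' Left/right reward probabilities come in three difficulty levels — low
#' (33 vs 0%), mid (66 vs 33%) and high (100 vs 66%) — plus their mirror
#' images, giving six settings. The two sides always differ, so one choice
#' is optimal in every setting.
#'
#' @return Data frame with columns `setting` (1..6), `pL`, `pR`.
#' @export
reward_settings <- function() {
  data.frame(setting = 1:6,
             pL = c(1, 2 / 3, 1 / 3, 2 / 3, 1 / 3, 0),
             pR = c(2 / 3, 1 / 3, 0, 1, 2 / 3, 1 / 3))
}

#' Generate a block schedule of reward-probability settings
#'
#' Settings are drawn so that (i) each aligned window of six blocks
#' (blocks 1-6, 7-12, ...) contains all six settings exactly once and
#' (ii) no setting repeats in consecutive blocks, including across window
#' boundaries. Within these constraints the order is uniform random. A
#' trailing partial window is the prefix of a valid window.
#'
#' @param n_blocks Number of blocks, at least 6.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return Integer vector of setting ids (rows of [reward_settings()]).
#' @export
make_schedule <- function(n_blocks, seed = NULL) {
  stopifnot(is.numeric(n_blocks), n_blocks >= 6)
  if (!is.null(seed)) set.seed(seed)
  n_windows <- ceiling(n_blocks / 6)
  sched <- integer(0)
  for (w in seq_len(n_windows)) {
    repeat {
      perm <- sample.int(6)
      if (length(sched) == 0L || perm[1] != sched[length(sched)]) break
    }
    sched <- c(sched, perm)
  }
  sched[seq_len(n_blocks)]
}

#' Block-change rule of the adaptive task
#'
#' A block ends when it has lasted at least 20 trials and the rate of
#' choosing the more rewarding hole has reached 80% over the last 20 trials
#' (i.e. at least 16 of 20 optimal choices).
#'
#' @param optimal_last20 Logical (or 0/1) vector of optimal-choice flags for
#'   the last up-to-20 trials of the block.
#' @param trials_in_block Number of trials completed in the block so far.
#' @return `TRUE` if the block should change.
#' @export
block_should_change <- function(optimal_last20, trials_in_block) {
  stopifnot(trials_in_block >= 0)
  if (trials_in_block < 20L) return(FALSE)
  flags <- tail(as.numeric(optimal_last20), 20L)
  length(flags) == 20L && sum(flags) >= 16
}

#' Simulate one session of the free-choice task
#'
#' Runs an agent through a block schedule in closed loop: each trial the
#' agent emits a left-choice probability, a choice is sampled, a reward is
#' sampled from the current setting's probability for the chosen side, the
#' agent observes the outcome, and the block advances when the 80%-in-last-20
#' criterion fires ([block_should_change()]). The session ends when the last
#' scheduled block's criterion fires, or at `max_trials` (a cap is needed
#' because a poor agent may never reach criterion); in the latter case the
#' returned session carries `attr(, "truncated") = TRUE`.
#'
#' Only success trials exist in this simulation; error trials (hold failures,
#' response timeouts) are not modelled, matching an analysis pipeline that
#' removes them before modelling.
#'
#' @param agent An agent from [make_agent()].
#' @param schedule Integer setting ids from [make_schedule()].
#' @param seed Optional integer seed for choice/reward sampling.
#' @param max_trials Safety cap on session length.
#' @param session_id,rat_id Labels stored in the output.
#' @return Data frame with columns `session_id`, `trial`, `block`, `pL`,
#'   `pR`, `choice`, `reward` (one row per trial; 1-based trial and block
#'   indices), with attributes `truncated` and `seed`.
#' @export
run_session <- function(agent, schedule, seed = NULL, max_trials = 5000,
                        session_id = "s1", rat_id = NA_character_) {
  stopifnot(length(schedule) >= 1L, all(schedule %in% 1:6))
  if (!is.null(seed)) set.seed(seed)
  agent$reset()
  settings <- reward_settings()
  n_cap <- as.integer(max_trials)
  choice <- character(n_cap); reward <- integer(n_cap)
  block <- integer(n_cap); pL <- numeric(n_cap); pR <- numeric(n_cap)
  b <- 1L
  t <- 0L
  in_block <- 0L
  opt_flags <- logical(0)
  truncated <- FALSE
  repeat {
    if (t >= n_cap) { truncated <- b <= length(schedule); break }
    t <- t + 1L
    in_block <- in_block + 1L
    s <- settings[schedule[b], ]
    p_left <- agent$prob()
    ch <- if (runif(1) < p_left) "L" else "R"
    p_ch <- if (ch == "L") s$pL else s$pR
    rw <- as.integer(runif(1) < p_ch)
    agent$update(ch, rw)
    choice[t] <- ch; reward[t] <- rw
    block[t] <- b; pL[t] <- s$pL; pR[t] <- s$pR
    optimal <- (ch == "L") == (s$pL > s$pR)
    opt_flags <- c(tail(opt_flags, 19L), optimal)
    if (block_should_change(opt_flags, in_block)) {
      b <- b + 1L
      in_block <- 0L
      opt_flags <- logical(0)
      if (b > length(schedule)) break
    }
  }
  out <- data.frame(session_id = session_id, rat_id = rat_id,
                    trial = seq_len(t), block = block[seq_len(t)],
                    pL = pL[seq_len(t)], pR = pR[seq_len(t)],
                    choice = choice[seq_len(t)], reward = reward[seq_len(t)],
                    stringsAsFactors = FALSE)
  attr(out, "truncated") <- truncated
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  out
}

#' Flag each trial's choice as optimal or not
#'
#' The optimal choice is the side with the higher reward probability under
#' the trial's setting.
#'
#' @param sessions Session data frame with `pL`, `pR`, `choice`.
#' @return The input with a logical `optimal` column appended.
#' @export
add_optimal <- function(sessions) {
  stopifnot(all(c("pL", "pR", "choice") %in% names(sessions)))
  sessions$optimal <- (sessions$choice == "L") == (sessions$pL > sessions$pR)
  sessions
}

#' Validate the structural invariants of a session collection
#'
#' Checks, per session: required columns; choice labels in `{L, R}`; rewards
#' in `{0, 1}`; 1-based consecutive trial indices; block indices
#' non-decreasing and starting at 1; reward probabilities drawn from the six
#' task settings with `pL != pR`; every completed block (all but possibly the
#' last) at least 20 trials long with an optimal-choice rate of at least 80%
#' over its final 20 trials; the first six blocks covering all six settings
#' and no setting repeated in consecutive blocks; and at least `min_blocks`
#' blocks.
#'
#' @param sessions Session data frame (possibly several `session_id`s).
#' @param min_blocks Minimum number of blocks a usable session must have
#'   (sessions with fewer than seven blocks are conventionally discarded).
#' @return Invisibly `TRUE`; stops with a message naming the offending
#'   session on failure.
#' @export
validate_sessions <- function(sessions, min_blocks = 7L) {
  need <- c("session_id", "trial", "block", "pL", "pR", "choice", "reward")
  if (!all(need %in% names(sessions)))
    stop("missing columns: ", paste(setdiff(need, names(sessions)), collapse = ", "))
  canon <- reward_settings()
  for (sid in unique(sessions$session_id)) {
    s <- sessions[sessions$session_id == sid, , drop = FALSE]
    fail <- function(msg) stop("session ", sid, ": ", msg)
    if (!all(s$choice %in% c("L", "R"))) fail("invalid choice label")
    if (!all(s$reward %in% c(0, 1))) fail("invalid reward value")
    if (!identical(as.integer(s$trial), seq_len(nrow(s)))) fail("trial indices not 1..N")
    if (s$block[1] != 1L || any(diff(s$block) < 0) || any(diff(s$block) > 1))
      fail("block indices must be consecutive from 1")
    key <- paste(round(s$pL, 6), round(s$pR, 6))
    ckey <- paste(round(canon$pL, 6), round(canon$pR, 6))
    if (!all(key %in% ckey)) fail("reward probabilities not among the six settings")
    s <- add_optimal(s)
    blocks <- split(s, s$block)
    nb <- length(blocks)
    if (nb < min_blocks) fail(paste0("fewer than ", min_blocks, " blocks"))
    for (i in seq_len(nb - 1L)) {
      blk <- blocks[[i]]
      if (nrow(blk) < 20L) fail(paste0("completed block ", i, " shorter than 20 trials"))
      if (mean(tail(blk$optimal, 20L)) < 0.8)
        fail(paste0("block ", i, " ended below the 80% criterion"))
      if (length(unique(paste(blk$pL, blk$pR))) != 1L)
        fail(paste0("block ", i, " mixes settings"))
    }
    bset <- match(vapply(blocks, function(b) paste(round(b$pL[1], 6), round(b$pR[1], 6)),
                         character(1)), ckey)
    if (nb >= 6L && length(unique(bset[1:6])) != 6L)
      fail("first six blocks do not cover all six settings")
    if (any(diff(bset) == 0)) fail("same setting in consecutive blocks")
  }
  invisible(TRUE)
}
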