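SESSION_COLUMNS <- c("session_id", "rat_id", "trial", "block", "pL", "pR",
                     "choice", "reward")

# Snap reward probabilities to the canonical setting values {0, 1/3, 2/3, 1}
# so that CSV round-trips are exact despite decimal truncation.
snap_probs <- function(p) {
  canon <- c(0, 1 / 3, 2 / 3, 1)
  i <- vapply(p, function(x) which.min(abs(canon - x)), integer(1))
  ifelse(abs(canon[i] - p) < 1e-6, canon[i], p)
}

#' Write sessions to a delimited trial log
#'
#' One row per success trial, CSV with header `session_id, rat_id, trial,
#' block, pL, pR, choice, reward`. Choices are serialized as `"L"`/`"R"`,
#' rewards as 0/1, probabilities as decimals. Output is deterministic:
#' writing the same collection twice produces byte-identical files.
#'
#' @param sessions Session data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sessions <- function(sessions, path) {
  stopifnot(all(setdiff(SESSION_COLUMNS, "rat_id") %in% names(sessions)))
  if (!"rat_id" %in% names(sessions)) sessions$rat_id <- NA_character_
  out <- sessions[, SESSION_COLUMNS]
  out$pL <- sprintf("%.6f", out$pL)
  out$pR <- sprintf("%.6f", out$pR)
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sessions from a delimited trial log
#'
#' Reads and validates a trial-log CSV written by [write_sessions()] (or any
#' file in the same dialect). Malformed rows are reported with their file
#' line numbers. Reward probabilities within `1e-6` of the canonical setting
#' values `{0, 1/3, 2/3, 1}` are snapped exactly, so a write/read round trip
#' is the identity.
#'
#' @param path Input file path.
#' @param validate Run [validate_sessions()] on the result (structural
#'   session invariants); row-level field checks always run.
#' @param min_blocks Passed to [validate_sessions()].
#' @return Session data frame.
#' @export
read_sessions <- function(path, validate = TRUE, min_blocks = 7L) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 colClasses = c(session_id = "character",
                                rat_id = "character"))
  missing <- setdiff(setdiff(SESSION_COLUMNS, "rat_id"), names(df))
  if (length(missing) > 0L)
    stop("header is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty trial log: ", path)
    return(df)
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- function(cond, what) {
    if (any(cond))
      stop("line ", line[which(cond)[1]], ": ", what)
  }
  bad(!df$choice %in% c("L", "R"), "unknown choice label")
  bad(!df$reward %in% c(0, 1), "reward must be 0 or 1")
  bad(is.na(df$trial) | df$trial < 1, "invalid trial index")
  for (sid in unique(df$session_id)) {
    idx <- which(df$session_id == sid)
    tr <- df$trial[idx]
    if (any(diff(tr) != 1) || tr[1] != 1)
      stop("line ", line[idx[c(tr[1] != 1, diff(tr) != 1)][1]],
           ": non-monotone trial index in session ", sid)
  }
  df$pL <- snap_probs(df$pL)
  df$pR <- snap_probs(df$pR)
  if (validate) validate_sessions(df, min_blocks = min_blocks)
  df
}
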