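#' 2-fold cross-validation model comparison
#'
#' Splits the sessions into two equal folds (at random, seeded; with odd
#' counts the folds differ by one session). For each fold, every variant is
#' fitted to the *other* fold's sessions with one shared parameter vector
#' ([fit_group()]), and each held-out session is then scored by its
#' normalized likelihood under those out-of-sample parameters. Every session
#' is thus scored exactly once per variant with parameters it did not
#' influence, which implicitly penalizes free parameters: extra flexibility
#' that only overfits the training fold does not raise held-out `Z`.
#'
#' @param sessions Session data frame with at least two `session_id`s.
#' @param variants Character vector of [model_variants()] to compare.
#' @param split_seed Integer seed for the fold split.
#' @param stratify_by Optional column name (e.g. `"rat_id"`); if given, the
#'   split is balanced within each level of that column.
#' @inheritParams fit_session
#' @return Object of class `bq_cv`: `scores` (data frame `session_id`,
#'   `variant`, `fold`, `Z` — `fold` is the fold the session was *validated*
#'   in), `folds` (named fold assignment), and `group_fits` (per fold and
#'   variant).
#' @export
cross_validate <- function(sessions, variants, split_seed = 1,
                           n_starts = 20, seed = 1, stratify_by = NULL) {
  ids <- unique(sessions$session_id)
  if (length(ids) < 2L) stop("cross-validation needs at least two sessions")
  set.seed(as.integer(split_seed))
  if (is.null(stratify_by)) {
    shuffled <- sample(ids)
    fold <- stats::setNames(rep(1:2, length.out = length(ids)),
                            shuffled)[ids]
  } else {
    strat <- vapply(ids, function(i)
      as.character(sessions[[stratify_by]][sessions$session_id == i][1]),
      character(1))
    fold <- stats::setNames(integer(length(ids)), ids)
    for (g in unique(strat)) {
      gi <- sample(ids[strat == g])
      fold[gi] <- rep(1:2, length.out = length(gi))
    }
  }
  group_fits <- list()
  scores <- list()
  for (f in 1:2) {
    train <- sessions[sessions$session_id %in% ids[fold != f], ]
    valid_ids <- ids[fold == f]
    for (v in variants) {
      gf <- fit_group(train, v, n_starts = n_starts, seed = seed)
      group_fits[[paste0("fold", f, ".", v)]] <- gf
      zs <- vapply(valid_ids, function(sid) {
        normalized_likelihood(sessions[sessions$session_id == sid, ],
                              v, gf$params)$Z
      }, numeric(1))
      scores[[paste0(f, v)]] <- data.frame(
        session_id = valid_ids, variant = v, fold = f, Z = unname(zs),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(scores = do.call(rbind, c(scores, make.row.names = FALSE)),
                 folds = fold, variants = variants,
                 group_fits = group_fits),
            class = "bq_cv")
}

#' @export
print.bq_cv <- function(x, ...) {
  cat("2-fold cross-validation over", length(x$folds), "sessions\n")
  agg <- stats::aggregate(Z ~ variant, data = x$scores, FUN = mean)
  agg <- agg[order(-agg$Z), ]
  cat("mean held-out normalized likelihood:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}
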