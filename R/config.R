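#' Run configuration for a simulate/fit/compare pipeline
#'
#' Bundles every seed and setting a full pipeline run needs, so that a run
#' is reproducible from its configuration alone.
#'
#' @param master_seed Seed for cohort generation.
#' @param optimizer_seed Seed for optimizer start points.
#' @param split_seed Seed for the cross-validation fold split.
#' @param variants Model variants to fit/compare.
#' @param cohort List of [rat_spec()] objects.
#' @param n_starts Optimizer starts per fit.
#' @param significance Significance threshold for coefficient tests.
#' @param out_dir Output directory for written artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(master_seed, optimizer_seed = master_seed,
                       split_seed = master_seed,
                       variants = c("FQ", "asymmetricBQ",
                                    "asymmetricBQ_phi0"),
                       cohort = list(), n_starts = 20,
                       significance = 0.01, out_dir = ".") {
  stopifnot(is.numeric(master_seed), is.numeric(optimizer_seed),
            is.numeric(split_seed),
            all(variants %in% model_variants()))
  structure(list(master_seed = as.integer(master_seed),
                 optimizer_seed = as.integer(optimizer_seed),
                 split_seed = as.integer(split_seed),
                 variants = variants, cohort = cohort,
                 n_starts = n_starts, significance = significance,
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$cohort <- lapply(x$cohort, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cohort <- lapply(x$cohort, function(r)
    rat_spec(r$rat_id, r$variant, lapply(r$params, as.numeric),
             r$n_sessions, r$n_blocks))
  run_config(x$master_seed, x$optimizer_seed, x$split_seed,
             variants = unlist(x$variants), cohort = cohort,
             n_starts = x$n_starts, significance = x$significance,
             out_dir = x$out_dir)
}
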