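# Hand-built policies with known conditional structure exercise the
# experience-conditional choice table.

test_that("experience-conditional table matches degenerate policies analytically", {
  set.seed(101)
  # perseverating agent: always repeats its previous choice
  blocks <- lapply(1:40, function(b) {
    first <- sample(c("L", "R"), 1)
    data.frame(choice = rep(first, 24), reward = rbinom(24, 1, 0.5),
               pL = 2 / 3, pR = 1 / 3)
  })
  s <- stack_blocks(blocks, session_id = "persev")
  tab <- conditional_optimal_choice(s, window = "first", depth = 1)
  sm <- tab$summary
  get <- function(k) sm$pooled_p[sm$key == k]
  for (k in c("Opt-Rew", "Opt-NonRew")) {
    if (!sm$empty[sm$key == k]) expect_equal(get(k), 1)
  }
  for (k in c("NonOpt-Rew", "NonOpt-NonRew")) {
    if (!sm$empty[sm$key == k]) expect_equal(get(k), 0)
  }

  # win-stay/lose-shift: optimal after Opt-Rew and NonOpt-NonRew, never else
  set.seed(102)
  wsls_block <- function(n = 24) {
    ch <- character(n); rw <- integer(n)
    ch[1] <- sample(c("L", "R"), 1)
    for (t in seq_len(n)) {
      p <- if (ch[t] == "L") 2 / 3 else 1 / 3
      rw[t] <- rbinom(1, 1, p)
      if (t < n) ch[t + 1] <- if (rw[t] == 1) ch[t] else setdiff(c("L", "R"), ch[t])
    }
    data.frame(choice = ch, reward = rw, pL = 2 / 3, pR = 1 / 3)
  }
  sw <- stack_blocks(lapply(1:60, function(b) wsls_block()), "wsls")
  tw <- conditional_optimal_choice(sw, window = "last", depth = 1)$summary
  getw <- function(k) tw$pooled_p[tw$key == k]
  expect_equal(getw("Opt-Rew"), 1)
  expect_equal(getw("Opt-NonRew"), 0)
  expect_equal(getw("NonOpt-Rew"), 0)
  expect_equal(getw("NonOpt-NonRew"), 1)
})

test_that("a random chooser's conditional cells sit near 0.5 and lag-2 keys work", {
  set.seed(103)
  blocks <- lapply(1:3000, function(b)
    data.frame(choice = sample(c("L", "R"), 20, replace = TRUE),
               reward = rbinom(20, 1, 0.5), pL = 1 / 3, pR = 2 / 3))
  s <- stack_blocks(blocks, "random")
  t1 <- conditional_optimal_choice(s, window = "first", depth = 1)$summary
  cond <- t1[t1$key != "Choice0", ]
  tol <- 4 * sqrt(0.25 / pmax(cond$n_trials, 1))
  expect_true(all(abs(cond$pooled_p - 0.5) < tol))
  expect_equal(t1$pooled_p[t1$key == "Choice0"], 0.5, tolerance = 0.02)
  t2 <- conditional_optimal_choice(s, window = "last", depth = 2)$summary
  expect_equal(nrow(t2), 17L)  # Choice0 + 16 lag-2 combinations
  expect_true(all(t2$pooled_p[!t2$empty] >= 0 & t2$pooled_p[!t2$empty] <= 1))
})

test_that("between-window tests and empty-cell flagging are reported", {
  coh <- default_bq_cohort()
  tab <- conditional_optimal_choice(coh$sessions, depth = 1)
  expect_false(is.null(tab$tests))
  expect_setequal(tab$tests$key, c("Choice0", "Opt-Rew", "NonOpt-Rew",
                                   "Opt-NonRew", "NonOpt-NonRew"))
  expect_true(all(tab$summary$n_trials[!tab$summary$empty] > 0))
  # the adapting agent chooses optimally more often late in blocks
  p_first <- tab$summary$pooled_p[tab$summary$key == "Choice0" &
                                    tab$summary$window == "first"]
  p_last <- tab$summary$pooled_p[tab$summary$key == "Choice0" &
                                   tab$summary$window == "last"]
  expect_gt(p_last, p_first)
})

test_that("learning-rate regression recovers exact linear structure and flags degeneracy", {
  set.seed(104)
  n <- 300
  mu <- runif(n, 0.4, 0.7)
  sdv <- runif(n, 0.05, 0.25)
  fake_fit <- function(ea) {
    structure(list(variant = "asymmetricBQ",
                   trajectory = data.frame(ea = ea, ea_conc = ea,
                                           mu_chosen = mu,
                                           sd_chosen = sdv)),
              class = "bq_fit")
  }
  # ea built exactly as a + b * sd: recovered b, zero mean-coefficient
  r <- suppressWarnings(learning_rate_regression(fake_fit(0.1 + 0.8 * sdv)))
  expect_false(r$degenerate)
  expect_equal(r$coef_sd, 0.8, tolerance = 1e-8)
  expect_equal(r$coef_mu, 0, tolerance = 1e-8)
  expect_true(r$sig_sd)
  # constant regressor flagged, not silently solved
  sdv_const <- sdv; sdv_const[] <- 0.1
  bad <- structure(list(variant = "asymmetricBQ",
                        trajectory = data.frame(ea = 0.1 + mu,
                                                ea_conc = 0.1 + mu,
                                                mu_chosen = mu,
                                                sd_chosen = sdv_const)),
                   class = "bq_fit")
  rb <- learning_rate_regression(bad)
  expect_true(rb$degenerate)
  expect_true(is.na(rb$coef_sd))
  # exactly collinear regressors flagged
  col <- structure(list(variant = "asymmetricBQ",
                        trajectory = data.frame(ea = mu, ea_conc = mu,
                                                mu_chosen = mu,
                                                sd_chosen = 2 * mu)),
                   class = "bq_fit")
  expect_true(learning_rate_regression(col)$degenerate)
  # shuffled effective rates lose significance almost always
  set.seed(105)
  n_sig <- 0L
  for (i in 1:20) {
    rs <- learning_rate_regression(fake_fit(sample(0.1 + 0.8 * sdv)))
    n_sig <- n_sig + (isTRUE(rs$sig_sd) || isTRUE(rs$sig_mu))
  }
  expect_lte(n_sig, 2L)
})

test_that("blockwise effective learning rates are consistent window averages", {
  coh <- default_bq_cohort()
  sid <- coh$manifest$session_id[1]
  s <- coh$sessions[coh$sessions$session_id == sid, ]
  fit <- fit_session(s, "asymmetricBQ", n_starts = 5, seed = 4)
  bw <- blockwise_effective_learning_rates(s, fits = setNames(list(fit), sid))
  expect_true(all(bw$n_trials >= 20))
  blk <- bw$block[1]
  idx <- which(s$block == blk)
  expect_equal(bw$ea_first[1], mean(fit$trajectory$ea_conc[idx[1:10]]))
  expect_equal(bw$ea_last[1], mean(fit$trajectory$ea_conc[tail(idx, 10)]))
  bwr <- blockwise_effective_learning_rates(s, fits = setNames(list(fit), sid),
                                            rate = "realized")
  expect_equal(bwr$ea_first[1], mean(fit$trajectory$ea[idx[1:10]]))
  # conjugate (G = Inf) special case: ea decays deterministically within a
  # run of rewarded trials, so early windows must exceed late windows
  det <- toy_session(rep("L", 40), rep(1, 40))
  traj <- run_model_forward(det, "originalBQ", bq_params(G = Inf, k = 1,
                                                         beta = 2, phi = 0))
  expect_equal(traj$ea, 1 / (seq_len(40) + 2))
  expect_gt(mean(traj$ea[1:10]), mean(traj$ea[31:40]))
})

test_that("blockwise FQ learning-rate refits respect the frozen-parameter protocol", {
  coh <- default_bq_cohort()
  sid <- coh$manifest$session_id[3]
  s <- coh$sessions[coh$sessions$session_id == sid, ]
  fit <- fit_session(s, "FQ", n_starts = 5, seed = 4)
  bw <- blockwise_fq_learning_rates(s, fits = setNames(list(fit), sid))
  expect_true(all(bw$n_trials >= 20))
  expect_true(all(bw$alpha_first >= 0 & bw$alpha_first <= 1))
  expect_true(all(bw$alpha_last >= 0 & bw$alpha_last <= 1))
  # a window of constant choices and rewards drives alpha to a bound
  const <- toy_session(rep("L", 25), rep(1, 25))
  cfit <- structure(list(variant = "FQ",
                         params = variant_params("FQ", c(alpha1 = 0.3, k1 = 1,
                                                         k2 = 0.3, beta = 5)),
                         trajectory = NULL),
                    class = "bq_fit")
  cbw <- blockwise_fq_learning_rates(const, fits = list(toy = cfit))
  expect_true(cbw$at_bound_first || cbw$at_bound_last)
})

test_that("a constant-learning-rate agent shows no first>last rate signature", {
  # the block boundary is endogenous (a block ends on a 16/20-optimal
  # streak), which biases last-window refits toward determinism; the control
  # therefore checks the one-sided direction of interest only
  coh <- fixture("fq_cohort_neg", {
    generate_cohort(rat_spec("fqc", "FQ", fq_agent_params(),
                             n_sessions = 8, n_blocks = 14), seed = 602)
  })
  fits <- fit_sessions(coh$sessions, "FQ", n_starts = 5, seed = 3)
  bw <- blockwise_fq_learning_rates(coh$sessions, fits)
  expect_gt(nrow(bw), 80)
  p_greater <- wilcox.test(bw$alpha_first, bw$alpha_last, paired = TRUE,
                           alternative = "greater")$p.value
  expect_gt(p_greater, 0.1)
})

test_that("model-comparison report summarizes and tests variant pairs", {
  fake_cv <- function(zmat, variants) {
    ids <- paste0("s", seq_len(nrow(zmat)))
    scores <- do.call(rbind, lapply(seq_along(variants), function(j)
      data.frame(session_id = ids, variant = variants[j],
                 fold = rep(1:2, length.out = length(ids)),
                 Z = zmat[, j], stringsAsFactors = FALSE)))
    structure(list(scores = scores,
                   folds = setNames(rep(1:2, length.out = length(ids)), ids),
                   variants = variants, group_fits = list()),
              class = "bq_cv")
  }
  # identical score vectors: constant difference flagged, wins at N/2
  z <- runif(20, 0.4, 0.7)
  cv1 <- fake_cv(cbind(z, z), c("asymmetricBQ", "FQ"))
  rep1 <- model_comparison_report(cv1)
  expect_true(rep1$tests$constant_diff)
  expect_true(is.na(rep1$tests$p_value))
  expect_equal(rep1$tests$wins_a, 10)
  # a systematic 0.01 advantage is detected with vanishing p as N grows
  set.seed(107)
  z2 <- runif(200, 0.4, 0.7)
  cv2 <- fake_cv(cbind(z2 + 0.01 + rnorm(200, 0, 1e-3), z2),
                 c("asymmetricBQ", "FQ"))
  rep2 <- model_comparison_report(cv2)
  expect_lt(rep2$tests$p_value, 1e-10)
  expect_equal(rep2$tests$wins_a, 200)
  expect_equal(rep2$summary$variant[1], "asymmetricBQ")
})

test_that("the uncertainty-bonus distribution report tests the median location", {
  all0 <- phi_distribution_report(rep(0, 10))
  expect_equal(all0$median, 0)
  expect_gte(all0$p_value, 0.9)
  set.seed(106)
  pos <- phi_distribution_report(rnorm(40, 3.5, 1))
  expect_gt(pos$median, 2)
  expect_lt(pos$p_value, 1e-5)
  neg <- phi_distribution_report(rnorm(40, -3.5, 1),
                                 method = "two_sample_vs_zero")
  expect_lt(neg$median, -2)
  expect_lt(neg$p_value, 1e-5)
  expect_equal(sum(pos$histogram$count), 40)
  fits <- list(a = list(par = c(G = 1, beta = 2, phi = 1.5)),
               b = list(par = c(G = 1, beta = 2, phi = 2.5)))
  expect_equal(phi_distribution_report(fits)$median, 2)
})
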