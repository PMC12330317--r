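test_that("endpoint laws hold in the noiseless limit", {
  par0 <- noiseless_params(w_v = 0.5, eta = 1)
  p_spec <- list(target_type = "P", target_x = 0, target_y = 300,
                 vcue_x = NA, vcue_y = NA)
  r <- simulate_trial(p_spec, par0)
  expect_equal(r$endpoint, c(0, 300))

  par_b <- noiseless_params(w_v = 0.5, eta = 1, b_p0 = c(0, 10))
  r <- simulate_trial(p_spec, par_b)
  expect_equal(r$endpoint, c(0, 310))

  # bimodal update: eta = 1, w_v = 0.5, offset 10 splits the conflict evenly
  vp_spec <- list(target_type = "VP", target_x = 0, target_y = 300,
                  vcue_x = 0, vcue_y = 310)
  r <- simulate_trial(vp_spec, noiseless_params(0.5, 1))
  expect_equal(r$state$b_p, c(0, 5))
  expect_equal(r$state$b_v, c(0, 5))

  # missing cue / target raises a schedule error
  expect_error(simulate_trial(list(target_type = "V", target_x = 0,
                                   target_y = 300, vcue_x = NA, vcue_y = NA),
                              par0), "schedule error")
  expect_error(simulate_trial(list(target_type = "VP", target_x = NA,
                                   target_y = NA, vcue_x = 0, vcue_y = 310),
                              par0), "schedule error")
})

test_that("noiseless sessions match the closed-form trajectory oracle", {
  for (w in c(0.3, 0.5, 0.7)) {
    eta <- 0.08
    par <- noiseless_params(w, eta)
    ses <- simulate_session(build_conflict_block(seed = 1), par, seed = 2)
    orc <- oracle_conflict_traj(w, eta)
    # endpoint offsets relative to the felt-target base position
    base_y <- ses$target_y
    expect_equal(ses$endpoint_y - base_y, orc$endpoint_rel, tolerance = 1e-12)
    term <- attr(ses, "terminal")[[1]]
    u_final <- orc$u[nrow(orc)]
    expect_equal(term$b_p[2], w * u_final, tolerance = 1e-12)
    expect_equal(term$b_v[2], (1 - w) * u_final, tolerance = 1e-12)
  }
})

test_that("veridical sessions leave opposing biases unchanged in the noiseless limit", {
  # the observer perceives a standing conflict of -(b_p + b_v); biases are
  # stationary under veridical cues exactly when they cancel
  par <- noiseless_params(0.4, 0.08, b_p0 = c(1, 2), b_v0 = c(-1, -2))
  ses <- simulate_session(build_baseline_block("expt2_veridical", 1), par,
                          seed = 5)
  term <- attr(ses, "terminal")[[1]]
  expect_equal(term$b_p, c(1, 2))
  expect_equal(term$b_v, c(-1, -2))
  p <- ses[ses$target_type == "P", ]
  expect_equal(p$endpoint_y, p$target_y + 2)

  # non-cancelling biases decay: the summed bias shrinks over VP trials
  par2 <- noiseless_params(0.4, 0.08, b_p0 = c(0, 4), b_v0 = c(0, 4))
  ses2 <- simulate_session(build_baseline_block("expt2_veridical", 1), par2,
                           seed = 5)
  term2 <- attr(ses2, "terminal")[[1]]
  expect_lt(abs(term2$b_p[2] + term2$b_v[2]), 8)
  expect_gt(term2$b_p[2] + term2$b_v[2], 0)
})

test_that("zero-conflict blocks produce zero-mean recalibration", {
  # property: E[terminal bias - baseline] = 0 under veridical schedules
  set.seed(7)
  sched <- build_baseline_block("expt2_veridical", 1)
  par <- observer_params(sigma_p = 8, sigma_v = 10.5, sigma_m = 8,
                         w_v = 0.4, eta = 0.08)
  term <- vapply(1:200, function(i) {
    s <- simulate_session(sched, par, seed = i)
    attr(s, "terminal")[[1]]$b_p[2]
  }, numeric(1))
  se <- sd(term) / sqrt(length(term))
  expect_lt(abs(mean(term)), 3 * se)
})

test_that("recalibration split ratio increases with the visual weight", {
  grid <- seq(0.1, 0.9, by = 0.2)
  ratio <- vapply(grid, function(w) {
    ses <- simulate_session(build_conflict_block(1), noiseless_params(w, 0.08),
                            seed = 1)
    term <- attr(ses, "terminal")[[1]]
    term$b_p[2] / term$b_v[2]
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
})

test_that("total terminal recalibration stays below the imposed conflict", {
  for (eta in c(0.05, 0.3, 1)) {
    ses <- simulate_session(build_conflict_block(1),
                            noiseless_params(0.5, eta), seed = 1)
    term <- attr(ses, "terminal")[[1]]
    tot <- term$b_p[2] + term$b_v[2]
    expect_gte(tot, 0)
    expect_lte(tot, 70 + 1e-9)
  }
})

test_that("cohort simulation is deterministic and carries ground truth", {
  cfg <- cohort_config("expt2", n_per_group = 3, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 9)
  expect_setequal(unique(a$truth$group), c("S1", "M1", "Sham"))
  # sham multipliers = 1: pre/post sigma_p identical in ground truth
  sham <- a$truth[a$truth$group == "Sham", ]
  expect_equal(sham$sigma_p_post, sham$sigma_p)
  s1 <- a$truth[a$truth$group == "S1", ]
  expect_equal(s1$sigma_p_post, s1$sigma_p * 1.3)
  expect_error(simulate_cohort(
    cohort_config("expt2", n_per_group = 2, seed = 1,
                  group_effects = list(S1 = list(sigma_p = 1, eta = 1)))),
    "unknown group")
})

test_that("S1 noise multiplier raises mean post-pre proprioceptive variance", {
  cfg <- cohort_config("expt2", n_per_group = 34, seed = 9)
  co <- simulate_cohort(cfg)
  est <- estimate_cohort(co$trials)
  v1 <- est[est$block_label == "veridical1", ]
  v2 <- est[est$block_label == "veridical2", ]
  d <- v2$raw_var_p - v1$raw_var_p
  expect_gt(mean(d[v1$group == "S1"]), 0)
  # and clearly larger than the unstimulated groups on average (100+ draws)
  expect_gt(mean(d[v1$group == "S1"]),
            mean(d[v1$group != "S1"]))
})

test_that("heterogeneous cohorts show the inverse recalibration relationship", {
  co <- simulate_cohort(cohort_config("expt1", n_per_group = 100, seed = 21))
  cs <- co$sai[co$sai$session == "conflict", ]
  expect_lt(cor(cs$recal_p, cs$recal_v), 0)
})

test_that("control cohorts have no proprioceptive targets in the shift block", {
  co <- simulate_cohort(cohort_config("control", n_per_group = 2, seed = 3))
  sh <- co$trials[co$trials$block_label == "vshift_control", ]
  expect_true(all(sh$target_type == "V"))
  expect_true(all(is.na(sh$target_x)))
})
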