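test_that("generators emit valid, seed-reproducible observation sets", {
  cfg <- sim_config(seed = 80)
  per_expect <- 4 * 30
  for (gen in list(
    function() generate_homogeneous(cfg, 0.05),
    function() generate_beta_dyadic(cfg, 0.04, 0.5)$obs,
    function() generate_bonded_markov(cfg)$obs,
    function() generate_arena(sim_config(N = 6, periods_per_day = 8,
                                         days = c(1, 4), seed = 80)))) {
    o1 <- gen(); o2 <- gen()
    expect_s3_class(o1, "observation_set")
    expect_equal(o1$records, o2$records)  # bit-reproducible under the seed
  }
  obs <- generate_homogeneous(cfg, 0.05)
  expect_equal(n_periods(obs), per_expect)   # the study layout: 30 x 4
  expect_equal(obs$N, 12)
  expect_equal(unique(obs$periods$day), c(1, 4, 7, 10))
})

test_that("homogeneous generator spans its limiting cases", {
  cfg <- sim_config(N = 6, periods_per_day = 5, days = 1, seed = 81)
  solo <- generate_homogeneous(cfg, 0)
  expect_true(all(association_matrix(solo)$AI == 0))
  expect_equal(unname(gregariousness(solo)), rep(0, 6))

  herd <- generate_homogeneous(cfg, 1)
  am <- association_matrix(herd)$AI
  expect_true(all(am[upper.tri(am)] == 1))

  # mean AI is stable across seeds at fixed p (self-consistency against a
  # larger reference run)
  set.seed(82)
  big <- generate_homogeneous(sim_config(N = 12, periods_per_day = 30,
                                         days = c(1, 4, 7, 10, 13, 16, 19, 22)),
                              0.05)
  ref <- mean(association_matrix(big)$AI[upper.tri(diag(12))])
  set.seed(83)
  small_means <- replicate(12, {
    o <- generate_homogeneous(sim_config(), 0.05)
    mean(association_matrix(o)$AI[upper.tri(diag(12))])
  })
  mc_se <- sd(small_means) / sqrt(length(small_means))
  expect_lt(abs(mean(small_means) - ref), 4 * mc_se + 0.01)
})

test_that("beta-dyadic generator has exactly known ground truth", {
  cfg <- sim_config(seed = 84)
  # degenerate CV: all true probabilities equal the mean
  g0 <- generate_beta_dyadic(cfg, 0.04, 0)
  expect_true(all(g0$true_p[upper.tri(g0$true_p)] == 0.04))

  # drawn probability matrices hit the requested CV on average
  set.seed(85)
  cvs <- replicate(300, {
    g <- generate_beta_dyadic(sim_config(N = 12, periods_per_day = 1, days = 1),
                              0.04, 0.5)
    p <- g$true_p[upper.tri(g$true_p)]
    sd(p) / mean(p)
  })
  mc_se <- sd(cvs) / sqrt(length(cvs))
  expect_lt(abs(mean(cvs) - 0.5), 2 * mc_se + 0.03)

  # observed co-membership frequency tracks the dyad's own true p
  set.seed(86)
  g <- generate_beta_dyadic(sim_config(days = c(1, 4, 7, 10, 13, 16)),
                            0.04, 0.5)
  am <- association_matrix(g$obs)
  ut <- upper.tri(am$AI)
  expect_gt(cor(am$AI[ut], g$true_p[ut]), 0.5)
  expect_lt(abs(mean(am$AI[ut]) - mean(g$true_p[ut])), 0.01)

  expect_error(generate_beta_dyadic(cfg, 0.2, 0.5), "below 1/")
  expect_error(generate_beta_dyadic(cfg, 0.05, 5), "no Beta")
})

test_that("bonded Markov generator produces two-timescale persistence", {
  # both hazards tiny: associations freeze within a day -> g = 1
  frozen <- generate_bonded_markov(sim_config(N = 6, periods_per_day = 10,
                                              days = 1, seed = 87),
                                   bonded_markov_params(
                                     fraction_bonded = 0.5,
                                     p_assoc_eq_fast = 0.4,
                                     p_assoc_eq_slow = 0.4,
                                     rate_fast = 1e-9, rate_slow = 1e-9))
  cur <- lar_curve(frozen$obs, "minute")
  expect_true(all(cur$g[cur$n_pairs > 0] == 1))

  # implied mixture bookkeeping
  p <- bonded_markov_params(0.3, 0.1, 0.35, 1, 0.01)
  sim <- generate_bonded_markov(sim_config(seed = 88), p)
  expect_equal(sim$implied$rate_fast, 1 / 0.9)
  expect_equal(sim$implied$rate_slow, 0.01 / 0.65)
  expect_equal(sum(sim$bonded[upper.tri(sim$bonded)]), round(0.3 * 66))

  # persistent structure: observed LAR exceeds the null rate
  cur2 <- lar_curve(sim$obs, "minute")
  expect_gt(mean(cur2$g[cur2$n_pairs > 0]), cur2$null_rate)
})

test_that("arena generator obeys the chain rule and its limits", {
  # three fish in a line at 3.9 body-length spacing: one group spanning
  # 7.8 body lengths
  bl <- 2.69  # cm
  xy <- cbind(c(0, 3.9 * bl, 7.8 * bl), c(0, 0, 0))
  expect_equal(group_by_chain_rule(xy, 4 * bl), rep(1L, 3))
  # at 4.1 body-length spacing they are three singletons
  xy2 <- cbind(c(0, 4.1 * bl, 8.2 * bl), c(0, 0, 0))
  expect_equal(group_by_chain_rule(xy2, 4 * bl), 1:3)

  # tight cohesion, no fission, no noise -> one permanent group
  tight <- generate_arena(sim_config(N = 6, periods_per_day = 10, days = 1,
                                     seed = 89),
                          arena_params(step_sd_cm = 0.1, cohesion = 0.95,
                                       fission_hazard = 0, fusion_hazard = 1))
  am <- association_matrix(tight)$AI
  expect_gt(mean(am[upper.tri(am)]), 0.9)

  # pure fast diffusion (no cohesion, steps the size of the arena) leaves
  # no preferred companions
  set.seed(90)
  nonsig <- replicate(12, {
    obs <- generate_arena(sim_config(N = 8, periods_per_day = 20, days = 1),
                          arena_params(step_sd_cm = 60, cohesion = 0,
                                       fission_hazard = 0, fusion_hazard = 0))
    permutation_test_cv(obs, permutation_config(200, 100))$p_high > 0.05
  })
  expect_gte(mean(nonsig), 0.75)
})
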