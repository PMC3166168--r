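test_that("lagged association rate hits its limiting cases", {
  # frozen groups where everyone has an associate -> g = 1 at every lag
  frozen <- observation_set(data.frame(
    day = rep(c(1, 4), each = 12),
    minute = rep(rep(0:5, each = 2), 2),
    group_id = "g1",
    individual_id = rep(c("A", "B"), 12)))
  cur <- lar_curve(frozen, "minute")
  expect_true(all(cur$g == 1))
  expect_equal(cur$null_rate, 1)
  day_cur <- lar_curve(frozen, "day")
  expect_true(all(day_cur$g == 1))

  # all singletons -> null rate 0, no contributing pairs anywhere
  solo <- generate_homogeneous(sim_config(N = 4, periods_per_day = 5,
                                          days = 1, seed = 1), 0)
  expect_equal(null_association_rate(solo), 0)
  expect_equal(lagged_association_rate(solo, 1, "minute")$n_pairs, 0)
  expect_true(is.na(lagged_association_rate(solo, 1, "minute")$g))

  # one group of N always -> null rate 1
  all_in <- generate_homogeneous(sim_config(N = 5, periods_per_day = 4,
                                            days = 1, seed = 2), 1)
  expect_equal(null_association_rate(all_in), 1)
})

test_that("toy curve with one partner switch equals hand enumeration", {
  obs <- toy_obs()   # m0,m1: {A,B},{C}; m2: {A,C},{B}
  cur <- lar_curve(obs, "minute")
  # lag 1: pairs (m0,m1): AB assoc at both (2 ordered) of 2 at risk;
  #        (m1,m2): AB assoc at m1 but apart at m2 (0 of 2)
  # lag 2: (m0,m2): 0 of 2
  expect_equal(cur$lags, c(1, 2))
  expect_equal(cur$num, c(2, 0))
  expect_equal(cur$den, c(4, 2))
  expect_equal(cur$g, c(0.5, 0))
  # null rate: 9 (i,t) slots, associated ones have 1 associate of 2 others
  expect_equal(cur$null_rate, oracle_null_rate(obs))
})

test_that("estimator equals full enumeration on random data", {
  set.seed(63)
  for (rep in 1:6) {
    obs <- random_obs(N = sample(3:6, 1), n_days = 2, ppd = sample(2:5, 1))
    for (scale in c("minute", "day")) {
      cur <- lar_curve(obs, scale)
      orc <- oracle_lar(obs, scale)
      expect_equal(cur$lags, orc$lag)
      expect_equal(cur$num, orc$num)
      expect_equal(cur$den, orc$den)
    }
    expect_equal(null_association_rate(obs), oracle_null_rate(obs))
    expect_true(all(is.na(cur$g) | (cur$g >= 0 & cur$g <= 1)))
  }
})

test_that("duplicating every period's records leaves the estimator fixed", {
  set.seed(64)
  obs <- random_obs(N = 5, n_days = 1, ppd = 4, p_absent = 0)
  rec <- data.frame(day = obs$periods$day[obs$records$period],
                    minute = obs$periods$minute[obs$records$period],
                    group_id = obs$records$group_id,
                    individual_id = obs$records$individual_id)
  rec2 <- rbind(rec, transform(rec, day = day + 10))
  obs2 <- observation_set(rec2, individuals = obs$individuals)
  c1 <- lar_curve(obs, "minute")
  c2 <- lar_curve(obs2, "minute")
  expect_equal(c2$g[match(c1$lags, c2$lags)], c1$g)
})

test_that("moving-average smoothing pools ratios of sums", {
  set.seed(65)
  obs <- generate_homogeneous(sim_config(N = 6, periods_per_day = 10,
                                         days = 1), 0.2)
  cur <- lar_curve(obs, "minute")
  expect_equal(smooth_lar(cur, 1)$g, cur$g)

  # constant-g data: smoothing changes nothing
  frozen <- observation_set(data.frame(
    day = 1, minute = rep(0:7, each = 2), group_id = "g1",
    individual_id = rep(c("A", "B"), 8)))
  fc <- lar_curve(frozen, "minute")
  expect_equal(smooth_lar(fc, 5)$g, fc$g)

  # window wider than everything -> one pooled estimate everywhere
  pooled <- smooth_lar(cur, 1e9)
  expect_equal(pooled$g, rep(sum(cur$num) / sum(cur$den), length(cur$g)))

  # a step change is bridged monotonically by a wide window
  step <- list(tau = 1:10, num = c(rep(90, 5), rep(10, 5)),
               den = rep(100, 10))
  sc <- structure(list(lags = step$tau, g = step$num / step$den,
                       num = step$num, den = step$den,
                       n_pairs = step$den, scale = "minute",
                       null_rate = 0.1, se = NULL), class = "lar_curve")
  sm <- smooth_lar(sc, 300)
  expect_true(all(diff(sm$g) <= 1e-12))
})

test_that("jackknife SEs across period blocks behave correctly", {
  # identical blocks -> SE 0
  frozen <- observation_set(data.frame(
    day = rep(c(1, 4, 7), each = 20),
    minute = rep(rep(0:9, each = 2), 3),
    group_id = "g1",
    individual_id = rep(c("A", "B"), 30)))
  jk <- lar_jackknife(frozen, "minute", "five_minutes")
  expect_equal(attr(jk, "k_blocks"), 6)   # 2 five-minute blocks x 3 days
  expect_true(all(jk$se[!is.na(jk$se)] == 0))

  # k = 2 reduces to the closed form |g1 - g2| / 2
  set.seed(66)
  obs <- generate_homogeneous(sim_config(N = 6, periods_per_day = 5,
                                         days = c(1, 4)), 0.3)
  jk2 <- lar_jackknife(obs, "minute", "one_day")
  per <- obs$periods
  halves <- lapply(c(4, 1), function(drop_day) {
    keep <- obs$records[per$day[obs$records$period] != drop_day, ]
    lar_curve(observation_set(data.frame(
      day = per$day[keep$period], minute = per$minute[keep$period],
      group_id = keep$group_id, individual_id = keep$individual_id),
      individuals = obs$individuals), "minute")
  })
  manual <- abs(halves[[1]]$g - halves[[2]]$g) / 2
  expect_equal(jk2$se, manual)

  expect_error(lar_jackknife(observation_set(data.frame(
    day = 1, minute = 0:3, group_id = "g1",
    individual_id = rep(c("A", "B"), 2))), "minute", "one_day"),
    "at least 2 blocks")
})
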