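test_that("model family evaluates to its exact functional forms", {
  th <- c(a = 0.3, b = 1.0, c = 0.5, d = 0.01)
  expect_equal(evaluate_lar_model("rd_2ca", th, 0), 0.8)   # a + c at tau = 0
  expect_equal(evaluate_lar_model("rd_2ca", c(a = 0.3, b = 0, c = 0.4, d = 0),
                                  c(0, 5, 50)), rep(0.7, 3))
  # reported parameter set of a strongly bonded population evaluates to
  # its amplitude sum at lag zero
  expect_equal(evaluate_lar_model("rd_2ca",
                                  c(a = 0.01, b = 1.03, c = 0.69, d = 0.01),
                                  0), 0.70)
  expect_equal(evaluate_lar_model("rd_ca", c(a = 0.6, b = 0.2), 5),
               0.6 * exp(-1))
  expect_equal(evaluate_lar_model("rd_cc_ca", c(a = 0.2, c = 0.3, b = 0.5), 0),
               0.5)
  expect_equal(evaluate_lar_model("linear", c(f = 0.4, e = -0.01), 10), 0.3)
  expect_equal(evaluate_lar_model("rd_cc", c(a = 0.25), c(1, 99)),
               c(0.25, 0.25))
})

test_that("quasi-likelihood fitting recovers generating parameters", {
  set.seed(70)
  # constant g = 0.7 over 50 lags x 5000 trials
  sim <- simulate_lar_counts("rd_cc", c(a = 0.7), 1:50, rep(5000, 50))
  f <- fit_lar_model(sim, "rd_cc")
  expect_true(f$converged)
  expect_lt(abs(f$theta[["a"]] - 0.7), 0.01)

  # two-timescale truth: components recovered, fast one reported first
  des <- lar_lag_design(2.5e5)
  sim2 <- simulate_lar_counts("rd_2ca", c(a = 0.3, b = 1, c = 0.5, d = 0.01),
                              des$tau, des$den)
  f2 <- fit_lar_model(sim2, "rd_2ca")
  expect_gte(f2$theta[["b"]], f2$theta[["d"]])
  expect_lt(abs(f2$theta[["a"]] - 0.3), 0.1)
  expect_lt(abs(f2$theta[["c"]] - 0.5), 0.1)
  expect_equal(f2$timescales[["1/b"]], 1 / f2$theta[["b"]])

  # underdetermined: a 4-parameter model on a single lag errors
  expect_error(fit_lar_model(list(tau = 1, num = 10, den = 100), "rd_2ca"),
               "distinct lags")
})

test_that("nested models never lose quasi-likelihood and QAIC = AIC at chat 1", {
  set.seed(71)
  des <- lar_lag_design(2e4)
  sim <- simulate_lar_counts("rd_ca", c(a = 0.6, b = 0.3), des$tau, des$den)
  f_small <- fit_lar_model(sim, "rd_ca")
  f_big <- fit_lar_model(sim, "rd_2ca")
  expect_gte(f_big$lnQL, f_small$lnQL - 1e-6)
  expect_equal(qaic(f_small, chat = 1), -2 * f_small$lnQL + 2 * f_small$k)
  # the larger model collapses onto the single-exponential truth: either a
  # spare amplitude shrinks or the two rates coincide, so the fitted curves
  # agree everywhere
  g_small <- evaluate_lar_model("rd_ca", f_small$theta, des$tau)
  g_big <- evaluate_lar_model("rd_2ca", f_big$theta, des$tau)
  expect_lt(max(abs(g_big - g_small)), 0.02)
})

test_that("QAIC selection prefers truth at both ends of complexity", {
  set.seed(72)
  des <- lar_lag_design(2.5e5)
  sim <- simulate_lar_counts("rd_2ca", c(a = 0.3, b = 1, c = 0.5, d = 0.01),
                             des$tau, des$den)
  sel <- select_lar_model(sim)
  expect_equal(sel$best$model, "rd_2ca")
  expect_equal(nrow(sel$table), 4)
  expect_equal(sel$table$dQAIC[1], 0)
  expect_gte(sel$chat, 1)

  sim_const <- simulate_lar_counts("rd_cc", c(a = 0.7), des$tau, des$den)
  sel2 <- select_lar_model(sim_const, models = c("rd_cc", "rd_2ca"))
  expect_equal(sel2$best$model, "rd_cc")

  # single candidate comes back unchanged
  sel3 <- select_lar_model(sim_const, models = "rd_cc")
  expect_equal(sel3$best$model, "rd_cc")
})

test_that("class comparison uses pooled t and Benjamini-Yekutieli control", {
  # m = 4 dependent comparisons at alpha = 0.05: largest-rank critical
  # value is alpha / sum(1/i) = 0.024
  crit <- by_critical_values(4, 0.05)
  expect_equal(round(crit[4], 3), 0.024)
  expect_equal(crit[1], 0.05 / (4 * sum(1 / (1:4))))
  expect_true(all(diff(crit) > 0))

  # identical class samples -> t = 0, p = 1
  est <- data.frame(a = rep(c(0.2, 0.2), c(4, 4)))
  cmp0 <- compare_classes(est, rep(c("h", "l"), c(4, 4)))
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p, 1)
  expect_false(cmp0$significant)

  # 7 vs 5 populations: pooled df = 10, matching a two-sample design
  set.seed(73)
  est2 <- data.frame(a = c(rnorm(7, 0.01, 0.1), rnorm(5, 0.32, 0.2)),
                     b = c(rnorm(7, 1.03, 0.2), rnorm(5, 0.20, 0.3)))
  cmp <- compare_classes(est2, rep(c("high", "low"), c(7, 5)))
  expect_equal(cmp$df, c(10, 10))
  # pooled t equals the textbook formula
  v1 <- est2$a[1:7]; v2 <- est2$a[8:12]
  sp <- sqrt((6 * var(v1) + 4 * var(v2)) / 10)
  expect_equal(cmp$t[1], (mean(v1) - mean(v2)) / (sp * sqrt(1 / 7 + 1 / 5)))

  # a glaring difference survives the FDR control
  est3 <- data.frame(x = c(rep(0, 4), rep(10, 4)) + rnorm(8, 0, 0.1),
                     y = rnorm(8))
  cmp3 <- compare_classes(est3, rep(c("h", "l"), c(4, 4)))
  expect_true(cmp3$significant[cmp3$parameter == "x"])
  expect_false(cmp3$significant[cmp3$parameter == "y"])
})
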