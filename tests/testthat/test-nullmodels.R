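test_that("checkerboard swaps flip 2x2 checkerboards and nothing else", {
  obs <- observation_set(data.frame(
    day = 1, minute = 0, group_id = c("g1", "g2"),
    individual_id = c("A", "B")))
  gbi <- to_gbi(obs)   # [[1,0],[0,1]] in one period
  set.seed(50)
  flipped <- FALSE
  for (k in 1:100) {
    out <- checkerboard_swap(gbi, within = "period")
    if (attr(out, "swapped")) {
      expect_equal(unname(unclass(out))[1:2, 1:2], rbind(c(0L, 1L), c(1L, 0L)))
      flipped <- TRUE
      break
    }
  }
  expect_true(flipped)

  # an all-ones column (an individual present in every group) admits no
  # checkerboard: it never changes, while others still swap
  obs2 <- observation_set(data.frame(
    day = 1, minute = rep(0:3, each = 2),
    group_id = "g1",
    individual_id = c("A", "C", "B", "C", "A", "C", "B", "C")))
  gbi2 <- to_gbi(obs2)
  res <- swap_chain(gbi2, 10000, within = "day")
  expect_equal(res$gbi[, "C"], gbi2[, "C"])
  expect_identical(colSums(res$gbi), colSums(gbi2))

  # margins conserved over a long chain on random data
  set.seed(51)
  obs3 <- generate_homogeneous(sim_config(N = 8, periods_per_day = 10,
                                          days = c(1, 4)), 0.15)
  gbi3 <- to_gbi(obs3)
  for (w in c("period", "day", "none")) {
    res <- swap_chain(gbi3, 10000, within = w)
    expect_identical(rowSums(res$gbi), rowSums(gbi3))
    expect_identical(colSums(res$gbi), colSums(gbi3))
    if (w == "period") {
      # same-scan swaps keep each period a valid partition
      for (p in unique(attr(gbi3, "period"))) {
        block <- res$gbi[attr(gbi3, "period") == p, , drop = FALSE]
        expect_true(all(colSums(block) == 1))
      }
    }
  }
})

test_that("swap chains mix more with more flips between recordings", {
  set.seed(52)
  obs <- generate_homogeneous(sim_config(), 0.05)
  denom <- association_matrix(obs)$denom
  ut <- upper.tri(denom)
  run <- function(flips) {
    gbi <- to_gbi(obs)
    block <- attr(gbi, "period")
    vals <- numeric(80)
    for (k in 1:80) {
      r <- fissionet:::.swap_chain_cpp(gbi, block, flips, TRUE)
      gbi <- r$gbi
      x <- crossprod(gbi)
      ai <- x[ut] / denom[ut]
      vals[k] <- sd(ai) / mean(ai)
    }
    stats::acf(vals, lag.max = 1, plot = FALSE)$acf[2]
  }
  expect_lt(run(500), run(5))
})

test_that("CV permutation test honours its contract", {
  set.seed(53)
  obs <- generate_homogeneous(sim_config(N = 8, periods_per_day = 10,
                                         days = c(1, 4)), 0.1)
  r1 <- permutation_test_cv(obs, permutation_config(1, 50))
  expect_length(r1$null_values, 1)
  expect_gte(r1$p_high + r1$p_low, 1)

  # two permanent cliques: observed CV exceeds every null CV
  cliques <- observation_set(data.frame(
    day = rep(c(1, 1, 4, 4), each = 30),
    minute = rep(rep(0:9, each = 6), 2),
    group_id = rep(rep(c("g1", "g1", "g1", "g2", "g2", "g2"), 10), 2),
    individual_id = rep(sprintf("i%d", c(1:3, 4:6)), 20)))
  set.seed(54)
  rc <- permutation_test_cv(cliques, permutation_config(200, 100))
  expect_equal(rc$p_high, rc$attainable_min_p * sum(rc$null_values >= rc$observed))
  expect_lte(rc$p_high, 0.01)
  expect_true(all(rc$null_values <= rc$observed))

  # degenerate data (single group always): no swap possible, flagged
  frozen <- generate_homogeneous(sim_config(N = 4, periods_per_day = 5,
                                            days = 1, seed = 3), 1)
  rd <- suppressWarnings(permutation_test_gregariousness(
    frozen, permutation_config(5, 10)))
  expect_false(rd$informative)
})

test_that("gregariousness statistic equals its hand computation", {
  # 3 individuals, 4 periods: A and B always paired, C always alone
  obs <- observation_set(data.frame(
    day = 1, minute = rep(0:3, each = 3),
    group_id = rep(c("g1", "g1", "g2"), 4),
    individual_id = rep(c("A", "B", "C"), 4)))
  set.seed(55)
  r <- permutation_test_gregariousness(obs, permutation_config(10, 10))
  # typical group sizes: A = 2, B = 2, C = 1
  expect_equal(r$observed, sd(c(2, 2, 1)))
})

test_that("dyadic significance flags structure and guards degeneracy", {
  # single-period data: every dyad untestable (denominator 1)
  single <- observation_set(data.frame(
    day = 1, minute = 0, group_id = c("g1", "g1", "g2", "g2"),
    individual_id = c("A", "B", "C", "D")))
  set.seed(56)
  ds1 <- dyadic_significance(single, permutation_config(20, 10))
  expect_true(all(ds1$dyads$status == "untestable"))

  # a permanent pair in homogeneous noise is detected as preferred
  set.seed(57)
  obs <- generate_homogeneous(sim_config(), 0.05,
                              permanent_dyads = rbind(c(1, 2)))
  ds <- dyadic_significance(obs, permutation_config(300, 200))
  expect_true(any(ds$preferred$id1 == "i01" & ds$preferred$id2 == "i02"))
  expect_gt(ds$dyads$quantile[ds$dyads$id1 == "i01" & ds$dyads$id2 == "i02"],
            0.975)
})
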