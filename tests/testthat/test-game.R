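test_that("joint outcome follows each collective criterion", {
  expect_equal(joint_outcome(trial_spec("additive", 2, 3, 5, 10)), 10)
  expect_equal(joint_outcome(trial_spec("additive", 2, 2, 5, 10)), 0)
  expect_equal(joint_outcome(trial_spec("disjunctive", 6, 1, 5, 10)), 10)
  expect_equal(joint_outcome(trial_spec("disjunctive", 2, 2, 5, 10)), 0)
  # simple: pot always awarded, threshold irrelevant
  expect_equal(joint_outcome(trial_spec("simple", 4, 4, NA, 8)), 8)
  # inclusive threshold comparison: equality wins
  expect_equal(joint_outcome(trial_spec("additive", 2, 3, 5, 10)), 10)
  expect_equal(joint_outcome(trial_spec("disjunctive", 5, 0, 5, 10)), 10)
})

test_that("invalid trials are rejected", {
  expect_error(trial_spec("additive", -1, 3, 5, 10), "non-negative")
  expect_error(trial_spec("additive", 2, 3, 5, 0), "pot")
  expect_error(trial_spec("conjunctive", 2, 3, 5, 10), "criterion")
  expect_error(characteristic_function(trial_spec("additive", 2, 3, 5, -10)),
               "loss")
  expect_error(agent_target_ratio(list(), trial_spec("additive", 2, 3, 5, -10)),
               "loss")
})

test_that("characteristic function matches the coalition structure", {
  g <- characteristic_function(trial_spec("additive", 2, 3, 5, 10))
  expect_equal(unlist(g[c("v_p1", "v_p2", "v_both")]),
               c(v_p1 = 0, v_p2 = 0, v_both = 10))
  g <- characteristic_function(trial_spec("additive", 6, 1, 5, 10))
  expect_equal(unlist(g[c("v_p1", "v_p2", "v_both")]),
               c(v_p1 = 10, v_p2 = 0, v_both = 10))
  g <- characteristic_function(trial_spec("disjunctive", 6, 7, 5, 10))
  expect_equal(unlist(g[c("v_p1", "v_p2", "v_both")]),
               c(v_p1 = 10, v_p2 = 10, v_both = 10))
  # simple: proportional to each coalition's summed correct responses
  g <- characteristic_function(trial_spec("simple", 2, 6, NA, 8))
  expect_equal(unlist(g[c("v_p1", "v_p2", "v_both")]),
               c(v_p1 = 2, v_p2 = 6, v_both = 8))
})

test_that("closed-form Shapley equals the permutation oracle on random games", {
  games <- random_monotone_games(1500, seed = 7)
  phi <- shapley_values(games)
  orc <- t(mapply(shapley_oracle, games$v_p1, games$v_p2, games$v_both))
  expect_equal(phi$phi1, unname(orc[, 1]))
  expect_equal(phi$phi2, unname(orc[, 2]))
  # efficiency holds exactly (integer-cents games)
  expect_identical(phi$phi1 + phi$phi2, games$v_both)
})

test_that("Shapley axioms: symmetry and dummy player", {
  games <- random_monotone_games(500, seed = 11)
  phi <- shapley_values(games)
  swapped <- shapley_values(data.frame(v_p1 = games$v_p2, v_p2 = games$v_p1,
                                       v_both = games$v_both))
  expect_identical(phi$phi1, swapped$phi2)
  expect_identical(phi$phi2, swapped$phi1)
  # equal stand-alone values imply equal shares
  sym <- data.frame(v_p1 = c(0, 3, 5), v_p2 = c(0, 3, 5), v_both = c(10, 8, 5))
  psym <- shapley_values(sym)
  expect_identical(psym$phi1, psym$phi2)
  # dummy: v_p2 = 0 and v_both = v_p1 gives player 2 nothing
  dummy <- shapley_values(data.frame(v_p1 = 7, v_p2 = 0, v_both = 7))
  expect_identical(dummy$phi2, 0)
  expect_error(shapley_values(data.frame(v_p1 = 11, v_p2 = 0, v_both = 10)),
               "monotone")
})

test_that("Shapley ratios reproduce the three contribution benchmarks", {
  expect_equal(shapley_ratio(trial_spec("additive", 2, 3, 5, 10)), 0.5)
  expect_equal(shapley_ratio(trial_spec("additive", 6, 1, 5, 10)), 1)
  expect_equal(shapley_ratio(trial_spec("disjunctive", 1, 6, 5, 10)), 0)
  expect_equal(shapley_ratio(trial_spec("simple", 4, 4, NA, 8)), 0.5)
  # simple-criterion ratio equals relative performance
  expect_equal(shapley_ratio(trial_spec("simple", 2, 6, NA, 8)), 0.25)
  # goal missed: no value to divide
  expect_error(shapley_ratio(trial_spec("additive", 1, 1, 5, 10)), "zero total")
})

test_that("contribution categories partition the full performance grid", {
  for (crit in c("additive", "disjunctive")) {
    for (thr in c(3, 5, 8)) {
      grid <- expand.grid(p1 = 0:10, p2 = 0:10)
      tr <- trial_spec(crit, grid$p1, grid$p2, thr, 10)
      rewarded <- joint_outcome(tr) > 0
      tr <- tr[rewarded, , drop = FALSE]
      cat_ <- contribution_category(tr)
      expect_false(anyNA(cat_))
      ratio <- shapley_ratio(tr)
      # category reconstructs the colored-region map exactly
      expect_identical(as.character(cat_),
                       ifelse(ratio == 1, "player1_only",
                       ifelse(ratio == 0, "player2_only", "both")))
      # swapping players mirrors the categories
      swapped <- contribution_category(
        trial_spec(crit, tr$p2, tr$p1, thr, 10))
      map <- c(player1_only = "player2_only", both = "both",
               player2_only = "player1_only")
      expect_identical(as.character(swapped), unname(map[as.character(cat_)]))
    }
  }
  # simple trials are always "both"
  expect_true(all(contribution_category(
    trial_spec("simple", 0:5, 5:0 + 1, NA, 10)) == "both"))
})
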