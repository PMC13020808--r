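unbiased_agent <- function(w = 1, b0 = 0, svo_z = 0, b_svo = 0,
                           b_contrib = 0, dw = 0) {
  list(participant_id = "P001", svo_z = svo_z, b0 = b0, b_svo = b_svo,
       w_perf_other = w, dw_self = dw, b_contrib = b_contrib,
       phi_prec = 30, zoi = 0.1, coi = 0.5)
}

test_that("latent mean reduces to identities in the degenerate cases", {
  tr <- trial_spec("additive", c(2, 6, 1), c(3, 1, 6), 5, 10,
                   condition = "SforS")
  # no bias, full performance weight: mu = relative performance
  expect_equal(agent_target_ratio(unbiased_agent(w = 1), tr),
               relative_performance(tr$p1, tr$p2))
  # equal performance: mu = 0.5 whatever the weight
  sym <- trial_spec("additive", 3, 3, 5, 10, condition = "SforS")
  expect_equal(agent_target_ratio(unbiased_agent(w = 0.3), sym), 0.5)
  # bias gated by recipient: no shift in OforO
  biased <- unbiased_agent(w = 0.6, b0 = 0.8)
  oo <- trial_spec("additive", c(2, 6), c(3, 1), 5, 10, condition = "OforO")
  ss <- trial_spec("additive", c(2, 6), c(3, 1), 5, 10, condition = "SforS")
  expect_equal(agent_target_ratio(biased, oo),
               agent_target_ratio(unbiased_agent(w = 0.6), oo))
  expect_true(all(agent_target_ratio(biased, ss) >
                    agent_target_ratio(unbiased_agent(w = 0.6), ss)))
  # source gating flips which conditions carry the bias
  os <- trial_spec("additive", 2, 3, 5, 10, condition = "OforS")
  unb <- agent_target_ratio(unbiased_agent(w = 0.6), os)  # 0.6*0.4 + 0.2
  expect_gt(agent_target_ratio(biased, os, gate = "recipient"), unb)
  expect_equal(agent_target_ratio(biased, os, gate = "source"), unb)
})

test_that("sampled allocations conserve the pot and match the boundary rate", {
  ag <- unbiased_agent(w = 0.6, b0 = 0.3)
  tr <- trial_spec("additive", rep(c(2, 4, 6), 400), rep(c(3, 4, 1), 400),
                   5, 10, condition = "SforS")
  rec <- sample_allocation(ag, tr, seed = 5)
  expect_equal(rec$allocation_p1 + rec$allocation_p2, rep(10, nrow(rec)))
  # slider granularity respected
  expect_true(all(abs(rec$allocation_p1 / 0.1 -
                        round(rec$allocation_p1 / 0.1)) < 1e-9))
  # boundary frequency ~ zoi within 3 binomial SEs
  n <- nrow(rec)
  p_hat <- mean(rec$relative_allocation %in% c(0, 1))
  # rounding can push near-boundary beta draws onto the boundary, so the
  # empirical rate sits slightly above zoi; allow 3 SE around it
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(p_hat - 0.1), 3 * se + 0.02)
})

test_that("precision governs dispersion around the latent mean", {
  tr <- trial_spec("additive", 2, 3, 5, 10, condition = "SforS")
  tight <- unbiased_agent(w = 0.8)
  tight$phi_prec <- 5000; tight$zoi <- 0
  rec <- sample_allocation(tight, tr[rep(1, 500), ], seed = 3)
  expect_lt(sd(rec$relative_allocation), 0.02)
  expect_equal(mean(rec$relative_allocation),
               agent_target_ratio(tight, tr), tolerance = 0.01)
})

test_that("unbiased cohorts allocate 0.5 on average in every condition", {
  co <- small_cohort("null", n = 12, seed = 9, population = null_population())
  tab <- analysis_table(co)
  cs <- condition_summary(tab)
  expect_true(all(abs(cs$mean - 0.5) < 3 * cs$se + 0.01))
  # grand self-relevant mean within Monte-Carlo error of 0.5
  expect_equal(mean(tab$relative_allocation[tab$condition == "SforS"]), 0.5,
               tolerance = 0.01)
})

test_that("raising the baseline bias raises the SforS-OforO gap", {
  lay <- experiment_layout("exp2")
  st <- generate_stimulus_list(lay, seed = 4)
  gap <- vapply(c(0, 0.2, 0.5), function(b0) {
    co <- simulate_cohort(8, agent_population(b0_mean = b0, b0_sd = 0,
                                              b_svo_mean = 0, b_svo_sd = 0),
                          lay, seed = 31, stimuli = st)
    r <- co$records
    mean(r$relative_allocation[r$condition == "SforS"]) -
      mean(r$relative_allocation[r$condition == "OforO"])
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})

test_that("cohort bookkeeping: ground truth, miss flags, size guards", {
  co <- small_cohort()
  expect_s3_class(co, "alloc_cohort")
  expect_equal(nrow(co$agents), 12)
  expect_equal(nrow(co$records),
               12 * sum(!co$trials$loss))
  expect_lt(mean(co$records$miss), 0.03)
  expect_error(simulate_cohort(1, agent_population()), "at least 2")
})
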