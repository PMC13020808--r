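test_that("relative measures obey the complement identity", {
  expect_equal(relative_allocation(10, 0), 1)
  expect_equal(relative_allocation(5, 5), 0.5)
  expect_equal(relative_allocation(3, 7), 0.3)
  expect_equal(relative_performance(2, 3), 0.4)
  expect_equal(relative_performance(4, 4), 0.5)
  set.seed(1)
  a <- sample(0:20, 50, replace = TRUE)
  b <- sample(0:20, 50, replace = TRUE)
  keep <- a + b > 0
  expect_equal(relative_performance(a[keep], b[keep]) +
                 relative_performance(b[keep], a[keep]),
               rep(1, sum(keep)))
  expect_equal(relative_allocation(a[keep] + 0.5, b[keep]) +
                 relative_allocation(b[keep], a[keep] + 0.5),
               rep(1, sum(keep)))
  expect_error(relative_allocation(0, 0), "zero total")
  expect_error(relative_allocation(-1, 2), "non-negative")
  expect_warning(relative_performance(0, 0), "zero total")
})

test_that("self-allocation bias is the matched condition difference", {
  rec <- data.frame(
    participant_id = "P001",
    stimulus_id = rep(c("s1", "s2"), 2),
    condition = rep(c("SforS", "OforO"), each = 2),
    contribution_category = "both",
    relative_performance = 0.4,
    relative_allocation = c(0.7, 0.55, 0.5, 0.55),
    stringsAsFactors = FALSE
  )
  b <- self_allocation_bias(rec)
  expect_equal(nrow(b), 2)
  expect_equal(b$bias[b$stimulus_id == "s1"], 0.2)
  expect_equal(b$bias[b$stimulus_id == "s2"], 0)
  expect_equal(attr(b, "n_excluded"), 0)
  # unmatched stimuli are excluded and counted
  rec2 <- rbind(rec, data.frame(participant_id = "P001", stimulus_id = "s3",
                                condition = "SforS",
                                contribution_category = "both",
                                relative_performance = 0.4,
                                relative_allocation = 0.9))
  b2 <- self_allocation_bias(rec2)
  expect_equal(nrow(b2), 2)
  expect_equal(attr(b2, "n_excluded"), 1)
  expect_error(self_allocation_bias(rec[rec$condition == "SforS", ]),
               "absent")
})

test_that("bias table row count follows exact bookkeeping", {
  co <- small_cohort()
  b <- bias_table(co)
  rec <- co$records[!co$records$miss, ]
  matched <- sum(vapply(split(rec, rec$participant_id), function(d) {
    length(intersect(d$stimulus_id[d$condition == "SforS"],
                     d$stimulus_id[d$condition == "OforO"]))
  }, numeric(1)))
  expect_equal(nrow(b), matched)
  expect_true(all(b$bias >= -1 & b$bias <= 1))
  expect_equal(b$bias01, (b$bias + 1) / 2)
})

test_that("Experiment-3 contrasts expose recipient and source differences", {
  co <- .fixture_env$exp3 <- .fixture_env$exp3 %||%
    simulate_cohort(6, agent_population(), experiment_layout("exp3"),
                    seed = 15)
  rec <- co$records[!co$records$miss, ]
  br <- self_allocation_bias(rec, contrast = "recipient")
  bs <- self_allocation_bias(rec, contrast = "source")
  expect_setequal(unique(br$pairing), c("SforS-SforO", "OforS-OforO"))
  expect_setequal(unique(bs$pairing), c("SforS-OforS", "SforO-OforO"))
  # recipient-gated generator: recipient bias positive, source bias ~ 0
  expect_gt(mean(br$bias), 0.02)
  expect_lt(abs(mean(bs$bias)), 0.02)
})

test_that("SVO angle scoring matches the slider-measure convention", {
  items <- svo_items()
  expect_equal(nrow(items), 54)
  expect_setequal(unique(items$item), 1:6)
  # perfect midpoint responder: mean_other = 50 gives 0 degrees
  # item choices engineered from the instrument's payoffs
  mid <- svo_angle(c(5, 9, 9, 9, 1, 1))
  expect_equal(mid$mean_other, 50)
  expect_equal(mid$angle, 0)
  # equal offsets above 50 give 45 degrees
  alt <- svo_angle(c(1, 9, 9, 1, 5, 9))
  expect_equal(alt$angle, 45, tolerance = 1e-6)
  # own-payoff maximizer lands in the individualistic band
  self_max <- vapply(1:6, function(it) {
    opts <- items[items$item == it, ]
    opts$option[which.max(opts$self)]
  }, numeric(1))
  res <- svo_angle(self_max)
  expect_equal(as.character(res$category), "individualistic")
  expect_true(res$angle > -12.04 && res$angle < 22.45)
  # invariance to affine rescaling of payoffs about 50
  scaled <- items
  scaled$self <- 50 + 2 * (scaled$self - 50)
  scaled$other <- 50 + 2 * (scaled$other - 50)
  expect_equal(svo_angle(self_max, items = scaled)$angle, res$angle)
  expect_error(svo_angle(c(1, 2, 3)), "six")
})

test_that("condition summaries aggregate participant-first", {
  co <- small_cohort()
  rec <- co$records
  cs <- condition_summary(rec)
  expect_equal(nrow(cs), 6)
  # single participant: group mean equals that participant's mean
  one <- rec[rec$participant_id == rec$participant_id[1], ]
  cs1 <- condition_summary(one)
  manual <- tapply(one$relative_allocation,
                   paste(one$condition, one$criterion), mean)
  expect_equal(cs1$mean,
               as.vector(manual[paste(cs1$condition, cs1$criterion)]))
  # invariant to trial order
  shuf <- rec[sample(nrow(rec)), ]
  cs2 <- condition_summary(shuf)
  expect_equal(cs2[order(cs2$condition, cs2$criterion), ],
               cs[order(cs$condition, cs$criterion), ],
               ignore_attr = TRUE)
})
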