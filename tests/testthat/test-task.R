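test_that("number lists hold 20 primes, 10 even and 10 odd non-primes", {
  for (seed in c(1, 99, 2024)) {
    nl <- generate_number_list(seed)
    expect_equal(nrow(nl), 40)
    expect_equal(unname(table(nl$label)[c("prime", "even_nonprime",
                                          "odd_nonprime")]),
                 c(20L, 10L, 10L), ignore_attr = TRUE)
    expect_true(all(nl$number >= 1 & nl$number <= 1000))
    expect_false(anyDuplicated(nl$number) > 0)
    # labels verified by independent trial division
    expect_identical(is_prime_naive(nl$number), nl$label == "prime")
    expect_true(all(nl$number[nl$label == "even_nonprime"] %% 2 == 0))
    expect_true(all(nl$number[nl$label == "odd_nonprime"] %% 2 == 1))
  }
  expect_identical(generate_number_list(5), generate_number_list(5))
})

test_that("layouts carry the published trial and session counts", {
  e1 <- experiment_layout("exp1")
  e2 <- experiment_layout("exp2")
  e3 <- experiment_layout("exp3")
  expect_equal(e1$n_trials, 384)
  expect_equal(e1$n_sessions, 4)
  expect_equal(e2$n_trials, 216)
  expect_equal(e2$n_sessions, 6)
  expect_setequal(e2$conditions, c("SforS", "OforO"))
  expect_setequal(e3$conditions, c("SforS", "SforO", "OforS", "OforO"))
  # every cell gets the same count; exp3 mirrors exp2 cell sizes
  expect_equal(e3$trials_per_cell, e2$trials_per_cell)
})

test_that("stimulus lists are symmetric, matched and criterion-consistent", {
  for (exp_name in c("exp1", "exp2", "exp3")) {
    lay <- experiment_layout(exp_name)
    st <- generate_stimulus_list(lay, seed = 21)
    expect_equal(nrow(st), lay$n_trials)
    reward <- st[!st$loss, ]
    # exact player symmetry of the reward trials
    expect_equal(mean(relative_performance(reward$p1, reward$p2)), 0.5)
    pair_key <- function(d) sort(paste(d$p1, d$p2, d$criterion))
    swapped <- reward
    swapped[c("p1", "p2")] <- reward[c("p2", "p1")]
    expect_identical(pair_key(reward), pair_key(swapped))
    # reward trials always meet their criterion
    expect_true(all(joint_outcome(reward) > 0))
    # matched stimuli identical across conditions
    base <- st[st$condition == lay$conditions[1],
               c("stimulus_id", "p1", "p2", "threshold", "pot")]
    for (cond in lay$conditions[-1]) {
      other <- st[st$condition == cond,
                  c("stimulus_id", "p1", "p2", "threshold", "pot")]
      m <- merge(base, other, by = "stimulus_id")
      expect_identical(m$p1.x, m$p1.y)
      expect_identical(m$threshold.x, m$threshold.y)
      expect_identical(m$pot.x, m$pot.y)
    }
    # all three contribution structures represented in threshold criteria
    thr <- reward[reward$criterion != "simple", ]
    expect_setequal(as.character(unique(contribution_category(thr))),
                    c("player1_only", "both", "player2_only"))
    # loss fraction within one trial of the configured 20% per criterion cell
    per_cell <- tapply(st$loss, paste(st$condition, st$criterion), sum)
    expect_true(all(abs(per_cell - 0.2 * lay$trials_per_cell) <= 1))
  }
})

test_that("stimulus generation is deterministic and CSV round-trip stable", {
  lay <- experiment_layout("exp2")
  a <- generate_stimulus_list(lay, seed = 77)
  b <- generate_stimulus_list(lay, seed = 77)
  expect_identical(a, b)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trials(a, path)
  expect_equal(read_trials(path), a, tolerance = 1e-12)
})

test_that("block assignment alternates all cells within every session", {
  lay <- experiment_layout("exp2")
  st <- generate_stimulus_list(lay, seed = 3)
  ord <- assign_blocks(lay, st, seed = 8)
  expect_equal(nrow(ord), nrow(st))
  counts <- table(ord$session, paste(ord$condition, ord$criterion))
  expect_true(all(counts == lay$trials_per_cell / lay$n_sessions))
  # instruction labels follow the criteria
  expect_identical(unique(ord$block_label[ord$criterion == "simple"]),
                   "no goal")
  expect_identical(unique(ord$block_label[ord$criterion == "additive"]),
                   "mutual reach")
  expect_identical(unique(ord$block_label[ord$criterion == "disjunctive"]),
                   "one reaches")
  # trials within a block share one cell
  cells <- tapply(paste(ord$condition, ord$criterion), ord$block,
                  function(x) length(unique(x)))
  expect_true(all(cells == 1))
  # reordering with another seed permutes but preserves cell counts
  ord2 <- assign_blocks(lay, st, seed = 9)
  expect_false(identical(ord$trial_id, ord2$trial_id))
  expect_equal(table(ord2$session, paste(ord2$condition, ord2$criterion)),
               counts)
})
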