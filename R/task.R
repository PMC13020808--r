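# Task-design generators: prime-judgement number lists, experiment
# layouts, symmetric stimulus lists, and session/block assignment.

sieve_primes <- function(n) {
  is_p <- rep(TRUE, n)
  is_p[1] <- FALSE
  for (i in 2:floor(sqrt(n))) {
    if (is_p[i]) is_p[seq(i * i, n, by = i)] <- FALSE
  }
  which(is_p)
}

#' Generate a 40-number list for the prime-judgement performance task
#'
#' Each list holds 40 distinct numbers in 1..1000: 20 primes, 10 even
#' non-primes and 10 odd non-primes (1 counts as an odd non-prime),
#' shuffled. Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @return `data.frame` with columns `number` and `label`
#'   (`prime` / `even_nonprime` / `odd_nonprime`).
#' @export
generate_number_list <- function(seed = 1L) {
  local_seed(seed, {
    primes <- sieve_primes(1000)
    evens <- setdiff(seq(2, 1000, by = 2), primes)
    odds <- setdiff(seq(1, 999, by = 2), primes)
    picked <- data.frame(
      number = c(sample(primes, 20), sample(evens, 10), sample(odds, 10)),
      label = rep(c("prime", "even_nonprime", "odd_nonprime"),
                  times = c(20, 10, 10)),
      stringsAsFactors = FALSE
    )
    out <- picked[sample.int(40), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Experiment layout descriptions
#'
#' Returns the session/trial structure of the three experiment layouts:
#' `exp1` (384 trials in 4 sessions, conditions SforS/OforO, 8 s decision
#' limit), `exp2` (216 trials in 6 sessions, SforS/OforO, 6 s limit) and
#' `exp3` (crossed source x recipient conditions SforS/SforO/OforS/OforO;
#' trial counts mirror exp2 cell sizes across the 4 conditions). Every
#' (condition x criterion) cell receives an equal trial count.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @return list of class `"experiment_layout"`.
#' @export
experiment_layout <- function(experiment = c("exp2", "exp1", "exp3")) {
  experiment <- match.arg(experiment)
  conds <- switch(experiment,
                  exp1 = c("SforS", "OforO"),
                  exp2 = c("SforS", "OforO"),
                  exp3 = condition_levels)
  n_sessions <- switch(experiment, exp1 = 4L, exp2 = 6L, exp3 = 6L)
  per_cell <- switch(experiment, exp1 = 64L, exp2 = 36L, exp3 = 36L)
  n_cells <- length(conds) * length(criterion_levels)
  out <- list(
    experiment = experiment,
    conditions = conds,
    criteria = criterion_levels,
    n_sessions = n_sessions,
    trials_per_cell = per_cell,
    n_trials = per_cell * n_cells,
    trials_per_session = per_cell * n_cells %/% n_sessions,
    decision_time_limit = switch(experiment, exp1 = 8, exp2 = 6, exp3 = 6)
  )
  class(out) <- "experiment_layout"
  out
}

#' @export
print.experiment_layout <- function(x, ...) {
  cat(sprintf("<experiment_layout %s>: %d trials, %d sessions, %d per cell\n",
              x$experiment, x$n_trials, x$n_sessions, x$trials_per_cell))
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  criteria:  ", paste(x$criteria, collapse = ", "), "\n")
  invisible(x)
}

#' Default performance configuration for stimulus generation
#'
#' Parameters governing the parametric manipulation of displayed
#' performance: the discrete grid of per-player correct-response counts,
#' the threshold grid, pot values, the simple-criterion unit value per
#' correct response, the loss-trial fraction and the slider granularity.
#'
#' @param performance_grid integer grid of per-player counts.
#' @param thresholds integer grid of thresholds for additive/disjunctive
#'   trials.
#' @param pots pot values in yen for threshold criteria.
#' @param unit_value yen per correct response for simple trials.
#' @param loss_fraction fraction of trials flagged as loss trials
#'   (generated, excluded from analysis).
#' @param granularity slider step in yen.
#' @return a list of settings.
#' @export
perf_config <- function(performance_grid = 1:8, thresholds = 3:8,
                        pots = c(6, 8, 10, 12), unit_value = 1,
                        loss_fraction = 0.2, granularity = 0.1) {
  stopifnot(all(performance_grid >= 0), all(thresholds >= 0),
            all(pots > 0), unit_value > 0,
            loss_fraction >= 0, loss_fraction < 1, granularity > 0)
  if (max(performance_grid) * 2 < min(thresholds)) {
    stop("infeasible config: no performance pair can reach the smallest ",
         "threshold")
  }
  list(performance_grid = performance_grid, thresholds = thresholds,
       pots = pots, unit_value = unit_value,
       loss_fraction = loss_fraction, granularity = granularity)
}

# Draw one (p1, p2, threshold) triple realising `category` under
# `criterion`; reward trials always meet their criterion.
draw_performance <- function(criterion, category, config) {
  grid <- config$performance_grid
  repeat {
    p1 <- sample(grid, 1)
    p2 <- sample(grid, 1)
    if (criterion == "simple") {
      if (p1 + p2 > 0) return(c(p1, p2, NA))
      next
    }
    thr <- config$thresholds
    ok <- switch(criterion,
      additive = switch(category,
        both = thr[thr <= p1 + p2 & thr > pmax(p1, p2)],
        player1_only = thr[thr <= p1 & thr > p2],
        player2_only = thr[thr <= p2 & thr > p1]),
      disjunctive = switch(category,
        both = thr[thr <= pmin(p1, p2)],
        player1_only = thr[thr <= p1 & thr > p2],
        player2_only = thr[thr <= p2 & thr > p1]))
    if (length(ok)) return(c(p1, p2, if (length(ok) == 1) ok else sample(ok, 1)))
  }
}

#' Generate a symmetric stimulus list for an experiment layout
#'
#' Builds the per-criterion stimulus sets shared across all
#' self-relevance conditions (identical `stimulus_id`, performances,
#' threshold and pot), mirrored between players so the multiset of
#' (p1, p2) pairs is invariant under swapping players — hence the mean
#' relative performance of player 1 over reward trials is exactly 0.5.
#' Reward trials always meet their criterion and, for threshold
#' criteria, cycle through the three contribution structures. A fixed
#' fraction of mirrored stimulus pairs is flagged as loss trials
#' (negative pot); these are generated but excluded from analysis.
#'
#' @param layout an [experiment_layout()].
#' @param config a [perf_config()].
#' @param seed integer seed.
#' @return trial `data.frame` (one row per trial, all conditions) with
#'   columns `trial_id`, `stimulus_id`, `condition`, `criterion`, `p1`,
#'   `p2`, `threshold`, `pot`, `loss`.
#' @export
generate_stimulus_list <- function(layout, config = perf_config(), seed = 1L) {
  stopifnot(inherits(layout, "experiment_layout"))
  n_stim <- layout$trials_per_cell          # stimuli per criterion
  if (n_stim %% 2L != 0L) stop("trials per cell must be even for mirroring")
  n_base <- n_stim %/% 2L
  local_seed(seed, {
    per_crit <- lapply(layout$criteria, function(crit) {
      cats <- if (crit == "simple") rep("both", n_base)
              else rep_len(c("both", "player1_only", "player2_only"), n_base)
      base <- t(vapply(cats, function(ca) draw_performance(crit, ca, config),
                       numeric(3)))
      pot <- if (crit == "simple") {
        config$unit_value * (base[, 1] + base[, 2])
      } else sample(config$pots, n_base, replace = TRUE)
      df <- data.frame(criterion = crit,
                       p1 = c(base[, 1], base[, 2]),
                       p2 = c(base[, 2], base[, 1]),
                       threshold = c(base[, 3], base[, 3]),
                       pot = c(pot, pot),
                       pair = rep(seq_len(n_base), 2L),
                       stringsAsFactors = FALSE)
      n_loss_pairs <- round(config$loss_fraction * n_base)
      if (n_loss_pairs > 0) {
        loss_pairs <- sample(n_base, n_loss_pairs)
        df$pot[df$pair %in% loss_pairs] <- -abs(df$pot[df$pair %in% loss_pairs])
      }
      df
    })
    stim <- do.call(rbind, per_crit)
    stim$stimulus_id <- sprintf("%s_s%03d", layout$experiment, seq_len(nrow(stim)))
    trials <- do.call(rbind, lapply(layout$conditions, function(cond) {
      d <- stim
      d$condition <- cond
      d
    }))
    trials$loss <- trials$pot < 0
    trials$trial_id <- sprintf("%s_t%04d", layout$experiment, seq_len(nrow(trials)))
    trials <- trials[, c("trial_id", "stimulus_id", "condition", "criterion",
                         "p1", "p2", "threshold", "pot", "loss")]
    rownames(trials) <- NULL
    validate_trials(trials)
    trials
  })
}

block_label <- function(criterion) {
  c(simple = "no goal", additive = "mutual reach",
    disjunctive = "one reaches")[criterion]
}

#' Order stimuli into sessions and alternating mini-blocks
#'
#' Distributes each (condition x criterion) cell evenly over sessions;
#' within a session the cells appear as mini-blocks in seeded random
#' order, each block tagged with its instruction label ("no goal",
#' "mutual reach", "one reaches") and condition. Cell counts are
#' invariant to the seed; only ordering changes.
#'
#' @param layout an [experiment_layout()].
#' @param stimuli trial table from [generate_stimulus_list()].
#' @param seed integer seed (e.g. a per-participant seed).
#' @return the trial table with added `session`, `block`,
#'   `block_label`, and `trial_in_session` columns, in presentation
#'   order.
#' @export
assign_blocks <- function(layout, stimuli, seed = 1L) {
  stopifnot(inherits(layout, "experiment_layout"))
  cells <- expand.grid(condition = layout$conditions,
                       criterion = layout$criteria,
                       stringsAsFactors = FALSE)
  per_session <- layout$trials_per_cell / layout$n_sessions
  if (per_session != round(per_session)) {
    stop("trial count per cell (", layout$trials_per_cell,
         ") is not divisible across ", layout$n_sessions, " sessions")
  }
  local_seed(seed, {
    pieces <- vector("list", layout$n_sessions * nrow(cells))
    k <- 0L
    # split each cell's stimuli randomly into equal per-session chunks
    chunks <- lapply(seq_len(nrow(cells)), function(i) {
      rows <- which(stimuli$condition == cells$condition[i] &
                    stimuli$criterion == cells$criterion[i])
      if (length(rows) != layout$trials_per_cell) {
        stop("stimuli do not cover cell ", cells$condition[i], " x ",
             cells$criterion[i])
      }
      split(sample(rows), rep(seq_len(layout$n_sessions), each = per_session))
    })
    for (s in seq_len(layout$n_sessions)) {
      cell_order <- sample(nrow(cells))
      for (ci in cell_order) {
        k <- k + 1L
        blk <- stimuli[chunks[[ci]][[s]], , drop = FALSE]
        blk$session <- s
        blk$block <- k
        blk$block_label <- unname(block_label(blk$criterion))
        pieces[[k]] <- blk
      }
    }
    out <- do.call(rbind, pieces)
    out$trial_in_session <- stats::ave(seq_len(nrow(out)), out$session,
                                       FUN = seq_along)
    rownames(out) <- NULL
    out
  })
}

#' Read/write trial tables as CSV
#'
#' Round-trip stable writers/readers for trial tables with the
#' documented columns (`trial_id`, `stimulus_id`, `condition`,
#' `criterion`, `p1`, `p2`, `threshold`, `pot`, plus any derived
#' columns present).
#'
#' @param trials a trial table.
#' @param path file path.
#' @return `read_trials()` returns the trial table; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(tr)
  tr
}
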