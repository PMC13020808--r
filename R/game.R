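#' Construct a table of allocation-task trials
#'
#' A trial records the collective task criterion, both players'
#' performance (correct-response counts), the threshold (ignored for the
#' simple criterion), the pot to divide, and the self-relevance condition.
#' All downstream functions (`joint_outcome()`, `shapley_ratio()`,
#' cohort simulation, model fitting) consume this table.
#'
#' Conditions follow the crossed source/recipient naming: `SforS`
#' (self performance, self recipient; the self-relevant condition),
#' `OforO` (self-irrelevant), plus `SforO` and `OforS` for layouts that
#' decouple whose performance generated the outcome from who receives it.
#'
#' @param criterion character, one of `"simple"`, `"additive"`,
#'   `"disjunctive"` (recycled).
#' @param p1,p2 non-negative integer correct-response counts.
#' @param threshold non-negative integer; `NA` allowed (and ignored) for
#'   simple trials.
#' @param pot pot in yen; positive for reward trials, negative for loss
#'   trials (flagged and excluded from game construction).
#' @param condition one of `"SforS"`, `"SforO"`, `"OforS"`, `"OforO"`.
#' @param trial_id,stimulus_id identifiers; `stimulus_id` is shared by
#'   matched trials across conditions.
#' @return a `data.frame` with one row per trial and a `loss` flag
#'   (`pot < 0`).
#' @export
#' @examples
#' trial_spec("additive", p1 = 2, p2 = 3, threshold = 5, pot = 10)
trial_spec <- function(criterion, p1, p2, threshold = NA_integer_, pot,
                       condition = "SforS",
                       trial_id = NULL, stimulus_id = NULL) {
  n <- max(length(criterion), length(p1), length(p2), length(threshold),
           length(pot), length(condition))
  tr <- data.frame(
    trial_id = if (is.null(trial_id)) seq_len(n) else trial_id,
    stimulus_id = if (is.null(stimulus_id)) seq_len(n) else stimulus_id,
    condition = rep_len(as.character(condition), n),
    criterion = rep_len(as.character(criterion), n),
    p1 = rep_len(p1, n), p2 = rep_len(p2, n),
    threshold = rep_len(threshold, n),
    pot = rep_len(pot, n),
    stringsAsFactors = FALSE
  )
  tr$loss <- tr$pot < 0
  validate_trials(tr)
  tr
}

criterion_levels <- c("simple", "additive", "disjunctive")
condition_levels <- c("SforS", "SforO", "OforS", "OforO")

validate_trials <- function(trials) {
  req <- c("criterion", "p1", "p2", "threshold", "pot")
  miss <- setdiff(req, names(trials))
  if (length(miss)) {
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(trials$criterion %in% criterion_levels)) {
    stop("criterion must be one of: ", paste(criterion_levels, collapse = ", "))
  }
  if ("condition" %in% names(trials) &&
      !all(trials$condition %in% condition_levels)) {
    stop("condition must be one of: ", paste(condition_levels, collapse = ", "))
  }
  if (any(trials$p1 < 0 | trials$p2 < 0, na.rm = TRUE) ||
      any(trials$p1 != round(trials$p1) | trials$p2 != round(trials$p2))) {
    stop("performances must be non-negative integers")
  }
  thr <- trials$threshold[trials$criterion != "simple"]
  if (any(!is.finite(thr)) || any(thr < 0)) {
    stop("additive/disjunctive trials need a non-negative threshold")
  }
  if (any(trials$pot == 0)) stop("pot must be non-zero (negative = loss trial)")
  invisible(trials)
}

#' Joint outcome of a trial under its collective task criterion
#'
#' The pot is awarded when the criterion is met: always for the simple
#' criterion (the pot itself scales with total performance), when the
#' summed performance reaches the threshold for the additive criterion,
#' and when the best single performance reaches it for the disjunctive
#' criterion. Threshold comparison is inclusive (`>=`).
#'
#' @param trials a trial table (see [trial_spec()]).
#' @return numeric vector of joint outcomes in yen (0 when the goal is
#'   missed). Loss trials yield `NA`.
#' @export
#' @examples
#' joint_outcome(trial_spec("additive", 2, 3, 5, 10))  # 10
#' joint_outcome(trial_spec("additive", 2, 2, 5, 10))  # 0
joint_outcome <- function(trials) {
  validate_trials(trials)
  met <- ifelse(trials$criterion == "simple", TRUE,
         ifelse(trials$criterion == "additive",
                trials$p1 + trials$p2 >= trials$threshold,
                pmax(trials$p1, trials$p2) >= trials$threshold))
  out <- ifelse(met, trials$pot, 0)
  out[trials$pot < 0] <- NA_real_
  out
}

#' Characteristic function of a trial's two-player coalition game
#'
#' Computes the value every coalition would earn on its own under the
#' trial's criterion: for threshold criteria a coalition wins the full
#' pot iff its members' performances meet the criterion by themselves;
#' for the simple criterion value is proportional to the coalition's
#' summed correct responses. `v_empty` is 0 by convention.
#'
#' @param trials a trial table of reward trials.
#' @return `data.frame` with columns `v_empty`, `v_p1`, `v_p2`, `v_both`
#'   (yen), class `"coalition_game"`.
#' @export
#' @examples
#' characteristic_function(trial_spec("additive", 2, 3, 5, 10))
characteristic_function <- function(trials) {
  validate_trials(trials)
  if (any(trials$pot < 0)) {
    stop("coalition game undefined for loss trials (pot < 0)")
  }
  if (any(trials$criterion == "simple" & trials$p1 + trials$p2 == 0)) {
    stop("simple-criterion game undefined when both performances are 0")
  }
  pot_c <- to_cents(trials$pot)
  val <- function(p_self, p_other) {
    ifelse(trials$criterion == "simple",
           round(pot_c * p_self / (trials$p1 + trials$p2)),
           ifelse(trials$criterion == "additive",
                  ifelse(p_self >= trials$threshold, pot_c, 0),
                  ifelse(p_self >= trials$threshold, pot_c, 0)))
  }
  v_both <- ifelse(trials$criterion == "simple", pot_c,
            ifelse(trials$criterion == "additive",
                   ifelse(trials$p1 + trials$p2 >= trials$threshold, pot_c, 0),
                   ifelse(pmax(trials$p1, trials$p2) >= trials$threshold,
                          pot_c, 0)))
  g <- data.frame(v_empty = 0,
                  v_p1 = from_cents(val(trials$p1, trials$p2)),
                  v_p2 = from_cents(val(trials$p2, trials$p1)),
                  v_both = from_cents(v_both))
  class(g) <- c("coalition_game", class(g))
  validate_game(g)
  g
}

validate_game <- function(game) {
  stopifnot(all(c("v_p1", "v_p2", "v_both") %in% names(game)))
  if (!is.null(game$v_empty) && any(game$v_empty != 0)) {
    stop("v_empty must be 0")
  }
  bad <- game$v_p1 < 0 | game$v_p2 < 0 |
    game$v_p1 > game$v_both | game$v_p2 > game$v_both
  if (any(bad)) {
    stop("non-monotone coalition game: need 0 <= v_p1, v_p2 <= v_both")
  }
  invisible(game)
}

#' Shapley values of a two-player coalition game
#'
#' Each player's Shapley value is the average of their marginal
#' contribution over the two orders in which the coalition can form:
#' `phi1 = v_p1/2 + (v_both - v_p2)/2`, and symmetrically for player 2.
#' The division is efficient (`phi1 + phi2 = v_both`), symmetric, and
#' gives dummy players zero.
#'
#' @param game a `coalition_game` (from [characteristic_function()]) or
#'   any data frame with columns `v_p1`, `v_p2`, `v_both`.
#' @return `data.frame` with columns `phi1`, `phi2` in yen.
#' @export
#' @examples
#' shapley_values(data.frame(v_p1 = 0, v_p2 = 0, v_both = 10))   # 5, 5
#' shapley_values(data.frame(v_p1 = 10, v_p2 = 0, v_both = 10))  # 10, 0
shapley_values <- function(game) {
  validate_game(game)
  data.frame(phi1 = 0.5 * game$v_p1 + 0.5 * (game$v_both - game$v_p2),
             phi2 = 0.5 * game$v_p2 + 0.5 * (game$v_both - game$v_p1))
}

#' Shapley allocation ratio for player 1
#'
#' The share of the joint outcome the Shapley benchmark assigns to
#' player 1, `phi1 / (phi1 + phi2)`. For additive/disjunctive reward
#' trials this lies in `{0, 0.5, 1}`; for simple trials it equals
#' player 1's relative performance.
#'
#' @param trials a trial table of reward trials with positive joint
#'   outcome.
#' @return numeric vector of ratios in `[0, 1]`.
#' @export
#' @examples
#' shapley_ratio(trial_spec("additive", 2, 3, 5, 10))     # 0.5
#' shapley_ratio(trial_spec("disjunctive", 1, 6, 5, 10))  # 0
shapley_ratio <- function(trials) {
  phi <- shapley_values(characteristic_function(trials))
  tot <- phi$phi1 + phi$phi2
  if (any(tot <= 0)) {
    stop("Shapley ratio undefined: zero total value (goal not reached)")
  }
  phi$phi1 / tot
}

#' Contribution-structure category of a reward trial
#'
#' Classifies who was causally necessary for the reward: `player1_only`
#' (Shapley ratio 1), `both` (0.5) or `player2_only` (0). All simple
#' trials are `both` because no threshold gates the reward.
#'
#' @param trials a trial table of reward trials with positive joint
#'   outcome.
#' @return factor with levels `player1_only`, `both`, `player2_only`.
#' @export
#' @examples
#' contribution_category(trial_spec("disjunctive", 6, 3, 5, 10))
contribution_category <- function(trials) {
  validate_trials(trials)
  out <- rep(NA_character_, nrow(trials))
  simple <- trials$criterion == "simple"
  out[simple] <- "both"
  if (any(!simple)) {
    r <- shapley_ratio(trials[!simple, , drop = FALSE])
    cat_ <- ifelse(r == 1, "player1_only",
            ifelse(r == 0, "player2_only",
            ifelse(r == 0.5, "both", NA_character_)))
    if (anyNA(cat_)) {
      stop("internal inconsistency: threshold-game Shapley ratio outside ",
           "{0, 0.5, 1}")
    }
    out[!simple] <- cat_
  }
  factor(out, levels = c("player1_only", "both", "player2_only"))
}
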