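# Derived behavioral quantities: relative allocation/performance,
# trial-matched self-allocation bias, SVO slider scoring, and
# analysis-ready tables.

#' Relative allocation of player 1
#'
#' Player 1's share of the total allocated money, `a1 / (a1 + a2)`.
#'
#' @param a1,a2 non-negative allocations in yen with positive total.
#' @return fraction in `[0, 1]`.
#' @export
relative_allocation <- function(a1, a2) {
  if (any(a1 < 0 | a2 < 0)) stop("allocations must be non-negative")
  tot <- a1 + a2
  if (any(tot <= 0)) stop("relative allocation undefined for zero total")
  a1 / tot
}

#' Relative performance of player 1
#'
#' Player 1's share of the total correct responses, `p1 / (p1 + p2)`.
#' Satisfies the complement identity `f(p1, p2) + f(p2, p1) = 1`.
#'
#' @param p1,p2 non-negative correct-response counts.
#' @return fraction in `[0, 1]`; both-zero pairs yield `NA` and are
#'   flagged with a warning (such trials are excluded upstream).
#' @export
relative_performance <- function(p1, p2) {
  if (any(p1 < 0 | p2 < 0)) stop("performances must be non-negative")
  tot <- p1 + p2
  if (any(tot == 0)) {
    warning(sum(tot == 0), " trial(s) with zero total performance; NA returned")
  }
  ifelse(tot > 0, p1 / tot, NA_real_)
}

bias_contrasts <- list(
  classic = list(c(self = "SforS", other = "OforO")),
  recipient = list(c(self = "SforS", other = "SforO"),
                   c(self = "OforS", other = "OforO")),
  source = list(c(self = "SforS", other = "OforS"),
                c(self = "SforO", other = "OforO"))
)

#' Trial-matched self-allocation bias
#'
#' For every participant and matched stimulus (identical stimulus lists
#' across conditions make the matching exact and order-free), the bias
#' is the difference in relative allocation between a self-relevant and
#' the matched self-irrelevant trial. For the two-condition layouts the
#' `"classic"` contrast (SforS minus OforO) is the bias; for the
#' crossed layout the `"recipient"` (XforS minus XforO) and `"source"`
#' (SforX minus OforX) differences are exposed separately and labelled
#' — neither is privileged as "the" bias.
#'
#' @param records allocation records (e.g. `cohort$records`) with
#'   `participant_id`, `stimulus_id`, `condition`,
#'   `contribution_category` and `relative_allocation` columns; miss
#'   trials should be dropped first.
#' @param contrast `"classic"`, `"recipient"` or `"source"`.
#' @return `data.frame` of bias records (`participant_id`,
#'   `stimulus_id`, `pairing`, `contribution_category`,
#'   `relative_performance`, `bias` in `[-1, 1]`), with attribute
#'   `n_excluded` counting unmatched stimuli.
#' @export
self_allocation_bias <- function(records,
                                 contrast = c("classic", "recipient",
                                              "source")) {
  contrast <- match.arg(contrast)
  pairs <- bias_contrasts[[contrast]]
  out <- lapply(pairs, function(pr) {
    a <- records[records$condition == pr[["self"]], , drop = FALSE]
    b <- records[records$condition == pr[["other"]], , drop = FALSE]
    if (!nrow(a) || !nrow(b)) {
      stop("condition ", pr[["self"]], " or ", pr[["other"]],
           " absent from records")
    }
    m <- merge(
      a[, c("participant_id", "stimulus_id", "contribution_category",
            "relative_performance", "relative_allocation")],
      b[, c("participant_id", "stimulus_id", "relative_allocation")],
      by = c("participant_id", "stimulus_id"),
      suffixes = c("_self", "_other")
    )
    df <- data.frame(
      participant_id = m$participant_id,
      stimulus_id = m$stimulus_id,
      pairing = paste0(pr[["self"]], "-", pr[["other"]]),
      contribution_category = m$contribution_category,
      relative_performance = m$relative_performance,
      bias = m$relative_allocation_self - m$relative_allocation_other,
      stringsAsFactors = FALSE
    )
    attr(df, "n_excluded") <- (nrow(a) - nrow(m)) + (nrow(b) - nrow(m))
    df
  })
  n_excluded <- sum(vapply(out, attr, numeric(1), which = "n_excluded"))
  res <- do.call(rbind, out)
  res$contribution_category <- factor(res$contribution_category,
                                      c("player1_only", "both",
                                        "player2_only"))
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Payoff options of the six primary slider items
#'
#' The versioned plain-text fixture embedding the standard slider
#' instrument's six primary items, each offering nine (self, other)
#' payoff pairs.
#'
#' @return `data.frame` with columns `item`, `option`, `self`, `other`.
#' @export
svo_items <- function() {
  path <- system.file("extdata", "svo_slider_items.csv",
                      package = "allocbias", mustWork = TRUE)
  utils::read.csv(path)
}

#' Social value orientation angle from slider choices
#'
#' Averages the chosen self and other payoffs over the six primary
#' items and returns `atan2(mean_other - 50, mean_self - 50)` in
#' degrees. The two-argument arctangent handles `mean_self = 50`
#' exactly. Larger angles indicate more prosocial orientation. The
#' angle is invariant to rescaling all payoffs about 50 by a common
#' positive factor.
#'
#' @param choices integer vector of six chosen option indices (1..9),
#'   one per primary item in order.
#' @param items item payoff table, defaults to the embedded instrument.
#' @return list with `angle` (degrees), `mean_self`, `mean_other`, and
#'   `category` (`altruistic` / `prosocial` / `individualistic` /
#'   `competitive`).
#' @export
svo_angle <- function(choices, items = svo_items()) {
  if (length(choices) != 6L || any(choices < 1 | choices > 9) ||
      any(choices != round(choices))) {
    stop("choices must be six option indices in 1..9")
  }
  sel <- mapply(function(it, op) {
    row <- items[items$item == it & items$option == op, ]
    c(row$self, row$other)
  }, seq_len(6L), choices)
  mean_self <- mean(sel[1, ])
  mean_other <- mean(sel[2, ])
  angle <- atan2(mean_other - 50, mean_self - 50) * 180 / pi
  list(angle = angle, mean_self = mean_self, mean_other = mean_other,
       category = svo_category(angle))
}

#' @rdname svo_angle
#' @param angle angle in degrees.
#' @export
svo_category <- function(angle) {
  cut(angle, breaks = c(-Inf, -12.04, 22.45, 57.15, Inf),
      labels = c("competitive", "individualistic", "prosocial",
                 "altruistic"))
}

#' Per-condition descriptive summary of allocations
#'
#' Aggregates participant means per (condition x criterion) cell and
#' then averages across participants — the descriptive companion to
#' the model-based estimates (inference should come from the
#' hierarchical fits, not from these cell means).
#'
#' @param records allocation records.
#' @return `data.frame` with `condition`, `criterion`, `mean`, `se`
#'   (over participants) and `n_participants`.
#' @export
condition_summary <- function(records) {
  pm <- stats::aggregate(relative_allocation ~
                           participant_id + condition + criterion,
                         data = records, FUN = mean)
  agg <- stats::aggregate(relative_allocation ~ condition + criterion,
                          data = pm, FUN = function(x) {
                            c(mean = mean(x),
                              se = stats::sd(x) / sqrt(length(x)),
                              n = length(x))
                          })
  out <- cbind(agg[, c("condition", "criterion")],
               as.data.frame(agg$relative_allocation))
  names(out) <- c("condition", "criterion", "mean", "se", "n_participants")
  out$se[out$n_participants == 1] <- NA_real_
  out
}

#' Assemble the analysis-ready trial table from a cohort
#'
#' Drops miss trials, joins the cohort-standardized SVO angle, and adds
#' the model factors: `self_relevance` (reference `self_irrelevant`),
#' `criterion` (reference `simple`), and — for the crossed layout —
#' `recipient` and `source` factors (reference `other`).
#'
#' @param cohort an `alloc_cohort` (or a list with `records` and
#'   `agents`).
#' @return `data.frame` ready for [zoib()].
#' @export
analysis_table <- function(cohort) {
  d <- cohort$records
  d <- d[!d$miss, , drop = FALSE]
  d$svo_z <- cohort$agents$svo_z[match(d$participant_id,
                                       cohort$agents$participant_id)]
  d$self_relevance <- factor(
    ifelse(self_involved(d$condition, "recipient"),
           "self_relevant", "self_irrelevant"),
    levels = c("self_irrelevant", "self_relevant"))
  d$recipient <- factor(ifelse(self_involved(d$condition, "recipient"),
                               "self", "other"), levels = c("other", "self"))
  d$source <- factor(ifelse(self_involved(d$condition, "source"),
                            "self", "other"), levels = c("other", "self"))
  d$criterion <- factor(d$criterion, levels = criterion_levels)
  d$participant_id <- factor(d$participant_id)
  rownames(d) <- NULL
  d
}

#' Analysis-ready self-allocation-bias table
#'
#' Computes trial-matched bias records from a cohort and maps the bias
#' (range `[-1, 1]`) affinely onto `[0, 1]` as
#' `bias01 = (bias + 1) / 2` so the zero-one-inflated beta engine
#' applies; estimates are reported back on the bias scale by the
#' inverse map `2 * x - 1`.
#'
#' @inheritParams analysis_table
#' @param contrast passed to [self_allocation_bias()].
#' @return `data.frame` with `bias`, `bias01`, `contribution_category`
#'   (reference `player1_only`), `svo_z` and `participant_id`.
#' @export
bias_table <- function(cohort, contrast = "classic") {
  d <- cohort$records
  b <- self_allocation_bias(d[!d$miss, , drop = FALSE], contrast = contrast)
  b$bias01 <- (b$bias + 1) / 2
  b$svo_z <- cohort$agents$svo_z[match(b$participant_id,
                                       cohort$agents$participant_id)]
  b$participant_id <- factor(b$participant_id)
  b
}
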