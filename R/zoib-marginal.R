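# Estimated-marginal-mean and marginal-trend machinery for zoib fits:
# cell means on the response scale, pairwise contrasts as odds ratios,
# and per-level slopes of continuous covariates, all summarized by
# posterior medians and 95% highest-density intervals over the draws.

# Full reference grid: every combination of the model's factor levels,
# numeric covariates fixed at their training means (overridable).
ref_grid <- function(fit, at = list()) {
  levs <- fit$xlevels
  if (!length(levs)) stop("model contains no factors")
  grid <- do.call(expand.grid, c(levs, list(stringsAsFactors = FALSE)))
  for (v in names(fit$data_means)) {
    grid[[v]] <- if (v %in% names(at)) at[[v]] else fit$data_means[[v]]
  }
  for (v in names(at)) grid[[v]] <- at[[v]]
  grid
}

grid_eta_draws <- function(fit, grid) {
  tt <- stats::delete.response(fit$terms)
  mf <- stats::model.frame(tt, grid, xlev = fit$xlevels)
  X <- stats::model.matrix(tt, mf, contrasts.arg = fit$contrasts)
  X %*% t(fit$draws[, fit$idx$beta, drop = FALSE])   # cells x S
}

spec_vars <- function(spec, fit) {
  vars <- if (inherits(spec, "formula")) all.vars(spec) else as.character(spec)
  bad <- setdiff(vars, names(fit$xlevels))
  if (length(bad)) {
    stop("not factors in the model: ", paste(bad, collapse = ", "))
  }
  vars
}

summarize_draws <- function(mat, prob = 0.95) {
  est <- apply(mat, 1, stats::median)
  hpd <- t(apply(mat, 1, hpd_interval, prob = prob))
  data.frame(estimate = est, lower = hpd[, 1], upper = hpd[, 2])
}

#' Estimated marginal means and odds-ratio contrasts
#'
#' Computes cell means of the beta-component mean `mu` on the response
#' scale for every combination of the requested factors, averaging on
#' the link scale over the model's remaining factors (equal weights)
#' with continuous covariates held at their training means. Pairwise
#' cell contrasts are formed on the logit scale and exponentiated to
#' odds ratios; all intervals are 95% highest-density intervals over
#' the posterior draws.
#'
#' @param fit a [zoib()] fit.
#' @param spec factors to condition on: a one-sided formula
#'   (`~ self_relevance * criterion`) or character vector.
#' @param at named list fixing continuous covariates at given values.
#' @param reverse if `TRUE`, contrasts put the later factor level
#'   first (`OR(B, A)` instead of `OR(A, B)`).
#' @param prob interval mass.
#' @return list of class `"zoib_emm"` with `means` (response scale)
#'   and `contrasts` (odds ratios); both carry HPD intervals.
#' @export
marginal_means <- function(fit, spec, at = list(), reverse = FALSE,
                           prob = 0.95) {
  vars <- spec_vars(spec, fit)
  grid <- ref_grid(fit, at)
  eta <- grid_eta_draws(fit, grid)
  cells <- unique(grid[vars])
  rownames(cells) <- NULL
  if (!nrow(cells)) stop("empty cell specification")
  cell_eta <- t(vapply(seq_len(nrow(cells)), function(i) {
    rows <- rep(TRUE, nrow(grid))
    for (v in vars) rows <- rows & grid[[v]] == cells[[v]][i]
    if (!any(rows)) stop("empty cell in reference grid")
    colMeans(eta[rows, , drop = FALSE])
  }, numeric(ncol(eta))))
  labels <- apply(cells, 1, paste, collapse = ",")
  means <- cbind(cells, summarize_draws(inv_logit(cell_eta), prob))
  contrasts <- NULL
  if (nrow(cells) > 1) {
    pr <- utils::combn(nrow(cells), 2)
    if (reverse) pr <- pr[2:1, , drop = FALSE]
    or_draws <- exp(cell_eta[pr[1, ], , drop = FALSE] -
                      cell_eta[pr[2, ], , drop = FALSE])
    contrasts <- data.frame(
      contrast = paste(labels[pr[1, ]], "/", labels[pr[2, ]]),
      summarize_draws(or_draws, prob)
    )
    names(contrasts)[2] <- "odds_ratio"
  }
  structure(list(means = means, contrasts = contrasts, spec = vars,
                 prob = prob),
            class = "zoib_emm")
}

#' @export
print.zoib_emm <- function(x, ...) {
  cat("Marginal means (response scale), ",
      round(100 * x$prob), "% HPD:\n", sep = "")
  print(x$means, digits = 4, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("\nPairwise contrasts (odds ratios):\n")
    print(x$contrasts, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Marginal slopes of a continuous covariate by factor level
#'
#' Estimates the link-scale slope of `var` within each cell of the
#' `by` factors (averaging over the model's other factors), together
#' with pairwise slope differences — the trend analogue of
#' [marginal_means()]. Slopes are exact finite differences, which
#' coincide with derivatives because the linear predictor is linear in
#' the covariate.
#'
#' @param fit a [zoib()] fit.
#' @param var name of a continuous covariate in the model.
#' @param by factors to condition on (formula or character vector).
#' @param prob interval mass.
#' @return list of class `"zoib_emt"` with `slopes` and `differences`
#'   (both link scale, HPD intervals).
#' @export
marginal_slopes <- function(fit, var, by, prob = 0.95) {
  if (!var %in% all.vars(fit$fixed_formula)) {
    stop("covariate '", var, "' is not in the model")
  }
  if (!var %in% names(fit$data_means)) {
    stop("'", var, "' is not a continuous covariate")
  }
  vars <- spec_vars(by, fit)
  m <- fit$data_means[[var]]
  eta_hi <- grid_eta_draws(fit, ref_grid(fit, at = stats::setNames(
    list(m + 0.5), var)))
  eta_lo <- grid_eta_draws(fit, ref_grid(fit, at = stats::setNames(
    list(m - 0.5), var)))
  grid <- ref_grid(fit)
  cells <- unique(grid[vars])
  rownames(cells) <- NULL
  slope_draws <- t(vapply(seq_len(nrow(cells)), function(i) {
    rows <- rep(TRUE, nrow(grid))
    for (v in vars) rows <- rows & grid[[v]] == cells[[v]][i]
    colMeans(eta_hi[rows, , drop = FALSE] - eta_lo[rows, , drop = FALSE])
  }, numeric(ncol(eta_hi))))
  labels <- apply(cells, 1, paste, collapse = ",")
  slopes <- cbind(cells, summarize_draws(slope_draws, prob))
  differences <- NULL
  if (nrow(cells) > 1) {
    pr <- utils::combn(nrow(cells), 2)
    diff_draws <- slope_draws[pr[1, ], , drop = FALSE] -
      slope_draws[pr[2, ], , drop = FALSE]
    differences <- data.frame(
      contrast = paste(labels[pr[1, ]], "-", labels[pr[2, ]]),
      summarize_draws(diff_draws, prob)
    )
  }
  structure(list(slopes = slopes, differences = differences, var = var,
                 prob = prob),
            class = "zoib_emt")
}

#' @export
print.zoib_emt <- function(x, ...) {
  cat("Marginal slopes of ", x$var, " (link scale), ",
      round(100 * x$prob), "% HPD:\n", sep = "")
  print(x$slopes, digits = 4, row.names = FALSE)
  if (!is.null(x$differences)) {
    cat("\nPairwise slope differences:\n")
    print(x$differences, digits = 4, row.names = FALSE)
  }
  invisible(x)
}
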