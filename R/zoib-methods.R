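# S3 methods for "zoib" fits.

#' @export
print.zoib <- function(x, ...) {
  cat("Hierarchical zero-one-inflated beta regression\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  engine: %s | n = %d obs, %d groups | %s\n",
              x$engine, x$n, length(x$u),
              if (x$converged) "converged" else "NOT CONVERGED"))
  cat("Fixed effects (posterior mode, logit scale):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("sigma(group) = %.3f  phi = %.2f  zoi = %.3f  coi = %.3f\n",
              x$sigma, x$phi, x$zoi, x$coi))
  invisible(x)
}

#' Summarize a zoib fit
#'
#' Coefficient table with posterior SDs and 95% highest-density
#' intervals from the draws, plus auxiliary parameters and, for MCMC
#' fits, the largest split R-hat.
#'
#' @param object a `zoib` fit.
#' @param prob interval mass.
#' @param ... unused.
#' @export
summary.zoib <- function(object, prob = 0.95, ...) {
  bd <- object$draws[, object$idx$beta, drop = FALSE]
  tab <- data.frame(
    term = colnames(bd),
    estimate = object$coefficients,
    sd = apply(bd, 2, stats::sd),
    lower = apply(bd, 2, function(v) hpd_interval(v, prob)[1]),
    upper = apply(bd, 2, function(v) hpd_interval(v, prob)[2]),
    row.names = NULL
  )
  if (!is.null(object$rhat)) tab$rhat <- object$rhat[object$idx$beta]
  out <- list(coefficients = tab, sigma = object$sigma, phi = object$phi,
              zoi = object$zoi, coi = object$coi, engine = object$engine,
              converged = object$converged,
              max_rhat = if (!is.null(object$rhat)) max(object$rhat) else NA,
              formula = object$formula, n = object$n,
              n_groups = length(object$u))
  class(out) <- "summary.zoib"
  out
}

#' @export
print.summary.zoib <- function(x, ...) {
  cat("Zero-one-inflated beta mixed model (", x$engine, ")\n", sep = "")
  cat("  ", deparse(x$formula), "\n")
  cat(sprintf("  n = %d, groups = %d, %s", x$n, x$n_groups,
              if (x$converged) "converged" else "NOT CONVERGED"))
  if (is.finite(x$max_rhat)) cat(sprintf(", max R-hat = %.3f", x$max_rhat))
  cat("\n\nFixed effects (logit scale):\n")
  print(cbind(x$coefficients[1],
              round(x$coefficients[-1], 4)), row.names = FALSE)
  cat(sprintf("\nsigma = %.3f, phi = %.2f, zoi = %.3f, coi = %.3f\n",
              x$sigma, x$phi, x$zoi, x$coi))
  invisible(x)
}

#' @export
coef.zoib <- function(object, ...) object$coefficients

#' @export
vcov.zoib <- function(object, ...) {
  stats::cov(object$draws[, object$idx$beta, drop = FALSE])
}

#' @export
logLik.zoib <- function(object, ...) {
  structure(object$loglik_mode, df = length(object$mode),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.zoib <- function(object, ...) object$n

#' @export
formula.zoib <- function(x, ...) x$formula

#' Random-intercept modes of a zoib fit
#' @param object a `zoib` fit.
#' @param ... unused.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.zoib <- function(object, ...) object$u

#' Predict the beta-component mean from a zoib fit
#'
#' @param object a `zoib` fit.
#' @param newdata data frame of predictors; defaults to the training
#'   design.
#' @param type `"response"` (mean `mu` of the beta component) or
#'   `"link"` (logit scale).
#' @param re_form `NA` (default) for population-level predictions, or
#'   `NULL` to add the random intercept for groups seen in fitting.
#' @param ... unused.
#' @export
predict.zoib <- function(object, newdata = NULL,
                         type = c("response", "link"), re_form = NA, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- drop(object$X %*% object$coefficients) +
      object$u[as.integer(object$group)]
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf, contrasts.arg = object$contrasts)
    eta <- drop(X %*% object$coefficients)
    if (is.null(re_form) && object$group_var %in% names(newdata)) {
      lev <- as.character(newdata[[object$group_var]])
      u <- object$u[paste0("u.", lev)]
      u[is.na(u)] <- 0
      eta <- eta + u
    }
  }
  if (type == "link") eta else inv_logit(eta)
}

#' @export
fitted.zoib <- function(object, ...) predict(object)

#' @export
residuals.zoib <- function(object, ...) {
  # response residuals against the full mixture mean
  ey <- (1 - object$zoi) * fitted(object) + object$zoi * object$coi
  object$y - ey
}

#' Simulate responses from a fitted zoib model
#'
#' Draws zero-one-inflated beta responses at the fitted (posterior
#' mode) parameters, conditional on the fitted random intercepts.
#'
#' @param object a `zoib` fit.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @export
simulate.zoib <- function(object, nsim = 1, seed = 1L, ...) {
  mu <- fitted(object)
  local_seed(seed, {
    as.data.frame(replicate(nsim,
      rzoib(object$n, mu, object$phi, object$zoi, object$coi)))
  })
}

#' Diagnostic plot for a zoib fit
#'
#' Left: observed responses against fitted beta-component means with
#' the identity line. Right: histogram of the observed responses with
#' the fitted boundary masses marked.
#'
#' @param x a `zoib` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.zoib <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(fitted(x), x$y, xlab = "fitted mu", ylab = "observed",
                 pch = 16, cex = 0.4, col = grDevices::grey(0, 0.3), ...)
  graphics::abline(0, 1, col = 2)
  graphics::hist(x$y, breaks = 30, main = "", xlab = "response")
  graphics::abline(v = c(0, 1), col = 4, lty = 2)
  invisible(x)
}
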