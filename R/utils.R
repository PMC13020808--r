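#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never clobber the
# global random sequence.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Money is carried in integer cents internally: pots and slider steps are
# multiples of 0.01 yen, and sums/halves of integer cents are exact in
# double precision, so Shapley efficiency checks hold exactly.
to_cents <- function(x) round(x * 100)
from_cents <- function(x) x / 100

#' Shortest (highest-density) interval from posterior draws
#'
#' Computes the shortest interval containing a given probability mass,
#' the standard empirical HPD algorithm over sorted draws. Ties between
#' equally short candidate intervals are broken by the lower bound.
#'
#' @param draws numeric vector of draws.
#' @param prob probability mass, default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  stopifnot(is.numeric(draws), length(draws) > 3, prob > 0, prob < 1)
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(k + 1L):n] - x[1:(n - k)]
  i <- which.min(widths)  # which.min returns the first (lowest) minimiser
  c(lower = x[i], upper = x[i + k])
}

# Split R-hat (rank-normalisation omitted; adequate for the Gaussian-ish
# posteriors handled here). `mat` is iterations x chains.
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub)
  nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  b <- nn * stats::var(means)
  w <- mean(vars)
  if (w <= 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

logit <- stats::qlogis
inv_logit <- stats::plogis
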