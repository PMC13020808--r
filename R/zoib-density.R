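#' Zero-one-inflated beta density
#'
#' Mixture of point masses at 0 and 1 with a beta density on the open
#' interval, in the mean/precision parameterization: a boundary
#' response occurs with probability `zoi` and equals 1 with conditional
#' probability `coi`; otherwise the response follows
#' `Beta(mu * phi, (1 - mu) * phi)`. The density plus point masses
#' integrates to 1.
#'
#' @param y responses in `[0, 1]`.
#' @param mu beta mean in (0, 1).
#' @param phi beta precision, > 0.
#' @param zoi probability of a boundary response, in `[0, 1)`.
#' @param coi conditional probability a boundary response is 1.
#' @param log return log-density?
#' @return numeric vector of (log-)densities / point masses.
#' @export
#' @examples
#' dzoib(1, mu = 0.5, phi = 5, zoi = 0.1, coi = 0.5)  # 0.05
dzoib <- function(y, mu, phi, zoi, coi, log = FALSE) {
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
  stopifnot(all(mu > 0 & mu < 1), all(phi > 0),
            all(zoi >= 0 & zoi < 1), all(coi >= 0 & coi <= 1))
  n <- max(length(y), length(mu), length(phi), length(zoi), length(coi))
  y <- rep_len(y, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  zoi <- rep_len(zoi, n); coi <- rep_len(coi, n)
  ll <- numeric(n)
  i0 <- y == 0
  i1 <- y == 1
  ic <- !i0 & !i1
  ll[i0] <- log(zoi[i0]) + log1p(-coi[i0])
  ll[i1] <- log(zoi[i1]) + log(coi[i1])
  ll[ic] <- log1p(-zoi[ic]) +
    stats::dbeta(y[ic], mu[ic] * phi[ic], (1 - mu[ic]) * phi[ic], log = TRUE)
  if (log) ll else exp(ll)
}

#' @rdname dzoib
#' @param n number of draws.
#' @export
rzoib <- function(n, mu, phi, zoi, coi) {
  mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  zoi <- rep_len(zoi, n); coi <- rep_len(coi, n)
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  b <- stats::runif(n) < zoi
  y[b] <- as.numeric(stats::runif(sum(b)) < coi[b])
  y
}
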