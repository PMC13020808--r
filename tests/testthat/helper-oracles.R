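# Independent oracles used across the suite.

# Brute-force Shapley value: average marginal contribution over all
# orderings in which the two-player coalition can form.
shapley_oracle <- function(v_p1, v_p2, v_both) {
  # ordering 1 then 2: player 1 adds v_p1, player 2 adds v_both - v_p1
  # ordering 2 then 1: player 2 adds v_p2, player 1 adds v_both - v_p2
  phi1 <- mean(c(v_p1, v_both - v_p2))
  phi2 <- mean(c(v_p2, v_both - v_p1))
  c(phi1 = phi1, phi2 = phi2)
}

# Random monotone two-player games (whole-yen values so halves are
# exactly representable and the efficiency identity is exact).
random_monotone_games <- function(n, seed) {
  set.seed(seed)
  v_both <- sample(1:200, n, replace = TRUE)
  v_p1 <- vapply(v_both, function(vb) sample(0:vb, 1), numeric(1))
  v_p2 <- vapply(v_both, function(vb) sample(0:vb, 1), numeric(1))
  data.frame(v_p1 = v_p1, v_p2 = v_p2, v_both = as.numeric(v_both))
}

# Trial-division primality, independent of the generator's sieve.
is_prime_naive <- function(x) {
  vapply(x, function(k) {
    if (k < 2) return(FALSE)
    if (k < 4) return(TRUE)
    all(k %% 2:floor(sqrt(k)) != 0)
  }, logical(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small cohorts shared across test files, built once per run.
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(key = "biased", n = 12, seed = 42,
                         population = agent_population()) {
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_cohort(n, population, seed = seed)
  }
  .fixture_env[[key]]
}
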