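# Erlang serial-server model: a message is serviced by k stages in series,
# each with an exponential(mu) service time, so the total service time is
# Gamma(shape = k, scale = 1/mu). Closed forms, Laplace transforms and a
# stochastic simulator.

#' Erlang server specification
#'
#' @param n_stages Number of serial service stages `k` (positive integer).
#' @param stage_rate Exponential service rate `mu` of each stage (1/time).
#' @return An object of class `erlang_spec`.
#' @examples
#' erlang_server_spec(4, 2)
#' @export
erlang_server_spec <- function(n_stages, stage_rate) {
  if (!is.numeric(n_stages) || length(n_stages) != 1L ||
      n_stages < 1 || n_stages != round(n_stages)) {
    stop("`n_stages` must be a positive integer", call. = FALSE)
  }
  stop_if_not_scalar_pos(stage_rate, "stage_rate")
  structure(list(n_stages = as.integer(n_stages),
                 stage_rate = as.numeric(stage_rate)),
            class = "erlang_spec")
}

#' @export
print.erlang_spec <- function(x, ...) {
  cat(sprintf("Erlang server: %d stages in series, rate %g per stage\n",
              x$n_stages, x$stage_rate))
  invisible(x)
}

#' Density of a single service stage
#'
#' Each stage's service time is exponential with rate `mu`:
#' \eqn{f(x) = \mu e^{-\mu x}} for \eqn{x \ge 0}; negative arguments return
#' 0 by convention.
#'
#' @param x Time(s).
#' @param spec An [erlang_server_spec()].
#' @return Density value(s).
#' @export
stage_time_pdf <- function(x, spec) {
  stopifnot(inherits(spec, "erlang_spec"))
  mu <- spec$stage_rate
  ifelse(x < 0, 0, mu * exp(-mu * x))
}

#' Mean and variance of the total Erlang service time
#'
#' Summing expectation and variance across the `k` independent stages gives
#' mean \eqn{k/\mu} and variance \eqn{k/\mu^2}.
#'
#' @param spec An [erlang_server_spec()].
#' @return List with `mean` and `variance`.
#' @export
erlang_moments <- function(spec) {
  stopifnot(inherits(spec, "erlang_spec"))
  list(mean = spec$n_stages / spec$stage_rate,
       variance = spec$n_stages / spec$stage_rate^2)
}

#' Coefficient of variation of the total service time
#'
#' \eqn{CV = k^{-1/2}}: strictly below 1 for two or more stages
#' (hypoexponential — less dispersed than the exponential), equal to 1 for a
#' single stage. Identical to the Gamma-fit CV at shape `k`.
#'
#' @param n_stages Positive integer number of stages.
#' @return The dimensionless CV.
#' @export
erlang_cv <- function(n_stages) {
  if (any(n_stages < 1) || any(n_stages != round(n_stages))) {
    stop("`n_stages` must be positive integer(s)", call. = FALSE)
  }
  n_stages^(-0.5)
}

#' Laplace transform of the total service time
#'
#' Each exponential stage has transform \eqn{\mu / (\mu + s)}; the total
#' time, being a sum of `k` independent stages, has the product transform
#' \eqn{(\mu / (\mu + s))^k}. Defined for \eqn{\Re(s) > -\mu}.
#'
#' @param s Real or complex argument(s) with real part above `-mu`.
#' @param spec An [erlang_server_spec()].
#' @return Transform value(s).
#' @export
total_time_laplace <- function(s, spec) {
  stopifnot(inherits(spec, "erlang_spec"))
  mu <- spec$stage_rate
  if (any(Re(s) <= -mu)) {
    stop(sprintf("transform undefined for Re(s) <= -mu = %g", -mu),
         call. = FALSE)
  }
  (mu / (mu + s))^spec$n_stages
}

#' Density of the total Erlang service time
#'
#' Inverting the product transform gives
#' \deqn{f(x) = \frac{\mu^k x^{k-1} e^{-\mu x}}{(k-1)!},}
#' the Gamma density with integer shape `k` and scale \eqn{1/\mu}.
#'
#' @param x Time(s); negative arguments return 0.
#' @param spec An [erlang_server_spec()].
#' @return Density value(s).
#' @export
erlang_pdf <- function(x, spec) {
  stopifnot(inherits(spec, "erlang_spec"))
  k <- spec$n_stages
  mu <- spec$stage_rate
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- exp(k * log(mu) + (k - 1) * log(x[pos]) - mu * x[pos] -
                    lgamma(k))
  out[x == 0] <- if (k == 1L) mu else 0
  out
}

#' Simulate total service times of an Erlang server
#'
#' Each draw is the sum of `k` independent exponential(`mu`) stage times.
#'
#' @param spec An [erlang_server_spec()].
#' @param n Number of draws.
#' @param seed Explicit RNG seed (required for reproducibility).
#' @return Numeric vector of `n` total service times.
#' @examples
#' x <- simulate_erlang_server(erlang_server_spec(4, 0.2), 1000, seed = 1)
#' sd(x) / mean(x)  # about 0.5
#' @export
simulate_erlang_server <- function(spec, n, seed) {
  stopifnot(inherits(spec, "erlang_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  with_seed(seed, {
    colSums(matrix(stats::rexp(n * spec$n_stages, rate = spec$stage_rate),
                   nrow = spec$n_stages))
  })
}

#' Simulate a two-branch hyperexponential server
#'
#' The parallel-branch counterpart of the serial Erlang server: each message
#' is routed to branch 1 with probability `prob` and serviced by a single
#' exponential stage there, giving a mixture of exponentials whose CV
#' exceeds 1 whenever the branch rates differ. Provided for the
#' serial-vs-parallel dispersion contrast (CV < 1 vs CV > 1).
#'
#' @param rates Length-2 positive rates of the two branches.
#' @param prob Probability of routing to branch 1.
#' @param n Number of draws.
#' @param seed Explicit RNG seed.
#' @return Numeric vector of `n` service times.
#' @export
simulate_hyperexponential <- function(rates, prob, n, seed) {
  if (length(rates) != 2L || any(rates <= 0)) {
    stop("`rates` must be two positive rates", call. = FALSE)
  }
  if (prob <= 0 || prob >= 1) stop("`prob` must be in (0, 1)", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    branch <- stats::runif(n) < prob
    stats::rexp(n, rate = ifelse(branch, rates[1], rates[2]))
  })
}
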