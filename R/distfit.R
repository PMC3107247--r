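# Maximum-likelihood fitting of candidate inter-departure time
# distributions, dispersion statistics and chi-square goodness of fit.

dist_registry <- list(
  gamma = list(
    n_params = 2L,
    dfun = function(x, p, log = FALSE)
      stats::dgamma(x, shape = p[["shape"]], scale = p[["scale"]], log = log),
    qfun = function(q, p)
      stats::qgamma(q, shape = p[["shape"]], scale = p[["scale"]])
  ),
  weibull = list(
    n_params = 2L,
    dfun = function(x, p, log = FALSE)
      stats::dweibull(x, shape = p[["shape"]], scale = p[["scale"]], log = log),
    qfun = function(q, p)
      stats::qweibull(q, shape = p[["shape"]], scale = p[["scale"]])
  ),
  exponential = list(
    n_params = 1L,
    dfun = function(x, p, log = FALSE)
      stats::dexp(x, rate = p[["rate"]], log = log),
    qfun = function(q, p) stats::qexp(q, rate = p[["rate"]])
  ),
  lognormal = list(
    n_params = 2L,
    dfun = function(x, p, log = FALSE)
      stats::dlnorm(x, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]],
                    log = log),
    qfun = function(q, p)
      stats::qlnorm(q, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]])
  ),
  normal = list(
    n_params = 2L,
    dfun = function(x, p, log = FALSE)
      stats::dnorm(x, mean = p[["mean"]], sd = p[["sd"]], log = log),
    qfun = function(q, p) stats::qnorm(q, mean = p[["mean"]], sd = p[["sd"]])
  )
)

#' Construct a distribution-fit object directly from parameters
#'
#' Mostly useful for testing and for evaluating a fixed (not estimated)
#' distribution in [chi_square_gof()].
#'
#' @param distribution One of `"gamma"`, `"weibull"`, `"exponential"`,
#'   `"lognormal"`, `"normal"`.
#' @param params Named numeric vector of the distribution's parameters
#'   (e.g. `c(shape = 3, scale = 15)`).
#' @param loglik Optional log-likelihood.
#' @param n Optional sample size the fit is based on.
#' @param n_params Number of parameters *estimated from the data* (controls
#'   the degrees-of-freedom adjustment in [chi_square_gof()]); defaults to
#'   the distribution's parameter count.
#' @return An object of class `dist_fit` (Gamma fits additionally carry
#'   class `gamma_fit` and a `cv` field).
#' @export
dist_fit <- function(distribution, params, loglik = NA_real_, n = NA_integer_,
                     n_params = NULL) {
  distribution <- match.arg(distribution, names(dist_registry))
  reg <- dist_registry[[distribution]]
  if (is.null(n_params)) n_params <- reg$n_params
  obj <- list(distribution = distribution, params = params,
              loglik = loglik, n = n, n_params = as.integer(n_params))
  cls <- "dist_fit"
  if (distribution == "gamma") {
    obj$shape <- unname(params[["shape"]])
    obj$scale <- unname(params[["scale"]])
    obj$cv <- obj$shape^(-0.5)
    cls <- c("gamma_fit", cls)
  }
  if (distribution == "weibull") {
    obj$shape <- unname(params[["shape"]])
    obj$scale <- unname(params[["scale"]])
  }
  structure(obj, class = cls)
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %s): %s; loglik = %s\n",
              x$distribution, x$n,
              paste(names(x$params), signif(unlist(x$params), 6),
                    sep = " = ", collapse = ", "),
              format(x$loglik)))
  invisible(x)
}

as_intervals <- function(sample) {
  x <- if (inherits(sample, "idt_sample")) sample$intervals else sample
  if (!is.numeric(x)) stop("sample must be numeric", call. = FALSE)
  as.numeric(x)
}

check_fit_sample <- function(x, min_n, positive = TRUE) {
  if (length(x) < min_n) {
    stop(sprintf("insufficient sample: n = %d, minimum is %d",
                 length(x), min_n), call. = FALSE)
  }
  if (any(!is.finite(x))) stop("sample contains non-finite values",
                               call. = FALSE)
  if (positive && any(x <= 0)) {
    stop("all intervals must be strictly positive", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop(paste0("degenerate sample with zero variance: the maximum-",
                "likelihood shape diverges (shape -> Inf); no fit returned"),
         call. = FALSE)
  }
  invisible(x)
}

#' Gamma maximum-likelihood fit of an inter-departure time sample
#'
#' Jointly maximizes the two-parameter Gamma log-likelihood. The shape
#' estimate solves the profile-likelihood stationarity condition
#' \deqn{\log k - \psi(k) = \log \bar x - \overline{\log x},}
#' found by a safeguarded root search (bracket expansion around a
#' method-of-moments style starting value, then [stats::uniroot()] at
#' tolerance 1e-10); the scale is then \eqn{\hat\theta = \bar x / \hat k}.
#'
#' @param sample An `idt_sample` or positive numeric vector.
#' @param min_n Minimum sample size accepted (default 10).
#' @return A `gamma_fit` object with fields `shape`, `scale`, `loglik`, `n`
#'   and `cv` (the coefficient of variation \eqn{k^{-1/2}}).
#' @examples
#' x <- generate_gamma_sample(3, 15, 1000, seed = 1)
#' fit_gamma_mle(x)
#' @export
fit_gamma_mle <- function(sample, min_n = 10) {
  x <- as_intervals(sample)
  check_fit_sample(x, min_n)
  s <- log(mean(x)) - mean(log(x))  # > 0 for non-degenerate positive samples
  k0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  f <- function(k) log(k) - digamma(k) - s
  lo <- k0 / 2
  hi <- k0 * 2
  while (f(lo) < 0 && lo > 1e-12) lo <- lo / 4  # f decreasing in k
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 4
  k_hat <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  theta_hat <- mean(x) / k_hat
  ll <- sum(stats::dgamma(x, shape = k_hat, scale = theta_hat, log = TRUE))
  dist_fit("gamma", c(shape = k_hat, scale = theta_hat),
           loglik = ll, n = length(x))
}

#' Coefficient of variation implied by a Gamma fit
#'
#' For the Gamma distribution the ratio of standard deviation to mean is
#' \eqn{k^{-1/2}}, a normalized dispersion measure: values below 1 indicate
#' sub-exponential (hypoexponential) dispersion.
#'
#' @param fit A `gamma_fit`.
#' @return The dimensionless CV.
#' @export
gamma_cv <- function(fit) {
  stopifnot(inherits(fit, "gamma_fit"))
  fit$shape^(-0.5)
}

#' Weibull maximum-likelihood fit
#'
#' Profile-likelihood estimation: the shape \eqn{c} solves
#' \deqn{\frac{\sum x_i^c \log x_i}{\sum x_i^c} - \frac{1}{c}
#'       = \overline{\log x},}
#' by safeguarded root search; the scale is
#' \eqn{(\overline{x^c})^{1/c}}.
#'
#' @inheritParams fit_gamma_mle
#' @return A `dist_fit` with `shape` and `scale` fields.
#' @export
fit_weibull_mle <- function(sample, min_n = 10) {
  x <- as_intervals(sample)
  check_fit_sample(x, min_n)
  mlx <- mean(log(x))
  g <- function(c.) {
    xc <- x^c.
    sum(xc * log(x)) / sum(xc) - 1 / c. - mlx
  }
  cv <- stats::sd(x) / mean(x)
  c0 <- max(cv^(-1.086), 1e-3)  # standard moment-based start
  lo <- c0 / 2
  hi <- c0 * 2
  while (g(lo) > 0 && lo > 1e-12) lo <- lo / 4  # g increasing in c
  while (g(hi) < 0 && hi < 1e12) hi <- hi * 4
  c_hat <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  b_hat <- mean(x^c_hat)^(1 / c_hat)
  ll <- sum(stats::dweibull(x, shape = c_hat, scale = b_hat, log = TRUE))
  dist_fit("weibull", c(shape = c_hat, scale = b_hat),
           loglik = ll, n = length(x))
}

#' Fit one of the candidate distributions by maximum likelihood
#'
#' Gamma and Weibull use the profile-likelihood solvers of
#' [fit_gamma_mle()] and [fit_weibull_mle()]; exponential, lognormal and
#' normal have closed-form MLEs.
#'
#' @inheritParams fit_gamma_mle
#' @param distribution Candidate name.
#' @return A `dist_fit`.
#' @export
fit_distribution <- function(sample,
                             distribution = c("gamma", "weibull",
                                              "exponential", "lognormal",
                                              "normal"),
                             min_n = 10) {
  distribution <- match.arg(distribution)
  x <- as_intervals(sample)
  if (distribution == "gamma") return(fit_gamma_mle(x, min_n))
  if (distribution == "weibull") return(fit_weibull_mle(x, min_n))
  check_fit_sample(x, min_n, positive = distribution != "normal")
  n <- length(x)
  if (distribution == "exponential") {
    rate <- 1 / mean(x)
    ll <- sum(stats::dexp(x, rate = rate, log = TRUE))
    return(dist_fit("exponential", c(rate = rate), loglik = ll, n = n))
  }
  if (distribution == "lognormal") {
    ml <- mean(log(x))
    sl <- sqrt(mean((log(x) - ml)^2))
    ll <- sum(stats::dlnorm(x, ml, sl, log = TRUE))
    return(dist_fit("lognormal", c(meanlog = ml, sdlog = sl),
                    loglik = ll, n = n))
  }
  m <- mean(x)
  sdv <- sqrt(mean((x - m)^2))
  ll <- sum(stats::dnorm(x, m, sdv, log = TRUE))
  dist_fit("normal", c(mean = m, sd = sdv), loglik = ll, n = n)
}

default_n_bins <- function(n) min(max(6L, floor(n / 50)), 50L)

#' Chi-square goodness of fit with estimated-parameter df adjustment
#'
#' Bins are equiprobable under the fitted distribution (so every bin has the
#' same expected count \eqn{n / B}), the statistic is
#' \eqn{\sum_b (O_b - E_b)^2 / E_b}, and the degrees of freedom are
#' \eqn{B - 1 - p} with \eqn{p} the number of parameters estimated from the
#' data — the adjustment that plain Kolmogorov-Smirnov-style tests lack.
#' The default bin count is `max(6, floor(n / 50))` capped at 50.
#'
#' @param sample An `idt_sample` or numeric vector.
#' @param fit A `dist_fit`.
#' @param n_bins Number of bins; `NULL` for the default rule.
#' @return An object of class `gof_result`: `statistic`,
#'   `degrees_of_freedom`, `bin_edges`, `p_value`, `distribution_name`,
#'   `n_bins`.
#' @export
chi_square_gof <- function(sample, fit, n_bins = NULL) {
  stopifnot(inherits(fit, "dist_fit"))
  x <- as_intervals(sample)
  n <- length(x)
  if (is.null(n_bins)) n_bins <- default_n_bins(n)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("need at least 2 bins", call. = FALSE)
  expected <- n / n_bins
  if (expected < 1) {
    stop(sprintf(paste0("expected count per bin is %.2f (< 1); ",
                        "use fewer bins or a larger sample"), expected),
         call. = FALSE)
  }
  df <- n_bins - 1L - fit$n_params
  if (df < 1L) {
    stop(sprintf(paste0("degrees of freedom %d - 1 - %d < 1; ",
                        "use more bins"), n_bins, fit$n_params),
         call. = FALSE)
  }
  reg <- dist_registry[[fit$distribution]]
  edges <- reg$qfun(seq(0, 1, length.out = n_bins + 1L), fit$params)
  edges[1] <- -Inf
  edges[n_bins + 1L] <- Inf
  observed <- tabulate(findInterval(x, edges, left.open = TRUE,
                                    rightmost.closed = TRUE),
                       nbins = n_bins)
  statistic <- sum((observed - expected)^2 / expected)
  structure(
    list(statistic = statistic,
         degrees_of_freedom = df,
         bin_edges = edges,
         p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
         distribution_name = fit$distribution,
         n_bins = n_bins),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi-square GoF (%s): X2 = %.3f, df = %d, p = %.4g\n",
              x$distribution_name, x$statistic, x$degrees_of_freedom,
              x$p_value))
  invisible(x)
}

#' Rank candidate fits by chi-square goodness of fit
#'
#' All candidates are evaluated with the same number of equiprobable bins
#' (each under its own fitted distribution, so expected counts match) and
#' ordered by ascending chi-square statistic. Ties are broken by fewer
#' estimated parameters, then by name.
#'
#' @param sample An `idt_sample` or numeric vector.
#' @param fits List of `dist_fit` objects (length >= 1).
#' @param n_bins Common bin count; `NULL` for the default rule.
#' @return A data.frame (best first) with columns `distribution`,
#'   `statistic`, `df`, `p_value`, `n_params`.
#' @export
rank_fits <- function(sample, fits, n_bins = NULL) {
  if (!length(fits)) stop("need at least one candidate fit", call. = FALSE)
  if (inherits(fits, "dist_fit")) fits <- list(fits)
  x <- as_intervals(sample)
  if (is.null(n_bins)) n_bins <- default_n_bins(length(x))
  rows <- lapply(fits, function(f) {
    g <- chi_square_gof(x, f, n_bins = n_bins)
    data.frame(distribution = f$distribution,
               statistic = g$statistic,
               df = g$degrees_of_freedom,
               p_value = g$p_value,
               n_params = f$n_params,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$statistic, out$n_params, out$distribution), ]
  rownames(out) <- NULL
  out
}

#' Fit distributions to every cell of an IDT table
#'
#' @param idt_table Result of [extract_idt_table()].
#' @param distributions Candidate names fitted per cell (default Gamma and
#'   Weibull).
#' @param min_n Cells with fewer intervals are skipped (reported with `NA`
#'   fit columns).
#' @param gof Also compute the chi-square statistic per fit where the sample
#'   is large enough (default `TRUE`).
#' @return A data.frame with one row per (subject, condition, channel,
#'   frequency, distribution): columns `subject`, `condition`, `channel`,
#'   `frequency_hz`, `distribution`, `shape`, `scale`, `cv`, `loglik`, `n`,
#'   `chi2`, `chi2_df`.
#' @export
fit_idt_cells <- function(idt_table, distributions = c("gamma", "weibull"),
                          min_n = 10, gof = TRUE) {
  key <- interaction(idt_table$subject, idt_table$condition,
                     idt_table$channel, idt_table$frequency_hz, drop = TRUE)
  groups <- split(seq_len(nrow(idt_table)), key)
  rows <- lapply(groups, function(idx) {
    x <- idt_table$tau_samples[idx]
    meta <- idt_table[idx[1], c("subject", "condition", "channel",
                                "frequency_hz")]
    do.call(rbind, lapply(distributions, function(d) {
      row <- data.frame(meta, distribution = d, shape = NA_real_,
                        scale = NA_real_, cv = NA_real_, loglik = NA_real_,
                        n = length(x), chi2 = NA_real_, chi2_df = NA_integer_,
                        stringsAsFactors = FALSE)
      fit <- tryCatch(fit_distribution(x, d, min_n = min_n),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        if (!is.null(fit$shape)) row$shape <- fit$shape
        if (!is.null(fit$scale)) row$scale <- fit$scale
        if (!is.null(fit$cv)) row$cv <- fit$cv
        row$loglik <- fit$loglik
        if (gof && length(x) >= 2 * default_n_bins(length(x))) {
          g <- tryCatch(chi_square_gof(x, fit), error = function(e) NULL)
          if (!is.null(g)) {
            row$chi2 <- g$statistic
            row$chi2_df <- g$degrees_of_freedom
          }
        }
      }
      row
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject, out$condition, out$channel, out$frequency_hz,
            out$distribution), , drop = FALSE]
}
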