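test_that("gamma MLE recovers known parameters and matches MASS", {
  x <- generate_gamma_sample(3, 15, 10000, seed = 2024)
  fit <- fit_gamma_mle(x)
  expect_gt(fit$shape, 2.85)
  expect_lt(fit$shape, 3.15)
  expect_gt(fit$scale, 13.9)
  expect_lt(fit$scale, 16.1)
  expect_equal(fit$n, 10000L)
  expect_equal(fit$cv, fit$shape^(-0.5), tolerance = 1e-12)

  # independent optimizer as oracle
  ms <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  expect_equal(fit$shape, unname(ms$estimate["shape"]), tolerance = 1e-4)
  expect_equal(fit$scale, 1 / unname(ms$estimate["rate"]), tolerance = 1e-4)
  expect_equal(fit$loglik, unname(ms$loglik), tolerance = 1e-6)

  # exponential data is gamma with shape 1
  e <- with(list(), {set.seed(9); rexp(10000, rate = 1 / 20)})
  fe <- fit_gamma_mle(e)
  expect_gt(fe$shape, 0.95)
  expect_lt(fe$shape, 1.05)
})

test_that("gamma MLE is a stationary point of the log-likelihood", {
  x <- generate_gamma_sample(2.2, 8, 3000, seed = 5)
  fit <- fit_gamma_mle(x)
  ll <- function(p) sum(dgamma(x, shape = p[1], scale = p[2], log = TRUE))
  h <- 1e-6
  g1 <- (ll(c(fit$shape + h, fit$scale)) -
           ll(c(fit$shape - h, fit$scale))) / (2 * h)
  g2 <- (ll(c(fit$shape, fit$scale + h)) -
           ll(c(fit$shape, fit$scale - h))) / (2 * h)
  expect_lt(sqrt(g1^2 + g2^2) / fit$n, 1e-6)
})

test_that("gamma fit is scale equivariant", {
  x <- generate_gamma_sample(4, 2, 2000, seed = 31)
  f1 <- fit_gamma_mle(x)
  for (c. in c(0.5, 3.7)) {
    f2 <- fit_gamma_mle(c. * x)
    expect_equal(f2$shape, f1$shape, tolerance = 1e-6)
    expect_equal(f2$scale, c. * f1$scale, tolerance = 1e-6)
  }
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_gamma_mle(rep(5, 50)), "degenerate")
  expect_error(fit_gamma_mle(c(1, 2, 3)), "insufficient")
  expect_error(fit_weibull_mle(rep(5, 50)), "degenerate")
  expect_error(fit_gamma_mle(c(rep(2, 20), -1)), "positive")
})

test_that("gamma CV follows the closed form k^(-1/2)", {
  expect_equal(gamma_cv(dist_fit("gamma", c(shape = 4, scale = 1))), 0.5)
  expect_equal(gamma_cv(dist_fit("gamma", c(shape = 1, scale = 7))), 1)
  # Monte-Carlo agreement with the closed form
  for (k in c(1, 2, 4, 9)) {
    x <- generate_gamma_sample(k, 1, 1e5, seed = 100 + k)
    expect_equal(sd(x) / mean(x), k^(-0.5), tolerance = 0.02)
  }
})

test_that("weibull MLE recovers known parameters and matches MASS", {
  set.seed(12)
  x <- rweibull(10000, shape = 2, scale = 10)
  fit <- fit_weibull_mle(x)
  expect_gt(fit$shape, 1.9)
  expect_lt(fit$shape, 2.1)
  ms <- suppressWarnings(MASS::fitdistr(x, "weibull"))
  expect_equal(fit$shape, unname(ms$estimate["shape"]), tolerance = 1e-4)
  expect_equal(fit$scale, unname(ms$estimate["scale"]), tolerance = 1e-4)
  # exponential data: weibull shape near 1
  set.seed(13)
  fe <- fit_weibull_mle(rexp(10000, 0.1))
  expect_equal(fe$shape, 1, tolerance = 0.05)
})

test_that("closed-form candidate fits maximize their likelihoods", {
  x <- generate_gamma_sample(3, 15, 2000, seed = 77)
  for (d in c("exponential", "lognormal", "normal")) {
    fit <- fit_distribution(x, d)
    expect_s3_class(fit, "dist_fit")
    # small perturbations of the parameters never improve the likelihood
    reg <- fit$params
    for (j in seq_along(reg)) {
      for (eps in c(-1e-3, 1e-3)) {
        p <- reg
        p[j] <- p[j] * (1 + eps)
        ll <- switch(d,
          exponential = sum(dexp(x, p[["rate"]], log = TRUE)),
          lognormal = sum(dlnorm(x, p[["meanlog"]], p[["sdlog"]], log = TRUE)),
          normal = sum(dnorm(x, p[["mean"]], p[["sd"]], log = TRUE)))
        expect_lte(ll, fit$loglik + 1e-9)
      }
    }
  }
})

test_that("chi-square statistic is zero on perfectly equiprobable data", {
  fit <- dist_fit("gamma", c(shape = 3, scale = 15))
  # 10 points per equiprobable sextile by construction
  x <- qgamma((seq_len(60) - 0.5) / 60, shape = 3, scale = 15)
  g <- chi_square_gof(x, fit, n_bins = 6)
  expect_equal(g$statistic, 0)
  expect_equal(g$degrees_of_freedom, 3L)  # 6 - 1 - 2
  expect_equal(g$p_value, 1)
})

test_that("chi-square gof separates good fits from misfits", {
  x <- generate_gamma_sample(3, 15, 5000, seed = 321)
  gfit <- fit_gamma_mle(x)
  nfit <- fit_distribution(x, "normal")
  gg <- chi_square_gof(x, gfit, n_bins = 20)
  gn <- chi_square_gof(x, nfit, n_bins = 20)
  expect_gt(gn$statistic, gg$statistic)
  expect_gt(gg$p_value, 0.01)
  # df bookkeeping
  expect_equal(gg$degrees_of_freedom, 20L - 1L - 2L)
  expect_error(chi_square_gof(x[1:10], gfit, n_bins = 12), "fewer bins")
  expect_error(chi_square_gof(x, gfit, n_bins = 3), "more bins")
})

test_that("gamma data ranks gamma above the other candidates", {
  x <- generate_gamma_sample(3, 15, 5000, seed = 99)
  fits <- list(fit_gamma_mle(x), fit_weibull_mle(x),
               fit_distribution(x, "normal"),
               fit_distribution(x, "exponential"))
  rk <- rank_fits(x, fits)
  expect_equal(rk$distribution[1], "gamma")
  # ranking is stable across bin counts
  for (nb in c(10, 20, 30)) {
    rk2 <- rank_fits(x, fits, n_bins = nb)
    expect_equal(rk2$distribution[1], "gamma")
  }
  # single candidate trivially first; duplicated candidates tie stably
  expect_equal(rank_fits(x, list(fits[[1]]))$distribution, "gamma")
  dup <- rank_fits(x, list(fits[[2]], fits[[2]]))
  expect_equal(dup$distribution, c("weibull", "weibull"))
  expect_equal(dup$statistic[1], dup$statistic[2])
  # tie between equal statistics broken by fewer parameters
  x60 <- qgamma((seq_len(600) - 0.5) / 600, shape = 1, scale = 15)
  tie <- rank_fits(x60, list(dist_fit("gamma", c(shape = 1, scale = 15)),
                             dist_fit("exponential", c(rate = 1 / 15))),
                   n_bins = 6)
  expect_equal(tie$distribution[1], "exponential")
})

test_that("fits on simulated erlang output recover the integer stage count", {
  x <- simulate_erlang_server(erlang_server_spec(4, 0.2), 1e4, seed = 17)
  fit <- fit_gamma_mle(x)
  expect_lt(abs(fit$shape - 4), 0.15)
  expect_gt(fit$scale, 4.75)
  expect_lt(fit$scale, 5.25)
})

test_that("per-cell fitting reports every cell and skips undersized ones", {
  idt <- data.frame(
    subject = rep("s01", 60),
    condition = rep(c("a", "b"), each = 30),
    channel = "ch001",
    frequency_hz = rep(c(10, 10, 20), 20),
    tau_samples = c(generate_gamma_sample(3, 15, 40, seed = 1) + 1,
                    generate_gamma_sample(3, 15, 20, seed = 2) + 1))
  # make one cell undersized
  idt <- idt[!(idt$condition == "b" & idt$frequency_hz == 20) |
               seq_len(nrow(idt)) %in% which(idt$condition == "b" &
                                               idt$frequency_hz == 20)[1:5], ]
  fits <- fit_idt_cells(idt, distributions = c("gamma", "weibull"),
                        min_n = 10)
  expect_true(all(c("subject", "condition", "channel", "frequency_hz",
                    "distribution", "shape", "scale", "cv", "loglik", "n",
                    "chi2", "chi2_df") %in% names(fits)))
  small <- fits[fits$condition == "b" & fits$frequency_hz == 20, ]
  expect_true(all(is.na(small$shape)))
  big <- fits[fits$condition == "a" & fits$frequency_hz == 10 &
                fits$distribution == "gamma", ]
  expect_false(is.na(big$shape))
  expect_equal(big$cv, big$shape^(-0.5), tolerance = 1e-12)
})
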