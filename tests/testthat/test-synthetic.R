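small_spec <- function(...) {
  synth_spec(n_subjects = 2, n_channels = 2, epochs_per_condition = 2,
             epoch_duration = 10, ...)
}

test_that("generation is bit-identical under a fixed seed", {
  s1 <- generate_eeg(small_spec(seed = 5))
  s2 <- generate_eeg(small_spec(seed = 5))
  expect_identical(s1[[1]]$data, s2[[1]]$data)
  expect_identical(s1[[2]]$data, s2[[2]]$data)
  s3 <- generate_eeg(small_spec(seed = 6))
  expect_false(identical(s1[[1]]$data, s3[[1]]$data))
  # conditions alternate
  expect_equal(s1[[1]]$conditions,
               rep(c("eyes_closed", "eyes_open"), 2))
})

test_that("spec invariants are enforced", {
  expect_error(small_spec(effect_channels = 5), "index existing")
  expect_error(synth_spec(sampling_rate = 30), "twice the highest")
  expect_error(small_spec(burst_shape = -1))
})

test_that("gamma sample generator matches the moment formulas", {
  x <- generate_gamma_sample(3, 15, 1e6, seed = 11)
  expect_equal(mean(x), 45, tolerance = 0.5 / 45)
  expect_equal(var(x), 675, tolerance = 0.03)
  expect_identical(x[1:10], generate_gamma_sample(3, 15, 1e6, seed = 11)[1:10])
  # shape 1 is exponential: Q-Q against exponential quantiles is linear
  e <- generate_gamma_sample(1, 20, 20000, seed = 12)
  qq <- qexp(ppoints(length(e)), rate = 1 / 20)
  r2 <- cor(sort(e), qq)^2
  expect_gt(r2, 0.999)
})

test_that("background PSD slope tracks the requested exponent", {
  for (target in c(1, 1.6)) {
    slopes <- vapply(1:8, function(i) {
      set.seed(400 + i)
      x <- onef_noise(10000, 500, target)
      pg <- spec.pgram(ts(x, frequency = 500), plot = FALSE, taper = 0,
                       detrend = FALSE)
      keep <- pg$freq >= 2 & pg$freq <= 50
      -coef(lm(log(pg$spec[keep]) ~ log(pg$freq[keep])))[2]
    }, numeric(1))
    expect_lt(abs(mean(slopes) - target) / target, 0.15)
  }
})

test_that("preprocessing trims, demeans and suppresses the notch band", {
  fs <- 500
  tt <- seq(1 / fs, 30, by = 1 / fs)
  x <- sin(2 * pi * 10 * tt) + sin(2 * pi * 60 * tt) + 5
  rec <- epoched_recording(matrix(x, nrow = 1), fs, conditions = "a")
  out <- preprocess_epochs(rec, band = c(0.5, 120), notch = 60,
                           trim = c(5, 25))
  expect_equal(dim(out$data)[2], 20 * fs)
  expect_lt(abs(mean(out$data[1, , 1])), 1e-9)
  # regress the processed mid-epoch signal on 60 Hz quadrature pair
  y <- out$data[1, , 1]
  t2 <- seq_along(y) / fs
  amp60 <- function(v) {
    fit <- lm(v ~ sin(2 * pi * 60 * t2) + cos(2 * pi * 60 * t2))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  expect_lt(20 * log10(amp60(y) / 1), -20)  # > 20 dB down from unit input
  # the pass-band survives
  fit10 <- lm(y ~ sin(2 * pi * 10 * t2) + cos(2 * pi * 10 * t2))
  expect_gt(sqrt(sum(coef(fit10)[2:3]^2)), 0.5)
  # epochs shorter than the trim window are rejected
  short <- epoched_recording(matrix(rnorm(fs * 8), nrow = 1), fs, "a")
  expect_error(preprocess_epochs(short, trim = c(5, 25)), "trim window")
})

test_that("a null effect leaves conditions statistically indistinguishable", {
  sp <- synth_spec(n_subjects = 6, n_channels = 2, epochs_per_condition = 4,
                   epoch_duration = 20, effect_magnitude = 0, seed = 77)
  study <- preprocess_epochs(generate_eeg(sp), trim = NULL)
  fits <- fit_idt_cells(extract_idt_table(study), distributions = "gamma",
                        gof = FALSE)
  g <- fits[!is.na(fits$shape), ]
  cells <- unique(g[, c("channel", "frequency_hz")])
  pvals <- apply(cells, 1, function(cell) {
    sub <- g[g$channel == cell[1] & g$frequency_hz == as.numeric(cell[2]), ]
    w <- reshape(sub[, c("subject", "condition", "shape")],
                 idvar = "subject", timevar = "condition",
                 direction = "wide")
    t.test(w[[2]], w[[3]], paired = TRUE)$p.value
  })
  expect_gte(mean(pvals > 0.01), 0.9)
})
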