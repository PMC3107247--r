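test_that("trough detection handles edge cases of the definition", {
  # strictly monotone: no interior minima
  expect_length(detect_departures(1:10)$events, 0)
  # constant series: empty train, no error
  expect_length(detect_departures(rep(2, 10))$events, 0)
  expect_error(detect_departures(c(1, NaN, 1)), "finite")
  expect_error(detect_departures(c(1, 2)), "3 samples")
  expect_error(detect_departures(1:10, threshold_ratio = 1), "\\[0, 1\\)")

  # worked example: the 4.9 dip has prominence 0.1 = 2.5% of range, below 5%
  expect_equal(detect_departures(c(5, 1, 5, 4.9, 5, 1, 5), 0.05)$events,
               c(2L, 6L))
  # at 2% the shallow dip is kept
  expect_equal(detect_departures(c(5, 1, 5, 4.9, 5, 1, 5), 0.02)$events,
               c(2L, 4L, 6L))

  # plateau of equal minima yields one event at the midpoint (rounded down)
  expect_equal(detect_departures(c(5, 1, 1, 1, 5))$events, 3L)
  expect_equal(detect_departures(c(5, 1, 1, 5))$events, 2L)
  # plateaus touching the series ends are not events
  expect_equal(detect_departures(c(1, 1, 5, 0, 5))$events, 4L)
})

test_that("detector agrees exactly with the brute-force prominence oracle", {
  set.seed(101)
  for (i in 1:100) {
    x <- random_series(300, i)
    for (thr in c(0, 0.02, 0.05, 0.2)) {
      expect_identical(detect_departures(x, thr)$events,
                       as.integer(oracle_troughs(x, thr)))
    }
  }
  # including series with exact ties / plateaus
  set.seed(5)
  for (i in 1:50) {
    x <- sample(0:6, 80, replace = TRUE)
    expect_identical(detect_departures(x, 0.05)$events,
                     as.integer(oracle_troughs(x, 0.05)))
  }
})

test_that("event count is non-increasing in the threshold", {
  set.seed(11)
  thresholds <- c(0, 0.02, 0.05, 0.1, 0.3)
  for (i in 1:20) {
    x <- random_series(400, i)
    counts <- vapply(thresholds,
                     function(t) length(detect_departures(x, t)$events),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("inter-departure times difference successive events", {
  s <- inter_departure_times(c(10, 30, 35))
  expect_equal(s$intervals, c(20, 5))
  expect_equal(s$n, 2L)
  expect_equal(inter_departure_times(c(0, 1))$intervals, 1)
  expect_error(inter_departure_times(c(7)), "at least 2")
  expect_error(inter_departure_times(c(5, 3)), "increasing")
  # equally spaced events: zero dispersion
  iv <- inter_departure_times(seq(1, 100, by = 3))$intervals
  expect_true(all(iv == 3))
  expect_equal(sd(iv) / mean(iv), 0)
  # conversion to ms at 500 Hz
  expect_equal(idt_ms(s, 0.002), c(40, 10))
})

test_that("amplitude-modulated oscillation yields the modulation period", {
  # 10 Hz carrier, envelope cycling every 0.4 s: departures at the matching
  # scale should recover the 200-sample envelope period
  dt <- 1 / 500
  tt <- seq(dt, 20, by = dt)
  x <- (1 + sin(2 * pi * 2.5 * tt)) * sin(2 * pi * 10 * tt)
  rec <- epoched_recording(matrix(x, nrow = 1), 500, conditions = "a",
                           subject = "s1")
  idt <- extract_idt_table(rec)
  tau <- idt$tau_samples[idt$frequency_hz == 10]
  expect_gt(length(tau), 10)
  expect_lt(abs(mean(tau) - 200) / 200, 0.2)
})

test_that("intervals pool across epochs without spanning boundaries", {
  dt <- 1 / 500
  tt <- seq(dt, 20, by = dt)
  x <- (1 + sin(2 * pi * 2.5 * tt)) * sin(2 * pi * 10 * tt)
  one <- epoched_recording(matrix(x, nrow = 1), 500, conditions = "a")
  two <- epoched_recording(array(c(x, x), dim = c(1, length(x), 2)), 500,
                           conditions = c("a", "a"))
  idt1 <- extract_idt_table(one)
  idt2 <- extract_idt_table(two)
  n1 <- table(idt1$frequency_hz)
  n2 <- table(idt2$frequency_hz)
  # two identical epochs give exactly twice the per-epoch intervals: the
  # inter-epoch gap contributes nothing
  expect_equal(as.vector(n2[names(n1)]), 2 * as.vector(n1))
  expect_identical(sort(unique(idt2$tau_samples[idt2$frequency_hz == 10])),
                   sort(unique(idt1$tau_samples[idt1$frequency_hz == 10])))
})
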