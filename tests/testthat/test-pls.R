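test_that("the 99% bootstrap-ratio cutoff reproduces the 2.57 convention", {
  expect_identical(bootstrap_ratio_cutoff(), 2.57)
  expect_identical(bootstrap_ratio_cutoff(0.95), 1.95)
})

test_that("dataset assembly stacks condition blocks in canonical order", {
  tb <- expand.grid(subject = c("s3", "s1", "s2"),
                    condition = c("open", "closed"),
                    channel = c("cz", "oz"),
                    frequency_hz = c(10, 20),
                    stringsAsFactors = FALSE)
  tb$shape <- seq_len(nrow(tb)) / 10
  ds <- build_pls_dataset(tb, "shape")
  expect_equal(dim(ds$X), c(6, 4))
  expect_equal(ds$subjects, c("s1", "s2", "s3"))
  expect_equal(ds$conditions, c("closed", "open"))
  expect_equal(ds$elements$channel, c("cz", "cz", "oz", "oz"))
  expect_equal(ds$elements$frequency_hz, c(10, 20, 10, 20))
  # row 1 is (closed, s1), element 1 is (cz, 10)
  expect_equal(ds$X[1, 1],
               tb$shape[tb$subject == "s1" & tb$condition == "closed" &
                          tb$channel == "cz" & tb$frequency_hz == 10])
  # column ordering is invariant to input row order
  ds2 <- build_pls_dataset(tb[sample(nrow(tb)), ], "shape")
  expect_identical(ds$X, ds2$X)
  # round-trip: every table value sits in its cell
  for (r in seq_len(nrow(tb))) {
    i <- (match(tb$condition[r], ds$conditions) - 1L) * 3 +
      match(tb$subject[r], ds$subjects)
    j <- which(ds$elements$channel == tb$channel[r] &
                 ds$elements$frequency_hz == tb$frequency_hz[r])
    expect_equal(ds$X[i, j], tb$shape[r])
  }
})

test_that("incomplete designs are rejected with the subjects named", {
  tb <- expand.grid(subject = c("s1", "s2"), condition = c("a", "b"),
                    channel = "cz", frequency_hz = 10,
                    stringsAsFactors = FALSE)
  tb$shape <- 1:4
  err <- expect_error(build_pls_dataset(tb[-2, ], "shape"), "missing")
  expect_match(conditionMessage(err), "s2")
})

test_that("a single-element contrast concentrates the salience there", {
  S <- 8
  set.seed(3)
  X1 <- matrix(rnorm(S * 5, sd = 1e-6), S, 5) + 10
  X2 <- X1
  X2[, 1] <- X2[, 1] + 4
  ds <- pls_dataset(rbind(X1, X2), S, 2)
  res <- mean_centered_pls(ds)
  expect_length(res$singular_values, 1)  # 2 conditions -> 1 LV
  expect_gt(res$singular_values[1], 0)
  v <- res$element_saliences[, 1]
  expect_gt(abs(v[1]) / sqrt(sum(v^2)), 0.99)
  expect_equal(sum(res$effect_sizes), 1, tolerance = 1e-12)
})

test_that("identical condition means give all-zero singular values", {
  S <- 6
  X <- matrix(rnorm(S * 4), S, 4)
  ds <- pls_dataset(rbind(X, X), S, 2)
  res <- mean_centered_pls(ds)
  expect_true(res$degenerate)
  expect_equal(res$singular_values, 0)
})

test_that("multi-condition decomposition is orthonormal and reconstructs", {
  set.seed(21)
  S <- 10; C <- 4; P <- 7
  X <- matrix(rnorm(S * C * P), S * C, P) +
    rep(rnorm(C, sd = 2), each = S)  # condition offsets
  ds <- pls_dataset(X, S, C)
  res <- mean_centered_pls(ds)
  L <- length(res$singular_values)
  expect_equal(L, C - 1)
  U <- res$design_saliences
  V <- res$element_saliences
  expect_equal(crossprod(U), diag(L), tolerance = 1e-8)
  expect_equal(crossprod(V), diag(L), tolerance = 1e-8)
  expect_equal(U %*% diag(res$singular_values, L) %*% t(V),
               res$centered_means, tolerance = 1e-8)
  expect_equal(sum(res$effect_sizes), 1, tolerance = 1e-12)
  expect_true(all(diff(res$singular_values) <= 0))
})

test_that("permutation p-values detect a strong paired effect", {
  ds <- make_effect_dataset(20, 24, affected = 1:6, delta = 2, seed = 8)
  pt <- permutation_test(ds, n_permutations = 200, seed = 4)
  expect_lte(pt$p[1], 0.005)
  # p is invariant to global positive rescaling
  ds2 <- ds
  ds2$X <- 3.7 * ds$X
  pt2 <- permutation_test(ds2, n_permutations = 200, seed = 4)
  expect_identical(pt$p, pt2$p)
  # plus-one estimator never returns exactly zero
  pt3 <- permutation_test(ds, n_permutations = 50, seed = 4, plus_one = TRUE)
  expect_gte(pt3$p[1], 1 / 51)
})

test_that("null data yield roughly uniform permutation p-values", {
  set.seed(60)
  p1 <- vapply(1:40, function(i) {
    ds <- make_effect_dataset(12, 8, delta = 0, seed = 6000 + i)
    permutation_test(ds, n_permutations = 100, seed = i)$p[1]
  }, numeric(1))
  # fraction below 0.05 stays near the nominal level
  expect_lt(mean(p1 < 0.05), 0.2)
  expect_gt(mean(p1 > 0.3), 0.3)
})

test_that("bootstrap ratios recover injected elements and respect pairing", {
  ds <- make_effect_dataset(20, 24, affected = 1:6, delta = 2, seed = 15)
  bs <- bootstrap_saliences(ds, n_bootstraps = 300, seed = 2)
  expect_gte(mean(bs$reliable[1:6, 1]), 0.9)
  expect_lte(mean(bs$reliable[7:24, 1]), 0.15)
  # ratios are invariant to an overall sign flip of the LV (condition swap)
  S <- ds$n_subjects
  ds_sw <- pls_dataset(ds$X[c((S + 1):(2 * S), 1:S), ], S, 2)
  bs_sw <- bootstrap_saliences(ds_sw, n_bootstraps = 300, seed = 2)
  expect_equal(abs(bs$bootstrap_ratios), abs(bs_sw$bootstrap_ratios),
               tolerance = 1e-8)
  expect_identical(bs$reliable, bs_sw$reliable)
})

test_that("degenerate subjects trigger the zero-SE sentinel", {
  S <- 5
  one <- matrix(rep(c(1, 2, 3, 4), each = S), S, 4)
  ds <- pls_dataset(rbind(one, one + matrix(rep(c(1, 0, 0, 0), each = S),
                                            S, 4)), S, 2)
  expect_warning(bs <- bootstrap_saliences(ds, n_bootstraps = 20, seed = 1),
                 "zero bootstrap SE")
  expect_true(any(is.infinite(bs$bootstrap_ratios)))
})

test_that("task_pls bundles resampling results deterministically", {
  ds <- make_effect_dataset(10, 6, affected = 1:2, delta = 1.5, seed = 44)
  r1 <- task_pls(ds, n_permutations = 100, n_bootstraps = 100, seed = 7)
  r2 <- task_pls(ds, n_permutations = 100, n_bootstraps = 100, seed = 7)
  expect_identical(r1$permutation_p, r2$permutation_p)
  expect_identical(r1$bootstrap_ratios, r2$bootstrap_ratios)
  expect_equal(r1$reliability_threshold, 2.57)
  tabs <- pls_tables(r1)
  expect_named(tabs, c("lv", "saliences"))
  expect_equal(nrow(tabs$saliences), 6)
})
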