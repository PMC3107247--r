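# Mean-centered task PLS relating paired experimental conditions to
# channel-by-frequency parameter maps, with permutation significance and
# bootstrap salience reliability.

#' Two-sided normal bootstrap-ratio cutoff
#'
#' The reliability cutoff for bootstrap ratios at a given two-sided
#' confidence level, under the assumption that the bootstrap distribution of
#' a salience is unit normal. The conventional 99% value is quoted in the
#' PLS literature as 2.57, which is the normal critical value
#' \eqn{\Phi^{-1}(0.995) = 2.5758\ldots} truncated (not rounded) at two
#' decimals; this function reproduces that convention.
#'
#' @param conf Two-sided confidence level (default 0.99).
#' @return The cutoff, truncated at two decimals.
#' @examples
#' bootstrap_ratio_cutoff()  # 2.57
#' @export
bootstrap_ratio_cutoff <- function(conf = 0.99) {
  stopifnot(conf > 0, conf < 1)
  floor(stats::qnorm(1 - (1 - conf) / 2) * 100) / 100
}

#' Assemble a PLS dataset from a per-cell fit table
#'
#' Builds the observations-by-elements matrix analyzed by
#' [mean_centered_pls()]: rows are subject-within-condition observations
#' stacked by condition block (condition 1 subjects first, in sorted subject
#' order identical across blocks), columns are (channel, frequency) elements
#' in canonical sorted order. One Gamma parameter (shape or scale) is
#' analyzed at a time.
#'
#' @param fit_table Result of [fit_idt_cells()] (Gamma rows are used), or
#'   any data.frame with columns `subject`, `condition`, `channel`,
#'   `frequency_hz` and the chosen parameter.
#' @param parameter `"shape"` or `"scale"`.
#' @return An object of class `pls_dataset`.
#' @export
build_pls_dataset <- function(fit_table, parameter = c("shape", "scale")) {
  parameter <- match.arg(parameter)
  tb <- fit_table
  if ("distribution" %in% names(tb)) tb <- tb[tb$distribution == "gamma", ]
  if (!nrow(tb)) stop("no gamma rows in `fit_table`", call. = FALSE)
  subjects <- sort(unique(tb$subject))
  conditions <- sort(unique(tb$condition))
  if (length(conditions) < 2L) {
    stop("need at least 2 conditions", call. = FALSE)
  }
  present <- table(tb$subject, tb$condition) > 0
  incomplete <- rownames(present)[rowSums(present) < length(conditions)]
  if (length(incomplete)) {
    stop("subjects missing a condition: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  elements <- unique(tb[, c("channel", "frequency_hz")])
  elements <- elements[order(elements$channel, elements$frequency_hz), ,
                       drop = FALSE]
  rownames(elements) <- NULL
  S <- length(subjects)
  C <- length(conditions)
  P <- nrow(elements)
  X <- matrix(NA_real_, nrow = S * C, ncol = P)
  ekey <- paste(tb$channel, tb$frequency_hz, sep = "\r")
  col_of <- match(ekey, paste(elements$channel, elements$frequency_hz,
                              sep = "\r"))
  row_of <- (match(tb$condition, conditions) - 1L) * S +
    match(tb$subject, subjects)
  vals <- tb[[parameter]]
  X[cbind(row_of, col_of)] <- vals
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    stop(sprintf(paste0("%d empty (subject, condition, element) cells; ",
                        "impute or drop them upstream"), nrow(bad)),
         call. = FALSE)
  }
  pls_dataset(X, n_subjects = S, n_conditions = C, subjects = subjects,
              conditions = conditions, elements = elements,
              parameter = parameter)
}

#' Construct a PLS dataset from a matrix
#'
#' @param X Numeric matrix; rows are subject-within-condition observations
#'   stacked by condition block (all subjects of condition 1, then condition
#'   2, ...; subject order identical across blocks), columns are elements.
#' @param n_subjects,n_conditions Block structure; `nrow(X)` must equal
#'   their product.
#' @param subjects,conditions,elements Optional labels.
#' @param parameter Optional name of the analyzed parameter.
#' @return An object of class `pls_dataset`.
#' @export
pls_dataset <- function(X, n_subjects, n_conditions, subjects = NULL,
                        conditions = NULL, elements = NULL,
                        parameter = NA_character_) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) {
    stop("`X` must be finite with no missing values", call. = FALSE)
  }
  if (nrow(X) != n_subjects * n_conditions) {
    stop("nrow(X) must equal n_subjects * n_conditions", call. = FALSE)
  }
  if (is.null(subjects)) subjects <- sprintf("s%02d", seq_len(n_subjects))
  if (is.null(conditions)) conditions <- sprintf("c%d", seq_len(n_conditions))
  if (is.null(elements)) {
    elements <- data.frame(channel = sprintf("e%03d", seq_len(ncol(X))),
                           frequency_hz = NA_real_,
                           stringsAsFactors = FALSE)
  }
  structure(
    list(X = X, n_subjects = as.integer(n_subjects),
         n_conditions = as.integer(n_conditions),
         subjects = subjects, conditions = conditions,
         elements = elements, parameter = parameter),
    class = "pls_dataset"
  )
}

#' @export
print.pls_dataset <- function(x, ...) {
  cat(sprintf("PLS dataset: %d subjects x %d conditions x %d elements (%s)\n",
              x$n_subjects, x$n_conditions, ncol(x$X),
              ifelse(is.na(x$parameter), "unnamed parameter", x$parameter)))
  invisible(x)
}

# Condition-mean matrix (conditions x elements) of a stacked data matrix.
condition_means <- function(X, S, C) {
  M <- matrix(0, nrow = C, ncol = ncol(X))
  for (c. in seq_len(C)) {
    M[c., ] <- colMeans(X[((c. - 1L) * S + 1L):(c. * S), , drop = FALSE])
  }
  M
}

# Core decomposition: grand-mean-centered condition means, SVD, first
# n_conditions - 1 latent variables.
pls_svd <- function(X, S, C) {
  M <- condition_means(X, S, C)
  centered <- sweep(M, 2, colMeans(M))
  sv <- svd(centered)
  L <- min(C - 1L, ncol(X))
  list(singular_values = sv$d[seq_len(L)],
       design_saliences = sv$u[, seq_len(L), drop = FALSE],
       element_saliences = sv$v[, seq_len(L), drop = FALSE],
       centered = centered)
}

#' Mean-centered task PLS decomposition
#'
#' Computes the condition-mean matrix (conditions by elements), centers each
#' column by the grand mean of the condition means, and decomposes the
#' result by singular value decomposition. Each latent variable (LV) pairs a
#' vector of design saliences (one per condition) with a vector of element
#' saliences (one per channel-frequency element) and a singular value `s`;
#' the effect size of an LV is \eqn{s_i^2 / \sum_j s_j^2}. After centering
#' at most `n_conditions - 1` informative LVs exist, and only those are
#' returned.
#'
#' @param dataset A `pls_dataset`.
#' @return An object of class `pls_result` with `singular_values`,
#'   `design_saliences`, `element_saliences`, `effect_sizes`, `elements`,
#'   `conditions` and `degenerate` (`TRUE` when all condition means are
#'   identical so every singular value is 0).
#' @export
mean_centered_pls <- function(dataset) {
  stopifnot(inherits(dataset, "pls_dataset"))
  if (dataset$n_conditions < 2L) {
    stop("need at least 2 conditions", call. = FALSE)
  }
  dec <- pls_svd(dataset$X, dataset$n_subjects, dataset$n_conditions)
  d2 <- dec$singular_values^2
  degenerate <- sum(d2) == 0
  effect_sizes <- if (degenerate) rep(0, length(d2)) else d2 / sum(d2)
  structure(
    list(singular_values = dec$singular_values,
         design_saliences = dec$design_saliences,
         element_saliences = dec$element_saliences,
         effect_sizes = effect_sizes,
         centered_means = dec$centered,
         elements = dataset$elements,
         conditions = dataset$conditions,
         parameter = dataset$parameter,
         degenerate = degenerate),
    class = "pls_result"
  )
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("Mean-centered task PLS (%s): %d LV(s)\n",
              ifelse(is.na(x$parameter), "unnamed parameter", x$parameter),
              length(x$singular_values)))
  for (l in seq_along(x$singular_values)) {
    cat(sprintf("  LV%d: s = %.4g, effect size = %.3f%s\n", l,
                x$singular_values[l], x$effect_sizes[l],
                if (!is.null(x$permutation_p))
                  sprintf(", perm p = %.4g", x$permutation_p[l]) else ""))
  }
  invisible(x)
}

#' Permutation test of PLS latent variables
#'
#' Each permuted sample reassigns the order of conditions within every
#' participant independently (sampling without replacement of that
#' subject's condition labels), preserving the paired design. The p-value of
#' an LV is the proportion of permuted singular values at the same LV
#' position that equal or exceed the observed one; with
#' `plus_one = TRUE` the (b + 1) / (n + 1) estimator is used instead.
#'
#' @param dataset A `pls_dataset`.
#' @param n_permutations Number of replications (default 500).
#' @param seed Explicit RNG seed.
#' @param plus_one Use the (b + 1) / (n + 1) p-value estimator (default
#'   `FALSE`, plain proportion).
#' @return List with `p` (per-LV p-values), `observed` singular values,
#'   `permuted` (matrix, replications by LV) and `n_permutations`.
#' @export
permutation_test <- function(dataset, n_permutations = 500, seed = 1,
                             plus_one = FALSE) {
  stopifnot(inherits(dataset, "pls_dataset"))
  if (n_permutations < 1) stop("`n_permutations` must be >= 1", call. = FALSE)
  S <- dataset$n_subjects
  C <- dataset$n_conditions
  obs <- pls_svd(dataset$X, S, C)$singular_values
  L <- length(obs)
  permuted <- with_seed(seed, {
    pm <- vapply(seq_len(n_permutations), function(b) {
      Xp <- dataset$X
      for (i in seq_len(S)) {
        perm <- sample.int(C)
        rows <- (seq_len(C) - 1L) * S + i
        Xp[rows, ] <- dataset$X[(perm - 1L) * S + i, , drop = FALSE]
      }
      pls_svd(Xp, S, C)$singular_values
    }, numeric(L))
    if (is.matrix(pm)) t(pm) else matrix(pm, ncol = 1L)
  })
  exceed <- colSums(permuted >= matrix(obs, n_permutations, L, byrow = TRUE))
  p <- if (plus_one) (exceed + 1) / (n_permutations + 1)
       else exceed / n_permutations
  list(p = p, observed = obs, permuted = permuted,
       n_permutations = as.integer(n_permutations))
}

#' Bootstrap standard errors and reliability of element saliences
#'
#' Each replication resamples participants with replacement, applying the
#' same resampled subjects to every condition block so the pairing is
#' preserved, and recomputes the PLS decomposition. Because an LV's sign is
#' arbitrary, each bootstrap LV is sign-aligned to the original element
#' saliences (per-LV flip maximizing their inner product) before standard
#' errors are accumulated. The bootstrap ratio of an element is its original
#' salience divided by the bootstrap SE; an element is deemed reliable when
#' the absolute ratio reaches `threshold` (default 2.57, the two-sided 99%
#' normal cutoff, see [bootstrap_ratio_cutoff()]).
#'
#' @param dataset A `pls_dataset`.
#' @param n_bootstraps Number of replications (default 500).
#' @param seed Explicit RNG seed.
#' @param threshold Reliability cutoff on the absolute bootstrap ratio.
#' @return List with `bootstrap_ratios` (elements by LV), `se`, `reliable`
#'   (logical matrix), `threshold` and `n_bootstraps`. Elements with zero
#'   bootstrap SE get an infinite ratio and a warning.
#' @export
bootstrap_saliences <- function(dataset, n_bootstraps = 500, seed = 1,
                                threshold = bootstrap_ratio_cutoff()) {
  stopifnot(inherits(dataset, "pls_dataset"))
  if (n_bootstraps < 2) stop("`n_bootstraps` must be >= 2", call. = FALSE)
  S <- dataset$n_subjects
  C <- dataset$n_conditions
  orig <- pls_svd(dataset$X, S, C)
  V <- orig$element_saliences
  L <- ncol(V)
  P <- nrow(V)
  acc <- array(NA_real_, dim = c(n_bootstraps, P, L))
  with_seed(seed, {
    for (b in seq_len(n_bootstraps)) {
      idx <- sample.int(S, replace = TRUE)
      rows <- as.vector(outer(idx, (seq_len(C) - 1L) * S, `+`))
      Vb <- pls_svd(dataset$X[rows, , drop = FALSE], S, C)$element_saliences
      for (l in seq_len(L)) {
        sgn <- sign(sum(Vb[, l] * V[, l]))
        if (sgn == 0) sgn <- 1
        acc[b, , l] <- Vb[, l] * sgn
      }
    }
  })
  se <- apply(acc, c(2, 3), stats::sd)
  ratios <- V / se
  if (any(se == 0)) {
    warning("zero bootstrap SE at some elements; ratios reported as +/-Inf")
    ratios[se == 0] <- ifelse(V[se == 0] >= 0, Inf, -Inf)
  }
  list(bootstrap_ratios = ratios, se = se,
       reliable = abs(ratios) >= threshold,
       threshold = threshold, n_bootstraps = as.integer(n_bootstraps))
}

#' Full mean-centered task PLS with resampling
#'
#' Convenience wrapper running [mean_centered_pls()], [permutation_test()]
#' and [bootstrap_saliences()] with separate RNG substreams derived from one
#' seed.
#'
#' @inheritParams mean_centered_pls
#' @param n_permutations,n_bootstraps Replication counts (default 500 each).
#' @param seed Master seed.
#' @param threshold Bootstrap-ratio reliability cutoff.
#' @return A `pls_result` whose fields additionally include
#'   `permutation_p`, `bootstrap_ratios`, `bootstrap_se`, `reliable`,
#'   `reliability_threshold`, `n_permutations`, `n_bootstraps`.
#' @export
task_pls <- function(dataset, n_permutations = 500, n_bootstraps = 500,
                     seed = 1, threshold = bootstrap_ratio_cutoff()) {
  res <- mean_centered_pls(dataset)
  perm <- permutation_test(dataset, n_permutations,
                           seed = derive_seed(seed, 1L))
  boot <- bootstrap_saliences(dataset, n_bootstraps,
                              seed = derive_seed(seed, 2L),
                              threshold = threshold)
  res$permutation_p <- perm$p
  res$bootstrap_ratios <- boot$bootstrap_ratios
  res$bootstrap_se <- boot$se
  res$reliable <- boot$reliable
  res$reliability_threshold <- threshold
  res$n_permutations <- perm$n_permutations
  res$n_bootstraps <- boot$n_bootstraps
  res
}

#' Tabular summaries of a PLS result
#'
#' @param result A `pls_result` (from [task_pls()] for resampling columns).
#' @return List of two data.frames: `lv` (LV, singular value, effect size,
#'   permutation p) and `saliences` (channel, frequency, per-LV salience,
#'   bootstrap ratio and reliable flag for LV1).
#' @export
pls_tables <- function(result) {
  stopifnot(inherits(result, "pls_result"))
  lv <- data.frame(lv = seq_along(result$singular_values),
                   singular_value = result$singular_values,
                   effect_size = result$effect_sizes,
                   permutation_p = if (!is.null(result$permutation_p))
                     result$permutation_p else NA_real_)
  sal <- data.frame(channel = result$elements$channel,
                    frequency_hz = result$elements$frequency_hz,
                    salience = result$element_saliences[, 1],
                    stringsAsFactors = FALSE)
  if (!is.null(result$bootstrap_ratios)) {
    sal$bootstrap_ratio <- result$bootstrap_ratios[, 1]
    sal$reliable <- result$reliable[, 1]
  }
  list(lv = lv, saliences = sal)
}
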