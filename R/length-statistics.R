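#' Two-tailed Welch's t-test from first principles
#'
#' Location test for two groups of per-larva means without assuming equal
#' variances: `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)`, degrees
#' of freedom by the Welch-Satterthwaite approximation, two-tailed p from
#' the t distribution.
#'
#' @param a,b Numeric vectors of per-larva means (each of length >= 2), or
#'   lists with elements `label` and `values`.
#' @return A `welch_test`: list with `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
welch_t <- function(a, b) {
  a <- .group_values(a); b <- .group_values(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("group values must be finite", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  md <- mean(a) - mean(b)
  if (se2 == 0) {
    if (md == 0) {
      stop("both groups have zero variance and equal means; the statistic is undefined",
           call. = FALSE)
    }
    warning("both groups have zero variance; means differ, so p -> 0")
    return(structure(list(t = sign(md) * Inf, df = na + nb - 2, p = 0,
                          mean_a = mean(a), mean_b = mean(b),
                          n_a = na, n_b = nb), class = "welch_test"))
  }
  tt <- md / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  structure(list(t = tt, df = df, p = p, mean_a = mean(a), mean_b = mean(b),
                 n_a = na, n_b = nb), class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.5g, df = %.5g, p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

.group_values <- function(g) {
  if (is.list(g) && !is.null(g$values)) as.numeric(g$values) else as.numeric(g)
}

.group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups) |
                    c("group", "mean_top5_um") %in% names(groups)))
    vcol <- if ("value" %in% names(groups)) "value" else "mean_top5_um"
    split(groups[[vcol]], groups$group)
  } else {
    lapply(groups, .group_values)
  }
}

#' One-way ANOVA from the sum-of-squares decomposition
#'
#' `F = MS_between / MS_within` with `df1 = k - 1` and `df2 = N - k`
#' degrees of freedom, computed directly from the between/within
#' sum-of-squares decomposition of the per-larva means.
#'
#' @param groups Named list of numeric vectors, or a data.frame with
#'   columns `group` and `value` (or `mean_top5_um`).
#' @return An `anova_result`: list with `F`, `df1`, `df2`, `p`,
#'   `ss_between`, `ss_within`, `group_means`, `n`.
#' @export
anova_oneway <- function(groups) {
  gl <- .group_list(groups)
  k <- length(gl)
  ns <- vapply(gl, length, 1L)
  N <- sum(ns)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (N <= k) stop("need more observations than groups", call. = FALSE)
  gm <- vapply(gl, mean, 0)
  grand <- sum(ns * gm) / N
  ssb <- sum(ns * (gm - grand)^2)
  ssw <- sum(vapply(gl, function(v) sum((v - mean(v))^2), 0))
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) {
      f <- 0; p <- 1
    } else {
      warning("zero within-group variance everywhere; F is infinite")
      f <- Inf; p <- 0
    }
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = f, df1 = df1, df2 = df2, p = p,
                 ss_between = ssb, ss_within = ssw,
                 group_means = gm, n = ns),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Adjusted pairwise comparisons after ANOVA
#'
#' All `k(k-1)/2` group pairs. `"tukey"` (default) uses the Tukey honest
#' significant difference: the studentized range statistic
#' `q = |diff| / sqrt(MSE/2 * (1/n_i + 1/n_j))` referred to the
#' studentized-range distribution with `k` groups and `N - k` error
#' degrees of freedom (Tukey-Kramer for unequal n). `"holm"` runs pairwise
#' Welch tests with Holm step-down adjustment, which drops the
#' equal-variance assumption.
#'
#' @inheritParams anova_oneway
#' @param method `"tukey"` or `"holm"`.
#' @return Data.frame with columns `pair`, `estimate` (difference of
#'   means), `padj`.
#' @export
pairwise_adjusted <- function(groups, method = c("tukey", "holm")) {
  if (is.character(method) && !all(method %in% c("tukey", "holm"))) {
    stop(sprintf("unknown adjustment method '%s'", method[1]), call. = FALSE)
  }
  method <- match.arg(method)
  gl <- .group_list(groups)
  k <- length(gl)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  labs <- names(gl)
  if (is.null(labs)) labs <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  est <- apply(pairs, 2, function(ij) mean(gl[[ij[2]]]) - mean(gl[[ij[1]]]))
  pair_lab <- apply(pairs, 2, function(ij) paste(labs[ij[2]], labs[ij[1]], sep = "-"))
  if (method == "tukey") {
    ns <- vapply(gl, length, 1L)
    N <- sum(ns)
    mse <- sum(vapply(gl, function(v) sum((v - mean(v))^2), 0)) / (N - k)
    padj <- vapply(seq_len(ncol(pairs)), function(j) {
      ij <- pairs[, j]
      se <- sqrt(mse / 2 * (1 / ns[ij[1]] + 1 / ns[ij[2]]))
      if (se == 0) return(if (est[j] == 0) 1 else 0)
      stats::ptukey(abs(est[j]) / se, nmeans = k, df = N - k,
                    lower.tail = FALSE)
    }, 0)
  } else {
    praw <- vapply(seq_len(ncol(pairs)), function(j) {
      welch_t(gl[[pairs[1, j]]], gl[[pairs[2, j]]])$p
    }, 0)
    padj <- stats::p.adjust(praw, method = "holm")
  }
  data.frame(pair = pair_lab, estimate = est, padj = padj,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical type-I error of the Welch test under the null
#'
#' Simulates `reps` pairs of standard-normal groups of size `n_per_group`
#' and reports the fraction of two-tailed Welch tests rejecting at level
#' `alpha` -- a self-check that the implementation holds its nominal size.
#'
#' @param n_per_group Group size (>= 2).
#' @param reps Number of null replicates (>= 1).
#' @param alpha Nominal level (default 0.05).
#' @param rng_seed Integer seed.
#' @return Rejection rate (fraction in `[0, 1]`).
#' @export
validate_type_i <- function(n_per_group, reps, alpha = 0.05, rng_seed = 1L) {
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  if (n_per_group < 2) stop("`n_per_group` must be >= 2", call. = FALSE)
  withr::with_seed(as.integer(rng_seed), {
    n <- n_per_group
    A <- matrix(stats::rnorm(reps * n), nrow = reps)
    B <- matrix(stats::rnorm(reps * n), nrow = reps)
    ma <- rowMeans(A); mb <- rowMeans(B)
    va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
    se2 <- va / n + vb / n
    tt <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / n)^2 / (n - 1) + (vb / n)^2 / (n - 1))
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    mean(p < alpha)
  })
}

#' Detection rate of a group deficit in a simulated length study design
#'
#' Repeatedly simulates per-larva mean lengths for several groups (normal
#' with common within-group standard deviation), runs [anova_oneway()] on
#' each replicate, and reports the fraction with `p < alpha`. Used to show
#' that, at the study's group sizes, a several-micrometre kinocilial
#' length deficit is detected essentially always.
#'
#' @param means Named numeric vector of true group means (um).
#' @param ns Integer vector of per-group larva counts (same length).
#' @param sd Common within-group standard deviation of per-larva means, um.
#' @param reps Number of simulated studies.
#' @param alpha Detection threshold on the ANOVA p-value.
#' @param rng_seed Integer seed.
#' @return Fraction of replicates with `p < alpha`.
#' @export
simulate_anova_power <- function(means, ns, sd = 1, reps = 1000,
                                 alpha = 0.001, rng_seed = 1L) {
  stopifnot(length(means) == length(ns), all(ns >= 2), sd >= 0, reps >= 1)
  withr::with_seed(as.integer(rng_seed), {
    hits <- vapply(seq_len(reps), function(r) {
      gl <- lapply(seq_along(means), function(i) {
        stats::rnorm(ns[i], means[i], sd)
      })
      names(gl) <- names(means)
      anova_oneway(gl)$p < alpha
    }, TRUE)
    mean(hits)
  })
}
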