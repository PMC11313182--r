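group_result <- function(statistic, estimate, sd, stat_value, df, p,
                         cohen_d, n, tail) {
  structure(list(statistic = statistic, estimate = estimate, sd = sd,
                 stat_value = stat_value, df = df, p = p,
                 cohen_d = cohen_d, n = n, tail = tail),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("%s: estimate = %.4g, %s = %.3f, df = %.4g, p = %.4g (%s), d = %.3f, n = %s\n",
              x$statistic, x$estimate,
              if (grepl("chi", x$statistic)) "chi2" else "t",
              x$stat_value, x$df, x$p, x$tail, x$cohen_d,
              paste(x$n, collapse = "/")))
  invisible(x)
}

tail_p <- function(t, df, tail) {
  switch(tail,
         two = 2 * stats::pt(-abs(t), df),
         greater = stats::pt(t, df, lower.tail = FALSE),
         less = stats::pt(t, df))
}

#' One-sample t test with Cohen's d
#'
#' `t = mean / (SD / sqrt(n))`, `df = n - 1`, `d = mean / SD`. The tail
#' convention is recorded in the result: directional hypotheses about
#' tracking or coupling use one-tailed p values.
#'
#' @param values numeric sample, `n >= 2`.
#' @param tail `"two"`, `"greater"`, or `"less"`.
#' @param mu null value; default 0.
#' @return A `group_result`.
#' @export
one_sample_t <- function(values, tail = c("two", "greater", "less"), mu = 0) {
  tail <- match.arg(tail)
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance sample", call. = FALSE)
  m <- mean(values) - mu
  t <- m / (s / sqrt(n))
  group_result("one_sample_t", mean(values), s, t, n - 1,
               tail_p(t, n - 1, tail), m / s, n, tail)
}

#' Two-sample t test (pooled or Welch) with Cohen's d
#'
#' Pooled: classical equal-variance t with `df = n1 + n2 - 2`. Welch:
#' unequal-variance t with Welch-Satterthwaite fractional df. The estimate
#' is `mean(groupA) - mean(groupB)`; Cohen's d uses the pooled SD for both
#' variants.
#'
#' @param groupA,groupB numeric samples, each `n >= 2`.
#' @param variant `"pooled"` or `"welch"`.
#' @param tail `"two"`, `"greater"`, or `"less"` (direction of A - B).
#' @return A `group_result`.
#' @export
two_sample_t <- function(groupA, groupB, variant = c("pooled", "welch"),
                         tail = c("two", "greater", "less")) {
  variant <- match.arg(variant); tail <- match.arg(tail)
  n1 <- length(groupA); n2 <- length(groupB)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values", call. = FALSE)
  v1 <- stats::var(groupA); v2 <- stats::var(groupB)
  if (v1 == 0 && v2 == 0) stop("zero variance in both groups", call. = FALSE)
  diff <- mean(groupA) - mean(groupB)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  d <- diff / sqrt(sp2)
  if (variant == "pooled") {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- diff / se
  group_result(paste0("two_sample_t_", variant), diff,
               c(sqrt(v1), sqrt(v2)), t, df, tail_p(t, df, tail), d,
               c(n1, n2), tail)
}

#' Two-sample t test from printed summary statistics
#'
#' Reconstructs each group as a moment-matched sample and delegates to
#' [two_sample_t()]; used to recompute published table rows from their
#' mean (SD) entries.
#'
#' @param m1,s1,n1 mean, SD, n of group A.
#' @param m2,s2,n2 mean, SD, n of group B.
#' @inheritParams two_sample_t
#' @return A `group_result`.
#' @export
two_sample_t_summary <- function(m1, s1, n1, m2, s2, n2,
                                 variant = c("pooled", "welch"),
                                 tail = "two") {
  two_sample_t(moment_matched_sample(n1, m1, s1),
               moment_matched_sample(n2, m2, s2),
               variant = variant, tail = tail)
}

#' Pearson chi-squared test for a 2 x 2 table
#'
#' Without continuity correction, `df = 1`.
#'
#' @param table 2 x 2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return A `group_result` (with `cohen_d = NA`).
#' @export
#' @examples
#' chi2_2x2(matrix(c(11, 10, 9, 12), 2, byrow = TRUE))
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(abs(table - round(table)) > 1e-9))
    stop("need a 2 x 2 table of nonnegative integer counts", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in 2 x 2 table", call. = FALSE)
  e <- outer(rowSums(table), colSums(table)) / sum(table)
  chi2 <- sum((table - e)^2 / e)
  group_result("chi2_2x2", NA_real_, NA_real_, chi2, 1,
               stats::pchisq(chi2, 1, lower.tail = FALSE), NA_real_,
               sum(table), "upper")
}

#' Standardized symptom regression
#'
#' OLS of a z-scored outcome on z-scored predictors, with selected
#' predictors log1p-transformed before standardization (symptom scales can
#' legitimately score 0, so log1p rather than log). Complete cases only;
#' residual df = n - k - 1.
#'
#' @param outcome numeric outcome (e.g. per-participant PPI betas).
#' @param predictors data frame of predictors (e.g. MAS, BIS).
#' @param log_transform logical vector (recycled) flagging predictors to
#'   log1p-transform; default all `FALSE`.
#' @return Data frame with one row per predictor: `term`, `beta`
#'   (standardized), `se`, `t`, `df`, `p` (two-tailed), plus attributes
#'   `n` (complete cases) and `condition_number`.
#' @export
symptom_regression <- function(outcome, predictors, log_transform = FALSE) {
  predictors <- as.data.frame(predictors)
  k <- ncol(predictors)
  log_transform <- rep_len(log_transform, k)
  cc <- stats::complete.cases(outcome, predictors)
  y <- outcome[cc]
  P <- predictors[cc, , drop = FALSE]
  n <- length(y)
  if (n <= k + 1)
    stop("need more complete cases (", n, ") than predictors + 1", call. = FALSE)
  for (j in seq_len(k)) {
    v <- P[[j]]
    if (log_transform[j]) {
      if (any(v < 0)) stop("log1p transform of negative values in ",
                           names(P)[j], call. = FALSE)
      v <- log1p(v)
    }
    P[[j]] <- (v - mean(v)) / stats::sd(v)
  }
  yz <- (y - mean(y)) / stats::sd(y)
  X <- cbind(intercept = 1, as.matrix(P))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular predictor matrix", call. = FALSE)
  cn <- kappa(X, exact = TRUE)
  if (cn > 30)
    warning("ill-conditioned predictors (condition number ",
            format(cn, digits = 3), ")", call. = FALSE)
  beta <- qr.coef(qx, yz)
  res <- yz - X %*% beta
  df <- n - k - 1
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * chol2inv(qr.R(qx))))
  t <- beta / se
  out <- data.frame(term = colnames(X)[-1], beta = beta[-1], se = se[-1],
                    t = t[-1], df = df, p = 2 * stats::pt(-abs(t[-1]), df),
                    row.names = NULL)
  attr(out, "n") <- n
  attr(out, "condition_number") <- cn
  out
}

#' Bonferroni correction
#'
#' Thresholds a set of p values at `alpha / k`.
#'
#' @param pvalues numeric p values.
#' @param k number of tests in the family (`>= 1`); defaults to
#'   `length(pvalues)`.
#' @param alpha family-wise alpha; default 0.05.
#' @return List with `threshold` and logical `significant`.
#' @export
#' @examples
#' bonferroni(c(0.021, 0.031), k = 2)   # threshold 0.025
bonferroni <- function(pvalues, k = length(pvalues), alpha = 0.05) {
  stopifnot(k >= 1)
  list(threshold = alpha / k, significant = pvalues < alpha / k)
}
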