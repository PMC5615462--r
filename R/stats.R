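#' Reliability and validity statistics
#'
#' Repeatability of the three trials per condition (ICC, SEM, repeated
#' measures ANOVA), speed-accuracy correlation and group comparisons, all
#' operating on subjects x trials matrices built from the trial table.
#'
#' @name reliability-stats
NULL

# listwise-complete matrix + the two-way mean squares shared by icc() and
# rm_anova(): rows = subjects (random), columns = trials
two_way_ms <- function(m) {
  m <- as.matrix(m)
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 trials")
  mu <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ssr <- k * sum((rm_ - mu)^2)
  ssc <- n * sum((cm - mu)^2)
  sst <- sum((m - mu)^2)
  sse <- sst - ssr - ssc
  list(n = n, k = k, n_excluded = sum(!keep),
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), sst = sst, m = m)
}

#' Intraclass correlation of repeated trials
#'
#' Two-way (subjects x trials) single-measures ICC. `form = "consistency"`
#' treats the trial factor as fixed nuisance (ICC(3,1)-style):
#' `(MSR - MSE) / (MSR + (k-1) MSE)`. `form = "agreement"` is the two-way
#' random absolute-agreement form (ICC(2,1)):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. Confidence
#' intervals use the F-distribution method (exact for consistency,
#' Satterthwaite approximation for agreement).
#'
#' @param m subjects x trials matrix; rows with missing trials are dropped
#'   listwise.
#' @param form `"consistency"` or `"agreement"`.
#' @param conf confidence level.
#' @return list with `value`, `ci` (length 2), `form`, `n`, `k`,
#'   `n_excluded`, and the mean squares `msr`, `msc`, `mse`.
#' @export
icc <- function(m, form = c("consistency", "agreement"), conf = 0.95) {
  form <- match.arg(form)
  ms <- two_way_ms(m)
  if (ms$sst < 1e-12) stop("undefined ICC: zero total variance")
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf
  if (form == "consistency") {
    val <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    Fobs <- ms$msr / ms$mse
    fl <- Fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- Fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    val <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
    a <- (k * val) / (n * (1 - val))
    b <- 1 + (k * val * (n - 1)) / (n * (1 - val))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (ms$msr - fl * ms$mse) /
      (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    upper <- n * (fu * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
    ci <- c(lower, upper)
  }
  list(value = val, ci = ci, form = form, n = n, k = k,
       n_excluded = ms$n_excluded, msr = ms$msr, msc = ms$msc, mse = ms$mse)
}

#' Standard error of measurement from consecutive-trial differences
#'
#' Stacks each subject's consecutive-trial differences (trial 2 - trial 1,
#' trial 3 - trial 2, ...) into one vector and returns its standard deviation
#' divided by sqrt(2). The chi-square interval on the SD gives the confidence
#' interval. `method = "per_pair"` instead averages the per-pair SEMs.
#'
#' @param m subjects x trials matrix (k >= 2; the standard design has k = 3).
#' @param method `"pooled"` (default) or `"per_pair"`.
#' @param conf confidence level.
#' @return list with `value`, `ci`, `n_diffs`, `method`.
#' @export
sem_from_differences <- function(m, method = c("pooled", "per_pair"),
                                 conf = 0.95) {
  method <- match.arg(method)
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 subjects and 2 trials")
  k <- ncol(m)
  diffs <- m[, 2:k, drop = FALSE] - m[, 1:(k - 1), drop = FALSE]
  alpha <- 1 - conf
  ci_from_sd <- function(s, df) {
    s * sqrt(df / stats::qchisq(c(1 - alpha / 2, alpha / 2), df))
  }
  if (method == "pooled") {
    v <- as.vector(diffs)
    sem <- stats::sd(v) / sqrt(2)
    ci <- ci_from_sd(stats::sd(v), length(v) - 1) / sqrt(2)
    list(value = sem, ci = ci, n_diffs = length(v), method = method)
  } else {
    sems <- apply(diffs, 2, stats::sd) / sqrt(2)
    sem <- mean(sems)
    v <- as.vector(diffs)
    ci <- ci_from_sd(stats::sd(v), length(v) - 1) / sqrt(2)
    list(value = sem, ci = ci, n_diffs = length(v), method = method)
  }
}

#' Repeated-measures ANOVA over the trial factor
#'
#' One-way repeated-measures ANOVA testing for a systematic difference (e.g.
#' a learning effect) between the k trials: `F = MSC / MSE` on
#' `(k - 1, (n - 1)(k - 1))` degrees of freedom, sphericity assumed. Shares
#' its sums-of-squares decomposition with [icc()]. When the residual mean
#' square vanishes but the trial effect does not, the effect is perfectly
#' systematic and `F = Inf`, `p = 0` is returned with a note.
#'
#' @inheritParams icc
#' @return list with `F`, `df1`, `df2`, `p`, `note`.
#' @export
rm_anova <- function(m) {
  ms <- two_way_ms(m)
  if (ms$mse < 1e-12) {
    if (ms$msc < 1e-12) stop("degenerate matrix: no trial or residual variance")
    return(list(F = Inf, df1 = ms$k - 1, df2 = (ms$n - 1) * (ms$k - 1),
                p = 0, note = "perfect systematic effect (zero residual)"))
  }
  Fv <- ms$msc / ms$mse
  df1 <- ms$k - 1
  df2 <- (ms$n - 1) * (ms$k - 1)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE), note = NULL)
}

#' Spearman correlation between acuity and speed
#'
#' Rank correlation (mid-ranks for ties) with the t-approximation p-value;
#' used for the speed-accuracy trade-off, which is expected to be negative.
#'
#' @param acuity,speed paired numeric vectors (n >= 4).
#' @return list with `rho`, `p`, `n`.
#' @export
speed_accuracy_correlation <- function(acuity, speed) {
  ok <- stats::complete.cases(acuity, speed)
  x <- acuity[ok]; y <- speed[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined rank correlation: constant input vector")
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Compare two groups (paired or independent t-test)
#'
#' Paired t-test for within-subject contrasts (e.g. dominant vs non-dominant
#' hand), Welch's t-test for independent groups (e.g. with vs without hand
#' pain). A paired contrast whose differences have zero variance is flagged
#' as degenerate rather than producing a spurious statistic.
#'
#' @param a,b numeric vectors; equal length when `paired`.
#' @param paired logical.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param conf confidence level for the difference.
#' @return list with `estimate` (mean difference a - b), `t`, `df`, `p`,
#'   `ci`, `degenerate`.
#' @export
compare_groups <- function(a, b, paired = FALSE, var_equal = FALSE,
                           conf = 0.95) {
  if (paired) {
    stopifnot(length(a) == length(b))
    ok <- stats::complete.cases(a, b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 2) stop("need at least 2 complete pairs")
    d <- a - b
    if (stats::sd(d) < 1e-12) {
      md <- mean(d)
      return(list(estimate = md,
                  t = if (abs(md) < 1e-12) 0 else sign(md) * Inf,
                  df = length(d) - 1,
                  p = if (abs(md) < 1e-12) 1 else 0,
                  ci = c(md, md), degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, paired = TRUE, conf.level = conf)
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) stop("need at least 2 per group")
    tt <- stats::t.test(a, b, var.equal = var_equal, conf.level = conf)
  }
  list(estimate = if (paired) unname(tt$estimate) else
         unname(tt$estimate[1] - tt$estimate[2]),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = as.numeric(tt$conf.int), degenerate = FALSE)
}

#' Shapiro-Wilk normality check
#'
#' Gate used to choose between parametric and rank procedures.
#'
#' @param x numeric vector, 3 <= n <= 5000 after NA removal.
#' @return list with `W`, `p`, `n`.
#' @export
normality_gate <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) < 1e-12) stop("normality test undefined for constant input")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value, n = n)
}

#' Reliability report for one subjects x trials matrix
#'
#' Bundles everything the repeatability table needs for one condition: per
#' trial means and SDs, both ICC forms with 95% CIs, SEM with 95% CI, and the
#' repeated-measures ANOVA for systematic bias.
#'
#' @inheritParams icc
#' @param condition label for printing (e.g. "dominant hand, palmar").
#' @param headline_form which ICC form [print()] puts first.
#' @return object of class `reliability_report`.
#' @export
reliability_report <- function(m, condition = "", conf = 0.95,
                               headline_form = c("consistency", "agreement")) {
  headline_form <- match.arg(headline_form)
  m2 <- as.matrix(m)
  keep <- stats::complete.cases(m2)
  structure(list(
    condition = condition,
    n = sum(keep), k = ncol(m2), n_excluded = sum(!keep),
    trial_means = colMeans(m2[keep, , drop = FALSE]),
    trial_sds = apply(m2[keep, , drop = FALSE], 2, stats::sd),
    icc_consistency = icc(m2, "consistency", conf),
    icc_agreement = icc(m2, "agreement", conf),
    sem = sem_from_differences(m2, conf = conf),
    anova = rm_anova(m2),
    headline_form = headline_form
  ), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Repeatability report", if (nzchar(x$condition))
    paste0("- ", x$condition), "\n")
  cat(sprintf("  n = %d subjects, k = %d trials (%d excluded listwise)\n",
              x$n, x$k, x$n_excluded))
  tm <- sprintf("%.1f (%.1f)", x$trial_means, x$trial_sds)
  cat("  trial means (SD): ", paste(tm, collapse = "  "), "\n")
  hl <- if (x$headline_form == "consistency") x$icc_consistency else
    x$icc_agreement
  cat(sprintf("  ICC %s: %.2f (%.2f-%.2f)\n", x$headline_form, hl$value,
              hl$ci[1], hl$ci[2]))
  other <- if (x$headline_form == "consistency") x$icc_agreement else
    x$icc_consistency
  cat(sprintf("  ICC %s: %.2f (%.2f-%.2f)\n", other$form, other$value,
              other$ci[1], other$ci[2]))
  cat(sprintf("  SEM: %.2f (%.2f-%.2f)\n", x$sem$value, x$sem$ci[1],
              x$sem$ci[2]))
  cat(sprintf("  RM-ANOVA trial effect: F(%d,%d) = %.2f, p = %.3g%s\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p,
              if (is.null(x$anova$note)) "" else paste0(" [", x$anova$note, "]")))
  invisible(x)
}

#' @export
summary.reliability_report <- function(object, ...) {
  data.frame(condition = object$condition, n = object$n, k = object$k,
             icc_consistency = object$icc_consistency$value,
             icc_agreement = object$icc_agreement$value,
             sem = object$sem$value, anova_F = object$anova$F,
             anova_p = object$anova$p)
}

#' Subjects x trials matrix for one condition
#'
#' Pivots the long trial table into the wide matrix the reliability
#' statistics expect.
#'
#' @param records trial table.
#' @param outcome column to pivot (default `"acuity_pct"`).
#' @param hand,anatomical_direction condition selectors (NULL = no filter).
#' @param k number of trials per condition.
#' @export
condition_matrix <- function(records, outcome = "acuity_pct", hand = NULL,
                             anatomical_direction = NULL, k = 3) {
  r <- as.data.frame(records)
  if (is.null(r$anatomical_direction)) {
    r$anatomical_direction <- label_direction(r$hand, r$draw_direction)
  }
  if (!is.null(hand)) r <- r[r$hand == hand, ]
  if (!is.null(anatomical_direction)) {
    r <- r[r$anatomical_direction == anatomical_direction, ]
  }
  ids <- sort(unique(r$participant))
  m <- matrix(NA_real_, length(ids), k,
              dimnames = list(ids, paste0("trial", seq_len(k))))
  for (i in seq_len(nrow(r))) {
    if (r$trial[i] >= 1 && r$trial[i] <= k) {
      m[as.character(r$participant[i]), r$trial[i]] <- r[[outcome]][i]
    }
  }
  m
}

#' Reliability reports for all four hand x direction conditions
#'
#' @param records trial table.
#' @param outcome outcome column.
#' @param conf confidence level.
#' @param holm apply a Holm correction to the four ANOVA p-values.
#' @return named list of `reliability_report`s; with `holm`, each report
#'   gains `anova$p_adj`.
#' @export
reliability_by_condition <- function(records, outcome = "acuity_pct",
                                     conf = 0.95, holm = FALSE) {
  conds <- expand.grid(hand = c("left", "right"),
                       anatomical_direction = c("dorsal", "palmar"),
                       stringsAsFactors = FALSE)
  reports <- lapply(seq_len(nrow(conds)), function(i) {
    m <- condition_matrix(records, outcome, conds$hand[i],
                          conds$anatomical_direction[i])
    reliability_report(m, condition = paste(conds$hand[i], "hand,",
                                            conds$anatomical_direction[i]),
                       conf = conf)
  })
  names(reports) <- paste(conds$hand, conds$anatomical_direction, sep = "_")
  if (holm) {
    padj <- stats::p.adjust(vapply(reports, function(r) r$anova$p, 0), "holm")
    for (i in seq_along(reports)) reports[[i]]$anova$p_adj <- padj[i]
  }
  reports
}
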