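#' Descriptive summary
#'
#' Mean and sample standard deviation (n - 1 denominator) for numeric input;
#' counts and percentages for categorical input.
#'
#' @param values numeric or character/factor vector.
#' @return For numeric input a list with `mean`, `sd`, `n`; for categorical
#'   input a data frame with `level`, `count`, `percent`.
#' @export
descriptive_summary <- function(values) {
  if (length(values) == 0L) stop("empty input")
  if (is.numeric(values)) {
    list(mean = mean(values),
         sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
         n = length(values))
  } else {
    tab <- table(values)
    data.frame(level = names(tab), count = as.integer(tab),
               percent = 100 * as.integer(tab) / length(values))
  }
}

test_result <- function(statistic, p_value, effect_size = NA_real_,
                        df = NA_real_, n = NA_integer_, method = "") {
  structure(list(statistic = statistic, p_value = p_value,
                 effect_size = effect_size, df = df, n = n, method = method),
            class = "hrv_test_result")
}

#' @export
print.hrv_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, effect size = %.3g (n = %s)\n",
              x$method, x$statistic, x$p_value, x$effect_size,
              paste(x$n, collapse = "+")))
  invisible(x)
}

#' One-way repeated-measures ANOVA with partial eta squared
#'
#' Classic within-subject decomposition on a complete subjects x conditions
#' matrix (rows with any missing value are dropped):
#' `SS_total = SS_subject + SS_condition + SS_error`,
#' `F = MS_condition / MS_error` with `(k-1, (k-1)(n-1))` degrees of freedom
#' and partial eta^2 = `SS_condition / (SS_condition + SS_error)`. No
#' sphericity correction is applied by default.
#'
#' @param values numeric matrix, subjects in rows, conditions in columns.
#' @return An `hrv_test_result` (effect size = partial eta^2).
#' @export
rm_anova_eta2 <- function(values) {
  m <- as.matrix(values)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("need at least 2 conditions")
  if (n < 3L) stop("need at least 3 complete subjects")
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) (ss_cond / df1) / ms_err else if (ss_cond == 0) 0 else Inf
  p <- if (is.finite(f)) stats::pf(f, df1, df2, lower.tail = FALSE) else 0
  eta2 <- if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0
  test_result(f, p, eta2, df = c(df1, df2), n = n,
              method = "repeated-measures ANOVA (partial eta^2)")
}

#' Paired t test with Cohen's d
#'
#' Two-sided paired t test on the differences; Cohen's d =
#' `mean(diff) / sd(diff)`. Zero-variance differences make the statistic
#' undefined: `p` is reported missing with a warning, never 0 or 1.
#'
#' @param values_a,values_b paired numeric vectors of equal length >= 2.
#' @return An `hrv_test_result` (effect size = Cohen's d).
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("paired vectors differ in length")
  d <- values_a - values_b
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  sdd <- stats::sd(d)
  if (sdd == 0) {
    warning("zero-variance differences: t undefined, p reported missing")
    return(test_result(NA_real_, NA_real_, NA_real_, df = n - 1, n = n,
                       method = "paired t"))
  }
  t <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
  test_result(t, p, mean(d) / sdd, df = n - 1, n = n, method = "paired t")
}

#' Welch two-sample t test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom; effect
#' size is Cohen's d on the pooled SD.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return An `hrv_test_result`.
#' @export
welch_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  va <- stats::var(group_a) / na; vb <- stats::var(group_b) / nb
  if (va + vb == 0) {
    warning("zero variance in both groups: t undefined")
    return(test_result(NA_real_, NA_real_, NA_real_, n = c(na, nb),
                       method = "Welch t"))
  }
  t <- (mean(group_a) - mean(group_b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  sp <- sqrt(((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
               (na + nb - 2))
  d <- if (sp > 0) (mean(group_a) - mean(group_b)) / sp else NA_real_
  test_result(t, p, d, df = df, n = c(na, nb), method = "Welch t")
}

#' Mann-Whitney U test, exact for small samples
#'
#' Mid-ranks handle ties. For `n_a + n_b <= max_exact` the two-sided p value
#' is computed by full enumeration of all `choose(n_a + n_b, n_a)` group
#' assignments of the observed (mid-)ranks, counting assignments whose U is
#' at least as extreme (as far from `n_a n_b / 2`) as the observed one. For
#' larger samples the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param group_a,group_b numeric vectors (each length >= 1).
#' @param max_exact enumeration cutoff on the total sample size.
#' @return An `hrv_test_result` whose statistic is U for `group_a`.
#' @export
mann_whitney_exact <- function(group_a, group_b, max_exact = 12) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 1L || nb < 1L) stop("both groups must be non-empty")
  r <- rank(c(group_a, group_b))   # mid-ranks for ties
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  centre <- na * nb / 2
  if (na + nb <= max_exact) {
    picks <- utils::combn(na + nb, na)
    us <- colSums(matrix(r[picks], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    nties <- table(r)
    sigma <- sqrt(na * nb / 12 *
                    ((na + nb + 1) - sum(nties^3 - nties) /
                       ((na + nb) * (na + nb - 1))))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - centre) - 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
    }
    method <- "Mann-Whitney U (normal approximation)"
  }
  test_result(u_obs, p, n = c(na, nb), method = method)
}

#' Holm step-down adjustment
#'
#' Standard step-down multiplicity correction: monotone and never below the
#' raw p values. Provided as an option; no correction is applied anywhere by
#' default.
#'
#' @param p_values numeric vector of p values.
#' @return Adjusted p values in the input order.
#' @export
holm_adjust <- function(p_values) {
  n <- length(p_values)
  if (n == 0L) return(numeric(0))
  o <- order(p_values)
  adj <- pmin(1, (n - seq_len(n) + 1) * p_values[o])
  adj <- cummax(adj)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Phase-contrast analysis table
#'
#' Reproduces the acute-effect table structure: for every HRV index, a
#' repeated-measures ANOVA across the three phases on subject means, plus
#' paired t tests for the Pre->On and On->Post contrasts.
#'
#' @param table a tidy table from [phase_indices()].
#' @return A data frame, one row per index, with F, p, partial eta^2 and the
#'   two paired contrasts.
#' @export
phase_contrasts <- function(table) {
  idx_names <- hrv_index_names()
  out <- lapply(idx_names, function(ix) {
    agg <- stats::aggregate(table[[ix]],
                            by = list(subject = table$subject,
                                      phase = table$phase), FUN = mean)
    wide <- stats::reshape(agg, direction = "wide", idvar = "subject",
                           timevar = "phase")
    m <- as.matrix(wide[, c("x.Pre", "x.On", "x.Post")])
    an <- rm_anova_eta2(m)
    cc <- m[stats::complete.cases(m), , drop = FALSE]
    t_on <- paired_t(cc[, "x.On"], cc[, "x.Pre"])
    t_post <- paired_t(cc[, "x.Post"], cc[, "x.On"])
    data.frame(index = ix, F = an$statistic, p = an$p_value,
               eta2 = an$effect_size,
               t_pre_on = t_on$statistic, p_pre_on = t_on$p_value,
               t_on_post = t_post$statistic, p_on_post = t_post$p_value)
  })
  do.call(rbind, out)
}

#' Frequency-dose contrast analysis
#'
#' For each index, compares the per-subject stimulation deltas of the higher
#' frequency groups against the lowest by paired t tests (the dose-response
#' contrast).
#'
#' @param table a tidy table from [phase_indices()].
#' @param contrast passed to [delta_features()].
#' @return A data frame with one row per index and comparison.
#' @export
frequency_contrasts <- function(table, contrast = "post_minus_pre") {
  feats <- delta_features(table, contrast = contrast,
                          aggregate = "per_frequency")
  freqs <- sort(unique(table$frequency))
  idx_names <- hrv_index_names()
  ref <- freqs[1]
  rows <- list()
  for (ix in idx_names) {
    for (f in freqs[-1]) {
      a <- feats[[sprintf("%s_%gHz", ix, f)]]
      b <- feats[[sprintf("%s_%gHz", ix, ref)]]
      tr <- paired_t(a, b)
      rows[[length(rows) + 1L]] <-
        data.frame(index = ix, comparison = sprintf("%g vs %g Hz", f, ref),
                   t = tr$statistic, p = tr$p_value, d = tr$effect_size)
    }
  }
  do.call(rbind, rows)
}
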