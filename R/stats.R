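#' @title Statistical pipeline for maze VR data
#' @description Normality screening (Monte-Carlo Lilliefors), tests of VR
#'   against zero and between strains with a parametric/non-parametric gate,
#'   one-way ANOVA with Tukey compact letter displays, pairwise correlation
#'   tables and VR-versus-peak-power meta-analysis fits.
#' @name stats-pipeline
NULL

.stat_report <- function(test_name, statistic, p_value, alpha,
                         group_labels = NULL) {
  structure(
    list(test_name = test_name, statistic = unname(statistic),
         p_value = unname(p_value), alpha = alpha,
         significant = is.finite(p_value) && p_value < alpha,
         group_labels = group_labels),
    class = "stat_report"
  )
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s: statistic %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$test_name, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  if (!is.null(x$group_labels)) {
    cat("  letters:", paste(names(x$group_labels), x$group_labels,
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Lilliefors D for one sample: sup distance between the empirical CDF and
# the normal CDF with estimated mean and sd
.lillie_stat <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

# Null distribution of D depends only on n (the test is distribution-free
# after standardization), so it is simulated once per (n, B) under an
# internal fixed-seed stream and cached for the session.
.lillie_cache <- new.env(parent = emptyenv())

.lillie_null <- function(n, B) {
  key <- sprintf("n%d_B%d", n, B)
  if (!is.null(.lillie_cache[[key]])) return(.lillie_cache[[key]])
  d <- withr::with_seed(10619L + n, {
    m <- matrix(stats::rnorm(B * n), nrow = B)
    m <- t(apply(m, 1, sort))
    mu <- rowMeans(m)
    sdv <- sqrt((rowSums(m^2) - n * mu^2) / (n - 1))
    z <- stats::pnorm((m - mu) / sdv)
    steps_hi <- matrix(seq_len(n) / n, nrow = B, ncol = n, byrow = TRUE)
    dplus <- apply(steps_hi - z, 1, max)
    dminus <- apply(z - (steps_hi - 1 / n), 1, max)
    pmax(dplus, dminus)
  })
  .lillie_cache[[key]] <- d
  d
}

#' Lilliefors test of normality with Monte-Carlo p-values
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean and
#' standard deviation estimated from the sample. Because the parameters are
#' estimated, standard KS tables do not apply; the p-value is computed by
#' Monte-Carlo simulation of the null (default 10^4 replicates), which
#' depends only on the sample size and is cached per size. A constant
#' sample is degenerate and rejected by convention.
#'
#' @param values Numeric sample, n >= 5.
#' @param alpha Significance level (default 0.05).
#' @param n_sim Number of null replicates (default 10000).
#' @return A `stat_report`.
#' @export
lilliefors_test <- function(values, alpha = 0.05, n_sim = 10000L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 5L) stop("Lilliefors test requires n >= 5", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  if (stats::sd(values) == 0) {
    message("constant sample: normality rejected by convention")
    return(.stat_report("Lilliefors (degenerate)", NA_real_, 0, alpha))
  }
  d <- .lillie_stat(values)
  null_d <- .lillie_null(n, as.integer(n_sim))
  p <- (1 + sum(null_d >= d)) / (length(null_d) + 1)
  .stat_report("Lilliefors", d, p, alpha)
}

#' Test whether per-maze VRs differ from zero
#'
#' The VR sample is first screened for normality with [lilliefors_test()]
#' (at `normality_alpha`); if normality is not rejected a one-sample t-test
#' against 0 is used, otherwise the Wilcoxon signed-rank test (the
#' one-sample non-parametric analogue). Samples too small for the normality
#' screen (n < 5) default to the t-test.
#'
#' @param per_maze_vr Numeric vector of per-maze VRs, n >= 2.
#' @param alpha Significance level (default 0.01, the psychophysics level).
#' @param normality_alpha Level of the normality gate (default 0.05).
#' @return A `stat_report`.
#' @export
test_vs_zero <- function(per_maze_vr, alpha = 0.01, normality_alpha = 0.05) {
  x <- as.numeric(per_maze_vr)
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(x) == 0) {
    p <- if (mean(x) == 0) 1 else 0
    return(.stat_report("degenerate (constant sample)", mean(x), p, alpha))
  }
  normal_ok <- if (length(x) >= 5L)
    !lilliefors_test(x, alpha = normality_alpha)$significant else TRUE
  if (normal_ok) {
    tt <- stats::t.test(x, mu = 0)
    .stat_report("one-sample t-test vs 0", tt$statistic, tt$p.value, alpha)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = FALSE))
    .stat_report("Wilcoxon signed-rank vs 0", wt$statistic, wt$p.value, alpha)
  }
}

#' Compare two strains (or conditions)
#'
#' Welch two-sample t-test when both samples pass the normality screen,
#' otherwise the Mann-Whitney U test.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param alpha Significance level (default 0.01).
#' @param normality_alpha Level of the normality gate (default 0.05).
#' @return A `stat_report`.
#' @export
compare_groups <- function(a, b, alpha = 0.01, normality_alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  gate <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    if (length(x) < 5L) return(TRUE)
    !lilliefors_test(x, alpha = normality_alpha)$significant
  }
  if (gate(a) && gate(b)) {
    tt <- stats::t.test(a, b)
    .stat_report("Welch t-test", tt$statistic, tt$p.value, alpha)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    .stat_report("Mann-Whitney U", wt$statistic, wt$p.value, alpha)
  }
}

# compact letter display by insert-and-absorb: groups sharing a letter are
# not significantly different under the supplied pairwise flags
.letter_display <- function(labels, diff_pairs) {
  k <- length(labels)
  cols <- list(rep(TRUE, k))
  for (pr in diff_pairs) {
    i <- pr[1]; j <- pr[2]
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] <= cols[[cj]]) && any(cols[[ci]] < cols[[cj]]))
        keep[ci] <- FALSE
    }
    cols <- cols[keep]
  }
  lets <- vapply(seq_len(k), function(i)
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = ""),
    character(1))
  stats::setNames(lets, labels)
}

#' One-way ANOVA with Tukey compact letter groups
#'
#' Fits a one-way ANOVA across the supplied groups; if the omnibus F-test is
#' significant at `alpha`, all pairwise Tukey HSD comparisons at the same
#' level determine a compact letter display: groups sharing a letter are not
#' significantly different. A non-significant omnibus test assigns every
#' group the letter "a".
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Significance level (default 0.01).
#' @return A `stat_report` whose `group_labels` hold the letters.
#' @export
anova_letter_groups <- function(groups, alpha = 0.01) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  labels <- names(groups)
  if (is.finite(pval) && pval < alpha) {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    sig <- rownames(tk)[tk[, "p adj"] < alpha]
    diff_pairs <- lapply(strsplit(sig, "-", fixed = TRUE), function(s)
      c(match(s[1], labels), match(s[2], labels)))
    letters_out <- .letter_display(labels, diff_pairs)
  } else {
    letters_out <- stats::setNames(rep("a", length(labels)), labels)
  }
  .stat_report("one-way ANOVA + Tukey HSD", fstat, pval, alpha,
               group_labels = letters_out)
}

#' Pairwise Pearson correlation table
#'
#' Pearson r and two-sided p-value for each labelled (x, y) pair, in the
#' style of a parameter-sweep correlation table; pairs with zero variance in
#' either member get a missing r (with a message).
#'
#' @param series List of lists with elements `label`, `x`, `y` (paired
#'   vectors of equal length >= 3).
#' @param alpha Bolding/significance level (default 0.05).
#' @return Data frame with columns `label`, `n`, `r`, `p`, `significant`.
#' @export
correlation_table <- function(series, alpha = 0.05) {
  stopifnot(is.list(series), length(series) >= 1L)
  rows <- lapply(series, function(s) {
    x <- as.numeric(s$x); y <- as.numeric(s$y)
    if (length(x) != length(y) || length(x) < 3L)
      stop(sprintf("series '%s': x and y must be paired with length >= 3",
                   s$label), call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      message(sprintf("series '%s': zero variance, correlation undefined",
                      s$label))
      return(data.frame(label = s$label, n = length(x), r = NA_real_,
                        p = NA_real_, significant = NA))
    }
    ct <- stats::cor.test(x, y)
    data.frame(label = s$label, n = length(x), r = unname(ct$estimate),
               p = ct$p.value, significant = ct$p.value < alpha)
  })
  do.call(rbind, rows)
}

#' Fit the VR-versus-peak-power meta-analysis model
#'
#' Ordinary least squares fit of VR (y) on peak spectral power (x), either
#' linear or quadratic. The reported `correlation_r` is the Pearson
#' correlation between fitted and observed y (for the linear model this
#' equals |r(x, y)|), with its two-sided p-value.
#'
#' @param x Peak powers.
#' @param y Visual responses.
#' @param model `"quadratic"` or `"linear"`.
#' @return A `meta_fit` with `model`, `coefficients` (highest degree
#'   first), `correlation_r`, `p_value`, `n_points`.
#' @export
meta_fit <- function(x, y, model = c("quadratic", "linear")) {
  model <- match.arg(model)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  degree <- if (model == "quadratic") 2L else 1L
  if (length(x) <= degree + 1L)
    stop("need more points than coefficients", call. = FALSE)
  if (length(unique(x)) <= degree)
    stop("design is rank-deficient (too few distinct x values)",
         call. = FALSE)
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  coefs <- rev(unname(stats::coef(fit)))   # highest degree first
  fitted_y <- stats::fitted(fit)
  if (stats::sd(fitted_y) == 0 || stats::sd(y) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(y, fitted_y)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(
    list(model = model, coefficients = coefs, correlation_r = r,
         p_value = p, n_points = length(x), fit = fit),
    class = "meta_fit"
  )
}

#' @export
print.meta_fit <- function(x, ...) {
  terms <- rev(paste0("x^", seq_along(x$coefficients) - 1L))
  terms[length(terms)] <- ""
  eq <- paste(sprintf("%+.4g%s", x$coefficients,
                      sub("\\^1$", "", terms)), collapse = " ")
  cat(sprintf("<meta_fit> %s: y = %s; correlation = %.3g (p = %.3g, n = %d)\n",
              x$model, eq, x$correlation_r, x$p_value, x$n_points))
  invisible(x)
}
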