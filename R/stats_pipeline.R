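#' Min-max normalisation to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant column maps to all zeros by
#' convention. Pearson correlations are unchanged by this affine rescaling.
#'
#' @param x numeric vector.
#' @return numeric vector in [0, 1].
#' @export
min_max_normalize <- function(x) {
  if (length(x) < 1L) stop("need at least one value", call. = FALSE)
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(0, length(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Classify correlation strength
#'
#' Contiguous half-open bands on |r|: >= 0.80 very strong; [0.60, 0.80)
#' moderately strong; [0.30, 0.60) moderate; < 0.30 weak.
#'
#' @param r Pearson coefficient, |r| <= 1.
#' @return one of `"very strong"`, `"moderately strong"`, `"moderate"`,
#'   `"weak"`.
#' @export
classify_strength <- function(r) {
  if (is.na(r) || abs(r) > 1) {
    stop(sprintf("invalid correlation coefficient %s", format(r)), call. = FALSE)
  }
  a <- abs(r)
  if (a >= 0.80) "very strong"
  else if (a >= 0.60) "moderately strong"
  else if (a >= 0.30) "moderate"
  else "weak"
}

#' Pearson correlation with two-sided p-value and strength label
#'
#' Standard Pearson r with the two-sided p-value from the t distribution on
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return list with `r`, `p_value`, `n`, `strength`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant; correlation undefined", call. = FALSE)
  if (stats::sd(y) == 0) stop("y is constant; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, p_value = ct$p.value, n = length(x), strength = classify_strength(r))
}

#' Exact pooled Pearson correlation from per-group moments
#'
#' Closed form for the Pearson correlation between a group variable and a
#' measurement, reconstructed from group sizes, means and SDs alone using
#' divisor-n moments: the total variance decomposes into within-group plus
#' between-group parts, and the covariance depends only on the group means.
#' Any dataset whose per-group divisor-n moments match the inputs has exactly
#' this correlation.
#'
#' @param ns integer group sizes.
#' @param means group means of the measurement.
#' @param sds group SDs of the measurement (divisor-n).
#' @param group_values numeric value assigned to each group (e.g. grades 1-4).
#' @return Pearson r.
#' @export
pooled_pearson_from_group_stats <- function(ns, means, sds,
                                            group_values = seq_along(ns)) {
  stopifnot(length(ns) == length(means), length(ns) == length(sds),
            length(ns) == length(group_values))
  if (any(ns <= 0)) stop("group sizes must be positive", call. = FALSE)
  N <- sum(ns)
  w <- ns / N
  gbar <- sum(w * group_values)
  ybar <- sum(w * means)
  cov_gy <- sum(w * (group_values - gbar) * (means - ybar))
  var_g <- sum(w * (group_values - gbar)^2)
  var_y <- sum(w * sds^2) + sum(w * (means - ybar)^2)
  if (var_g == 0 || var_y == 0) {
    stop("zero total variance; correlation undefined", call. = FALSE)
  }
  cov_gy / sqrt(var_g * var_y)
}

#' Compare a measurement across grade groups
#'
#' Per-group descriptives (mean and SD with divisor n - 1, the reporting
#' convention), an omnibus test, and all pairwise two-sided rank-sum
#' (Wilcoxon/Mann-Whitney) tests with Bonferroni correction. With
#' `method = "auto"` the omnibus test is Kruskal-Wallis when any group fails
#' a Shapiro-Wilk normality check at 0.05 and one-way ANOVA otherwise,
#' mirroring a normality-dependent test choice.
#'
#' @param values numeric measurements.
#' @param grades group labels (coerced to factor).
#' @param method `"auto"`, `"kruskal"` or `"anova"`.
#' @param alpha significance level for the pairwise decisions.
#' @return object of class `grade_comparison`: list with `descriptives`,
#'   `omnibus` (method, statistic, p_value) and `pairwise` (data frame with
#'   raw and Bonferroni-adjusted p-values).
#' @export
grade_comparison <- function(values, grades, method = c("auto", "kruskal", "anova"),
                             alpha = 0.05) {
  method <- match.arg(method)
  g <- factor(grades)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L)) {
    stop(sprintf("group '%s' has fewer than 2 values",
                 names(sizes)[which(sizes < 2L)[1L]]), call. = FALSE)
  }
  descriptives <- data.frame(
    group = levels(g),
    n = as.integer(sizes),
    mean = as.numeric(tapply(values, g, mean)),
    sd = as.numeric(tapply(values, g, stats::sd)))
  if (method == "auto") {
    norm_p <- vapply(levels(g), function(l) {
      v <- values[g == l]
      if (length(unique(v)) < 3L) return(0)     # degenerate: treat as non-normal
      stats::shapiro.test(v)$p.value
    }, numeric(1))
    method <- if (any(norm_p < 0.05)) "kruskal" else "anova"
  }
  omnibus <- if (method == "kruskal") {
    kt <- stats::kruskal.test(values, g)
    list(method = "kruskal_wallis", statistic = unname(kt$statistic),
         p_value = kt$p.value)
  } else {
    fit <- stats::aov(values ~ g)
    s <- summary(fit)[[1L]]
    list(method = "anova", statistic = s[["F value"]][1L],
         p_value = s[["Pr(>F)"]][1L])
  }
  pairs <- utils::combn(levels(g), 2L)
  m <- ncol(pairs)
  pairwise <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    wt <- suppressWarnings(stats::wilcox.test(values[g == a], values[g == b],
                                              alternative = "two.sided",
                                              exact = FALSE, correct = TRUE))
    data.frame(group_a = a, group_b = b, p_raw = wt$p.value,
               p_adjusted = min(1, m * wt$p.value))
  }))
  pairwise$significant <- pairwise$p_adjusted < alpha
  structure(list(descriptives = descriptives, omnibus = omnibus,
                 pairwise = pairwise, alpha = alpha),
            class = "grade_comparison")
}

#' @export
print.grade_comparison <- function(x, ...) {
  cat("Grade-group comparison\n")
  d <- x$descriptives
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  group %s (n = %d): %.2f +/- %.2f\n",
                d$group[i], d$n[i], d$mean[i], d$sd[i]))
  }
  cat(sprintf("  omnibus %s: statistic %.3f, p %s\n", x$omnibus$method,
              x$omnibus$statistic, format.pval(x$omnibus$p_value, digits = 3)))
  p <- x$pairwise
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %s vs %s: adjusted p %s%s\n", p$group_a[i], p$group_b[i],
                format.pval(p$p_adjusted[i], digits = 3),
                if (p$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' Correlate every feature with a reference column
#'
#' Computes the Pearson correlation (with p-value and strength class) of each
#' feature against a reference variable — e.g. each of the 21 echotexture
#' features against echovariation, or against the impairment grade.
#'
#' @param table data frame of features (plus metadata).
#' @param reference name of the reference column.
#' @param features feature columns to correlate (the reference itself is
#'   skipped).
#' @return data frame with `feature`, `r`, `p_value`, `n`, `strength`.
#' @export
correlate_features <- function(table, reference, features = feature_names()) {
  features <- setdiff(features, reference)
  ref <- table[[reference]]
  if (is.null(ref)) stop(sprintf("reference column '%s' not found", reference),
                         call. = FALSE)
  rows <- lapply(features, function(f) {
    res <- pearson_with_p(table[[f]], ref)
    data.frame(feature = f, r = res$r, p_value = res$p_value, n = res$n,
               strength = res$strength)
  })
  do.call(rbind, rows)
}
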