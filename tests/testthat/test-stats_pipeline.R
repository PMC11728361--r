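test_that("min-max normalisation maps to [0,1] with the constant-column convention", {
  expect_equal(min_max_normalize(c(10, 20, 30)), c(0, 0.5, 1))
  expect_equal(min_max_normalize(c(5, 5, 5)), c(0, 0, 0))
  set.seed(2)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(cor(min_max_normalize(x), min_max_normalize(y)), cor(x, y),
               tolerance = 1e-12)        # Pearson is affine invariant
})

test_that("Pearson correlation, p-value and strength match hand computations", {
  x <- 1:10
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  res <- pearson_with_p(1:4, c(2, 1, 4, 3))
  expect_equal(res$r, 0.6, tolerance = 1e-12)
  expect_equal(res$p_value, 0.4, tolerance = 1e-3)   # t(2) two-sided tail
  expect_identical(res$n, 4L)
  expect_error(pearson_with_p(rep(1, 5), 1:5), "constant")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
})

test_that("correlation strength bands are contiguous and half-open", {
  expect_identical(classify_strength(-0.81), "very strong")
  expect_identical(classify_strength(0.80), "very strong")
  expect_identical(classify_strength(0.79), "moderately strong")
  expect_identical(classify_strength(0.60), "moderately strong")
  expect_identical(classify_strength(-0.37), "moderate")
  expect_identical(classify_strength(0.30), "moderate")
  expect_identical(classify_strength(0), "weak")
  expect_error(classify_strength(1.2), "invalid")
})

test_that("pooled-moment correlation equals direct Pearson on matched data", {
  set.seed(12)
  for (rep in 1:10) {
    ns <- sample(3:30, 4, replace = TRUE)
    means <- rnorm(4, 50, 15)
    sds <- runif(4, 1, 10)
    gvals <- 1:4
    y <- unlist(lapply(1:4, function(g) moment_matched_sample(ns[g], means[g], sds[g])))
    g <- rep(gvals, times = ns)
    expect_equal(pooled_pearson_from_group_stats(ns, means, sds, gvals),
                 cor(g, y), tolerance = 1e-12)
  }
  expect_equal(pooled_pearson_from_group_stats(c(5, 5), c(3, 3), c(1, 2), 1:2), 0)
  expect_error(pooled_pearson_from_group_stats(c(5, 5), c(3, 3), c(0, 0), c(1, 1)),
               "zero total variance")
  # two well-separated groups approach perfect correlation
  r <- pooled_pearson_from_group_stats(c(10, 10), c(0, 100), c(1e-6, 1e-6), 1:2)
  expect_equal(r, 1, tolerance = 1e-9)
})

test_that("grade comparison reports descriptives, omnibus and Bonferroni pairs", {
  set.seed(33)
  prof <- grade_profiles()
  values <- unlist(lapply(1:4, function(g) sample_grade_ev(prof[g, ], prof$n[g])))
  grades <- rep(1:4, times = prof$n)
  cmp <- grade_comparison(values, grades)
  expect_identical(cmp$descriptives$n, c(24L, 58L, 24L, 24L))
  expect_equal(sum(cmp$descriptives$n), length(values))
  expect_lt(cmp$omnibus$p_value, 0.001)
  expect_identical(nrow(cmp$pairwise), 6L)
  expect_true(all(cmp$pairwise$p_adjusted < 0.001))  # every grade pair separates
  expect_true(all(cmp$pairwise$p_adjusted >= cmp$pairwise$p_raw))
  expect_equal(cmp$pairwise$p_adjusted,
               pmin(1, 6 * cmp$pairwise$p_raw))
})

test_that("grade comparison validates input and honours the method switch", {
  expect_error(grade_comparison(1:5, c(1, 1, 1, 1, 2)), "fewer than 2")
  set.seed(4)
  v <- c(rnorm(20), rnorm(20, 5))
  g <- rep(1:2, each = 20)
  cmp_k <- grade_comparison(v, g, method = "kruskal")
  cmp_a <- grade_comparison(v, g, method = "anova")
  expect_identical(cmp_k$omnibus$method, "kruskal_wallis")
  expect_identical(cmp_a$omnibus$method, "anova")
  expect_identical(nrow(cmp_k$pairwise), 1L)
  expect_true(cmp_k$pairwise$significant)
})

test_that("feature correlation tables cover all features except the reference", {
  set.seed(6)
  tab <- as.data.frame(matrix(rnorm(50 * 21), 50, 21,
                              dimnames = list(NULL, feature_names())))
  ct <- correlate_features(tab, "echovariation")
  expect_identical(nrow(ct), 20L)
  expect_false("echovariation" %in% ct$feature)
  expect_true(all(abs(ct$r) <= 1))
  expect_true(all(ct$strength %in%
                    c("very strong", "moderately strong", "moderate", "weak")))
})
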