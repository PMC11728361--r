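test_that("first-order moments match hand computations", {
  const <- matrix(128L, 8, 8)
  fo <- first_order_features(const)
  expect_equal(fo$echointensity, 128)
  expect_equal(fo$variance, 0)
  expect_equal(fo$sd, 0)
  expect_equal(fo$echovariation, 0)
  expect_equal(fo$skew, 0)
  expect_equal(fo$kurtosis, 0)
  expect_true(fo$degenerate)

  two <- matrix(c(100L, 150L), 1, 2)
  fo2 <- first_order_features(two)
  expect_equal(fo2$echointensity, 125)
  expect_equal(fo2$sd, 25)                # population sigma
  expect_equal(fo2$echovariation, 20)

  spike <- matrix(c(0L, 0L, 0L, 255L), 2, 2)
  fo3 <- first_order_features(spike)
  expect_equal(fo3$echointensity, 63.75)
  expect_equal(fo3$echovariation, 100 * sqrt(3 * 63.75^2) / 63.75,
               tolerance = 1e-12)
  expect_gt(fo3$skew, 0)
})

test_that("first-order moments agree with a brute-force oracle", {
  set.seed(21)
  img <- random_byte_image(9, 13)
  x <- as.numeric(img)
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  fo <- first_order_features(img)
  expect_equal(fo$echointensity, m, tolerance = 1e-12)
  expect_equal(fo$variance, v, tolerance = 1e-12)
  expect_equal(fo$skew, sum((x - m)^3) / n / v^1.5, tolerance = 1e-12)
  expect_equal(fo$kurtosis, sum((x - m)^4) / n / v^2 - 3, tolerance = 1e-12)
})

test_that("GLCM pair counting matches enumeration on tiny images", {
  img <- rbind(c(0L, 0L), c(1L, 1L))
  m <- glcm_matrix(img, distance = 1, angle = 0, levels = 2)
  expect_equal(m$p, rbind(c(0.5, 0), c(0, 0.5)))

  const <- matrix(3L, 4, 4)
  mc <- glcm_matrix(const, distance = 1, angle = 0, levels = 8)
  expect_equal(sum(mc$p != 0), 1)
  expect_equal(mc$p[4, 4], 1)

  set.seed(5)
  any_img <- random_level_image(7, 9, 8)
  expect_equal(sum(glcm_matrix(any_img, 2, 0, 8)$p), 1, tolerance = 1e-14)

  expect_error(glcm_matrix(matrix(0L, 3, 3), distance = 5, angle = 0),
               "no pixel pair")
})

test_that("GLCM features match hand computation on the two-run matrix", {
  g <- glcm_features(rbind(c(0.5, 0), c(0, 0.5)))
  expect_equal(g$contrast, 0)
  expect_equal(g$dissimilarity, 0)
  expect_equal(g$homogeneity, 1)
  expect_equal(g$asm, 0.5)
  expect_equal(g$energy, sqrt(0.5))
  expect_equal(g$max_probability, 0.5)
  expect_equal(g$entropy, log(2))
  expect_equal(g$correlation, 1)
  expect_equal(g$cluster_shade, 0)
  expect_equal(g$cluster_prominence, 1)
})

test_that("single-entry GLCM is the degenerate texture", {
  p <- matrix(0, 4, 4); p[3, 3] <- 1
  g <- glcm_features(p)
  expect_equal(g$asm, 1)
  expect_equal(g$entropy, 0)
  expect_equal(g$contrast, 0)
  expect_equal(g$cluster_shade, 0)
  expect_equal(g$correlation, 1)          # zero-variance marginal convention
  expect_error(glcm_features(p * 0.9), "not normalised")
})

test_that("GLCM features equal the brute-force oracle on random images", {
  set.seed(42)
  for (rep in 1:30) {
    L <- sample(c(2L, 4L, 8L), 1)
    img <- random_level_image(sample(4:16, 1), sample(4:16, 1), L)
    d <- sample(1:3, 1)
    p <- glcm_matrix(img, d, 0, L)$p
    expect_equal(p, oracle_glcm_matrix(img, d, 0, L), tolerance = 1e-14)
    got <- glcm_features(p)
    want <- oracle_glcm_features(p)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12)
  }
})

test_that("run-length features match hand enumeration", {
  row <- matrix(c(0L, 0L, 128L, 128L, 128L), 1, 5)  # levels 0 and 1 of 2
  f <- glrlm_features(row, levels = 2, angles = 0)
  expect_equal(f$sre, (1 / 4 + 1 / 9) / 2)
  expect_equal(f$lre, (4 + 9) / 2)
  expect_equal(f$glu, 1)
  expect_equal(f$rlu, 1)
  expect_equal(f$rpc, 2 / 5)

  const <- matrix(200L, 6, 6)
  fc <- glrlm_features(const, levels = 16, angles = 0)
  expect_equal(fc$lre, 36)                # one run of length n per row
  expect_equal(fc$rpc, 1 / 6)
})

test_that("run-length matrices and features equal the enumeration oracle", {
  set.seed(77)
  for (rep in 1:20) {
    L <- sample(c(2L, 4L, 8L, 16L), 1)
    img <- random_byte_image(sample(4:16, 1), sample(4:16, 1))
    for (ang in c(0, 45, 90, 135, 180)) {
      got <- glrlm_features(img, levels = L, angles = ang)
      want <- oracle_glrlm_features(img, L, ang)
      for (nm in names(want)) expect_equal(got[[nm]], want[[nm]])
    }
    # run-count matrix against explicit run enumeration
    runs <- oracle_glrlm_runs(img, L, 45)
    rmat <- glrlm_matrix(quantize_levels(img, L), L, 45)
    expect_equal(sum(rmat), length(runs$length))
    for (g in unique(runs$level)) {
      expect_equal(sum(rmat[g + 1L, ]), sum(runs$level == g))
    }
    # 180 degrees duplicates the 0-degree runs
    expect_identical(glrlm_matrix(quantize_levels(img, L), L, 180),
                     glrlm_matrix(quantize_levels(img, L), L, 0))
  }
})

test_that("echovariation is invariant under multiplicative intensity scaling", {
  set.seed(9)
  img <- matrix(2L * (sample.int(128L, 150, replace = TRUE) - 1L), 10, 15)
  half <- img / 2L
  storage.mode(half) <- "integer"
  fo1 <- first_order_features(img)
  fo2 <- first_order_features(half)
  expect_equal(fo2$echovariation, fo1$echovariation, tolerance = 1e-12)
  expect_equal(fo2$echointensity, fo1$echointensity * 0.5, tolerance = 1e-12)
})

test_that("grid-aligned constant shifts move the mean but not the texture", {
  set.seed(13)
  img <- matrix(sample.int(128L, 120, replace = TRUE) - 1L, 10, 12)
  shifted <- img + 16L                    # shift by one full quantisation bin
  fo1 <- first_order_features(img); fo2 <- first_order_features(shifted)
  expect_equal(fo2$variance, fo1$variance)
  expect_equal(fo2$sd, fo1$sd)
  expect_lt(fo2$echovariation, fo1$echovariation)
  expect_equal(glcm_features(glcm_matrix(shifted, 2, 0, 256))$contrast,
               glcm_features(glcm_matrix(img, 2, 0, 256))$contrast)
  expect_equal(glrlm_features(shifted), glrlm_features(img))
})

test_that("ASM never exceeds the maximum probability; entropy vanishes iff ASM is 1", {
  set.seed(31)
  for (rep in 1:20) {
    img <- random_level_image(8, 8, sample(c(2L, 4L, 8L), 1))
    g <- glcm_features(glcm_matrix(img, 1, 0, 8))
    expect_lte(g$asm, g$max_probability + 1e-15)
    expect_lte(g$max_probability, 1)
    if (g$asm == 1) expect_equal(g$entropy, 0) else expect_gt(g$entropy, 0)
  }
})

test_that("extract_all returns 21 named finite features, deterministically", {
  set.seed(1)
  img <- random_byte_image(32, 40)
  v1 <- extract_all(img)
  expect_identical(names(v1), feature_names())
  expect_length(v1, 21L)
  expect_true(all(is.finite(v1)))
  expect_identical(v1, extract_all(img))

  const <- matrix(90L, 16, 16)
  vc <- extract_all(const)
  expect_equal(unname(vc["correlation"]), 1)
  expect_equal(unname(vc["echovariation"]), 0)
  expect_length(vc, 21L)
})
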