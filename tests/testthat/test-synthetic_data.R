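small_profiles <- function(n = 2L) {
  p <- grade_profiles()
  p$n <- rep(n, 4)
  p
}

test_that("per-grade EV draws reproduce the target moments", {
  set.seed(100)
  prof4 <- grade_profiles()[4, ]
  draws <- sample_grade_ev(prof4, 1e5)
  expect_equal(mean(draws), 26.85, tolerance = 0.05 / 26.85)
  expect_equal(sd(draws), 4.06, tolerance = 0.05 / 4.06)
  expect_true(all(draws > 5 & draws < 150))
})

test_that("truncation is inactive for grades 2-4 at the default profiles", {
  prof <- grade_profiles()
  for (g in 2:4) {
    set.seed(200 + g)
    truncated <- sample_grade_ev(prof[g, ], 1e5)
    set.seed(200 + g)
    raw <- rnorm(1e5, prof$ev_mean[g], prof$ev_sd[g])
    expect_identical(truncated, raw)     # no draw was ever rejected
  }
})

test_that("EV draws are reproducible under a fixed seed", {
  prof <- grade_profiles()[2, ]
  set.seed(7); a <- sample_grade_ev(prof, 50)
  set.seed(7); b <- sample_grade_ev(prof, 50)
  expect_identical(a, b)
})

test_that("generated images round-trip their EV and EI targets", {
  cfg <- synthetic_config()
  for (g in c(1L, 4L)) {
    r <- generate_image(g, cfg, seed = 1000 + g)
    fo <- first_order_features(r$image)
    expect_lte(abs(fo$echovariation - r$truth$ev_target), 1.5)
    expect_lte(abs(fo$echointensity - r$truth$ei_target), 2)
    expect_true(all(r$image >= 0 & r$image <= 255))
  }
})

test_that("uncorrelated speckle has near-zero GLCM correlation", {
  cfg <- synthetic_config(correlation_length = 0, striation_amplitude = 0)
  r <- generate_image(2L, cfg, seed = 5)
  g <- glcm_features(glcm_matrix(r$image))
  expect_lt(abs(g$correlation), 0.05)
})

test_that("images and cohorts are byte-identical under a fixed seed", {
  cfg <- synthetic_config(profiles = small_profiles(), seed = 99L)
  a <- generate_image(3L, cfg, seed = 42)
  b <- generate_image(3L, cfg, seed = 42)
  expect_identical(a, b)
  ca <- generate_cohort(cfg)
  cb <- generate_cohort(cfg)
  expect_identical(ca, cb)
  cc <- generate_cohort(synthetic_config(profiles = small_profiles(), seed = 98L))
  expect_false(identical(ca$images, cc$images))
  expect_identical(names(ca$images), names(cc$images))   # schema unchanged
})

test_that("small cohorts have the configured size and schema", {
  cohort <- generate_cohort(synthetic_config(profiles = small_profiles(), seed = 1L))
  expect_length(cohort$images, 8L)
  expect_identical(as.integer(table(cohort$table$grade)), rep(2L, 4))
  expect_identical(cohort$table$image_id, names(cohort$images))
  expect_true(all(c("ev_target", "ei_target", "clip_fraction") %in%
                    names(cohort$truth)))
})

test_that("the default cohort is grade-monotone and calibrated to its EV targets", {
  cohort <- generate_cohort(synthetic_config(seed = 42L))
  expect_length(cohort$images, 130L)
  expect_identical(as.integer(table(cohort$table$grade)), c(24L, 58L, 24L, 24L))
  fo <- t(vapply(cohort$images, function(im) {
    f <- first_order_features(im)
    c(ei = f$echointensity, ev = f$echovariation)
  }, numeric(2)))
  mean_ei <- tapply(fo[, "ei"], cohort$table$grade, mean)
  mean_ev <- tapply(fo[, "ev"], cohort$table$grade, mean)
  expect_true(all(diff(mean_ei) > 0))    # EI rises with impairment grade
  expect_true(all(diff(mean_ev) < 0))    # EV falls with impairment grade
  expect_gte(cor(fo[, "ev"], cohort$truth$ev_target), 0.99)
})

test_that("cohorts write images, table and ground truth to disk", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(synthetic_config(profiles = small_profiles(), seed = 3L))
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_length(list.files(dir, pattern = "\\.png$"), 8L)
  back <- read_grey_image(file.path(dir, paste0(cohort$table$image_id[1], ".png")))
  expect_equal(back, cohort$images[[1L]], ignore_attr = TRUE)
  tab <- load_cohort_table(file.path(dir, "cohort.csv"))
  expect_identical(tab$grade, cohort$table$grade)
})

test_that("infeasible EV/EI combinations raise a generation error", {
  prof <- data.frame(grade = 1:4,
                     ev_mean = c(140, 120, 100, 80), ev_sd = rep(0.5, 4),
                     ei_mean = c(120, 160, 200, 240), n = rep(2L, 4))
  cfg <- synthetic_config(profiles = prof)
  expect_error(generate_image(4L, cfg, seed = 1), "infeasible|round-trip")
})
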