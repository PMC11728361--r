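#' Default per-grade cohort profiles
#'
#' One row per modified Heckmatt grade: the target echovariation (EV)
#' distribution (percent; mean and SD), the target mean echointensity (EI)
#' and the group size. The EV distributions and group sizes reproduce the
#' study conditions of a 130-image post-stroke gastrocnemius medialis cohort:
#' EV falls and EI rises with increasing impairment grade. The EI profile is
#' a modelling choice (no per-grade EI values are published); see the methods
#' vignette.
#'
#' @return data frame with columns `grade`, `ev_mean`, `ev_sd`, `ei_mean`, `n`.
#' @export
grade_profiles <- function() {
  data.frame(grade = 1:4,
             ev_mean = c(67.28, 46.62, 37.16, 26.85),
             ev_sd = c(15.05, 7.17, 4.94, 4.06),
             ei_mean = c(60, 105, 150, 195),
             n = c(24L, 58L, 24L, 24L))
}

#' Synthetic cohort configuration
#'
#' @param profiles per-grade profile data frame (see [grade_profiles()]).
#' @param image_size integer `(rows, cols)`, each at least 64.
#' @param correlation_length speckle correlation length in pixels (Gaussian
#'   smoothing scale of the underlying random field); 0 gives pixelwise
#'   independent speckle.
#' @param striation_amplitude amplitude of the sinusoidal fascicular banding
#'   as a fraction of the speckle field; the banding is strongest at grade 1
#'   (scaled by `(5 - grade) / 4`) and vanishes as the muscle architecture is
#'   effaced at grade 4.
#' @param striation_period vertical period of the banding in pixels.
#' @param seed integer RNG seed; a fixed seed yields a byte-identical cohort.
#' @return an object of class `cohort_config`.
#' @export
synthetic_config <- function(profiles = grade_profiles(),
                             image_size = c(128L, 128L),
                             correlation_length = 2,
                             striation_amplitude = 0.2,
                             striation_period = 16,
                             seed = 42L) {
  stopifnot(is.data.frame(profiles),
            all(c("grade", "ev_mean", "ev_sd", "ei_mean", "n") %in%
                  names(profiles)))
  if (any(profiles$ev_mean <= 0) || any(profiles$ev_sd <= 0) ||
      any(profiles$ei_mean <= 0) || any(profiles$ei_mean >= 255)) {
    stop("grade profiles need ev_mean > 0, ev_sd > 0, ei_mean in (0, 255)",
         call. = FALSE)
  }
  o <- order(profiles$grade)
  if (any(diff(profiles$ei_mean[o]) <= 0) || any(diff(profiles$ev_mean[o]) >= 0)) {
    stop("profiles must be grade-monotone: ei_mean increasing, ev_mean decreasing",
         call. = FALSE)
  }
  if (length(image_size) != 2L || any(image_size < 64L)) {
    stop("image_size must be (rows, cols) with both >= 64", call. = FALSE)
  }
  structure(list(profiles = profiles,
                 image_size = as.integer(image_size),
                 correlation_length = correlation_length,
                 striation_amplitude = striation_amplitude,
                 striation_period = striation_period,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw per-image echovariation targets for a grade
#'
#' Samples from Normal(ev_mean, ev_sd^2) truncated to (5, 150) percent, by
#' rejection. For the default profiles the truncation is effectively inactive
#' at grades 2-4 (the bounds lie more than 5 SDs from the means).
#'
#' @param profile one row of a profile data frame.
#' @param n number of draws.
#' @return numeric vector of EV targets in percent.
#' @export
sample_grade_ev <- function(profile, n = 1L) {
  lo <- 5; hi <- 150
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n - length(out), profile$ev_mean, profile$ev_sd)
    out <- c(out, draw[draw > lo & draw < hi])
  }
  out
}

# Separable Gaussian smoothing with truncated, edge-renormalised kernels.
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  band <- function(n) {
    B <- outer(seq_len(n), seq_len(n),
               function(i, j) ifelse(abs(i - j) <= rad, k[abs(i - j) + rad + 1L], 0))
    B / rowSums(B)
  }
  band(nrow(mat)) %*% mat %*% t(band(ncol(mat)))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Generate one synthetic graded speckle image
#'
#' Emulates a B-mode muscle ultrasound ROI at a given impairment grade:
#' \enumerate{
#'   \item draw the image's EV target from the grade's truncated normal;
#'   \item build a spatially correlated lognormal speckle field (Gaussian
#'     random field smoothed to `correlation_length`, standardised to the
#'     log-scale SD matching the target coefficient of variation, then
#'     exponentiated);
#'   \item add sinusoidal fascicular striation scaled by
#'     `striation_amplitude * (5 - grade) / 4`;
#'   \item affinely standardise the field so the continuous image has exactly
#'     the target mean EI and SD `ei_mean * EV / 100`, iterating the
#'     standardise-and-clip step so the clipped image retains the target
#'     moments (saturated pixels at 0/255 model acoustic saturation);
#'   \item round to 8-bit.
#' }
#' Generation fails if the target SD exceeds the Bhatia-Davis variance bound
#' for a [0, 255] distribution with the target mean (infeasible EV/EI
#' combination) or if the extracted EV of the final 8-bit image deviates from
#' the target by more than 1.5 percent-points.
#'
#' @param grade impairment grade 1-4.
#' @param config a [synthetic_config()].
#' @param seed optional integer seed for this single image; by default the
#'   current RNG state is used (as inside [generate_cohort()]).
#' @return list with `image` (integer matrix) and `truth` (one-row data frame
#'   with `grade`, `ev_target`, `ei_target`, `clip_fraction`).
#' @export
generate_image <- function(grade, config = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  prof <- config$profiles[config$profiles$grade == grade, , drop = FALSE]
  if (nrow(prof) != 1L) stop(sprintf("no profile for grade %s", grade), call. = FALSE)
  ev_target <- sample_grade_ev(prof, 1L)
  ei_target <- prof$ei_mean
  nr <- config$image_size[1L]; nc <- config$image_size[2L]

  g <- matrix(stats::rnorm(nr * nc), nr, nc)
  g <- gauss_smooth(g, config$correlation_length)
  cv <- ev_target / 100
  sigma_log <- sqrt(log1p(cv^2))            # lognormal shape matched to target CV
  g <- (g - mean(g)) / pop_sd(g) * sigma_log
  f <- exp(g)
  if (config$striation_amplitude > 0) {
    amp <- config$striation_amplitude * (5 - grade) / 4
    f <- f + amp * sin(2 * pi * seq_len(nr) / config$striation_period)
  }

  s_target <- ei_target * cv
  # Bhatia-Davis: a distribution on [0, 255] with mean m has variance at most
  # m * (255 - m); targets near that bound cannot survive clipping
  if (s_target^2 > 0.95 * ei_target * (255 - ei_target)) {
    stop(sprintf(
      "infeasible EV target %.2f at grade %d: SD %.1f exceeds the [0,255] bound for mean EI %.0f",
      ev_target, grade, s_target, ei_target), call. = FALSE)
  }
  v <- ei_target + (f - mean(f)) / pop_sd(f) * s_target
  clip_fraction <- mean(v < 0 | v > 255)
  # iterate standardise-and-clip so the clipped image keeps the exact moments
  for (it in 1:60) {
    w <- pmin(pmax(v, 0), 255)
    if (abs(mean(w) - ei_target) < 1e-6 && abs(pop_sd(w) - s_target) < 1e-6) break
    v <- ei_target + (w - mean(w)) / pop_sd(w) * s_target
  }
  img <- round(pmin(pmax(v, 0), 255))
  storage.mode(img) <- "integer"
  fo <- first_order_features(img)
  if (abs(fo$echovariation - ev_target) > 1.5) {
    stop(sprintf(
      "round-trip failure at grade %d: extracted EV %.2f vs target %.2f",
      grade, fo$echovariation, ev_target), call. = FALSE)
  }
  list(image = img,
       truth = data.frame(grade = grade, ev_target = ev_target,
                          ei_target = ei_target,
                          clip_fraction = clip_fraction))
}

#' Generate a full graded synthetic cohort
#'
#' Emits one image per cohort row (default group sizes 24/58/24/24 for grades
#' 1-4, i.e. 130 images), a cohort metadata table whose ROI is the full image,
#' and a ground-truth table. Fully deterministic for a fixed `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `images` (named list of matrices), `table` (cohort data
#'   frame) and `truth` (data frame with per-image EV/EI targets and clip
#'   fractions, plus the seed).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  grades <- rep(config$profiles$grade, times = config$profiles$n)
  n_total <- length(grades)
  ids <- sprintf("img%03d", seq_len(n_total))
  images <- vector("list", n_total)
  names(images) <- ids
  truth <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    gi <- generate_image(grades[i], config)
    images[[i]] <- gi$image
    truth[[i]] <- gi$truth
  }
  truth <- do.call(rbind, truth)
  truth <- cbind(image_id = ids, truth, seed = config$seed)
  table <- data.frame(image_id = ids,
                      row_start = 0L, row_end = config$image_size[1L],
                      col_start = 0L, col_end = config$image_size[2L],
                      subject_id = sprintf("S%02d", (seq_len(n_total) - 1L) %/% 6L + 1L),
                      limb = rep(c("left", "right"), length.out = n_total),
                      grade = grades)
  list(images = images, table = table, truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Writes `<image_id>.png` files, the cohort CSV and a ground-truth JSON into
#' `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$images)) {
    write_grey_image(cohort$images[[id]], file.path(dir, paste0(id, ".png")))
  }
  write_cohort_table(cohort$table, file.path(dir, "cohort.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
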