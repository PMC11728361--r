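#' Canonical names of the 21 echotexture features
#'
#' Six first-order (histogram) features, ten grey-level co-occurrence matrix
#' (GLCM) features and five grey-level run length matrix (GLRLM) features.
#'
#' @return character vector of length 21.
#' @export
feature_names <- function() {
  c("echointensity", "variance", "sd", "echovariation", "skew", "kurtosis",
    "correlation", "dissimilarity", "contrast", "homogeneity", "asm",
    "energy", "max_probability", "entropy", "cluster_shade",
    "cluster_prominence",
    "sre", "lre", "glu", "rlu", "rpc")
}

#' First-order (histogram) features of a ROI
#'
#' All moments are population moments (divisor n) over the full ROI pixel
#' population. Echointensity (EI) is the mean intensity; echovariation (EV)
#' is the coefficient of variation of intensity in percent, 100 * sd / mean.
#' Skewness is Fisher-Pearson g1 and kurtosis is Fisher excess kurtosis
#' (normal -> 0), both the biased (divisor n) estimators. For a constant ROI
#' (sd = 0) skew and kurtosis are reported as 0 and the result is flagged
#' degenerate; an all-black ROI additionally has EV = 0 by convention.
#'
#' @param roi greyscale intensity matrix.
#' @return a list with elements `echointensity`, `variance`, `sd`,
#'   `echovariation`, `skew`, `kurtosis` and a logical `degenerate` flag.
#' @export
first_order_features <- function(roi) {
  assert_grey_image(roi, "ROI")
  x <- as.numeric(roi)
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- sqrt(v)
  degenerate <- s == 0
  ev <- if (m > 0) 100 * s / m else 0
  if (degenerate) {
    g1 <- 0
    g2 <- 0
  } else {
    g1 <- mean((x - m)^3) / s^3
    g2 <- mean((x - m)^4) / v^2 - 3
  }
  list(echointensity = m, variance = v, sd = s, echovariation = ev,
       skew = g1, kurtosis = g2, degenerate = degenerate)
}

glcm_offset <- function(angle, distance) {
  switch(as.character(angle),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stop(sprintf("unsupported GLCM angle %s (use 0, 45, 90 or 135)", angle),
              call. = FALSE))
}

#' Grey-level co-occurrence matrix
#'
#' Counts ordered (non-symmetric) pixel pairs (reference, neighbour) at the
#' given offset and normalises by the pair count. With the defaults
#' (distance 5, angle 0, 256 levels) the neighbour is 5 pixels to the right
#' and 8-bit intensities are used directly as levels, with no rescaling.
#'
#' @param roi greyscale intensity matrix with values `< levels`.
#' @param distance pixel offset between the members of a pair.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param levels number of grey levels.
#' @return an object of class `glcm`: list with the `levels` x `levels`
#'   probability matrix `p` and the settings.
#' @export
glcm_matrix <- function(roi, distance = 5L, angle = 0, levels = 256L) {
  assert_grey_image(roi, "ROI")
  distance <- as.integer(distance)
  levels <- as.integer(levels)
  if (distance < 1L) stop("distance must be >= 1", call. = FALSE)
  if (any(roi >= levels)) {
    stop(sprintf("ROI has intensities >= levels (%d)", levels), call. = FALSE)
  }
  off <- glcm_offset(angle, distance)
  nr <- nrow(roi); nc <- ncol(roi)
  r_lo <- max(1L, 1L - off[1L]); r_hi <- min(nr, nr - off[1L])
  c_lo <- max(1L, 1L - off[2L]); c_hi <- min(nc, nc - off[2L])
  if (r_lo > r_hi || c_lo > c_hi) {
    stop(sprintf("ROI %d x %d has no pixel pair at distance %d, angle %s",
                 nr, nc, distance, angle), call. = FALSE)
  }
  r0 <- r_lo:r_hi
  c0 <- c_lo:c_hi
  ref <- roi[r0, c0, drop = FALSE]
  nb <- roi[r0 + off[1L], c0 + off[2L], drop = FALSE]
  idx <- as.integer(ref) * levels + as.integer(nb) + 1L
  counts <- tabulate(idx, nbins = levels * levels)
  p <- matrix(counts / sum(counts), nrow = levels, ncol = levels, byrow = TRUE)
  structure(list(p = p, distance = distance, angle = angle, levels = levels),
            class = "glcm")
}

#' GLCM texture features
#'
#' Computes the ten second-order features from a normalised co-occurrence
#' matrix: correlation, dissimilarity, contrast, homogeneity, angular second
#' moment (ASM), energy, maximum probability, entropy (natural log over
#' nonzero entries), cluster shade and cluster prominence (Conners moments of
#' order 3 and 4 about the marginal means). Correlation is defined as 1 when
#' either marginal has zero variance.
#'
#' @param m a `glcm` object or a normalised probability matrix.
#' @return named list of the ten feature values.
#' @export
glcm_features <- function(m) {
  p <- if (inherits(m, "glcm")) m$p else m
  if (!is.matrix(p) || nrow(p) != ncol(p)) {
    stop("GLCM must be a square matrix", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("GLCM is not normalised (sum = %.12g)", sum(p)), call. = FALSE)
  }
  L <- nrow(p)
  lv <- seq_len(L) - 1                      # levels 0 .. L-1
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  mu_i <- sum(lv * pi_)
  mu_j <- sum(lv * pj_)
  sd_i <- sqrt(sum((lv - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((lv - mu_j)^2 * pj_))
  D <- outer(lv, lv, "-")                   # i - j
  S <- outer(lv - mu_i, lv - mu_j, "+")     # (i - mu_i) + (j - mu_j)
  contrast <- sum(p * D^2)
  dissimilarity <- sum(p * abs(D))
  homogeneity <- sum(p / (1 + D^2))
  asm <- sum(p^2)
  correlation <- if (sd_i * sd_j == 0) 1 else {
    sum(p * outer(lv - mu_i, lv - mu_j)) / (sd_i * sd_j)
  }
  pos <- p[p > 0]
  list(correlation = correlation,
       dissimilarity = dissimilarity,
       contrast = contrast,
       homogeneity = homogeneity,
       asm = asm,
       energy = sqrt(asm),
       max_probability = max(p),
       entropy = -sum(pos * log(pos)),
       cluster_shade = sum(p * S^3),
       cluster_prominence = sum(p * S^4))
}

#' Quantise 8-bit intensities to run-length grey levels
#'
#' Equal-width binning: `floor(g * levels / 256)`, mapping 0..255 onto
#' 0..levels-1.
#'
#' @param img intensity matrix (0..255).
#' @param levels number of quantised levels.
#' @return integer matrix of levels in 0..levels-1.
#' @export
quantize_levels <- function(img, levels = 16L) {
  assert_grey_image(img)
  q <- floor(img * as.integer(levels) / 256)
  storage.mode(q) <- "integer"
  q
}

# Decompose a matrix into scan lines for one run-length direction.
# Runs are direction-insensitive along a line, so 0 and 180 degrees share
# lines; both are still computed when requested.
glrlm_lines <- function(q, angle) {
  nr <- nrow(q); nc <- ncol(q)
  if (angle %in% c(0, 180)) {
    lines <- lapply(seq_len(nr), function(r) q[r, ])
    if (angle == 180) lines <- lapply(lines, rev)
  } else if (angle == 90) {
    lines <- lapply(seq_len(nc), function(c) q[, c])
  } else if (angle == 45) {
    # constant r + c, traversed up-right
    lines <- lapply(split(as.vector(q), row(q) + col(q)),
                    function(v) rev(v))
  } else if (angle == 135) {
    # constant r - c
    lines <- split(as.vector(q), row(q) - col(q))
  } else {
    stop(sprintf("unsupported GLRLM angle %s", angle), call. = FALSE)
  }
  lines
}

#' Grey-level run length matrix for one direction
#'
#' Entry `r[g + 1, l]` counts the maximal runs of `l` consecutive pixels at
#' quantised level `g` along the direction.
#'
#' @param q integer matrix of quantised levels (0..n_levels-1).
#' @param n_levels number of quantised levels.
#' @param angle one of 0, 45, 90, 135, 180 (degrees).
#' @return matrix with `n_levels` rows and `max(nrow, ncol)` columns.
#' @export
glrlm_matrix <- function(q, n_levels = 16L, angle = 0) {
  lines <- glrlm_lines(q, angle)
  max_len <- max(nrow(q), ncol(q))
  r <- matrix(0, nrow = n_levels, ncol = max_len)
  for (v in lines) {
    runs <- rle(as.integer(v))
    for (k in seq_along(runs$lengths)) {
      r[runs$values[k] + 1L, runs$lengths[k]] <-
        r[runs$values[k] + 1L, runs$lengths[k]] + 1
    }
  }
  r
}

glrlm_features_one <- function(q, n_levels, angle) {
  lines <- glrlm_lines(q, angle)
  lens <- integer(0)
  levs <- integer(0)
  for (v in lines) {
    runs <- rle(as.integer(v))
    lens <- c(lens, runs$lengths)
    levs <- c(levs, runs$values)
  }
  n_r <- length(lens)
  n_p <- length(q)
  list(sre = sum(1 / lens^2) / n_r,
       lre = sum(as.numeric(lens)^2) / n_r,
       glu = sum(as.numeric(table(levs))^2) / n_r,
       rlu = sum(as.numeric(table(lens))^2) / n_r,
       rpc = n_r / n_p)
}

#' GLRLM texture features
#'
#' Quantises the ROI to `levels` equal-width grey bins, builds a run length
#' matrix for each of the five analysed directions (0, 45, 90, 135 and 180
#' degrees) and reports the arithmetic mean of each feature across the
#' directions: short run emphasis (SRE), long run emphasis (LRE), grey-level
#' uniformity (GLU), run length uniformity (RLU) and run percentage (RPC).
#' The 180-degree scan yields the same runs as the 0-degree scan; it is
#' nevertheless computed and included in the average by default, matching the
#' five-angle protocol. Set `angles = c(0, 45, 90, 135)` for the conventional
#' four-direction average.
#'
#' @param roi greyscale intensity matrix.
#' @param levels number of quantised grey levels.
#' @param angles directions (degrees) to average over.
#' @return named list with `sre`, `lre`, `glu`, `rlu`, `rpc`.
#' @export
glrlm_features <- function(roi, levels = 16L, angles = c(0, 45, 90, 135, 180)) {
  assert_grey_image(roi, "ROI")
  q <- quantize_levels(roi, levels)
  per_angle <- lapply(angles, function(a) glrlm_features_one(q, levels, a))
  out <- lapply(c("sre", "lre", "glu", "rlu", "rpc"), function(nm) {
    mean(vapply(per_angle, `[[`, numeric(1), nm))
  })
  names(out) <- c("sre", "lre", "glu", "rlu", "rpc")
  out
}

#' Extract all 21 echotexture features of a ROI
#'
#' Combines [first_order_features()] (on raw 8-bit intensities), the GLCM
#' features at distance 5, angle 0, 256 levels, and the GLRLM features at 16
#' levels averaged over the five directions.
#'
#' @param roi greyscale intensity matrix.
#' @param glcm_distance,glcm_angle,glcm_levels GLCM settings.
#' @param glrlm_levels,glrlm_angles GLRLM settings.
#' @return named numeric vector of length 21 (see [feature_names()]).
#' @export
extract_all <- function(roi, glcm_distance = 5L, glcm_angle = 0,
                        glcm_levels = 256L, glrlm_levels = 16L,
                        glrlm_angles = c(0, 45, 90, 135, 180)) {
  fo <- first_order_features(roi)
  g <- glcm_features(glcm_matrix(roi, glcm_distance, glcm_angle, glcm_levels))
  r <- glrlm_features(roi, glrlm_levels, glrlm_angles)
  out <- c(unlist(fo[c("echointensity", "variance", "sd", "echovariation",
                       "skew", "kurtosis")]),
           unlist(g), unlist(r))
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Extract features for every image of a cohort
#'
#' @param images named list of greyscale matrices (names are image ids), or a
#'   directory containing `<image_id>.png` files.
#' @param table cohort data frame (see [load_cohort_table()]); ROIs are
#'   cropped before extraction.
#' @param ... passed to [extract_all()].
#' @return data frame: metadata columns followed by the 21 feature columns.
#' @export
extract_cohort_features <- function(images, table, ...) {
  feats <- matrix(NA_real_, nrow = nrow(table), ncol = 21L,
                  dimnames = list(NULL, feature_names()))
  for (i in seq_len(nrow(table))) {
    id <- table$image_id[i]
    img <- if (is.character(images)) {
      read_grey_image(file.path(images, paste0(id, ".png")))
    } else {
      images[[id]]
    }
    if (is.null(img)) stop(sprintf("no image for id '%s'", id), call. = FALSE)
    roi <- extract_roi(img, roi_box(table$row_start[i], table$row_end[i],
                                    table$col_start[i], table$col_end[i]))
    feats[i, ] <- tryCatch(extract_all(roi, ...), error = function(e) {
      stop(sprintf("feature extraction failed for image '%s': %s",
                   id, conditionMessage(e)), call. = FALSE)
    })
  }
  cbind(table, as.data.frame(feats))
}
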