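# Independent brute-force oracles for the texture features. These deliberately
# use naive elementwise loops over pixels and matrix cells, sharing no code
# with the package implementation.

oracle_glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d))
}

# Count ordered co-occurrence pairs pixel by pixel, then normalise.
oracle_glcm_matrix <- function(img, distance, angle, levels) {
  off <- oracle_glcm_offset(angle, distance)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      r2 <- r + off[1L]; c2 <- c + off[2L]
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
        i <- img[r, c]; j <- img[r2, c2]
        counts[i + 1L, j + 1L] <- counts[i + 1L, j + 1L] + 1
      }
    }
  }
  counts / sum(counts)
}

# All ten GLCM features by explicit double loops over matrix cells.
oracle_glcm_features <- function(p) {
  L <- nrow(p)
  mu_i <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  var_i <- 0; var_j <- 0
  for (i in 1:L) for (j in 1:L) {
    var_i <- var_i + (i - 1 - mu_i)^2 * p[i, j]
    var_j <- var_j + (j - 1 - mu_j)^2 * p[i, j]
  }
  contrast <- 0; dissim <- 0; homog <- 0; asm <- 0; ent <- 0
  corr_num <- 0; shade <- 0; prom <- 0
  for (i in 1:L) for (j in 1:L) {
    pij <- p[i, j]
    dd <- (i - 1) - (j - 1)
    ss <- (i - 1 - mu_i) + (j - 1 - mu_j)
    contrast <- contrast + pij * dd^2
    dissim <- dissim + pij * abs(dd)
    homog <- homog + pij / (1 + dd^2)
    asm <- asm + pij^2
    if (pij > 0) ent <- ent - pij * log(pij)
    corr_num <- corr_num + pij * (i - 1 - mu_i) * (j - 1 - mu_j)
    shade <- shade + pij * ss^3
    prom <- prom + pij * ss^4
  }
  corr <- if (var_i * var_j == 0) 1 else corr_num / sqrt(var_i * var_j)
  list(correlation = corr, dissimilarity = dissim, contrast = contrast,
       homogeneity = homog, asm = asm, energy = sqrt(asm),
       max_probability = max(p), entropy = ent, cluster_shade = shade,
       cluster_prominence = prom)
}

# Enumerate maximal runs along one direction by walking each scan line.
oracle_glrlm_runs <- function(img255, levels, angle) {
  q <- matrix(floor(as.numeric(img255) * levels / 256), nrow(img255))
  nr <- nrow(q); nc <- ncol(q)
  starts <- switch(as.character(angle),
    "0" = , "180" = lapply(seq_len(nr), function(r) c(r, 1L)),
    "90" = lapply(seq_len(nc), function(c) c(1L, c)),
    # 45: walk up-right from left column and bottom row
    "45" = c(lapply(seq_len(nr), function(r) c(r, 1L)),
             if (nc > 1) lapply(2:nc, function(c) c(nr, c))),
    # 135: walk down-right from top row and left column
    "135" = c(lapply(seq_len(nc), function(c) c(1L, c)),
              if (nr > 1) lapply(2:nr, function(r) c(r, 1L))))
  step <- switch(as.character(angle),
                 "0" = c(0L, 1L), "180" = c(0L, 1L), "90" = c(1L, 0L),
                 "45" = c(-1L, 1L), "135" = c(1L, 1L))
  run_level <- integer(0); run_len <- integer(0)
  for (s in starts) {
    r <- s[1L]; c <- s[2L]
    cur <- NA_integer_; len <- 0L
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- q[r, c]
      if (!is.na(cur) && v == cur) {
        len <- len + 1L
      } else {
        if (len > 0L) {
          run_level <- c(run_level, cur); run_len <- c(run_len, len)
        }
        cur <- v; len <- 1L
      }
      r <- r + step[1L]; c <- c + step[2L]
    }
    if (len > 0L) {
      run_level <- c(run_level, cur); run_len <- c(run_len, len)
    }
  }
  list(level = run_level, length = run_len)
}

oracle_glrlm_features <- function(img255, levels, angle) {
  runs <- oracle_glrlm_runs(img255, levels, angle)
  n_r <- length(runs$length)
  n_p <- length(img255)
  sre <- 0; lre <- 0
  for (l in runs$length) {
    sre <- sre + 1 / l^2
    lre <- lre + l^2
  }
  glu <- 0
  for (g in unique(runs$level)) glu <- glu + sum(runs$level == g)^2
  rlu <- 0
  for (l in unique(runs$length)) rlu <- rlu + sum(runs$length == l)^2
  list(sre = sre / n_r, lre = lre / n_r, glu = glu / n_r, rlu = rlu / n_r,
       rpc = n_r / n_p)
}

random_level_image <- function(nr, nc, levels) {
  matrix(sample.int(levels, nr * nc, replace = TRUE) - 1L, nr, nc)
}

random_byte_image <- function(nr, nc) {
  matrix(sample.int(256L, nr * nc, replace = TRUE) - 1L, nr, nc)
}

# Construct a vector with exact divisor-n mean and SD (for pooled-moment checks)
moment_matched_sample <- function(n, mean, sd) {
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / sqrt(base::mean((z - base::mean(z))^2))
  mean + sd * z
}
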