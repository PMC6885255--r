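# Independent brute-force oracles: every statistic is recomputed here by
# explicit enumeration over pixels/pairs, sharing no code with the package
# implementations.

# random small image + lesion mask fixture
random_lesion <- function(seed, max_dim = 10) {
  set.seed(seed)
  nr <- sample(5:max_dim, 1)
  nc <- sample(5:max_dim, 1)
  img <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
  repeat {
    mask <- matrix(stats::runif(nr * nc) < 0.7, nr, nc)
    if (sum(mask) >= 4) break
  }
  list(image = img, mask = mask)
}

oracle_glcm <- function(image, mask, levels = 16) {
  vals <- image[mask]
  lo <- min(vals); hi <- max(vals)
  nr <- nrow(image); nc <- ncol(image)
  qm <- matrix(NA_integer_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) if (mask[r, c]) {
    qm[r, c] <- if (hi > lo)
      min(levels - 1, floor((image[r, c] - lo) / (hi - lo) * levels)) else 0L
  }
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  acc <- NULL
  for (d in dirs) {
    P <- matrix(0, levels, levels)
    for (r in 1:nr) for (c in 1:nc) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          mask[r, c] && mask[r2, c2]) {
        P[qm[r, c] + 1, qm[r2, c2] + 1] <- P[qm[r, c] + 1, qm[r2, c2] + 1] + 1
        P[qm[r2, c2] + 1, qm[r, c] + 1] <- P[qm[r2, c2] + 1, qm[r, c] + 1] + 1
      }
    }
    if (sum(P) == 0) next
    p <- P / sum(P)
    energy <- 0; contrast <- 0; entropy <- 0; deficit <- 0
    for (i in 0:(levels - 1)) for (j in 0:(levels - 1)) {
      pij <- p[i + 1, j + 1]
      energy <- energy + pij^2
      contrast <- contrast + (i - j)^2 * pij
      if (pij > 0) entropy <- entropy - pij * log2(pij)
      deficit <- deficit + pij / (1 + (i - j)^2)
    }
    mu_i <- 0; mu_j <- 0
    for (i in 0:(levels - 1)) for (j in 0:(levels - 1)) {
      mu_i <- mu_i + i * p[i + 1, j + 1]
      mu_j <- mu_j + j * p[i + 1, j + 1]
    }
    var_i <- 0; var_j <- 0; cov <- 0
    for (i in 0:(levels - 1)) for (j in 0:(levels - 1)) {
      var_i <- var_i + (i - mu_i)^2 * p[i + 1, j + 1]
      var_j <- var_j + (j - mu_j)^2 * p[i + 1, j + 1]
      cov <- cov + (i - mu_i) * (j - mu_j) * p[i + 1, j + 1]
    }
    correlation <- if (sqrt(var_i * var_j) <= .Machine$double.eps) 0 else
      cov / sqrt(var_i * var_j)
    acc <- rbind(acc, c(energy, contrast, correlation, entropy, deficit))
  }
  stats::setNames(colMeans(acc),
                  c("energy", "contrast", "correlation", "entropy", "deficit_matrix"))
}

# neighbor offsets p = 0..7: top-left then clockwise
oracle_lbp_hist <- function(image, mask) {
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  nr <- nrow(image); nc <- ncol(image)
  counts <- numeric(256)
  ncoded <- 0
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c]) next
    if (r == 1 || r == nr || c == 1 || c == nc) next
    code <- 0
    for (p in 0:7) {
      nb <- image[r + offs[[p + 1]][1], c + offs[[p + 1]][2]]
      if (nb - image[r, c] >= 0) code <- code + 2^p
    }
    counts[code + 1] <- counts[code + 1] + 1
    ncoded <- ncoded + 1
  }
  h <- if (ncoded > 0) counts / ncoded else counts
  stats::setNames(h, as.character(0:255))
}

oracle_kinetic_pixelwise <- function(phase_T, phase_t, mask) {
  rs <- c()
  for (r in 1:nrow(mask)) for (c in 1:ncol(mask)) {
    if (mask[r, c] && phase_t[r, c] > 0) {
      rs <- c(rs, (phase_T[r, c] - phase_t[r, c]) / phase_t[r, c])
    }
  }
  m <- sum(rs) / length(rs)
  c(std = sqrt(sum((rs - m)^2) / length(rs)), mean = m, max = max(rs))
}

oracle_stats <- function(image, mask) {
  v <- c()
  for (r in 1:nrow(mask)) for (c in 1:ncol(mask)) {
    if (mask[r, c]) v <- c(v, image[r, c])
  }
  n <- length(v)
  m <- sum(v) / n
  s <- sqrt(sum((v - m)^2) / n)
  tab <- table(round(v))
  p <- as.numeric(tab) / n
  ent <- -sum(p * log2(p))
  if (s == 0) {
    bias <- 0; peak <- 0
  } else {
    bias <- sum(((v - m) / s)^3) / n
    peak <- sum(((v - m) / s)^4) / n - 3
  }
  c(mean = m, std = s, entropy = ent, max = max(v), bias = bias, peak = peak)
}

# exhaustive Otsu: maximize between-class variance over all 255 cut points
oracle_otsu <- function(patch) {
  v <- as.numeric(patch)
  n <- length(v)
  best_t <- NA_integer_
  best_var <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / n
    w1 <- length(hi) / n
    bv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bv > best_var + 1e-12) {
      best_var <- bv
      best_t <- t
    }
  }
  best_t
}
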