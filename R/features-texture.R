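# Texture features over the segmented lesion: gray-level co-occurrence
# statistics and local binary pattern histograms.

GLCM_DIRECTIONS <- list(
  d0   = c(0L, 1L),     # 0 degrees
  d45  = c(-1L, 1L),    # 45 degrees
  d90  = c(-1L, 0L),    # 90 degrees
  d135 = c(-1L, -1L)    # 135 degrees
)

#' Gray-level co-occurrence features of a lesion
#'
#' Lesion intensities are min-max quantized to `levels` gray levels; pixel
#' pairs at distance 1 in the four directions (0, 45, 90, 135 degrees) with
#' both pixels inside the mask are accumulated symmetrically. Each
#' direction's matrix is normalized to probabilities p(i, j) and five
#' statistics are computed and averaged over the directions:
#' energy sum p^2, contrast sum (i-j)^2 p, correlation
#' sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j), entropy -sum p log2 p,
#' and the homogeneity ("deficit matrix") statistic sum p / (1 + (i-j)^2).
#'
#' @param image Numeric grayscale matrix.
#' @param mask Logical lesion mask (nonempty).
#' @param levels Number of quantization levels (default 16).
#' @param directions Subset of `c("d0", "d45", "d90", "d135")`.
#' @return Named vector `(energy, contrast, correlation, entropy,
#'   deficit_matrix)`. Correlation is 0 by convention when a marginal
#'   standard deviation vanishes.
#' @export
glcm_features <- function(image, mask, levels = 16,
                          directions = names(GLCM_DIRECTIONS)) {
  if (!any(mask)) abort("empty mask", "feature_error")
  vals <- image[mask]
  rng <- range(vals)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (rng[2] > rng[1]) {
    q[mask] <- pmin(levels - 1L,
                    as.integer(floor((vals - rng[1]) / (rng[2] - rng[1]) * levels)))
  } else {
    q[mask] <- 0L
  }
  per_dir <- list()
  for (dn in directions) {
    off <- GLCM_DIRECTIONS[[dn]]
    a <- q
    b <- shift_mat_na(q, -off[1], -off[2])  # b[r,c] = q[r + dr, c + dc]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    i <- a[ok]; j <- b[ok]
    # symmetric accumulation: count (i, j) and (j, i)
    counts <- tabulate(c(i * levels + j, j * levels + i) + 1L,
                       nbins = levels * levels)
    p <- counts / sum(counts)
    per_dir[[dn]] <- glcm_stats(matrix(p, levels, levels), levels)
  }
  if (length(per_dir) == 0)
    abort("no valid pixel pair in any requested direction", "feature_error")
  if (length(per_dir) < length(directions))
    warning("some GLCM directions had no valid pixel pair and were dropped")
  colMeans(do.call(rbind, per_dir))
}

# p is the levels x levels probability matrix, p[i+1, j+1] = p(i, j).
glcm_stats <- function(p, levels) {
  lv <- 0:(levels - 1)
  I <- matrix(lv, levels, levels)
  J <- t(I)
  energy <- sum(p^2)
  contrast <- sum((I - J)^2 * p)
  pi_m <- rowSums(p)
  mu_i <- sum(lv * pi_m)
  sigma_i <- sqrt(sum((lv - mu_i)^2 * pi_m))
  pj_m <- colSums(p)
  mu_j <- sum(lv * pj_m)
  sigma_j <- sqrt(sum((lv - mu_j)^2 * pj_m))
  correlation <- if (sigma_i * sigma_j <= .Machine$double.eps) 0 else
    sum((I - mu_i) * (J - mu_j) * p) / (sigma_i * sigma_j)
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  deficit <- sum(p / (1 + (I - J)^2))
  c(energy = energy, contrast = contrast, correlation = correlation,
    entropy = entropy, deficit_matrix = deficit)
}

# Shift with NA padding (used to pair pixels with their offset neighbors).
shift_mat_na <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_integer_, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Local binary pattern code of one 3x3 neighborhood
#'
#' `code = sum_p S(g_p - g_c) 2^p` with `S(u) = 1` if `u >= 0` and 0
#' otherwise; neighbor p = 0 is the top-left pixel and p increases
#' clockwise.
#'
#' @param center Center pixel value `g_c`.
#' @param neighbors The 8 neighbor values `g_0 .. g_7` in fixed order
#'   (top-left, then clockwise).
#' @return Integer code in 0..255.
#' @export
lbp_code <- function(center, neighbors) {
  stopifnot(length(neighbors) == 8)
  sum(as.integer(neighbors - center >= 0) * 2^(0:7))
}

LBP_RETAINED_BINS <- c(1:15, 240:255)

#' Local binary pattern histogram of a lesion
#'
#' Codes are computed for every pixel whose center lies in the mask and
#' whose 3x3 neighborhood fits inside the image (neighbors are read from
#' the raw image regardless of mask membership). The full 256-bin histogram
#' is normalized by the number of coded pixels and the 31 retained bins
#' `{1..15, 240..255}` are returned.
#'
#' @param image Numeric grayscale matrix.
#' @param mask Logical lesion mask.
#' @param full Return the full 256-bin histogram instead of the retained
#'   bins (used by oracles and diagnostics).
#' @return Named numeric vector of bin frequencies (sums to <= 1; the full
#'   histogram sums to exactly 1 when at least one pixel was coded).
#' @export
lbp_histogram <- function(image, mask, full = FALSE) {
  if (!any(mask)) abort("empty mask", "feature_error")
  nr <- nrow(image); nc <- ncol(image)
  interior <- matrix(FALSE, nr, nc)
  if (nr >= 3 && nc >= 3) interior[2:(nr - 1), 2:(nc - 1)] <- TRUE
  centers <- mask & interior
  hist256 <- numeric(256)
  if (!any(centers)) {
    warning("no codable pixel in mask: all-zero LBP histogram")
  } else {
    code <- matrix(0L, nr, nc)
    for (p in 0:7) {
      off <- NEIGHBOUR_OFFSETS_8[p + 1, ]
      nb <- shift_mat_num(image, -off[1], -off[2])
      code <- code + as.integer(nb - image >= 0) * 2L^p
    }
    counts <- tabulate(code[centers] + 1L, nbins = 256)
    hist256 <- counts / sum(counts)
  }
  names(hist256) <- as.character(0:255)
  if (full) hist256 else hist256[as.character(LBP_RETAINED_BINS)]
}

shift_mat_num <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}
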