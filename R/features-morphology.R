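# Boundary morphology of the segmented lesion, built on normalized radial
# lengths (NRL): centroid-to-boundary distances scaled by their maximum.

# Boundary pixels: mask pixels with at least one 4-neighbor outside the
# mask (image edges count as outside), ordered by polar angle about the
# mask centroid.
boundary_pixels <- function(mask) {
  inside <- shift_mat(mask, 1, 0, fill = FALSE) &
    shift_mat(mask, -1, 0, fill = FALSE) &
    shift_mat(mask, 0, 1, fill = FALSE) &
    shift_mat(mask, 0, -1, fill = FALSE)
  b <- mask & !inside
  idx <- which(b, arr.ind = TRUE)
  ctr <- colMeans(which(mask, arr.ind = TRUE))
  ang <- atan2(idx[, 1] - ctr[1], idx[, 2] - ctr[2])
  ord <- order(ang, idx[, 1], idx[, 2])
  list(coords = idx[ord, , drop = FALSE], centroid = ctr)
}

# Moore-neighbor contour tracing (ring scanned in a fixed cyclic order,
# restarting just past the backtrack pixel). Terminates when the
# (pixel, backtrack-direction) state repeats, which closes the contour.
trace_contour <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  start <- as.integer(idx[order(idx[, 1], idx[, 2])[1], ])  # topmost-leftmost
  # cyclic ring order: W, NW, N, NE, E, SE, S, SW
  ring <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                   0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                 ncol = 2, byrow = TRUE)
  dir_index <- function(delta) {
    which(ring[, 1] == delta[1] & ring[, 2] == delta[2])
  }
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc &&
    mask[p[1], p[2]]
  cur <- start
  b_dir <- 1L   # backtrack pixel is W of the topmost-leftmost start: background
  seen <- new.env(hash = TRUE)
  path <- list()
  repeat {
    k <- paste(cur[1], cur[2], b_dir)
    first <- seen[[k]]
    if (!is.null(first)) {                       # state repeats: cycle closed
      return(do.call(rbind, path[first:length(path)]))
    }
    seen[[k]] <- length(path) + 1L
    path[[length(path) + 1L]] <- cur
    found <- FALSE
    for (s in 1:8) {
      d <- (b_dir - 1L + s) %% 8L + 1L          # first probe: one past backtrack
      p <- cur + ring[d, ]
      if (inside(p)) {
        prev_bg <- cur + ring[(d - 2L) %% 8L + 1L, ]  # last background examined
        b_dir <- dir_index(prev_bg - p)
        cur <- p
        found <- TRUE
        break
      }
    }
    if (!found) return(matrix(start, ncol = 2))  # isolated pixel
  }
}

# Perimeter: traced contour length with step weight 1 for axial moves and
# sqrt(2) for diagonal moves (closed contour).
contour_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(0)
  steps <- rbind(diff(contour), contour[1, ] - contour[n, ])
  steps <- steps[rowSums(abs(steps)) > 0, , drop = FALSE]
  sum(ifelse(rowSums(abs(steps)) == 2, sqrt(2), 1))
}

#' Morphology features of a lesion mask
#'
#' Seven descriptors built from the normalized radial lengths (NRL) of the
#' boundary and the traced contour: M1 NRL mean, M2 NRL standard deviation,
#' M3 compactness (tightness) `P^2 / (4 pi A)`, M4 roughness (cyclic mean
#' absolute difference of consecutive NRL values), M5 smoothness (cyclic
#' mean absolute deviation of each NRL value from the mean of its two
#' neighbors), M6 roundness `4 pi A / P^2`, and M7 area (pixel count).
#'
#' @param mask Logical mask, one 8-connected component with a boundary of
#'   at least 3 pixels.
#' @return Named vector `(M1, ..., M7)`.
#' @export
morphology_features <- function(mask) {
  if (!any(mask)) abort("empty mask", "feature_error")
  if (!is_single_component(mask, 8))
    abort("mask must be one 8-connected component", "feature_error")
  bp <- boundary_pixels(mask)
  k <- nrow(bp$coords)
  if (k < 3) abort("boundary shorter than 3 pixels", "feature_error")
  d <- sqrt((bp$coords[, 1] - bp$centroid[1])^2 +
              (bp$coords[, 2] - bp$centroid[2])^2)
  nrl <- d / max(d)
  m1 <- mean(nrl)
  m2 <- pop_sd(nrl)
  nxt <- c(nrl[-1], nrl[1])
  prv <- c(nrl[k], nrl[-k])
  m4 <- mean(abs(nrl - nxt))
  m5 <- mean(abs(nrl - (prv + nxt) / 2))
  area <- sum(mask)
  P <- contour_perimeter(trace_contour(mask))
  m3 <- P^2 / (4 * pi * area)
  m6 <- 4 * pi * area / P^2
  c(M1 = m1, M2 = m2, M3 = m3, M4 = m4, M5 = m5, M6 = m6, M7 = area)
}
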