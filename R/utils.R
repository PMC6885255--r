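# Internal helpers shared across modules.

# Error constructor carrying a condition class so callers can test for the
# specific failure mode (degenerate threshold, empty segmentation, ...).
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "subtyperad_error")))
}

# Shift a matrix by (dr, dc), padding the vacated band with `fill`.
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# 8-neighbourhood offsets in the fixed order used by the LBP operator:
# top-left, then clockwise.
NEIGHBOUR_OFFSETS_8 <- matrix(c(
  -1L, -1L,
  -1L,  0L,
  -1L,  1L,
   0L,  1L,
   1L,  1L,
   1L,  0L,
   1L, -1L,
   0L, -1L
), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("dr", "dc")))

# Binary dilation with the 8-connected structuring element (keeps original).
dilate8 <- function(m) {
  out <- m
  for (k in seq_len(nrow(NEIGHBOUR_OFFSETS_8))) {
    out <- out | shift_mat(m, NEIGHBOUR_OFFSETS_8[k, 1], NEIGHBOUR_OFFSETS_8[k, 2])
  }
  out
}

# Connected component of `candidate` containing seed (linear index), using
# 4- or 8-connectivity. Vectorized expansion: each pass dilates the current
# component and intersects with the candidate set.
connected_component <- function(candidate, seed_index, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  if (!candidate[seed_index]) {
    return(matrix(FALSE, nrow(candidate), ncol(candidate)))
  }
  offs <- if (connectivity == 8) NEIGHBOUR_OFFSETS_8 else
    NEIGHBOUR_OFFSETS_8[NEIGHBOUR_OFFSETS_8[, 1] == 0 | NEIGHBOUR_OFFSETS_8[, 2] == 0, , drop = FALSE]
  comp <- matrix(FALSE, nrow(candidate), ncol(candidate))
  comp[seed_index] <- TRUE
  repeat {
    grown <- comp
    for (k in seq_len(nrow(offs))) {
      grown <- grown | shift_mat(comp, offs[k, 1], offs[k, 2])
    }
    grown <- grown & candidate
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# TRUE iff the mask is a single connected component (and nonempty).
is_single_component <- function(mask, connectivity = 8) {
  n <- sum(mask)
  if (n == 0) return(FALSE)
  seed <- which(mask)[1]
  sum(connected_component(mask, seed, connectivity)) == n
}

# Stratified fold assignment: every class is spread as evenly as possible
# across the k folds. Returns an integer vector of fold ids per sample.
make_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  n <- length(labels)
  folds <- integer(n)
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Cross-validation scheme descriptor.
#' Cross-validation scheme
#'
#' Describes how out-of-fold predictions are produced: stratified k-fold
#' (default, `k = 5`) or leave-one-out.
#'
#' @param type `"kfold"` or `"loo"`.
#' @param k Number of folds for `"kfold"`.
#' @param seed Integer seed controlling the fold assignment.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(type = c("kfold", "loo"), k = 5, seed = 1) {
  type <- match.arg(type)
  structure(list(type = type, k = as.integer(k), seed = as.integer(seed)),
            class = "cv_scheme")
}

cv_fold_ids <- function(scheme, labels) {
  if (scheme$type == "loo") {
    seq_along(labels)
  } else {
    make_folds(labels, scheme$k, scheme$seed)
  }
}

# Population standard deviation (denominator n, not n - 1).
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}
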