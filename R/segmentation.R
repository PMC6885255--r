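# Lesion segmentation: seeded region growing inside a rectangular ROI.
#
# The dynamic mode derives its growth threshold from the ROI patch by Otsu's
# method, so no per-case parameter is needed; the classical fixed-threshold
# baseline grows by absolute intensity difference from the seed. Both share
# the same seed rule (geometric center of the ROI) and 8-connectivity.

#' Rectangular ROI annotation
#'
#' Coordinates are 0-based and half-open: the box covers image rows
#' `[row0, row1)` and columns `[col0, col1)`, matching the JSON annotation
#' format written by the phantom generator.
#'
#' @param row0,col0,row1,col1 Integer pixel bounds.
#' @return An `roi_box` object.
#' @export
roi_box <- function(row0, col0, row1, col1) {
  row0 <- as.integer(row0); col0 <- as.integer(col0)
  row1 <- as.integer(row1); col1 <- as.integer(col1)
  if (row1 <= row0 || col1 <= col0) abort("empty ROI box", "roi_error")
  if (row0 < 0 || col0 < 0) abort("ROI box outside image bounds", "roi_error")
  if ((row1 - row0) * (col1 - col0) < 9) abort("ROI box area must be >= 9 px", "roi_error")
  structure(list(row0 = row0, col0 = col0, row1 = row1, col1 = col1),
            class = "roi_box")
}

roi_rows <- function(roi) (roi$row0 + 1L):roi$row1
roi_cols <- function(roi) (roi$col0 + 1L):roi$col1

check_roi_in_image <- function(roi, image) {
  if (roi$row1 > nrow(image) || roi$col1 > ncol(image))
    abort("ROI box outside image bounds", "roi_error")
  invisible(roi)
}

#' Region-growing options
#'
#' @param mode `"dynamic_otsu"` (threshold from the ROI patch by Otsu's
#'   method) or `"fixed"` (preset threshold `T`).
#' @param threshold Fixed intensity threshold T (> 0) for `mode = "fixed"`.
#' @param connectivity 4 or 8 (default 8).
#' @param restrict_to_roi Keep growth inside the ROI box (default TRUE).
#' @param fill_holes Fill enclosed holes in the grown mask (default FALSE).
#' @param seed_relocation_window Half-width in pixels of the window searched
#'   for a brighter seed when the ROI center falls below the threshold.
#' @param criterion Growth criterion for the dynamic mode:
#'   `"otsu_foreground"` (default) grows the connected Otsu-foreground
#'   component containing the seed; `"seed_delta"` instead accepts pixels
#'   with `|I(p) - I(seed)| < |I(seed) - t*|`.
#' @return A `grow_options` object.
#' @export
grow_options <- function(mode = c("dynamic_otsu", "fixed"),
                         threshold = NULL,
                         connectivity = 8,
                         restrict_to_roi = TRUE,
                         fill_holes = FALSE,
                         seed_relocation_window = 3,
                         criterion = c("otsu_foreground", "seed_delta")) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  if (mode == "fixed") {
    if (is.null(threshold) || threshold <= 0)
      abort("fixed mode requires threshold T > 0", "grow_options_error")
  }
  stopifnot(connectivity %in% c(4, 8))
  structure(list(mode = mode, threshold = threshold,
                 connectivity = connectivity,
                 restrict_to_roi = isTRUE(restrict_to_roi),
                 fill_holes = isTRUE(fill_holes),
                 seed_relocation_window = as.integer(seed_relocation_window),
                 criterion = criterion),
            class = "grow_options")
}

#' Otsu threshold of an intensity patch
#'
#' Maximizes the between-class variance over the 256-bin histogram of
#' integer intensities in `[0, 255]`. The returned level `t*` defines the
#' foreground as pixels with intensity strictly greater than `t*`; among
#' tied maximizers the smallest level is returned.
#'
#' @param patch Numeric matrix or vector of integer intensities in 0..255.
#' @return The threshold level `t*` (integer in 0..254).
#' @export
otsu_threshold <- function(patch) {
  v <- as.numeric(patch)
  if (length(v) == 0) abort("empty patch", "degenerate_threshold_error")
  if (any(v < 0 | v > 255) || any(v != round(v)))
    abort("patch must contain integer intensities in [0, 255]", "degenerate_threshold_error")
  h <- tabulate(as.integer(v) + 1L, nbins = 256)
  if (sum(h > 0) < 2)
    abort("constant patch: Otsu threshold is degenerate", "degenerate_threshold_error")
  n <- sum(h)
  p <- h / n
  levels <- 0:255
  w0 <- cumsum(p)                       # class {I <= t}
  mu0 <- cumsum(p * levels)
  mu_t <- mu0[256]
  w1 <- 1 - w0
  # between-class variance at each cut t = 0..254
  t_idx <- 1:255
  valid <- w0[t_idx] > 0 & w1[t_idx] > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0[t_idx][valid] - mu0[t_idx][valid])^2 /
    (w0[t_idx][valid] * w1[t_idx][valid])
  which.max(sigma_b) - 1L               # smallest arg-max, level scale
}

# Seed pixel for region growing: geometric center of the ROI, optionally
# relocated to the brightest pixel in a small window when the center falls
# below the acceptance threshold.
roi_seed <- function(image, roi, threshold = -Inf, window = 3) {
  sr <- floor((roi$row0 + 1 + roi$row1) / 2)
  sc <- floor((roi$col0 + 1 + roi$col1) / 2)
  if (image[sr, sc] <= threshold && window > 0) {
    rs <- max(roi$row0 + 1, sr - window):min(roi$row1, sr + window)
    cs <- max(roi$col0 + 1, sc - window):min(roi$col1, sc + window)
    sub <- image[rs, cs, drop = FALSE]
    k <- which.max(sub)
    sr <- rs[(k - 1) %% length(rs) + 1]
    sc <- cs[(k - 1) %/% length(rs) + 1]
  }
  c(sr, sc)
}

fill_mask_holes <- function(mask) {
  # background connected to the image border stays background; enclosed
  # holes are absorbed into the mask
  bg <- !mask
  border <- which(bg & (row(mask) == 1 | row(mask) == nrow(mask) |
                          col(mask) == 1 | col(mask) == ncol(mask)))
  if (length(border) == 0) return(mask)
  outside <- connected_component(bg, border[1], 4)
  # several border components are possible; union them
  for (b in border) {
    if (!outside[b]) outside <- outside | connected_component(bg, b, 4)
  }
  mask | (bg & !outside)
}

#' Segment a lesion by region growing with a dynamic (Otsu) threshold
#'
#' The growth threshold `t*` is determined from the ROI patch by Otsu's
#' method; the mask is the connected component of the thresholded foreground
#' (`I > t*`) that contains the seed, the geometric center of the ROI
#' (relocated to the brightest pixel in a small window when the center is
#' not above `t*`).
#'
#' @param image Integer grayscale matrix (0-255).
#' @param roi An [roi_box()].
#' @param options A [grow_options()]; `mode` must be `"dynamic_otsu"`.
#' @return Logical lesion mask in full-image coordinates.
#' @export
region_grow <- function(image, roi, options = grow_options()) {
  check_roi_in_image(roi, image)
  if (options$mode != "dynamic_otsu")
    abort("use region_grow_fixed() for the fixed-threshold mode", "grow_options_error")
  patch <- image[roi_rows(roi), roi_cols(roi), drop = FALSE]
  tstar <- otsu_threshold(patch)
  seed <- roi_seed(image, roi, threshold = tstar,
                   window = options$seed_relocation_window)
  in_roi <- matrix(FALSE, nrow(image), ncol(image))
  in_roi[roi_rows(roi), roi_cols(roi)] <- TRUE
  if (options$criterion == "otsu_foreground") {
    candidate <- image > tstar
  } else {
    delta <- abs(image[seed[1], seed[2]] - tstar)
    candidate <- abs(image - image[seed[1], seed[2]]) < delta
    candidate[seed[1], seed[2]] <- TRUE
  }
  if (options$restrict_to_roi) candidate <- candidate & in_roi
  seed_idx <- (seed[2] - 1L) * nrow(image) + seed[1]
  if (!candidate[seed_idx])
    abort("seed pixel below threshold: empty segmentation", "empty_segmentation_error")
  mask <- connected_component(candidate, seed_idx, options$connectivity)
  if (!any(mask)) abort("empty segmentation", "empty_segmentation_error")
  if (options$fill_holes) mask <- fill_mask_holes(mask)
  mask
}

#' Segment a lesion by fixed-threshold region growing
#'
#' Classical baseline: starting from the ROI-center seed, a neighbor `p` is
#' accepted iff `|I(p) - I(seed)| < T`, with 8-connectivity, restricted to
#' the ROI.
#'
#' @param image Integer grayscale matrix.
#' @param roi An [roi_box()].
#' @param threshold Intensity threshold T > 0.
#' @param options A [grow_options()] (connectivity / ROI restriction).
#' @return Logical lesion mask in full-image coordinates.
#' @export
region_grow_fixed <- function(image, roi, threshold,
                              options = grow_options(mode = "fixed", threshold = threshold)) {
  check_roi_in_image(roi, image)
  if (threshold <= 0) abort("threshold T must be > 0", "grow_options_error")
  seed <- roi_seed(image, roi, threshold = -Inf, window = 0)
  candidate <- abs(image - image[seed[1], seed[2]]) < threshold
  if (options$restrict_to_roi) {
    in_roi <- matrix(FALSE, nrow(image), ncol(image))
    in_roi[roi_rows(roi), roi_cols(roi)] <- TRUE
    candidate <- candidate & in_roi
  }
  seed_idx <- (seed[2] - 1L) * nrow(image) + seed[1]
  if (!candidate[seed_idx]) abort("empty segmentation", "empty_segmentation_error")
  mask <- connected_component(candidate, seed_idx, options$connectivity)
  if (!any(mask)) abort("empty segmentation", "empty_segmentation_error")
  mask
}

#' Dice similarity coefficient between two masks
#'
#' S = 2 |X intersect Y| / (|X| + |Y|); 1 means the masks coincide, 0 means
#' they are disjoint.
#'
#' @param mask_x,mask_y Logical matrices of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_x, mask_y) {
  if (!all(dim(mask_x) == dim(mask_y))) abort("mask shapes differ", "dice_error")
  nx <- sum(mask_x); ny <- sum(mask_y)
  if (nx + ny == 0) abort("both masks are empty", "dice_error")
  2 * sum(mask_x & mask_y) / (nx + ny)
}

#' Segmentation benchmark on phantom cases with varying contrast
#'
#' Generates single-class phantom cases whose post-contrast lesion/background
#' contrast is drawn uniformly per case, then scores the dynamic-Otsu mode
#' and a set of fixed thresholds against the ground-truth masks (dice on the
#' first post-contrast phase).
#'
#' @param n_cases Number of cases.
#' @param contrast_range Per-case uniform range of the mean lesion-minus-
#'   background contrast at phase T1, intensity units.
#' @param fixed_thresholds Fixed T values to benchmark.
#' @param noise_sd Additive noise standard deviation.
#' @param seed Integer seed.
#' @return A list with `per_case` (data.frame of dice per case and method)
#'   and `summary` (mean dice per method).
#' @export
segmentation_benchmark <- function(n_cases = 50,
                                   contrast_range = c(60, 180),
                                   fixed_thresholds = c(20, 30, 40, 50),
                                   noise_sd = 4,
                                   seed = 1) {
  set.seed(seed)
  contrasts <- stats::runif(n_cases, contrast_range[1], contrast_range[2])
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  methods <- c("dynamic_otsu", paste0("fixed_T", fixed_thresholds))
  res <- matrix(NA_real_, n_cases, length(methods),
                dimnames = list(NULL, methods))
  base <- phantom_spec(n_cases = 4, noise_sd = noise_sd, seed = seed)
  for (i in seq_len(n_cases)) {
    # one class-B-shaped lesion whose T1 contrast is pinned to the draw:
    # lesion T1 mean = background + contrast  =>  ratio1 = target / baseline
    ratio1 <- (base$background + contrasts[i]) / base$lesion_baseline
    sp <- base
    sp$kinetics$B <- kinetic_profile(ratio1, ratio1 * 1.1, 0.12)
    case <- generate_case(sp, "B", sprintf("bench_%03d", i), seed = case_seeds[i])
    img <- case$phases[[2]]
    res[i, "dynamic_otsu"] <- dice(region_grow(img, case$roi), case$truth_mask)
    for (Tt in fixed_thresholds) {
      m <- tryCatch(region_grow_fixed(img, case$roi, Tt),
                    subtyperad_error = function(e) NULL)
      res[i, paste0("fixed_T", Tt)] <-
        if (is.null(m)) 0 else dice(m, case$truth_mask)
    }
  }
  per_case <- data.frame(case = seq_len(n_cases), contrast = contrasts, res)
  list(per_case = per_case, summary = colMeans(res))
}
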