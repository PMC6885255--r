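# Synthetic DCE-MRI phantom cohorts.
#
# Cases are 2D multi-phase grayscale images (one pre-contrast phase T0 and
# two post-contrast phases T1, T2 by default) containing a single star-convex
# lesion on a noisy parenchymal background. Class-dependent structure enters
# through three per-class profiles: shape (boundary irregularity), texture
# (intra-lesion intensity field) and kinetics (enhancement ratios across
# phases). Ground-truth masks, padded ROI boxes and labels come with every
# case, so segmentation, feature extraction and classification can all be
# validated without patient data.

SUBTYPE_LEVELS <- c("A", "B", "C", "D")

#' Per-class kinetic profile
#'
#' Targets for the whole-lesion enhancement ratios S1/S0 and S2/S0, plus the
#' relative spread of per-pixel enhancement around those targets.
#'
#' @param ratio1,ratio2 Dimensionless enhancement targets for phases T1 and
#'   T2 relative to the pre-contrast phase T0. Must be positive.
#' @param heterogeneity Relative standard deviation of the per-pixel
#'   enhancement ratio field (0 = perfectly homogeneous enhancement).
#' @return A `kinetic_profile` list.
#' @export
kinetic_profile <- function(ratio1, ratio2, heterogeneity = 0) {
  if (ratio1 <= 0 || ratio2 <= 0) abort("enhancement ratios must be > 0", "phantom_spec_error")
  if (heterogeneity < 0) abort("heterogeneity must be >= 0", "phantom_spec_error")
  structure(list(ratio1 = ratio1, ratio2 = ratio2, heterogeneity = heterogeneity),
            class = "kinetic_profile")
}

#' Per-class lesion shape profile
#'
#' The lesion boundary is a star-convex radial function
#' r(theta) = r0 * (1 + sum_j a_j cos(j theta + phi_j)) with random phases;
#' `irregularity` fixes the total harmonic amplitude sum(a_j), so larger
#' values give spiculated boundaries and 0 gives a rasterized disk.
#'
#' @param radius Base radius r0 in pixels (>= 5).
#' @param irregularity Total boundary perturbation amplitude, in units of r0
#'   (0 <= irregularity < 1).
#' @param harmonics Number of cosine harmonics.
#' @return A `shape_profile` list.
#' @export
shape_profile <- function(radius, irregularity = 0, harmonics = 4) {
  if (radius < 5) abort("base radius must be >= 5 px", "phantom_spec_error")
  if (irregularity < 0 || irregularity >= 1) abort("irregularity must be in [0, 1)", "phantom_spec_error")
  structure(list(radius = radius, irregularity = irregularity,
                 harmonics = as.integer(harmonics)),
            class = "shape_profile")
}

#' Per-class intra-lesion texture profile
#'
#' @param contrast Standard deviation (intensity units) of the smooth
#'   intra-lesion texture field added to the lesion baseline.
#' @param corr_length Correlation length of the field in pixels.
#' @return A `texture_profile` list.
#' @export
texture_profile <- function(contrast = 0, corr_length = 4) {
  if (contrast < 0 || corr_length <= 0) abort("invalid texture profile", "phantom_spec_error")
  structure(list(contrast = contrast, corr_length = corr_length),
            class = "texture_profile")
}

default_kinetics <- function() list(
  A = kinetic_profile(1.6, 1.9, 0.10),
  B = kinetic_profile(2.0, 2.3, 0.12),
  C = kinetic_profile(2.4, 2.1, 0.15),
  D = kinetic_profile(2.8, 2.2, 0.18)
)

default_shapes <- function() list(
  A = shape_profile(16, 0.06, 3),
  B = shape_profile(18, 0.14, 4),
  C = shape_profile(13, 0.22, 5),
  D = shape_profile(15, 0.30, 6)
)

default_textures <- function() list(
  A = texture_profile(6, 5),
  B = texture_profile(10, 4),
  C = texture_profile(14, 4),
  D = texture_profile(18, 3)
)

#' Phantom cohort specification
#'
#' Bundles everything that determines a synthetic cohort. Identical specs
#' (including `seed`) generate identical cohorts.
#'
#' @param n_cases Number of cases (>= 4).
#' @param image_size Image dimensions `c(rows, cols)`.
#' @param class_proportions Four non-negative weights summing to 1; the
#'   default reproduces the 183/241/143/70 subtype imbalance of the
#'   637-patient cohort the pipeline is designed around.
#' @param kinetics,shapes,textures Named per-class profile lists (names
#'   `A`..`D`); see [kinetic_profile()], [shape_profile()],
#'   [texture_profile()].
#' @param background Background parenchyma level (intensity units, 0-255).
#' @param lesion_baseline Mean pre-contrast lesion intensity.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param roi_pad ROI padding around the truth bounding box, pixels.
#' @param n_phases Number of phases generated (>= 3; features use T0-T2).
#' @param quantize Round and clip phases to integers in `[0, 255]` (needed
#'   for the 256-bin histogram operators; turn off only for exactness
#'   studies of the kinetic algebra).
#' @param seed Integer RNG seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(n_cases = 64,
                         image_size = c(128, 128),
                         class_proportions = c(A = 183, B = 241, C = 143, D = 70) / 637,
                         kinetics = default_kinetics(),
                         shapes = default_shapes(),
                         textures = default_textures(),
                         background = 30,
                         lesion_baseline = 70,
                         noise_sd = 4,
                         roi_pad = 4,
                         n_phases = 3,
                         quantize = TRUE,
                         seed = 1) {
  class_proportions <- unname(class_proportions)
  if (length(class_proportions) != 4 || any(class_proportions < 0))
    abort("class_proportions must be 4 non-negative weights", "phantom_spec_error")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    abort("class_proportions must sum to 1", "phantom_spec_error")
  if (noise_sd < 0) abort("noise_sd must be >= 0", "phantom_spec_error")
  if (n_cases < 4) abort("n_cases must be >= 4", "phantom_spec_error")
  if (n_phases < 3) abort("at least 3 phases (T0, T1, T2) are required", "phantom_spec_error")
  for (cl in SUBTYPE_LEVELS) {
    sp <- shapes[[cl]]
    if (is.null(sp) || is.null(kinetics[[cl]]) || is.null(textures[[cl]]))
      abort(sprintf("missing profile for class %s", cl), "phantom_spec_error")
    rmax <- sp$radius * (1 + sp$irregularity)
    if (2 * (rmax + 4) >= min(image_size))
      abort(sprintf("class %s lesion cannot fit with a 4 px margin", cl),
            "phantom_spec_error")
  }
  structure(list(
    n_cases = as.integer(n_cases), image_size = as.integer(image_size),
    class_proportions = class_proportions, kinetics = kinetics,
    shapes = shapes, textures = textures, background = background,
    lesion_baseline = lesion_baseline, noise_sd = noise_sd,
    roi_pad = as.integer(roi_pad), n_phases = as.integer(n_phases),
    quantize = isTRUE(quantize), seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Smooth zero-mean Gaussian random field with approximate unit variance,
# built by separable Gaussian smoothing of white noise (circular edges).
smooth_field <- function(nr, nc, corr_length) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  sigma <- corr_length / 2
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  sm_rows <- apply(z, 2, function(col) {
    as.numeric(stats::filter(c(col, col, col), kern, circular = TRUE))[(nr + 1):(2 * nr)]
  })
  sm <- t(apply(sm_rows, 1, function(row) {
    as.numeric(stats::filter(c(row, row, row), kern, circular = TRUE))[(nc + 1):(2 * nc)]
  }))
  s <- stats::sd(as.numeric(sm))
  if (s < .Machine$double.eps) matrix(0, nr, nc) else (sm - mean(sm)) / s
}

#' Generate a star-convex lesion mask
#'
#' Rasterizes the radial boundary function
#' r(theta) = r0 (1 + sum_j a_j cos(j theta + phi_j)), with harmonic
#' amplitudes a_j drawn once (scaled so their sum equals the profile's
#' irregularity) and uniform random phases. Consumes the current RNG state
#' unless `seed` is given.
#'
#' @param profile A [shape_profile()].
#' @param image_size `c(rows, cols)` of the target image.
#' @param center Lesion center `c(row, col)`; defaults to the image center.
#' @param seed Optional integer seed for reproducibility of a single call.
#' @return A logical mask matrix (single 8-connected component).
#' @export
generate_lesion_shape <- function(profile, image_size = c(128, 128),
                                  center = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- image_size[1]; nc <- image_size[2]
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  J <- profile$harmonics
  amp <- profile$irregularity
  if (amp > 0 && J >= 1) {
    u <- stats::runif(J, 0.3, 1)
    a <- amp * u / sum(u)
    phi <- stats::runif(J, 0, 2 * pi)
  } else {
    a <- numeric(0)
    phi <- numeric(0)
  }
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dy <- rows - center[1]
  dx <- cols - center[2]
  theta <- atan2(dy, dx)
  rad <- rep(profile$radius, length(theta))
  for (j in seq_along(a)) {
    rad <- rad + profile$radius * a[j] * cos(j * theta + phi[j])
  }
  mask <- matrix(sqrt(dy^2 + dx^2) <= rad, nr, nc)
  if (!any(mask)) abort("generated lesion is empty", "lesion_bounds_error")
  rng <- which(mask, arr.ind = TRUE)
  if (min(rng) <= 4 || max(rng[, 1]) > nr - 4 || max(rng[, 2]) > nc - 4)
    abort("lesion exceeds image bounds (margin 4 px)", "lesion_bounds_error")
  if (!is_single_component(mask, 8))
    abort("generated lesion is not a single 8-connected component", "lesion_bounds_error")
  mask
}

#' Generate one phantom case
#'
#' Phase T0 is background plus the baseline lesion (baseline level plus the
#' class texture field); later phases scale each lesion pixel by a per-pixel
#' enhancement ratio drawn around the class targets; Gaussian noise is added
#' everywhere and intensities are clipped to `[0, 255]` (and rounded when
#' the spec requests quantization). Consumes the current RNG state unless
#' `seed` is given.
#'
#' @param spec A [phantom_spec()].
#' @param class_label One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param case_id Case identifier string.
#' @param seed Optional integer seed.
#' @return A `phantom_case` list with elements `phases` (list of matrices),
#'   `truth_mask`, `roi` ([roi_box()]), `label` and `case_id`.
#' @export
generate_case <- function(spec, class_label, case_id = "case", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!class_label %in% SUBTYPE_LEVELS) abort("unknown class label", "phantom_spec_error")
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  shp <- spec$shapes[[class_label]]
  kin <- spec$kinetics[[class_label]]
  tex <- spec$textures[[class_label]]

  rmax <- shp$radius * (1 + shp$irregularity)
  slack <- floor(min(nr, nc) / 2 - rmax - 5)
  jitter_max <- max(0, min(6, slack))
  center <- c((nr + 1) / 2, (nc + 1) / 2) +
    stats::runif(2, -jitter_max, jitter_max)
  mask <- generate_lesion_shape(shp, spec$image_size, center)

  baseline <- matrix(spec$background, nr, nc)
  if (tex$contrast > 0) {
    field <- smooth_field(nr, nc, tex$corr_length)
    baseline[mask] <- pmax(1, spec$lesion_baseline + tex$contrast * field[mask])
  } else {
    baseline[mask] <- spec$lesion_baseline
  }

  ratios <- c(kin$ratio1, kin$ratio2)
  if (spec$n_phases > 3) ratios <- c(ratios, rep(kin$ratio2, spec$n_phases - 3))
  phases <- vector("list", spec$n_phases)
  phases[[1]] <- baseline
  for (k in seq_along(ratios)) {
    ph <- baseline
    if (kin$heterogeneity > 0) {
      rf <- ratios[k] * (1 + kin$heterogeneity * smooth_field(nr, nc, tex$corr_length))
      rf <- pmax(rf, 0.05)
      ph[mask] <- baseline[mask] * rf[mask]
    } else {
      ph[mask] <- baseline[mask] * ratios[k]
    }
    phases[[k + 1]] <- ph
  }
  for (k in seq_along(phases)) {
    if (spec$noise_sd > 0) {
      phases[[k]] <- phases[[k]] + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    if (spec$quantize) {
      phases[[k]] <- matrix(as.integer(pmin(255, pmax(0, round(phases[[k]])))), nr, nc)
    } else {
      phases[[k]] <- pmin(255, pmax(0, phases[[k]]))
    }
  }

  idx <- which(mask, arr.ind = TRUE)
  pad <- spec$roi_pad
  roi <- roi_box(max(0L, min(idx[, 1]) - 1L - pad),
                 max(0L, min(idx[, 2]) - 1L - pad),
                 min(nr, max(idx[, 1]) + pad),
                 min(nc, max(idx[, 2]) + pad))
  structure(list(phases = phases, truth_mask = mask, roi = roi,
                 label = class_label, case_id = case_id),
            class = "phantom_case")
}

#' Allocate class counts by largest-remainder rounding
#'
#' @param n Total number of cases.
#' @param proportions Non-negative weights summing to 1.
#' @return Integer counts summing to `n`.
#' @export
allocate_class_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a reproducible phantom cohort
#'
#' Class counts follow largest-remainder rounding of the spec proportions;
#' every case is generated from a seed drawn deterministically from the
#' cohort seed, so identical specs give identical cohorts.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_cohort` list: `cases` (list of `phantom_case`) and
#'   `manifest` (data.frame of case_id, label, case seed).
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  counts <- allocate_class_counts(spec$n_cases, spec$class_proportions)
  if (any(counts == 0 & spec$class_proportions > 0) && spec$n_cases >= 4)
    warning("a class with positive proportion received 0 cases")
  labels <- rep(SUBTYPE_LEVELS, counts)
  labels <- labels[sample.int(length(labels))]
  case_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_cases)
  ids <- sprintf("case_%04d", seq_len(spec$n_cases))
  cases <- vector("list", spec$n_cases)
  for (i in seq_len(spec$n_cases)) {
    cases[[i]] <- generate_case(spec, labels[i], ids[i], seed = case_seeds[i])
  }
  manifest <- data.frame(case_id = ids, label = labels, seed = case_seeds,
                         stringsAsFactors = FALSE)
  structure(list(cases = cases, manifest = manifest, spec = spec),
            class = "phantom_cohort")
}
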