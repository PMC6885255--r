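# The fixed 146-value feature schema and whole-case extraction.
#
# Label scheme (phase-major where applicable):
#   F1-F15          GLCM energy, contrast, correlation, entropy, deficit
#                   matrix for phases T0, T1, T2 (5 per phase)
#   F16_b/F17_b/F18_b  LBP histogram frequencies at the retained bins
#                   b in {1..15, 240..255} for phases T0, T1, T2
#   T1-T9           pixel-wise enhancement std/mean/max for the phase pairs
#                   (1,0), (2,0), (2,1) in that order
#   T10-T13         whole-lesion enhancement/absorption rates ER_10, AR_10,
#                   ER_20, AR_20
#   C1-C18          intensity mean, std, entropy, max, bias, peak per phase
#   M1-M7           morphology (NRL mean/std, compactness, roughness,
#                   smoothness, roundness, area)

GLCM_STAT_NAMES <- c("energy", "contrast", "correlation", "entropy", "deficit_matrix")

#' The fixed feature label schema
#'
#' @return Character vector of the 146 feature labels in canonical order.
#' @export
feature_schema <- function() {
  c(paste0("F", 1:15),
    paste0("F16_", LBP_RETAINED_BINS),
    paste0("F17_", LBP_RETAINED_BINS),
    paste0("F18_", LBP_RETAINED_BINS),
    paste0("T", 1:13),
    paste0("C", 1:18),
    paste0("M", 1:7))
}

#' Extract the full feature vector for one case
#'
#' Computes all texture, kinetic, statistical and morphological features on
#' the segmented lesion across the first three phases and returns them as a
#' named vector in the fixed schema order.
#'
#' @param phases List of >= 3 grayscale matrices (T0, T1, T2 used).
#' @param mask Logical lesion mask.
#' @param glcm_levels GLCM quantization levels (default 16).
#' @return Named numeric vector of length 146.
#' @export
extract_all <- function(phases, mask, glcm_levels = 16) {
  if (length(phases) < 3) abort("3 usable phases are required", "feature_error")
  if (!any(mask)) abort("empty mask", "feature_error")
  glcm <- unlist(lapply(phases[1:3], function(ph)
    unname(glcm_features(ph, mask, levels = glcm_levels))))
  lbp <- suppressWarnings(
    unlist(lapply(phases[1:3], function(ph) unname(lbp_histogram(ph, mask)))))
  pairs <- list(c(2, 1), c(3, 1), c(3, 2))
  kin_px <- unlist(lapply(pairs, function(pr)
    unname(kinetic_pixelwise(phases[[pr[1]]], phases[[pr[2]]], mask))))
  s <- vapply(phases[1:3], function(ph) mean(ph[mask]), numeric(1))
  kin_whole <- unname(kinetic_whole(s[1], s[2], s[3]))
  stats3 <- unlist(lapply(phases[1:3], function(ph)
    unname(stats_features(ph, mask))))
  morph <- unname(morphology_features(mask))
  out <- c(glcm, lbp, kin_px, kin_whole, stats3, morph)
  names(out) <- feature_schema()
  if (any(!is.finite(out))) abort("non-finite feature value", "feature_error")
  out
}

#' Extract a cohort feature table
#'
#' @param cases List of `phantom_case` objects (or any list with `phases`,
#'   `case_id`, `label` and either `mask` or `truth_mask`).
#' @param masks Optional list of segmented masks (by default the case's own
#'   mask is used).
#' @param glcm_levels GLCM quantization levels.
#' @return Data frame with `case_id`, `label` and the 146 feature columns.
#' @export
extract_cohort <- function(cases, masks = NULL, glcm_levels = 16) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    mask <- if (!is.null(masks)) masks[[i]] else
      if (!is.null(cs$mask)) cs$mask else cs$truth_mask
    fv <- tryCatch(extract_all(cs$phases, mask, glcm_levels = glcm_levels),
                   subtyperad_error = function(e) {
                     abort(sprintf("feature extraction failed for case %s: %s",
                                   cs$case_id, conditionMessage(e)),
                           "feature_error")
                   })
    c(list(case_id = cs$case_id, label = cs$label), as.list(fv))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Drop all-zero feature columns
#'
#' Removes feature columns that are 0 for every case (the "invalid
#' columns"); the removed labels are attached as the `"removed"` attribute
#' and reported via a message.
#'
#' @param table Feature table as returned by [extract_cohort()].
#' @return The table without all-zero feature columns.
#' @export
drop_invalid_columns <- function(table) {
  feat_cols <- setdiff(names(table), c("case_id", "label"))
  all_zero <- vapply(feat_cols, function(cl) all(table[[cl]] == 0), logical(1))
  removed <- feat_cols[all_zero]
  if (length(removed) > 0) {
    message("removed ", length(removed), " all-zero feature columns: ",
            paste(removed, collapse = ", "))
    table <- table[, !(names(table) %in% removed), drop = FALSE]
  }
  attr(table, "removed") <- removed
  table
}
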