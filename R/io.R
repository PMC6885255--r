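# Artifact I/O: 8-bit grayscale PNG images, 0/255 PNG masks, JSON
# manifests/annotations, CSV tables. All writers are deterministic so that
# reruns from one seed are byte-identical.

write_image_png <- function(image, path) {
  m <- matrix(pmin(255, pmax(0, round(image))) / 255, nrow(image), ncol(image))
  png::writePNG(m, path)
  invisible(path)
}

read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

read_mask_png <- function(path) {
  read_image_png(path) > 127
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, pretty = TRUE, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a phantom cohort to disk
#'
#' Images go to `images/<case_id>_phase<k>.png` (8-bit grayscale), truth
#' masks to `truth_masks/<case_id>.png` (0/255), and `manifest.json` lists
#' case ids, labels, ROI boxes (`[row0, col0, row1, col1]`, 0-based
#' half-open) and file paths.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth_masks"), recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$cases, function(cs) {
    phase_files <- sprintf("images/%s_phase%d.png", cs$case_id,
                           seq_along(cs$phases) - 1L)
    for (k in seq_along(cs$phases)) {
      write_image_png(cs$phases[[k]], file.path(dir, phase_files[k]))
    }
    mask_file <- sprintf("truth_masks/%s.png", cs$case_id)
    write_mask_png(cs$truth_mask, file.path(dir, mask_file))
    list(case_id = cs$case_id, label = cs$label,
         roi = c(cs$roi$row0, cs$roi$col0, cs$roi$row1, cs$roi$col1),
         phases = phase_files, truth_mask = mask_file)
  })
  manifest <- list(n_cases = length(entries), cases = entries)
  write_json_artifact(manifest, file.path(dir, "manifest.json"))
  invisible(manifest)
}

#' Read a phantom cohort (or any conforming case directory) from disk
#'
#' @param dir Directory holding `manifest.json` as written by
#'   [write_cohort()].
#' @param masks_dir Optional subdirectory of segmented masks
#'   (`<case_id>.png`) to attach as each case's `mask`.
#' @return List of case lists (`phases`, `truth_mask`, `roi`, `label`,
#'   `case_id`, optionally `mask`).
#' @export
read_cohort <- function(dir, masks_dir = NULL) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(manifest$cases, function(e) {
    phases <- lapply(e$phases, function(f) read_image_png(file.path(dir, f)))
    roi <- roi_box(e$roi[[1]], e$roi[[2]], e$roi[[3]], e$roi[[4]])
    truth <- if (!is.null(e$truth_mask))
      read_mask_png(file.path(dir, e$truth_mask)) else NULL
    mask <- if (!is.null(masks_dir)) {
      f <- file.path(dir, masks_dir, paste0(e$case_id, ".png"))
      if (file.exists(f)) read_mask_png(f) else NULL
    } else NULL
    list(phases = phases, truth_mask = truth, roi = roi,
         label = e$label, case_id = e$case_id, mask = mask)
  })
}

write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

report_to_list <- function(rep) {
  list(accuracy = rep$accuracy,
       macro = as.list(rep$macro),
       weighted = as.list(rep$weighted),
       per_class = rep$per_class,
       confusion = unname(apply(rep$confusion, 1, as.list)))
}
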