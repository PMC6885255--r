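# Phantom generator: shapes, kinetics, cohort allocation, determinism.

test_that("zero irregularity gives a rasterized disk with roundness near 1", {
  m <- generate_lesion_shape(shape_profile(16, 0, 3), c(96, 96), seed = 1)
  mo <- morphology_features(m)
  expect_gt(mo["M6"], 0.9)
  expect_lt(mo["M6"], 1.1)
  expect_lt(mo["M2"], 0.05)
  # area close to pi r^2
  expect_lt(abs(sum(m) - pi * 16^2) / (pi * 16^2), 0.05)
})

test_that("lesion shapes are seeded-deterministic and amplitude scales NRL spread", {
  m1 <- generate_lesion_shape(shape_profile(14, 0.3, 5), c(96, 96), seed = 42)
  m2 <- generate_lesion_shape(shape_profile(14, 0.3, 5), c(96, 96), seed = 42)
  expect_identical(m1, m2)
  lo <- generate_lesion_shape(shape_profile(14, 0.05, 5), c(96, 96), seed = 42)
  expect_gt(morphology_features(m1)["M2"], morphology_features(lo)["M2"])
})

test_that("lesions too large for the image raise a generation error", {
  expect_error(generate_lesion_shape(shape_profile(40, 0, 3), c(64, 64)),
               class = "lesion_bounds_error")
})

test_that("generated masks are single 8-connected components", {
  for (s in 1:10) {
    m <- generate_lesion_shape(shape_profile(12, 0.3, 6), c(96, 96), seed = s)
    expect_true(subtyperad:::is_single_component(m, 8))
  }
})

test_that("noiseless homogeneous cases reproduce the configured ratio exactly", {
  sp <- phantom_spec(noise_sd = 0, quantize = FALSE)
  sp$kinetics$A <- kinetic_profile(1.8, 2.2, heterogeneity = 0)
  sp$textures$A <- texture_profile(0)
  case <- generate_case(sp, "A", seed = 3)
  s <- vapply(case$phases[1:3], function(ph) mean(ph[case$truth_mask]), numeric(1))
  kw <- kinetic_whole(s[1], s[2], s[3])
  expect_equal(unname(kw["ER_10"]), 1.8, tolerance = 1e-12)
  expect_equal(unname(kw["ER_20"]), 2.2, tolerance = 1e-12)
  # unit ratios give zero absorption rates
  sp$kinetics$A <- kinetic_profile(1, 1, 0)
  case0 <- generate_case(sp, "A", seed = 3)
  s0 <- vapply(case0$phases[1:3], function(ph) mean(ph[case0$truth_mask]), numeric(1))
  expect_equal(unname(kinetic_whole(s0[1], s0[2], s0[3])["AR_10"]), 0, tolerance = 1e-12)
})

test_that("measured enhancement tracks the configured ratio under noise", {
  sp <- phantom_spec(noise_sd = 2)
  sp$kinetics$A <- kinetic_profile(1.8, 2.0, heterogeneity = 0.1)
  ers <- vapply(1:50, function(s) {
    case <- generate_case(sp, "A", seed = s)
    m <- case$truth_mask
    mean(case$phases[[2]][m]) / mean(case$phases[[1]][m])
  }, numeric(1))
  expect_gt(mean(ers), 1.7)
  expect_lt(mean(ers), 1.9)
})

test_that("cohort allocation uses largest-remainder rounding", {
  expect_identical(allocate_class_counts(637, c(183, 241, 143, 70) / 637),
                   c(183L, 241L, 143L, 70L))
  expect_identical(allocate_class_counts(64, rep(0.25, 4)), rep(16L, 4))
  expect_equal(sum(allocate_class_counts(101, c(0.4, 0.3, 0.2, 0.1))), 101)
})

test_that("cohorts are reproducible from the spec seed", {
  sp <- phantom_spec(n_cases = 6, image_size = c(64, 64),
                     shapes = list(A = shape_profile(8, 0.06, 3),
                                   B = shape_profile(9, 0.14, 4),
                                   C = shape_profile(7, 0.22, 5),
                                   D = shape_profile(8, 0.30, 6)),
                     seed = 11)
  c1 <- suppressWarnings(generate_cohort(sp))
  c2 <- suppressWarnings(generate_cohort(sp))
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$cases[[3]]$phases, c2$cases[[3]]$phases)
  expect_identical(c1$cases[[3]]$truth_mask, c2$cases[[3]]$truth_mask)
})

test_that("a positive-proportion class receiving no cases warns", {
  sp <- phantom_spec(n_cases = 5, image_size = c(64, 64),
                     class_proportions = c(0.6, 0.3, 0.08, 0.02),
                     shapes = list(A = shape_profile(8, 0.06, 3),
                                   B = shape_profile(9, 0.14, 4),
                                   C = shape_profile(7, 0.22, 5),
                                   D = shape_profile(8, 0.30, 6)))
  expect_warning(generate_cohort(sp), "0 cases")
})

test_that("roughness increases with configured irregularity over many seeds", {
  m4_at <- function(amp) {
    mean(vapply(1:20, function(s)
      morphology_features(
        generate_lesion_shape(shape_profile(14, amp, 5), c(96, 96), seed = s))["M4"],
      numeric(1)))
  }
  vals <- vapply(c(0, 0.1, 0.25), m4_at, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("truth mask lies inside the padded ROI which lies inside the image", {
  case <- generate_case(phantom_spec(), "D", seed = 9)
  idx <- which(case$truth_mask, arr.ind = TRUE)
  roi <- case$roi
  expect_true(min(idx[, 1]) > roi$row0 && max(idx[, 1]) <= roi$row1)
  expect_true(min(idx[, 2]) > roi$col0 && max(idx[, 2]) <= roi$col1)
  expect_true(roi$row1 <= nrow(case$phases[[1]]) && roi$col1 <= ncol(case$phases[[1]]))
})
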