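# Otsu thresholding, region growing (dynamic and fixed) and dice scoring.

test_that("otsu splits a two-level patch exactly between the levels", {
  patch <- matrix(c(rep(10, 32), rep(200, 32)), 8, 8)
  t <- otsu_threshold(patch)
  expect_gte(t, 10)
  expect_lt(t, 200)
  expect_identical(sort(unique(patch[patch > t])), 200)
  expect_identical(sort(unique(patch[patch <= t])), 10)
})

test_that("constant patches raise a degenerate-threshold error", {
  expect_error(otsu_threshold(matrix(42, 5, 5)),
               class = "degenerate_threshold_error")
})

test_that("otsu equals exhaustive between-class-variance search", {
  for (s in 1:30) {
    set.seed(s)
    patch <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_identical(otsu_threshold(patch), oracle_otsu(patch))
  }
})

make_disk_image <- function(nr = 60, nc = 60, r = 10, fg = 200, bg = 10,
                            center = c(30, 30)) {
  d <- sqrt(outer((1:nr - center[1])^2, (1:nc - center[2])^2, "+"))
  img <- matrix(bg, nr, nc)
  img[d <= r] <- fg
  list(image = img, mask = d <= r)
}

test_that("dynamic region growing recovers an ideal-contrast disk exactly", {
  di <- make_disk_image()
  roi <- roi_box(10, 10, 50, 50)
  mask <- region_grow(di$image, roi)
  expect_equal(dice(mask, di$mask), 1.0)
})

test_that("growth is restricted to the component containing the seed", {
  img <- matrix(10, 40, 40)
  img[8:12, 8:12] <- 200     # blob away from the ROI center
  img[18:24, 18:24] <- 200   # blob at the center (seed lands here)
  roi <- roi_box(2, 2, 38, 38)
  mask <- region_grow(img, roi)
  expect_true(all(which(mask, arr.ind = TRUE)[, 1] >= 18))
  expect_equal(sum(mask), 49)
})

test_that("dynamic mode ignores intensities outside the ROI when restricted", {
  di <- make_disk_image()
  roi <- roi_box(12, 12, 48, 48)
  m1 <- region_grow(di$image, roi)
  img2 <- di$image
  img2[1:5, ] <- 255                     # corrupt pixels outside the ROI
  m2 <- region_grow(img2, roi)
  expect_identical(m1, m2)
})

test_that("fixed-threshold growing matches its acceptance rule", {
  di <- make_disk_image()
  roi <- roi_box(10, 10, 50, 50)
  expect_equal(dice(region_grow_fixed(di$image, roi, 50), di$mask), 1.0)
  # saturating threshold floods the whole ROI
  full <- region_grow_fixed(di$image, roi, 255)
  expect_equal(sum(full), 40 * 40)
})

test_that("fixed-mode masks are non-shrinking in T", {
  case <- generate_case(phantom_spec(), "C", seed = 21)
  img <- case$phases[[2]]
  prev <- NULL
  for (T in c(10, 20, 40, 80, 160)) {
    m <- region_grow_fixed(img, case$roi, T)
    if (!is.null(prev)) expect_true(all(m[prev]))
    prev <- m
  }
})

test_that("dice satisfies its identities and arithmetic", {
  a <- matrix(FALSE, 6, 6); a[2:3, 2:3] <- TRUE
  b <- matrix(FALSE, 6, 6); b[5:6, 5:6] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0)
  # |X| = |Y| = 4 with overlap 2
  c2 <- matrix(FALSE, 6, 6); c2[2:3, 3:4] <- TRUE
  expect_equal(dice(a, c2), 0.5)
  expect_error(dice(a, matrix(FALSE, 5, 5)), class = "dice_error")
  expect_error(dice(matrix(FALSE, 6, 6), matrix(FALSE, 6, 6)), class = "dice_error")
})

test_that("dice is symmetric and 1 only for identical masks", {
  set.seed(7)
  for (i in 1:10) {
    a <- matrix(stats::runif(36) < 0.4, 6, 6)
    b <- matrix(stats::runif(36) < 0.4, 6, 6)
    if (sum(a) + sum(b) == 0) next
    expect_equal(dice(a, b), dice(b, a))
    s <- dice(a, b)
    expect_gte(s, 0); expect_lte(s, 1)
    if (s == 1) expect_identical(a, b)
  }
})

test_that("dynamic mode outperforms fixed thresholds under varying contrast", {
  bench <- segmentation_benchmark(n_cases = 25, seed = 7)
  dyn <- bench$summary["dynamic_otsu"]
  fixed <- bench$summary[grep("^fixed", names(bench$summary))]
  expect_gte(dyn, 0.90)
  expect_gte(dyn, max(fixed))
})
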