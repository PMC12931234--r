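test_that("a constant image yields an empty mask", {
  img <- calibrated_image(matrix(128, 64, 64), 1)
  expect_false(any(tem_preprocess(img)))
  expect_error(tem_preprocess(img, threshold_low = 200, threshold_high = 100),
               "threshold")
})

test_that("a dark disk on a light background segments to one component", {
  dm <- disk_mask(20)
  px <- matrix(200, nrow(dm), ncol(dm))
  px[dm] <- 60
  mask <- tem_preprocess(calibrated_image(px, 1))
  expect_true(any(mask))
  lab <- aggrekin:::label_components(mask)
  expect_equal(max(lab), 1)
  # the filled component covers the disk interior
  expect_gt(sum(mask), 0.5 * sum(disk_mask(20)))
})

test_that("zero blur sigma is the identity filter", {
  set.seed(2)
  px <- matrix(runif(64 * 64, 0, 255), 64)
  m0 <- tem_preprocess(px, sigma = 0, edge_halfwidth = 0)
  # recompute by hand without any smoothing step
  img <- EBImage::Image(px / 255)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  mag <- pmin(sqrt(EBImage::imageData(EBImage::filter2(img, kx))^2 +
                     EBImage::imageData(EBImage::filter2(img, t(kx)))^2) * 255,
              255)
  ref <- EBImage::imageData(EBImage::fillHull(EBImage::Image(
    (mag >= 80 & mag <= 255) * 1))) > 0
  expect_identical(m0, ref)
})

test_that("rasterized disks are round to the morphometric measures", {
  for (r in c(10, 20, 30)) {
    pt <- measure_particles(disk_mask(r), 1, exclude_edge = FALSE)
    expect_equal(nrow(pt), 1L)
    expect_gte(pt$circularity, 0.90)
    expect_lte(pt$circularity, 1.05)
    expect_lte(abs(pt$max_feret_nm - 2 * r) / (2 * r), 0.05)
    expect_lt(pt$aspect_ratio, 1.1)
    expect_gte(pt$max_feret_nm, 2 * sqrt(pt$area_nm2 / pi) * 0.99)
  }
})

test_that("a 10:1 rectangle is elongated to the morphometric measures", {
  m <- matrix(FALSE, 120, 40)
  m[11:110, 16:25] <- TRUE
  pt <- measure_particles(m, 1, exclude_edge = FALSE)
  expect_lt(abs(pt$aspect_ratio - 10) / 10, 0.10)
  expect_lte(pt$circularity, 0.45)
  expect_lt(abs(pt$max_feret_nm - sqrt(100^2 + 10^2)) / sqrt(100^2 + 10^2),
            0.02)
})

test_that("degenerate masks are measured without crashing", {
  empty <- measure_particles(matrix(FALSE, 10, 10), 1)
  expect_equal(nrow(empty), 0L)
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  pt <- measure_particles(single, 2, exclude_edge = FALSE, min_px = 1L)
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$area_nm2, 4)  # one pixel at 2 nm/px
  expect_equal(pt$class, "unclassified")
})

test_that("classification applies the area/circularity/aspect gates", {
  tab <- data.frame(particle = 1:3,
                    area_nm2 = c(30, 100, 60),
                    perimeter_nm = 1, aspect_ratio = c(1, 5, 2),
                    circularity = c(0.95, 0.15, 0.6),
                    max_feret_nm = c(6, 40, 10),
                    x_px = 0, y_px = 0, class = "unclassified")
  out <- classify_particles(tab)
  # small round particle: below the 40 nm2 area gate, not an oligomer
  expect_equal(out$class, c("unclassified", "fibril", "unclassified"))
  big <- tab; big$area_nm2[1] <- 50
  expect_equal(classify_particles(big)$class[1], "oligomer")
  expect_warning(classify_particles(tab, fibril_circ_max = 0.95), "overlap")
})

test_that("size summaries report medians with bootstrap intervals", {
  tab <- data.frame(max_feret_nm = c(10, 20, 30), class = "oligomer")
  s <- summarize_sizes(tab, n_boot = 500, seed = 1)
  expect_equal(s$oligomer$median_nm, 20)
  expect_equal(s$oligomer$n, 3)
  # duplicated table with the same seed: identical summary
  s2 <- summarize_sizes(tab, n_boot = 500, seed = 1)
  expect_identical(s, s2)
  expect_error(summarize_sizes(tab[0, ]), "classified")
})

test_that("the pipeline recovers known particles from a synthetic field", {
  fld <- generate_tem_field(n_oligomers = 50, n_fibrils = 10, seed = 3)
  mask <- tem_preprocess(fld$image)
  pt <- classify_particles(measure_particles(mask, fld$image$nm_per_px))
  got <- match_particles(pt, fld$truth)
  expect_gte(mean(!is.na(got)), 0.9)                       # recall
  expect_gte(mean(got == fld$truth$class, na.rm = TRUE), 0.9)  # accuracy
})

test_that("oligomer median size is recovered from a 12 nm field", {
  fld <- generate_tem_field(n_oligomers = 60, n_fibrils = 0,
                            oligomer_meanlog = log(12), oligomer_sdlog = 0.15,
                            seed = 5)
  mask <- tem_preprocess(fld$image)
  pt <- classify_particles(measure_particles(mask, fld$image$nm_per_px))
  s <- summarize_sizes(pt[pt$class == "oligomer", ], seed = 2)
  expect_lt(abs(s$oligomer$median_nm - 12) / 12, 0.10)
})
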