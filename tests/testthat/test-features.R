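test_that("segmentation labels disjoint components and tolerates blanks", {
  img <- matrix(0, 64, 64)
  img[10:20, 10:20] <- 1
  img[40:50, 40:50] <- 1
  lab <- segment_image(img, threshold = 0.5)
  expect_identical(max(lab), 2L)
  expect_identical(max(segment_image(matrix(0, 16, 16), threshold = 0.5)), 0L)
  expect_error(segment_image(array(0, c(4, 4, 2))), "matrix")
  # disc pixel-count oracle
  disc <- raster_disc(20) + 0
  lab <- segment_image(disc, threshold = 0.5)
  expect_equal(sum(lab == 1L), pi * 400, tolerance = 0.03)
})

test_that("disc features match circle symmetry and second-moment oracles", {
  m <- raster_disc(20)
  f <- compute_features(m, "core7", pixel_size = 1,
                        intensity = flat_intensity(m))
  expect_equal(f[["FormFactor"]], 1, tolerance = 0.05)
  expect_equal(f[["Elongation"]], 1, tolerance = 0.05)
  expect_equal(f[["ChordRatio"]], 1, tolerance = 0.05)
  expect_equal(f[["GyrationRadius"]], 20 / sqrt(2), tolerance = 0.05)
  expect_equal(f[["Compactness"]], 2 * 20 / 3, tolerance = 0.05)
  expect_equal(f[["Displacement"]], 0, tolerance = 1e-8)
  ft <- compute_features(m, "tissue6", pixel_size = 1)
  expect_equal(ft[["Circularity"]], 1, tolerance = 0.05)
  expect_equal(ft[["Eccentricity"]], 0, tolerance = 0.05)
})

test_that("feature extraction matches closed forms on analytic ellipses", {
  a <- 24
  for (ratio in c(1, 0.75, 0.5, 0.25)) {
    b <- a * ratio
    m <- raster_ellipse(a, b)
    f <- compute_features(m, "extended17", pixel_size = 1)
    expect_equal(f[["Area"]], pi * a * b, tolerance = 0.05)
    expect_equal(f[["Perimeter"]], ellipse_perimeter(a, b), tolerance = 0.05)
    expect_equal(f[["Eccentricity"]], sqrt(1 - ratio^2), tolerance = 0.05)
    expect_equal(f[["MajorAxisLength"]], 2 * a, tolerance = 0.05)
    expect_equal(f[["MinorAxisLength"]], 2 * b, tolerance = 0.05)
    expect_equal(f[["MaxFeretDiameter"]], 2 * a, tolerance = 2 / (2 * a))
    expect_equal(f[["MinFeretDiameter"]], 2 * b, tolerance = 2 / (2 * b))
    expect_equal(f[["EquivalentDiameter"]], 2 * sqrt(a * b), tolerance = 0.05)
    expect_equal(f[["FormFactor"]],
                 4 * pi * (pi * a * b) / ellipse_perimeter(a, b)^2,
                 tolerance = 0.05)
    expect_equal(f[["Solidity"]], 1, tolerance = 0.05)
    # ellipse mean squared radius = (a^2 + b^2) / 4
    fc <- compute_features(m, "core7", pixel_size = 1,
                           intensity = flat_intensity(m))
    expect_equal(fc[["GyrationRadius"]], sqrt((a^2 + b^2) / 4),
                 tolerance = 0.05)
    expect_equal(fc[["Elongation"]], ratio, tolerance = 0.05)
  }
})

test_that("features are scale-equivariant in pixel size", {
  m <- raster_ellipse(18, 12, theta = 0.4)
  f1 <- compute_features(m, "tissue6", pixel_size = 0.5)
  f2 <- compute_features(m, "tissue6", pixel_size = 1.0)
  expect_equal(f2[["Area"]], 4 * f1[["Area"]])
  for (len in c("Perimeter", "MaxCaliper", "MinCaliper")) {
    expect_equal(f2[[len]], 2 * f1[[len]])
  }
  for (ratio in c("Circularity", "Eccentricity")) {
    expect_equal(f2[[ratio]], f1[[ratio]])
  }
})

test_that("features are rotation invariant", {
  m <- raster_ellipse(20, 11, theta = 0.3)
  rot90 <- function(x) t(x)[, rev(seq_len(nrow(x))), drop = FALSE]
  f0 <- compute_features(m, "tissue6", pixel_size = 1)
  f90 <- compute_features(rot90(m), "tissue6", pixel_size = 1)
  expect_equal(f0, f90, tolerance = 1e-10) # exact under 90-degree rotation
  # arbitrary rotation within rasterization tolerance
  f_any <- compute_features(raster_ellipse(20, 11, theta = 1.1), "tissue6",
                            pixel_size = 1)
  for (nm in names(f0)) expect_equal(f_any[[nm]], f0[[nm]], tolerance = 0.05)
})

test_that("degenerate regions and missing intensity raise errors", {
  tiny <- matrix(FALSE, 8, 8); tiny[4, 4:6] <- TRUE
  expect_error(compute_features(tiny, "core7"), "degenerate")
  m <- raster_disc(10)
  expect_error(compute_features(m, "core7", intensity = NULL), "intensity")
})

test_that("qc_filter excludes by edge, diameter and intensity with a log", {
  img <- matrix(0, 60, 60)
  img[1:12, 20:31] <- 1          # touches row edge
  img[30:41, 5:16] <- 1          # interior, diameter ~13.5 px = 6.8 um
  img[50:52, 50:52] <- 1         # tiny: diameter ~1.7 um
  lab <- segment_image(img, threshold = 0.5)
  rec <- extract_nuclei(lab, "tissue6", pixel_size = 0.5,
                        intensity = img * 0.4)
  res <- qc_filter(rec, qc_params(min_diameter = 5, max_diameter = 40,
                                  min_intensity = 0.2))
  expect_identical(nrow(res$kept), 1L)
  expect_setequal(res$excluded$reason, c("edge", "diameter"))
  # under-intensity exclusion
  res2 <- qc_filter(rec, qc_params(min_diameter = 1, max_diameter = 40,
                                   min_intensity = 0.9,
                                   exclude_edge_objects = FALSE))
  expect_true(all(res2$excluded$reason == "intensity"))
  # all-pass identity
  res3 <- qc_filter(rec, qc_params(min_diameter = 0.1, max_diameter = 100,
                                   exclude_edge_objects = FALSE))
  expect_identical(res3$kept, rec)
  expect_identical(nrow(res3$excluded), 0L)
})
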