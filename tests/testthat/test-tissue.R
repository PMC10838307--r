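test_that("marker status is strict > threshold with override", {
  cells <- data.frame(dab_od_mean = c(0.25, 0.20, 0.15))
  expect_identical(classify_marker_status(cells), c(1L, 0L, 0L))
  expect_identical(classify_marker_status(cells, threshold = 0.3),
                   c(0L, 0L, 0L))
  expect_error(classify_marker_status(data.frame(x = 1)), "missing")
})

test_that("reference derivation averages negatives and top-k positives", {
  fs <- feature_set("tissue6")$features
  base <- as.data.frame(as.list(stats::setNames(rep(1, 6), fs)))
  cells <- base[rep(1, 6), ]
  # positives (rows 4-6) differ on every feature to keep the pair valid
  for (f in fs) cells[[f]] <- c(1, 1, 1, 2, 2, 2)
  cells$Area <- c(1, 1, 1, 10, 20, 30)        # negatives identical
  cells$dab_od_mean <- c(0.1, 0.15, 0.05, 0.9, 0.8, 0.3)
  cells$cell_id <- 1:6
  ref <- derive_ideal_reference(cells, top_k = 2)
  expect_equal(unname(ref$p_normal["Area"]), 1)       # exactly the negatives
  expect_equal(unname(ref$p_senescent["Area"]), 15)   # mean of 0.9, 0.8 cells
  expect_equal(sum(ref$weights), 1)
  # permuting rows leaves the reference unchanged
  perm <- cells[c(4, 2, 6, 1, 5, 3), ]
  expect_equal(derive_ideal_reference(perm, top_k = 2), ref)
  expect_error(derive_ideal_reference(cells, top_k = 5), "at least 5")
  # degenerate reference (equal means) errors
  cells2 <- cells
  cells2$Area <- 1
  expect_error(derive_ideal_reference(cells2, top_k = 2), "degenerate")
})

test_that("CSS endpoint contract holds for 1000 random references", {
  withr::local_seed(123)
  for (i in 1:1000) {
    ref <- random_reference()
    expect_equal(cell_senescence_score(ref$p_senescent, ref), 1,
                 tolerance = 1e-12)
    expect_equal(cell_senescence_score(ref$p_normal, ref), 0,
                 tolerance = 1e-12)
  }
})

test_that("CSS is affine per feature with slope sign(P^S - P^N) * w", {
  withr::local_seed(5)
  ref <- random_reference()
  mid <- (ref$p_normal + ref$p_senescent) / 2
  expect_equal(cell_senescence_score(mid, ref), 0.5, tolerance = 1e-12)
  for (f in names(mid)) {
    x <- mid
    x[f] <- x[f] + 1
    slope <- cell_senescence_score(x, ref) - cell_senescence_score(mid, ref)
    expected_sign <- sign(ref$p_senescent[[f]] - ref$p_normal[[f]])
    expect_equal(sign(slope), expected_sign)
    expect_equal(abs(slope),
                 ref$weights[[f]] / abs(ref$p_senescent[[f]] - ref$p_normal[[f]]),
                 tolerance = 1e-12)
  }
})

test_that("the literal printed composition misses the endpoint contract", {
  withr::local_seed(8)
  ref <- random_reference()
  lit <- cell_senescence_score(ref$p_senescent, ref, literal = TRUE)
  expect_false(isTRUE(all.equal(lit, 1)))
})

test_that("TSS counts the closed window [1, 5]", {
  expect_equal(tissue_senescence_score(rep(2, 10)), 100)
  expect_equal(tissue_senescence_score(rep(0, 10)), 0)
  expect_equal(tissue_senescence_score(c(0, 2, 6, 3)), 50)
  expect_equal(tissue_senescence_score(c(1, 5, 0.999, 5.001)), 50) # closed
  expect_equal(tissue_senescence_score(c(0, 2, 6, 3), window = c(2, 6)), 75)
  expect_error(tissue_senescence_score(numeric()), "no cells")
})

test_that("sample filters: circularity strict > 0.7, 10,000-cell minimum", {
  tab <- generate_tissue_table(tissue_spec(n_cells = 1000, seed = 3))
  tab$Circularity[1] <- 0.69
  tab$Circularity[2] <- 0.70
  tab$Circularity[3] <- 0.71
  flt <- filter_tissue_sample(tab, hepatocyte_filter = TRUE, min_cells = 10)
  expect_false(any(flt$cells$Circularity <= 0.7))
  # filter off: identity at the cell level
  flt2 <- filter_tissue_sample(tab, hepatocyte_filter = FALSE, min_cells = 10)
  expect_identical(flt2$cells, tab)
  # sample below 10,000 cells is excluded (strict <)
  big <- tab[rep(1:1000, 10), ]           # exactly 10,000
  expect_false(filter_tissue_sample(big)$sample_excluded)
  expect_true(filter_tissue_sample(big[-1, ])$sample_excluded) # 9,999
})

test_that("TSS rises with the true senescent fraction and tracks markers", {
  fracs <- c(0.02, 0.1, 0.3)
  tss <- sapply(1:10, function(s) {
    vapply(fracs, function(f) {
      tab <- generate_tissue_table(
        tissue_spec(n_cells = 6000, senescent_fraction = f, seed = s))
      ref <- derive_ideal_reference(tab, top_k = 50)
      tissue_senescence_score(cell_senescence_score(tab, ref))
    }, numeric(1))
  })
  means <- rowMeans(tss)
  expect_true(all(diff(means) > 0)) # strictly increasing across fractions
  # across 20 samples, TSS correlates with the marker-positive percentage
  ref <- derive_ideal_reference(
    generate_tissue_table(tissue_spec(20000, 0.15, seed = 99)))
  stats <- vapply(1:20, function(s) {
    f <- runif(1, 0.02, 0.35)
    tab <- generate_tissue_table(
      tissue_spec(n_cells = 4000, senescent_fraction = f, seed = 300 + s))
    c(tss = tissue_senescence_score(cell_senescence_score(tab, ref)),
      pos = 100 * mean(classify_marker_status(tab) == 1))
  }, numeric(2))
  expect_gt(cor(stats["tss", ], stats["pos", ]), 0.5)
})

test_that("references are reusable across cohorts and round-trip as JSON", {
  tab <- generate_tissue_table(tissue_spec(20000, 0.15, seed = 42))
  ref <- derive_ideal_reference(tab)
  other <- generate_tissue_table(tissue_spec(500, 0.2, seed = 43))
  css1 <- cell_senescence_score(other, ref)
  path <- withr::local_tempfile(fileext = ".json")
  save_reference(ref, path)
  ref2 <- load_reference(path)
  expect_equal(cell_senescence_score(other, ref2), css1, tolerance = 1e-12)
  expect_equal(ref2$p_normal, ref$p_normal, tolerance = 1e-12)
})
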