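test_that("toxicity filter applies the strict 40% viability rule per plate", {
  pl <- generate_screen_plates(
    screen_spec(rows = 4, cols = 6, n_drugs = 16, n_replicates = 1, seed = 1))
  # force exact counts for the boundary check
  pl$count[pl$role == "pos_control"] <- 1000
  drug_rows <- which(pl$role == "drug")
  pl$count[drug_rows[1]] <- 350   # < 400: excluded
  pl$count[drug_rows[2]] <- 400   # = 400: kept (strict <)
  pl$count[drug_rows[-(1:2)]] <- 900
  res <- toxicity_filter(pl)
  expect_true(res$plates$excluded[drug_rows[1]])
  expect_false(res$plates$excluded[drug_rows[2]])
  expect_identical(res$exclusions$reason, "toxicity")
  expect_identical(res$toxic_drugs, pl$drug_id[drug_rows[1]])
  # all-pass identity
  pl$count[drug_rows] <- 900
  res2 <- toxicity_filter(pl)
  expect_identical(nrow(res2$exclusions), 0L)
  # missing positive controls error
  pl2 <- pl[pl$role != "pos_control", ]
  expect_error(toxicity_filter(pl2), "positive-control")
})

test_that("B-scores vanish on constant plates and ignore location shifts", {
  m <- matrix(7, 8, 12)
  bs <- bscore_normalize(m)
  expect_true(all(bs$bscore == 0))
  m2 <- matrix(rnorm(96), 8, 12)
  b1 <- bscore_normalize(m2)$bscore
  b2 <- bscore_normalize(m2 + 100)$bscore
  expect_equal(b1, b2, tolerance = 1e-9)
  expect_error(bscore_normalize(matrix(1, 1, 5)), "2 rows")
})

test_that("a single spiked well attains the unique maximum |B|", {
  m <- matrix(5, 8, 12)
  m[3, 7] <- 25
  m <- m + rnorm(96, sd = 0.2) # small noise so the MAD is positive
  bs <- bscore_normalize(m)
  expect_identical(which.max(abs(bs$bscore)), which(row(m) == 3 & col(m) == 7))
})

test_that("median polish matches the stats::medpolish oracle and", {
  withr::local_seed(11)
  for (i in 1:10) {
    m <- matrix(rnorm(60), 6, 10) + outer(rnorm(6, sd = 2), rnorm(10, sd = 2), "+")
    # medpolish's eps criterion tracks the sum of |residuals| and stops
    # long before the residuals settle; force both to full convergence
    ours <- bscore_normalize(m, tol = 1e-13, max_iter = 2000)
    oracle <- suppressWarnings(
      stats::medpolish(m, eps = 0, maxiter = 400, trace.iter = FALSE))
    expect_equal(ours$residuals, oracle$residuals, tolerance = 1e-6,
                 ignore_attr = TRUE)
    # residual row/column medians vanish at convergence
    expect_lt(max(abs(apply(ours$residuals, 1, median))), 1e-8)
    expect_lt(max(abs(apply(ours$residuals, 2, median))), 1e-8)
  }
})

test_that("hit calling is strict > threshold in >= 2 replicates", {
  bs <- data.frame(
    drug_id = rep(c("a", "b", "c", "d"), each = 3),
    replicate = rep(1:3, 4),
    bscore = c(16, 17, 3,   16, 3, 3,   15, 15, 15,   20, 20, 20))
  h <- call_hits(bs)
  expect_identical(h$hit[h$drug_id == "a"], TRUE)
  expect_identical(h$hit[h$drug_id == "b"], FALSE)
  expect_identical(h$hit[h$drug_id == "c"], FALSE) # 15 is not > 15
  expect_identical(h$hit[h$drug_id == "d"], TRUE)
  # a replicate lost to toxicity counts toward neither side
  h2 <- call_hits(bs[bs$drug_id != "a" | bs$replicate != 3, ])
  expect_identical(h2$hit[h2$drug_id == "a"], TRUE)
  expect_identical(h2$n_replicates[h2$drug_id == "a"], 2L)
})

test_that("selectivity partitions the shared drug universe", {
  mk <- function(ids, hits) data.frame(drug_id = ids, hit = ids %in% hits)
  ids <- sprintf("d%02d", 1:10)
  tab <- classify_selectivity(mk(ids, c("d01", "d02", "d03")),
                              mk(ids, c("d03", "d04")))
  counts <- attr(tab, "counts")
  expect_identical(unname(counts["lineA_only"]), 2L)
  expect_identical(unname(counts["lineB_only"]), 1L)
  expect_identical(unname(counts["both"]), 1L)
  expect_identical(sum(counts[c("lineA_only", "lineB_only", "both")]),
                   length(unique(c("d01", "d02", "d03", "d04"))))
  expect_error(classify_selectivity(mk(ids, "d01"), mk(ids[-1], "d03")),
               "universes")
})

test_that("end-to-end screen recovers spiked actives and rejects toxics", {
  res <- vapply(1:10, function(s) {
    pl <- generate_screen_plates(
      screen_spec(n_drugs = 610, active_drugs = 10, toxic_drugs = 10,
                  seed = s))
    tox <- toxicity_filter(pl)
    hits <- call_hits(bscore_plates(tox$plates))
    truth <- attr(pl, "truth_active")
    toxic <- attr(pl, "truth_toxic")
    hit_ids <- hits$drug_id[hits$hit]
    c(sens = mean(truth %in% hit_ids),
      fpr = sum(!(hit_ids %in% truth)) / (610 - length(truth)),
      toxic_hit = as.numeric(any(toxic %in% hit_ids)))
  }, numeric(3))
  expect_gte(mean(res["sens", ]), 0.9)
  expect_lte(mean(res["fpr", ]), 0.01)
  expect_identical(sum(res["toxic_hit", ]), 0) # toxic drugs never hits
})
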