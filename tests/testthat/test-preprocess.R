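test_that("Ct inversion maps cycles to the expression scale", {
  hi <- matrix(c(30, 49.5), 2, 1,
               dimnames = list(c("hsa-miR-21-5p", "hsa-miR-16-5p"), "s1"))
  eh <- invert_ct(ct_table(hi, censor_limit = 50))
  expect_equal(unname(eh$values[, 1]), c(20, 0.5))
  m <- matrix(c(30, 41), 2, 1,
              dimnames = list(c("hsa-miR-21-5p", "hsa-miR-99a-5p"), "s1"))
  e <- invert_ct(ct_table(m, censor_limit = 40))
  expect_equal(unname(e$values[, 1]), c(20, 10))
  expect_identical(unname(e$detected[, 1]), c(TRUE, FALSE))
  # involution up to the 50 offset
  expect_equal(50 - (50 - m[1, 1]), m[1, 1])
})

test_that("normalizer selection applies exclusion flags and the median-Ct cutoff", {
  n <- 20
  ct <- matrix(30, n, 4,
               dimnames = list(sprintf("hsa-miR-%d-3p", 100 + seq_len(n)),
                               sprintf("s%d", 1:4)))
  ct[19, ] <- 38            # median Ct above 37.5
  ct[20, ] <- c(37, 37, 38, 39)  # median 37.5: kept (strictly-above rule)
  expr <- expr_fixture(50 - ct)
  flagged <- rownames(ct)[1:6]
  kept <- select_normalizers(expr, rownames(ct), exclude = flagged)
  expect_length(kept, 13)
  expect_false(rownames(ct)[19] %in% kept)
  expect_true(rownames(ct)[20] %in% kept)
  expect_false(any(flagged %in% kept))
  # no flags, nothing above the cutoff: identity, order preserved
  expr_lo <- expr_fixture(50 - ct[1:18, ])
  expect_identical(select_normalizers(expr_lo, rownames(ct)[1:18]),
                   rownames(ct)[1:18])
  # a 20-candidate panel with 6 flagged abundant candidates leaves 14
  expect_length(select_normalizers(expr_lo, rownames(ct)[1:18],
                                   exclude = flagged[1:4]), 14)
  expect_error(select_normalizers(expr_lo, rownames(ct)[1:2],
                                  exclude = rownames(ct)[1:2]),
               "no normalizer")
})

test_that("mean-subset normalization anchors at the grand mean", {
  v <- rbind(c(8, 12), c(12, 16), c(20, 25))
  dimnames(v) <- list(c("hsa-miR-1-3p", "hsa-miR-2-5p", "hsa-miR-3-5p"),
                      c("A", "B"))
  expr <- expr_fixture(v)
  norms <- c("hsa-miR-1-3p", "hsa-miR-2-5p")  # sample means 10 and 14, G = 12
  out <- normalize_expression(expr, norms)
  expect_equal(out$values[, "A"], v[, "A"] + 2)
  expect_equal(out$values[, "B"], v[, "B"] - 2)
  expect_true(out$normalized)
  expect_identical(out$normalizer_set, norms)
})

test_that("normalization removes per-sample shifts and is idempotent", {
  set.seed(42)
  v <- matrix(runif(60, 10, 30), 6, 10,
              dimnames = list(sprintf("hsa-miR-%d-5p", 1:6),
                              sprintf("s%d", 1:10)))
  expr <- expr_fixture(v)
  norms <- rownames(v)[1:3]
  # pure centering is exactly invariant to arbitrary per-sample shifts
  cbase <- normalize_expression(expr, norms, anchor = "none")
  shifted <- expr_fixture(sweep(v, 2, runif(10, -5, 5), `+`))
  expect_lt(max(abs(normalize_expression(shifted, norms,
                                         anchor = "none")$values -
                      cbase$values)), 1e-9)
  # the anchored scale absorbs shifts up to their common mean, so it is
  # exactly invariant to any shift pattern that sums to zero
  base <- normalize_expression(expr, norms)
  zshift <- runif(10, -4, 4); zshift <- zshift - mean(zshift)
  shifted0 <- expr_fixture(sweep(v, 2, zshift, `+`))
  expect_lt(max(abs(normalize_expression(shifted0, norms)$values -
                      base$values)), 1e-9)
  expect_equal(normalize_expression(base, norms)$values, base$values)
  # single constant normalizer: G equals the constant, so nothing moves
  v2 <- v; v2[1, ] <- 15
  e2 <- expr_fixture(v2)
  expect_equal(normalize_expression(e2, rownames(v)[1])$values, v2)
})

test_that("undetected normalizers are refused with the culprit named", {
  m <- tiny_ct_matrix(2, 2)
  ct <- ct_table(m)
  ct$detected[1, 2] <- FALSE
  ct$values[1, 2] <- ct$censor_limit
  expr <- invert_ct(ct)
  expect_error(normalize_expression(expr, rownames(m)[1]),
               paste0(rownames(m)[1], ".*s2"))
})

test_that("input-volume adjustment supports log-additive and literal modes", {
  v <- matrix(c(20, 22), 1, 2,
              dimnames = list("hsa-miR-21-5p", c("serum_s", "exo_s")))
  expr <- expr_fixture(v)
  ann <- data.frame(sample_id = c("serum_s", "exo_s"),
                    donor_id = "d", fraction = c("serum", "exosome"),
                    group = "calibration", input_volume_ml = c(0.2, 0.5))
  la <- adjust_for_input_volume(expr, ann, reference_volume = 1)
  expect_equal(la$values[1, "serum_s"], 20 + log2(5))
  expect_equal(la$values[1, "exo_s"], 22 + 1)
  ls <- adjust_for_input_volume(expr, ann, reference_volume = 1,
                                mode = "literal_scale")
  expect_equal(ls$values[1, "serum_s"], 100)
  expect_equal(ls$values[1, "exo_s"], 44)
  # reference volume equal to the input leaves values unchanged
  ann$input_volume_ml <- 1
  for (mode in c("log_additive", "literal_scale"))
    expect_equal(adjust_for_input_volume(expr, ann, 1, mode)$values,
                 expr$values)
  ann$input_volume_ml <- c(0, 1)
  expect_error(adjust_for_input_volume(expr, ann), "positive")
})

test_that("global expression is the per-sample median, censored values included", {
  v <- matrix(c(10, 20, 30, 10, 10, 10), 3, 2,
              dimnames = list(sprintf("hsa-miR-%d-5p", 1:3), c("a", "b")))
  expr <- expr_fixture(v)
  expect_equal(unname(global_expression(expr)), c(20, 10))
  all_und <- ct_table(matrix(41, 3, 2, dimnames = dimnames(v)),
                      censor_limit = 40)
  expect_equal(unname(global_expression(invert_ct(all_und))), c(10, 10))
})

test_that("simulated Ago1 global expression sits below every other serum fraction", {
  sim <- simulate_cohort(default_study_config(), seed = 21)
  ann <- sim$cohort$annotations
  cal <- ann$sample_id[ann$group == "calibration" &
                         !ann$fraction %in% c("rbc", "wbc", "platelet")]
  adj <- adjust_for_input_volume(
    subset_table(invert_ct(sim$cohort$ct), samples = cal), ann, 1)
  g <- global_expression(adj)
  med <- tapply(g, ann$fraction[match(names(g), ann$sample_id)], median)
  expect_true(all(med["ago1"] < med[setdiff(names(med), "ago1")]))
})
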