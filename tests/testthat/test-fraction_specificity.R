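test_that("signed fold change follows the negative-reciprocal convention", {
  expect_equal(signed_fold_change(log2(1.7)), 1.7)
  expect_equal(signed_fold_change(-log2(1.8)), -1.8)
  expect_equal(signed_fold_change(0.766), 1.70, tolerance = 2e-3)
  expect_equal(signed_fold_change(-0.848), -1.80, tolerance = 2e-3)
  expect_equal(signed_fold_change(0), 1)
  d <- seq(-4, 4, by = 0.37)
  d <- d[d != 0]
  expect_equal(signed_fold_change(-d), -signed_fold_change(d))
  expect_true(all(abs(signed_fold_change(c(d, 0))) >= 1))
})

blood_fixture <- function(rbc, wbc, platelet) {
  v <- cbind(rbc = rbc, wbc = wbc, platelet = platelet)
  rownames(v) <- sprintf("hsa-miR-%d-3p", 200 + seq_along(rbc))
  expr <- expr_fixture(t(t(v)))
  ann <- data.frame(sample_id = colnames(v), donor_id = "B1",
                    fraction = colnames(v), group = "calibration",
                    input_volume_ml = 1)
  list(expr = expr, ann = ann)
}

test_that("blood-fraction specificity applies the percentile and margin rules", {
  # 10 miRNAs; candidate sits at the top of the RBC profile with margins > 2
  rbc <- c(30, seq(18, 26, length.out = 9))
  wbc <- c(25, seq(18, 26, length.out = 9))
  plt <- c(24, seq(18, 26, length.out = 9))
  fx <- blood_fixture(rbc, wbc, plt)
  calls <- call_blood_specific(fx$expr, fx$ann)
  expect_identical(calls$label[1], "rbc")
  expect_true(all(calls$label[-1] == "none"))

  # margin 1.5 <= 2 blocks the call even at the top of the profile
  fx2 <- blood_fixture(rbc, c(28.5, wbc[-1]), plt)
  expect_identical(call_blood_specific(fx2$expr, fx2$ann)$label[1], "none")

  # WBC rule compares against RBC only
  fx3 <- blood_fixture(c(22, rbc[-1]), c(30, wbc[-1]), c(29, plt[-1]))
  expect_identical(call_blood_specific(fx3$expr, fx3$ann)$label[1], "wbc")

  # platelet-dominant miRNAs are never labelled
  fx4 <- blood_fixture(c(20, rbc[-1]), c(20, wbc[-1]), c(34, plt[-1]))
  expect_false("platelet" %in% call_blood_specific(fx4$expr, fx4$ann)$label)
  expect_identical(call_blood_specific(fx4$expr, fx4$ann)$label[1], "none")

  # missing fraction profile is a hard error
  expect_error(call_blood_specific(fx$expr, fx$ann[-3, ]), "platelet")
})

ago_fixture <- function(deltas, base = 20, ago2 = 18, n_extra = 2,
                        ct_break = NULL) {
  # one miRNA of interest with given per-donor ago1-ago2 deltas (log2),
  # plus flat helper miRNAs so the tables are non-degenerate
  donors <- sprintf("D%d", seq_along(deltas))
  s1 <- paste0(donors, "_ago1"); s2 <- paste0(donors, "_ago2")
  v <- rbind(c(ago2 + deltas, rep(ago2, length(deltas))))
  for (i in seq_len(n_extra)) v <- rbind(v, rep(base + i, 2 * length(deltas)))
  dimnames(v) <- list(c("hsa-miR-222-3p",
                        sprintf("hsa-miR-%d-5p", 300 + seq_len(n_extra))),
                      c(s1, s2))
  if (!is.null(ct_break)) v[1, ct_break] <- 50 - 38  # raw Ct 38 there
  ct <- ct_table(50 - v)
  ann <- data.frame(sample_id = c(s1, s2),
                    donor_id = rep(donors, 2),
                    fraction = rep(c("ago1", "ago2"), each = length(donors)),
                    group = "calibration", input_volume_ml = 1)
  list(expr = invert_ct(ct), ct = ct, ann = ann)
}

test_that("ago differential recovers per-donor paired deltas", {
  fx <- ago_fixture(c(1.2, 1.1, 1.3))
  res <- ago_differential(fx$expr, fx$ct, fx$ann)
  r <- res[res$mirna == "hsa-miR-222-3p", ]
  expect_equal(r$median_delta, 1.2)
  expect_equal(r$median_fc, 2^1.2)
  expect_identical(r$direction, "ago1")
  expect_true(r$passes)

  # a median delta of exactly 1 cycle gives fc = 2, failing the strict rule
  b <- ago_differential(ago_fixture(c(0.9, 1.0, 1.1))$expr,
                        ago_fixture(c(0.9, 1.0, 1.1))$ct,
                        ago_fixture(c(0.9, 1.0, 1.1))$ann)
  expect_equal(b$median_fc[b$mirna == "hsa-miR-222-3p"], 2)
  expect_false(b$passes[b$mirna == "hsa-miR-222-3p"])
})

test_that("a single raw Ct at 38 vetoes the call regardless of fold change", {
  fx <- ago_fixture(c(3.2, 3.1, 3.3), ct_break = 4)  # one ago2 sample at Ct 38
  res <- ago_differential(fx$expr, fx$ct, fx$ann)
  r <- res[res$mirna == "hsa-miR-222-3p", ]
  expect_false(r$ct_ok)
  expect_false(r$passes)
  expect_gt(abs(r$median_fc), 2)
})

test_that("swapping the ago sample labels flips directions and signs only", {
  fx <- ago_fixture(c(1.6, 1.4, 1.8))
  a <- ago_differential(fx$expr, fx$ct, fx$ann)
  ann2 <- fx$ann
  ann2$fraction <- c(ago1 = "ago2", ago2 = "ago1")[fx$ann$fraction]
  b <- ago_differential(fx$expr, fx$ct, ann2)
  expect_equal(b$median_delta, -a$median_delta)
  nz <- a$median_delta != 0  # fold changes of flat miRNAs stay at +1
  expect_equal(b$median_fc[nz], -a$median_fc[nz])
  expect_equal(b$p_value, a$p_value)
  expect_identical(b$passes, a$passes)
  i <- a$mirna == "hsa-miR-222-3p"
  expect_identical(a$direction[i], "ago1")
  expect_identical(b$direction[i], "ago2")
})

test_that("unpaired donors are refused by name", {
  fx <- ago_fixture(c(1.2, 1.1, 1.3))
  expr <- subset_table(fx$expr,
                       samples = setdiff(samples(fx$expr), "D2_ago2"))
  expect_error(ago_differential(expr, fx$ct, fx$ann,
                                donors = c("D1", "D2", "D3")),
               "D2")
})

test_that("planted carrier contrasts are recovered and neutral miRNAs stay quiet", {
  cfg <- default_study_config(noise_sd = 0.3)
  planted <- names(cfg$specificity_plan)[cfg$specificity_plan %in%
                                           c("rbc_ago2", "wbc_ago1",
                                             "ago1_pref", "ago2_pref")]
  neutral <- setdiff(names(cfg$panel),
                     c(names(cfg$specificity_plan),
                       unique(cfg$hf_effects$mirna)))
  hit <- 0; n_planted <- 0; fp <- 0; n_neutral <- 0
  for (s in 1:60) {
    sim <- simulate_cohort(cfg, seed = 4000 + s)
    ann <- sim$cohort$annotations
    cal <- ann$sample_id[ann$group == "calibration" &
                           ann$fraction %in% c("ago1", "ago2")]
    expr <- subset_table(invert_ct(sim$cohort$ct), samples = cal)
    nexpr <- normalize_expression(
      expr, select_normalizers(expr, mirnas(expr)))
    res <- ago_differential(nexpr, sim$cohort$ct, ann)
    pl <- res[res$mirna %in% planted & res$ct_ok, ]
    hit <- hit + sum(pl$passes); n_planted <- n_planted + nrow(pl)
    ne <- res[res$mirna %in% neutral, ]
    fp <- fp + sum(ne$passes); n_neutral <- n_neutral + nrow(ne)
  }
  expect_gte(hit / n_planted, 0.95)
  expect_lte(fp / n_neutral, 0.05)
})
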