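#' Signed linear fold change from a log2 difference
#'
#' Uses the negative-reciprocal reporting convention common in qPCR work:
#' a log2 difference `d >= 0` becomes `2^d` (>= 1), a negative difference
#' becomes `-2^(-d)` (<= -1), so a 1.8-fold down-regulation is reported as
#' -1.8 and no value ever falls strictly inside (-1, 1).
#'
#' @param delta_log2 numeric vector of log2 differences.
#' @return Numeric vector of signed fold changes.
#' @examples
#' signed_fold_change(c(0.766, -0.848, 0))  # ~1.70, ~-1.80, 1
#' @export
signed_fold_change <- function(delta_log2) {
  ifelse(delta_log2 >= 0, 2^delta_log2, -2^(-delta_log2))
}

#' Call blood-fraction-specific miRNAs
#'
#' Operates on the single-donor RBC/WBC/platelet expression profiles. A
#' miRNA is called RBC-specific if its RBC expression is at or above the
#' 80th percentile of the RBC profile and exceeds both the platelet and WBC
#' expression by strictly more than `margin` cycles (log2 units);
#' WBC-specific if its WBC expression is at or above the 80th percentile of
#' the WBC profile and exceeds the RBC expression by more than `margin`.
#' No platelet rule exists (none was found to be needed under analogous
#' criteria), so platelet labels are never produced.
#'
#' @param expr unnormalized `expr_table` containing the blood-fraction
#'   samples.
#' @param ann annotation data frame covering those samples.
#' @param margin required expression margin in log2 units (Ct cycles),
#'   default 2.
#' @param percentile profile quantile a candidate must reach in its own
#'   fraction, default 0.80 (linear-interpolation definition).
#' @return Data frame with one row per miRNA: `mirna`, `label`
#'   (`"rbc"`, `"wbc"` or `"none"`), the three fraction expressions, and the
#'   rule margins.
#' @export
call_blood_specific <- function(expr, ann, margin = 2, percentile = 0.80) {
  stopifnot(inherits(expr, "expr_table"))
  profile <- function(frac) {
    ids <- ann$sample_id[ann$fraction == frac]
    ids <- intersect(ids, samples(expr))
    if (!length(ids))
      stop("no ", frac, " sample available for blood-specificity calling")
    rowMeans(expr$values[, ids, drop = FALSE])
  }
  r <- profile("rbc"); w <- profile("wbc"); p <- profile("platelet")
  q_r <- stats::quantile(r, percentile, names = FALSE, type = 7)
  q_w <- stats::quantile(w, percentile, names = FALSE, type = 7)
  rbc_call <- r >= q_r & (r - p) > margin & (r - w) > margin
  wbc_call <- w >= q_w & (w - r) > margin
  label <- ifelse(rbc_call, "rbc", ifelse(wbc_call, "wbc", "none"))
  data.frame(mirna = mirnas(expr), label = label,
             expr_rbc = r, expr_wbc = w, expr_platelet = p,
             rbc_margin_platelet = r - p, rbc_margin_wbc = r - w,
             wbc_margin_rbc = w - r,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ago1-vs-Ago2 differential association
#'
#' For each miRNA, computes the per-donor paired difference
#' `delta = expr(ago1) - expr(ago2)` (log2 units), summarizes it as a signed
#' median fold change, and tests the deltas against zero with a paired test.
#' A miRNA passes (is called selectively associated) when
#' `|median_fc| > fc_threshold`, `p < p_threshold`, and its raw Ct stays
#' below `ct_limit` (and detected) in every in-scope sample.
#'
#' @param expr normalized `expr_table` covering the paired samples.
#' @param ct the matching raw [ct_table] (for the expressed-everywhere
#'   condition).
#' @param ann annotation data frame.
#' @param fractions length-2 character vector, default `c("ago1", "ago2")`;
#'   the first fraction is the positive direction.
#' @param donors donor ids to use; default: all donors annotated in both
#'   fractions.
#' @param fc_threshold strict fold-change threshold, default 2.
#' @param p_threshold significance threshold, default 0.05.
#' @param ct_limit raw-Ct expression requirement, default 37.5.
#' @param test `"t"` (paired t-test on deltas; default, usable at n = 3
#'   donors) or `"wilcoxon"` (paired signed-rank).
#' @param fc_from `"median_delta"` (signed fold change of the median delta;
#'   default) or `"median_fc"` (median of per-donor signed fold changes).
#' @return Data frame with one row per miRNA: `mirna`, `median_delta`,
#'   `median_fc`, `p_value`, `ct_ok`, `direction`, `passes`.
#' @export
ago_differential <- function(expr, ct, ann,
                             fractions = c("ago1", "ago2"), donors = NULL,
                             fc_threshold = 2, p_threshold = 0.05,
                             ct_limit = 37.5,
                             test = c("t", "wilcoxon"),
                             fc_from = c("median_delta", "median_fc")) {
  test <- match.arg(test)
  fc_from <- match.arg(fc_from)
  stopifnot(inherits(expr, "expr_table"), inherits(ct, "ct_table"),
            length(fractions) == 2)
  sub <- ann[ann$fraction %in% fractions &
               ann$sample_id %in% samples(expr), , drop = FALSE]
  if (is.null(donors)) {
    tab <- table(sub$donor_id, sub$fraction)
    donors <- rownames(tab)[rowSums(tab[, fractions, drop = FALSE] >= 1) == 2]
  }
  if (length(donors) < 2)
    stop("paired test needs at least 2 donors with both fractions")
  pick <- function(d, f) {
    id <- sub$sample_id[sub$donor_id == d & sub$fraction == f]
    if (length(id) != 1)
      stop("donor ", d, " lacks a unique ", f, " sample")
    id
  }
  s1 <- vapply(donors, pick, "", f = fractions[1])
  s2 <- vapply(donors, pick, "", f = fractions[2])
  scope <- c(s1, s2)
  deltas <- expr$values[, s1, drop = FALSE] - expr$values[, s2, drop = FALSE]
  ct_sub <- subset_table(ct, samples = scope, mirnas = mirnas(expr))
  ct_ok <- apply(ct_sub$values < ct_limit & ct_sub$detected, 1, all)
  res <- lapply(seq_len(nrow(deltas)), function(i) {
    d <- deltas[i, ]
    med <- stats::median(d)
    fc <- if (fc_from == "median_delta") signed_fold_change(med)
          else stats::median(signed_fold_change(d))
    p <- if (all(d == d[1])) {
      if (d[1] == 0) 1 else NA_real_
    } else if (test == "t") stats::t.test(d)$p.value
    else stats::wilcox.test(d, exact = TRUE)$p.value
    data.frame(mirna = mirnas(expr)[i], median_delta = med, median_fc = fc,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$ct_ok <- unname(ct_ok)
  out$direction <- ifelse(out$median_delta > 0, fractions[1], fractions[2])
  out$passes <- abs(out$median_fc) > fc_threshold &
    !is.na(out$p_value) & out$p_value < p_threshold & out$ct_ok
  out
}
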