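#' Abundance filter on normalized expression
#'
#' Keeps a miRNA if its median normalized expression is strictly above
#' `threshold` in the HF group or in the control group within the fraction
#' under test (OR semantics: detectably expressed in at least one group).
#'
#' @param expr normalized `expr_table`.
#' @param ann annotation data frame.
#' @param fraction fraction under test (e.g. `"ago1"`).
#' @param threshold expression-units threshold, default 12.
#' @param groups length-2 character vector of group labels, default
#'   `c("hf", "control")`.
#' @return Character vector of retained miRNA ids, in panel order.
#' @export
abundance_filter <- function(expr, ann, fraction, threshold = 12,
                             groups = c("hf", "control")) {
  stopifnot(inherits(expr, "expr_table"))
  ids <- function(g) intersect(
    ann$sample_id[ann$fraction == fraction & ann$group == g],
    samples(expr))
  a <- ids(groups[1]); b <- ids(groups[2])
  if (!length(a) || !length(b))
    stop("both groups need samples in fraction ", fraction)
  med <- function(s) apply(expr$values[, s, drop = FALSE], 1, stats::median)
  keep <- med(a) > threshold | med(b) > threshold
  mirnas(expr)[keep]
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact by default at the small group sizes typical of qPCR cohorts. For
#' untied data the exact null U distribution is used directly; with ties
#' the test enumerates U over all label assignments of the mid-ranked
#' pooled sample while that enumeration is feasible
#' (`choose(n1 + n2, n1) <= 2e5`), and otherwise falls back to the normal
#' approximation with tie correction. `method = "normal_approx"` forces
#' the approximation.
#'
#' @param x,y numeric vectors for the two groups.
#' @param method `"auto"` (exact when `min(n) <= 12`; default), `"exact"`,
#'   or `"normal_approx"`.
#' @param correct continuity correction for the normal approximation,
#'   default `TRUE`.
#' @return List with `statistic` (U for the first group), `p_value`
#'   (two-sided) and `method` actually used (`"exact"`, `"exact_ties"`,
#'   `"normal_approx"`, or `"degenerate"`).
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal_approx"),
                         correct = TRUE) {
  method <- match.arg(method)
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (all(c(x, y) == c(x, y)[1]))
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate"))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  ties <- anyDuplicated(c(x, y)) > 0
  want_exact <- switch(method,
                       auto = min(n1, n2) <= 12,
                       exact = TRUE,
                       normal_approx = FALSE)
  if (want_exact && ties && choose(n, n1) <= 2e5) {
    # exact permutation null of U on mid-ranks (symmetric about n1*n2/2)
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    w <- colSums(matrix(r[utils::combn(n, n1)], nrow = n1))
    u <- w - n1 * (n1 + 1) / 2
    # two-sided as twice the smaller tail (the mid-rank U null need not be
    # symmetric), capped at 1 -- the same convention as the untied exact test
    p <- min(1, 2 * min(mean(u <= u_obs + 1e-9), mean(u >= u_obs - 1e-9)))
    return(list(statistic = u_obs, p_value = p, method = "exact_ties"))
  }
  used <- if (want_exact && !ties) "exact" else "normal_approx"
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = want_exact, correct = correct))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, method = used)
}

#' Heart-failure vs control differential calling within a fraction
#'
#' For every miRNA surviving the abundance filter: fold change from the
#' group medians of normalized expression (signed, negative-reciprocal
#' convention) and a two-sided Mann-Whitney P value. A miRNA passes when it
#' is expressed, `|fc| > fc_threshold` (strict) and `p < p_threshold`.
#' Benjamini-Hochberg q-values are reported for transparency but never gate
#' the call.
#'
#' @param expr normalized `expr_table`.
#' @param ann annotation data frame.
#' @param fraction fraction under test.
#' @param fc_threshold strict signed-fold-change threshold, default 1.5.
#' @param p_threshold default 0.05.
#' @param abundance_threshold passed to [abundance_filter], default 12.
#' @param fc_stat `"median"` (default) or `"mean"` group summary.
#' @param mw_method passed to [mann_whitney].
#' @return Data frame sorted by `p_value` then decreasing `|fc|`, columns
#'   `mirna`, `fraction`, `median_control`, `median_hf`, `fc`, `p_value`,
#'   `q_value`, `expressed`, `passes`.
#' @export
hf_differential <- function(expr, ann, fraction, fc_threshold = 1.5,
                            p_threshold = 0.05, abundance_threshold = 12,
                            fc_stat = c("median", "mean"),
                            mw_method = "auto") {
  fc_stat <- match.arg(fc_stat)
  stopifnot(inherits(expr, "expr_table"))
  if (!fraction %in% ann$fraction)
    stop("unknown fraction: ", fraction)
  ids <- function(g) intersect(
    ann$sample_id[ann$fraction == fraction & ann$group == g],
    samples(expr))
  ctrl <- ids("control"); hf <- ids("hf")
  if (!length(ctrl) || !length(hf))
    stop("both hf and control groups need samples in fraction ", fraction)
  expressed <- abundance_filter(expr, ann, fraction,
                                threshold = abundance_threshold)
  summ <- if (fc_stat == "median") stats::median else mean
  rows <- lapply(mirnas(expr), function(m) {
    a <- expr$values[m, ctrl]
    b <- expr$values[m, hf]
    mw <- mann_whitney(b, a, method = mw_method)
    data.frame(mirna = m, fraction = fraction,
               median_control = summ(a), median_hf = summ(b),
               fc = signed_fold_change(summ(b) - summ(a)),
               p_value = mw$p_value,
               expressed = m %in% expressed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  out$q_value[out$expressed] <- stats::p.adjust(out$p_value[out$expressed],
                                                method = "BH")
  out$passes <- out$expressed & abs(out$fc) > fc_threshold &
    out$p_value < p_threshold
  out <- out[order(out$p_value, -abs(out$fc)), ]
  rownames(out) <- NULL
  out[, c("mirna", "fraction", "median_control", "median_hf", "fc",
          "p_value", "q_value", "expressed", "passes")]
}
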