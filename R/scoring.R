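#' Composite score panel
#'
#' A named set of miRNAs with signs: up-regulated members enter a composite
#' score with weight +1, down-regulated members with -1.
#'
#' @param name panel name.
#' @param members named numeric vector of signs (+1 / -1) keyed by miRNA id.
#' @return Object of class `score_panel`.
#' @export
score_panel <- function(name, members) {
  stopifnot(length(members) >= 1, !is.null(names(members)),
            all(members %in% c(-1, 1)))
  structure(list(name = name, members = members), class = "score_panel")
}

#' @export
print.score_panel <- function(x, ...) {
  cat("score_panel '", x$name, "': ",
      paste0(ifelse(x$members > 0, "+", "-"), names(x$members),
             collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Built-in composite panels
#'
#' `ago1_hf_panel()`: the four miRNAs differential in the Ago1 fraction
#' (miR-222-3p, miR-497-5p, miR-21-5p up; let-7a-5p down, entering with
#' sign -1). `hf_panel()`: the four serum-derived HF markers (miR-22-3p,
#' miR-423-5p, miR-320a, miR-92b-3p), all up-regulated.
#'
#' @return A [score_panel].
#' @export
ago1_hf_panel <- function() {
  score_panel("ago1_hf",
              c("hsa-miR-222-3p" = 1, "hsa-let-7a-5p" = -1,
                "hsa-miR-497-5p" = 1, "hsa-miR-21-5p" = 1))
}

#' @rdname ago1_hf_panel
#' @export
hf_panel <- function() {
  score_panel("hf",
              c("hsa-miR-22-3p" = 1, "hsa-miR-423-5p" = 1,
                "hsa-miR-320a" = 1, "hsa-miR-92b-3p" = 1))
}

#' Composite score per sample
#'
#' `score(s) = sum over panel members of sign * normalized expression`.
#' With `signed = FALSE` every member enters with +1 (literal summation).
#' Undetected member entries contribute at their censored value, with a
#' warning.
#'
#' @param expr normalized `expr_table`.
#' @param panel a [score_panel].
#' @param ann annotation data frame (needed when `fraction` is given).
#' @param fraction restrict scoring to this fraction's samples; default all
#'   samples in `expr`.
#' @param signed use the panel signs (default `TRUE`).
#' @return Named numeric vector of scores, one per sample.
#' @export
composite_score <- function(expr, panel, ann = NULL, fraction = NULL,
                            signed = TRUE) {
  stopifnot(inherits(expr, "expr_table"), inherits(panel, "score_panel"))
  miss <- setdiff(names(panel$members), mirnas(expr))
  if (length(miss))
    stop("panel miRNA absent from table: ", paste(miss, collapse = ", "))
  smp <- samples(expr)
  if (!is.null(fraction)) {
    if (is.null(ann)) stop("annotations needed to restrict by fraction")
    smp <- intersect(ann$sample_id[ann$fraction == fraction], smp)
    if (!length(smp)) stop("no samples in fraction ", fraction)
  }
  sub <- expr$values[names(panel$members), smp, drop = FALSE]
  if (any(!expr$detected[names(panel$members), smp]))
    warning("undetected panel entries contribute at the censored value")
  w <- if (signed) panel$members else abs(panel$members)
  colSums(sub * w)
}

#' Empirical ROC curve and AUC for a two-group score
#'
#' HF is the positive class and higher scores are more HF-like. The curve
#' is evaluated at every distinct score (classifying `score >= threshold`
#' as positive), the AUC is the trapezoidal area under the resulting
#' polygon (equal to the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`), and the operating point maximizes the Youden index
#' `sensitivity + specificity - 1`, taking the lowest threshold on ties.
#'
#' @param scores numeric vector of per-sample scores.
#' @param labels vector of group labels aligned with `scores`.
#' @param positive label of the positive (diseased) class, default `"hf"`.
#' @return Object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `best_threshold`, `sens_at_best`, `spec_at_best`,
#'   `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = "hf") {
  stopifnot(length(scores) == length(labels))
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (!length(pos) || !length(neg))
    stop("both classes must be present to build a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(pos >= t), 0)
  spec <- vapply(thr, function(t) mean(neg < t), 0)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  finite <- is.finite(thr)
  j <- sens + spec - 1
  jf <- j[finite]; tf <- thr[finite]
  best_i <- which(jf == max(jf))
  best_i <- best_i[which.min(tf[best_i])]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 best_threshold = tf[best_i],
                 sens_at_best = sens[finite][best_i],
                 spec_at_best = spec[finite][best_i],
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("roc_result: AUC %.3f (%d positive / %d negative); ",
                     "Youden threshold %.3g -> sens %.1f%%, spec %.1f%%\n"),
              x$auc, x$n_pos, x$n_neg, x$best_threshold,
              100 * x$sens_at_best, 100 * x$spec_at_best))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(1 - x$specificity, x$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), xlim = c(0, 1),
       ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Score a cohort across fractions and summarize discrimination
#'
#' For each requested fraction: per-sample composite scores, group medians,
#' a two-sided Mann-Whitney P value, and the empirical ROC.
#'
#' @param expr normalized `expr_table`.
#' @param ann annotation data frame.
#' @param panel a [score_panel].
#' @param fractions character vector of fractions to evaluate.
#' @param signed use panel signs (default `TRUE`).
#' @return Object of class `score_report`: `summary` (one row per fraction
#'   with `n_control`, `n_hf`, medians, `p_value`, `auc`, the Youden
#'   operating point), plus per-fraction `scores` and `roc` lists.
#' @export
score_report <- function(expr, ann, panel, fractions, signed = TRUE) {
  rows <- list(); scores <- list(); rocs <- list()
  for (f in fractions) {
    sc <- composite_score(expr, panel, ann, fraction = f, signed = signed)
    grp <- ann$group[match(names(sc), ann$sample_id)]
    mw <- mann_whitney(sc[grp == "hf"], sc[grp == "control"])
    roc <- roc_curve(sc, grp, positive = "hf")
    scores[[f]] <- sc
    rocs[[f]] <- roc
    rows[[f]] <- data.frame(
      panel = panel$name, fraction = f,
      n_control = sum(grp == "control"), n_hf = sum(grp == "hf"),
      median_control = stats::median(sc[grp == "control"]),
      median_hf = stats::median(sc[grp == "hf"]),
      p_value = mw$p_value, auc = roc$auc,
      best_threshold = roc$best_threshold,
      sens_at_best = roc$sens_at_best, spec_at_best = roc$spec_at_best,
      stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 scores = scores, roc = rocs, panel = panel),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
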