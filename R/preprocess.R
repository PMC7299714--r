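#' Expression table (inverted Ct scale)
#'
#' Internal constructor shared by the preprocessing stages. Expression is
#' the inverted cycle threshold, `50 - Ct`, a log2-like quantity where
#' higher means more abundant.
#'
#' @noRd
expr_table <- function(values, detected, censor_limit, normalized = FALSE,
                       normalizer_set = character(0),
                       volume_adjusted = FALSE) {
  structure(list(values = values, detected = detected,
                 censor_limit = censor_limit, normalized = normalized,
                 normalizer_set = normalizer_set,
                 volume_adjusted = volume_adjusted),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("expr_table: %d miRNAs x %d samples (inverted-Ct scale%s%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized)
                sprintf(", normalized on %d miRNAs", length(x$normalizer_set))
              else ", unnormalized",
              if (x$volume_adjusted) ", volume-adjusted" else ""))
  invisible(x)
}

#' @export
as.matrix.expr_table <- function(x, ...) x$values

#' Invert Ct values to the expression scale
#'
#' Expression is defined as `50 - Ct`, so higher values mean higher
#' abundance. The detection mask is carried through; undetected entries sit
#' at `50 - censor_limit`.
#'
#' @param ct a [ct_table].
#' @return An `expr_table` of the same shape.
#' @examples
#' m <- matrix(c(30, 40), 1, 2, dimnames = list("hsa-miR-21-5p", c("a", "b")))
#' invert_ct(ct_table(m))$values  # 20 and 10
#' @export
invert_ct <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  expr_table(50 - ct$values, ct$detected, ct$censor_limit)
}

#' Recover raw Ct values from an unnormalized expression table
#' @noRd
raw_ct_values <- function(expr) {
  if (expr$normalized || expr$volume_adjusted)
    stop("raw Ct can only be recovered from an unnormalized, unadjusted table")
  50 - expr$values
}

#' Select the reference subset used for mean normalization
#'
#' Starting from a candidate list, removes every miRNA flagged in any
#' exclusion set (previously group-differential, blood-fraction-specific, or
#' Ago1/Ago2-selective miRNAs) and every candidate whose median raw Ct across
#' the in-scope samples exceeds `ct_limit`. Candidate order is preserved.
#'
#' @param expr unnormalized `expr_table` restricted to the samples in scope.
#' @param candidates character vector of candidate miRNA ids.
#' @param exclude character vector (or list of vectors, internally unioned)
#'   of flagged miRNA ids to drop.
#' @param ct_limit candidates with median raw Ct strictly above this are
#'   dropped (default 37.5 cycles).
#' @param require_detected drop candidates undetected in any in-scope sample
#'   (default `TRUE`), since [normalize_expression] refuses undetected
#'   normalizers.
#' @return Character vector of retained normalizers; errors if empty.
#' @export
select_normalizers <- function(expr, candidates, exclude = character(0),
                               ct_limit = 37.5, require_detected = TRUE) {
  stopifnot(inherits(expr, "expr_table"), length(candidates) >= 1)
  if (is.list(exclude)) exclude <- unique(unlist(exclude, use.names = FALSE))
  miss <- setdiff(candidates, mirnas(expr))
  if (length(miss))
    stop("candidate not in table: ", paste(miss, collapse = ", "))
  ct <- raw_ct_values(expr)
  keep <- !(candidates %in% exclude)
  med <- apply(ct[candidates, , drop = FALSE], 1, stats::median)
  keep <- keep & med <= ct_limit
  if (require_detected)
    keep <- keep & apply(expr$detected[candidates, , drop = FALSE], 1, all)
  out <- candidates[keep]
  if (!length(out))
    stop("no normalizer candidates survive the exclusion filters")
  out
}

#' Mean-subset normalization of expression values
#'
#' Subtracts from every sample the mean expression of the reference subset
#' in that sample, then adds back the grand mean of those per-sample means
#' so that normalized values remain on the inverted-Ct scale (and absolute
#' abundance thresholds stay interpretable). With `anchor = "none"` the
#' values are purely centered per sample.
#'
#' @param expr an `expr_table`.
#' @param normalizers character vector of reference miRNA ids; each must be
#'   detected in every sample.
#' @param anchor `"grand_mean"` (default) or `"none"`.
#' @return A normalized `expr_table` with `normalizer_set` recorded.
#' @export
normalize_expression <- function(expr, normalizers,
                                 anchor = c("grand_mean", "none")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(expr, "expr_table"), length(normalizers) >= 1)
  miss <- setdiff(normalizers, mirnas(expr))
  if (length(miss))
    stop("normalizer not in table: ", paste(miss, collapse = ", "))
  det <- expr$detected[normalizers, , drop = FALSE]
  if (any(!det)) {
    bad <- which(!det, arr.ind = TRUE)[1, ]
    stop("normalizer ", normalizers[bad[1]], " undetected in sample ",
         colnames(det)[bad[2]])
  }
  m_s <- colMeans(expr$values[normalizers, , drop = FALSE])
  g <- if (anchor == "grand_mean") mean(m_s) else 0
  expr$values <- sweep(expr$values, 2, m_s) + g
  expr$normalized <- TRUE
  expr$normalizer_set <- normalizers
  expr
}

#' Adjust expression for the serum input volume of each preparation
#'
#' Different fractions are prepared from different serum amounts; this
#' rescales every sample to a common reference volume. The default
#' `log_additive` mode adds `log2(reference_volume / input_volume)` to the
#' log2-scale expression values; `literal_scale` multiplies the expression
#' values by the volume ratio (provided to reproduce published
#' global-expression figures computed that way).
#'
#' @param expr an `expr_table`.
#' @param ann annotation data frame with `sample_id` and `input_volume_ml`.
#' @param reference_volume reference volume in mL, default 1.
#' @param mode `"log_additive"` (default) or `"literal_scale"`.
#' @return The adjusted `expr_table`.
#' @export
adjust_for_input_volume <- function(expr, ann, reference_volume = 1,
                                    mode = c("log_additive",
                                             "literal_scale")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expr_table"))
  vol <- ann$input_volume_ml[match(samples(expr), ann$sample_id)]
  if (any(is.na(vol)))
    stop("no input volume for sample ",
         samples(expr)[which(is.na(vol))[1]])
  if (any(vol <= 0) || reference_volume <= 0)
    stop("input volumes must be positive")
  ratio <- reference_volume / vol
  expr$values <- if (mode == "log_additive")
    sweep(expr$values, 2, log2(ratio), `+`)
  else sweep(expr$values, 2, ratio, `*`)
  expr$volume_adjusted <- TRUE
  expr
}

#' Global expression per sample
#'
#' Defined as the median expression over the full panel for each sample;
#' censored entries contribute at their stored (detection-limit) value.
#'
#' @param expr an `expr_table`.
#' @return Named numeric vector, one value per sample.
#' @export
global_expression <- function(expr) {
  stopifnot(inherits(expr, "expr_table"), nrow(expr$values) >= 1)
  apply(expr$values, 2, stats::median)
}
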