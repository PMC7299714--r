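#' Cycle-threshold table
#'
#' Container for a miRNA-by-sample matrix of raw qRT-PCR cycle-threshold (Ct)
#' values together with a detection mask. Entries that never crossed the
#' amplification threshold (no-calls, or Ct at/beyond the instrument's
#' reliable range) are stored at the censor limit with `detected = FALSE`;
#' downstream stages decide how censored entries are treated.
#'
#' @param values numeric matrix of Ct values (PCR cycles); rownames are miRNA
#'   identifiers (miRBase-style, e.g. `"hsa-miR-222-3p"`), colnames are sample
#'   identifiers. Detected values must lie in (0, 50).
#' @param detected logical matrix of the same shape; `FALSE` marks censored
#'   (undetected) entries. Defaults to `values < censor_limit`.
#' @param censor_limit Ct value (cycles) at and beyond which a measurement is
#'   considered undetected. Default 40.
#' @return An object of class `ct_table`.
#' @examples
#' m <- matrix(c(25, 30, 41, 28), 2, 2,
#'             dimnames = list(c("hsa-miR-21-5p", "hsa-let-7a-5p"),
#'                             c("s1", "s2")))
#' ct <- ct_table(m)
#' ct$detected
#' @export
ct_table <- function(values, detected = NULL, censor_limit = 40) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("Ct values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("Ct matrix needs miRNA rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate miRNA ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (is.null(detected)) {
    detected <- !is.na(values) & values < censor_limit
  }
  detected <- as.matrix(detected)
  storage.mode(detected) <- "logical"
  if (!identical(dim(detected), dim(values)))
    stop("'detected' mask dimensions do not match the Ct matrix")
  dimnames(detected) <- dimnames(values)
  values[!detected] <- censor_limit
  if (any(is.na(values)))
    stop("NA Ct values among detected entries")
  if (any(values[detected] <= 0 | values[detected] >= 50))
    stop("detected Ct values must lie in (0, 50)")
  structure(list(values = values, detected = detected,
                 censor_limit = censor_limit),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d miRNAs x %d samples (censor limit Ct %.4g; %d undetected entries)\n",
              nrow(x$values), ncol(x$values), x$censor_limit,
              sum(!x$detected)))
  invisible(x)
}

#' @rdname mirnas
#' @export
mirnas <- function(x) UseMethod("mirnas")

#' Identifiers stored in a Ct or expression table
#'
#' @param x a `ct_table` or `expr_table`.
#' @return Character vector of miRNA (`mirnas`) or sample (`samples`) ids,
#'   in table order.
#' @export
mirnas.default <- function(x) rownames(x$values)

#' @rdname mirnas
#' @export
samples <- function(x) UseMethod("samples")

#' @rdname mirnas
#' @export
samples.default <- function(x) colnames(x$values)

#' @export
as.matrix.ct_table <- function(x, ...) x$values

#' Subset a table by sample and/or miRNA
#'
#' @param x a `ct_table` or `expr_table`.
#' @param samples,mirnas character vectors of ids to keep (in the given
#'   order); `NULL` keeps all.
#' @return An object of the same class restricted to the requested entries.
#' @export
subset_table <- function(x, samples = NULL, mirnas = NULL) {
  stopifnot(inherits(x, c("ct_table", "expr_table")))
  s <- if (is.null(samples)) colnames(x$values) else samples
  m <- if (is.null(mirnas)) rownames(x$values) else mirnas
  missing_s <- setdiff(s, colnames(x$values))
  missing_m <- setdiff(m, rownames(x$values))
  if (length(missing_s))
    stop("unknown samples: ", paste(missing_s, collapse = ", "))
  if (length(missing_m))
    stop("unknown miRNAs: ", paste(missing_m, collapse = ", "))
  x$values <- x$values[m, s, drop = FALSE]
  x$detected <- x$detected[m, s, drop = FALSE]
  x
}
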