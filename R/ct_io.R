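#' Read a Ct table from a delimited text file
#'
#' Two layouts are supported. `wide`: first column is the miRNA id, every
#' further column one sample. `long`: columns `mirna`, `sample`, `ct`, one
#' measurement per row. Cells that are empty, `"Undetermined"`, `"NA"`, or
#' numeric at/above `censor_limit` are flagged undetected and stored at the
#' censor limit.
#'
#' @param path file path (CSV or TSV; delimiter inferred from the extension
#'   unless given).
#' @param layout `"wide"` or `"long"`.
#' @param delimiter field separator; default `","` for `.csv`, `"\t"` for
#'   `.tsv`/`.txt`.
#' @param censor_limit Ct censoring limit (cycles), default 40.
#' @param undetected_tokens strings treated as no-calls.
#' @return A [ct_table].
#' @export
read_ct_table <- function(path, layout = c("wide", "long"), delimiter = NULL,
                          censor_limit = 40,
                          undetected_tokens = c("", "Undetermined", "NA")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           fileEncoding = "UTF-8")
  parse_ct <- function(txt, rows) {
    txt <- trimws(txt)
    und <- txt %in% undetected_tokens
    val <- suppressWarnings(as.numeric(txt))
    bad <- !und & is.na(val)
    if (any(bad))
      stop("non-numeric Ct value '", txt[bad][1], "' at input row ",
           rows[bad][1])
    high <- !und & val >= censor_limit
    val[und | high] <- censor_limit
    list(values = val, detected = !(und | high))
  }
  if (layout == "wide") {
    if (ncol(raw) < 2) stop("wide layout needs an id column plus samples")
    ids <- trimws(raw[[1]])
    if (anyDuplicated(ids))
      stop("duplicate miRNA id in wide table: ",
           ids[duplicated(ids)][1])
    smp <- trimws(colnames(raw)[-1])
    vals <- matrix(NA_real_, length(ids), length(smp),
                   dimnames = list(ids, smp))
    det <- matrix(TRUE, length(ids), length(smp), dimnames = dimnames(vals))
    for (j in seq_along(smp)) {
      p <- parse_ct(raw[[j + 1]], seq_along(ids) + 1L)
      vals[, j] <- p$values
      det[, j] <- p$detected
    }
  } else {
    need <- c("mirna", "sample", "ct")
    if (!all(need %in% colnames(raw)))
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    key <- paste(trimws(raw$mirna), trimws(raw$sample), sep = "\r")
    if (anyDuplicated(key)) {
      d <- strsplit(key[duplicated(key)][1], "\r")[[1]]
      stop("duplicate (mirna, sample) pair: (", d[1], ", ", d[2], ")")
    }
    p <- parse_ct(raw$ct, seq_len(nrow(raw)) + 1L)
    ids <- unique(trimws(raw$mirna))
    smp <- unique(trimws(raw$sample))
    vals <- matrix(censor_limit, length(ids), length(smp),
                   dimnames = list(ids, smp))
    det <- matrix(FALSE, length(ids), length(smp), dimnames = dimnames(vals))
    idx <- cbind(match(trimws(raw$mirna), ids), match(trimws(raw$sample), smp))
    vals[idx] <- p$values
    det[idx] <- p$detected
  }
  ct_table(vals, det, censor_limit = censor_limit)
}

#' Write a Ct table to a delimited text file
#'
#' Values are written at full double precision so that
#' `read_ct_table(write_ct_table(x))` reproduces `x` exactly; undetected
#' entries are written as `"Undetermined"`.
#'
#' @param ct a [ct_table].
#' @param path output path; delimiter inferred from the extension unless given.
#' @param layout `"wide"` or `"long"`.
#' @param delimiter field separator override.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, layout = c("wide", "long"),
                           delimiter = NULL) {
  layout <- match.arg(layout)
  stopifnot(inherits(ct, "ct_table"))
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  fmt <- function(v, det) ifelse(det, sprintf("%.17g", v), "Undetermined")
  if (layout == "wide") {
    out <- data.frame(mirna = rownames(ct$values), check.names = FALSE,
                      stringsAsFactors = FALSE)
    for (s in colnames(ct$values))
      out[[s]] <- fmt(ct$values[, s], ct$detected[, s])
  } else {
    idx <- expand.grid(m = seq_len(nrow(ct$values)),
                       s = seq_len(ncol(ct$values)))
    out <- data.frame(mirna = rownames(ct$values)[idx$m],
                      sample = colnames(ct$values)[idx$s],
                      ct = fmt(ct$values[cbind(idx$m, idx$s)],
                               ct$detected[cbind(idx$m, idx$s)]),
                      stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

KNOWN_FRACTIONS <- c("serum", "exosome", "ago1", "ago2", "ago1+ago2",
                     "rbc", "wbc", "platelet", "plasma")
KNOWN_GROUPS <- c("control", "hf", "calibration")

#' Read a sample annotation table
#'
#' CSV/TSV with columns `sample_id`, `donor_id`, `fraction`, `group`,
#' `input_volume_ml`.
#'
#' @param path file path.
#' @param delimiter field separator override.
#' @return A data frame of annotations, one row per sample.
#' @export
read_annotations <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  ann <- utils::read.table(path, sep = delimiter, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  need <- c("sample_id", "donor_id", "fraction", "group", "input_volume_ml")
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stop("annotation table missing columns: ", paste(miss, collapse = ", "))
  ann
}

#' Write a sample annotation table
#'
#' @param ann annotation data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Bundle a Ct table with its sample annotations
#'
#' @param ct a [ct_table].
#' @param annotations annotation data frame (see [read_annotations]).
#' @return An object of class `mir_cohort`.
#' @export
mir_cohort <- function(ct, annotations) {
  stopifnot(inherits(ct, "ct_table"), is.data.frame(annotations))
  structure(list(ct = ct, annotations = annotations), class = "mir_cohort")
}

#' @export
print.mir_cohort <- function(x, ...) {
  print(x$ct)
  tab <- table(x$annotations$fraction[match(samples(x$ct),
                                            x$annotations$sample_id)])
  cat("fractions:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Check a cohort for structural problems
#'
#' Reporting operation: returns machine-readable findings rather than
#' raising. An empty result means the cohort is internally consistent.
#'
#' @param cohort a [mir_cohort].
#' @return Data frame with columns `kind` (e.g. `missing_annotation`,
#'   `unknown_fraction`, `unknown_group`, `empty_group`, `orphan_annotation`,
#'   `nonpositive_volume`, `duplicate_annotation`) and `detail`; zero rows if
#'   no findings.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "mir_cohort"))
  ann <- cohort$annotations
  f <- list()
  add <- function(kind, detail)
    f[[length(f) + 1L]] <<- data.frame(kind = kind, detail = detail,
                                       stringsAsFactors = FALSE)
  for (s in setdiff(samples(cohort$ct), ann$sample_id))
    add("missing_annotation", s)
  for (s in setdiff(ann$sample_id, samples(cohort$ct)))
    add("orphan_annotation", s)
  for (s in unique(ann$sample_id[duplicated(ann$sample_id)]))
    add("duplicate_annotation", s)
  for (fr in setdiff(unique(ann$fraction), KNOWN_FRACTIONS))
    add("unknown_fraction", fr)
  for (g in setdiff(unique(ann$group), KNOWN_GROUPS))
    add("unknown_group", g)
  present <- ann$sample_id %in% samples(cohort$ct)
  for (g in setdiff(unique(ann$group), unique(ann$group[present])))
    add("empty_group", g)
  bad_vol <- !is.na(ann$input_volume_ml) & ann$input_volume_ml <= 0
  for (s in ann$sample_id[bad_vol])
    add("nonpositive_volume", s)
  if (length(f)) do.call(rbind, f)
  else data.frame(kind = character(), detail = character(),
                  stringsAsFactors = FALSE)
}
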