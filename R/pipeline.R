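#' Pipeline parameter set
#'
#' All stage thresholds in one place; defaults are the study's stated
#' values. Any override is recorded verbatim in the run manifest.
#'
#' @param ct_limit raw-Ct expression requirement (cycles), default 37.5.
#' @param abundance_threshold normalized-expression abundance gate,
#'   default 12.
#' @param ago_fc_threshold strict Ago1-vs-Ago2 fold-change gate, default 2.
#' @param hf_fc_threshold strict HF-vs-control fold-change gate, default 1.5.
#' @param p_threshold significance gate, default 0.05.
#' @param k_top_cv miRNAs kept for clustering, default 40.
#' @param linkage clustering linkage, default `"average"`.
#' @param blood_margin blood-specificity margin (cycles), default 2.
#' @param reference_volume volume-adjustment reference (mL), default 1.
#' @param signed_scores use panel signs in composite scores, default `TRUE`.
#' @return A named list of parameters.
#' @export
pipeline_params <- function(ct_limit = 37.5, abundance_threshold = 12,
                            ago_fc_threshold = 2, hf_fc_threshold = 1.5,
                            p_threshold = 0.05, k_top_cv = 40,
                            linkage = "average", blood_margin = 2,
                            reference_volume = 1, signed_scores = TRUE) {
  as.list(environment())
}

#' Run the full serum-fraction analysis pipeline
#'
#' Either simulates a cohort from `config` or loads one from `ct_file` /
#' `ann_file`, then runs every stage: validation, Ct inversion,
#' volume-adjusted global expression, sample clustering of the calibration
#' fractions, blood-fraction specificity calls, Ago1-vs-Ago2 differential
#' association, reference-subset normalization of the HF experiment,
#' HF-vs-control differential calling, and composite scores with ROC in
#' the Ago1 and serum fractions. All tabular outputs, a JSON manifest
#' (package version, seed, parameters, input checksums, findings) and a
#' plain-text report are written to `out_dir`. Identical config and seed
#' reproduce identical artifacts (manifest timestamp aside).
#'
#' @param out_dir output directory (created if missing).
#' @param config a [sim_config] used when no input files are given;
#'   default [default_study_config()].
#' @param ct_file,ann_file optional input files (wide Ct table CSV and
#'   annotation CSV) to analyse instead of simulating.
#' @param seed simulation seed, default `config$seed`.
#' @param params a [pipeline_params] list.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(out_dir, config = default_study_config(),
                         ct_file = NULL, ann_file = NULL,
                         seed = config$seed, params = pipeline_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- list()
  truth <- NULL
  if (!is.null(ct_file) || !is.null(ann_file)) {
    if (is.null(ct_file) || is.null(ann_file))
      stop("both ct_file and ann_file are required to load a cohort")
    if (!file.exists(ct_file)) stop("Ct table not found: ", ct_file)
    if (!file.exists(ann_file)) stop("annotation file not found: ", ann_file)
    cohort <- mir_cohort(read_ct_table(ct_file, "wide"),
                         read_annotations(ann_file))
    checksums <- as.list(tools::md5sum(c(ct_file, ann_file)))
  } else {
    sim <- simulate_cohort(config, seed = seed)
    cohort <- sim$cohort
    truth <- sim$truth
    write_ct_table(cohort$ct, file.path(out_dir, "ct_table.csv"))
    write_annotations(cohort$annotations,
                      file.path(out_dir, "annotations.csv"))
    write_planted_truth(truth, file.path(out_dir, "planted_truth.json"))
  }
  ann <- cohort$annotations
  findings <- validate_cohort(cohort)
  expr <- invert_ct(cohort$ct)

  # -- calibration: global expression (volume-adjusted) ---------------------
  cal_ids <- ann$sample_id[ann$group == "calibration" &
                             !ann$fraction %in% c("rbc", "wbc", "platelet")]
  glob <- NULL
  if (length(cal_ids)) {
    adj <- adjust_for_input_volume(subset_table(expr, samples = cal_ids),
                                   ann, params$reference_volume)
    glob <- data.frame(sample_id = cal_ids,
                       fraction = ann$fraction[match(cal_ids, ann$sample_id)],
                       global_expression = unname(global_expression(adj)),
                       stringsAsFactors = FALSE)
    utils::write.csv(glob, file.path(out_dir, "global_expression.csv"),
                     row.names = FALSE)
  }

  # -- calibration: clustering, blood specificity, ago differential ---------
  clustering <- NULL; blood <- NULL; ago <- NULL
  norm_cal <- NULL
  if (length(cal_ids) >= 3) {
    cal_expr <- subset_table(expr, samples = cal_ids)
    cal_norm_set <- select_normalizers(cal_expr, mirnas(cal_expr),
                                       ct_limit = params$ct_limit)
    norm_cal <- normalize_expression(cal_expr, cal_norm_set)
    clustering <- cluster_samples(norm_cal, k_top = params$k_top_cv,
                                  linkage = params$linkage)
    write_tree_newick(clustering, file.path(out_dir, "cluster_tree.nwk"))
    jsonlite::write_json(
      list(linkage = clustering$linkage,
           labels = clustering$labels,
           merge = clustering$merge, height = clustering$height,
           order = clustering$order,
           selected_mirnas = clustering$selected_mirnas),
      file.path(out_dir, "cluster_tree.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  blood_ids <- ann$sample_id[ann$fraction %in% c("rbc", "wbc", "platelet")]
  if (length(unique(ann$fraction[match(blood_ids, ann$sample_id)])) == 3) {
    blood <- call_blood_specific(subset_table(expr, samples = blood_ids),
                                 ann, margin = params$blood_margin)
    utils::write.csv(blood, file.path(out_dir, "blood_specificity.csv"),
                     row.names = FALSE)
  }
  if (!is.null(norm_cal) &&
      all(c("ago1", "ago2") %in% ann$fraction[match(cal_ids,
                                                    ann$sample_id)])) {
    ago <- ago_differential(norm_cal, cohort$ct, ann,
                            fc_threshold = params$ago_fc_threshold,
                            p_threshold = params$p_threshold,
                            ct_limit = params$ct_limit)
    utils::write.csv(ago, file.path(out_dir, "ago_differential.csv"),
                     row.names = FALSE)
  }

  # -- HF experiment: normalization, differential calling, scoring ----------
  hf_ids <- ann$sample_id[ann$group %in% c("hf", "control")]
  diff_res <- list(); reports <- list(); norm_hf <- NULL
  if (length(hf_ids)) {
    hf_expr <- subset_table(expr, samples = hf_ids)
    exclude <- unique(c(
      names(ago1_hf_panel()$members), names(hf_panel()$members),
      if (!is.null(blood)) blood$mirna[blood$label != "none"],
      if (!is.null(ago)) ago$mirna[ago$passes]))
    norm_set <- select_normalizers(hf_expr, mirnas(hf_expr),
                                   exclude = exclude,
                                   ct_limit = params$ct_limit)
    norm_hf <- normalize_expression(hf_expr, norm_set)
    hf_fracs <- intersect(c("ago1", "serum"),
                          ann$fraction[match(hf_ids, ann$sample_id)])
    for (f in hf_fracs) {
      diff_res[[f]] <- hf_differential(
        norm_hf, ann, f, fc_threshold = params$hf_fc_threshold,
        p_threshold = params$p_threshold,
        abundance_threshold = params$abundance_threshold)
      utils::write.csv(diff_res[[f]],
                       file.path(out_dir,
                                 paste0("hf_differential_", f, ".csv")),
                       row.names = FALSE)
    }
    for (p in list(ago1_hf_panel(), hf_panel())) {
      rep <- score_report(norm_hf, ann, p, hf_fracs,
                          signed = params$signed_scores)
      reports[[p$name]] <- rep
      utils::write.csv(rep$summary,
                       file.path(out_dir,
                                 paste0("scores_", p$name, ".csv")),
                       row.names = FALSE)
    }
  }

  manifest <- list(
    package = "agomir",
    version = as.character(utils::packageVersion("agomir")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = as.integer(seed),
    parameters = params,
    simulated = is.null(ct_file),
    input_checksums = checksums,
    findings = findings,
    normalizers_hf = if (!is.null(norm_hf)) norm_hf$normalizer_set,
    stages_run = c("validate", "global_expression",
                   if (!is.null(clustering)) "clustering",
                   if (!is.null(blood)) "blood_specificity",
                   if (!is.null(ago)) "ago_differential",
                   if (length(diff_res)) "hf_differential",
                   if (length(reports)) "scoring"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  write_report(file.path(out_dir, "report.txt"), manifest, glob, clustering,
               blood, ago, diff_res, reports)
  invisible(list(cohort = cohort, truth = truth, manifest = manifest,
                 global_expression = glob, clustering = clustering,
                 blood_specificity = blood, ago_differential = ago,
                 hf_differential = diff_res, score_reports = reports,
                 normalized = norm_hf))
}

#' @noRd
write_report <- function(path, manifest, glob, clustering, blood, ago,
                         diff_res, reports) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("agomir pipeline report (seed %d)", manifest$seed)
  w("stages: %s", paste(manifest$stages_run, collapse = ", "))
  if (!is.null(glob)) {
    w("\n== Global expression (volume-adjusted median, by fraction) ==")
    med <- tapply(glob$global_expression, glob$fraction, stats::median)
    for (f in names(med)) w("  %-10s %.2f", f, med[f])
  }
  if (!is.null(clustering)) {
    w("\n== Clustering ==")
    w("  %d samples, %s linkage, %d top-CV miRNAs",
      length(clustering$labels), clustering$linkage,
      length(clustering$selected_mirnas))
  }
  if (!is.null(blood)) {
    w("\n== Blood-fraction specificity ==")
    w("  RBC-specific: %s",
      paste(blood$mirna[blood$label == "rbc"], collapse = ", "))
    w("  WBC-specific: %s",
      paste(blood$mirna[blood$label == "wbc"], collapse = ", "))
  }
  if (!is.null(ago)) {
    w("\n== Ago1 vs Ago2 differential association ==")
    w("  Ago1-selective: %d; Ago2-selective: %d",
      sum(ago$passes & ago$direction == "ago1"),
      sum(ago$passes & ago$direction == "ago2"))
  }
  for (f in names(diff_res)) {
    d <- diff_res[[f]]
    w("\n== HF vs control differential (%s) ==", f)
    hits <- d[d$passes, ]
    if (nrow(hits)) {
      for (i in seq_len(nrow(hits)))
        w("  %-18s fc %+.2f  p %.4g", hits$mirna[i], hits$fc[i],
          hits$p_value[i])
    } else w("  no miRNA passed the criteria")
  }
  for (nm in names(reports)) {
    w("\n== Composite score '%s' ==", nm)
    s <- reports[[nm]]$summary
    for (i in seq_len(nrow(s)))
      w("  %-8s AUC %.3f  p %.4g  sens %.0f%%  spec %.0f%%", s$fraction[i],
        s$auc[i], s$p_value[i], 100 * s$sens_at_best[i],
        100 * s$spec_at_best[i])
  }
}
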