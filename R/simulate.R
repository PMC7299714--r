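#' Simulation configuration for a synthetic serum-fraction cohort
#'
#' Defines the generative model used by [simulate_cohort]: per-miRNA baseline
#' Ct, additive fraction loading offsets, carrier/cell specificity profiles,
#' group (heart failure) effects, measurement noise, and censoring. On the
#' Ct scale one log2 unit of expression equals one PCR cycle (perfect
#' doubling), so effects configured as log2 fold changes are planted as Ct
#' shifts of the same magnitude, with up-regulation lowering Ct.
#'
#' @param panel named numeric vector: baseline Ct (cycles, whole-serum scale)
#'   per miRNA.
#' @param n_control,n_hf cohort sizes (donors per group), defaults 10 and 8.
#' @param n_calibration_donors donors in the fraction-calibration set,
#'   default 3.
#' @param fraction_offsets named numeric: additive Ct offset per fraction
#'   (larger = less abundant fraction).
#' @param specificity_plan named character: carrier/cell profile label per
#'   miRNA (a name of `plan_effects`); miRNAs not listed are neutral.
#' @param plan_effects named list: per profile label, a named numeric vector
#'   of expression deltas (log2 units, positive = enriched) per fraction.
#' @param hf_effects data frame with columns `mirna`, `fraction`, `log2fc`:
#'   planted HF-vs-control effects (positive = up in HF).
#' @param noise_sd per-measurement Gaussian noise SD on the Ct scale.
#' @param donor_sd SD of an additive per-donor random effect (cycles),
#'   default 0 (no donor effect).
#' @param censor_limit Ct detection limit, default 40.
#' @param cohort_fractions fractions measured for the control/HF cohort.
#' @param calibration_fractions serum fractions measured for each
#'   calibration donor.
#' @param blood_fractions blood-cell fractions measured once (single control
#'   donor).
#' @param volumes named numeric: millilitres of serum/plasma per fraction
#'   preparation (used for the `input_volume_ml` annotation).
#' @param seed default RNG seed for [simulate_cohort].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(panel,
                       n_control = 10, n_hf = 8, n_calibration_donors = 3,
                       fraction_offsets = c(serum = 0),
                       specificity_plan = character(0),
                       plan_effects = list(),
                       hf_effects = data.frame(mirna = character(),
                                               fraction = character(),
                                               log2fc = numeric()),
                       noise_sd = 0.3, donor_sd = 0, censor_limit = 40,
                       cohort_fractions = c("serum", "ago1"),
                       calibration_fractions = c("serum", "exosome", "ago1",
                                                 "ago2", "ago1+ago2"),
                       blood_fractions = c("rbc", "wbc", "platelet"),
                       volumes = c(serum = 0.2, exosome = 0.5, ago1 = 1,
                                   ago2 = 1, `ago1+ago2` = 1, rbc = 1,
                                   wbc = 1, platelet = 1, plasma = 1),
                       seed = 1L) {
  stopifnot(is.numeric(panel), length(panel) >= 1, !is.null(names(panel)))
  if (noise_sd < 0 || donor_sd < 0) stop("noise_sd and donor_sd must be >= 0")
  if (n_control < 1 || n_hf < 1) stop("n_control and n_hf must be >= 1")
  bad <- setdiff(union(hf_effects$mirna, names(specificity_plan)),
                 names(panel))
  if (length(bad))
    stop("effect for miRNA not in panel: ", paste(bad, collapse = ", "))
  bad_lab <- setdiff(unique(specificity_plan), names(plan_effects))
  if (length(bad_lab))
    stop("specificity_plan label without plan_effects entry: ",
         paste(bad_lab, collapse = ", "))
  structure(list(panel = panel, n_control = n_control, n_hf = n_hf,
                 n_calibration_donors = n_calibration_donors,
                 fraction_offsets = fraction_offsets,
                 specificity_plan = specificity_plan,
                 plan_effects = plan_effects, hf_effects = hf_effects,
                 noise_sd = noise_sd, donor_sd = donor_sd,
                 censor_limit = censor_limit,
                 cohort_fractions = cohort_fractions,
                 calibration_fractions = calibration_fractions,
                 blood_fractions = blood_fractions,
                 volumes = volumes, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default study-design configuration
#'
#' An 84-miRNA panel measured as in the emulated study design: 3 calibration
#' donors across the five serum fractions, one blood-cell control donor
#' (RBC/WBC/platelet), and a 10-control / 8-HF cohort measured in whole serum
#' and Ago1 RIP. Planted structure: Ago1 is the least abundant fraction;
#' red-cell miRNAs (miR-451a, miR-486-5p, miR-16-5p, ...) are enriched in
#' Ago2, leukocyte miRNAs (miR-223-3p, ...) in Ago1; four HF markers
#' (miR-222-3p +1.7x, miR-497-5p +1.8x, miR-21-5p +1.6x, let-7a-5p -1.8x)
#' act in the Ago1 fraction with the same trends attenuated (x0.4 on the
#' log2 scale) in whole serum; four serum-panel markers (miR-22-3p,
#' miR-423-5p, miR-320a, miR-92b-3p) are up-regulated in both fractions.
#'
#' @param noise_sd measurement noise SD (Ct cycles), default 0.3.
#' @param seed default seed carried into the config.
#' @param serum_attenuation multiplier applied to the four Ago1-marker log2
#'   effects when planted in whole serum, default 0.4.
#' @return A [sim_config].
#' @export
default_study_config <- function(noise_sd = 0.3, seed = 1L,
                                 serum_attenuation = 0.4) {
  special <- c(
    # HF markers, Ago1 fraction (abundant, mid-range baselines)
    "hsa-miR-222-3p" = 27, "hsa-miR-497-5p" = 29, "hsa-miR-21-5p" = 23,
    "hsa-let-7a-5p" = 24,
    # serum HF panel
    "hsa-miR-22-3p" = 26, "hsa-miR-423-5p" = 28, "hsa-miR-320a" = 27,
    "hsa-miR-92b-3p" = 30,
    # red-cell profile, carried by Ago2
    "hsa-miR-451a" = 23, "hsa-miR-486-5p" = 25, "hsa-miR-16-5p" = 22,
    "hsa-miR-92a-3p" = 24, "hsa-miR-25-3p" = 26,
    # leukocyte profile, carried by Ago1
    "hsa-miR-223-3p" = 23, "hsa-miR-150-5p" = 26, "hsa-miR-155-5p" = 28,
    "hsa-miR-142-3p" = 25, "hsa-miR-146a-5p" = 27,
    # Ago1-preferring without blood-cell identity
    "hsa-miR-339-5p" = 27, "hsa-miR-378a-3p" = 28, "hsa-miR-424-5p" = 29,
    "hsa-miR-199a-3p" = 26, "hsa-miR-126-5p" = 27,
    # Ago2-preferring
    "hsa-miR-122-5p" = 26, "hsa-miR-192-5p" = 27, "hsa-miR-375" = 28,
    "hsa-miR-148a-3p" = 27, "hsa-miR-30d-5p" = 29,
    # vesicle-carried (serum/exosome) profile
    "hsa-miR-126-3p" = 25, "hsa-miR-133a-3p" = 27, "hsa-miR-133b" = 26,
    "hsa-miR-208a-3p" = 28, "hsa-miR-499a-5p" = 30, "hsa-miR-1-3p" = 31)
  neutral_names <- paste0("hsa-", c(
    "let-7b-5p", "let-7c-5p", "let-7d-5p", "let-7e-5p", "let-7f-5p",
    "let-7g-5p", "let-7i-5p", "miR-103a-3p", "miR-106a-5p", "miR-106b-5p",
    "miR-107", "miR-10a-5p", "miR-10b-5p", "miR-125a-5p", "miR-125b-5p",
    "miR-130a-3p", "miR-140-3p", "miR-143-3p", "miR-145-5p", "miR-148b-3p",
    "miR-151a-3p", "miR-15a-5p", "miR-15b-5p", "miR-17-5p", "miR-181a-5p",
    "miR-185-5p", "miR-186-5p", "miR-18a-5p", "miR-191-5p", "miR-195-5p",
    "miR-197-3p", "miR-19a-3p", "miR-19b-3p", "miR-200c-3p", "miR-20a-5p",
    "miR-23a-3p", "miR-24-3p", "miR-26a-5p", "miR-26b-5p", "miR-27a-3p",
    "miR-27b-3p", "miR-28-3p", "miR-29a-3p", "miR-29c-3p", "miR-30a-5p",
    "miR-30c-5p", "miR-342-3p", "miR-34a-5p", "miR-93-5p", "miR-99a-5p"))
  neutral <- stats::setNames(seq(22, 34, length.out = length(neutral_names)),
                             neutral_names)
  panel <- c(special, neutral)

  plan_effects <- list(
    rbc_ago2  = c(rbc = 6, ago2 = 3, `ago1+ago2` = 2.5,
                  serum = 1.5, exosome = 1.5),
    wbc_ago1  = c(wbc = 6, ago1 = 3, `ago1+ago2` = 0.8),
    ago1_pref = c(ago1 = 2.5, `ago1+ago2` = 0.6),
    ago2_pref = c(ago2 = 2.5, `ago1+ago2` = 2.0),
    vesicle   = c(serum = 2, exosome = 2))
  plan <- c(
    stats::setNames(rep("rbc_ago2", 5),
                    c("hsa-miR-451a", "hsa-miR-486-5p", "hsa-miR-16-5p",
                      "hsa-miR-92a-3p", "hsa-miR-25-3p")),
    stats::setNames(rep("wbc_ago1", 5),
                    c("hsa-miR-223-3p", "hsa-miR-150-5p", "hsa-miR-155-5p",
                      "hsa-miR-142-3p", "hsa-miR-146a-5p")),
    stats::setNames(rep("ago1_pref", 5),
                    c("hsa-miR-339-5p", "hsa-miR-378a-3p", "hsa-miR-424-5p",
                      "hsa-miR-199a-3p", "hsa-miR-126-5p")),
    stats::setNames(rep("ago2_pref", 5),
                    c("hsa-miR-122-5p", "hsa-miR-192-5p", "hsa-miR-375",
                      "hsa-miR-148a-3p", "hsa-miR-30d-5p")),
    stats::setNames(rep("vesicle", 6),
                    c("hsa-miR-126-3p", "hsa-miR-133a-3p", "hsa-miR-133b",
                      "hsa-miR-208a-3p", "hsa-miR-499a-5p", "hsa-miR-1-3p")))

  ago1_lfc <- c("hsa-miR-222-3p" = log2(1.7), "hsa-miR-497-5p" = log2(1.8),
                "hsa-miR-21-5p" = log2(1.6), "hsa-let-7a-5p" = -log2(1.8))
  serum_panel <- c("hsa-miR-22-3p", "hsa-miR-423-5p", "hsa-miR-320a",
                   "hsa-miR-92b-3p")
  hf_effects <- rbind(
    data.frame(mirna = names(ago1_lfc), fraction = "ago1",
               log2fc = unname(ago1_lfc), stringsAsFactors = FALSE),
    data.frame(mirna = names(ago1_lfc), fraction = "serum",
               log2fc = unname(ago1_lfc) * serum_attenuation,
               stringsAsFactors = FALSE),
    data.frame(mirna = serum_panel, fraction = "ago1", log2fc = 0.8,
               stringsAsFactors = FALSE),
    data.frame(mirna = serum_panel, fraction = "serum", log2fc = 0.5,
               stringsAsFactors = FALSE))

  sim_config(panel = panel,
             fraction_offsets = c(serum = 0, exosome = 0.3,
                                  `ago1+ago2` = 1.0, ago2 = 1.5, ago1 = 5.0,
                                  rbc = -1.0, wbc = 0.5, platelet = 0.5,
                                  plasma = 0),
             specificity_plan = plan, plan_effects = plan_effects,
             hf_effects = hf_effects, noise_sd = noise_sd, seed = seed)
}

#' Simulate a synthetic cohort with planted ground truth
#'
#' Generates Ct values as
#' `Ct(m, s) = baseline(m) + offset(fraction(s)) - plan_delta(m, fraction(s))
#'  - hf_effect(m, fraction(s)) * [group(s) = hf] + donor(s) + N(0, noise_sd^2)`,
#' censors values at the detection limit, and returns the cohort together
#' with an immutable record of what was planted. Deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param config a [sim_config].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list with elements `cohort` (a [mir_cohort]) and `truth`
#'   (class `planted_truth`: planted effects, profiles, baselines, offsets,
#'   and the seed used).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  need <- unique(c(config$cohort_fractions, config$calibration_fractions,
                   config$blood_fractions))
  miss <- setdiff(need, names(config$fraction_offsets))
  if (length(miss))
    stop("no fraction_offset for: ", paste(miss, collapse = ", "))

  donors <- c(sprintf("C%02d", seq_len(config$n_control)),
              sprintf("H%02d", seq_len(config$n_hf)),
              sprintf("D%d", seq_len(config$n_calibration_donors)), "B1")
  dgroup <- c(rep("control", config$n_control), rep("hf", config$n_hf),
              rep("calibration", config$n_calibration_donors), "calibration")
  dfrac <- c(rep(list(config$cohort_fractions),
                 config$n_control + config$n_hf),
             rep(list(config$calibration_fractions),
                 config$n_calibration_donors),
             list(config$blood_fractions))

  ann <- do.call(rbind, lapply(seq_along(donors), function(i) {
    fr <- dfrac[[i]]
    data.frame(sample_id = paste(donors[i], fr, sep = "_"),
               donor_id = donors[i], fraction = fr, group = dgroup[i],
               input_volume_ml = unname(config$volumes[fr]),
               stringsAsFactors = FALSE)
  }))

  mir <- names(config$panel)
  n_m <- length(mir)
  n_s <- nrow(ann)
  mu <- matrix(config$panel, n_m, n_s)
  mu <- mu + matrix(config$fraction_offsets[ann$fraction], n_m, n_s,
                    byrow = TRUE)
  # carrier/cell specificity profiles (expression deltas lower Ct)
  for (m in names(config$specificity_plan)) {
    eff <- config$plan_effects[[config$specificity_plan[[m]]]]
    hit <- ann$fraction %in% names(eff)
    mu[match(m, mir), hit] <- mu[match(m, mir), hit] - eff[ann$fraction[hit]]
  }
  # HF effects (up in HF = lower Ct in the hf group)
  he <- config$hf_effects
  if (nrow(he)) {
    for (i in seq_len(nrow(he))) {
      hit <- ann$group == "hf" & ann$fraction == he$fraction[i]
      mu[match(he$mirna[i], mir), hit] <-
        mu[match(he$mirna[i], mir), hit] - he$log2fc[i]
    }
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  if (config$donor_sd > 0) {
    dre <- stats::rnorm(length(donors), 0, config$donor_sd)
    mu <- mu + matrix(dre[match(ann$donor_id, donors)], n_m, n_s,
                      byrow = TRUE)
  }
  vals <- mu + matrix(stats::rnorm(n_m * n_s, 0, config$noise_sd), n_m, n_s)
  dimnames(vals) <- list(mir, ann$sample_id)
  vals <- pmax(vals, 0.5)  # physical floor; baselines keep values far above
  det <- vals < config$censor_limit
  vals[!det] <- config$censor_limit

  truth <- structure(list(hf_effects = config$hf_effects,
                          specificity_plan = config$specificity_plan,
                          plan_effects = config$plan_effects,
                          baseline = config$panel,
                          fraction_offsets = config$fraction_offsets,
                          noise_sd = config$noise_sd,
                          censor_limit = config$censor_limit,
                          seed = as.integer(seed)),
                     class = "planted_truth")
  list(cohort = mir_cohort(ct_table(vals, det,
                                    censor_limit = config$censor_limit),
                           ann),
       truth = truth)
}

#' Serialize the planted truth of a simulation run
#'
#' @param truth a `planted_truth` record from [simulate_cohort].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
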