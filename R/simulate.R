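#' Simulation configuration for synthetic multi-omics cohorts
#'
#' Describes a cohort with `k_true` latent subtypes that differ both in a
#' minority of molecular features (mean shifts of `effect_size` within-group
#' standard deviations) and in survival (one exponential hazard per subtype),
#' with independent right-censoring calibrated to a target censored fraction
#' and partial per-platform patient coverage.
#'
#' Defaults emulate a serous ovarian cancer cohort: ~600 patients, four
#' latent subtypes, ~47% censoring, hazards geometrically spanning a 5-fold
#' range (so every adjacent subtype pair is prognostically distinct; median
#' survivals of roughly 200 to 1000 days), and per-platform feature counts
#' scaled down from a typical TCGA-style multi-omics study.
#'
#' @param n_patients Number of patients.
#' @param k_true Number of latent subtypes (>= 2).
#' @param platform_dims Named integer vector platform -> feature count.
#' @param frac_informative Fraction of features per platform carrying subtype
#'   signal, in (0,1).
#' @param effect_size Mean shift of informative features in within-group SDs.
#' @param hazard_per_subtype Exponential hazard (events/day) per subtype;
#'   exactly `k_true` strictly positive entries.
#' @param censor_rate Target censored fraction in (0,1).
#' @param platform_coverage Named vector platform -> fraction of patients
#'   assayed on that platform.
#' @param seed Integer seed; all outputs are pure functions of the config.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_patients = 600,
                              k_true = 4,
                              platform_dims = c(mrna = 2000, methylation = 500,
                                                protein = 100, mirna = 150),
                              frac_informative = 0.10,
                              effect_size = 1.5,
                              hazard_per_subtype = 0.0035 * 5^(-(0:3) / 3),
                              censor_rate = 0.47,
                              platform_coverage = c(mrna = 1, methylation = 0.97,
                                                    protein = 0.69, mirna = 0.79),
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), k_true = as.integer(k_true),
              platform_dims = platform_dims, frac_informative = frac_informative,
              effect_size = effect_size, hazard_per_subtype = hazard_per_subtype,
              censor_rate = censor_rate, platform_coverage = platform_coverage,
              seed = as.integer(seed))
  fail <- function(field, msg) stop("invalid simulation config: field '", field,
                                    "' ", msg, call. = FALSE)
  if (cfg$k_true < 2) fail("k_true", "must be >= 2")
  if (cfg$n_patients < 4 * cfg$k_true) fail("n_patients", "must be >= 4*k_true")
  if (length(cfg$hazard_per_subtype) != cfg$k_true || any(cfg$hazard_per_subtype <= 0))
    fail("hazard_per_subtype", "needs exactly k_true strictly positive rates")
  if (!(cfg$frac_informative > 0 && cfg$frac_informative < 1))
    fail("frac_informative", "must lie in (0,1)")
  if (!(cfg$censor_rate > 0 && cfg$censor_rate < 1))
    fail("censor_rate", "must lie in (0,1)")
  known <- c("mrna", "methylation", "protein", "mirna")
  if (is.null(names(cfg$platform_dims)) || !all(names(cfg$platform_dims) %in% known))
    fail("platform_dims", "must be named with known platforms")
  if (any(cfg$platform_dims < 1)) fail("platform_dims", "feature counts must be >= 1")
  if (!all(names(cfg$platform_dims) %in% names(cfg$platform_coverage)))
    fail("platform_coverage", "must cover every platform in platform_dims")
  if (any(cfg$platform_coverage <= 0 | cfg$platform_coverage > 1))
    fail("platform_coverage", "fractions must lie in (0,1]")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate right-censored survival from per-subtype exponential hazards
#'
#' Event times are exponential with the hazard of each patient's subtype.
#' Censoring times come from an independent exponential whose rate is
#' calibrated by bisection so that the expected censored fraction equals
#' `censor_rate`; `censor_rate = 0` disables censoring. Times are reported
#' in whole days (ceiling), hence strictly positive.
#'
#' @param labels Named integer vector patient -> subtype index.
#' @param hazards Strictly positive hazard rates, one per subtype.
#' @param censor_rate Target censored fraction in `[0, 1)`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A [survival_table()] with one row per patient.
#' @export
simulate_survival <- function(labels, hazards, censor_rate = 0, seed = NULL) {
  if (any(hazards <= 0)) stop("hazards must be strictly positive", call. = FALSE)
  if (length(labels) && (any(labels < 1) || any(labels > length(hazards))))
    stop("subtype label out of range of the hazard list", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  if (length(labels) == 0)
    return(survival_table(character(0), integer(0), numeric(0)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  hz <- hazards[labels]
  t_event <- stats::rexp(length(labels), rate = hz)
  if (censor_rate > 0) {
    lc <- calibrate_censor_rate(hz, censor_rate)
    t_cens <- stats::rexp(length(labels), rate = lc)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, length(labels))
    time <- t_event
  }
  ids <- names(labels) %||% paste0("P", seq_along(labels))
  survival_table(ids, event, ceiling(time))
}

# expected censored fraction mean(lc/(lc+hz)) is increasing in lc; bisect
calibrate_censor_rate <- function(hz, target, iter = 200) {
  f <- function(lc) mean(lc / (lc + hz)) - target
  lo <- min(hz) * 1e-8
  hi <- max(hz) * 1e8
  for (i in seq_len(iter)) {
    mid <- sqrt(lo * hi)  # bisect on log scale: rates span orders of magnitude
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Simulate a multi-platform cohort with planted subtypes
#'
#' Draws latent subtype labels, per-platform feature matrices in which a
#' random `frac_informative` subset of features carries a non-constant
#' per-subtype shift pattern of +-`effect_size`/2 within-group SDs (so any
#' two subtypes the pattern distinguishes sit `effect_size` SDs apart, and
#' features whose pattern aligns with the hazard ordering are prognostic),
#' per-subtype exponential survival with calibrated censoring, partial
#' platform coverage (a random patient subset per platform), and a small
#' clinical table with one subtype-linked and one null variable of each kind.
#'
#' Value domains follow each platform: methylation beta values are
#' logistic-transformed Gaussians in (0,1); mRNA/miRNA are log-normal style
#' (2 to the latent Gaussian) and hence non-negative; protein values are
#' real-valued Gaussians.
#'
#' @param config A [simulation_config()].
#' @return A list of class `SyntheticCohort` with elements `matrices` (named
#'   list of [omics_matrix()]), `survival`, `true_labels` (named by patient),
#'   `planted_features` (named list of informative feature ids), `clinical`
#'   and `sample_types` (all `"primary"`).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    config <- do.call(simulation_config, config)
  set.seed(config$seed)
  n <- config$n_patients
  k <- config$k_true
  patients <- sprintf("P%04d", seq_len(n))
  labels <- stats::setNames(sample(rep_len(seq_len(k), n)), patients)

  matrices <- list()
  planted <- list()
  for (p in names(config$platform_dims)) {
    g <- gen_platform(p, config$platform_dims[[p]], labels, config)
    keep <- sort(sample(n, max(2L, round(config$platform_coverage[[p]] * n))))
    matrices[[p]] <- omics_matrix(g$values[, keep, drop = FALSE], platform = p)
    planted[[p]] <- g$informative
  }

  surv <- simulate_survival(labels, config$hazard_per_subtype,
                            config$censor_rate, seed = NULL)

  noisy <- sample(n, round(0.25 * n))
  stage_cat <- LETTERS[labels]
  stage_cat[noisy] <- sample(LETTERS[seq_len(k)], length(noisy), replace = TRUE)
  clinical <- clinical_table(
    patients,
    variables = list(
      marker_level  = 2 * labels + stats::rnorm(n),        # subtype-linked
      age_years     = stats::rnorm(n, 60, 10),             # null quantitative
      stage_like    = stage_cat,                           # subtype-linked
      center        = sample(c("site1", "site2", "site3"), n, replace = TRUE)
    ),
    kinds = c(marker_level = "quantitative", age_years = "quantitative",
              stage_like = "categorical", center = "categorical"))

  structure(list(matrices = matrices, survival = surv, true_labels = labels,
                 planted_features = planted, clinical = clinical,
                 sample_types = stats::setNames(rep("primary", n), patients),
                 config = config),
            class = "SyntheticCohort")
}

# latent Gaussian with planted subtype shifts, then platform-specific transform
gen_platform <- function(platform, n_feat, labels, config) {
  n <- length(labels)
  k <- config$k_true
  z <- matrix(stats::rnorm(n_feat * n), n_feat, n)
  n_inf <- max(1L, round(config$frac_informative * n_feat))
  inf_idx <- sort(sample(n_feat, n_inf))
  # each informative feature gets a non-constant +-effect/2 shift per subtype,
  # so differing subtypes are effect_size within-group SDs apart and features
  # whose pattern aligns with the hazard ordering are prognostic as well
  for (i in seq_len(n_inf)) {
    pat <- sample(c(-1, 1), k, replace = TRUE)
    while (length(unique(pat)) == 1) pat <- sample(c(-1, 1), k, replace = TRUE)
    if (config$effect_size != 0)
      z[inf_idx[i], ] <- z[inf_idx[i], ] + pat[labels] * config$effect_size / 2
  }
  ids <- switch(platform,
                methylation = sprintf("cg%05d", seq_len(n_feat)),
                mrna = sprintf("gene%05d", seq_len(n_feat)),
                mirna = sprintf("mir%04d", seq_len(n_feat)),
                protein = sprintf("prot%03d", seq_len(n_feat)))
  vals <- switch(platform,
                 methylation = stats::plogis(stats::rnorm(n_feat, 0, 1.5) + z),
                 mrna = 2^(stats::runif(n_feat, 3, 8) + z),
                 mirna = 2^(stats::runif(n_feat, 2, 7) + z),
                 protein = z)  # RPPA-style: normalized, centered per protein
  dimnames(vals) <- list(ids, names(labels))
  list(values = vals, informative = ids[inf_idx])
}

#' Write a synthetic cohort to TSV files
#'
#' Emits one matrix TSV per platform (first column `feature_id`), the
#' survival and clinical tables, clinical variable kinds, sample types,
#' planted-feature lists, and a `manifest.tsv` listing every file written.
#'
#' @param cohort A `SyntheticCohort`.
#' @param directory Output directory (created if needed).
#' @return The manifest as a `data.frame` (kind, platform, path), invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  if (!dir.exists(directory))
    if (!dir.create(directory, recursive = TRUE))
      stop("cannot create output directory: ", directory, call. = FALSE)
  manifest <- list()
  add <- function(kind, platform, file) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      kind = kind, platform = platform, path = file, stringsAsFactors = FALSE)
  }
  surv_path <- file.path(directory, "survival.tsv")
  utils::write.table(
    data.frame(patient_id = cohort$survival$patient_id,
               vital_status = cohort$survival$event,
               days = as.integer(cohort$survival$time_days)),
    surv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  add("survival", NA, "survival.tsv")
  for (p in names(cohort$matrices)) {
    f <- paste0(p, ".tsv")
    write_matrix(cohort$matrices[[p]], file.path(directory, f))
    add("matrix", p, f)
    pf <- paste0("planted_", p, ".txt")
    writeLines(cohort$planted_features[[p]], file.path(directory, pf))
    add("planted_features", p, pf)
  }
  if (!is.null(cohort$clinical)) {
    cl <- cohort$clinical
    df <- data.frame(patient_id = cl$patient_id, stringsAsFactors = FALSE)
    for (v in names(cl$variables)) df[[v]] <- cl$variables[[v]]
    utils::write.table(df, file.path(directory, "clinical.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add("clinical", NA, "clinical.tsv")
    utils::write.table(
      data.frame(variable = names(cl$kinds), kind = unname(cl$kinds)),
      file.path(directory, "clinical_kinds.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    add("clinical_kinds", NA, "clinical_kinds.tsv")
  }
  if (!is.null(cohort$sample_types)) {
    utils::write.table(
      data.frame(sample_id = names(cohort$sample_types),
                 sample_type = unname(cohort$sample_types)),
      file.path(directory, "sample_types.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    add("sample_types", NA, "sample_types.tsv")
  }
  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
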