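#' Read a feature-by-sample matrix TSV
#'
#' The matrix dialect has one header row, a first column `feature_id`, and
#' one tab-separated column per sample. The platform determines the value
#' domain that is enforced on read (methylation -> unit interval,
#' mRNA/miRNA -> non-negative, protein/pathway -> real).
#'
#' @param path Path to the TSV file.
#' @param platform Platform tag, see [omics_matrix()].
#' @return An [omics_matrix()].
#' @export
read_matrix <- function(path, platform) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 1 || names(df)[1] != "feature_id")
    stop("matrix TSV must start with a 'feature_id' column: ", path, call. = FALSE)
  fid <- df[[1]]
  samples <- names(df)[-1]
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(fid, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(is.na(raw) | raw %in% c("NA", "")))
    if (length(bad))
      stop("non-numeric cell in ", path, " at feature '", fid[bad[1]],
           "', sample '", samples[j], "': '", raw[bad[1]], "'", call. = FALSE)
    vals[, j] <- num
  }
  omics_matrix(vals, platform)
}

#' Write a matrix TSV (inverse of [read_matrix()])
#' @param m An [omics_matrix()].
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(feature_id = feature_ids(m), stringsAsFactors = FALSE,
                   check.names = FALSE)
  vals <- m$values
  for (j in seq_len(ncol(vals))) df[[colnames(vals)[j]]] <- vals[, j]
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a patient survival TSV
#'
#' Expects columns `patient_id`, `vital_status` (0 alive/censored, 1 death)
#' and `days`. Rows with missing status or days are dropped; the drop count
#' is attached as attribute `n_dropped` and reported via a message. A status
#' outside \{0,1\} or non-positive days is a format error.
#'
#' @param path Path to the TSV file.
#' @return A [survival_table()], with attribute `n_dropped`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "vital_status", "days")
  if (!all(need %in% names(df)))
    stop("survival TSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  status <- suppressWarnings(as.numeric(df$vital_status))
  days <- suppressWarnings(as.numeric(df$days))
  drop <- is.na(status) | is.na(days)
  if (any(drop)) message(sum(drop), " survival row(s) with missing values dropped")
  status <- status[!drop]; days <- days[!drop]; ids <- df$patient_id[!drop]
  if (length(status) && !all(status %in% c(0, 1)))
    stop("vital_status outside {0,1} in ", path, call. = FALSE)
  if (length(days) && any(days <= 0))
    stop("non-positive survival days in ", path, call. = FALSE)
  out <- survival_table(ids, as.integer(status), days)
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Read a clinical table plus its variable-kind sidecar
#'
#' @param path Clinical TSV (`patient_id` plus one column per variable).
#' @param kinds_path TSV with columns `variable`, `kind`
#'   (quantitative/categorical); variables without a declared kind are
#'   treated as categorical.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path, kinds_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df))
    stop("clinical TSV needs a 'patient_id' column", call. = FALSE)
  vars <- setdiff(names(df), "patient_id")
  kinds <- stats::setNames(rep("categorical", length(vars)), vars)
  if (!is.null(kinds_path)) {
    kd <- utils::read.delim(kinds_path, stringsAsFactors = FALSE)
    kinds[kd$variable[kd$variable %in% vars]] <-
      kd$kind[kd$variable %in% vars]
  }
  clinical_table(df$patient_id, as.list(df[vars]), kinds)
}

#' Read the sample-type sidecar TSV (`sample_id`, `sample_type`)
#' @param path Path to the TSV.
#' @return Named character vector sample id -> type.
#' @export
read_sample_types <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$sample_type, df$sample_id)
}

#' Apply the cohort inclusion rules
#'
#' Retains exactly the samples that are (a) primary tumor, (b) present in
#' the survival table, and (c) not wholly missing, and aligns the survival
#' table to the retained samples in matrix column order. Patient ids are
#' taken to equal sample ids (one primary sample per patient).
#'
#' @param matrix An [omics_matrix()].
#' @param survival A [survival_table()].
#' @param sample_type_of Named character vector mapping every matrix sample
#'   to one of `primary`, `recurrent`, `normal`, `blood`; `NULL` treats all
#'   samples as primary.
#' @return List with elements `matrix`, `survival` (aligned), and `n_dropped`.
#' @export
filter_cohort <- function(matrix, survival, sample_type_of = NULL) {
  sids <- sample_ids(matrix)
  if (is.null(sample_type_of)) {
    sample_type_of <- stats::setNames(rep("primary", length(sids)), sids)
  }
  missing_types <- setdiff(sids, names(sample_type_of))
  if (length(missing_types))
    stop("sample type undefined for: ",
         paste(utils::head(missing_types, 5), collapse = ", "), call. = FALSE)
  keep <- sids[sample_type_of[sids] == "primary" & sids %in% survival$patient_id]
  if (length(keep)) {
    all_missing <- apply(is.na(matrix$values[, keep, drop = FALSE]), 2, all)
    if (nrow(matrix$values) == 0) all_missing <- rep(FALSE, length(keep))
    keep <- keep[!all_missing]
  }
  if (length(keep) == 0)
    stop("empty cohort: no primary samples with survival remain", call. = FALSE)
  m <- matrix[, keep]
  sv <- survival[match(keep, survival$patient_id), , drop = FALSE]
  rownames(sv) <- NULL
  class(sv) <- c("SurvivalTable", "data.frame")
  list(matrix = m, survival = sv, n_dropped = length(sids) - length(keep))
}

#' Printed-style categorical summary of a clinical variable
#'
#' Counts every category (missing values form their own `missing` category)
#' over all patients and reports percentages rounded half-up to one decimal,
#' matching the printed cohort-description style (e.g. 46.9% alive).
#'
#' @param table A [clinical_table()].
#' @param variable Name of a categorical variable.
#' @return `data.frame` with columns `category`, `count`, `percent`.
#' @export
summarize_clinical <- function(table, variable) {
  if (!variable %in% names(table$variables))
    stop("unknown clinical variable: ", variable, call. = FALSE)
  if (table$kinds[[variable]] != "categorical")
    stop("variable '", variable, "' is not categorical", call. = FALSE)
  raw <- table$variables[[variable]]
  v <- as.character(raw)
  v[is.na(v) | v == ""] <- "missing"
  total <- length(v)
  lv <- if (is.factor(raw)) union(levels(raw), unique(v)) else unique(v)
  counts <- table(factor(v, levels = lv))  # factor levels keep 0-count categories
  cats <- names(counts)
  ord <- order(match(cats, c(setdiff(cats, "missing"), "missing")))
  data.frame(category = cats[ord], count = as.integer(counts[ord]),
             percent = round_half_up(100 * as.integer(counts[ord]) / total, 1),
             stringsAsFactors = FALSE)
}

#' Align several platforms on their survival-covered samples
#'
#' @param matrices Named list of [omics_matrix()].
#' @param survival A [survival_table()].
#' @return List with `samples` (per platform, the samples that have
#'   survival), `shared` (per platform pair, the shared-sample set used by
#'   [overlap_partitions()]), and `counts` (per-platform sample counts).
#' @export
harmonize_samples <- function(matrices, survival) {
  if (length(matrices) < 1) stop("need at least one matrix", call. = FALSE)
  if (is.null(names(matrices))) names(matrices) <- paste0("platform", seq_along(matrices))
  samples <- lapply(matrices, function(m) intersect(sample_ids(m), survival$patient_id))
  shared <- list()
  nm <- names(matrices)
  if (length(nm) > 1) {
    for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm)) {
      key <- paste(nm[i], nm[j], sep = ":")
      shared[[key]] <- intersect(samples[[nm[i]]], samples[[nm[j]]])
    }
  }
  counts <- data.frame(platform = nm,
                       n_samples = vapply(samples, length, integer(1)),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(samples = samples, shared = shared, counts = counts)
}
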