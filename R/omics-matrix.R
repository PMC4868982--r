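#' Feature-by-sample omics matrix
#'
#' The basic data container of the pipeline: a numeric matrix with features
#' in rows and samples in columns, tagged with the molecular platform it came
#' from and the value domain that platform implies.  DNA methylation beta
#' values live on the unit interval, mRNA and miRNA expression are
#' non-negative, protein (RPPA) abundances are real-valued, and derived
#' pathway-activity scores are real-valued as well.
#'
#' @param values Numeric matrix (features x samples) with unique, non-empty
#'   row and column names.
#' @param platform One of `"methylation"`, `"protein"`, `"mirna"`, `"mrna"`,
#'   `"pathway"`.
#' @param value_domain Value-domain contract; defaults to the platform's
#'   natural domain (`methylation` -> `unit_interval`, `mrna`/`mirna` ->
#'   `nonnegative`, `protein`/`pathway` -> `real`).
#' @return An object of class `OmicsMatrix`.
#' @examples
#' m <- omics_matrix(matrix(runif(6), 2, 3,
#'                          dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))),
#'                   platform = "methylation")
#' dim(m)
#' @export
omics_matrix <- function(values, platform, value_domain = platform_domain(platform)) {
  platform <- match.arg(platform, c("methylation", "protein", "mirna", "mrna", "pathway"))
  value_domain <- match.arg(value_domain, c("unit_interval", "nonnegative", "real"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  fid <- rownames(values)
  sid <- colnames(values)
  if (nrow(values) > 0 && (is.null(fid) || anyNA(fid) || any(fid == "")))
    stop("feature ids (rownames) must be present and non-empty", call. = FALSE)
  if (ncol(values) > 0 && (is.null(sid) || anyNA(sid) || any(sid == "")))
    stop("sample ids (colnames) must be present and non-empty", call. = FALSE)
  if (anyDuplicated(fid)) stop("duplicate feature ids: ",
                               paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid)) stop("duplicate sample ids: ",
                               paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  viol <- domain_violations(values, value_domain)
  if (!is.null(viol))
    stop("value domain '", value_domain, "' violated at feature ", viol[1],
         ", sample ", viol[2], " (value ", viol[3], ")", call. = FALSE)
  structure(list(platform = platform, values = values, value_domain = value_domain),
            class = "OmicsMatrix")
}

#' @rdname omics_matrix
#' @export
platform_domain <- function(platform) {
  switch(platform,
         methylation = "unit_interval",
         mrna = ,
         mirna = "nonnegative",
         protein = ,
         pathway = "real",
         stop("unknown platform: ", platform, call. = FALSE))
}

# first violating (feature, sample, value) or NULL; NAs are permitted
domain_violations <- function(values, value_domain) {
  bad <- switch(value_domain,
                unit_interval = which(!is.na(values) & (values < 0 | values > 1)),
                nonnegative   = which(!is.na(values) & values < 0),
                real          = integer(0))
  if (length(bad) == 0) return(NULL)
  i <- arrayInd(bad[1], dim(values))
  c(rownames(values)[i[1]], colnames(values)[i[2]], format(values[bad[1]]))
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix [%s, %s]: %d features x %d samples\n",
              x$platform, x$value_domain, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
`[.OmicsMatrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  omics_matrix(v, x$platform, x$value_domain)
}

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Survival table constructor
#'
#' Per-patient right-censored overall survival: `event` is 0 for
#' alive/censored and 1 for death; `time_days` is strictly positive.
#'
#' @param patient_id Character vector of unique patient ids.
#' @param event Integer 0/1 event indicator.
#' @param time_days Positive follow-up or survival time in days.
#' @return A `data.frame` of class `SurvivalTable` with those three columns.
#' @export
survival_table <- function(patient_id, event, time_days) {
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id))
    stop("duplicate patient ids in survival table", call. = FALSE)
  if (length(event) != length(patient_id) || length(time_days) != length(patient_id))
    stop("patient_id, event, time_days must have equal length", call. = FALSE)
  if (length(event) && !all(event %in% c(0, 1)))
    stop("event must be 0 (alive/censored) or 1 (death)", call. = FALSE)
  if (length(time_days) && !all(is.finite(time_days) & time_days > 0))
    stop("time_days must be strictly positive", call. = FALSE)
  structure(data.frame(patient_id = patient_id, event = as.integer(event),
                       time_days = as.numeric(time_days), stringsAsFactors = FALSE),
            class = c("SurvivalTable", "data.frame"))
}

#' Clustering partition
#'
#' A clustering result: the algorithm that produced it, the number of
#' clusters k, a label in 1..k per sample, and the method-specific objective
#' value (total medoid cost for PAM, merge height for HC, best reconstruction
#' error for NMF).
#'
#' @param method `"PAM"`, `"HC"` or `"NMF"`.
#' @param k Number of clusters.
#' @param labels Named integer vector (names = sample ids) with values in 1..k.
#' @param quality Method-specific objective value.
#' @return An object of class `Partition`.
#' @export
partition <- function(method, k, labels, quality = NA_real_) {
  method <- match.arg(method, c("PAM", "HC", "NMF"))
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop("labels must be named by unique sample ids", call. = FALSE)
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (!all(labels %in% seq_len(k)))
    stop("labels must lie in 1..k", call. = FALSE)
  if (!all(seq_len(k) %in% labels))
    stop("every cluster 1..k must be non-empty", call. = FALSE)
  structure(list(method = method, k = as.integer(k), labels = labels,
                 quality = quality), class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat(sprintf("Partition: %s, k = %d, n = %d (sizes: %s)\n", x$method, x$k,
              length(x$labels), paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Clinical variable table
#'
#' Patient-level clinical variables with a declared kind per variable, used
#' by [clinical_association()]. Quantitative variables are tested across
#' subtypes by one-way ANOVA, categorical ones by the chi-square test.
#'
#' @param patient_id Unique patient ids.
#' @param variables Named list of vectors (one per variable), each the same
#'   length as `patient_id`; `NA` marks missing.
#' @param kinds Named character vector mapping each variable to
#'   `"quantitative"` or `"categorical"`.
#' @return An object of class `ClinicalTable`.
#' @export
clinical_table <- function(patient_id, variables, kinds) {
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id)) stop("duplicate patient ids", call. = FALSE)
  if (!all(names(variables) %in% names(kinds)))
    stop("every variable needs a declared kind", call. = FALSE)
  if (!all(kinds %in% c("quantitative", "categorical")))
    stop("kinds must be 'quantitative' or 'categorical'", call. = FALSE)
  for (v in names(variables))
    if (length(variables[[v]]) != length(patient_id))
      stop("variable '", v, "' length mismatch", call. = FALSE)
  structure(list(patient_id = patient_id, variables = variables,
                 kinds = kinds[names(variables)]), class = "ClinicalTable")
}
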