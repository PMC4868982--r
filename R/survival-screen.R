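#' Univariate Cox proportional-hazards fit for one feature
#'
#' Fits a one-covariate Cox model on the z-scored feature by maximizing the
#' partial likelihood (Breslow handling of ties) and reports the Wald test
#' p-value plus the score test statistic. Selection is scale-invariant, so
#' standardization only aids numerical stability. A zero-variance feature or
#' a fit that fails to converge is reported with `converged = FALSE` and is
#' never selected.
#'
#' @param feature Named numeric vector, one value per survival patient.
#' @param survival A [survival_table()].
#' @param alpha Selection threshold on the Wald p-value.
#' @return One-row `data.frame`: `beta`, `se`, `p_value`, `score_chi2`,
#'   `converged`, `selected`.
#' @export
cox_fit_single <- function(feature, survival, alpha = 0.05) {
  if (sum(survival$event) < 2)
    stop("degenerate input: need at least 2 events for Cox screening", call. = FALSE)
  x <- align_feature(feature, survival)
  y <- survival::Surv(survival$time_days, survival$event)
  cox_fit_vector(x, y, alpha)
}

align_feature <- function(feature, survival) {
  if (!is.null(names(feature))) {
    if (!all(survival$patient_id %in% names(feature)))
      stop("feature undefined for some survival patients", call. = FALSE)
    feature <- feature[survival$patient_id]
  } else if (length(feature) != nrow(survival)) {
    stop("feature length does not match survival table", call. = FALSE)
  }
  as.numeric(feature)
}

# core single-covariate fit shared by cox_fit_single and screen_features
cox_fit_vector <- function(x, y, alpha) {
  row <- data.frame(beta = NA_real_, se = NA_real_, p_value = NA_real_,
                    score_chi2 = NA_real_, converged = FALSE, selected = FALSE)
  sdx <- stats::sd(x)
  if (!is.finite(sdx) || sdx == 0) return(row)
  z <- matrix((x - mean(x)) / sdx, ncol = 1)
  ctrl <- survival::coxph.control()
  warned <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph.fit(z, y, strata = NULL, offset = NULL, init = 0,
                          control = ctrl, weights = rep(1, nrow(z)),
                          method = "breslow", rownames = NULL),
      warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") }),
    error = function(e) NULL)
  if (is.null(fit)) return(row)
  beta <- unname(fit$coefficients[1])
  se <- sqrt(fit$var[1, 1])
  if (warned || !is.finite(beta) || !is.finite(se) || se <= 0 ||
      fit$iter >= ctrl$iter.max) return(row)
  p <- stats::pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
  data.frame(beta = beta, se = se, p_value = p,
             score_chi2 = unname(fit$score), converged = TRUE,
             selected = p < alpha)
}

#' Cox screening of every feature of a matrix against survival
#'
#' Each feature is fit by [cox_fit_single()]; features with a Wald p-value
#' below `alpha` constitute the selected feature set used for clustering.
#' Selection uses raw p-values by default (`adjust = "none"`), matching the
#' plain p < 0.05 screening rule; Benjamini-Hochberg adjustment is available
#' via `adjust = "BH"`.
#'
#' Features with more than `max_missing` missing fraction are dropped before
#' screening; remaining missing values are imputed by the feature median.
#'
#' @param matrix An [omics_matrix()] whose samples match the survival table.
#' @param survival A [survival_table()] covering every matrix sample.
#' @param alpha Screening threshold.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param max_missing Maximum tolerated per-feature missing fraction.
#' @return List: `selected` ([omics_matrix()] of selected features, original
#'   order), `screen` (`data.frame` with one [cox_fit_single()] row per
#'   screened feature).
#' @export
screen_features <- function(matrix, survival, alpha = 0.05,
                            adjust = c("none", "BH"), max_missing = 0.2) {
  adjust <- match.arg(adjust)
  if (!setequal(sample_ids(matrix), survival$patient_id))
    stop("matrix and survival table cover different samples", call. = FALSE)
  if (sum(survival$event) < 2)
    stop("degenerate input: need at least 2 events for Cox screening", call. = FALSE)
  vals <- matrix$values[, survival$patient_id, drop = FALSE]
  miss_frac <- rowMeans(is.na(vals))
  dropped <- rownames(vals)[miss_frac > max_missing]
  vals <- vals[miss_frac <= max_missing, , drop = FALSE]
  if (anyNA(vals)) {
    for (i in which(rowSums(is.na(vals)) > 0)) {
      v <- vals[i, ]
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      vals[i, ] <- v
    }
  }
  y <- survival::Surv(survival$time_days, survival$event)
  rows <- vector("list", nrow(vals))
  for (i in seq_len(nrow(vals))) rows[[i]] <- cox_fit_vector(vals[i, ], y, alpha)
  screen <- do.call(rbind, rows)
  screen <- cbind(data.frame(feature_id = rownames(vals), stringsAsFactors = FALSE),
                  screen)
  if (adjust == "BH") {
    padj <- stats::p.adjust(screen$p_value, method = "BH")
    screen$p_adjusted <- padj
    screen$selected <- screen$converged & !is.na(padj) & padj < alpha
  }
  attr(screen, "dropped_features") <- dropped
  sel_ids <- screen$feature_id[screen$selected]
  if (length(sel_ids) == 0)
    stop("empty selection: no feature passed Cox screening at alpha = ", alpha,
         "; clustering cannot proceed", call. = FALSE)
  list(selected = matrix[sel_ids, ], screen = screen)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param survival A [survival_table()] with at least one record.
#' @return Object of class `KMCurve`: `time` (distinct event times),
#'   `surv` (non-increasing survival probabilities), `n_risk`,
#'   `median_survival` (smallest time with survival <= 0.5; `NA` if the
#'   curve never reaches 0.5).
#' @export
km_estimate <- function(survival) {
  if (nrow(survival) < 1) stop("need at least one survival record", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = survival)
  has_event <- fit$n.event > 0
  time <- fit$time[has_event]
  surv <- fit$surv[has_event]
  n_risk <- fit$n.risk[has_event]
  med <- if (any(surv <= 0.5)) time[which(surv <= 0.5)[1]] else NA_real_
  structure(list(time = time, surv = surv, n_risk = n_risk,
                 median_survival = med, n = nrow(survival)),
            class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
  cat(sprintf("KM curve: n = %d, %d event times, median survival = %s\n",
              x$n, length(x$time),
              if (is.na(x$median_survival)) "not reached" else x$median_survival))
  invisible(x)
}

#' k-sample log-rank test
#'
#' Standard log-rank comparison of k survival distributions: at each distinct
#' event time the observed minus expected events per group under the
#' hypergeometric model are pooled into a chi-square statistic with k-1
#' degrees of freedom.
#'
#' @param survival A [survival_table()].
#' @param labels Named integer vector patient -> cluster in 1..k.
#' @param k Number of clusters; defaults to `max(labels)`.
#' @return List: `chi2`, `df` (= k-1), `p_value`.
#' @export
logrank_test <- function(survival, labels, k = max(labels)) {
  if (k < 2) stop("log-rank test needs k >= 2 groups", call. = FALSE)
  lab <- if (!is.null(names(labels))) labels[survival$patient_id] else labels
  if (length(lab) != nrow(survival) || anyNA(lab))
    stop("labels must cover every survival patient", call. = FALSE)
  if (!all(seq_len(k) %in% lab))
    stop("every cluster 1..k must be non-empty", call. = FALSE)
  if (sum(survival$event) < 1)
    stop("log-rank test needs at least one event", call. = FALSE)
  sd <- survival::survdiff(
    survival::Surv(survival$time_days, survival$event) ~ factor(lab, levels = seq_len(k)))
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, df = k - 1,
       p_value = stats::pchisq(chi2, df = k - 1, lower.tail = FALSE))
}
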