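#' Complexity-penalized clustering score
#'
#' Scores a candidate subtyping model by the significance of its k-sample
#' log-rank test, discounted for model complexity: adding clusters tends to
#' improve survival separation mechanically while harming interpretability,
#' so each cluster beyond two costs `lambda` score units:
#'
#'   score = -log10(p) - lambda * (N - 2)
#'
#' The score is strictly decreasing in p for fixed N, and strictly
#' decreasing in N for fixed p whenever `lambda > 0`. A p-value of exactly 0
#' (numerical underflow) is clamped to the smallest positive double, with a
#' warning.
#'
#' @param p Log-rank p-value in (0, 1].
#' @param N Number of clusters (>= 2).
#' @param lambda Non-negative penalty weight per extra cluster (default 1).
#' @return The numeric score (vectorized over `p` and `N`).
#' @export
penalized_score <- function(p, N, lambda = 1) {
  if (any(N < 2)) stop("N must be >= 2", call. = FALSE)
  if (any(!is.na(p) & p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  if (any(!is.na(p) & p < 0)) stop("p must lie in (0, 1]", call. = FALSE)
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  if (any(!is.na(p) & p == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  -log10(p) - lambda * (N - 2)
}

#' Choose the optimal subtyping model from a sweep table
#'
#' Computes the penalized score for every (method, k) row with a defined
#' log-rank p-value and picks the argmax. Ties are broken by smaller N,
#' then by method order PAM < HC < NMF.
#'
#' @param sweep `data.frame` with columns `method`, `k`, `logrank_p`
#'   (as produced by [screen_k()]).
#' @param lambda Penalty weight, see [penalized_score()].
#' @return List: `method`, `k`, `score`, and `table` (the full sweep ranked
#'   by score with a `selected` flag).
#' @export
choose_model <- function(sweep, lambda = 1) {
  tab <- sweep
  tab$score <- NA_real_
  ok <- !is.na(tab$logrank_p)
  if (!any(ok)) stop("no candidate model has a defined log-rank p", call. = FALSE)
  tab$score[ok] <- penalized_score(tab$logrank_p[ok], tab$k[ok], lambda)
  method_rank <- match(tab$method, c("PAM", "HC", "NMF"))
  ord <- order(-tab$score, tab$k, method_rank, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$selected <- FALSE
  tab$selected[1] <- TRUE
  list(method = tab$method[1], k = tab$k[1], score = tab$score[1], table = tab)
}

#' Per-cluster sample counts and Kaplan-Meier median survival
#'
#' @param partition A [partition()].
#' @param survival A [survival_table()] covering the partitioned samples.
#' @return `data.frame`: `cluster`, `n`, `median_days` (`NA` when the KM
#'   curve never reaches 0.5).
#' @export
median_survival_per_cluster <- function(partition, survival) {
  labs <- partition$labels
  if (!all(names(labs) %in% survival$patient_id))
    stop("survival table does not cover every partitioned sample", call. = FALSE)
  sv <- survival[match(names(labs), survival$patient_id), , drop = FALSE]
  out <- lapply(seq_len(partition$k), function(cl) {
    idx <- labs == cl
    if (!any(idx)) stop("empty cluster ", cl, call. = FALSE)
    km <- km_estimate(sv[idx, , drop = FALSE])
    data.frame(cluster = cl, n = sum(idx), median_days = km$median_survival)
  })
  do.call(rbind, out)
}
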