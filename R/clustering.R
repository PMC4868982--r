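#' Sample distance matrix used by PAM and HC
#'
#' Euclidean distance on feature-standardized data by default (each feature
#' z-scored across samples), or correlation distance `1 - cor`.
#'
#' @param matrix An [omics_matrix()].
#' @param metric `"euclidean"` or `"correlation"`.
#' @param standardize Z-score features first (Euclidean only).
#' @return A `dist` object over samples.
#' @export
sample_dist <- function(matrix, metric = c("euclidean", "correlation"),
                        standardize = TRUE) {
  metric <- match.arg(metric)
  v <- matrix$values
  if (metric == "euclidean") {
    if (standardize) v <- standardize_rows(v)
    stats::dist(t(v))
  } else {
    stats::as.dist(1 - stats::cor(v))
  }
}

#' Partitioning Around Medoids clustering of samples
#'
#' k-medoids via the classical BUILD initialization followed by SWAP
#' refinement to a local optimum of the total within-cluster distance
#' (the reported `quality`). The procedure is deterministic; `seed` is
#' accepted for interface uniformity with [nmf_cluster()].
#'
#' @param matrix An [omics_matrix()] (samples are columns).
#' @param k Number of clusters, `2 <= k <= n`.
#' @param seed Unused by PAM itself (deterministic); kept for uniformity.
#' @param metric,standardize Passed to [sample_dist()].
#' @return A [partition()] with `method = "PAM"`.
#' @export
pam_cluster <- function(matrix, k, seed = NULL,
                        metric = c("euclidean", "correlation"),
                        standardize = TRUE) {
  n <- ncol(matrix$values)
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  sids <- sample_ids(matrix)
  if (k == n)  # every sample its own cluster, zero cost
    return(partition("PAM", k, stats::setNames(seq_len(n), sids), quality = 0))
  d <- sample_dist(matrix, metric, standardize)
  fit <- cluster::pam(d, k = k, diss = TRUE)
  partition("PAM", k, stats::setNames(fit$clustering, sids),
            quality = unname(fit$objective["swap"]) * n)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Builds the agglomerative tree under the chosen linkage and cuts it into
#' exactly k groups. Ward linkage uses the squared-distance implementation
#' (`ward.D2`). The reported `quality` is the merge height at the cut.
#'
#' @param matrix An [omics_matrix()].
#' @param k Number of clusters.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @param metric,standardize Passed to [sample_dist()].
#' @return A [partition()] with `method = "HC"`.
#' @export
hc_cluster <- function(matrix, k, linkage = c("average", "complete", "ward"),
                       metric = c("euclidean", "correlation"),
                       standardize = TRUE) {
  linkage <- match.arg(linkage)
  n <- ncol(matrix$values)
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  tree <- hc_tree(matrix, linkage, metric, standardize)
  labs <- stats::cutree(tree, k = k)
  quality <- if (k < n) tree$height[n - k] else 0
  partition("HC", k, labs, quality = quality)
}

hc_tree <- function(matrix, linkage, metric = "euclidean", standardize = TRUE) {
  d <- sample_dist(matrix, metric, standardize)
  stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
}

#' Shift a real-valued matrix into the non-negative orthant for NMF
#'
#' Unit-interval and non-negative inputs pass through unchanged; real-valued
#' inputs are shifted per feature by subtracting the feature minimum, so a
#' constant feature becomes all zeros (such rows carry no information and
#' are dropped by [nmf_cluster()]).
#'
#' @param matrix An [omics_matrix()].
#' @return A non-negative [omics_matrix()].
#' @export
nonneg_transform <- function(matrix) {
  if (matrix$value_domain %in% c("unit_interval", "nonnegative")) return(matrix)
  v <- matrix$values
  v <- v - apply(v, 1, min)
  omics_matrix(v, matrix$platform, value_domain = "nonnegative")
}

#' Non-negative matrix factorization clustering of samples
#'
#' Minimizes the Frobenius reconstruction error ||V - WH||^2 by the
#' classical multiplicative updates, restarted `n_restarts` times from
#' random uniform initializations scaled to the data mean; the restart with
#' the lowest final objective (among restarts whose dominant-component
#' sample assignment leaves no cluster empty) wins. Constant/all-zero rows
#' are dropped before factorization. The per-iteration objective trace of
#' the winning restart is returned and is non-increasing.
#'
#' @param matrix A non-negative [omics_matrix()] (apply [nonneg_transform()]
#'   first for real-valued platforms).
#' @param k Rank / number of clusters, `2 <= k < min(n_features, n_samples)`.
#' @param seed Integer seed; restart r uses seed + r - 1.
#' @param n_restarts Number of random restarts.
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Relative objective-decrease convergence tolerance (0 disables
#'   early stopping).
#' @return Object of class `NMFResult`: `W`, `H`, `objective_trace`,
#'   `partition` (a [partition()] with `method = "NMF"`, quality = final
#'   objective).
#' @export
nmf_cluster <- function(matrix, k, seed = 1L, n_restarts = 10L,
                        max_iter = 500L, tol = 1e-5) {
  v <- matrix$values
  if (anyNA(v)) stop("NMF input must be complete (impute first)", call. = FALSE)
  if (any(v < 0)) stop("NMF requires non-negative input; see nonneg_transform()",
                       call. = FALSE)
  keep <- apply(v, 1, function(r) max(r) > min(r))
  v <- v[keep, , drop = FALSE]
  n <- ncol(v); m <- nrow(v)
  if (k < 2 || k >= min(m, n))
    stop("need 2 <= k < min(n_features, n_samples) after dropping constant rows",
         call. = FALSE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    run <- nmf_run(v, k, seed = (as.integer(seed) + r - 1L) %% .Machine$integer.max,
                   max_iter = max_iter, tol = tol)
    labs <- apply(run$H, 2, which.max)
    run$valid <- all(seq_len(k) %in% labs)
    run$labels <- labs
    if (run$valid && (is.null(best) || run$objective < best$objective)) best <- run
  }
  if (is.null(best))
    stop("all NMF restarts produced an empty cluster at k = ", k, call. = FALSE)
  part <- partition("NMF", k, stats::setNames(best$labels, colnames(v)),
                    quality = best$objective)
  structure(list(W = best$W, H = best$H, objective_trace = best$trace,
                 partition = part), class = "NMFResult")
}

# one multiplicative-update run; eps guards zero denominators
nmf_run <- function(v, k, seed, max_iter, tol, eps = 1e-10) {
  set.seed(seed)
  m <- nrow(v); n <- ncol(v)
  a <- 2 * sqrt(mean(v) / k)  # E[WH] matches E[V] at init
  w <- matrix(stats::runif(m * k, 0, a), m, k)
  h <- matrix(stats::runif(k * n, 0, a), k, n)
  trace <- numeric(max_iter)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, v) / (crossprod(w) %*% h + eps))
    w <- w * (v %*% t(h)) / (w %*% tcrossprod(h) + eps)
    obj <- sum((v - w %*% h)^2)
    trace[it] <- obj
    if (tol > 0 && is.finite(prev) && (prev - obj) <= tol * prev) {
      trace <- trace[seq_len(it)]
      break
    }
    prev <- obj
  }
  list(W = w, H = h, objective = trace[length(trace)], trace = trace)
}

#' Cluster-number sweep over methods and k
#'
#' Runs each requested clustering algorithm for every k in `k_range` and
#' scores each candidate partition by the k-sample log-rank test against
#' survival. Failures (e.g. every NMF restart yielding an empty cluster)
#' are recorded with an undefined p-value and excluded from model selection
#' rather than aborting the sweep.
#'
#' @param matrix The screened [omics_matrix()] (selected features only).
#' @param survival A [survival_table()] aligned to the matrix samples.
#' @param methods Subset of `c("PAM", "HC", "NMF")`.
#' @param k_range Candidate cluster counts (default 2..9).
#' @param seed Seed forwarded to NMF restarts.
#' @param linkage HC linkage.
#' @param nmf_restarts,nmf_max_iter,nmf_tol NMF controls.
#' @return List: `sweep` (`data.frame` method, k, logrank_chi2, logrank_p,
#'   status), `partitions` (named list `"<method>_<k>"` of [partition()]).
#' @export
screen_k <- function(matrix, survival, methods = c("PAM", "HC", "NMF"),
                     k_range = 2:9, seed = 1L, linkage = "average",
                     nmf_restarts = 10L, nmf_max_iter = 500L, nmf_tol = 1e-5) {
  methods <- match.arg(methods, c("PAM", "HC", "NMF"), several.ok = TRUE)
  if (!setequal(sample_ids(matrix), survival$patient_id))
    stop("matrix and survival table cover different samples", call. = FALSE)
  n <- ncol(matrix$values)
  if (n < 2 * max(k_range))
    stop("need at least 2*max(k_range) samples for the sweep", call. = FALSE)
  d <- if (any(c("PAM", "HC") %in% methods)) sample_dist(matrix) else NULL
  tree <- if ("HC" %in% methods)
    stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  else NULL
  nn <- if ("NMF" %in% methods) nonneg_transform(matrix) else NULL
  sids <- sample_ids(matrix)

  rows <- list(); partitions <- list()
  for (method in methods) for (k in k_range) {
    part <- tryCatch(switch(method,
      PAM = {
        fit <- cluster::pam(d, k = k, diss = TRUE)
        partition("PAM", k, stats::setNames(fit$clustering, sids),
                  quality = unname(fit$objective["swap"]) * n)
      },
      HC = partition("HC", k, stats::cutree(tree, k = k),
                     quality = tree$height[n - k]),
      NMF = nmf_cluster(nn, k, seed = seed, n_restarts = nmf_restarts,
                        max_iter = nmf_max_iter, tol = nmf_tol)$partition),
      error = function(e) e)
    if (inherits(part, "error")) {
      rows[[paste(method, k)]] <- data.frame(
        method = method, k = k, logrank_chi2 = NA_real_, logrank_p = NA_real_,
        status = conditionMessage(part), stringsAsFactors = FALSE)
      next
    }
    lr <- logrank_test(survival, part$labels, k)
    rows[[paste(method, k)]] <- data.frame(
      method = method, k = k, logrank_chi2 = lr$chi2, logrank_p = lr$p_value,
      status = "ok", stringsAsFactors = FALSE)
    partitions[[paste0(method, "_", k)]] <- part
  }
  sweep <- do.call(rbind, rows)
  rownames(sweep) <- NULL
  list(sweep = sweep, partitions = partitions)
}
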