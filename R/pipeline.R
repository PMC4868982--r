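#' Run the full subtyping workflow for one platform
#'
#' Reproduces the per-platform workflow: cohort filtering, an optional
#' per-platform value transform, univariate Cox screening at `alpha`,
#' the (method x k) clustering sweep scored by the k-sample log-rank test,
#' complexity-penalized model selection, per-cluster median survival, and
#' (for expression-like platforms) subtype-specific fold-change gene sets
#' computed on the linear scale.
#'
#' The default transform is log2(x + 1) for the count-like platforms
#' (`mrna`, `mirna`) and the identity otherwise; screening and clustering
#' see transformed values, characterization sees the raw scale.
#'
#' @param matrix An [omics_matrix()].
#' @param survival A [survival_table()].
#' @param sample_types Optional sample-type map, see [filter_cohort()].
#' @param alpha Cox screening threshold.
#' @param methods Clustering methods for the sweep.
#' @param k_range Candidate cluster numbers (default 2..9).
#' @param lambda Model-selection penalty, see [penalized_score()].
#' @param seed Seed for the NMF restarts.
#' @param transform `"default"`, `"none"`, or `"log2"` (force log2(x+1)).
#' @param characterize Compute fold-change gene sets and heatmap row order
#'   (default: only for the mrna platform).
#' @param out_dir Optional directory; when given, every stage's output is
#'   written as TSV and listed in the returned `manifest` with md5 hashes.
#' @param ... Further arguments to [screen_k()] (HC linkage, NMF controls).
#' @return Object of class `PlatformResult`: `platform`, `n_samples`,
#'   `screen`, `sweep`, `model` (chosen method/k/score + ranked table),
#'   `partition`, `medians`, `gene_sets`, `row_order`, `manifest`.
#' @export
run_platform <- function(matrix, survival, sample_types = NULL,
                         alpha = 0.05, methods = c("PAM", "HC", "NMF"),
                         k_range = 2:9, lambda = 1, seed = 1L,
                         transform = c("default", "none", "log2"),
                         characterize = matrix$platform == "mrna",
                         out_dir = NULL, ...) {
  transform <- match.arg(transform)
  flt <- filter_cohort(matrix, survival, sample_types)
  raw <- flt$matrix
  work <- apply_transform(raw, transform)
  scr <- screen_features(work, flt$survival, alpha = alpha)
  sw <- screen_k(scr$selected, flt$survival, methods = methods,
                 k_range = k_range, seed = seed, ...)
  model <- choose_model(sw$sweep, lambda = lambda)
  part <- sw$partitions[[paste0(model$method, "_", model$k)]]
  medians <- median_survival_per_cluster(part, flt$survival)
  gene_sets <- NULL; row_order <- NULL
  if (isTRUE(characterize)) {
    raw_sel <- raw[scr$screen$feature_id[scr$screen$selected], ]
    gene_sets <- fold_change_sets(raw_sel, part)
    row_order <- order_rows_for_heatmap(raw_sel, part, gene_sets)
  }
  res <- structure(list(platform = matrix$platform,
                        n_samples = ncol(raw$values),
                        screen = scr$screen, sweep = sw$sweep, model = model,
                        partition = part, medians = medians,
                        gene_sets = gene_sets, row_order = row_order,
                        seed = seed, manifest = NULL),
                   class = "PlatformResult")
  if (!is.null(out_dir)) res$manifest <- write_platform_result(res, out_dir)
  res
}

apply_transform <- function(matrix, transform) {
  use_log <- switch(transform,
                    none = FALSE,
                    log2 = TRUE,
                    default = matrix$platform %in% c("mrna", "mirna"))
  if (!use_log) return(matrix)
  omics_matrix(log2(matrix$values + 1), matrix$platform,
               value_domain = "nonnegative")
}

#' @export
print.PlatformResult <- function(x, ...) {
  cat(sprintf("Platform '%s': %d samples, %d/%d features selected\n",
              x$platform, x$n_samples, sum(x$screen$selected), nrow(x$screen)))
  cat(sprintf("Selected model: %s with %d clusters (score %.3f, log-rank p %.3g)\n",
              x$model$method, x$model$k, x$model$score,
              x$model$table$logrank_p[1]))
  print(x$medians)
  invisible(x)
}

write_platform_result <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- res$platform
  files <- character(0)
  wt <- function(df, name) {
    path <- file.path(out_dir, paste0(p, "_", name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  wt(res$screen, "screen")
  wt(res$sweep, "sweep")
  wt(cbind(res$model$table), "model")
  wt(data.frame(sample_id = names(res$partition$labels),
                cluster = unname(res$partition$labels)), "partition")
  wt(res$medians, "medians")
  if (!is.null(res$gene_sets)) wt(res$gene_sets$counts, "gene_set_counts")
  data.frame(path = basename(files), md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-platform integration of subtype partitions
#'
#' Tests every platform's partition against a reference partition (default:
#' the mRNA platform, if present) on their shared samples via
#' [overlap_partitions()], star-coded at 0.05/0.01/0.001. Pairs with no
#' shared samples are skipped with a note.
#'
#' @param partitions Named list of [partition()] objects (>= 2).
#' @param reference Name of the reference platform; default `"mrna"` if
#'   present, else the first.
#' @return List: `reference`, `overlaps` (named list of `OverlapResult`),
#'   `skipped` (named character of skip reasons).
#' @export
run_integration <- function(partitions, reference = NULL) {
  if (length(partitions) < 2)
    stop("integration needs at least 2 partitions", call. = FALSE)
  if (is.null(names(partitions)))
    stop("partitions must be a named list", call. = FALSE)
  reference <- reference %||%
    (if ("mrna" %in% names(partitions)) "mrna" else names(partitions)[1])
  if (!reference %in% names(partitions))
    stop("reference partition '", reference, "' not found", call. = FALSE)
  overlaps <- list(); skipped <- character(0)
  for (p in setdiff(names(partitions), reference)) {
    res <- tryCatch(overlap_partitions(partitions[[p]], partitions[[reference]]),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) skipped[p] <- res else overlaps[[p]] <- res
  }
  list(reference = reference, overlaps = overlaps, skipped = skipped)
}

#' Run the pipeline on every platform of a synthetic cohort
#'
#' Convenience driver for simulated data: [run_platform()] per platform
#' followed by [run_integration()] of all resulting partitions.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param platforms Platforms to run (default: all in the cohort).
#' @param reference Reference platform for integration.
#' @param ... Passed to [run_platform()].
#' @return List: `platforms` (named list of `PlatformResult`), `integration`
#'   (`NULL` if fewer than 2 platforms succeeded), `failed` (named character
#'   of per-platform failure messages).
#' @export
run_cohort <- function(cohort, platforms = names(cohort$matrices),
                       reference = NULL, ...) {
  results <- list(); failed <- character(0)
  for (p in platforms) {
    res <- tryCatch(run_platform(cohort$matrices[[p]], cohort$survival,
                                 sample_types = cohort$sample_types, ...),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) failed[p] <- res else results[[p]] <- res
  }
  integration <- NULL
  if (length(results) >= 2)
    integration <- run_integration(lapply(results, function(r) r$partition),
                                   reference = reference)
  list(platforms = results, integration = integration, failed = failed)
}
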