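#' Signed, weighted pathway topology
#'
#' Gene membership plus directed regulatory edges with signed weights
#' (+1 activation, -1 inhibition, or any real weight), the inputs of the
#' SPIA-style perturbation propagation in [pathway_tA()]. A pathway with no
#' edges is valid (its accumulated perturbation is always zero).
#'
#' @param pathway_id Identifier.
#' @param edges `data.frame` with columns `source`, `target`, `beta`
#'   (may have zero rows).
#' @param genes Optional gene ids beyond the edge endpoints.
#' @return Object of class `PathwayTopology` with `genes`, `edges`, and
#'   `n_downstream` (outgoing edge count per gene).
#' @export
pathway_topology <- function(pathway_id, edges = NULL, genes = NULL) {
  if (is.null(edges))
    edges <- data.frame(source = character(0), target = character(0),
                        beta = numeric(0), stringsAsFactors = FALSE)
  need <- c("source", "target", "beta")
  if (!all(need %in% names(edges)))
    stop("edges need columns source, target, beta", call. = FALSE)
  all_genes <- unique(c(genes, edges$source, edges$target))
  if (length(all_genes) == 0)
    stop("pathway '", pathway_id, "' has no genes", call. = FALSE)
  ndown <- stats::setNames(integer(length(all_genes)), all_genes)
  if (nrow(edges)) {
    tb <- table(edges$source)
    ndown[names(tb)] <- as.integer(tb)
  }
  structure(list(pathway_id = pathway_id, genes = all_genes,
                 edges = edges, n_downstream = ndown),
            class = "PathwayTopology")
}

#' Read pathway topologies from an edge-list TSV
#'
#' Edge TSV columns: `pathway_id`, `source_gene`, `target_gene`, `beta`.
#' An optional membership TSV (`pathway_id`, `gene`) adds edge-free genes
#' or entirely edge-free pathways.
#'
#' @param path Edge-list TSV.
#' @param membership_path Optional membership TSV.
#' @return Named list of [pathway_topology()] objects.
#' @export
read_topologies <- function(path, membership_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway_id", "source_gene", "target_gene", "beta")
  if (!all(need %in% names(df)))
    stop("topology TSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  members <- NULL
  if (!is.null(membership_path))
    members <- utils::read.delim(membership_path, stringsAsFactors = FALSE)
  ids <- unique(c(df$pathway_id, members$pathway_id))
  out <- lapply(ids, function(pid) {
    e <- df[df$pathway_id == pid, , drop = FALSE]
    pathway_topology(pid,
                     edges = data.frame(source = e$source_gene,
                                        target = e$target_gene,
                                        beta = as.numeric(e$beta),
                                        stringsAsFactors = FALSE),
                     genes = members$gene[members$pathway_id == pid])
  })
  stats::setNames(out, ids)
}

#' Per-sample log fold change against the cohort mean
#'
#' logFC(g, s) = log2((x(g,s) + eps) / (mean over samples of x(g,.) + eps)).
#' The pseudocount guards all-zero genes; a gene constant across samples has
#' logFC identically zero. Doubling every expression value leaves the result
#' unchanged only approximately when eps > 0 (exactly in the eps -> 0 limit).
#'
#' @param matrix A non-negative expression [omics_matrix()].
#' @param eps Pseudocount added to numerator and cohort mean (default 1).
#' @return Plain numeric matrix of logFC values, same dimnames.
#' @export
compute_logfc <- function(matrix, eps = 1) {
  v <- matrix$values
  if (any(v < 0, na.rm = TRUE)) stop("expression must be non-negative", call. = FALSE)
  log2((v + eps) / (rowMeans(v) + eps))
}

# 1'((I-M)^{-1} - I): tA is this linear functional applied to Delta E.
# M[target, source] = beta / n_downstream(source). NULL when near-singular.
pathway_weights <- function(topology, rcond_tol = 1e-12) {
  g <- topology$genes
  n <- length(g)
  if (nrow(topology$edges) == 0) return(stats::setNames(numeric(n), g))
  m <- matrix(0, n, n, dimnames = list(g, g))
  e <- topology$edges
  for (i in seq_len(nrow(e)))
    m[e$target[i], e$source[i]] <- m[e$target[i], e$source[i]] +
      e$beta[i] / topology$n_downstream[[e$source[i]]]
  a <- diag(n) - m
  if (rcond(a) < rcond_tol) return(NULL)
  w <- solve(t(a), rep(1, n))
  stats::setNames(w - 1, g)
}

#' SPIA-style net accumulated perturbation of one pathway
#'
#' Solves the linear perturbation system
#' PF(g) = DeltaE(g) + sum over upstream genes u of beta(u->g) * PF(u) /
#' n_downstream(u), then accumulates Acc(g) = PF(g) - DeltaE(g) and returns
#' tA = sum of Acc over the pathway genes. A pathway with no edges has
#' tA = 0; a topology whose system is (near-)singular — e.g. a pure
#' feedback cycle with unit weights — is unavailable and yields `NA`.
#'
#' @param delta_e Named gene-level log fold changes; pathway genes missing
#'   from it are taken as 0.
#' @param topology A [pathway_topology()].
#' @param rcond_tol Reciprocal-condition-number threshold below which the
#'   system is declared singular.
#' @return The scalar tA, or `NA` if the pathway is unavailable.
#' @export
pathway_tA <- function(delta_e, topology, rcond_tol = 1e-12) {
  w <- pathway_weights(topology, rcond_tol)
  if (is.null(w)) return(NA_real_)
  de <- stats::setNames(numeric(length(topology$genes)), topology$genes)
  hit <- intersect(names(delta_e), topology$genes)
  de[hit] <- delta_e[hit]
  sum(w * de)
}

#' Pathway-activity matrix: tA per pathway per sample
#'
#' Converts an expression matrix into per-sample pathway-activity features:
#' gene-level logFC against the cohort mean ([compute_logfc()]), then the
#' net accumulated perturbation tA of every pathway for every sample.
#' Pathway genes absent from the expression matrix contribute DeltaE = 0
#' (the unresolved fraction per pathway is recorded); pathways whose
#' propagation system is singular are dropped and flagged unavailable.
#' The result is an `OmicsMatrix` of platform `"pathway"` and can be fed to
#' [screen_features()] and the clustering sweep exactly like a measured
#' platform.
#'
#' @param expression A non-negative expression [omics_matrix()].
#' @param topologies List of [pathway_topology()] objects.
#' @param eps logFC pseudocount, see [compute_logfc()].
#' @param rcond_tol Singularity threshold, see [pathway_tA()].
#' @return An [omics_matrix()] (pathways x samples) with attributes
#'   `availability` (named logical over all input pathways) and
#'   `unresolved_fraction` (fraction of pathway genes not measured).
#' @export
activity_matrix <- function(expression, topologies, eps = 1, rcond_tol = 1e-12) {
  if (length(topologies) == 0) stop("no pathway topologies given", call. = FALSE)
  ids <- vapply(topologies, function(tp) tp$pathway_id, character(1))
  lfc <- compute_logfc(expression, eps = eps)
  avail <- stats::setNames(logical(length(topologies)), ids)
  unresolved <- stats::setNames(numeric(length(topologies)), ids)
  rows <- list()
  for (i in seq_along(topologies)) {
    tp <- topologies[[i]]
    w <- pathway_weights(tp, rcond_tol)
    if (is.null(w)) next
    avail[i] <- TRUE
    hit <- intersect(tp$genes, rownames(lfc))
    unresolved[i] <- 1 - length(hit) / length(tp$genes)
    rows[[tp$pathway_id]] <- if (length(hit))
      as.numeric(w[hit] %*% lfc[hit, , drop = FALSE])
    else rep(0, ncol(lfc))
  }
  if (!any(avail))
    stop("all pathways unavailable (singular propagation systems)", call. = FALSE)
  vals <- do.call(rbind, rows)
  dimnames(vals) <- list(names(rows), colnames(lfc))
  out <- omics_matrix(vals, platform = "pathway")
  attr(out, "availability") <- avail
  attr(out, "unresolved_fraction") <- unresolved
  out
}
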