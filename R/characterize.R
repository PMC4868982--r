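#' Subtype-specific up- and down-regulated feature sets
#'
#' For every cluster c and feature g, the one-vs-rest fold-change ratio is
#' computed on the linear expression scale:
#' ratio(g, c) = (mean in c + eps) / (mean in all other clusters + eps).
#' Features with ratio >= `up` are c's up-regulated set, ratio <= `down` the
#' down-regulated set (defaults 2-fold / 0.5-fold).
#'
#' @param matrix An [omics_matrix()] on the linear scale.
#' @param partition A [partition()] over the matrix samples.
#' @param up,down Ratio thresholds.
#' @param epsilon Pseudocount; defaults to the smallest positive matrix
#'   value (1 if all values are zero), guarding division by a zero mean.
#' @return Object of class `SubtypeGeneSets`: `sets` (per cluster, `up` and
#'   `down` feature id vectors), `ratios` (features x clusters), `counts`
#'   (`data.frame` cluster, n_up, n_down), `up`, `down`, `epsilon`.
#' @export
fold_change_sets <- function(matrix, partition, up = 2, down = 0.5,
                             epsilon = NULL) {
  if (partition$k < 2)
    stop("fold-change sets need at least 2 clusters (no 'rest' set)", call. = FALSE)
  labs <- partition$labels[sample_ids(matrix)]
  if (anyNA(labs)) stop("partition does not cover every matrix sample", call. = FALSE)
  v <- matrix$values
  if (is.null(epsilon)) {
    pos <- v[!is.na(v) & v > 0]
    epsilon <- if (length(pos)) min(pos) else 1
  }
  k <- partition$k
  ratios <- base::matrix(NA_real_, nrow(v), k,
                         dimnames = list(rownames(v), paste0("C", seq_len(k))))
  for (cl in seq_len(k)) {
    inc <- labs == cl
    ratios[, cl] <- (rowMeans(v[, inc, drop = FALSE], na.rm = TRUE) + epsilon) /
      (rowMeans(v[, !inc, drop = FALSE], na.rm = TRUE) + epsilon)
  }
  sets <- lapply(seq_len(k), function(cl)
    list(up = rownames(v)[ratios[, cl] >= up],
         down = rownames(v)[ratios[, cl] <= down]))
  counts <- data.frame(cluster = seq_len(k),
                       n_up = vapply(sets, function(s) length(s$up), integer(1)),
                       n_down = vapply(sets, function(s) length(s$down), integer(1)))
  structure(list(sets = sets, ratios = ratios, counts = counts,
                 up = up, down = down, epsilon = epsilon),
            class = "SubtypeGeneSets")
}

#' Heatmap row order: features grouped by the cluster they mark
#'
#' Each feature is assigned to the cluster in which it is up-regulated
#' (highest ratio wins when up in several); blocks follow cluster order and
#' are sorted within by descending ratio. Features up-regulated in no
#' cluster are appended last in their original order.
#'
#' @param matrix An [omics_matrix()].
#' @param partition A [partition()].
#' @param sets A [fold_change_sets()] result for the same inputs.
#' @return List: `order` (feature ids), `block` (named cluster index per
#'   feature, `NA` for the unassigned tail).
#' @export
order_rows_for_heatmap <- function(matrix, partition, sets) {
  fids <- feature_ids(matrix)
  ratios <- sets$ratios[fids, , drop = FALSE]
  is_up <- ratios >= sets$up
  assigned <- rep(NA_integer_, length(fids))
  for (i in seq_along(fids)) {
    ups <- which(is_up[i, ])
    if (length(ups))
      assigned[i] <- ups[which.max(ratios[i, ups])]
  }
  ordered <- character(0)
  for (cl in seq_len(partition$k)) {
    in_block <- which(assigned == cl)
    ordered <- c(ordered, fids[in_block[order(-ratios[in_block, cl])]])
  }
  tail_ids <- fids[is.na(assigned)]
  list(order = c(ordered, tail_ids),
       block = stats::setNames(assigned, fids))
}

#' Mean expression of marker features per cluster
#'
#' @param matrix An [omics_matrix()].
#' @param partition A [partition()] over the matrix samples.
#' @param genes Feature ids to profile; unknown ids are an error.
#' @return Numeric matrix genes x clusters of per-cluster means.
#' @export
marker_profile <- function(matrix, partition, genes) {
  unknown <- setdiff(genes, feature_ids(matrix))
  if (length(unknown))
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  labs <- partition$labels[sample_ids(matrix)]
  out <- sapply(seq_len(partition$k), function(cl)
    rowMeans(matrix$values[genes, labs == cl, drop = FALSE], na.rm = TRUE))
  out <- base::matrix(out, nrow = length(genes),
                      dimnames = list(genes, paste0("C", seq_len(partition$k))))
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: term, description, then the member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of gene id vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric upper-tail p per annotation term, against a
#' fixed gene universe; terms with no overlap with the universe are skipped.
#' Significance is called at raw p < alpha (Benjamini-Hochberg optional).
#'
#' @param genes Query gene set (must be a subset of `universe`).
#' @param universe Background gene ids.
#' @param annotation Named list of gene sets (e.g. from [read_gmt()]).
#' @param alpha Significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame`: `term`, `term_size`, `overlap`, `p_value`,
#'   `significant`.
#' @export
enrich_gene_set <- function(genes, universe, annotation, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  genes <- unique(genes)
  if (!all(genes %in% universe))
    stop("query genes must be a subset of the universe", call. = FALSE)
  rows <- lapply(names(annotation), function(term) {
    in_univ <- intersect(annotation[[term]], universe)
    if (length(in_univ) == 0) return(NULL)
    ov <- length(intersect(genes, in_univ))
    p <- stats::phyper(ov - 1, length(in_univ),
                       length(universe) - length(in_univ),
                       length(genes), lower.tail = FALSE)
    data.frame(term = term, term_size = length(in_univ), overlap = ov,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), term_size = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      significant = logical(0)))
  p_use <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p_use < alpha
  rownames(out) <- NULL
  out
}

#' Overlap test between two partitions on their shared samples
#'
#' Overall chi-square test of independence on the k_A x k_B contingency
#' table, plus a per-pair test for every cluster pair (a, b): the table is
#' collapsed to 2x2 (in a vs not, in b vs not) and tested by the chi-square
#' without continuity correction. Stars follow the conventional thresholds
#' (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @param part_a,part_b [partition()] objects; the test runs on their shared
#'   samples (at least 2 clusters of each must be present there).
#' @return Object of class `OverlapResult`: `contingency`, `pair_p`,
#'   `stars`, `chi2`, `df`, `p_value`, `n_shared`.
#' @export
overlap_partitions <- function(part_a, part_b) {
  shared <- intersect(names(part_a$labels), names(part_b$labels))
  if (length(shared) == 0) stop("no shared samples between partitions", call. = FALSE)
  la <- factor(part_a$labels[shared], levels = seq_len(part_a$k))
  lb <- factor(part_b$labels[shared], levels = seq_len(part_b$k))
  if (length(unique(la)) < 2 || length(unique(lb)) < 2)
    stop("need >= 2 clusters per side among shared samples", call. = FALSE)
  tab <- table(a = la, b = lb)
  overall <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- length(shared)
  pair_p <- base::matrix(NA_real_, part_a$k, part_b$k,
                         dimnames = list(paste0("A", seq_len(part_a$k)),
                                         paste0("B", seq_len(part_b$k))))
  for (i in seq_len(part_a$k)) for (j in seq_len(part_b$k)) {
    a <- tab[i, j]
    b <- sum(tab[i, ]) - a
    c <- sum(tab[, j]) - a
    d <- n - a - b - c
    denom <- as.numeric(a + b) * (c + d) * (a + c) * (b + d)
    if (denom == 0) next  # empty margin: pair untestable
    chi <- n * (as.numeric(a) * d - as.numeric(b) * c)^2 / denom
    pair_p[i, j] <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }
  stars <- base::matrix(p_stars(pair_p), nrow(pair_p), ncol(pair_p),
                        dimnames = dimnames(pair_p))
  structure(list(contingency = tab, pair_p = pair_p, stars = stars,
                 chi2 = unname(overall$statistic), df = unname(overall$parameter),
                 p_value = unname(overall$p.value), n_shared = n),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("Partition overlap on %d shared samples: chi2 = %.3f (df %d), p = %.3g\n",
              x$n_shared, x$chi2, x$df, x$p_value))
  print(x$stars)
  invisible(x)
}

#' Association of clinical variables with a subtype partition
#'
#' Quantitative variables are tested by one-way ANOVA across clusters
#' (missing values dropped per variable); categorical variables by the
#' chi-square test of independence on the cluster x category table. A
#' variable with a single observed level is skipped with a note; tables
#' where more than 20% of expected counts fall below 5 are flagged
#' `low-count` but still reported.
#'
#' @param clinical A [clinical_table()].
#' @param partition A [partition()]; patients are matched by id.
#' @return `data.frame`: `variable`, `test`, `statistic`, `p_value`,
#'   `stars`, `note`.
#' @export
clinical_association <- function(clinical, partition) {
  shared <- intersect(clinical$patient_id, names(partition$labels))
  if (length(shared) == 0) stop("no patients shared with the partition", call. = FALSE)
  cl <- factor(partition$labels[shared], levels = seq_len(partition$k))
  idx <- match(shared, clinical$patient_id)
  rows <- lapply(names(clinical$variables), function(v) {
    x <- clinical$variables[[v]][idx]
    kind <- clinical$kinds[[v]]
    row <- data.frame(variable = v, test = NA_character_, statistic = NA_real_,
                      p_value = NA_real_, stars = NA_character_, note = "",
                      stringsAsFactors = FALSE)
    keep <- !is.na(x)
    if (kind == "quantitative") {
      g <- droplevels(cl[keep])
      if (nlevels(g) < 2 || sum(keep) <= nlevels(g)) {
        row$test <- "anova"; row$note <- "skipped: fewer than 2 informative groups"
        return(row)
      }
      an <- stats::anova(stats::lm(as.numeric(x[keep]) ~ g))
      row$test <- "anova"
      row$statistic <- an$`F value`[1]
      row$p_value <- an$`Pr(>F)`[1]
    } else {
      xv <- factor(x[keep])
      if (nlevels(droplevels(xv)) < 2) {
        row$test <- "chi-square"; row$note <- "skipped: single observed level"
        return(row)
      }
      tab <- table(droplevels(cl[keep]), droplevels(xv))
      if (nrow(tab) < 2) {
        row$test <- "chi-square"; row$note <- "skipped: fewer than 2 informative groups"
        return(row)
      }
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      row$test <- "chi-square"
      row$statistic <- unname(ct$statistic)
      row$p_value <- unname(ct$p.value)
      if (mean(ct$expected < 5) > 0.2) row$note <- "low-count"
    }
    row$stars <- p_stars(row$p_value)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
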