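# Shared fixtures and independent oracles, all built in code.

make_mat <- function(values, platform = "protein", features = NULL, samples = NULL) {
  features <- features %||% sprintf("f%02d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  omics_matrix(values, platform)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_surv <- function(time, event, ids = sprintf("s%02d", seq_along(time))) {
  survival_table(ids, event, time)
}

# small planted two-group cohort for clustering tests
small_cohort <- function(seed = 1, n = 40, n_feat = 30, effect = 4, k = 2) {
  set.seed(seed)
  labels <- rep_len(seq_len(k), n)
  v <- matrix(rnorm(n_feat * n), n_feat, n)
  for (f in seq_len(n_feat)) {
    cl <- (f - 1) %% k + 1
    v[f, labels == cl] <- v[f, labels == cl] + effect
  }
  m <- make_mat(v, "protein")
  list(matrix = m, labels = stats::setNames(labels, colnames(m$values)))
}

random_dag_topology <- function(seed, n_genes = 6, p_edge = 0.4) {
  set.seed(seed)
  g <- LETTERS[seq_len(n_genes)]
  edges <- NULL
  for (i in seq_len(n_genes - 1)) for (j in (i + 1):n_genes)
    if (runif(1) < p_edge)
      edges <- rbind(edges, data.frame(source = g[i], target = g[j],
                                       beta = sample(c(-1, 1), 1)))
  if (is.null(edges)) edges <- data.frame(source = g[1], target = g[2], beta = 1)
  pathway_topology(paste0("dag", seed), edges, genes = g)
}

# --- independent oracles -----------------------------------------------------

# exhaustive k-medoids: best total distance over all medoid subsets
brute_force_pam_cost <- function(d, k) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(dm[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# naive O(n^3) average-linkage agglomeration; returns labels at cut k
naive_average_linkage <- function(d, k) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      dd <- mean(dm[groups[[i]], groups[[j]]])
      if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  labs <- integer(n)
  for (g in seq_along(groups)) labs[groups[[g]]] <- g
  labs
}

# direct O-E log-rank statistic for k groups (pooled over event times)
naive_logrank_chi2 <- function(time, event, group, k = max(group)) {
  times <- sort(unique(time[event == 1]))
  o_minus_e <- numeric(k)
  v <- matrix(0, k, k)
  for (t in times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    for (g in seq_len(k)) {
      n_g <- sum(at_risk & group == g)
      d_g <- sum(event == 1 & time == t & group == g)
      o_minus_e[g] <- o_minus_e[g] + d_g - d_t * n_g / n_t
    }
    if (n_t > 1) {
      for (g in seq_len(k)) for (h in seq_len(k)) {
        n_g <- sum(at_risk & group == g); n_h <- sum(at_risk & group == h)
        v[g, h] <- v[g, h] + d_t * (n_t - d_t) / (n_t - 1) *
          (n_g / n_t * ((g == h) - n_h / n_t))
      }
    }
  }
  drop(t(o_minus_e[-k]) %*% solve(v[-k, -k]) %*% o_minus_e[-k])
}

# brute-force SPIA propagation: dense solve of PF = dE + M PF, then sum(PF - dE)
naive_tA <- function(delta_e, topology) {
  g <- topology$genes
  n <- length(g)
  m <- matrix(0, n, n, dimnames = list(g, g))
  e <- topology$edges
  if (nrow(e)) for (i in seq_len(nrow(e)))
    m[e$target[i], e$source[i]] <- m[e$target[i], e$source[i]] +
      e$beta[i] / topology$n_downstream[[e$source[i]]]
  de <- stats::setNames(numeric(n), g)
  de[intersect(names(delta_e), g)] <- delta_e[intersect(names(delta_e), g)]
  pf <- solve(diag(n) - m, de)
  sum(pf - de)
}

# forward propagation in topological order (acyclic topologies only)
forward_prop_tA <- function(delta_e, topology) {
  g <- topology$genes
  de <- stats::setNames(numeric(length(g)), g)
  de[intersect(names(delta_e), g)] <- delta_e[intersect(names(delta_e), g)]
  e <- topology$edges
  pf <- de
  remaining <- g
  resolved <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(x)
      all(e$source[e$target == x] %in% resolved), logical(1))]
    stopifnot(length(ready) > 0)  # would loop forever on a cyclic input
    for (x in ready) {
      inc <- e[e$target == x, , drop = FALSE]
      pf[x] <- de[x] + sum(inc$beta * pf[inc$source] /
                             topology$n_downstream[inc$source])
    }
    resolved <- c(resolved, ready)
    remaining <- setdiff(remaining, ready)
  }
  sum(pf - de)
}

# fraction of clusters in part_a whose best-overlap partner in part_b is starred
starred_diagonal_count <- function(part_a, part_b) {
  ov <- overlap_partitions(part_a, part_b)
  hits <- 0
  for (i in seq_len(nrow(ov$contingency))) {
    j <- which.max(ov$contingency[i, ])
    if (!is.na(ov$pair_p[i, j]) && ov$pair_p[i, j] < 0.05) hits <- hits + 1
  }
  hits
}
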