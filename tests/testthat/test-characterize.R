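two_cluster_fixture <- function() {
  # 6 samples, clusters {1,2,3} and {4,5,6}
  v <- rbind(up_gene = c(10, 10, 10, 4, 4, 4),
             flat_gene = c(5, 5, 5, 5, 5, 5),
             zero_rest = c(1, 1, 1, 0, 0, 0))
  m <- make_mat(v, "mrna", features = rownames(v))
  part <- partition("PAM", 2, stats::setNames(rep(1:2, each = 3),
                                              colnames(m$values)))
  list(m = m, part = part)
}

test_that("fold-change gene sets apply the 2-fold / 0.5-fold rule one-vs-rest", {
  fx <- two_cluster_fixture()
  sets <- fold_change_sets(fx$m, fx$part, epsilon = 0.01)
  # mean 10 vs 4 -> ratio ~2.5: up in cluster 1, down in cluster 2
  expect_true("up_gene" %in% sets$sets[[1]]$up)
  expect_true("up_gene" %in% sets$sets[[2]]$down)
  # equal means -> ratio 1 -> neither
  expect_false("flat_gene" %in% c(sets$sets[[1]]$up, sets$sets[[1]]$down))
  # rest mean 0 with pseudocount -> large finite ratio, no division by zero
  expect_true("zero_rest" %in% sets$sets[[1]]$up)
  expect_true(all(is.finite(sets$ratios)))
  expect_equal(sets$counts$n_up[1], 2)

  one <- partition("PAM", 1, stats::setNames(rep(1L, 6), colnames(fx$m$values)))
  expect_error(fold_change_sets(fx$m, one), "2 clusters")
})

test_that("up and down sets are disjoint and exhaustive at threshold 1", {
  set.seed(23)
  m <- make_mat(matrix(rexp(40 * 12, 0.3), 40, 12), "mrna")
  part <- partition("HC", 3, stats::setNames(rep(1:3, each = 4),
                                             colnames(m$values)))
  sets <- fold_change_sets(m, part)
  for (cl in 1:3)
    expect_length(intersect(sets$sets[[cl]]$up, sets$sets[[cl]]$down), 0)

  all_in <- fold_change_sets(m, part, up = 1, down = 1)
  for (cl in 1:3) {
    tied <- rownames(m$values)[abs(all_in$ratios[, cl] - 1) < 1e-12]
    both <- union(all_in$sets[[cl]]$up, all_in$sets[[cl]]$down)
    expect_setequal(setdiff(rownames(m$values), both), setdiff(character(0), tied))
    expect_length(intersect(all_in$sets[[cl]]$up, all_in$sets[[cl]]$down), 0)
  }
})

test_that("heatmap rows are grouped by marking cluster and ordered by ratio", {
  set.seed(24)
  # 9 genes, each up-regulated in exactly one of 3 clusters
  labels <- rep(1:3, each = 4)
  v <- matrix(1, 9, 12)
  for (g in 1:9) v[g, labels == ((g - 1) %% 3 + 1)] <- 4 + g
  m <- make_mat(v, "mrna")
  part <- partition("PAM", 3, stats::setNames(labels, colnames(m$values)))
  sets <- fold_change_sets(m, part, epsilon = 0.01)
  ord <- order_rows_for_heatmap(m, part, sets)
  blocks <- ord$block[ord$order]
  expect_equal(unname(blocks), rep(1:3, each = 3))  # three contiguous blocks

  # a gene up in two clusters goes to the block with the higher ratio
  v2 <- rbind(c(8, 4, 1, 1), c(5, 5, 5, 5))
  m2 <- make_mat(v2, "mrna")
  part2 <- partition("PAM", 4, stats::setNames(1:4, colnames(m2$values)))
  sets2 <- fold_change_sets(m2, part2, up = 1.5, epsilon = 0.01)
  ord2 <- order_rows_for_heatmap(m2, part2, sets2)
  expect_equal(unname(ord2$block[["f01"]]), 1)      # ratio highest in cluster 1

  # nothing up anywhere: all genes in the tail, original order
  flat <- make_mat(matrix(5, 3, 4), "mrna")
  setsf <- fold_change_sets(flat, part2)
  ordf <- order_rows_for_heatmap(flat, part2, setsf)
  expect_equal(ordf$order, rownames(flat$values))
  expect_true(all(is.na(ordf$block)))
})

test_that("marker profiles are per-cluster means", {
  fx <- two_cluster_fixture()
  prof <- marker_profile(fx$m, fx$part, c("up_gene", "flat_gene"))
  expect_equal(unname(prof["up_gene", ]), c(10, 4))
  expect_equal(unname(prof["flat_gene", ]), c(5, 5))
  expect_error(marker_profile(fx$m, fx$part, "nope"), "nope")

  # one-sample clusters return the single values
  m <- make_mat(matrix(c(1, 2, 3), 1, 3), "mrna")
  p3 <- partition("PAM", 3, stats::setNames(1:3, colnames(m$values)))
  expect_equal(unname(marker_profile(m, p3, "f01")[1, ]), c(1, 2, 3))
})

test_that("hypergeometric enrichment matches the closed form and calibrates", {
  universe <- sprintf("g%04d", 1:1000)
  term <- universe[1:10]
  res <- enrich_gene_set(term, universe, list(hit = term, miss = universe[500:520]))
  p_exact <- 1 / choose(1000, 10)
  expect_equal(res$p_value[res$term == "hit"], p_exact, tolerance = 1e-10)
  expect_lt(res$p_value[res$term == "hit"], 1e-15)
  expect_true(res$significant[res$term == "hit"])

  # terms disjoint from the universe are skipped
  res2 <- enrich_gene_set(term, universe, list(out = c("x1", "x2"), hit = term))
  expect_equal(res2$term, "hit")

  expect_error(enrich_gene_set("zz", universe, list(a = term)), "subset")
  expect_error(enrich_gene_set(term, character(0), list(a = term)), "empty")

  # null calibration: random queries are significant for ~5% of terms
  # (term/query sizes large enough that the hypergeometric is not too discrete)
  set.seed(31)
  anns <- lapply(1:20, function(i) sample(universe, 150))
  names(anns) <- paste0("t", 1:20)
  frac <- mean(replicate(200, {
    q <- sample(universe, 80)
    mean(enrich_gene_set(q, universe, anns)$p_value < 0.05)
  }))
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})

test_that("partition overlap tests match the 2x2 chi-square closed form", {
  ids <- sprintf("s%02d", 1:20)
  a <- partition("PAM", 2, stats::setNames(rep(1:2, each = 10), ids))
  ov <- overlap_partitions(a, a)
  expect_equal(unname(ov$contingency[1, ]), c(10, 0))
  expect_equal(ov$pair_p[1, 1],
               stats::pchisq(20, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(ov$stars[1, 1], "***")

  # relabeling one side permutes the p matrix under the bijection
  b <- partition("PAM", 2, stats::setNames(3L - rep(1:2, each = 10), ids))
  ovb <- overlap_partitions(a, b)
  expect_equal(ovb$pair_p[1, 2], ov$pair_p[1, 1], tolerance = 1e-12)

  # swapping the sides transposes the table and preserves the overall chi2
  set.seed(33)
  c1 <- partition("PAM", 3, stats::setNames(sample(1:3, 60, TRUE,
                                                   prob = c(.5, .3, .2)), sprintf("t%02d", 1:60)))
  c2 <- partition("HC", 2, stats::setNames(sample(1:2, 60, TRUE),
                                           sprintf("t%02d", 1:60)))
  o12 <- overlap_partitions(c1, c2)
  o21 <- overlap_partitions(c2, c1)
  expect_equal(o12$chi2, o21$chi2, tolerance = 1e-10)
  expect_equal(o12$p_value, o21$p_value, tolerance = 1e-10)
  expect_equal(unclass(o12$contingency), t(unclass(o21$contingency)),
               ignore_attr = TRUE)

  disj <- partition("PAM", 2, stats::setNames(rep(1:2, 5), sprintf("u%02d", 1:10)))
  expect_error(overlap_partitions(a, disj), "shared")
})

test_that("independent partitions star ~5% of pairs", {
  set.seed(35)
  ids <- sprintf("s%03d", 1:300)
  frac <- mean(replicate(60, {
    pa <- partition("PAM", 3, stats::setNames(sample(1:3, 300, TRUE), ids))
    pb <- partition("HC", 3, stats::setNames(sample(1:3, 300, TRUE), ids))
    ov <- overlap_partitions(pa, pb)
    mean(ov$pair_p < 0.05, na.rm = TRUE)
  }))
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.10)
})

test_that("clinical association uses ANOVA for quantitative, chi-square otherwise", {
  ids <- sprintf("p%02d", 1:6)
  part <- partition("PAM", 2, stats::setNames(rep(1:2, each = 3), ids))
  ct <- clinical_table(ids,
                       list(num = c(1, 2, 3, 4, 5, 6),
                            const = rep("x", 6)),
                       c(num = "quantitative", const = "categorical"))
  res <- clinical_association(ct, part)
  num <- res[res$variable == "num", ]
  expect_equal(num$test, "anova")
  expect_equal(num$statistic, 13.5, tolerance = 1e-10)  # SSB 13.5 / MSW 1
  cst <- res[res$variable == "const", ]
  expect_match(cst$note, "single observed level")
  expect_true(is.na(cst$p_value))

  # null categorical variable: p > 0.05 in >= 90% of simulations
  set.seed(37)
  big_ids <- sprintf("q%03d", 1:600)
  bp <- partition("PAM", 4, stats::setNames(rep(1:4, each = 150), big_ids))
  hits <- mean(replicate(100, {
    ct2 <- clinical_table(big_ids,
                          list(v = sample(c("a", "b", "c"), 600, TRUE)),
                          c(v = "categorical"))
    clinical_association(ct2, bp)$p_value > 0.05
  }))
  expect_gte(hits, 0.9)
})
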