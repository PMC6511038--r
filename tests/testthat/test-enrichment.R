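test_that("median-rank enrichment matches exhaustive enumeration on a tiny universe", {
  universe <- sprintf("g%02d", 1:10)
  ranking <- universe  # rank = index
  # exact oracle: all C(10, 2) target placements
  all_pairs <- combn(10, 2)
  exact_tail <- function(target_idx) {
    obs <- median(target_idx)
    meds <- apply(all_pairs, 2, median)
    mean(meds <= obs)
  }
  for (target_idx in list(c(1, 2), c(3, 7), c(9, 10))) {
    res <- median_rank_enrichment(ranking, universe[target_idx],
                                  n_resample = 4000, alternative = "low",
                                  seed = 2)
    exact <- exact_tail(target_idx)
    # add-one MC estimate approximates the exact tail within MC error
    se <- sqrt(exact * (1 - exact) / 4000)
    expect_lt(abs(res$p - exact), max(4 * se, 0.01))
    expect_equal(res$observed_median_rank, median(target_idx))
  }
})

test_that("median-rank enrichment is at the floor for the top of the list and depends only on ranks", {
  ranking <- sprintf("g%03d", 1:200)
  res <- median_rank_enrichment(ranking, ranking[1:10], n_resample = 999,
                                alternative = "low", seed = 3)
  expect_equal(res$p, 1 / 1000)
  # gene_table input with arbitrary monotone z values gives identical output
  gt <- data.frame(gene_id = ranking, rank = 1:200,
                   z_score = exp(seq(5, -5, length.out = 200)))
  class(gt) <- c("gene_table", "data.frame")
  res2 <- median_rank_enrichment(gt, ranking[1:10], n_resample = 999,
                                 alternative = "low", seed = 3)
  expect_identical(res[c("observed_median_rank", "p")],
                   res2[c("observed_median_rank", "p")])
  expect_error(median_rank_enrichment(ranking, c("zz1", "zz2"),
                                      n_resample = 999), "disjoint")
  expect_error(median_rank_enrichment(ranking, ranking[1:3],
                                      n_resample = 10), "at least 100")
})

test_that("random targets give calibrated median-rank p-values", {
  ranking <- sprintf("g%03d", 1:150)
  set.seed(71)
  ps <- vapply(1:60, function(i)
    median_rank_enrichment(ranking, sample(ranking, 12), n_resample = 199,
                           alternative = "low", seed = 1000 + i)$p,
    numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_true(all(ps >= 1 / 200 & ps <= 1))
})

test_that("sign concordance matches the exact rank-sum tail under complete separation", {
  gt <- data.frame(gene_id = sprintf("g%02d", 1:12),
                   z_score = c(-(6:1), 1:6), pls1_weight = c(-(6:1), 1:6))
  up <- sprintf("g%02d", 1:6)    # all weights below every down gene
  down <- sprintf("g%02d", 7:12)
  res <- sign_concordance_test(gt, up, down)
  # exact two-sided tail for complete separation of 6 vs 6
  expect_equal(res$p, 2 / choose(12, 6), tolerance = 1e-12)
  expect_equal(res$direction, "up-labeled lower")
  swapped <- sign_concordance_test(gt, down, up)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)
  expect_equal(swapped$direction, "down-labeled lower")
  expect_error(sign_concordance_test(gt, c("zz"), down), "intersect")
})

test_that("random labels give calibrated sign-concordance p-values", {
  set.seed(72)
  gt <- data.frame(gene_id = sprintf("g%03d", 1:80), z_score = rnorm(80))
  ps <- vapply(1:80, function(i) {
    lab <- sample(gt$gene_id, 40)
    sign_concordance_test(gt, lab, setdiff(gt$gene_id, lab))$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("PPI edge enrichment matches the Erdos-Renyi density oracle", {
  net <- generate_network(150, 0.1, seed = 5)
  universe <- attr(net, "nodes")
  res <- ppi_edge_enrichment(net, universe[1:40], universe, n_perm = 2000,
                             seed = 6)
  density <- nrow(net) / choose(150, 2)
  expected_oracle <- density * choose(40, 2)
  expect_lt(abs(res$expected_edges - expected_oracle),
            0.15 * expected_oracle)
  # whole universe: observed equals the full edge count, p = 1
  res_all <- ppi_edge_enrichment(net, universe, universe, n_perm = 200,
                                 seed = 7)
  expect_equal(res_all$observed_edges, nrow(net))
  expect_equal(res_all$p, 1)
  expect_error(ppi_edge_enrichment(net, c("nope"), universe), "subset")
})

test_that("a planted clique is detected at the permutation floor", {
  net <- generate_network(120, 0.02, planted_clique = 1:15, seed = 8)
  universe <- attr(net, "nodes")
  res <- ppi_edge_enrichment(net, universe[1:15], universe, n_perm = 999,
                             seed = 9)
  expect_gte(res$observed_edges, choose(15, 2))
  expect_equal(res$p, 1 / 1000)
  expect_gt(res$observed_edges, 3 * res$expected_edges)
})

test_that("edge lists are normalized: no self-loops, no duplicate pairs, no stray endpoints", {
  edges <- data.frame(from = c("a", "b", "a", "c", "d"),
                      to = c("b", "a", "a", "d", "zzz"))
  res <- ppi_edge_enrichment(edges, c("a", "b"), c("a", "b", "c", "d"),
                             n_perm = 100, seed = 1)
  expect_equal(res$observed_edges, 1)  # a-b counted once; a-a and d-zzz dropped
})

test_that("gene-set collection testing controls FDR across sets", {
  ranking <- sprintf("g%03d", 1:200)
  sets <- list(top = ranking[1:15], rand1 = ranking[c(30, 77, 120, 180)],
               bottom = ranking[186:200])
  res <- enrich_gene_sets(ranking, sets, n_resample = 999,
                          alternative = "two.sided", seed = 11)
  expect_equal(res$set, names(sets))
  expect_true(res$fdr_significant[res$set == "top"])
  expect_true(res$fdr_significant[res$set == "bottom"])
  expect_false(res$fdr_significant[res$set == "rand1"])
})

test_that("GMT and edge-list files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c(alpha = "first", beta = "second"))
  back <- read_gmt(path)
  expect_identical(back$alpha, sets$alpha)
  expect_identical(back$beta, sets$beta)
  expect_identical(attr(back, "descriptions")[["alpha"]], "first")
  net <- generate_network(20, 0.3, seed = 2)
  epath <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, epath)
  back_e <- read_edge_list(epath)
  expect_equal(nrow(back_e), nrow(net))
})
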