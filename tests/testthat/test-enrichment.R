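ranked_from_scores <- function(scores) {
  rank_by_logfc(data.frame(gene_id = sprintf("g%03d", seq_along(scores)),
                           logfc = scores))
}

test_that("ranking is a stable descending sort with documented tie rule", {
  r <- rank_by_logfc(data.frame(gene_id = c("A", "B", "C"),
                                logfc = c(2, -1, 0)))
  expect_equal(r$gene_id, c("A", "C", "B"))
  r2 <- rank_by_logfc(data.frame(gene_id = c("B", "A"), logfc = c(1, 1)))
  expect_equal(r2$gene_id, c("A", "B"))
  # permuted input yields the identical ranking
  tab <- data.frame(gene_id = sprintf("g%02d", 1:20), logfc = rnorm(20))
  expect_equal(rank_by_logfc(tab), rank_by_logfc(tab[sample(20), ]))
  expect_error(rank_by_logfc(data.frame(gene_id = c("A", "A"),
                                        logfc = c(1, 2))), "duplicate")
  expect_error(rank_by_logfc(data.frame(gene_id = "A", logfc = NA)),
               "finite")
})

test_that("single-member extremes give |ES| = 1 at the list ends", {
  scores <- seq(10, 1)
  r <- ranked_from_scores(scores)
  # member at rank 1: P_hit jumps to 1 before any miss decrement
  expect_equal(enrichment_score(r, r$gene_id[1])$es, 1)
  # member at rank N: the running sum bottoms out at -(N-1)/(N-1) = -1
  expect_equal(enrichment_score(r, r$gene_id[10])$es, -1)
})

test_that("enrichment score equals the brute-force running sum", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(20:80, 1)
    m <- sample(2:8, 1)
    scores <- round(rnorm(n), 3)
    r <- ranked_from_scores(scores)
    members <- sample(r$gene_id, m)
    got <- enrichment_score(r, members)
    want <- bf_enrichment_score(r$score, r$gene_id %in% members)
    expect_equal(got$es, want, tolerance = 1e-12)
    expect_true(abs(got$es) <= 1 + 1e-12)
    expect_equal(got$n_hits, m)
  }
})

test_that("enrichment score agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(5)
  for (i in 1:20) {
    scores <- sort(rnorm(100), decreasing = TRUE)
    r <- ranked_from_scores(scores)
    idx <- sort(sample(100, 10))
    got <- enrichment_score(r, r$gene_id[idx])$es
    want <- fgsea::calcGseaStat(r$score, idx, gseaParam = 1)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("reversing a tie-free list negates the enrichment score", {
  set.seed(9)
  scores <- sort(rnorm(60), decreasing = TRUE)  # continuous: tie-free
  r <- ranked_from_scores(scores)
  members <- sample(r$gene_id, 6)
  rev_r <- rank_by_logfc(data.frame(gene_id = r$gene_id, logfc = -r$score))
  expect_equal(enrichment_score(rev_r, members)$es,
               -enrichment_score(r, members)$es, tolerance = 1e-12)
})

test_that("permutation test is seeded, deterministic, and never returns p = 0", {
  sim <- synth_ranked_list(n_genes = 300, set_size = 30, effect_size = -2,
                           seed = 14)
  a <- permutation_test(sim$ranked, sim$target_set, n_perm = 99, seed = 7)
  b <- permutation_test(sim$ranked, sim$target_set, n_perm = 99, seed = 7)
  expect_identical(a, b)
  expect_gt(a$p_nominal, 0)
  expect_gte(a$p_nominal, 1 / (a$n_perm + 1))
  expect_lt(a$es, 0)
  expect_true(a$nes_defined)
  expect_lt(a$nes, 0)
  # a different seed changes the null draw but not the observed ES
  c <- permutation_test(sim$ranked, sim$target_set, n_perm = 99, seed = 8)
  expect_identical(a$es, c$es)
})

test_that("permutation test does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  sim <- synth_ranked_list(n_genes = 100, set_size = 10, seed = 2)
  invisible(permutation_test(sim$ranked, sim$target_set, n_perm = 19,
                             seed = 3))
  expect_identical(runif(1), before)
})

test_that("type-I error is controlled at nominal level", {
  # null lists: a random member set carries no signal
  n_sim <- 120
  rejections <- 0
  for (i in seq_len(n_sim)) {
    sim <- synth_ranked_list(n_genes = 300, set_size = 30, effect_size = 0,
                             seed = 1000 + i)
    res <- permutation_test(sim$ranked, sim$target_set, n_perm = 99,
                            seed = 2000 + i)
    if (res$p_nominal < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_sim
  # binomial 99.9% band around 0.05 at n = 120
  expect_gt(rate, 0.0)
  expect_lt(rate, 0.13)
})

test_that("a planted negative shift is detected with high power", {
  hits <- 0
  for (i in 1:20) {
    sim <- synth_ranked_list(n_genes = 2000, set_size = 100,
                             effect_size = -2, noise_sd = 1, seed = 300 + i)
    res <- permutation_test(sim$ranked, sim$target_set, n_perm = 200,
                            seed = 400 + i)
    if (res$es < 0 && res$p_nominal < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("run_family reports one row per overlapping threshold", {
  tx <- synth_transcriptome(n_genes = 30,
                            tract_plan = c("12" = 6, "16" = 6), unit = "CTG",
                            seed = 21)
  fam <- build_gene_set_family(stitch_gene_models(tx$regions), "CTG", 10:19)
  genes <- tx$truth$gene_id
  sim <- synth_ranked_list(n_genes = length(genes), seed = 3,
                           target_set = character(0), set_size = 0)
  tab <- sim$table
  tab$gene_id <- genes
  ranked <- rank_by_logfc(tab)
  res <- run_family(ranked, fam, n_perm = 49, seed = 17)
  # thresholds 17..19 have no members -> absent; 10..16 reported
  expect_equal(res$threshold, 10:16)
  expect_equal(res$set_size, vapply(as.character(10:16), function(t)
    length(fam$sets[[t]]), integer(1)), ignore_attr = TRUE)
  # identical member sets across thresholds give identical ES
  expect_equal(res$es[res$threshold %in% 13:16],
               rep(res$es[res$threshold == 13], 4))
})
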