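test_that("signal-to-noise ranking matches the floored formula", {
  set.seed(51)
  m <- random_matrix(20, 6)
  lab <- two_group_labels(colnames(m), 3, c("A", "B"))
  rk <- rank_metric(m, lab, groups = c("A", "B"))
  a <- colnames(m)[1:3]; b <- colnames(m)[4:6]
  ref <- sapply(rownames(m), function(g) {
    mu_a <- mean(m[g, a]); mu_b <- mean(m[g, b])
    (mu_a - mu_b) / (max(sd(m[g, a]), 0.2 * abs(mu_a)) +
                     max(sd(m[g, b]), 0.2 * abs(mu_b)))
  })
  expect_equal(setNames(rk$score, rk$gene), ref[rk$gene], tolerance = 1e-12)
  expect_false(is.unsorted(rev(rk$score)))
  # reversing the phenotype pair negates every score
  rk_rev <- rank_metric(m, lab, groups = c("B", "A"))
  expect_equal(setNames(rk_rev$score, rk_rev$gene)[rk$gene],
               -setNames(rk$score, rk$gene), tolerance = 1e-12)
})

test_that("rank_metric tie-breaking and small-group handling", {
  m <- matrix(5, 4, 4, dimnames = list(c("D", "B", "C", "A"), paste0("s", 1:4)))
  lab <- two_group_labels(colnames(m), 2, c("A", "B"))
  rk <- rank_metric(m, lab)
  expect_true(all(rk$score == 0))
  expect_identical(rk$gene, c("A", "B", "C", "D"))  # alphabetical on ties
  one <- m[, 1:3]
  lab1 <- two_group_labels(colnames(one), 1, c("A", "B"))
  expect_error(rank_metric(one, lab1), "difference_of_means")
  expect_silent(rank_metric(one, lab1, metric = "difference_of_means"))
})

test_that("enrichment score attains +/-1 for single extreme genes at p = 0", {
  ranked <- data.frame(gene = LETTERS[1:10], score = 10:1)
  top <- enrichment_score(ranked, "A", p_weight = 0)
  expect_equal(top$es, 1)
  bottom <- enrichment_score(ranked, "J", p_weight = 0)
  expect_equal(bottom$es, -1)
  expect_error(enrichment_score(ranked, "ZZ"), "disjoint")
  expect_error(enrichment_score(ranked, LETTERS[1:10]), "whole")
})

test_that("enrichment score equals the brute-force running sum on random instances", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(10:50, 1)
    genes <- sprintf("G%02d", 1:n)
    scores <- sort(rnorm(n), decreasing = TRUE)
    members <- sample(genes, sample(2:(n - 1), 1))
    for (p in c(0, 1)) {
      got <- enrichment_score(data.frame(gene = genes, score = scores),
                              members, p_weight = p)
      expect_equal(got$es, es_oracle(genes, scores, members, p),
                   tolerance = 1e-12)
      expect_lte(abs(got$es), 1 + 1e-12)
      expect_lte(max(abs(got$running)), 1 + 1e-12)
    }
  }
})

test_that("enrichment score agrees with the fgsea statistic at weight 1", {
  skip_if_not_installed("fgsea")
  set.seed(71)
  genes <- sprintf("G%02d", 1:40)
  scores <- sort(rnorm(40), decreasing = TRUE)
  for (rep in 1:10) {
    members <- sample(genes, 6)
    mine <- enrichment_score(data.frame(gene = genes, score = scores),
                             members)$es
    ref <- fgsea::calcGseaStat(setNames(scores, genes),
                               which(genes %in% members), gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("reversing the ranked list negates the unweighted enrichment score", {
  set.seed(81)
  genes <- sprintf("G%02d", 1:30)
  scores <- sort(rnorm(30), decreasing = TRUE)
  members <- sample(genes, 7)
  fwd <- enrichment_score(data.frame(gene = genes, score = scores),
                          members, p_weight = 0)$es
  rev_es <- enrichment_score(data.frame(gene = rev(genes),
                                        score = rev(scores)),
                             members, p_weight = 0)$es
  expect_equal(fwd, -rev_es, tolerance = 1e-12)
})

test_that("nominal p matches exhaustive phenotype enumeration on a 4+4 design", {
  set.seed(91)
  n_genes <- 25
  m <- random_matrix(n_genes, 8)
  m[1:5, 1:4] <- m[1:5, 1:4] * 4  # make the set genuinely enriched in A
  lab <- two_group_labels(colnames(m), 4, c("A", "B"))
  members <- rownames(m)[1:5]
  res <- gsea(m, lab, list(SET = members), n_perm = 70, seed = 1,
              groups = c("A", "B"))
  expect_identical(res$n_perm, 70L)  # choose(8,4) enumerated exhaustively

  # independent oracle: every label assignment, own metric + running sum
  es_for <- function(cols_a) {
    a <- colnames(m)[cols_a]; b <- setdiff(colnames(m), a)
    mu_a <- rowMeans(m[, a]); mu_b <- rowMeans(m[, b])
    sn <- (mu_a - mu_b) / (pmax(apply(m[, a], 1, sd), 0.2 * abs(mu_a)) +
                           pmax(apply(m[, b], 1, sd), 0.2 * abs(mu_b)))
    ord <- order(-sn, rownames(m), method = "radix")
    es_oracle(rownames(m)[ord], sn[ord], members, 1)
  }
  null_es <- apply(combn(8, 4), 2, es_for)
  obs <- es_for(1:4)
  expect_equal(res$es, obs, tolerance = 1e-12)
  p_ref <- if (obs >= 0) mean(null_es[null_es >= 0] >= obs)
           else mean(null_es[null_es < 0] <= obs)
  expect_equal(res$p, p_ref, tolerance = 1e-12)
})

test_that("a planted up-shifted set is significant and GSEA is seed-deterministic", {
  set.seed(7)
  m <- random_matrix(200, 16)
  lab <- two_group_labels(colnames(m), 8, c("A", "B"))
  planted <- rownames(m)[1:40]
  m[planted, 1:8] <- m[planted, 1:8] * 2^1.5
  decoy <- rownames(m)[101:140]
  res <- gsea(m, lab, list(PLANTED = planted, DECOY = decoy),
              n_perm = 1000, seed = 17, groups = c("A", "B"))
  planted_row <- res[res$set == "PLANTED", ]
  expect_gt(planted_row$es, 0)
  expect_lt(planted_row$fdr_q, 0.25)
  res2 <- gsea(m, lab, list(PLANTED = planted, DECOY = decoy),
               n_perm = 1000, seed = 17, groups = c("A", "B"))
  expect_identical(res, res2)
})

test_that("random gene sets are rarely called significant under the null", {
  set.seed(111)
  m <- random_matrix(100, 10)
  lab <- two_group_labels(colnames(m), 5, c("A", "B"))
  p_vals <- replicate(25, {
    members <- sample(rownames(m), 10)
    gsea(m, lab, list(S = members), n_perm = 100, seed = sample.int(1e6, 1),
         metric = "difference_of_means", groups = c("A", "B"))$p
  })
  expect_gte(mean(p_vals >= 0.05), 0.8)
})

test_that("too few distinct label splits falls back to gene-set permutation", {
  set.seed(121)
  m <- random_matrix(50, 5)
  lab <- two_group_labels(colnames(m), 2, c("A", "B"))  # choose(5,2) = 10
  expect_warning(res <- gsea(m, lab, list(S = rownames(m)[1:8]),
                             n_perm = 100, seed = 3, groups = c("A", "B")),
                 "gene_set")
  expect_identical(attr(res, "params")$perm_type, "gene_set")
  expect_error(gsea(m, lab, list(S = rownames(m)[1:8]), n_perm = 5),
               "n_perm")
})
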