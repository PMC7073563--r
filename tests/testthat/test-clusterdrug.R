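test_that("clustering handles singletons, duplicates and planted blobs", {
  X <- named_matrix(8, 5, seed = 1, rprefix = "LV", cprefix = "P")
  all_single <- cluster_lvs(X, k = 8)
  expect_equal(sort(all_single$assignment$cluster), 1:8)

  # duplicated rows merge first and stay co-assigned
  Xd <- rbind(X, X)
  rownames(Xd) <- c(rownames(X), paste0(rownames(X), "_dup"))
  cld <- cluster_lvs(Xd, k = 4)
  a <- cld$assignment
  for (lv in rownames(X)) {
    expect_equal(a$cluster[a$lv == lv],
                 a$cluster[a$lv == paste0(lv, "_dup")])
  }

  # two well-separated blobs are recovered across seeds
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    blob <- rbind(matrix(rnorm(10 * 6, 0, 0.3), 10),
                  matrix(rnorm(10 * 6, 5, 0.3), 10))
    dimnames(blob) <- list(paste0("LV", 1:20), paste0("P", 1:6))
    cl <- cluster_lvs(blob, k = 2)$assignment$cluster
    length(unique(cl[1:10])) == 1 && length(unique(cl[11:20])) == 1 &&
      cl[1] != cl[20]
  }, logical(1))
  expect_gte(sum(hits), 19)

  expect_error(cluster_lvs(X, k = 20), "exceeds")
  Xna <- X
  Xna[1, 1] <- NA
  expect_message(cluster_lvs(Xna, k = 2), "imputed")
})

test_that("consensus rankings are cluster means, order-invariant", {
  corr <- rbind(LV1 = c(0.2, 0.8), LV2 = c(0.4, 0.6), LV3 = c(-1, 1))
  colnames(corr) <- c("Pa", "Pb")
  cl <- structure(list(assignment = tibble::tibble(lv = rownames(corr),
                                                   cluster = c(1, 1, 2)),
                       tree = NULL, k = 2),
                  class = "lv_clusters")
  rk <- consensus_protein_ranking(corr, cl)
  c1 <- rk[rk$cluster == 1, ]
  expect_equal(c1$mean_correlation[c1$protein == "Pa"], 0.3)
  expect_equal(c1$mean_correlation[c1$protein == "Pb"], 0.7)
  expect_equal(c1$protein[1], "Pb")  # sorted descending
  # singleton cluster equals its row
  c2 <- rk[rk$cluster == 2, ]
  expect_equal(setNames(c2$mean_correlation, c2$protein),
               sort(corr["LV3", ], decreasing = TRUE))
  # permuting LV order within the cluster changes nothing
  cl2 <- cl
  cl2$assignment <- cl2$assignment[c(2, 1, 3), ]
  expect_equal(consensus_protein_ranking(corr, cl2), rk)
})

test_that("enrichment ES matches fgsea and reverses with the ranking", {
  set.seed(2)
  rk <- setNames(rnorm(50), paste0("R", 1:50))
  tg <- sample(names(rk), 8)
  ours <- drug_enrichment(rk, list(X = tg), n_perm = 50, seed = 3)
  sorted <- sort(rk, decreasing = TRUE)
  fg_es <- fgsea::calcGseaStat(sorted, which(names(sorted) %in% tg),
                               gseaParam = 1)
  expect_equal(ours$es, fg_es, tolerance = 1e-12)
  rev_es <- drug_enrichment(-rk, list(X = tg), n_perm = 50, seed = 3)$es
  expect_equal(rev_es, -ours$es, tolerance = 1e-12)
})

test_that("exact enrichment p matches exhaustive enumeration; permutation approximates it", {
  ranking <- setNames(c(3, 2.5, 1.5, 1, 0.5, 0.2), paste0("P", 1:6))
  sets <- list(drugA = c("P1", "P2"), drugB = c("P5", "P6"))
  ex <- drug_enrichment(ranking, sets, exact = TRUE)

  sorted <- sort(ranking, decreasing = TRUE)
  all_es <- apply(combn(6, 2), 2, naive_gsea_es, sorted_scores = sorted)
  pA_oracle <- mean(all_es >= naive_gsea_es(c(1, 2), sorted))
  expect_equal(ex$p[ex$drug == "drugA"], pA_oracle, tolerance = 1e-12)

  pm <- drug_enrichment(ranking, sets, n_perm = 20000, seed = 4)
  se <- sqrt(pA_oracle * (1 - pA_oracle) / 20000)
  expect_lt(abs(pm$p[pm$drug == "drugA"] - pA_oracle), 3 * se + 1e-4)
})

test_that("a drug targeting the top of the ranking is significantly enriched", {
  set.seed(5)
  rk <- setNames(sort(rnorm(100, 0, 0.3), decreasing = TRUE),
                 sprintf("Q%03d", 1:100))
  de <- drug_enrichment(rk, list(planted = names(rk)[1:3],
                                 rand = sample(names(rk), 3)),
                        n_perm = 10000, seed = 6)
  expect_gt(de$es[de$drug == "planted"], 0)
  expect_lte(de$p[de$drug == "planted"], 0.01)
  expect_true(de$significant[de$drug == "planted"])

  # BH: significant set at q < 0.01 nests inside the set at q < 0.05
  sig01 <- de$drug[de$q_bh < 0.01]
  sig05 <- de$drug[de$q_bh < 0.05]
  expect_true(all(sig01 %in% sig05))

  expect_message(drug_enrichment(rk, list(planted = names(rk)[1:3],
                                          off = "nope"), n_perm = 10),
                 "dropped")
})

test_that("cluster expression summarizes LV means by tumor type", {
  B <- named_matrix(6, 8, seed = 7, rprefix = "LV")
  meta <- meta_for(colnames(B), rep(c("cNF", "MPNST"), each = 4))
  meta$tumor_type <- rep(c("cNF", "MPNST"), each = 4)
  cl <- structure(list(assignment = tibble::tibble(lv = rownames(B),
                                                   cluster = c(1, 1, 1, 2, 2, 3)),
                       tree = NULL, k = 3),
                  class = "lv_clusters")
  tb <- cluster_expression_by_type(B, cl, meta)
  expect_equal(nrow(tb), 3 * 8)
  # singleton cluster equals its LV row
  c3 <- tb[tb$cluster == 3, ]
  expect_equal(c3$mean_expression, unname(B["LV6", c3$sample_id]))
  # constant matrix gives constant means
  Bc <- B * 0 + 2
  tbc <- cluster_expression_by_type(Bc, cl, meta)
  expect_true(all(tbc$mean_expression == 2))

  # planted MPNST-high cluster is highest in MPNST
  Bp <- B
  Bp[c("LV4", "LV5"), meta$sample_id[meta$tumor_type == "MPNST"]] <-
    Bp[c("LV4", "LV5"), meta$sample_id[meta$tumor_type == "MPNST"]] + 4
  tbp <- cluster_expression_by_type(Bp, cl, meta) |>
    dplyr::filter(.data$cluster == 2) |>
    dplyr::group_by(.data$tumor_type) |>
    dplyr::summarise(m = mean(.data$mean_expression))
  expect_gt(tbp$m[tbp$tumor_type == "MPNST"], tbp$m[tbp$tumor_type == "cNF"])

  meta_missing <- meta[-1, ]
  expect_warning(cluster_expression_by_type(B, cl, meta_missing), "missing")
})
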