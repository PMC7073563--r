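test_that("gen_model produces a valid sparse non-negative model, deterministically", {
  m <- gen_model(100, 10, sparsity = 0.1, seed = 1)
  expect_s3_class(m, "plier_model")
  expect_equal(dim(m$Z), c(100, 10))
  expect_true(all(m$Z >= 0))
  expect_true(all(colSums(m$Z != 0) >= 1))
  # expected density close to the requested sparsity
  expect_lt(abs(mean(m$Z != 0) - 0.1), 0.05)
  m2 <- gen_model(100, 10, sparsity = 0.1, seed = 1)
  expect_identical(m$Z, m2$Z)
  expect_false(identical(m$Z, gen_model(100, 10, sparsity = 0.1, seed = 2)$Z))
})

test_that("gen_model rejects invalid shapes and sparsity", {
  expect_error(gen_model(5, 10, 0.1), "n_genes")
  expect_error(gen_model(100, 10, 0), "sparsity")
  expect_error(gen_model(100, 10, 1), "sparsity")
})

test_that("noiseless cohort without signal is exactly Z B", {
  m <- gen_model(60, 8, 0.2, seed = 3)
  co <- gen_cohort(m, c(A = 5, B = 5), planted_per_class = 2,
                   effect_size = 0, noise_sd = 0, batch_shift = 0, seed = 4)
  expect_equal(co$expression, m$Z %*% co$B, tolerance = 1e-12)
})

test_that("planting only shifts the planted LV rows, by exactly the effect", {
  m <- gen_model(60, 10, 0.2, seed = 3)
  base <- gen_cohort(m, c(A = 6, B = 6), planted_per_class = 2,
                     effect_size = 0, noise_sd = 0, seed = 5)
  shifted <- gen_cohort(m, c(A = 6, B = 6), planted_per_class = 2,
                        effect_size = 3, noise_sd = 0, seed = 5)
  planted <- shifted$truth$planted_lvs_per_class
  expect_length(intersect(planted$A, planted$B), 0)
  for (cl in c("A", "B")) {
    in_cl <- shifted$metadata$tumor_type == cl
    diff <- shifted$B[planted[[cl]], in_cl] - base$B[planted[[cl]], in_cl]
    expect_equal(unname(diff), matrix(3, 2, sum(in_cl)), tolerance = 1e-12)
  }
  others <- setdiff(rownames(base$B), unlist(planted))
  expect_identical(base$B[others, ], shifted$B[others, ])
})

test_that("planted class separation reaches the requested effect in B", {
  m <- gen_model(200, 40, 0.15, seed = 6)
  co <- gen_cohort(m, c(cNF = 15, MPNST = 15, NF = 15, pNF = 15),
                   planted_per_class = 5, effect_size = 3, noise_sd = 0.5,
                   seed = 7)
  for (cl in names(co$truth$planted_lvs_per_class)) {
    in_cl <- co$metadata$tumor_type == cl
    for (lv in co$truth$planted_lvs_per_class[[cl]]) {
      gap <- mean(co$B[lv, in_cl]) - mean(co$B[lv, !in_cl])
      expect_gte(gap, 2)
    }
  }
})

test_that("a confounded batch shift separates studies on gene-space PCs", {
  m <- gen_model(200, 30, 0.15, seed = 5)
  co <- gen_cohort(m, c(cNF = 10, MPNST = 10, NF = 10, pNF = 10),
                   planted_per_class = 2, effect_size = 1, noise_sd = 0.5,
                   batch_shift = 2, seed = 6)
  pr <- prcomp(t(co$expression), center = TRUE)
  sil <- cluster::silhouette(as.integer(factor(co$metadata$study_id)),
                             dist(pr$x[, 1:2]))
  expect_gt(mean(sil[, 3]), 0.25)
})

test_that("gen_cohort rejects empty classes", {
  m <- gen_model(60, 8, 0.2, seed = 3)
  expect_error(gen_cohort(m, c(A = 5, B = 0)), "at least one sample")
  expect_error(gen_cohort(m, c(5, 5)), "named")
})

test_that("gen_regulons draws distinct signed-mode targets, deterministically", {
  regs <- gen_regulons(5, 10, paste0("g", 1:100), seed = 7)
  expect_length(regs, 5)
  for (r in regs) {
    expect_s3_class(r, "regulon")
    expect_length(unique(r$targets$gene), 10)
    expect_true(all(r$targets$mode %in% c(-1, 1)))
    expect_equal(sum(r$targets$likelihood), 1)
  }
  regs2 <- gen_regulons(5, 10, paste0("g", 1:100), seed = 7)
  expect_identical(regs, regs2)
  expect_error(gen_regulons(5, 10, paste0("g", 1:5)), "universe")
})

test_that("gen_variants with zero background places variants only in effect genes", {
  meta <- meta_for(sprintf("S%02d", 1:20), c("cNF", "pNF"))
  vs <- gen_variants(meta,
                     tibble::tibble(gene = "NF1", lv = "LV1", shift = 2,
                                    n_carriers = 6),
                     background_rate = 0, seed = 8)
  expect_setequal(unique(vs$variants$Hugo_Symbol), "NF1")
  expect_length(unique(vs$variants$Tumor_Sample_Barcode), 6)
  expect_error(
    gen_variants(meta, tibble::tibble(gene = "X", lv = "LV1", shift = 1,
                                      n_carriers = 50)),
    "carriers")
})

test_that("apply_variant_effects shifts carriers only, in SD units", {
  meta <- meta_for(sprintf("S%02d", 1:20), c("cNF", "pNF"))
  vs <- gen_variants(meta,
                     tibble::tibble(gene = "NF1", lv = "LV2", shift = 2,
                                    n_carriers = 5),
                     background_rate = 0, seed = 9)
  B <- named_matrix(4, 20, seed = 10, rprefix = "LV", cprefix = "S0")
  colnames(B) <- meta$sample_id
  B2 <- apply_variant_effects(B, vs)
  who <- vs$carriers$NF1
  expect_equal(B2["LV2", who], B["LV2", who] + 2 * sd(B["LV2", ]))
  expect_identical(B2["LV2", setdiff(colnames(B), who)],
                   B["LV2", setdiff(colnames(B), who)])
  expect_identical(B2[c("LV1", "LV3", "LV4"), ], B[c("LV1", "LV3", "LV4"), ])
})

test_that("the planted drug draws its targets from the top stratum", {
  u <- sprintf("P%03d", 1:50)
  ds <- gen_drug_sets(8, 5, u, planted_drug_top_k = 10, seed = 11)
  overlap <- mean(ds$sets[[ds$planted_drug]] %in% ds$top_stratum)
  expect_gte(overlap, 0.8)
  expect_error(gen_drug_sets(3, 20, u, planted_drug_top_k = 10), "smaller")
})

test_that("immune mixing fractions form a simplex", {
  meta <- meta_for(sprintf("S%02d", 1:15), c("cNF", "pNF", "NF"))
  imm <- gen_immune_mixture(meta, n_cell_types = 4, markers_per_type = 6,
                            seed = 12)
  expect_true(all(imm$fractions >= 0))
  expect_equal(unname(colSums(imm$fractions)), rep(1, 15), tolerance = 1e-9)
  expect_true(all(imm$signature >= 0))
  expect_true(all(imm$expr_linear >= 0))
})

test_that("with no planted signal, no LV differs between classes (null calibration)", {
  clean <- vapply(1:20, function(s) {
    m <- gen_model(100, 40, 0.15, seed = 100 + s)
    co <- gen_cohort(m, c(A = 10, B = 10, C = 10), planted_per_class = 2,
                     effect_size = 0, noise_sd = 0.5, batch_shift = 0,
                     seed = s)
    p <- apply(co$B, 1L, function(x) {
      kruskal.test(x, factor(co$metadata$tumor_type))$p.value
    })
    sum(p.adjust(p, "BH") < 0.05) == 0
  }, logical(1))
  expect_gte(sum(clean), 19)
})
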