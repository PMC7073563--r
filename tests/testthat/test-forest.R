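make_lab <- function(meta) setNames(meta$tumor_type, meta$sample_id)

test_that("model/test split is stratified, exhaustive and disjoint", {
  meta <- meta_for(sprintf("S%02d", 1:40), rep(c("A", "B", "C", "D"), each = 10))
  meta$tumor_type <- rep(c("A", "B", "C", "D"), each = 10)
  sp <- split_model_test(meta, 0.8, seed = 1)
  expect_length(sp$model_ids, 32)
  expect_length(sp$test_ids, 8)
  expect_setequal(c(sp$model_ids, sp$test_ids), meta$sample_id)
  expect_length(intersect(sp$model_ids, sp$test_ids), 0)
  tt <- table(meta$tumor_type[meta$sample_id %in% sp$test_ids])
  expect_true(all(tt == 2))

  # per-class model proportions stay within one sample of the global fraction
  meta2 <- meta_for(sprintf("S%02d", 1:33), NULL)
  meta2$tumor_type <- c(rep("A", 14), rep("B", 11), rep("C", 8))
  for (s in 1:50) {
    sp2 <- split_model_test(meta2, 0.8, seed = s)
    n_model <- table(meta2$tumor_type[meta2$sample_id %in% sp2$model_ids])
    n_all <- table(meta2$tumor_type)
    expect_true(all(abs(n_model - 0.8 * n_all) <= 1))
  }

  meta$tumor_type[1:10] <- c("E", meta$tumor_type[2:10])
  expect_error(split_model_test(meta), "fewer than 2")
})

test_that("tuning returns the single grid point, is deterministic, ties break small", {
  m <- gen_model(60, 10, 0.3, seed = 2)
  co <- gen_cohort(m, c(A = 10, B = 10), planted_per_class = 2,
                   effect_size = 4, noise_sd = 0.2, seed = 3)
  lab <- make_lab(co$metadata)
  cfg1 <- ensemble_config(mtry_grid = 3, ntree_grid = 100, cv_folds = 3,
                          seed = 4)
  hp <- tune_hyperparams(co$B, lab, cfg1)
  expect_equal(hp$mtry, 3L)
  expect_equal(hp$ntrees, 100L)
  hp2 <- tune_hyperparams(co$B, lab, cfg1)
  expect_identical(hp$grid, hp2$grid)

  # perfectly separable: every grid point reaches macro-F1 1; smallest wins
  sep <- co$B
  sep["LV1", ] <- ifelse(lab == "A", 10, -10)
  cfg2 <- ensemble_config(mtry_grid = c(1, 2), ntree_grid = c(100, 50),
                          cv_folds = 3, seed = 5)
  hps <- tune_hyperparams(sep, lab, cfg2)
  expect_equal(max(hps$grid$mean_macro_f1), 1)
  expect_equal(hps$ntrees, 50L)
  expect_equal(hps$mtry, 1L)

  # mtry beyond the feature count is skipped
  cfg3 <- ensemble_config(mtry_grid = c(2, 500), ntree_grid = 50,
                          cv_folds = 3, seed = 6)
  expect_false(500 %in% tune_hyperparams(co$B, lab, cfg3)$grid$mtry)
})

test_that("per-class F1 follows the degenerate-confusion convention", {
  # no true and no predicted positives for class C -> F1 = 0
  expect_equal(
    unname(lvscape:::f1_by_class(c("A", "A", "B"), c("A", "B", "B"),
                                 c("A", "B", "C"))),
    c(2 / 3, 2 / 3, 0))
})

test_that("a planted separator earns top class importance and high F1", {
  m <- gen_model(120, 30, 0.2, seed = 7)
  co <- gen_cohort(m, c(A = 12, B = 12, C = 12, D = 12),
                   planted_per_class = 0, effect_size = 0, noise_sd = 0.3,
                   seed = 8)
  lab <- make_lab(co$metadata)
  B <- co$B
  B["LV1", ] <- ifelse(lab == "A", 5, 0) + rnorm(48, 0, 0.1)
  cfg <- ensemble_config(n_iterations = 30, seed = 9)
  ens <- run_ensemble(B, lab, config = cfg, ntrees = 250)
  medA <- apply(ens$importance_permutation[, "A", ], 2L, median)
  expect_equal(names(which.max(medA)), "LV1")
  expect_gte(median(ens$f1[, "A"]), 0.95)
})

test_that("the ensemble is reproducible from its config seed", {
  m <- gen_model(60, 12, 0.3, seed = 10)
  co <- gen_cohort(m, c(A = 8, B = 8), planted_per_class = 2,
                   effect_size = 3, noise_sd = 0.5, seed = 11)
  lab <- make_lab(co$metadata)
  cfg <- ensemble_config(n_iterations = 10, top_k = 4, seed = 12)
  e1 <- run_ensemble(co$B, lab, config = cfg, ntrees = 100)
  e2 <- run_ensemble(co$B, lab, config = cfg, ntrees = 100)
  expect_identical(e1$f1, e2$f1)
  expect_identical(select_top_features(e1, 4)$union,
                   select_top_features(e2, 4)$union)
})

test_that("removing the signal-carrying LVs collapses classification", {
  m <- gen_model(150, 30, 0.2, seed = 13)
  co <- gen_cohort(m, c(A = 14, B = 14), planted_per_class = 5,
                   effect_size = 3, noise_sd = 0.5, seed = 14)
  lab <- make_lab(co$metadata)
  planted_A <- co$truth$planted_lvs_per_class$A
  pool <- setdiff(rownames(co$B), co$truth$planted_lvs_per_class$B)
  cfg <- ensemble_config(n_iterations = 25, seed = 15)
  with_sig <- run_ensemble(co$B, lab, features = pool, config = cfg,
                           ntrees = 250)
  without <- run_ensemble(co$B, lab, features = setdiff(pool, planted_A),
                          config = cfg, ntrees = 250)
  drop_A <- median(with_sig$f1[, "A"]) - median(without$f1[, "A"])
  expect_gte(drop_A, 0.2)
})

test_that("top-feature union size reflects per-class ranking overlap", {
  skeleton <- function(imp_per_class) {
    classes <- names(imp_per_class)
    feats <- paste0("LV", seq_len(length(imp_per_class[[1]])))
    ip <- array(0, c(3, length(classes), length(feats)),
                dimnames = list(NULL, classes, feats))
    for (cl in classes) {
      ip[, cl, ] <- matrix(rep(imp_per_class[[cl]], each = 3), 3)
    }
    structure(list(f1 = matrix(1, 3, length(classes),
                               dimnames = list(NULL, classes)),
                   importance_permutation = ip,
                   importance_gini = matrix(rep(seq_along(feats), each = 3), 3,
                                            dimnames = list(NULL, feats)),
                   classes = classes, features = feats, mtry = 1, ntrees = 1,
                   evaluate_on = "holdout", n_iterations = 3, seed = 1),
              class = "lv_ensemble")
  }
  # disjoint top-2 lists -> union of 4; identical rankings -> union of 2
  disjoint <- skeleton(list(A = c(9, 8, 1, 1), B = c(1, 1, 9, 8)))
  expect_length(select_top_features(disjoint, 2)$union, 4)
  same <- skeleton(list(A = c(9, 8, 1, 1), B = c(9, 8, 1, 1)))
  expect_length(select_top_features(same, 2)$union, 2)
  # gini metric applies one shared ranking to every class
  gsel <- select_top_features(disjoint, 2, metric = "gini")
  expect_identical(gsel$per_class$A, gsel$per_class$B)
  expect_warning(select_top_features(same, 10), "capped")
})

test_that("Mood's median test matches the hand-computed 2x2 chi-square", {
  mt <- mood_median_test(c(1, 1, 2, 2), c(3, 3, 4, 4))
  expect_equal(mt$statistic, 8)
  expect_equal(mt$p_value, pchisq(8, 1, lower.tail = FALSE))
  expect_equal(mt$p_value, 0.004677735, tolerance = 1e-6)
  expect_equal(unname(mt$table), rbind(c(0, 4), c(4, 0)))

  # identical distributions -> degenerate table handled as p = 1
  expect_equal(mood_median_test(c(1, 1, 1), c(1, 1))$p_value, 1)
  # symmetry
  expect_equal(mood_median_test(c(3, 3, 4, 4), c(1, 1, 2, 2))$p_value,
               mt$p_value)
})

test_that("compare_restricted reports medians and per-class Mood p-values", {
  f_full <- cbind(A = c(0.5, 0.5, 0.6, 0.6), B = c(0.9, 0.9, 1, 1))
  f_res <- cbind(A = c(0.8, 0.8, 0.9, 0.9), B = c(0.9, 0.9, 1, 1))
  cmp <- compare_restricted(f_full, f_res)
  expect_equal(cmp$median_full, c(0.55, 0.95))
  expect_equal(cmp$median_restricted, c(0.85, 0.95))
  expect_lt(cmp$p_value[1], 0.01)
  expect_equal(cmp$p_value[2], 1)
})

test_that("tidy and glance summarize an ensemble", {
  m <- gen_model(40, 8, 0.3, seed = 16)
  co <- gen_cohort(m, c(A = 6, B = 6), planted_per_class = 2,
                   effect_size = 3, noise_sd = 0.5, seed = 17)
  ens <- run_ensemble(co$B, make_lab(co$metadata),
                      config = ensemble_config(n_iterations = 5, seed = 18),
                      ntrees = 50)
  td <- tidy(ens)
  expect_named(td, c("iteration", "class", "f1"))
  expect_equal(nrow(td), 10)
  expect_true(all(td$f1 >= 0 & td$f1 <= 1))
  gl <- glance(ens)
  expect_equal(gl$n_iterations, 5)
  expect_s3_class(autoplot(ens), "ggplot")
})
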