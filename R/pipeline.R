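# End-to-end orchestration: a single config drives projection, LV
# deduplication, ensemble feature selection, microenvironment scoring,
# regulon activity, variant association and cluster/drug enrichment, with
# every intermediate written to disk and a content-hash manifest.

#' Build a pipeline configuration
#'
#' All inputs are file paths (TSV/GMT/JSON/MAF as produced by the package's
#' writers); optional stages are skipped when their inputs are `NULL`.
#' A single global seed fans out to per-stage seeds by fixed offsets so
#' each stage is independently reproducible.
#'
#' @param expression,model,metadata Required input paths (expression TSV,
#'   loading-matrix TSV with JSON sidecar, metadata TSV).
#' @param variants,markers,signature,regulons,drug_sets Optional input
#'   paths (`regulons` may be a vector of network JSON files).
#' @param out_dir Output directory (created if absent).
#' @param dedup_threshold LV deduplication cutoff (default 0.5).
#' @param top_lv_fraction Most-variable-LV report fraction (default 0.05).
#' @param ensemble An [ensemble_config()].
#' @param mtry,ntrees Forest hyperparameters; `NULL` uses defaults without
#'   grid tuning, `tune = TRUE` runs the CV grid search.
#' @param tune Run hyperparameter tuning (default FALSE)?
#' @param k_clusters Clusters to cut (default 5).
#' @param n_perm Drug-enrichment permutations (default 1000).
#' @param q_variant Variant-association BH cutoff (default 0.01).
#' @param min_mutated Minimum carriers per tested gene (default 3).
#' @param cor_threshold Activity-correlation count threshold (default
#'   0.65).
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, model, metadata, variants = NULL,
                            markers = NULL, signature = NULL,
                            regulons = NULL, drug_sets = NULL,
                            out_dir = "lvscape_out",
                            dedup_threshold = 0.5, top_lv_fraction = 0.05,
                            ensemble = ensemble_config(), mtry = NULL,
                            ntrees = NULL, tune = FALSE, k_clusters = 5,
                            n_perm = 1000, q_variant = 0.01,
                            min_mutated = 3, cor_threshold = 0.65,
                            seed = 1L) {
  required <- c(expression = expression, model = model, metadata = metadata)
  for (nm in names(required)) {
    if (!file.exists(required[[nm]])) {
      abort(sprintf("Input file for '%s' not found: %s", nm, required[[nm]]))
    }
  }
  structure(
    list(expression = expression, model = model, metadata = metadata,
         variants = variants, markers = markers, signature = signature,
         regulons = regulons, drug_sets = drug_sets, out_dir = out_dir,
         dedup_threshold = dedup_threshold,
         top_lv_fraction = top_lv_fraction, ensemble = ensemble,
         mtry = mtry, ntrees = ntrees, tune = tune,
         k_clusters = k_clusters, n_perm = n_perm, q_variant = q_variant,
         min_mutated = min_mutated, cor_threshold = cor_threshold,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @param path Path to a YAML file whose keys mirror the
#'   [pipeline_config()] arguments (`ensemble:` is a mapping of
#'   [ensemble_config()] arguments).
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$ensemble)) y$ensemble <- do.call(ensemble_config, y$ensemble)
  do.call(pipeline_config, y)
}

.write_tbl <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full latent-variable landscape pipeline
#'
#' Executes project -> dedup -> ensemble select -> (immune, activity,
#' variants) -> cluster/drugs from a [pipeline_config()]. Each stage writes
#' its outputs under `out_dir`; stages whose inputs are absent are skipped
#' with an explicit notice; a stage failure aborts naming the stage. The
#' returned manifest lists every output file with its MD5 content hash, so
#' reruns with the same config are checkable byte for byte.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with `manifest` (tibble: stage, file, md5) and
#'   the in-memory stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list()
  note <- function(stage, path) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)))
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  results <- list()

  # -- load -----------------------------------------------------------
  model <- stage("load", read_plier_model(config$model))
  Y <- stage("load", read_matrix_tsv(config$expression))
  meta <- stage("load", {
    m <- tibble::as_tibble(read.delim(config$metadata,
                                      stringsAsFactors = FALSE))
    assert_metadata(m)
    m
  })

  # -- dedup + projection --------------------------------------------
  retained <- stage("dedup", dedup_lvs(model, config$dedup_threshold))
  model_d <- new_plier_model(model$Z[, retained, drop = FALSE],
                             model$lambda2,
                             model$lv_annotations[retained])
  writeLines(retained, out("retained_lvs.txt"))
  note("dedup", out("retained_lvs.txt"))

  B <- stage("project", project_lv(model_d, zscore_genes(Y)))
  write_matrix_tsv(B, out("lv_scores.tsv"), id_name = "lv")
  note("project", out("lv_scores.tsv"))
  results$B <- B

  top_lvs <- stage("top_variable",
                   top_variable_lvs(B, config$top_lv_fraction))
  writeLines(top_lvs, out("top_variable_lvs.txt"))
  note("top_variable", out("top_variable_lvs.txt"))

  batch <- stage("batch_check", pca_batch_assessment(Y, B, meta))
  .write_tbl(tidy(batch), out("batch_assessment.tsv"))
  note("batch_check", out("batch_assessment.tsv"))
  results$batch <- batch

  # -- ensemble feature selection ------------------------------------
  results$selection <- stage("select", {
    split <- split_model_test(meta, config$ensemble$model_fraction,
                              seed = config$seed + 100L)
    lab <- setNames(meta$tumor_type, meta$sample_id)
    cfg <- config$ensemble
    cfg$seed <- config$seed + 200L
    hp <- if (config$tune) {
      tune_hyperparams(B[, split$model_ids, drop = FALSE],
                       lab[split$model_ids], cfg)
    } else {
      list(mtry = config$mtry, ntrees = config$ntrees)
    }
    full <- run_ensemble(B[, split$model_ids, drop = FALSE],
                         lab[split$model_ids], config = cfg,
                         mtry = hp$mtry, ntrees = hp$ntrees)
    sel <- select_top_features(full, top_k = cfg$top_k)
    cfg$seed <- config$seed + 300L
    restricted <- run_ensemble(
      B[, split$model_ids, drop = FALSE], lab[split$model_ids],
      features = sel$union, config = cfg, mtry = hp$mtry,
      ntrees = hp$ntrees, evaluate_on = "independent",
      independent_B = B[, split$test_ids, drop = FALSE],
      independent_labels = lab[split$test_ids])
    comparison <- compare_restricted(full, restricted)

    .write_tbl(dplyr::bind_rows(
      dplyr::mutate(tidy(full), ensemble = "full"),
      dplyr::mutate(tidy(restricted), ensemble = "restricted")),
      out("f1_distributions.tsv"))
    note("select", out("f1_distributions.tsv"))
    .write_tbl(sel$medians, out("importance_medians.tsv"))
    note("select", out("importance_medians.tsv"))
    jsonlite::write_json(list(union = sel$union, per_class = sel$per_class),
                         out("selected.json"), auto_unbox = FALSE)
    note("select", out("selected.json"))
    .write_tbl(comparison, out("f1_comparison.tsv"))
    note("select", out("f1_comparison.tsv"))
    list(split = split, full = full, selection = sel,
         restricted = restricted, comparison = comparison)
  })
  sel_union <- results$selection$selection$union

  # -- immune scoring -------------------------------------------------
  if (is.null(config$markers)) {
    inform("No marker sets supplied; immune stage skipped.")
  } else {
    results$immune <- stage("immune", {
      markers <- read_gmt(config$markers)
      sc <- marker_scores(Y, markers)
      .write_tbl(tidy(sc), out("immune_marker_scores.tsv"))
      note("immune", out("immune_marker_scores.tsv"))
      if (!is.null(config$signature)) {
        S <- read_matrix_tsv(config$signature)
        fr <- deconvolve_fractions(Y, S, log2_input = TRUE)
        .write_tbl(tidy(fr), out("immune_fractions.tsv"))
        note("immune", out("immune_fractions.tsv"))
      } else {
        fr <- NULL
      }
      cors <- correlate_immune_lv(sc, B[sel_union, , drop = FALSE])
      .write_tbl(cors, out("immune_lv_correlation.tsv"))
      note("immune", out("immune_lv_correlation.tsv"))
      list(marker = sc, fractions = fr, correlation = cors)
    })
  }

  # -- regulon activity + clustering + drugs -------------------------
  if (is.null(config$regulons)) {
    inform("No regulon networks supplied; activity and cluster/drug stages skipped.")
  } else {
    results$activity <- stage("activity", {
      sig <- rank_signature(Y)
      nets <- lapply(config$regulons, read_regulons_json)
      acts <- lapply(nets, function(nw) regulon_activity(sig, nw))
      consensus <- metaviper_consensus(acts)
      write_matrix_tsv(consensus, out("activity.tsv"), id_name = "protein")
      note("activity", out("activity.tsv"))
      ac <- correlate_activity_lv(consensus, B[sel_union, , drop = FALSE],
                                  threshold = config$cor_threshold)
      .write_tbl(ac$counts, out("activity_correlation_counts.tsv"))
      note("activity", out("activity_correlation_counts.tsv"))
      list(consensus = consensus, correlation = ac)
    })

    results$clusters <- stage("cluster_drug", {
      ac <- results$activity$correlation
      cl <- cluster_lvs(ac, k = config$k_clusters)
      .write_tbl(cl$assignment, out("clusters.tsv"))
      note("cluster_drug", out("clusters.tsv"))
      rank_tbl <- consensus_protein_ranking(ac, cl)
      .write_tbl(rank_tbl, out("consensus_rankings.tsv"))
      note("cluster_drug", out("consensus_rankings.tsv"))
      expr_tbl <- cluster_expression_by_type(B, cl, meta)
      .write_tbl(expr_tbl, out("cluster_expression.tsv"))
      note("cluster_drug", out("cluster_expression.tsv"))
      enr <- NULL
      if (is.null(config$drug_sets)) {
        inform("No drug-target sets supplied; enrichment skipped.")
      } else {
        sets <- read_gmt(config$drug_sets)
        enr <- purrr::map_dfr(sort(unique(rank_tbl$cluster)), function(k) {
          r <- rank_tbl[rank_tbl$cluster == k, ]
          ranking <- setNames(r$mean_correlation, r$protein)
          de <- drug_enrichment(ranking, sets, n_perm = config$n_perm,
                                seed = config$seed + 400L + k)
          de$cluster <- k
          de
        })
        .write_tbl(enr, out("drug_enrichment.tsv"))
        note("cluster_drug", out("drug_enrichment.tsv"))
      }
      list(clusters = cl, ranking = rank_tbl, expression = expr_tbl,
           enrichment = enr)
    })
  }

  # -- variant association -------------------------------------------
  if (is.null(config$variants) || !file.exists(config$variants %||% "")) {
    inform("No variant table supplied; variant stage skipped.")
  } else {
    results$variants <- stage("variants", {
      maf <- read_maf(config$variants)
      assoc <- lv_variant_association(B, maf, meta,
                                      min_mutated = config$min_mutated,
                                      q_threshold = config$q_variant)
      .write_tbl(assoc, out("variant_association.tsv"))
      note("variants", out("variant_association.tsv"))
      assoc
    })
  }

  manifest <- dplyr::bind_rows(manifest)
  .write_tbl(manifest, out("manifest.tsv"))
  results$manifest <- manifest
  inform(sprintf("Pipeline complete: %d output files in %s.",
                 nrow(manifest), config$out_dir))
  invisible(results)
}

#' Write a self-contained synthetic input bundle
#'
#' Generates a synthetic model, cohort (with immune mixture, batch effect,
#' planted class LVs), two regulon networks, a variant table and drug
#' target sets, and writes them in the pipeline's file formats. The cohort
#' mirrors the class imbalance of an NF1 nerve sheath tumor collection
#' (cNF-heavy, one small class) at a desk-test scale.
#'
#' @param dir Directory to write into (created if absent).
#' @param seed Integer seed.
#' @param n_genes,n_lvs Model size (defaults 300 x 40).
#' @param n_per_class Named sample counts (default cNF 16, MPNST 8, NF 8,
#'   pNF 10).
#' @return Invisibly, a list of the written paths plus the ground `truth`.
#' @export
write_demo_inputs <- function(dir, seed = 1L, n_genes = 300, n_lvs = 40,
                              n_per_class = c(cNF = 16, MPNST = 8, NF = 8,
                                              pNF = 10)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- gen_model(n_genes, n_lvs, sparsity = 0.15, seed = seed)
  cohort <- gen_cohort(model, n_per_class, planted_per_class = 3,
                       effect_size = 3, noise_sd = 0.5, batch_shift = 1,
                       seed = seed + 1L)
  imm <- gen_immune_mixture(cohort$metadata, n_cell_types = 4,
                            markers_per_type = 8, seed = seed + 2L)
  Y <- rbind(cohort$expression, imm$expr_log2)

  nets <- lapply(1:2, function(k) {
    gen_regulons(15, 10, rownames(model$Z), prefix = sprintf("TF%d_", k),
                 seed = seed + 10L + k)
  })
  regulators <- unlist(lapply(nets, function(nw) {
    vapply(nw, function(r) r$regulator, character(1))
  }))
  drugs <- gen_drug_sets(8, 5, regulators, planted_drug_top_k = 10,
                         seed = seed + 20L)
  vs <- gen_variants(
    cohort$metadata,
    tibble::tibble(gene = c("NF1", "SUZ12"),
                   lv = rownames(cohort$B)[1:2],
                   shift = 2, n_carriers = c(8L, 6L)),
    background_rate = 0.01,
    background_genes = rownames(model$Z)[1:10],
    seed = seed + 30L)

  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    model = file.path(dir, "model.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    markers = file.path(dir, "markers.gmt"),
    signature = file.path(dir, "signature.tsv"),
    regulons = file.path(dir, c("network1.json", "network2.json")),
    drug_sets = file.path(dir, "drugs.gmt"),
    variants = file.path(dir, "variants.maf")
  )
  write_matrix_tsv(Y, paths$expression, id_name = "gene")
  write_plier_model(model, paths$model)
  .write_tbl(cohort$metadata, paths$metadata)
  write_gmt(imm$markers, paths$markers)
  write_matrix_tsv(imm$signature, paths$signature, id_name = "gene")
  write_regulons_json(nets[[1]], paths$regulons[1])
  write_regulons_json(nets[[2]], paths$regulons[2])
  write_gmt(drugs$sets, paths$drug_sets)
  write_maf(vs$variants, paths$variants)

  truth <- cohort$truth
  truth$mixing_fractions <- imm$fractions
  truth$effect_gene_lv_pairs <- vs$effect_pairs
  truth$enriched_drugs <- drugs$planted_drug
  c(paths, list(truth = truth, cohort = cohort, immune = imm,
                networks = nets, drugs = drugs, variant_sim = vs))
}
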