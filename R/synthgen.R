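# Synthetic-data generators with recorded ground truth. Every generator is a
# pure function of its arguments including `seed`, so reruns are
# byte-identical and downstream stages can be tested against known plantings.

#' Generate a sparse non-negative loading matrix
#'
#' Draws a PLIER-like model: entries are |Normal(0, 1)| masked by
#' Bernoulli(`sparsity`), so loadings are non-negative and sparse. Any LV
#' column left all-zero by the mask receives one positive entry so the model
#' stays valid.
#'
#' @param n_genes,n_lvs Matrix dimensions; `n_genes >= n_lvs >= 2`.
#' @param sparsity Expected fraction of nonzero entries, in (0, 1).
#' @param lambda2 Ridge constant stored with the model (default 1).
#' @param seed Integer seed.
#' @return A [new_plier_model()] object with genes `g0001...` and LVs
#'   `LV1...`.
#' @export
gen_model <- function(n_genes, n_lvs, sparsity = 0.1, lambda2 = 1,
                      seed = 1L) {
  n_genes <- assert_count(n_genes, 2)
  n_lvs <- assert_count(n_lvs, 2)
  if (n_genes < n_lvs) abort("`n_genes` must be >= `n_lvs`.")
  assert_fraction(sparsity)
  with_seed(seed, {
    mask <- matrix(rbinom(n_genes * n_lvs, 1L, sparsity), n_genes, n_lvs)
    Z <- abs(matrix(rnorm(n_genes * n_lvs), n_genes, n_lvs)) * mask
    empty <- which(colSums(Z != 0) == 0)
    for (j in empty) Z[sample.int(n_genes, 1L), j] <- abs(rnorm(1))
    dimnames(Z) <- list(sprintf("g%04d", seq_len(n_genes)),
                        paste0("LV", seq_len(n_lvs)))
    new_plier_model(Z, lambda2 = lambda2)
  })
}

#' Generate a synthetic tumor cohort with planted class signatures
#'
#' Simulates log2-scale expression `Y = Z B + noise` from a loading model.
#' LV scores `B` are standard normal; for each tumor class,
#' `planted_per_class` LV rows are shifted by `effect_size` standard
#' deviations in that class's samples (planted sets are disjoint across
#' classes). An optional additive batch effect is applied in gene space:
#' a fraction of genes receives a study-specific offset that grows by
#' `batch_shift` log2 units per study index.
#'
#' @param model A `plier_model`.
#' @param n_per_class Named integer vector, class -> sample count; at least
#'   two classes, each >= 1.
#' @param planted_per_class LVs planted per class (default 5).
#' @param effect_size Planted shift in LV-score SD units (default 3).
#' @param noise_sd Gene-space Gaussian noise SD (default 0.5).
#' @param batch_map Named character vector class -> study id; defaults to one
#'   study per class (fully confounded, the worst case for batch effects).
#' @param batch_shift Additive per-study offset in log2 units (default 0).
#' @param batch_gene_fraction Fraction of genes carrying the batch offset
#'   (default 0.3).
#' @param seed Integer seed.
#' @return A list with `expression` (genes x samples), `B` (true LV scores,
#'   LVs x samples), `metadata` (tibble: sample_id, tumor_type, study_id)
#'   and `truth` (a `synthetic_truth` record of all plantings).
#' @export
gen_cohort <- function(model, n_per_class, planted_per_class = 5,
                       effect_size = 3, noise_sd = 0.5, batch_map = NULL,
                       batch_shift = 0, batch_gene_fraction = 0.3,
                       seed = 1L) {
  validate_plier_model(model)
  if (is.null(names(n_per_class)) || length(n_per_class) < 2L) {
    abort("`n_per_class` must be a named vector covering >= 2 classes.")
  }
  if (any(n_per_class < 1)) abort("Every class needs at least one sample.")
  planted_per_class <- assert_count(planted_per_class, 0)
  n_lvs <- ncol(model$Z)
  classes <- names(n_per_class)
  if (planted_per_class * length(classes) > n_lvs) {
    abort("Not enough LVs for disjoint planted sets.")
  }
  batch_map <- batch_map %||%
    setNames(paste0("study", seq_along(classes)), classes)
  if (!all(classes %in% names(batch_map))) {
    abort("`batch_map` must name a study for every class.")
  }

  with_seed(seed, {
    n <- sum(n_per_class)
    sample_id <- sprintf("S%03d", seq_len(n))
    tumor_type <- rep(classes, times = n_per_class)
    study_id <- unname(batch_map[tumor_type])
    meta <- tibble::tibble(sample_id = sample_id, tumor_type = tumor_type,
                           study_id = study_id)

    B <- matrix(rnorm(n_lvs * n), n_lvs, n,
                dimnames = list(colnames(model$Z), sample_id))
    pool <- colnames(model$Z)
    planted <- list()
    for (cl in classes) {
      lvs <- if (planted_per_class > 0) sample(pool, planted_per_class)
             else character(0)
      pool <- setdiff(pool, lvs)
      planted[[cl]] <- sort(lvs)
      B[lvs, tumor_type == cl] <- B[lvs, tumor_type == cl] + effect_size
    }

    Y <- model$Z %*% B
    if (noise_sd > 0) Y <- Y + matrix(rnorm(length(Y), 0, noise_sd), nrow(Y))

    batch_genes <- character(0)
    if (batch_shift != 0) {
      batch_genes <- sort(sample(rownames(model$Z),
                                 ceiling(batch_gene_fraction * nrow(model$Z))))
      studies <- unique(study_id)
      for (k in seq_along(studies)) {
        cols <- study_id == studies[k]
        Y[batch_genes, cols] <- Y[batch_genes, cols] + (k - 1) * batch_shift
      }
    }

    truth <- structure(
      list(planted_lvs_per_class = planted,
           effect_size = effect_size,
           batch_shift_genes = batch_genes,
           batch_shift = batch_shift,
           mixing_fractions = NULL,
           effect_gene_lv_pairs = NULL,
           enriched_drugs = character(0),
           seed = seed),
      class = "synthetic_truth"
    )
    list(expression = Y, B = B, metadata = meta, truth = truth)
  })
}

#' Generate random regulons
#'
#' Each regulator gets `targets_per_regulon` distinct targets drawn from the
#' gene universe, modes drawn from \{-1, +1\} (activating with probability
#' `activation_prob`) and Uniform(0.5, 1) likelihood weights.
#'
#' @param n_regulators,targets_per_regulon Counts.
#' @param gene_universe Character vector of available gene ids.
#' @param activation_prob Probability of mode +1 (default 0.7).
#' @param prefix Regulator id prefix (default "TF").
#' @param seed Integer seed.
#' @return A list of [new_regulon()] objects.
#' @export
gen_regulons <- function(n_regulators, targets_per_regulon, gene_universe,
                         activation_prob = 0.7, prefix = "TF", seed = 1L) {
  n_regulators <- assert_count(n_regulators)
  targets_per_regulon <- assert_count(targets_per_regulon, 2)
  if (length(gene_universe) < targets_per_regulon) {
    abort("Gene universe smaller than `targets_per_regulon`.")
  }
  with_seed(seed, {
    lapply(seq_len(n_regulators), function(i) {
      genes <- sample(gene_universe, targets_per_regulon)
      new_regulon(
        sprintf("%s%03d", prefix, i),
        tibble::tibble(
          gene = genes,
          mode = ifelse(runif(targets_per_regulon) < activation_prob, 1, -1),
          likelihood = runif(targets_per_regulon, 0.5, 1)
        )
      )
    })
  })
}

#' Generate a variant table with planted LV-shifting genes
#'
#' For each effect pair a carrier set is drawn from the cohort's samples;
#' carriers receive a non-silent variant call in the effect gene. Background
#' noise adds variants in `background_genes` independently at
#' `background_rate` per (sample, gene). Apply the planted LV shifts to a
#' score matrix with [apply_variant_effects()].
#'
#' @param meta Sample metadata tibble (see [gen_cohort()]).
#' @param effect_pairs Tibble with columns `gene`, `lv`, `shift`
#'   (LV-score SD units) and `n_carriers`.
#' @param background_rate Per-(sample, gene) background variant probability.
#' @param background_genes Genes eligible for background variants.
#' @param seed Integer seed.
#' @return A `variant_sim` list: `variants` (MAF-style tibble), `carriers`
#'   (gene -> sample ids) and `effect_pairs`.
#' @export
gen_variants <- function(meta, effect_pairs, background_rate = 0.02,
                         background_genes = character(0), seed = 1L) {
  assert_metadata(meta)
  assert_fraction(background_rate, open_left = FALSE, open_right = FALSE)
  effect_pairs <- tibble::as_tibble(effect_pairs)
  if (nrow(effect_pairs) &&
      !all(c("gene", "lv", "shift", "n_carriers") %in% names(effect_pairs))) {
    abort("`effect_pairs` needs columns gene, lv, shift, n_carriers.")
  }
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Splice_Site")
  with_seed(seed, {
    rows <- list()
    carriers <- list()
    for (i in seq_len(nrow(effect_pairs))) {
      p <- effect_pairs[i, ]
      if (p$n_carriers > nrow(meta)) abort("More carriers than samples.")
      who <- sort(sample(meta$sample_id, p$n_carriers))
      carriers[[p$gene]] <- who
      rows[[length(rows) + 1L]] <- tibble::tibble(
        Tumor_Sample_Barcode = who,
        Hugo_Symbol = p$gene,
        Variant_Classification = sample(classes, length(who), replace = TRUE)
      )
    }
    if (background_rate > 0 && length(background_genes)) {
      grid <- expand.grid(sample = meta$sample_id, gene = background_genes,
                          stringsAsFactors = FALSE)
      hit <- runif(nrow(grid)) < background_rate
      if (any(hit)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          Tumor_Sample_Barcode = grid$sample[hit],
          Hugo_Symbol = grid$gene[hit],
          Variant_Classification = sample(classes, sum(hit), replace = TRUE)
        )
      }
    }
    variants <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(Tumor_Sample_Barcode = character(0),
                     Hugo_Symbol = character(0),
                     Variant_Classification = character(0))
    structure(list(variants = variants, carriers = carriers,
                   effect_pairs = effect_pairs, seed = seed),
              class = "variant_sim")
  })
}

#' @param B LV-score matrix (LVs x samples) to shift in place.
#' @param sim A `variant_sim` from [gen_variants()].
#' @rdname gen_variants
#' @export
apply_variant_effects <- function(B, sim) {
  stopifnot(inherits(sim, "variant_sim"))
  assert_named_matrix(B, "B")
  for (i in seq_len(nrow(sim$effect_pairs))) {
    p <- sim$effect_pairs[i, ]
    who <- intersect(sim$carriers[[p$gene]], colnames(B))
    B[p$lv, who] <- B[p$lv, who] + p$shift * sd(B[p$lv, ])
  }
  B
}

#' Generate drug-target sets with one planted enriched drug
#'
#' The first `planted_drug_top_k` proteins of `protein_universe` form the
#' "top" stratum (the universe is taken in ranking order). The planted
#' drug's targets are drawn from that stratum; all other drugs draw targets
#' uniformly from the whole universe, so only the planted drug is enriched
#' near the top of a concordant ranking.
#'
#' @param n_drugs,targets_per_drug Counts.
#' @param protein_universe Protein ids in descending ranking order.
#' @param planted_drug_top_k Size of the top stratum; must be >=
#'   `targets_per_drug`.
#' @param seed Integer seed.
#' @return A list: `sets` (drug -> protein ids), `planted_drug`,
#'   `top_stratum`.
#' @export
gen_drug_sets <- function(n_drugs, targets_per_drug, protein_universe,
                          planted_drug_top_k, seed = 1L) {
  n_drugs <- assert_count(n_drugs)
  targets_per_drug <- assert_count(targets_per_drug)
  planted_drug_top_k <- assert_count(planted_drug_top_k)
  if (length(protein_universe) < targets_per_drug ||
      planted_drug_top_k < targets_per_drug ||
      planted_drug_top_k > length(protein_universe)) {
    abort("Protein universe or top stratum smaller than requested set sizes.")
  }
  with_seed(seed, {
    stratum <- protein_universe[seq_len(planted_drug_top_k)]
    sets <- lapply(seq_len(n_drugs), function(i) {
      sort(sample(protein_universe, targets_per_drug))
    })
    names(sets) <- sprintf("drug%03d", seq_len(n_drugs))
    planted <- "drug001"
    sets[[planted]] <- sort(sample(stratum, targets_per_drug))
    list(sets = sets, planted_drug = planted, top_stratum = stratum)
  })
}

#' Generate an immune-cell mixture over marker genes
#'
#' Draws per-sample cell-type fractions from a symmetric Dirichlet, builds
#' disjoint marker sets and a non-negative signature matrix (markers of a
#' type are high in that type, low elsewhere), and produces two views of the
#' marker block: a linear-scale mixture `S f` with Gaussian noise (for
#' deconvolution) and a log2-scale block whose marker expression increases
#' linearly with the owning type's fraction (for marker scores).
#'
#' @param meta Sample metadata tibble.
#' @param n_cell_types,markers_per_type Counts.
#' @param noise_sd Noise SD on the log2 marker block (default 0.1).
#' @param alpha Dirichlet concentration (default 1, uniform on the simplex).
#' @param seed Integer seed.
#' @return List: `fractions` (cell types x samples, columns sum to 1),
#'   `markers` (named list), `signature` (markers x cell types, linear
#'   scale), `expr_log2`, `expr_linear` (markers x samples).
#' @export
gen_immune_mixture <- function(meta, n_cell_types = 4, markers_per_type = 10,
                               noise_sd = 0.1, alpha = 1, seed = 1L) {
  assert_metadata(meta)
  n_cell_types <- assert_count(n_cell_types, 2)
  markers_per_type <- assert_count(markers_per_type)
  with_seed(seed, {
    types <- paste0("celltype", seq_len(n_cell_types))
    n <- nrow(meta)
    F <- matrix(rgamma(n_cell_types * n, shape = alpha), n_cell_types, n)
    F <- sweep(F, 2, colSums(F), "/")
    dimnames(F) <- list(types, meta$sample_id)

    markers <- lapply(seq_len(n_cell_types), function(t) {
      sprintf("IMM_T%d_M%02d", t, seq_len(markers_per_type))
    })
    names(markers) <- types
    genes <- unlist(markers, use.names = FALSE)

    S <- matrix(5, length(genes), n_cell_types,
                dimnames = list(genes, types))
    for (t in seq_len(n_cell_types)) {
      S[markers[[t]], t] <- 100 + runif(markers_per_type, 0, 20)
    }

    lin <- S %*% F
    lin <- lin + matrix(rnorm(length(lin), 0, noise_sd * 5), nrow(lin))
    lin[lin < 0] <- 0

    log2b <- matrix(2, length(genes), n, dimnames = list(genes, meta$sample_id))
    for (t in seq_len(n_cell_types)) {
      log2b[markers[[t]], ] <- 2 +
        3 * matrix(rep(F[t, ], each = markers_per_type), markers_per_type) +
        matrix(rnorm(markers_per_type * n, 0, noise_sd), markers_per_type)
    }

    list(fractions = F, markers = markers, signature = S,
         expr_log2 = log2b, expr_linear = lin)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  for (cl in names(x$planted_lvs_per_class)) {
    cat(sprintf("  %s: %s\n", cl,
                paste(x$planted_lvs_per_class[[cl]], collapse = ", ")))
  }
  cat(sprintf("  effect %g SD, batch shift %g on %d genes, seed %d\n",
              x$effect_size, x$batch_shift, length(x$batch_shift_genes),
              x$seed))
  invisible(x)
}
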