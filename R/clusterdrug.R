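# Clustering of LVs by their protein-activity correlation profiles,
# per-cluster consensus protein rankings, preranked drug-target set
# enrichment (weighted Kolmogorov-Smirnov with label permutation), and
# per-cluster mean LV expression by tumor type.

#' Cluster latent variables by correlation profiles
#'
#' Agglomerative hierarchical clustering of the LV rows of a correlation
#' matrix (Euclidean distance, complete linkage), cut into `k` groups.
#' Missing correlations are imputed as 0 before clustering (reported).
#'
#' @param corr LV x protein correlation matrix (e.g.
#'   `correlate_activity_lv()$correlation`).
#' @param k Number of clusters (default 5).
#' @return An `lv_clusters` list: `assignment` (tibble lv, cluster),
#'   `tree` (hclust), `k`.
#' @export
cluster_lvs <- function(corr, k = 5) {
  if (inherits(corr, "activity_correlation")) corr <- corr$correlation
  k <- assert_count(k)
  if (!is.matrix(corr) || is.null(rownames(corr))) {
    abort("`corr` must be a matrix with LV row names.")
  }
  if (k > nrow(corr)) abort("`k` exceeds the number of LVs.")
  if (anyNA(corr)) {
    inform(sprintf("%d NA correlations imputed as 0 before clustering.",
                   sum(is.na(corr))))
    corr[is.na(corr)] <- 0
  }
  tree <- hclust(dist(corr), method = "complete")
  cl <- cutree(tree, k = k)
  structure(
    list(assignment = tibble::tibble(lv = names(cl), cluster = unname(cl)),
         tree = tree, k = k),
    class = "lv_clusters"
  )
}

#' @export
print.lv_clusters <- function(x, ...) {
  cat(sprintf("<lv_clusters> %d LVs in %d clusters (sizes: %s)\n",
              nrow(x$assignment), x$k,
              paste(table(x$assignment$cluster), collapse = ", ")))
  invisible(x)
}

#' Per-cluster consensus protein ranking
#'
#' For each cluster, each protein's consensus score is the arithmetic mean
#' of its correlations over the cluster's LVs; proteins are returned sorted
#' by descending score within cluster.
#'
#' @param corr LV x protein correlation matrix.
#' @param clusters An `lv_clusters` object covering `corr`'s LVs.
#' @return Tibble: cluster, protein, mean_correlation (sorted descending
#'   within cluster).
#' @export
consensus_protein_ranking <- function(corr, clusters) {
  if (inherits(corr, "activity_correlation")) corr <- corr$correlation
  stopifnot(inherits(clusters, "lv_clusters"))
  asg <- clusters$assignment
  if (!all(asg$lv %in% rownames(corr))) {
    abort("Cluster assignment names LVs absent from `corr`.")
  }
  purrr::map_dfr(sort(unique(asg$cluster)), function(cl) {
    lvs <- asg$lv[asg$cluster == cl]
    m <- colMeans(corr[lvs, , drop = FALSE], na.rm = TRUE)
    tibble::tibble(cluster = cl, protein = names(m),
                   mean_correlation = unname(m)) |>
      dplyr::arrange(dplyr::desc(.data$mean_correlation), .data$protein)
  })
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score (weight =
# |score|^1) of set-membership positions within a descending ranking.
.gsea_es <- function(in_set, weights) {
  n <- length(in_set)
  nh <- sum(in_set)
  nr <- sum(weights[in_set])
  hit <- if (nr > 0) ifelse(in_set, weights / nr, 0) else
    ifelse(in_set, 1 / nh, 0)
  miss <- ifelse(in_set, 0, 1 / (n - nh))
  run <- cumsum(hit - miss)
  run[which.max(abs(run))]
}

#' Preranked drug-target set enrichment
#'
#' Sorts proteins by score descending (ties by protein id) and computes the
#' weighted Kolmogorov-Smirnov enrichment score (weight exponent 1) for
#' each drug's target set. The p-value comes from `n_perm` random
#' placements of the set in the ranking (one-sided toward positive
#' enrichment, as only positively enriched drugs are called); with
#' `exact = TRUE` all placements are enumerated instead. Benjamini-Hochberg
#' adjustment is applied across drugs; a drug is significant when `ES > 0`
#' and `q < q_threshold`.
#'
#' @param ranking Named numeric vector, protein -> score (e.g. one
#'   cluster's consensus ranking).
#' @param drug_sets Named list, drug -> character vector of target
#'   proteins. Drugs with no target in the ranking are dropped (reported);
#'   sets covering the whole universe are skipped.
#' @param n_perm Number of permutations (default 10000).
#' @param q_threshold BH significance cutoff (default 0.05).
#' @param exact Enumerate all placements (only feasible for tiny
#'   universes)?
#' @param seed Integer seed for the permutations.
#' @return Tibble: drug, n_targets, es, p, q_bh, significant.
#' @export
drug_enrichment <- function(ranking, drug_sets, n_perm = 10000,
                            q_threshold = 0.05, exact = FALSE, seed = 1L) {
  if (!is.numeric(ranking) || is.null(names(ranking)) ||
      length(ranking) < 2L) {
    abort("`ranking` must be a named numeric vector with >= 2 proteins.")
  }
  stopifnot(is.list(drug_sets), !is.null(names(drug_sets)))
  ord <- order(-ranking, names(ranking))
  scores <- ranking[ord]
  universe <- names(scores)
  weights <- abs(scores)
  n <- length(universe)

  kept <- list()
  for (d in names(drug_sets)) {
    tg <- intersect(drug_sets[[d]], universe)
    if (!length(tg)) {
      inform(sprintf("Drug '%s' has no target in the ranking; dropped.", d))
    } else if (length(tg) == n) {
      warn(sprintf("Drug '%s' targets the whole universe; skipped.", d))
    } else {
      kept[[d]] <- tg
    }
  }
  if (!length(kept)) abort("No testable drug set.")

  res <- with_seed(seed, {
    purrr::map_dfr(names(kept), function(d) {
      tg <- kept[[d]]
      in_set <- universe %in% tg
      es <- .gsea_es(in_set, weights)
      k <- length(tg)
      if (exact) {
        placements <- combn(n, k)
        es_null <- apply(placements, 2L, function(pos) {
          v <- logical(n)
          v[pos] <- TRUE
          .gsea_es(v, weights)
        })
        p <- mean(es_null >= es)
      } else {
        es_null <- vapply(seq_len(n_perm), function(i) {
          v <- logical(n)
          v[sample.int(n, k)] <- TRUE
          .gsea_es(v, weights)
        }, numeric(1))
        p <- (1 + sum(es_null >= es)) / (n_perm + 1)
      }
      tibble::tibble(drug = d, n_targets = k, es = es, p = p)
    })
  })
  res$q_bh <- p.adjust(res$p, method = "BH")
  res$significant <- res$es > 0 & res$q_bh < q_threshold
  res
}

#' Mean cluster expression per sample and tumor type
#'
#' For each (cluster, sample) the arithmetic mean of the cluster's LV
#' scores, joined with the sample's tumor type — the summary behind
#' per-cluster expression comparisons across tumor types.
#'
#' @param B LVs x samples score matrix.
#' @param clusters An `lv_clusters` object whose LVs are rows of `B`.
#' @param meta Sample metadata; samples missing from it are dropped with a
#'   warning.
#' @return Tibble: cluster, sample_id, tumor_type, mean_expression.
#' @export
cluster_expression_by_type <- function(B, clusters, meta) {
  assert_named_matrix(B, "B")
  stopifnot(inherits(clusters, "lv_clusters"))
  assert_metadata(meta)
  asg <- clusters$assignment
  if (!all(asg$lv %in% rownames(B))) {
    abort("Cluster assignment names LVs absent from `B`.")
  }
  missing <- setdiff(colnames(B), meta$sample_id)
  if (length(missing)) {
    warn(sprintf("%d sample(s) missing from metadata dropped.",
                 length(missing)))
  }
  samples <- intersect(colnames(B), meta$sample_id)
  purrr::map_dfr(sort(unique(asg$cluster)), function(cl) {
    lvs <- asg$lv[asg$cluster == cl]
    m <- colMeans(B[lvs, samples, drop = FALSE])
    tibble::tibble(cluster = cl, sample_id = samples,
                   mean_expression = unname(m))
  }) |>
    dplyr::left_join(meta[, c("sample_id", "tumor_type")], by = "sample_id") |>
    dplyr::select("cluster", "sample_id", "tumor_type", "mean_expression")
}
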