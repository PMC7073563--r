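# Latent-variable space: gene standardization, ridge projection onto the
# transferred loading matrix, LV deduplication, variability report, and the
# PCA-based batch-effect comparison between gene space and LV space.

#' Z-score expression rows
#'
#' Standardizes each gene row to mean 0 and sample SD 1, the convention the
#' ridge projection assumes. Rows with zero variance are set to all-zero and
#' flagged in the `"zero_variance"` attribute.
#'
#' @param Y Genes x samples numeric matrix (log2 scale), >= 2 samples.
#' @return The standardized matrix, with attribute `zero_variance` listing
#'   flagged genes.
#' @export
zscore_genes <- function(Y) {
  assert_named_matrix(Y, "Y")
  if (ncol(Y) < 2L) abort("Need >= 2 samples to standardize (SD undefined).")
  mu <- rowMeans(Y)
  s <- apply(Y, 1L, sd)
  flat <- s == 0
  s[flat] <- 1
  Z <- (Y - mu) / s
  Z[flat, ] <- 0
  if (any(flat)) {
    inform(sprintf("%d zero-variance gene(s) set to 0.", sum(flat)))
  }
  attr(Z, "zero_variance") <- rownames(Y)[flat]
  Z
}

#' Project expression into latent-variable space
#'
#' Ridge-regularized projection onto the model's loadings:
#' `B = (Z'Z + lambda2 I)^{-1} Z' Y'`, where `Y'` is the standardized input
#' restricted to the model's genes (genes absent from the input are filled
#' with 0, the post-standardization mean).
#'
#' @param model A `plier_model`.
#' @param Y Standardized genes x samples matrix (see [zscore_genes()]).
#' @param min_overlap Minimum fraction of model genes that must be present
#'   in `Y` (default 0.2).
#' @return LVs x samples score matrix.
#' @export
project_lv <- function(model, Y, min_overlap = 0.2) {
  validate_plier_model(model)
  assert_named_matrix(Y, "Y")
  shared <- intersect(rownames(model$Z), rownames(Y))
  overlap <- length(shared) / nrow(model$Z)
  if (overlap < min_overlap) {
    abort(sprintf(
      "Gene overlap with the model is %.1f%% (< %.1f%% required).",
      100 * overlap, 100 * min_overlap))
  }
  Yp <- matrix(0, nrow(model$Z), ncol(Y),
               dimnames = list(rownames(model$Z), colnames(Y)))
  Yp[shared, ] <- Y[shared, , drop = FALSE]
  A <- crossprod(model$Z) + model$lambda2 * diag(ncol(model$Z))
  B <- solve(A, crossprod(model$Z, Yp))
  dimnames(B) <- list(colnames(model$Z), colnames(Y))
  B
}

#' Deduplicate correlated latent variables
#'
#' Scans LVs in ascending column order and drops any LV whose loading
#' column has Pearson correlation above `threshold` with an already-retained
#' LV, so the retained set has all pairwise loading correlations <=
#' `threshold`. The greedy ascending rule (keep the earlier-indexed member
#' of each offending pair) makes the result deterministic.
#'
#' @param model A `plier_model`.
#' @param threshold Correlation cutoff in (0, 1] (default 0.5).
#' @return Character vector of retained LV ids, in column order.
#' @export
dedup_lvs <- function(model, threshold = 0.5) {
  validate_plier_model(model)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].")
  }
  Z <- model$Z
  lvs <- colnames(Z)
  # constant columns have undefined correlation; treat as uncorrelated
  sds <- apply(Z, 2L, sd)
  C <- suppressWarnings(cor(Z))
  C[is.na(C)] <- 0
  keep <- logical(length(lvs))
  for (i in seq_along(lvs)) {
    prior <- which(keep)
    keep[i] <- !length(prior) || all(C[i, prior] <= threshold)
  }
  lvs[keep]
}

#' Report the most variable latent variables
#'
#' Returns the `ceil(fraction * n_lvs)` LVs with the largest across-sample
#' standard deviation; ties are broken by LV id.
#'
#' @param B LVs x samples score matrix with >= 2 samples.
#' @param fraction Fraction of LVs to report, in (0, 1] (default 0.05).
#' @return Character vector of LV ids.
#' @export
top_variable_lvs <- function(B, fraction = 0.05) {
  assert_named_matrix(B, "B")
  if (ncol(B) < 2L) abort("Need >= 2 samples.")
  assert_fraction(fraction, open_right = FALSE)
  n <- ceiling(fraction * nrow(B))
  s <- apply(B, 1L, sd)
  ord <- order(-s, rownames(B))
  rownames(B)[ord][seq_len(n)]
}

# Normalized within-study pairwise distances over the first n_pcs principal
# component scores of `mat` (features x samples). Studies with one sample
# are skipped with a warning.
.within_study_distances <- function(mat, meta, n_pcs, space) {
  m <- meta[match(colnames(mat), meta$sample_id), ]
  pr <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pr$x))
  sc <- pr$x[, seq_len(k), drop = FALSE]
  overall <- as.vector(dist(sc))
  within <- numeric(0)
  used <- FALSE
  for (st in unique(m$study_id)) {
    idx <- which(m$study_id == st)
    if (length(idx) < 2L) {
      warn(sprintf("Study '%s' has one sample; skipped in %s space.",
                   st, space))
      next
    }
    used <- TRUE
    within <- c(within, as.vector(dist(sc[idx, , drop = FALSE])))
  }
  if (!used) abort("All studies have fewer than 2 samples.")
  within / mean(overall)
}

#' Compare batch structure in gene space versus LV space
#'
#' Runs centered PCA separately on the gene-space and LV-space matrices
#' (samples as observations), collects all within-study pairwise Euclidean
#' distances over the first `n_pcs` scores, normalizes each space's
#' distances by that space's mean overall pairwise distance (the two spaces
#' have incommensurable scales), and compares the two normalized distance
#' sets with a two-sided Wilcoxon rank-sum test. Smaller LV-space distances
#' indicate that projection attenuated the batch effect.
#'
#' @param Y Genes x samples expression matrix.
#' @param B LVs x samples score matrix over the same samples.
#' @param meta Sample metadata with `study_id`.
#' @param n_pcs Number of principal components to use (default 2).
#' @return A `batch_assessment` list: `distances_gene`, `distances_lv`,
#'   `p_value`, `statistic`.
#' @export
pca_batch_assessment <- function(Y, B, meta, n_pcs = 2) {
  assert_named_matrix(Y, "Y")
  assert_named_matrix(B, "B")
  assert_metadata(meta)
  n_pcs <- assert_count(n_pcs)
  shared <- intersect(colnames(Y), colnames(B))
  shared <- intersect(shared, meta$sample_id)
  if (length(shared) < 4L) abort("Need >= 4 shared samples.")
  Y <- Y[, shared, drop = FALSE]
  B <- B[, shared, drop = FALSE]
  dg <- .within_study_distances(Y, meta, n_pcs, "gene")
  dl <- .within_study_distances(B, meta, n_pcs, "LV")
  wt <- suppressWarnings(wilcox.test(dg, dl, alternative = "two.sided",
                                     exact = FALSE, correct = FALSE))
  structure(
    list(distances_gene = dg, distances_lv = dl,
         p_value = wt$p.value, statistic = unname(wt$statistic)),
    class = "batch_assessment"
  )
}

#' @export
print.batch_assessment <- function(x, ...) {
  cat(sprintf(
    "<batch_assessment> median within-study distance gene %.3f vs LV %.3f, Wilcoxon p = %.3g\n",
    median(x$distances_gene), median(x$distances_lv), x$p_value))
  invisible(x)
}

#' @method tidy batch_assessment
#' @export
tidy.batch_assessment <- function(x, ...) {
  tibble::tibble(
    space = c("gene", "lv"),
    n_pairs = c(length(x$distances_gene), length(x$distances_lv)),
    median_within_distance = c(median(x$distances_gene),
                               median(x$distances_lv)),
    p_value = x$p_value
  )
}
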