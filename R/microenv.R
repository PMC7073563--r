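# Tumor-microenvironment scoring: marker-based abundance scores (the
# MCP-counter estimator — arithmetic mean of log2 marker expression),
# constrained-least-squares deconvolution against a signature matrix, and
# correlation of immune scores with latent-variable expression.

#' Marker-based immune-cell scores
#'
#' For each cell type, the score of a sample is the arithmetic mean of the
#' log2 expression of that type's marker genes present in the input.
#' Missing markers are reported via the `"missing_markers"` attribute; a
#' set with no genes in the input is omitted with a warning.
#'
#' @param Y Genes x samples log2 expression matrix.
#' @param markers Named list, cell type -> character vector of marker genes.
#' @return An `immune_scores` object: cell-type x sample matrix with
#'   `method = "marker"`.
#' @export
marker_scores <- function(Y, markers) {
  assert_named_matrix(Y, "Y")
  stopifnot(is.list(markers), !is.null(names(markers)))
  rows <- list()
  missing <- list()
  for (ct in names(markers)) {
    present <- intersect(markers[[ct]], rownames(Y))
    gone <- setdiff(markers[[ct]], rownames(Y))
    if (length(gone)) missing[[ct]] <- gone
    if (!length(present)) {
      warn(sprintf("No markers of '%s' found in the expression matrix; omitted.",
                   ct))
      next
    }
    rows[[ct]] <- colMeans(Y[present, , drop = FALSE])
  }
  if (!length(rows)) abort("No marker set overlaps the expression matrix.")
  scores <- do.call(rbind, rows)
  dimnames(scores) <- list(names(rows), colnames(Y))
  structure(list(scores = scores, method = "marker", rmse = NULL,
                 missing_markers = missing),
            class = "immune_scores")
}

#' Constrained-least-squares cell-fraction deconvolution
#'
#' Per sample, solves `min || S f - y ||_2` subject to `f >= 0` over the
#' genes shared between the signature matrix and the input, then normalizes
#' `f` to sum to 1 (an all-zero solution stays zero). Input on log2 scale is
#' unlogged (`2^Y`) before fitting since the mixture model is linear.
#'
#' @param Y Genes x samples expression matrix.
#' @param S Genes x cell-types signature matrix (linear scale,
#'   non-negative).
#' @param log2_input Is `Y` on log2 scale? (default `FALSE` — already
#'   linear.)
#' @param min_overlap Minimum fraction of signature genes that must be in
#'   `Y` (default 0.5).
#' @return An `immune_scores` object with `method = "fractions"` and a
#'   per-sample `rmse` vector.
#' @export
deconvolve_fractions <- function(Y, S, log2_input = FALSE,
                                 min_overlap = 0.5) {
  assert_named_matrix(Y, "Y")
  assert_named_matrix(S, "S")
  if (any(S < 0)) abort("Signature matrix must be non-negative.")
  shared <- intersect(rownames(S), rownames(Y))
  if (length(shared) / nrow(S) < min_overlap) {
    abort(sprintf("Only %.0f%% of signature genes found (need >= %.0f%%).",
                  100 * length(shared) / nrow(S), 100 * min_overlap))
  }
  Ys <- Y[shared, , drop = FALSE]
  if (log2_input) Ys <- 2^Ys
  Ss <- S[shared, , drop = FALSE]
  fracs <- matrix(0, ncol(S), ncol(Y),
                  dimnames = list(colnames(S), colnames(Y)))
  rmse <- setNames(numeric(ncol(Y)), colnames(Y))
  for (j in seq_len(ncol(Ys))) {
    fit <- pracma::lsqnonneg(Ss, Ys[, j])
    f <- fit$x
    rmse[j] <- sqrt(mean((Ss %*% f - Ys[, j])^2))
    if (sum(f) > 0) f <- f / sum(f)
    fracs[, j] <- f
  }
  structure(list(scores = fracs, method = "fractions", rmse = rmse,
                 missing_markers = NULL),
            class = "immune_scores")
}

#' @export
print.immune_scores <- function(x, ...) {
  cat(sprintf("<immune_scores> %d cell types x %d samples (%s)\n",
              nrow(x$scores), ncol(x$scores), x$method))
  invisible(x)
}

#' @method tidy immune_scores
#' @export
tidy.immune_scores <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "cell_type") |>
    tidyr::pivot_longer(-"cell_type", names_to = "sample_id",
                        values_to = "score") |>
    dplyr::mutate(method = x$method)
}

# Correlate rows of two matrices over shared samples; returns a long tibble
# with BH q-values across all testable pairs. Constant vectors yield r = NA
# and are excluded from BH.
.correlate_rows <- function(A, B, a_name, b_name, method, min_shared = 3L) {
  shared <- intersect(colnames(A), colnames(B))
  if (length(shared) < min_shared) {
    abort(sprintf("Need >= %d shared samples.", min_shared))
  }
  A <- A[, shared, drop = FALSE]
  B <- B[, shared, drop = FALSE]
  grid <- expand.grid(a = rownames(A), b = rownames(B),
                      stringsAsFactors = FALSE)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    va <- A[grid$a[i], ]
    vb <- B[grid$b[i], ]
    if (sd(va) == 0 || sd(vb) == 0) {
      return(tibble::tibble(r = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(va, vb, method = method, exact = FALSE))
    tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- tibble::tibble(grid$a, grid$b, r = res$r, p = res$p)
  names(out)[1:2] <- c(a_name, b_name)
  out$q_bh <- NA_real_
  ok <- !is.na(out$p)
  out$q_bh[ok] <- p.adjust(out$p[ok], method = "BH")
  out$n <- length(shared)
  out
}

#' Correlate immune scores with latent-variable expression
#'
#' Computes the correlation of every (LV, cell type) pair over shared
#' samples — optionally within each tumor type — with Benjamini-Hochberg
#' q-values across all reported pairs. Pairs with a constant vector are
#' reported with `r = NA` and excluded from the BH adjustment.
#'
#' @param scores An `immune_scores` object (or cell-type x sample matrix).
#' @param B LVs x samples score matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param meta Optional metadata; with `group_by_type = TRUE` correlations
#'   are computed within each tumor type.
#' @param group_by_type Group correlations by tumor type?
#' @return Tibble: lv, cell_type, (tumor_type,) r, p, q_bh, n.
#' @export
correlate_immune_lv <- function(scores, B, method = c("pearson", "spearman"),
                                meta = NULL, group_by_type = FALSE) {
  method <- match.arg(method)
  S <- if (inherits(scores, "immune_scores")) scores$scores else scores
  assert_named_matrix(S, "scores")
  assert_named_matrix(B, "B")
  if (!group_by_type) {
    out <- .correlate_rows(B, S, "lv", "cell_type", method)
    return(out)
  }
  if (is.null(meta)) abort("Grouping by tumor type requires `meta`.")
  assert_metadata(meta)
  groups <- unique(meta$tumor_type)
  res <- purrr::map_dfr(groups, function(g) {
    ids <- meta$sample_id[meta$tumor_type == g]
    ids <- intersect(ids, intersect(colnames(B), colnames(S)))
    if (length(ids) < 3L) return(NULL)
    out <- .correlate_rows(B[, ids, drop = FALSE], S[, ids, drop = FALSE],
                           "lv", "cell_type", method)
    out$tumor_type <- g
    out
  })
  # BH across all grouped pairs jointly
  res$q_bh <- NA_real_
  ok <- !is.na(res$p)
  res$q_bh[ok] <- p.adjust(res$p[ok], method = "BH")
  res
}
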