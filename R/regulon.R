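# Regulon-activity inference: per-sample rank signatures, an analytic
# normalized enrichment score per regulon (one-tail, mode-weighted), a
# multi-network consensus, and Spearman correlation of protein activity
# with latent-variable expression.

#' Rank-transform expression into per-sample gene signatures
#'
#' Per sample, genes are ranked across genes (ties get average ranks),
#' ranks are mapped to (0, 1) by `(rank - 0.5) / n` and then to
#' standard-normal quantiles. An all-equal sample yields an all-zero
#' signature with a warning.
#'
#' @param Y Genes x samples expression matrix with >= 3 genes.
#' @return Genes x samples signature matrix.
#' @export
rank_signature <- function(Y) {
  assert_named_matrix(Y, "Y")
  if (nrow(Y) < 3L) abort("Need >= 3 genes.")
  n <- nrow(Y)
  sig <- apply(Y, 2L, function(y) {
    if (length(unique(y)) == 1L) {
      warn("All-equal expression column; signature set to zero.")
      return(rep(0, n))
    }
    qnorm((rank(y, ties.method = "average") - 0.5) / n)
  })
  dimnames(sig) <- dimnames(Y)
  sig
}

#' Analytic normalized enrichment score of a regulon
#'
#' The enrichment score of a sample is the likelihood-weighted,
#' mode-signed mean of the signature over the regulon's targets,
#' `ES = sum(l_i m_i s_i) / sum(l_i)`. The NES standardizes `ES` against
#' its analytic null: under a random signature the targets are a simple
#' random sample (without replacement) from the sample's `N` signature
#' values, so with normalized weights `w` and modes `m`,
#' `E[ES] = mu * sum(w m)` and
#' `Var(ES) = sigma^2 * (sum(w^2) (1 + 1/(N-1)) - (sum(w m))^2 / (N-1))`,
#' where `mu` and `sigma^2` are the mean and population variance of the
#' signature column. For rank signatures `mu ~ 0` and, as the gene count
#' grows, this converges to the independent-standard-normal variance
#' `sum(w^2)`; the finite-population form keeps the NES calibrated to a
#' standard-normal null even for small gene sets.
#'
#' @param signature Genes x samples signature matrix from
#'   [rank_signature()].
#' @param regulon A [new_regulon()] object; at least 2 targets must be
#'   present in the signature.
#' @return Named numeric vector of per-sample NES.
#' @export
area_nes <- function(signature, regulon) {
  assert_named_matrix(signature, "signature")
  stopifnot(inherits(regulon, "regulon"))
  tg <- regulon$targets[regulon$targets$gene %in% rownames(signature), ]
  if (nrow(tg) < 2L) {
    abort(sprintf("Regulon '%s' has < 2 targets in the signature.",
                  regulon$regulator))
  }
  w <- tg$likelihood / sum(tg$likelihood)
  es <- as.vector(crossprod(signature[tg$gene, , drop = FALSE], w * tg$mode))
  n_genes <- nrow(signature)
  mu <- colMeans(signature)
  sig2 <- colMeans(signature^2) - mu^2
  swm <- sum(w * tg$mode)
  v <- sig2 * (sum(w^2) * (1 + 1 / (n_genes - 1)) - swm^2 / (n_genes - 1))
  v[v <= 0] <- NA_real_
  nes <- (es - mu * swm) / sqrt(v)
  nes[is.na(nes)] <- 0
  setNames(nes, colnames(signature))
}

#' Infer a protein-activity matrix from one regulon network
#'
#' Applies [area_nes()] to every regulon of a network; regulons with fewer
#' than 2 targets present in the signature are skipped.
#'
#' @param signature Genes x samples signature matrix.
#' @param regulons List of `regulon` objects (one network).
#' @return Proteins x samples NES matrix.
#' @export
regulon_activity <- function(signature, regulons) {
  rows <- list()
  for (r in regulons) {
    nes <- tryCatch(area_nes(signature, r), error = function(e) NULL)
    if (!is.null(nes)) rows[[r$regulator]] <- nes
  }
  if (!length(rows)) abort("No regulon has >= 2 targets in the signature.")
  out <- do.call(rbind, rows)
  dimnames(out) <- list(names(rows), colnames(signature))
  out
}

#' Consensus protein activity across networks
#'
#' Integrates per-network activity matrices over their shared samples. The
#' default rule keeps, per (protein, sample), the value with maximum |NES|
#' across the networks containing that protein; the alternative is an
#' |NES|-weighted average. The chosen source network per protein-sample is
#' recorded in the `"provenance"` attribute (max-abs rule only).
#'
#' @param activities List of proteins x samples NES matrices.
#' @param rule `"max_abs"` (default) or `"weighted_mean"`.
#' @return Proteins x samples consensus matrix (union of proteins, shared
#'   samples).
#' @export
metaviper_consensus <- function(activities,
                                rule = c("max_abs", "weighted_mean")) {
  rule <- match.arg(rule)
  if (!length(activities)) abort("Need >= 1 activity matrix.")
  for (a in activities) assert_named_matrix(a, "activity")
  samples <- Reduce(intersect, lapply(activities, colnames))
  if (!length(samples)) abort("Networks share no samples.")
  proteins <- sort(unique(unlist(lapply(activities, rownames))))
  out <- matrix(NA_real_, length(proteins), length(samples),
                dimnames = list(proteins, samples))
  prov <- matrix(NA_integer_, length(proteins), length(samples),
                 dimnames = list(proteins, samples))
  for (p in proteins) {
    has <- which(vapply(activities, function(a) p %in% rownames(a),
                        logical(1)))
    vals <- do.call(rbind, lapply(activities[has], function(a) {
      a[p, samples]
    }))
    if (rule == "max_abs") {
      pick <- apply(abs(vals), 2L, which.max)
      out[p, ] <- vals[cbind(pick, seq_along(samples))]
      prov[p, ] <- has[pick]
    } else {
      w <- abs(vals)
      wsum <- colSums(w)
      wsum[wsum == 0] <- 1
      out[p, ] <- colSums(vals * w) / wsum
    }
  }
  attr(out, "provenance") <- if (rule == "max_abs") prov else NULL
  out
}

#' Correlate protein activity with latent-variable expression
#'
#' Spearman correlation of every (LV, protein) pair over shared samples,
#' plus a per-LV count of proteins whose correlation exceeds `threshold`.
#' Constant vectors give `r = NA` and are excluded from counts.
#'
#' @param activity Proteins x samples NES matrix.
#' @param B LVs x samples score matrix.
#' @param threshold Correlation cutoff for the per-LV count (default 0.65).
#' @return An `activity_correlation` list: `correlation` (LV x protein
#'   matrix), `counts` (tibble lv, n_above), `threshold`.
#' @export
correlate_activity_lv <- function(activity, B, threshold = 0.65) {
  assert_named_matrix(activity, "activity")
  assert_named_matrix(B, "B")
  shared <- intersect(colnames(activity), colnames(B))
  if (length(shared) < 3L) abort("Need >= 3 shared samples.")
  A <- activity[, shared, drop = FALSE]
  Bv <- B[, shared, drop = FALSE]
  const_a <- apply(A, 1L, sd) == 0
  const_b <- apply(Bv, 1L, sd) == 0
  R <- suppressWarnings(cor(t(Bv), t(A), method = "spearman"))
  R[const_b, ] <- NA_real_
  R[, const_a] <- NA_real_
  counts <- tibble::tibble(
    lv = rownames(R),
    n_above = apply(R, 1L, function(r) sum(r > threshold, na.rm = TRUE))
  )
  structure(list(correlation = R, counts = counts, threshold = threshold,
                 n = length(shared)),
            class = "activity_correlation")
}

#' @export
print.activity_correlation <- function(x, ...) {
  cat(sprintf(
    "<activity_correlation> %d LVs x %d proteins over %d samples; threshold %.2f\n",
    nrow(x$correlation), ncol(x$correlation), x$n, x$threshold))
  invisible(x)
}

#' @method tidy activity_correlation
#' @export
tidy.activity_correlation <- function(x, ...) {
  tibble::as_tibble(x$correlation, rownames = "lv") |>
    tidyr::pivot_longer(-"lv", names_to = "protein", values_to = "r")
}
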