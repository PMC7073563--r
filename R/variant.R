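# Gene-variant versus latent-variable association: for each gene with
# enough mutated samples, a two-sided Wilcoxon rank-sum test of each LV's
# scores in mutated versus wild-type assayed samples, BH-adjusted across
# all (gene, LV) pairs.

# Variant classes excluded by default (non-coding / silent).
.silent_classes <- c("Silent", "Intron", "3'UTR", "5'UTR", "3'Flank",
                     "5'Flank", "IGR", "RNA")

#' Associate gene variants with latent-variable expression
#'
#' Restricts to variant-assayed samples shared with the score matrix,
#' filters variant calls to non-silent classes, and for every gene carried
#' by at least `min_mutated` samples tests each LV with a two-sided
#' Wilcoxon rank-sum (exact when both groups have <= 25 samples and no
#' ties; otherwise the normal approximation with tie correction). BH
#' q-values are computed across all tested (gene, LV) pairs; the direction
#' is the sign of the mutated-minus-wild-type median difference.
#'
#' @param B LVs x samples score matrix.
#' @param variants MAF-style tibble (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#'   `Variant_Classification`) or a `variant_sim`.
#' @param meta Sample metadata.
#' @param assayed_samples Samples with variant data; only these enter the
#'   wild-type group (default: all samples shared between `B` and `meta`).
#' @param min_mutated Minimum mutated samples per tested gene (default 3;
#'   set 1 to allow single-carrier hits).
#' @param q_threshold BH significance cutoff (default 0.01).
#' @param exclude_classes Variant classes ignored (default: silent and
#'   non-coding classes).
#' @return Tibble: gene, lv, n_mut, n_wt, statistic, p, q_bh, direction,
#'   significant — empty (not an error) when no gene passes `min_mutated`.
#' @export
lv_variant_association <- function(B, variants, meta,
                                   assayed_samples = NULL, min_mutated = 3,
                                   q_threshold = 0.01,
                                   exclude_classes = .silent_classes) {
  assert_named_matrix(B, "B")
  assert_metadata(meta)
  if (inherits(variants, "variant_sim")) variants <- variants$variants
  min_mutated <- assert_count(min_mutated)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  if (!all(need %in% names(variants))) {
    abort(paste0("`variants` needs columns: ", paste(need, collapse = ", ")))
  }

  assayed <- assayed_samples %||% intersect(colnames(B), meta$sample_id)
  assayed <- intersect(assayed, colnames(B))
  if (length(assayed) < min_mutated + 2L) {
    abort("Too few assayed samples shared with `B`.")
  }

  v <- variants[!(variants$Variant_Classification %in% exclude_classes), ]
  off <- setdiff(unique(v$Tumor_Sample_Barcode), assayed)
  if (length(off)) {
    inform(sprintf("%d variant call(s) in non-assayed samples ignored.",
                   sum(v$Tumor_Sample_Barcode %in% off)))
  }
  v <- v[v$Tumor_Sample_Barcode %in% assayed, ]

  empty <- tibble::tibble(gene = character(0), lv = character(0),
                          n_mut = integer(0), n_wt = integer(0),
                          statistic = numeric(0), p = numeric(0),
                          q_bh = numeric(0), direction = numeric(0),
                          significant = logical(0))
  if (!nrow(v)) return(empty)

  carriers <- split(v$Tumor_Sample_Barcode, v$Hugo_Symbol)
  carriers <- lapply(carriers, unique)
  carriers <- carriers[vapply(carriers, length, integer(1)) >= min_mutated]
  carriers <- carriers[vapply(carriers, function(x) {
    length(x) <= length(assayed) - 1L
  }, logical(1))]
  if (!length(carriers)) return(empty)

  rows <- list()
  for (g in names(carriers)) {
    mut <- carriers[[g]]
    wt <- setdiff(assayed, mut)
    for (lv in rownames(B)) {
      x <- B[lv, mut]
      y <- B[lv, wt]
      use_exact <- length(x) <= 25L && length(y) <= 25L
      wtst <- suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                    correct = FALSE)
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = g, lv = lv, n_mut = length(mut), n_wt = length(wt),
        statistic = unname(wtst$statistic), p = wtst$p.value,
        direction = sign(median(x) - median(y))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$q_bh <- p.adjust(out$p, method = "BH")
  out$significant <- out$q_bh < q_threshold
  out[, c("gene", "lv", "n_mut", "n_wt", "statistic", "p", "q_bh",
          "direction", "significant")]
}
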