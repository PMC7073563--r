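#' PLIER-style model container
#'
#' A transferred latent-variable model: a non-negative loading matrix `Z`
#' (genes x LVs), the ridge constant `lambda2` used for projection, and
#' optional per-LV pathway annotations.
#'
#' @param Z Numeric genes x LVs matrix, entries >= 0, with row (gene) and
#'   column (LV) names.
#' @param lambda2 Positive ridge constant.
#' @param lv_annotations Optional named character vector (LV id -> label).
#' @return An object of class `plier_model`.
#' @export
new_plier_model <- function(Z, lambda2, lv_annotations = NULL) {
  assert_named_matrix(Z, "Z")
  if (any(Z < 0)) abort("Loading matrix `Z` must be non-negative.")
  if (!is.numeric(lambda2) || length(lambda2) != 1L || lambda2 <= 0) {
    abort("`lambda2` must be a single positive number.")
  }
  if (is.null(lv_annotations)) {
    lv_annotations <- setNames(rep(NA_character_, ncol(Z)), colnames(Z))
  }
  model <- structure(
    list(Z = Z, lambda2 = as.numeric(lambda2),
         lv_annotations = lv_annotations),
    class = "plier_model"
  )
  validate_plier_model(model)
}

#' @param model Object to validate.
#' @rdname new_plier_model
#' @export
validate_plier_model <- function(model) {
  if (!inherits(model, "plier_model")) abort("Not a `plier_model`.")
  assert_named_matrix(model$Z, "Z")
  if (any(model$Z < 0)) abort("Loading matrix `Z` must be non-negative.")
  if (any(colSums(model$Z != 0) == 0)) {
    abort("`Z` contains an all-zero LV column.")
  }
  if (model$lambda2 <= 0) abort("`lambda2` must be positive.")
  invisible(model)
}

#' @export
print.plier_model <- function(x, ...) {
  cat(sprintf("<plier_model> %d genes x %d LVs, lambda2 = %g\n",
              nrow(x$Z), ncol(x$Z), x$lambda2))
  n_ann <- sum(!is.na(x$lv_annotations))
  cat(sprintf("  %d annotated LVs\n", n_ann))
  invisible(x)
}

#' Regulon container
#'
#' A transcriptional regulator with signed-mode, weighted target genes.
#' Likelihood weights are normalized to sum to one internally.
#'
#' @param regulator Regulator (protein) identifier.
#' @param targets Tibble with columns `gene`, `mode` (in \[-1, 1\]) and
#'   `likelihood` (>= 0, not all zero).
#' @return An object of class `regulon`.
#' @export
new_regulon <- function(regulator, targets) {
  stopifnot(is.character(regulator), length(regulator) == 1L)
  targets <- tibble::as_tibble(targets)
  if (!all(c("gene", "mode", "likelihood") %in% names(targets))) {
    abort("`targets` needs columns gene, mode, likelihood.")
  }
  if (nrow(targets) < 2L) abort("A regulon needs at least 2 targets.")
  if (anyDuplicated(targets$gene)) abort("Regulon targets must be distinct.")
  if (any(abs(targets$mode) > 1)) abort("Modes must lie in [-1, 1].")
  if (any(targets$likelihood < 0) || sum(targets$likelihood) == 0) {
    abort("Likelihoods must be >= 0 and not all zero.")
  }
  targets$likelihood <- targets$likelihood / sum(targets$likelihood)
  structure(list(regulator = regulator, targets = targets), class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> %s: %d targets (%d repressed)\n", x$regulator,
              nrow(x$targets), sum(x$targets$mode < 0)))
  invisible(x)
}
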