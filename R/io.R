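#' Read and write identifier-keyed numeric matrices as TSV
#'
#' Expression matrices (genes x samples), latent-variable score matrices
#' (LVs x samples) and signature matrices are stored as plain TSV with the
#' identifier in the first column and one column per sample/cell type.
#'
#' @param path Path to a TSV file.
#' @return `read_matrix_tsv()` returns a numeric matrix with row and column
#'   names; `write_matrix_tsv()` returns `path` invisibly.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  assert_named_matrix(m, name = path)
}

#' @param x Numeric matrix with row and column names.
#' @param id_name Header for the identifier column.
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path, id_name = "id") {
  assert_named_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated, `name`, `description`,
#' then member identifiers.
#'
#' @param path Path to a `.gmt` file.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    members <- parts[-(1:2)]
    members[nzchar(members)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Serialize regulon networks as JSON
#'
#' A network is a list of regulons; each regulon is stored as
#' `regulator -> [{target, mode, likelihood}, ...]`.
#'
#' @param regulons List of `regulon` objects (see [gen_regulons()]).
#' @param path Path to a JSON file.
#' @export
write_regulons_json <- function(regulons, path) {
  payload <- lapply(regulons, function(r) {
    data.frame(target = r$targets$gene, mode = r$targets$mode,
               likelihood = r$targets$likelihood)
  })
  names(payload) <- vapply(regulons, function(r) r$regulator, character(1))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regulons_json
#' @return `read_regulons_json()` returns a list of `regulon` objects.
#' @export
read_regulons_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  regs <- lapply(names(payload), function(nm) {
    df <- payload[[nm]]
    new_regulon(nm, tibble::tibble(gene = df$target, mode = df$mode,
                                   likelihood = df$likelihood))
  })
  regs
}

#' Import regulons from a GMT file
#'
#' Targets in a GMT set get mode +1 and equal likelihoods.
#'
#' @inheritParams read_gmt
#' @export
read_regulons_gmt <- function(path) {
  sets <- read_gmt(path)
  lapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    new_regulon(nm, tibble::tibble(gene = genes, mode = 1,
                                   likelihood = 1 / length(genes)))
  })
}

#' Read and write MAF-style variant tables
#'
#' Only the three columns the association analysis consumes are required:
#' `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`.
#'
#' @param path Path to a tab-separated MAF-style file.
#' @return A tibble with the three MAF columns.
#' @export
read_maf <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  if (!all(need %in% names(df))) {
    abort(paste0("MAF file must contain columns: ", paste(need, collapse = ", ")))
  }
  tibble::as_tibble(df[, need])
}

#' @param variants Data frame with the three MAF columns.
#' @rdname read_maf
#' @export
write_maf <- function(variants, path) {
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  stopifnot(all(need %in% names(variants)))
  write.table(variants[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Serialize a PLIER-style model
#'
#' The loading matrix Z is written as TSV (gene rows, LV columns); the ridge
#' constant and per-LV annotations go to a JSON sidecar `<path>.json`.
#'
#' @param model A `plier_model`.
#' @param path Path for the loading-matrix TSV.
#' @export
write_plier_model <- function(model, path) {
  validate_plier_model(model)
  write_matrix_tsv(model$Z, path, id_name = "gene")
  side <- list(lambda2 = model$lambda2,
               lv_annotations = as.list(model$lv_annotations))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_plier_model
#' @return `read_plier_model()` returns a `plier_model`.
#' @export
read_plier_model <- function(path) {
  Z <- read_matrix_tsv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ann <- unlist(side$lv_annotations)
  anno <- setNames(rep(NA_character_, ncol(Z)), colnames(Z))
  if (length(ann)) anno[names(ann)] <- as.character(ann)
  new_plier_model(Z, side$lambda2, anno)
}
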