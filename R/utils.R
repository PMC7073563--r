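# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators compose without
# perturbing the session RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

assert_count <- function(x, min = 1, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, format(min)))
  }
  as.integer(x)
}

assert_fraction <- function(x, name = deparse(substitute(x)),
                            open_left = TRUE, open_right = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) {
    bounds <- paste0(if (open_left) "(0, " else "[0, ",
                     if (open_right) "1)" else "1]")
    abort(sprintf("`%s` must lie in %s.", name, bounds))
  }
  as.numeric(x)
}

assert_named_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", name))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must have row and column names.", name))
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    abort(sprintf("`%s` has duplicated row or column names.", name))
  }
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name))
  }
  invisible(x)
}

assert_metadata <- function(meta) {
  if (!is.data.frame(meta) ||
      !all(c("sample_id", "tumor_type", "study_id") %in% names(meta))) {
    abort("`meta` must have columns sample_id, tumor_type, study_id.")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("`meta$sample_id` must be unique.")
  }
  invisible(meta)
}

# Per-class one-vs-rest F1 from a multiclass confusion; a class with no true
# and no predicted positives scores 0 by convention.
f1_by_class <- function(truth, pred, classes) {
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

# Stratified index split: for each level of `labels`, assign round(frac * n)
# (clamped to [1, n - 1]) indices to the first part.
stratified_split <- function(labels, frac) {
  labels <- as.factor(labels)
  idx_first <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n <- length(idx)
    n_first <- min(max(round(frac * n), 1L), n - 1L)
    idx_first <- c(idx_first, sample(idx, n_first))
  }
  sort(idx_first)
}

`%_%` <- function(a, b) paste0(a, b)
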