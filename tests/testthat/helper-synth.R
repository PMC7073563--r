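# Small shared fixtures, built in code.

named_matrix <- function(nr, nc, seed = 1, rprefix = "g", cprefix = "S",
                         rnd = rnorm) {
  set.seed(seed)
  matrix(rnd(nr * nc), nr, nc,
         dimnames = list(paste0(rprefix, seq_len(nr)),
                         paste0(cprefix, seq_len(nc))))
}

meta_for <- function(samples, classes, studies = NULL) {
  tibble::tibble(
    sample_id = samples,
    tumor_type = rep_len(classes %||% "x", length(samples)),
    study_id = studies %||% "study1"
  )
}

# Independent naive enumeration oracle for the weighted KS enrichment score:
# a deliberately plain re-implementation used only to cross-check.
naive_gsea_es <- function(positions, sorted_scores) {
  n <- length(sorted_scores)
  inset <- seq_len(n) %in% positions
  w <- abs(sorted_scores)
  nr <- sum(w[inset])
  hit <- ifelse(inset, if (nr > 0) w / nr else 1 / sum(inset), 0)
  miss <- ifelse(inset, 0, 1 / (n - sum(inset)))
  run <- cumsum(hit - miss)
  run[which.max(abs(run))]
}
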