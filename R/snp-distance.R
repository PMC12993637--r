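#' Pairwise SNP distances between isolates
#'
#' Each isolate implies a sequence over the shared reference: its ALT allele
#' at every surviving variant position and the reference allele elsewhere.
#' The distance between two isolates is the number of positions where the
#' implied alleles differ: a variant private to one isolate counts 1, a
#' shared variant with identical ALT counts 0, and a shared position with
#' different ALT alleles counts 1 (one site, one SNP).
#'
#' @param filtered_sets Named list of surviving SNV tibbles (columns
#'   `chrom`, `pos`, `alt` at minimum), one per isolate. Duplicate records
#'   at the same position must agree on the ALT allele; conflicting
#'   duplicates are an error.
#' @return A symmetric non-negative integer matrix with isolate ids as
#'   dimnames and zero diagonal.
#' @export
snp_distances <- function(filtered_sets) {
  ids <- names(filtered_sets)
  if (is.null(ids)) abort("filtered_sets must be named by isolate")
  alleles <- lapply(ids, function(iso) {
    v <- filtered_sets[[iso]]
    key <- paste(v$chrom, v$pos, sep = ":")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)]
      conflict <- vapply(unique(dup), function(k) {
        length(unique(v$alt[key == k])) > 1
      }, logical(1))
      if (any(conflict)) {
        abort(sprintf("conflicting duplicate records in isolate %s at %s",
                      iso, paste(unique(dup)[conflict], collapse = ", ")))
      }
      v <- v[!duplicated(key), , drop = FALSE]
      key <- key[!duplicated(key)]
    }
    setNames(v$alt, key)
  })
  names(alleles) <- ids
  n <- length(ids)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ai <- alleles[[i]]; aj <- alleles[[j]]
      shared <- intersect(names(ai), names(aj))
      d <- (length(ai) - length(shared)) + (length(aj) - length(shared)) +
        sum(ai[shared] != aj[shared])
      m[i, j] <- m[j, i] <- as.integer(d)
    }
  }
  m
}
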