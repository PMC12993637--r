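#' Exclude low-depth samples from an OTU table
#'
#' Samples with fewer than `min_total` sequences are removed; a sample with
#' exactly `min_total` is kept. The excluded ids and their totals are
#' attached as the `"excluded"` attribute and retrievable with
#' [excluded_samples()].
#'
#' @param x OTU tibble of counts.
#' @param min_total Minimum sequence total to keep a sample (default 1000).
#' @return The filtered OTU tibble (possibly with zero rows).
#' @export
exclude_low_depth <- function(x, min_total = 1000) {
  validate_otu_table(x)
  stopifnot(min_total >= 0)
  totals <- sample_totals(x)
  drop <- totals$total < min_total
  out <- x[!drop, , drop = FALSE]
  attr(out, "otu_label") <- attr(x, "otu_label")
  attr(out, "excluded") <- totals[drop, , drop = FALSE]
  out
}

#' Exclusion report of [exclude_low_depth()]
#'
#' @param x The tibble returned by [exclude_low_depth()].
#' @return Tibble of excluded `sample_id` and `total`.
#' @export
excluded_samples <- function(x) {
  attr(x, "excluded") %||% tibble(sample_id = character(), total = double())
}

#' Convert OTU counts to relative abundances
#'
#' @param x OTU tibble of counts; every sample must have a positive total.
#' @return An OTU tibble of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(x) {
  validate_otu_table(x)
  m <- otu_matrix(x)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    abort(sprintf("zero-total sample(s): %s",
                  paste(rownames(m)[totals == 0], collapse = ", ")))
  }
  p <- sweep(m, 1, totals, "/")
  out <- dplyr::bind_cols(tibble(sample_id = x$sample_id),
                          as_tibble(as.data.frame(p), .name_repair = "minimal"))
  names(out) <- names(x)
  attr(out, "otu_label") <- attr(x, "otu_label")
  attr(out, "relative") <- TRUE
  out
}

#' Select OTUs for display
#'
#' An OTU qualifies when it has at least `min_total_seqs` sequences across
#' the whole dataset AND exceeds `min_max_relab` relative abundance in at
#' least one sample. Order follows the table.
#'
#' @param x OTU tibble of counts.
#' @param min_total_seqs Minimum dataset-wide sequence count (default 200).
#' @param min_max_relab Relative-abundance threshold that must be exceeded in
#'   at least one sample (default 0.02, strict `>`).
#' @return Character vector of qualifying OTU ids.
#' @export
select_display_otus <- function(x, min_total_seqs = 200, min_max_relab = 0.02) {
  validate_otu_table(x)
  m <- otu_matrix(x)
  totals <- colSums(m)
  rel <- otu_matrix(relative_abundance(x[rowSums(m) > 0, , drop = FALSE]))
  max_rel <- if (nrow(rel) > 0) apply(rel, 2, max) else rep(0, ncol(m))
  keep <- totals >= min_total_seqs & max_rel > min_max_relab
  colnames(m)[keep]
}

#' Long-format relative abundance table
#'
#' The tidy substitute for an abundance heat map: one row per sample/OTU,
#' optionally restricted to display OTUs.
#'
#' @param x OTU tibble of counts.
#' @param otus Optional character vector of OTU ids to keep (e.g. from
#'   [select_display_otus()]).
#' @return Tibble with `sample_id`, `otu_id`, `count`, `relab`.
#' @export
abundance_long <- function(x, otus = NULL) {
  validate_otu_table(x)
  rel <- relative_abundance(x)
  long_c <- tidyr::pivot_longer(x, -"sample_id", names_to = "otu_id",
                                values_to = "count")
  long_r <- tidyr::pivot_longer(rel, -"sample_id", names_to = "otu_id",
                                values_to = "relab")
  out <- dplyr::left_join(long_c, long_r, by = c("sample_id", "otu_id"))
  if (!is.null(otus)) out <- dplyr::filter(out, .data$otu_id %in% otus)
  out
}
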