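#' Read a mothur shared file into an OTU tibble
#'
#' Parses the tab-delimited mothur "shared" dialect: a header line
#' `label Group numOtus <otu ids...>` followed by one row per sample. The
#' `numOtus` column is checked against the actual number of OTU columns and
#' counts must be non-negative integers.
#'
#' @param path Path to a shared file.
#' @return A tibble with a `sample_id` column and one integer column per OTU,
#'   carrying the clustering label in `attr(x, "otu_label")`.
#' @seealso [write_shared()], [otu_matrix()]
#' @export
read_shared <- function(path) {
  if (!file.exists(path)) abort(sprintf("shared file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("shared file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 3 || tolower(header[1]) != "label" ||
      tolower(header[2]) != "group" || tolower(header[3]) != "numotus") {
    abort(sprintf("not a shared header (want 'label Group numOtus ...'): %s",
                  paste(utils::head(header, 4), collapse = " ")))
  }
  otu_ids <- header[-(1:3)]
  if (anyDuplicated(otu_ids)) abort("duplicate OTU ids in shared header")
  ncol_exp <- length(header)
  rows <- fields[-1]
  label <- NA_character_
  n <- length(rows)
  counts <- matrix(0L, nrow = n, ncol = length(otu_ids))
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    if (length(r) != ncol_exp) {
      abort(sprintf("ragged shared row at line %d: %d fields, expected %d",
                    i + 1L, length(r), ncol_exp))
    }
    num_otus <- suppressWarnings(as.integer(r[3]))
    if (is.na(num_otus) || num_otus != length(otu_ids)) {
      abort(sprintf("numOtus=%s at line %d inconsistent with %d OTU columns",
                    r[3], i + 1L, length(otu_ids)))
    }
    vals <- suppressWarnings(as.numeric(r[-(1:3)]))
    if (any(is.na(vals)) || any(vals != floor(vals)) || any(vals < 0)) {
      abort(sprintf("non-integer or negative count at line %d", i + 1L))
    }
    counts[i, ] <- as.integer(vals)
    sample_ids[i] <- r[2]
    label <- r[1]
  }
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("duplicate sample ids in shared file: %s",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  out <- tibble(sample_id = sample_ids)
  cnt <- as_tibble(as.data.frame(counts, stringsAsFactors = FALSE),
                   .name_repair = "minimal")
  names(cnt) <- otu_ids
  out <- dplyr::bind_cols(out, cnt)
  attr(out, "otu_label") <- label
  out
}

#' Write an OTU tibble as a mothur shared file
#'
#' @param x An OTU tibble (`sample_id` plus count columns).
#' @param path Output path.
#' @param label Clustering label for the first column; defaults to the
#'   `otu_label` attribute or `"0.03"`.
#' @return `path`, invisibly.
#' @export
write_shared <- function(x, path, label = NULL) {
  validate_otu_table(x)
  label <- label %||% attr(x, "otu_label") %||% "0.03"
  ids <- otu_cols(x)
  m <- otu_matrix(x)
  header <- paste(c("label", "Group", "numOtus", ids), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(label, rownames(m)[i], length(ids),
            format(m[i, ], scientific = FALSE, trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Per-sample sequence totals of an OTU tibble
#'
#' @inheritParams write_shared
#' @return A tibble with columns `sample_id` and `total`.
#' @export
sample_totals <- function(x) {
  validate_otu_table(x)
  tibble(sample_id = x$sample_id, total = unname(rowSums(otu_matrix(x))))
}
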