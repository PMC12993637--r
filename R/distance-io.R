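#' Write a distance matrix to disk
#'
#' Two dialects: `tidy_csv` writes one row per unordered pair (`id1`, `id2`,
#' `distance`; n(n-1)/2 rows), `phylip_lower` writes the classic
#' lower-triangle PHYLIP format. Values are written with full precision so
#' that a write/read round trip reproduces the matrix to 1e-9.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and dimnames.
#' @param path Output path.
#' @param dialect `"tidy_csv"` or `"phylip_lower"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, dialect = c("tidy_csv", "phylip_lower")) {
  dialect <- match.arg(dialect)
  check_distance_matrix(dm)
  ids <- rownames(dm)
  n <- length(ids)
  if (dialect == "tidy_csv") {
    pairs <- which(upper.tri(dm), arr.ind = TRUE)
    df <- tibble(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
                 distance = dm[pairs])
    df <- dplyr::arrange(df, .data$id1, .data$id2)
    lines <- c("id1,id2,distance",
               sprintf("%s,%s,%s", df$id1, df$id2,
                       formatC(df$distance, digits = 17, format = "g")))
    writeLines(lines, path)
  } else {
    lines <- as.character(n)
    for (i in seq_len(n)) {
      row <- if (i == 1) character(0) else
        formatC(dm[i, seq_len(i - 1)], digits = 17, format = "g")
      lines <- c(lines, paste(c(ids[i], row), collapse = "\t"))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path Input path.
#' @param dialect `"tidy_csv"` or `"phylip_lower"`.
#' @return A symmetric matrix with zero diagonal.
#' @export
read_distance_matrix <- function(path, dialect = c("tidy_csv", "phylip_lower")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("distance file not found: %s", path))
  if (dialect == "tidy_csv") {
    df <- readr::read_csv(path, col_types = "ccd", progress = FALSE,
                          comment = "#")
    ids <- unique(c(df$id1, df$id2))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(df$id1, df$id2)] <- df$distance
    m[cbind(df$id2, df$id1)] <- df$distance
    m
  } else {
    lines <- readLines(path, warn = FALSE)
    n <- as.integer(lines[1])
    fields <- strsplit(lines[1 + seq_len(n)], "\t", fixed = TRUE)
    ids <- vapply(fields, `[`, character(1), 1)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) {
      vals <- as.numeric(fields[[i]][-1])
      if (length(vals) != i - 1) {
        abort(sprintf("phylip lower-triangle row %d has %d values, expected %d",
                      i, length(vals), i - 1))
      }
      if (i > 1) {
        m[i, seq_len(i - 1)] <- vals
        m[seq_len(i - 1), i] <- vals
      }
    }
    m
  }
}

#' Long-format (tidy) view of a distance matrix
#'
#' @param dm Symmetric distance matrix with dimnames.
#' @return A tibble with one row per unordered pair.
#' @export
distances_long <- function(dm) {
  check_distance_matrix(dm)
  ids <- rownames(dm)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  dplyr::arrange(tibble(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
                        distance = dm[pairs]),
                 .data$id1, .data$id2)
}
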