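# Genomic interval masks. Internally every interval set is a tibble with
# columns chrom, start, end in 0-based half-open convention, normalised
# (sorted, merged, non-overlapping). Conversion from the 1-based inclusive
# GFF convention happens only at the I/O boundary (rtracklayer). The set
# algebra below works on sorted endpoints per chromosome; the interval sets
# the pipeline sees are tiny, and tests cross-check every operation against
# point-membership oracles.

interval_tibble <- function(chrom, start, end, label = NA_character_) {
  out <- tibble(chrom = as.character(chrom), start = as.numeric(start),
                end = as.numeric(end))
  attr(out, "mask_label") <- label
  out
}

empty_intervals <- function(label = NA_character_) {
  interval_tibble(character(), double(), double(), label = label)
}

from_granges0 <- function(gr, label = NA_character_) {
  interval_tibble(as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
                  label = label)
}

# merge sorted intervals of one chromosome; adjacency merges too
merge_sorted <- function(start, end) {
  n <- length(start)
  if (n <= 1) return(list(start = start, end = end))
  ms <- me <- numeric(n)
  k <- 1; ms[1] <- start[1]; me[1] <- end[1]
  for (i in 2:n) {
    if (start[i] <= me[k]) {
      me[k] <- max(me[k], end[i])
    } else {
      k <- k + 1; ms[k] <- start[i]; me[k] <- end[i]
    }
  }
  list(start = ms[1:k], end = me[1:k])
}

per_chrom <- function(iv, f) {
  chroms <- unique(iv$chrom)
  parts <- lapply(sort(chroms), function(ch) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    o <- order(sub$start, sub$end)
    res <- f(sub$start[o], sub$end[o])
    if (length(res$start) == 0) return(NULL)
    tibble(chrom = ch, start = res$start, end = res$end)
  })
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) out <- empty_intervals()
  attr(out, "mask_label") <- attr(iv, "mask_label")
  out
}

#' Normalise an interval set
#'
#' Sorts and merges overlapping or adjacent intervals so membership queries
#' see a canonical non-overlapping representation; zero-width intervals are
#' dropped.
#'
#' @param iv An interval tibble (`chrom`, `start`, `end`, 0-based half-open).
#' @return A normalised interval tibble.
#' @export
normalize_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  if (any(iv$end < iv$start)) {
    bad <- which(iv$end < iv$start)[1]
    abort(sprintf("interval end < start: %s:[%g,%g)", iv$chrom[bad],
                  iv$start[bad], iv$end[bad]))
  }
  iv <- iv[iv$end > iv$start, , drop = FALSE]
  per_chrom(iv, merge_sorted)
}

#' Read an interval mask from BED or GFF
#'
#' BED is 0-based half-open and taken verbatim; GFF3 features (the dialect
#' used for recombinant-tract output) are 1-based inclusive and converted to
#' the internal 0-based half-open convention. The result is normalised.
#'
#' @param path Path to the mask file.
#' @param dialect `"bed"` or `"gff"`; there is no sniffing.
#' @param label Optional semantic label (`"phage"`, `"repeat"`,
#'   `"recombinant"`, `"callable"`), stored as an attribute.
#' @return A normalised interval tibble.
#' @export
read_intervals <- function(path, dialect = c("bed", "gff"), label = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("mask file not found: %s", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "bed") "bed" else "gff3"),
    error = function(e) abort(sprintf("failed to parse %s as %s: %s",
                                      path, dialect, conditionMessage(e))))
  # both importers yield 1-based inclusive GRanges; start-1/end is the shared
  # conversion back to half-open
  normalize_intervals(from_granges0(gr, label = label))
}

#' Write an interval set as BED
#'
#' @param iv Interval tibble (0-based half-open — written verbatim).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  readr::write_tsv(iv[, c("chrom", "start", "end")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Write an interval set as GFF3 (recombinant-tract dialect)
#'
#' @inheritParams write_bed
#' @param source Value for the GFF source column.
#' @export
write_gff <- function(iv, path, source = "simulated") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tmisc_feature\t%d\t%d\t.\t.\t.\tnote=tract",
                     iv$chrom, source, as.integer(iv$start) + 1L, as.integer(iv$end)))
  writeLines(lines, path)
  invisible(path)
}

# intersection of two normalised single-chromosome interval lists
intersect_sorted <- function(a_start, a_end, b_start, b_end) {
  out_s <- out_e <- numeric(0)
  i <- j <- 1
  while (i <= length(a_start) && j <= length(b_start)) {
    s <- max(a_start[i], b_start[j])
    e <- min(a_end[i], b_end[j])
    if (s < e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
    if (a_end[i] < b_end[j]) i <- i + 1 else j <- j + 1
  }
  list(start = out_s, end = out_e)
}

intersect_intervals <- function(a, b) {
  a <- normalize_intervals(a); b <- normalize_intervals(b)
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  parts <- lapply(sort(chroms), function(ch) {
    sa <- a[a$chrom == ch, ]; sb <- b[b$chrom == ch, ]
    res <- intersect_sorted(sa$start, sa$end, sb$start, sb$end)
    if (length(res$start) == 0) return(NULL)
    tibble(chrom = ch, start = res$start, end = res$end)
  })
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) out <- empty_intervals()
  out
}

#' Intersect per-isolate callable intervals into a core genome
#'
#' The core genome is the set of reference positions callable in every
#' isolate: the fold of pairwise interval intersections.
#'
#' @param callable_sets A list of interval tibbles, one per isolate.
#' @return A normalised interval tibble (possibly empty, with a warning).
#' @export
core_genome <- function(callable_sets) {
  if (length(callable_sets) == 0) abort("core_genome needs at least one isolate")
  out <- Reduce(intersect_intervals, callable_sets)
  out <- normalize_intervals(out)
  attr(out, "mask_label") <- "callable"
  if (nrow(out) == 0) warn("core genome is empty: no position callable in all isolates")
  out
}

#' Total length (bp) of an interval set
#'
#' @param iv Interval tibble.
#' @return Total covered length after normalisation.
#' @export
interval_total_length <- function(iv) {
  iv <- normalize_intervals(iv)
  sum(iv$end - iv$start)
}

#' Subtract one interval set from another
#'
#' @param iv,minus Interval tibbles.
#' @return Normalised intervals of `iv` not covered by `minus`.
#' @export
subtract_intervals <- function(iv, minus) {
  iv <- normalize_intervals(iv)
  if (nrow(minus) == 0 || nrow(iv) == 0) return(iv)
  minus <- normalize_intervals(minus)
  parts <- lapply(seq_len(nrow(iv)), function(i) {
    ch <- iv$chrom[i]
    cuts <- minus[minus$chrom == ch & minus$end > iv$start[i] &
                    minus$start < iv$end[i], , drop = FALSE]
    if (nrow(cuts) == 0) {
      return(tibble(chrom = ch, start = iv$start[i], end = iv$end[i]))
    }
    starts <- c(iv$start[i], cuts$end)
    ends <- c(cuts$start, iv$end[i])
    keep <- starts < ends
    if (!any(keep)) return(NULL)
    tibble(chrom = ch, start = starts[keep], end = ends[keep])
  })
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) out <- empty_intervals()
  attr(out, "mask_label") <- attr(iv, "mask_label")
  normalize_intervals(out)
}

# membership of 0-based positions in a normalised interval set (same chrom
# vectorised); positions on chromosomes absent from `iv` return FALSE.
positions_in_intervals <- function(chrom, pos0, iv) {
  out <- logical(length(pos0))
  if (nrow(iv) == 0 || length(pos0) == 0) return(out)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    idx <- findInterval(pos0[sel], sub$start)
    hit <- idx >= 1 & pos0[sel] < sub$end[pmax(idx, 1)]
    out[sel] <- hit
  }
  out
}
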