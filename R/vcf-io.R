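#' Read variant records from a VCF file
#'
#' Loads a VCF (4.x, uncompressed or bgzipped) with `vcfR` and returns one
#' row per ALT allele, splitting multi-allelic sites so downstream filters
#' see per-variant records. Site-level `QUAL`, `MQ` and `FQ` are inherited by
#' every allele of a site. The read depth supporting the variant is taken
#' from the INFO key named by `alt_depth_field`: for `DP4`
#' (ref-fwd,ref-rev,alt-fwd,alt-rev) the last two entries are summed; any
#' other key is read as a plain number.
#'
#' Records missing a filter-relevant field (`QUAL`, `MQ`, `FQ` or the depth
#' key) are kept but flagged `unscorable = TRUE`; the hard-filter stage
#' treats them as failing, so nothing is silently dropped.
#'
#' @param path Path to the VCF file.
#' @param alt_depth_field INFO key carrying variant-supporting read depth
#'   (default `"DP4"`).
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `qual`, `mq`, `alt_depth`, `fq`, `is_indel`, `unscorable`.
#' @export
read_vcf_records <- function(path, alt_depth_field = "DP4") {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), qual = double(), mq = double(),
                  alt_depth = double(), fq = double(), is_indel = logical(),
                  unscorable = logical()))
  }
  mq <- suppressWarnings(vcfR::extract.info(v, "MQ", as.numeric = TRUE))
  fq <- suppressWarnings(vcfR::extract.info(v, "FQ", as.numeric = TRUE))
  depth_raw <- suppressWarnings(vcfR::extract.info(v, alt_depth_field))
  alt_depth <- if (identical(alt_depth_field, "DP4")) {
    vapply(depth_raw, function(s) {
      if (is.na(s)) return(NA_real_)
      parts <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
      if (length(parts) != 4 || any(is.na(parts))) return(NA_real_)
      parts[3] + parts[4]
    }, double(1), USE.NAMES = FALSE)
  } else {
    suppressWarnings(as.numeric(depth_raw))
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  pos <- as.integer(fix[, "POS"])
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  k <- lengths(alt_list)
  idx <- rep.int(seq_len(n), k)
  out <- tibble(
    chrom = fix[idx, "CHROM"],
    pos = pos[idx],
    ref = fix[idx, "REF"],
    alt = unlist(alt_list, use.names = FALSE),
    qual = qual[idx],
    mq = mq[idx],
    alt_depth = alt_depth[idx],
    fq = fq[idx]
  )
  if (any(out$pos < 1)) abort("VCF position < 1")
  same <- out$ref == out$alt
  if (any(same)) abort(sprintf("REF equals ALT at %s:%d", out$chrom[same][1],
                               out$pos[same][1]))
  out$is_indel <- nchar(out$ref) != nchar(out$alt)
  out$unscorable <- is.na(out$qual) | is.na(out$mq) | is.na(out$fq) |
    is.na(out$alt_depth)
  out
}
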