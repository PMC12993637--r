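# The variant-filter cascade. Stages, applied in this fixed order:
#   1. hard filters   (QUAL > 100, MQ > 50, alt depth >= 10, FQ < 0.025)
#   2. indel proximity (SNVs < 5 bp from an indel start)
#   3. phage/repeat region mask
#   4. core genome    (keep only positions callable in every isolate)
#   5. recombinant-tract mask
# A removed record is attributed to its first failing stage, so
#   input = surviving + sum(per-stage removals)
# holds exactly per isolate.

FILTER_STAGES <- c("fail_qual", "fail_mq", "fail_depth", "fail_fq",
                   "fail_indel_proximity", "fail_phage_repeat",
                   "fail_noncore", "fail_recombinant")

#' Hard-filter thresholds for variant quality
#'
#' Boundary semantics follow the conventional printed operators: site
#' quality and mapping quality are strict (`>`), supporting depth is
#' inclusive (`>=`), and the consensus-quality field FQ is strict (`<`).
#' The FQ comparison direction is configurable because some callers emit
#' FQ with the opposite sign convention.
#'
#' @param min_qual Site quality, exclusive lower bound (default 100).
#' @param min_mq Mapping quality, exclusive lower bound (default 50).
#' @param min_alt_depth Reads supporting the variant, inclusive (default 10).
#' @param max_fq FQ bound, exclusive (default 0.025).
#' @param indel_window_bp SNVs closer than this to an indel start are
#'   removed (strict `<`, default 5).
#' @param fq_direction `"less"` (default: pass iff `fq < max_fq`) or
#'   `"greater"`.
#' @return A list of class `hard_filter_config`.
#' @export
hard_filter_config <- function(min_qual = 100, min_mq = 50, min_alt_depth = 10,
                               max_fq = 0.025, indel_window_bp = 5,
                               fq_direction = c("less", "greater")) {
  fq_direction <- match.arg(fq_direction)
  stopifnot(is.finite(min_qual), is.finite(min_mq), is.finite(min_alt_depth),
            is.finite(max_fq), indel_window_bp >= 0)
  structure(list(min_qual = min_qual, min_mq = min_mq,
                 min_alt_depth = min_alt_depth, max_fq = max_fq,
                 indel_window_bp = indel_window_bp,
                 fq_direction = fq_direction),
            class = "hard_filter_config")
}

# per-record first failing hard-filter stage, NA_character_ when passing;
# a missing (NA) field fails its own stage.
hard_filter_stage <- function(records, cfg) {
  fail_q <- is.na(records$qual) | !(records$qual > cfg$min_qual)
  fail_m <- is.na(records$mq) | !(records$mq > cfg$min_mq)
  fail_d <- is.na(records$alt_depth) | !(records$alt_depth >= cfg$min_alt_depth)
  fq_ok <- if (cfg$fq_direction == "less") records$fq < cfg$max_fq
           else records$fq > cfg$max_fq
  fail_f <- is.na(records$fq) | !fq_ok
  stage <- rep(NA_character_, nrow(records))
  stage[fail_f] <- "fail_fq"
  stage[fail_d] <- "fail_depth"
  stage[fail_m] <- "fail_mq"
  stage[fail_q] <- "fail_qual"
  stage
}

#' Apply hard quality filters to variant records
#'
#' A record passes iff `qual > min_qual` AND `mq > min_mq` AND
#' `alt_depth >= min_alt_depth` AND `fq < max_fq` (direction per config).
#' Records with any missing field fail, attributed to the first stage whose
#' field is missing or failing (order: qual, mq, depth, fq).
#'
#' @param records Variant tibble from [read_vcf_records()].
#' @param cfg A [hard_filter_config()].
#' @return List with `pass` (tibble of surviving records) and `report`
#'   (named counts: input, fail_qual, fail_mq, fail_depth, fail_fq,
#'   surviving).
#' @export
apply_hard_filters <- function(records, cfg = hard_filter_config()) {
  stage <- hard_filter_stage(records, cfg)
  report <- c(input = nrow(records),
              fail_qual = sum(stage == "fail_qual", na.rm = TRUE),
              fail_mq = sum(stage == "fail_mq", na.rm = TRUE),
              fail_depth = sum(stage == "fail_depth", na.rm = TRUE),
              fail_fq = sum(stage == "fail_fq", na.rm = TRUE),
              surviving = sum(is.na(stage)))
  list(pass = records[is.na(stage), , drop = FALSE], report = report)
}

#' Remove SNVs close to indels
#'
#' An SNV is removed when the absolute difference between its position and
#' any indel's reference start position (both 1-based) is strictly less
#' than `window_bp`, on the same chromosome.
#'
#' @param snvs Tibble of SNV records.
#' @param indels Tibble of indel records (only `chrom`, `pos` are used).
#' @param window_bp Strict distance bound (default 5).
#' @return List with `pass` and `removed` tibbles.
#' @export
mask_near_indels <- function(snvs, indels, window_bp = 5) {
  if (nrow(indels) == 0 || nrow(snvs) == 0 || window_bp == 0) {
    return(list(pass = snvs, removed = snvs[0, , drop = FALSE]))
  }
  near <- vapply(seq_len(nrow(snvs)), function(i) {
    same <- indels$chrom == snvs$chrom[i]
    any(same) && min(abs(indels$pos[same] - snvs$pos[i])) < window_bp
  }, logical(1))
  list(pass = snvs[!near, , drop = FALSE], removed = snvs[near, , drop = FALSE])
}

#' Remove variants falling inside interval masks
#'
#' A record is removed when its 0-based coordinate (`pos - 1`) lies in any
#' mask interval. Records on chromosomes absent from the mask are kept with
#' a warning.
#'
#' @param records Variant tibble.
#' @param masks A normalised interval tibble (e.g. phage/repeat regions).
#' @param warn_chrom_mismatch Emit the chromosome-mismatch warning
#'   (default TRUE).
#' @return List with `pass` and `removed` tibbles.
#' @export
apply_region_masks <- function(records, masks, warn_chrom_mismatch = TRUE) {
  if (nrow(masks) == 0 || nrow(records) == 0) {
    return(list(pass = records, removed = records[0, , drop = FALSE]))
  }
  unknown <- setdiff(unique(records$chrom), unique(masks$chrom))
  if (length(unknown) > 0 && warn_chrom_mismatch) {
    warn(sprintf("records on chromosome(s) %s not covered by mask; kept",
                 paste(unknown, collapse = ", ")))
  }
  hit <- positions_in_intervals(records$chrom, records$pos - 1, masks)
  list(pass = records[!hit, , drop = FALSE],
       removed = records[hit, , drop = FALSE])
}

#' Remove variants inside recombinant tracts
#'
#' Identical mechanics to [apply_region_masks()]; kept as a separate stage
#' so removals are attributed to recombination in the filter report.
#'
#' @inheritParams apply_region_masks
#' @param recomb Normalised interval tibble of recombinant tracts.
#' @export
apply_recombination_mask <- function(records, recomb, warn_chrom_mismatch = TRUE) {
  apply_region_masks(records, recomb, warn_chrom_mismatch = warn_chrom_mismatch)
}

# keep only records inside the core genome
apply_core_filter <- function(records, core) {
  inside <- positions_in_intervals(records$chrom, records$pos - 1, core)
  list(pass = records[inside, , drop = FALSE],
       removed = records[!inside, , drop = FALSE])
}

#' Run the full variant-filter cascade over a set of isolates
#'
#' Applies, per isolate and in fixed order: hard filters, indel-proximity
#' masking, phage/repeat masking, core-genome restriction, recombination
#' masking; then computes the pairwise SNP distance matrix of the surviving
#' SNVs. Indels never enter the distance; they are consumed by the
#' proximity stage. The per-isolate filter report attributes every removed
#' SNV to its first failing stage.
#'
#' @param variant_sets Named list: one variant tibble (or VCF path) per
#'   isolate.
#' @param masks List with optional elements `phage_repeat` (interval
#'   tibble), `callable` (named list of per-isolate interval tibbles, or a
#'   single tibble used for all), and `recombinant` (interval tibble).
#' @param cfg A [hard_filter_config()].
#' @return List with `distances` (symmetric integer matrix),
#'   `reports` (tibble, one row per isolate with per-stage counts),
#'   `survivors` (named list of surviving SNV tibbles) and `core` (the core
#'   genome interval tibble, or NULL if no callable sets were given).
#' @export
run_filter_cascade <- function(variant_sets, masks = list(),
                               cfg = hard_filter_config()) {
  if (is.null(names(variant_sets)) || any(!nzchar(names(variant_sets)))) {
    abort("variant_sets must be a named list (isolate ids)")
  }
  variant_sets <- lapply(variant_sets, function(v) {
    if (is.character(v)) read_vcf_records(v) else v
  })
  phage_repeat <- masks$phage_repeat %||% interval_tibble(character(), double(), double())
  recomb <- masks$recombinant %||% interval_tibble(character(), double(), double())
  core <- NULL
  if (!is.null(masks$callable)) {
    callable <- masks$callable
    if (is.data.frame(callable)) callable <- list(callable)
    core <- core_genome(callable)
  }

  survivors <- list()
  reports <- list()
  for (iso in names(variant_sets)) {
    v <- variant_sets[[iso]]
    snvs <- v[!v$is_indel, , drop = FALSE]
    indels <- v[v$is_indel, , drop = FALSE]
    rep_counts <- c(input = nrow(snvs), fail_qual = 0L, fail_mq = 0L,
                    fail_depth = 0L, fail_fq = 0L, fail_indel_proximity = 0L,
                    fail_phage_repeat = 0L, fail_noncore = 0L,
                    fail_recombinant = 0L, surviving = 0L)

    hf <- apply_hard_filters(snvs, cfg)
    rep_counts[c("fail_qual", "fail_mq", "fail_depth", "fail_fq")] <-
      hf$report[c("fail_qual", "fail_mq", "fail_depth", "fail_fq")]
    cur <- hf$pass

    st <- mask_near_indels(cur, indels, cfg$indel_window_bp)
    rep_counts["fail_indel_proximity"] <- nrow(st$removed)
    cur <- st$pass

    st <- apply_region_masks(cur, phage_repeat)
    rep_counts["fail_phage_repeat"] <- nrow(st$removed)
    cur <- st$pass

    if (!is.null(core)) {
      st <- apply_core_filter(cur, core)
      rep_counts["fail_noncore"] <- nrow(st$removed)
      cur <- st$pass
    }

    st <- apply_recombination_mask(cur, recomb)
    rep_counts["fail_recombinant"] <- nrow(st$removed)
    cur <- st$pass

    rep_counts["surviving"] <- nrow(cur)
    stopifnot(rep_counts["input"] ==
                rep_counts["surviving"] + sum(rep_counts[FILTER_STAGES]))
    survivors[[iso]] <- cur
    reports[[iso]] <- as_tibble(as.list(rep_counts))
  }
  reports <- dplyr::bind_cols(tibble(isolate = names(variant_sets)),
                              dplyr::bind_rows(reports))
  list(distances = snp_distances(survivors), reports = reports,
       survivors = survivors, core = core)
}
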