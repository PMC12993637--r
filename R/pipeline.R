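# End-to-end orchestration. Both pipelines consume files, write fixed-name
# outputs under an output directory, log one structured record per stage
# and stamp every table with a provenance header (config hash, seed,
# package version).

#' Assemble a pipeline run configuration
#'
#' Defaults are the analysis defaults used throughout the package: depth
#' exclusion below 1000 sequences; display OTUs at 200 sequences overall
#' and >2% in at least one sample; hard filters QUAL>100, MQ>50, depth>=10,
#' FQ<0.025 with a 5 bp indel window; mutation rate 1e-9 per bp per
#' generation and a 365x24-hour year.
#'
#' @param shared,metadata Paths for the community pipeline.
#' @param vcfs Named character vector of per-isolate VCF paths.
#' @param phage_repeat_bed,recombinant_gff Mask paths (optional).
#' @param callable_beds Named character vector of per-isolate callable BED
#'   paths (optional).
#' @param out_dir Output directory.
#' @param min_total Depth-exclusion threshold (default 1000).
#' @param min_total_seqs,min_max_relab Display-OTU thresholds (200, 0.02).
#' @param hard_filters A [hard_filter_config()].
#' @param mutation_rate Substitutions per bp per generation (default 1e-9).
#' @param age_years Host age for the estimator (default 20).
#' @param genome_length Optional core-genome length override for the
#'   estimator; when `NULL` the masked core length measured by the cascade
#'   is used.
#' @param estimate_pairs List of 2-element character vectors of isolate ids
#'   to estimate on; `NULL` means every mother/daughter-style pair.
#' @param seed Integer seed for any stage that draws randomness.
#' @param verbose Print stage log lines (default TRUE).
#' @return A list of class `run_config`.
#' @export
run_config <- function(shared = NULL, metadata = NULL, vcfs = NULL,
                       phage_repeat_bed = NULL, recombinant_gff = NULL,
                       callable_beds = NULL, out_dir = tempfile("vertmicro_run_"),
                       min_total = 1000, min_total_seqs = 200,
                       min_max_relab = 0.02,
                       hard_filters = hard_filter_config(),
                       mutation_rate = 1e-9, age_years = 20,
                       genome_length = NULL, estimate_pairs = NULL,
                       seed = 1, verbose = TRUE) {
  structure(list(shared = shared, metadata = metadata, vcfs = vcfs,
                 phage_repeat_bed = phage_repeat_bed,
                 recombinant_gff = recombinant_gff,
                 callable_beds = callable_beds, out_dir = out_dir,
                 min_total = min_total, min_total_seqs = min_total_seqs,
                 min_max_relab = min_max_relab, hard_filters = hard_filters,
                 mutation_rate = mutation_rate, age_years = age_years,
                 genome_length = genome_length,
                 estimate_pairs = estimate_pairs, seed = as.integer(seed),
                 verbose = verbose),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level YAML keys mirror the [run_config()] arguments; keys under
#' `hard_filters:` mirror [hard_filter_config()].
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  hf <- do.call(hard_filter_config, y$hard_filters %||% list())
  y$hard_filters <- NULL
  args <- y[names(y) %in% names(formals(run_config))]
  do.call(run_config, c(args, list(hard_filters = hf)))
}

provenance_header <- function(cfg) {
  c(sprintf("# vertmicro %s", as.character(utils::packageVersion("vertmicro"))),
    sprintf("# seed=%d config_hash=%s", cfg$seed,
            rlang::hash(cfg[setdiff(names(cfg), "verbose")])))
}

write_csv_prov <- function(df, path, cfg) {
  writeLines(provenance_header(cfg), path)
  suppressWarnings(
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                       append = TRUE, col.names = TRUE))
  invisible(path)
}

stage_log <- function(cfg, log, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  if (isTRUE(cfg$verbose)) {
    message(sprintf("[%s] %s", stage,
                    paste(names(rec[-1]), unlist(rec[-1]), sep = "=",
                          collapse = " ")))
  }
  c(log, list(rec))
}

#' Run the community-similarity pipeline
#'
#' Reads a shared file and sample metadata, excludes low-depth samples,
#' computes theta-YC distances, groups them, runs the three-group
#' Kruskal-Wallis/Dunn test, the birth-mode and mother-reproductive-stage
#' rank-sum tests (each skipped with an explicit status when a group is
#' empty or the design has a single pair), and ordinates samples by PCoA.
#' Outputs are written under `cfg$out_dir` with fixed names.
#'
#' @param cfg A [run_config()] with `shared` and `metadata` set.
#' @return A list (invisibly returned bundle) with the grouped distances,
#'   test results, ordination, exclusion report, file paths and the stage
#'   log.
#' @export
run_community_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$shared) || is.null(cfg$metadata)) {
    abort("run_community_pipeline needs cfg$shared and cfg$metadata")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  log <- list()

  otu <- read_shared(cfg$shared)
  meta <- read_sample_metadata(cfg$metadata)
  log <- stage_log(cfg, log, "read", n_samples = nrow(otu), n_otus = length(otu_cols(otu)))

  kept <- exclude_low_depth(otu, cfg$min_total)
  excl <- excluded_samples(kept)
  log <- stage_log(cfg, log, "exclude_low_depth", min_total = cfg$min_total,
                   excluded = nrow(excl), kept = nrow(kept))
  write_csv_prov(excl, file.path(cfg$out_dir, "exclusion_report.csv"), cfg)
  if (nrow(kept) < 2) abort("exclude_low_depth: fewer than 2 samples remain")

  meta_kept <- meta[meta$sample_id %in% kept$sample_id, , drop = FALSE]
  disp <- select_display_otus(kept, cfg$min_total_seqs, cfg$min_max_relab)
  write_csv_prov(abundance_long(kept, disp),
                 file.path(cfg$out_dir, "display_abundances.csv"), cfg)
  log <- stage_log(cfg, log, "select_display_otus", n = length(disp))

  dm <- theta_yc_distances(relative_abundance(kept))
  write_distance_matrix(dm, file.path(cfg$out_dir, "sample_distances.csv"),
                        "tidy_csv")
  log <- stage_log(cfg, log, "theta_yc", n_samples = nrow(dm))

  gd <- group_distances(dm, meta_kept)
  subj_dm <- attr(gd, "subject_distances")
  write_distance_matrix(subj_dm,
                        file.path(cfg$out_dir, "subject_distances.csv"),
                        "tidy_csv")
  write_csv_prov(as_tibble(gd), file.path(cfg$out_dir, "grouped_distances.csv"),
                 cfg)
  counts <- attr(gd, "counts")
  log <- stage_log(cfg, log, "group_distances",
                   n_subjects = counts[["n_subjects"]],
                   n_pairs = counts[["n_pairs"]])

  tests <- list()
  n_groups <- length(unique(as_tibble(gd)$group))
  if (n_groups >= 2 && counts[["n_pairs"]] >= 2) {
    kw <- kruskal_dunn(gd, value, group)
    tests$three_group <- list(status = "ok", glance = glance(kw),
                              posttest = tidy(kw))
    log <- stage_log(cfg, log, "kruskal_dunn", p = kw$p_value)
  } else {
    tests$three_group <- list(status = "insufficient groups")
    log <- stage_log(cfg, log, "kruskal_dunn", status = "insufficient groups")
  }

  wp <- within_pair_table(gd, meta_kept)
  bm_v <- wp$value[wp$birth_mode_of_daughter == "vaginal"]
  bm_c <- wp$value[wp$birth_mode_of_daughter == "c_section"]
  if (length(bm_v) >= 1 && length(bm_c) >= 1) {
    bt <- wilcoxon_rank_sum(bm_v, bm_c)
    tests$birth_mode <- list(status = "ok", glance = glance(bt))
    log <- stage_log(cfg, log, "birth_mode_test", p = bt$p_value)
  } else {
    tests$birth_mode <- list(status = "insufficient groups")
    log <- stage_log(cfg, log, "birth_mode_test", status = "insufficient groups")
  }

  st_r <- wp$value[wp$mother_stage == "reproductive"]
  st_p <- wp$value[wp$mother_stage == "postmenopausal"]
  if (length(st_r) >= 1 && length(st_p) >= 1) {
    stt <- wilcoxon_rank_sum(st_r, st_p)
    tests$mother_stage <- list(status = "ok", glance = glance(stt))
    log <- stage_log(cfg, log, "mother_stage_test", p = stt$p_value)
  } else {
    tests$mother_stage <- list(status = "insufficient groups")
    log <- stage_log(cfg, log, "mother_stage_test", status = "insufficient groups")
  }
  jsonlite::write_json(
    lapply(tests, function(t) {
      t[names(t) %in% c("status", "glance", "posttest")]
    }), file.path(cfg$out_dir, "test_results.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  ord <- pcoa_ordination(dm, n_axes = min(3, nrow(dm) - 1))
  write_csv_prov(tidy(ord), file.path(cfg$out_dir, "pcoa_coordinates.csv"), cfg)
  log <- stage_log(cfg, log, "pcoa",
                   axis1 = round(ord$prop_variance[1], 4))

  jsonlite::write_json(log, file.path(cfg$out_dir, "stage_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(otu_table = kept, metadata = meta_kept, exclusions = excl,
                 distances = dm, grouped = gd, tests = tests,
                 ordination = ord, log = log, out_dir = cfg$out_dir))
}

#' Run the strain-transmission pipeline
#'
#' Reads per-isolate VCFs and masks, applies the filter cascade, writes
#' filter reports and the SNP distance matrix, and computes the
#' molecular-clock estimate for each requested isolate pair. The genome
#' length fed to the estimator defaults to the measured length of the
#' masked core genome (core minus phage/repeat minus recombinant tracts)
#' and can be overridden via `cfg$genome_length`.
#'
#' @param cfg A [run_config()] with `vcfs` set (named by isolate).
#' @return A list with the cascade result, estimates and file paths.
#' @export
run_transmission_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$vcfs)) abort("run_transmission_pipeline needs cfg$vcfs")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  log <- list()

  masks <- list()
  if (!is.null(cfg$phage_repeat_bed)) {
    masks$phage_repeat <- read_intervals(cfg$phage_repeat_bed, "bed", "phage")
  }
  if (!is.null(cfg$recombinant_gff)) {
    masks$recombinant <- read_intervals(cfg$recombinant_gff, "gff", "recombinant")
  }
  if (!is.null(cfg$callable_beds)) {
    masks$callable <- lapply(cfg$callable_beds, read_intervals,
                             dialect = "bed", label = "callable")
  }
  log <- stage_log(cfg, log, "read_masks",
                   phage_repeat = !is.null(masks$phage_repeat),
                   recombinant = !is.null(masks$recombinant),
                   callable = length(masks$callable %||% list()))

  casc <- run_filter_cascade(as.list(cfg$vcfs), masks, cfg$hard_filters)
  write_csv_prov(casc$reports, file.path(cfg$out_dir, "filter_reports.csv"), cfg)
  jsonlite::write_json(casc$reports,
                       file.path(cfg$out_dir, "filter_reports.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_distance_matrix(casc$distances,
                        file.path(cfg$out_dir, "snp_distances.csv"), "tidy_csv")
  write_distance_matrix(casc$distances,
                        file.path(cfg$out_dir, "snp_distances.phylip"),
                        "phylip_lower")
  for (i in seq_len(nrow(casc$reports))) {
    log <- stage_log(cfg, log, "filter_cascade",
                     isolate = casc$reports$isolate[i],
                     input = casc$reports$input[i],
                     surviving = casc$reports$surviving[i])
  }

  L <- cfg$genome_length %||% {
    if (is.null(casc$core)) {
      abort("no callable masks and no genome_length override: cannot size the core genome")
    }
    eff <- subtract_intervals(casc$core, masks$phage_repeat %||%
                                interval_tibble(character(), double(), double()))
    eff <- subtract_intervals(eff, masks$recombinant %||%
                                interval_tibble(character(), double(), double()))
    interval_total_length(eff)
  }
  log <- stage_log(cfg, log, "core_genome_length", bp = L)

  pairs <- cfg$estimate_pairs
  if (is.null(pairs)) {
    ids <- rownames(casc$distances)
    cmb <- utils::combn(ids, 2, simplify = FALSE)
    pairs <- cmb
  }
  estimates <- list()
  for (pr in pairs) {
    s <- casc$distances[pr[1], pr[2]]
    key <- paste(pr, collapse = "-")
    if (s == 0) {
      estimates[[key]] <- list(status = "error: zero surviving SNPs, doubling time unbounded")
      log <- stage_log(cfg, log, "estimate", pair = key, status = "zero_snps")
      next
    }
    est <- transmission_estimate(s, cfg$age_years, L, cfg$mutation_rate)
    estimates[[key]] <- c(list(status = "ok"), as.list(tidy(est)))
    log <- stage_log(cfg, log, "estimate", pair = key,
                     doubling_time_hours = est$doubling_time_hours_rounded)
  }
  jsonlite::write_json(estimates, file.path(cfg$out_dir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(log, file.path(cfg$out_dir, "stage_log.json"),
                       auto_unbox = TRUE, digits = NA)
  failed <- any(vapply(estimates, function(e) !identical(e$status, "ok"),
                       logical(1)))
  invisible(list(cascade = casc, estimates = estimates, core_length = L,
                 any_error = failed, log = log, out_dir = cfg$out_dir))
}
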