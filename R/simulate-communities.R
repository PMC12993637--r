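# Dirichlet-multinomial simulator for weekly-sampled mother/daughter vaginal
# communities. Transmission is modelled as a convex mixture: the daughter's
# latent composition is lambda * mother + (1 - lambda) * an independent
# draw, with lambda depending on birth mode (vaginal > C-section). Weekly
# samples resample each subject's latent composition with concentration
# kappa (large kappa = stable communities), then counts are multinomial at
# a negative-binomial sequencing depth with a small low-depth fraction to
# exercise the depth exclusion.

#' Configuration for the paired-community simulator
#'
#' Defaults emulate the study cohort: 13 mother/daughter pairs (3 of 13
#' daughters born by C-section), 5 weekly samples per subject and roughly
#' 23,000 +/- 10,000 reads per sample with ~5% of samples below the
#' 1000-read exclusion threshold.
#'
#' @param n_pairs Number of mother/daughter pairs (default 13).
#' @param n_weeks Weekly samples per subject (default 5, weeks 0-4).
#' @param n_otus Number of OTUs in the simulated table (default 40).
#' @param base_concentration Per-OTU symmetric Dirichlet concentration for
#'   latent compositions (default 0.2; sparse, dominance-prone communities).
#' @param lambda_vaginal,lambda_csection Transmission mixing weights in
#'   `[0, 1]` for vaginally-born and C-section-born daughters (defaults
#'   0.7 and 0.15).
#' @param kappa Within-subject stability: Dirichlet concentration for
#'   weekly resampling of the latent composition (default 100).
#' @param depth_mean,depth_dispersion Negative-binomial mean and size for
#'   per-sample read depth (defaults 23000 and 5).
#' @param low_depth_fraction Fraction of samples forced below 1000 reads
#'   (default 0.05).
#' @param fraction_csection Fraction of daughters born by C-section
#'   (default 3/13).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `community_sim_config`.
#' @export
community_sim_config <- function(n_pairs = 13, n_weeks = 5, n_otus = 40,
                                 base_concentration = 0.2,
                                 lambda_vaginal = 0.7, lambda_csection = 0.15,
                                 kappa = 100, depth_mean = 23000,
                                 depth_dispersion = 5,
                                 low_depth_fraction = 0.05,
                                 fraction_csection = 3 / 13, seed = 1) {
  cfg <- list(n_pairs = n_pairs, n_weeks = n_weeks, n_otus = n_otus,
              base_concentration = base_concentration,
              lambda_vaginal = lambda_vaginal,
              lambda_csection = lambda_csection, kappa = kappa,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              low_depth_fraction = low_depth_fraction,
              fraction_csection = fraction_csection, seed = as.integer(seed))
  with(cfg, {
    if (n_pairs < 1 || n_weeks < 1 || n_otus < 2) {
      abort("need n_pairs >= 1, n_weeks >= 1, n_otus >= 2")
    }
    if (lambda_vaginal < 0 || lambda_vaginal > 1 ||
        lambda_csection < 0 || lambda_csection > 1) {
      abort("transmission weights must lie in [0, 1]")
    }
    if (base_concentration <= 0 || kappa <= 0 || depth_dispersion <= 0) {
      abort("concentrations and dispersion must be positive")
    }
    if (low_depth_fraction < 0 || low_depth_fraction > 1 ||
        fraction_csection < 0 || fraction_csection > 1) {
      abort("fractions must lie in [0, 1]")
    }
  })
  structure(cfg, class = "community_sim_config")
}

#' Simulate a weekly-sampled mother/daughter cohort
#'
#' @param cfg A [community_sim_config()].
#' @return A list with `otu_table` (count tibble, shared-file layout),
#'   `metadata` (validated sample metadata tibble) and `truth` (latent
#'   compositions, mixing weights and per-sample depths). Deterministic
#'   given `cfg$seed`.
#' @export
simulate_pair_cohort <- function(cfg = community_sim_config()) {
  stopifnot(inherits(cfg, "community_sim_config"))
  set.seed(cfg$seed)
  n_cs <- round(cfg$n_pairs * cfg$fraction_csection)
  pair_ids <- sprintf("P%02d", seq_len(cfg$n_pairs))
  birth_mode <- rep("vaginal", cfg$n_pairs)
  if (n_cs > 0) birth_mode[seq.int(cfg$n_pairs - n_cs + 1, cfg$n_pairs)] <- "c_section"
  alpha <- rep(cfg$base_concentration, cfg$n_otus)
  otu_ids <- sprintf("Otu%03d", seq_len(cfg$n_otus))

  rows <- list(); meta <- list()
  truth_pairs <- list()
  for (p in seq_len(cfg$n_pairs)) {
    lambda <- if (birth_mode[p] == "vaginal") cfg$lambda_vaginal else cfg$lambda_csection
    mother <- rdirichlet1(alpha)
    indep <- rdirichlet1(alpha)
    daughter <- lambda * mother + (1 - lambda) * indep
    mother_stage <- if (birth_mode[p] == "vaginal") {
      if (runif(1) < 0.7) "reproductive" else "postmenopausal"
    } else {
      if (runif(1) < 1 / 3) "reproductive" else "postmenopausal"
    }
    daughter_stage <- if (runif(1) < 1 / 13) "premenarchal" else "reproductive"
    comps <- list(mother = mother, daughter = daughter)
    stages <- c(mother = mother_stage, daughter = daughter_stage)
    sample_comps <- list()
    for (role in c("mother", "daughter")) {
      subject <- paste0(pair_ids[p], if (role == "mother") "M" else "D")
      for (w in seq_len(cfg$n_weeks) - 1L) {
        comp_w <- rdirichlet1(cfg$kappa * comps[[role]])
        depth <- if (runif(1) < cfg$low_depth_fraction) {
          sample(100:999, 1)
        } else {
          max(1000L, stats::rnbinom(1, size = cfg$depth_dispersion,
                                    mu = cfg$depth_mean))
        }
        counts <- as.integer(rmultinom(1, depth, comp_w))
        sid <- sprintf("%s_w%d", subject, w)
        rows[[sid]] <- counts
        sample_comps[[sid]] <- comp_w
        meta[[sid]] <- tibble(
          sample_id = sid, subject_id = subject, pair_id = pair_ids[p],
          role = role, week_index = w,
          birth_mode_of_daughter = birth_mode[p],
          reproductive_stage = stages[[role]],
          menstruating = if (stages[[role]] == "reproductive")
            sample(c(TRUE, FALSE, NA), 1) else NA)
      }
    }
    truth_pairs[[pair_ids[p]]] <- list(
      lambda = lambda, birth_mode = birth_mode[p],
      mother_composition = mother, daughter_composition = daughter,
      independent_component = indep, sample_compositions = sample_comps)
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- otu_ids
  otu_table <- dplyr::bind_cols(
    tibble(sample_id = names(rows)),
    as_tibble(as.data.frame(counts), .name_repair = "minimal"))
  attr(otu_table, "otu_label") <- "0.03"
  metadata <- validate_sample_metadata(dplyr::bind_rows(meta))
  list(otu_table = otu_table, metadata = metadata,
       truth = list(pairs = truth_pairs, config = unclass(cfg)))
}

#' Write a simulated cohort to disk
#'
#' Emits the mothur-style shared file and the metadata CSV (and optionally
#' the generating truth as JSON) under `dir`.
#'
#' @param sim Result of [simulate_pair_cohort()].
#' @param dir Output directory (created if needed).
#' @param write_truth Also write `truth.json` (default TRUE).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort_sim <- function(sim, dir, write_truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shared <- file.path(dir, "cohort.shared")
  meta <- file.path(dir, "metadata.csv")
  write_shared(sim$otu_table, shared)
  readr::write_csv(sim$metadata, meta, progress = FALSE)
  paths <- c(shared = shared, metadata = meta)
  if (write_truth) {
    truth <- file.path(dir, "truth.json")
    jsonlite::write_json(sim$truth, truth, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth = truth)
  }
  invisible(paths)
}
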