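# Clonal genome-divergence simulator. Two lineages (mother and daughter)
# descend from a common ancestor at the daughter's birth; each accumulates
# Poisson(mu * L * G) point mutations over G = age_hours / doubling_time
# generations, at uniform positions redrawn on collision so all mutations
# are non-convergent. The mother contributes several isolates that share a
# trunk fraction of her branch. Recombinant tracts with dense SNPs are
# overlaid on random recipient isolates, and per-variant quality fields are
# drawn so a configurable fraction violates each hard filter.

#' Configuration for the genome-divergence simulator
#'
#' Defaults emulate the strain-transmission scenario: a ~941 kb
#' recombination-filtered core genome, mutation rate 1e-9 per bp per
#' generation, a 20-year-old daughter and a 13.2-hour doubling time, giving
#' about 25 expected clonal SNPs between a mother isolate and the
#' daughter's.
#'
#' @param genome_length Reference length in bp (default 940943).
#' @param mutation_rate Substitutions per bp per generation (default 1e-9).
#' @param doubling_time_hours Generation time in hours (default 13.2).
#' @param host_age_years Divergence time in years (default 20).
#' @param n_isolates_mother Number of mother isolates (default 2).
#' @param mother_split_fraction Fraction of the mother branch shared by her
#'   isolates before they split (default 0.75).
#' @param recomb_n_tracts,recomb_tract_length,recomb_snp_density Number,
#'   length (bp) and per-bp SNP density of horizontally acquired tracts
#'   (defaults 3, 5000, 0.005 — far denser than the clonal signal).
#' @param phage_repeat_fraction Fraction of the genome masked as
#'   phage/repeat (default 0.05).
#' @param uncallable_fraction Per-isolate fraction of the genome that is
#'   not callable (default 0.02).
#' @param hard_filter_fail_rate Independent probability that a variant's
#'   quality fields violate each hard filter (default 0.01).
#' @param n_indels Background indels per isolate (default 2).
#' @param seed Integer seed.
#' @return A list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(genome_length = 940943, mutation_rate = 1e-9,
                              doubling_time_hours = 13.2, host_age_years = 20,
                              n_isolates_mother = 2,
                              mother_split_fraction = 0.75,
                              recomb_n_tracts = 3, recomb_tract_length = 5000,
                              recomb_snp_density = 0.005,
                              phage_repeat_fraction = 0.05,
                              uncallable_fraction = 0.02,
                              hard_filter_fail_rate = 0.01,
                              n_indels = 2, seed = 1) {
  cfg <- list(genome_length = as.integer(genome_length),
              mutation_rate = mutation_rate,
              doubling_time_hours = doubling_time_hours,
              host_age_years = host_age_years,
              n_isolates_mother = as.integer(n_isolates_mother),
              mother_split_fraction = mother_split_fraction,
              recomb_n_tracts = as.integer(recomb_n_tracts),
              recomb_tract_length = as.integer(recomb_tract_length),
              recomb_snp_density = recomb_snp_density,
              phage_repeat_fraction = phage_repeat_fraction,
              uncallable_fraction = uncallable_fraction,
              hard_filter_fail_rate = hard_filter_fail_rate,
              n_indels = as.integer(n_indels), seed = as.integer(seed))
  with(cfg, {
    stopifnot(genome_length > 0, mutation_rate > 0, doubling_time_hours > 0,
              host_age_years > 0, n_isolates_mother >= 1,
              mother_split_fraction >= 0, mother_split_fraction <= 1,
              recomb_n_tracts >= 0, recomb_snp_density >= 0,
              phage_repeat_fraction >= 0, phage_repeat_fraction < 1,
              uncallable_fraction >= 0, uncallable_fraction < 1,
              hard_filter_fail_rate >= 0, hard_filter_fail_rate < 1)
  })
  exp_per_lineage <- with(cfg, mutation_rate * genome_length *
                            age_to_hours(host_age_years) / doubling_time_hours)
  if (exp_per_lineage > cfg$genome_length / 10) {
    abort("expected mutations exceed genome_length/10: sparse-SNP model invalid")
  }
  structure(cfg, class = "genome_sim_config")
}

#' Expected clonal pairwise SNP count between a mother and daughter isolate
#'
#' The analytic expectation `2 * mu * L * G` with `G = age_hours /
#' doubling_time`: both lineages accumulate mutations for the full
#' divergence time.
#'
#' @param cfg A [genome_sim_config()].
#' @return Expected SNP count (real).
#' @export
expected_snp_count <- function(cfg) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  2 * cfg$mutation_rate * cfg$genome_length *
    age_to_hours(cfg$host_age_years) / cfg$doubling_time_hours
}

BASES <- c("A", "C", "G", "T")

# draw variant quality fields; with prob fail_rate each hard filter is
# independently violated. Returns a tibble of fields + injected-fail flags.
draw_quality_fields <- function(n, fail_rate) {
  fail_q <- runif(n) < fail_rate
  fail_m <- runif(n) < fail_rate
  fail_d <- runif(n) < fail_rate
  fail_f <- runif(n) < fail_rate
  tibble(
    qual = ifelse(fail_q, runif(n, 20, 100), runif(n, 150, 250)),
    mq = ifelse(fail_m, runif(n, 10, 50), runif(n, 55, 65)),
    alt_depth = ifelse(fail_d, sample(0:9, n, replace = TRUE),
                       10 + rpois(n, 25)),
    fq = ifelse(fail_f, runif(n, 0.025, 1), runif(n, 0, 0.02)),
    inj_fail = fail_q | fail_m | fail_d | fail_f)
}

# random non-overlapping intervals covering about `fraction` of [0, L)
random_mask_intervals <- function(L, fraction, n_chunks, chrom) {
  if (fraction <= 0 || n_chunks == 0) {
    return(interval_tibble(character(), double(), double()))
  }
  width <- max(1, round(L * fraction / n_chunks))
  starts <- sort(sample.int(L - width, n_chunks))
  normalize_intervals(interval_tibble(rep(chrom, n_chunks), starts,
                                      pmin(starts + width, L)))
}

#' Simulate isolate genomes diverging from a common ancestor
#'
#' @param cfg A [genome_sim_config()].
#' @return A list with:
#' \describe{
#'   \item{variants}{named list of per-isolate variant tibbles (daughter
#'     `D1`, mother isolates `M1`, `M2`, ...) in the layout of
#'     [read_vcf_records()];}
#'   \item{masks}{list with `phage_repeat`, per-isolate `callable` interval
#'     sets and `recombinant` tracts, ready for [run_filter_cascade()];}
#'   \item{truth}{clonal SNP positions per branch, recombinant SNP
#'     positions, injected quality failures, true pairwise clonal counts
#'     and the generating config.}
#' }
#' Deterministic given `cfg$seed`.
#' @export
simulate_genome_divergence <- function(cfg = genome_sim_config()) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$genome_length
  chrom <- "ref"
  G <- age_to_hours(cfg$host_age_years) / cfg$doubling_time_hours
  rate <- cfg$mutation_rate * L

  k <- cfg$n_isolates_mother
  iso_ids <- c(paste0("M", seq_len(k)), "D1")
  # branch structure: daughter branch (G), mother trunk (split*G), mother
  # private branches ((1-split)*G each)
  n_daughter <- rpois(1, rate * G)
  n_trunk <- rpois(1, rate * G * cfg$mother_split_fraction)
  n_priv <- rpois(k, rate * G * (1 - cfg$mother_split_fraction))
  if (k == 1) { n_trunk <- n_trunk + n_priv[1]; n_priv <- 0L }
  total <- n_daughter + n_trunk + sum(n_priv)
  # unique positions across all branches = non-convergent mutations
  pos_all <- sample.int(L, total, replace = FALSE)
  split_idx <- rep(c("D", "trunk", paste0("priv", seq_len(k))),
                   c(n_daughter, n_trunk, n_priv))
  branch_pos <- split(pos_all, factor(split_idx,
                                      levels = c("D", "trunk",
                                                 paste0("priv", seq_len(k)))))
  ref_base <- sample(BASES, total, replace = TRUE)
  alt_base <- vapply(ref_base, function(b) sample(setdiff(BASES, b), 1),
                     character(1), USE.NAMES = FALSE)
  allele_of <- setNames(paste(ref_base, alt_base, sep = ">"), pos_all)

  clonal_sets <- setNames(vector("list", k + 1), iso_ids)
  for (i in seq_len(k)) {
    clonal_sets[[paste0("M", i)]] <-
      sort(c(branch_pos$trunk, branch_pos[[paste0("priv", i)]]))
  }
  clonal_sets[["D1"]] <- sort(branch_pos$D)

  # recombinant tracts: random recipient isolate, dense SNPs inside
  tracts <- interval_tibble(character(), double(), double(), label = "recombinant")
  recomb_sets <- setNames(rep(list(integer(0)), k + 1), iso_ids)
  if (cfg$recomb_n_tracts > 0) {
    tl <- min(cfg$recomb_tract_length, L)
    starts <- sample.int(L - tl, cfg$recomb_n_tracts)
    tracts <- normalize_intervals(
      interval_tibble(rep(chrom, cfg$recomb_n_tracts), starts, starts + tl,
                      label = "recombinant"))
    for (t in seq_len(cfg$recomb_n_tracts)) {
      recipient <- sample(iso_ids, 1)
      n_snp <- rbinom(1, tl, cfg$recomb_snp_density)
      if (n_snp == 0) next
      p <- starts[t] + sample.int(tl, n_snp) # 1-based within (start, start+tl]
      recomb_sets[[recipient]] <- sort(union(recomb_sets[[recipient]], p))
    }
  }

  masks_pr <- random_mask_intervals(L, cfg$phage_repeat_fraction, 5, chrom)
  callable <- setNames(lapply(iso_ids, function(i) {
    unc <- random_mask_intervals(L, cfg$uncallable_fraction, 4, chrom)
    subtract_intervals(interval_tibble(chrom, 0, L, label = "callable"), unc)
  }), iso_ids)

  variants <- list(); truth_fail <- list()
  for (iso in iso_ids) {
    cl <- clonal_sets[[iso]]
    rc <- setdiff(recomb_sets[[iso]], cl)
    pos <- c(cl, rc)
    is_recomb <- c(rep(FALSE, length(cl)), rep(TRUE, length(rc)))
    o <- order(pos)
    pos <- pos[o]; is_recomb <- is_recomb[o]
    n <- length(pos)
    ref <- alt <- character(n)
    known <- as.character(pos) %in% names(allele_of)
    pair <- strsplit(ifelse(known, allele_of[as.character(pos)], NA), ">",
                     fixed = TRUE)
    for (i in seq_len(n)) {
      if (known[i]) {
        ref[i] <- pair[[i]][1]; alt[i] <- pair[[i]][2]
      } else { # recombinant-only position
        ref[i] <- sample(BASES, 1)
        alt[i] <- sample(setdiff(BASES, ref[i]), 1)
      }
    }
    q <- draw_quality_fields(n, cfg$hard_filter_fail_rate)
    snvs <- tibble(chrom = rep(chrom, n), pos = as.integer(pos), ref = ref,
                   alt = alt, qual = q$qual, mq = q$mq,
                   alt_depth = q$alt_depth, fq = q$fq,
                   is_indel = FALSE, unscorable = FALSE)
    truth_fail[[iso]] <- tibble(pos = as.integer(pos), injected_fail = q$inj_fail,
                                recombinant = is_recomb)
    n_ind <- cfg$n_indels
    if (n_ind > 0) {
      ipos <- sample.int(L - 1, n_ind)
      iref <- sample(BASES, n_ind, replace = TRUE)
      qi <- draw_quality_fields(n_ind, 0)
      indels <- tibble(chrom = rep(chrom, n_ind), pos = as.integer(ipos),
                       ref = iref, alt = paste0(iref, "A"), qual = qi$qual,
                       mq = qi$mq, alt_depth = qi$alt_depth, fq = qi$fq,
                       is_indel = TRUE, unscorable = FALSE)
      snvs <- dplyr::arrange(dplyr::bind_rows(snvs, indels), .data$pos)
    }
    variants[[iso]] <- snvs
  }

  clonal_dist <- matrix(0L, k + 1, k + 1, dimnames = list(iso_ids, iso_ids))
  for (i in seq_along(iso_ids)) {
    for (j in seq_along(iso_ids)) {
      if (j <= i) next
      a <- clonal_sets[[iso_ids[i]]]; b <- clonal_sets[[iso_ids[j]]]
      clonal_dist[i, j] <- clonal_dist[j, i] <-
        length(setdiff(a, b)) + length(setdiff(b, a))
    }
  }

  list(
    variants = variants,
    masks = list(phage_repeat = masks_pr, callable = callable,
                 recombinant = tracts),
    truth = list(clonal_positions = clonal_sets,
                 recombinant_positions = recomb_sets,
                 quality = truth_fail,
                 clonal_distances = clonal_dist,
                 expected_pairwise_snps = expected_snp_count(cfg),
                 generations = G, config = unclass(cfg)))
}

# minimal VCF writer for simulator output (bcftools-like INFO fields)
write_sim_vcf <- function(records, path, contig_length) {
  info <- sprintf("DP=%d;DP4=%d,%d,%d,%d;MQ=%.2f;FQ=%g",
                  as.integer(2 * round(records$alt_depth) + 20), 10L, 10L,
                  as.integer(ceiling(round(records$alt_depth) / 2)),
                  as.integer(floor(round(records$alt_depth) / 2)),
                  records$mq, records$fq)
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", records$chrom[1] %||% "ref",
            contig_length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw depth\">",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Ref fwd, ref rev, alt fwd, alt rev\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=FQ,Number=1,Type=Float,Description=\"Consensus quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t%.2f\t.\t%s", records$chrom,
            records$pos, records$ref, records$alt, records$qual, info))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated genome-divergence experiment to disk
#'
#' Emits one VCF per isolate, BED masks (phage/repeat and per-isolate
#' callable intervals), the recombinant tracts as GFF3 and the truth as
#' JSON under `dir`. Optionally a random reference FASTA of the configured
#' length.
#'
#' @param sim Result of [simulate_genome_divergence()].
#' @param dir Output directory.
#' @param write_reference Also write `reference.fasta` (default FALSE; the
#'   pipeline never needs the sequence itself).
#' @return Named list of file paths, invisibly.
#' @export
write_genome_sim <- function(sim, dir, write_reference = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- sim$truth$config$genome_length
  vcfs <- vapply(names(sim$variants), function(iso) {
    p <- file.path(dir, paste0(iso, ".vcf"))
    write_sim_vcf(sim$variants[[iso]], p, L)
    p
  }, character(1))
  pr <- file.path(dir, "phage_repeat.bed")
  write_bed(sim$masks$phage_repeat, pr)
  callable <- vapply(names(sim$masks$callable), function(iso) {
    p <- file.path(dir, paste0(iso, ".callable.bed"))
    write_bed(sim$masks$callable[[iso]], p)
    p
  }, character(1))
  gff <- file.path(dir, "recombinant.gff")
  write_gff(sim$masks$recombinant, gff)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth[setdiff(names(sim$truth), "quality")],
                       truth, auto_unbox = TRUE, digits = NA, force = TRUE)
  paths <- list(vcfs = vcfs, phage_repeat = pr, callable = callable,
                recombinant = gff, truth = truth)
  if (write_reference) {
    fa <- file.path(dir, "reference.fasta")
    set.seed(sim$truth$config$seed)
    seq <- paste(sample(BASES, L, replace = TRUE), collapse = "")
    writeLines(c(">ref synthetic reference",
                 substring(seq, seq(1, L, 70), pmin(seq(70, L + 69, 70), L))),
               fa)
    paths$reference <- fa
  }
  invisible(paths)
}
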