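test_that("expected SNP count follows 2 mu L G", {
  cfg <- genome_sim_config(mutation_rate = 1e-9, genome_length = 1e6,
                           doubling_time_hours = 13.2, host_age_years = 20)
  expect_equal(expected_snp_count(cfg), 2 * 1e-9 * 1e6 * 175200 / 13.2)
  half <- genome_sim_config(mutation_rate = 1e-9, genome_length = 1e6,
                            doubling_time_hours = 26.4, host_age_years = 20)
  expect_equal(expected_snp_count(half), expected_snp_count(cfg) / 2)
  expect_error(genome_sim_config(host_age_years = 1e-9), NA) # tiny age fine
  expect_error(genome_sim_config(doubling_time_hours = 1e-7),
               "sparse-SNP model")
})

test_that("the genome generator is deterministic and non-convergent", {
  cfg <- genome_sim_config(seed = 5)
  a <- simulate_genome_divergence(cfg)
  b <- simulate_genome_divergence(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth$clonal_distances, b$truth$clonal_distances)
  # clonal mutations never collide across lineages: the daughter branch is
  # disjoint from both mother isolates, which share only their trunk
  cl <- a$truth$clonal_positions
  expect_equal(length(intersect(cl$D1, cl$M1)), 0)
  expect_equal(length(intersect(cl$D1, cl$M2)), 0)
  trunk <- intersect(cl$M1, cl$M2)
  expect_equal(a$truth$clonal_distances["M1", "M2"],
               as.integer(length(cl$M1) + length(cl$M2) - 2 * length(trunk)))
})

test_that("with no tracts and clean quality fields the cascade recovers truth exactly", {
  cfg <- genome_sim_config(recomb_n_tracts = 0, hard_filter_fail_rate = 0,
                           phage_repeat_fraction = 0, uncallable_fraction = 0,
                           n_indels = 0, seed = 21)
  sim <- simulate_genome_divergence(cfg)
  casc <- run_filter_cascade(sim$variants, sim$masks)
  expect_equal(casc$distances, sim$truth$clonal_distances)
  expect_true(all(casc$reports$input == casc$reports$surviving))
})

test_that("with masks equal to the true tract set, filtered distances match truth outside masks", {
  cfg <- genome_sim_config(hard_filter_fail_rate = 0, n_indels = 0, seed = 22)
  sim <- simulate_genome_divergence(cfg)
  casc <- suppressWarnings(run_filter_cascade(sim$variants, sim$masks))
  ids <- names(sim$variants)
  keep <- function(iso) {
    pos <- sim$truth$clonal_positions[[iso]]
    inside_pr <- vertmicro:::positions_in_intervals(rep("ref", length(pos)),
                                                    pos - 1, sim$masks$phage_repeat)
    inside_core <- vertmicro:::positions_in_intervals(rep("ref", length(pos)),
                                                      pos - 1, casc$core)
    inside_rc <- vertmicro:::positions_in_intervals(rep("ref", length(pos)),
                                                    pos - 1, sim$masks$recombinant)
    pos[!inside_pr & inside_core & !inside_rc]
  }
  for (a in ids) for (b in ids) {
    if (a >= b) next
    ka <- keep(a); kb <- keep(b)
    want <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
    expect_equal(casc$distances[a, b], as.integer(want))
  }
})

test_that("simulated mean pairwise SNP count tracks the analytic expectation", {
  # modest replicate count here; the acceptance suite runs the full check
  obs <- vapply(1:60, function(r) {
    s <- simulate_genome_divergence(genome_sim_config(seed = 3000 + r))
    s$truth$clonal_distances["M1", "D1"]
  }, double(1))
  expd <- expected_snp_count(genome_sim_config())
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expd), 3 * se)
})

test_that("emitted VCF and mask files reload into the same cascade inputs", {
  cfg <- genome_sim_config(seed = 31)
  sim <- simulate_genome_divergence(cfg)
  dir <- withr::local_tempdir()
  paths <- write_genome_sim(sim, dir)
  v <- read_vcf_records(paths$vcfs[["M1"]])
  orig <- sim$variants$M1
  expect_equal(v$pos, orig$pos)
  expect_equal(v$alt, orig$alt)
  expect_equal(v$is_indel, orig$is_indel)
  expect_equal(v$mq, orig$mq, tolerance = 1e-2)
  expect_equal(v$alt_depth, round(orig$alt_depth))

  rc <- read_intervals(paths$recombinant, "gff")
  expect_equal(rc[, c("start", "end")],
               sim$masks$recombinant[, c("start", "end")], ignore_attr = TRUE)
  cb <- read_intervals(paths$callable[["D1"]], "bed")
  expect_equal(cb[, c("start", "end")],
               sim$masks$callable$D1[, c("start", "end")], ignore_attr = TRUE)
})
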