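test_that("invalid configurations error before any sampling", {
  expect_error(community_sim_config(lambda_vaginal = 1.2), "\\[0, 1\\]")
  expect_error(community_sim_config(kappa = 0), "positive")
  expect_error(community_sim_config(n_otus = 1), "n_otus")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- community_sim_config(n_pairs = 3, seed = 99)
  a <- simulate_pair_cohort(cfg)
  b <- simulate_pair_cohort(cfg)
  expect_identical(a$otu_table, b$otu_table)
  expect_identical(a$metadata, b$metadata)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohort_sim(a, d1, write_truth = FALSE)
  p2 <- write_cohort_sim(b, d2, write_truth = FALSE)
  expect_identical(readLines(p1[["shared"]]), readLines(p2[["shared"]]))

  c2 <- simulate_pair_cohort(community_sim_config(n_pairs = 3, seed = 100))
  expect_false(identical(a$otu_table, c2$otu_table))
})

test_that("cohort structure matches the configuration", {
  sim <- simulate_pair_cohort(community_sim_config(seed = 2))
  expect_equal(nrow(sim$otu_table), 13 * 2 * 5)
  st <- subject_table(sim$metadata)
  expect_equal(sum(st$birth_mode_of_daughter == "c_section") / 2, 3)
  expect_true(all(sim$metadata$week_index %in% 0:4))
  # the generated shared file parses back identically
  dir <- withr::local_tempdir()
  paths <- write_cohort_sim(sim, dir)
  back <- read_shared(paths[["shared"]])
  expect_equal(otu_matrix(back), otu_matrix(sim$otu_table))
  md <- read_sample_metadata(paths[["metadata"]])
  expect_equal(md$sample_id, sim$metadata$sample_id)
})

test_that("perfect transmission and high stability collapse within-pair distances", {
  cfg <- community_sim_config(n_pairs = 4, lambda_vaginal = 1,
                              lambda_csection = 1, kappa = 1e6,
                              low_depth_fraction = 0, seed = 3)
  sim <- simulate_pair_cohort(cfg)
  dm <- theta_yc_distances(relative_abundance(sim$otu_table))
  gd <- group_distances(dm, sim$metadata)
  wp <- gd$value[gd$group == "within_pair"]
  expect_lt(max(wp), 0.05)
})

test_that("lambda = 0 makes within-pair and between-pair exchangeable", {
  # under no transmission every pair of distinct subjects has iid latent
  # compositions, so within-pair subject distances are distributionally
  # identical to pooled cross-pair subject distances
  wp_all <- bp_all <- numeric(0)
  for (r in 1:30) {
    cfg <- community_sim_config(n_pairs = 6, lambda_vaginal = 0,
                                lambda_csection = 0, low_depth_fraction = 0,
                                seed = 7000 + r)
    sim <- simulate_pair_cohort(cfg)
    dm <- theta_yc_distances(relative_abundance(sim$otu_table))
    gd <- group_distances(dm, sim$metadata)
    subj_dm <- attr(gd, "subject_distances")
    st <- subject_table(sim$metadata)
    pair_of <- setNames(st$pair_id, st$subject_id)
    cmb <- utils::combn(rownames(subj_dm), 2)
    same_pair <- pair_of[cmb[1, ]] == pair_of[cmb[2, ]]
    vals <- subj_dm[cbind(cmb[1, ], cmb[2, ])]
    wp_all <- c(wp_all, vals[same_pair])
    bp_all <- c(bp_all, vals[!same_pair])
  }
  # same generating distribution: rank-sum should not reject at alpha=0.01
  p <- wilcoxon_rank_sum(wp_all, bp_all)$p_value
  expect_gt(p, 0.01)
})

test_that("low-depth fraction produces samples under the exclusion threshold", {
  cfg <- community_sim_config(low_depth_fraction = 0.3, seed = 12)
  sim <- simulate_pair_cohort(cfg)
  totals <- sample_totals(sim$otu_table)$total
  expect_gt(sum(totals < 1000), 0)
  expect_true(all(totals[totals >= 1000] >= 1000))
})
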