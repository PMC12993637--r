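test_that("theta-YC matches hand-derived values", {
  expect_equal(theta_yc(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(theta_yc(c(1, 0), c(0, 1)), 1)
  # sum(pq)=0.375, sum(p^2)+sum(q^2)-sum(pq)=0.5 -> theta=0.75, d=0.25
  expect_equal(theta_yc(c(0.5, 0.5, 0), c(0.5, 0.25, 0.25)), 0.25)
})

test_that("named vectors align on the union of OTU ids with zero imputation", {
  p <- c(Otu1 = 0.5, Otu2 = 0.5)
  q <- c(Otu2 = 0.25, Otu3 = 0.75)
  expect_equal(theta_yc(p, q),
               theta_yc(c(0.5, 0.5, 0), c(0, 0.25, 0.75)))
  expect_error(theta_yc(p, c(0.5, 0.5)), "both or neither")
  expect_error(theta_yc(c(0, 0), c(0, 0)), "all-zero")
})

test_that("theta-YC properties hold over random compositions", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(3:12, 1)
    p <- rgamma(k, 0.5); p <- p / sum(p)
    q <- rgamma(k, 0.5); q <- q / sum(q)
    d <- theta_yc(p, q)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, theta_yc(q, p))
    expect_equal(theta_yc(p, p), 0)
    # disjoint supports -> exactly 1
    expect_equal(theta_yc(c(p, rep(0, k)), c(rep(0, k), q)), 1)
    expect_equal(d, theta_yc_oracle(p, q), tolerance = 1e-12)
  }
})

test_that("pairwise matrix equals the double-loop oracle", {
  set.seed(11)
  tab <- tibble::tibble(sample_id = paste0("s", 1:8))
  for (k in 1:6) tab[[paste0("Otu", k)]] <- rpois(8, 30)
  tab <- tab[rowSums(otu_matrix(tab)) > 0, ]
  rel <- relative_abundance(tab)
  dm <- theta_yc_distances(rel)
  expect_equal(dm, pairwise_oracle(otu_matrix(rel)), tolerance = 1e-12)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, nrow(dm)))

  dup <- tibble::tibble(sample_id = c("a", "b"), Otu1 = c(3, 3), Otu2 = c(1, 1))
  expect_equal(unname(theta_yc_distances(dup)), matrix(0, 2, 2))

  bad <- tibble::tibble(sample_id = c("a", "a"), Otu1 = c(1, 2))
  expect_error(theta_yc_distances(bad), "duplicate sample")
})

test_that("subject aggregation averages cross-sample distances", {
  md <- toy_metadata(n_pairs = 1, n_weeks = 2) # 2 subjects x 2 samples
  ids <- md$sample_id
  dm <- matrix(0, 4, 4, dimnames = list(ids, ids))
  cross <- c(0.1, 0.2, 0.3, 0.4)
  mo <- ids[1:2]; da <- ids[3:4]
  dm[mo[1], da[1]] <- dm[da[1], mo[1]] <- 0.1
  dm[mo[1], da[2]] <- dm[da[2], mo[1]] <- 0.2
  dm[mo[2], da[1]] <- dm[da[1], mo[2]] <- 0.3
  dm[mo[2], da[2]] <- dm[da[2], mo[2]] <- 0.4
  dm[mo[1], mo[2]] <- dm[mo[2], mo[1]] <- 0.05
  sub <- aggregate_subject_distances(dm, md)
  expect_equal(sub["P01M", "P01D"], mean(cross))

  # permuting sample order leaves the aggregate unchanged
  perm <- sample(4)
  sub2 <- aggregate_subject_distances(dm[perm, perm], md)
  expect_equal(sub2[rownames(sub), colnames(sub)], sub)

  # single-sample subjects: subject dm equals sample dm
  md1 <- md[md$week_index == 0, ]
  dm1 <- dm[md1$sample_id, md1$sample_id]
  sub1 <- aggregate_subject_distances(dm1, md1)
  expect_equal(unname(sub1), unname(dm1))
})

test_that("grouped distances match a brute-force enumeration on 2 pairs", {
  set.seed(23)
  md <- toy_metadata(n_pairs = 2, n_weeks = 2)
  tab <- tibble::tibble(sample_id = md$sample_id)
  for (k in 1:5) tab[[paste0("Otu", k)]] <- rpois(8, 40) + 1
  dm <- theta_yc_distances(relative_abundance(tab))
  gd <- group_distances(dm, md)

  subj <- setNames(md$subject_id, md$sample_id)
  pair <- setNames(md$pair_id, md$sample_id)
  subj_dm <- aggregate_subject_distances(dm, md)

  # within subject: mean of each subject's own sample pairs
  for (s in unique(md$subject_id)) {
    own <- md$sample_id[md$subject_id == s]
    want <- mean(dm[own[1], own[2]])
    got <- gd$value[gd$group == "within_subject" & gd$entity_id == s]
    expect_equal(got, want)
  }
  # within pair
  for (p in unique(md$pair_id)) {
    mo <- unique(md$subject_id[md$pair_id == p & md$role == "mother"])
    da <- unique(md$subject_id[md$pair_id == p & md$role == "daughter"])
    got <- gd$value[gd$group == "within_pair" & gd$entity_id == p]
    expect_equal(got, subj_dm[mo, da])
  }
  # between pairs: per-subject mean to unrelated subjects
  for (s in rownames(subj_dm)) {
    others <- rownames(subj_dm)[pair[match(rownames(subj_dm), subj)] !=
                                  pair[match(s, subj)]]
    got <- gd$value[gd$group == "between_pair" & gd$entity_id == s]
    expect_equal(got, mean(subj_dm[s, others]))
  }

  counts <- attr(gd, "counts")
  expect_equal(unname(counts["n_subjects"]), 4)
  expect_equal(unname(counts["n_pairs"]), 2)
  expect_equal(unname(counts["n_subjects_multi_sample"]), 4)
})

test_that("unordered subject pairs partition into within-pair and between-pair", {
  sim <- simulate_pair_cohort(community_sim_config(n_pairs = 4, seed = 5))
  dm <- theta_yc_distances(relative_abundance(sim$otu_table))
  gd <- group_distances(dm, sim$metadata)
  n_subj <- attr(gd, "counts")[["n_subjects"]]
  n_within <- attr(gd, "counts")[["n_pairs"]]
  # each subject's between-pair mean covers (n_subj - 2) unrelated subjects;
  # unordered pairs: choose(n,2) = within + between
  subj_dm <- attr(gd, "subject_distances")
  st <- subject_table(sim$metadata)
  pair_of <- setNames(st$pair_id, st$subject_id)
  cmb <- utils::combn(rownames(subj_dm), 2)
  cat_of <- apply(cmb, 2, function(pr) pair_of[pr[1]] == pair_of[pr[2]])
  expect_equal(sum(cat_of), n_within)
  expect_equal(sum(!cat_of) + sum(cat_of), choose(n_subj, 2))
})

test_that("identical samples give zero distances in every group", {
  md <- toy_metadata(n_pairs = 2, n_weeks = 2)
  tab <- tibble::tibble(sample_id = md$sample_id, Otu1 = 10, Otu2 = 5)
  dm <- theta_yc_distances(relative_abundance(tab))
  gd <- group_distances(dm, md)
  expect_true(all(gd$value == 0))
})

test_that("a pair losing one member is omitted and reported", {
  md <- toy_metadata(n_pairs = 2, n_weeks = 2)
  keep <- md$subject_id != "P02D"
  tab <- tibble::tibble(sample_id = md$sample_id[keep], Otu1 = rpois(6, 50) + 1,
                        Otu2 = rpois(6, 50) + 1)
  dm <- theta_yc_distances(relative_abundance(tab))
  gd <- group_distances(dm, md[keep, ])
  expect_equal(attr(gd, "omitted_pairs"), "P02")
  expect_false("P02" %in% gd$entity_id[gd$group == "within_pair"])
})
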