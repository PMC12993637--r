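test_that("hard-filter boundary semantics follow the printed operators", {
  pass <- make_variants(1, qual = 150, mq = 60, alt_depth = 12, fq = 0.01)
  expect_equal(unname(apply_hard_filters(pass)$report[["surviving"]]), 1)

  # QUAL strict: exactly 100 fails
  q100 <- make_variants(1, qual = 100, mq = 60, alt_depth = 12, fq = 0.01)
  r <- apply_hard_filters(q100)$report
  expect_equal(unname(r[["fail_qual"]]), 1)
  expect_equal(unname(r[["surviving"]]), 0)

  # depth inclusive: exactly 10 passes
  d10 <- make_variants(1, qual = 150, mq = 60, alt_depth = 10, fq = 0.01)
  expect_equal(unname(apply_hard_filters(d10)$report[["surviving"]]), 1)

  # MQ strict at 50, FQ strict at 0.025
  mq50 <- make_variants(1, qual = 150, mq = 50, alt_depth = 12, fq = 0.01)
  expect_equal(unname(apply_hard_filters(mq50)$report[["fail_mq"]]), 1)
  fq_edge <- make_variants(1, qual = 150, mq = 60, alt_depth = 12, fq = 0.025)
  expect_equal(unname(apply_hard_filters(fq_edge)$report[["fail_fq"]]), 1)
})

test_that("FQ comparison direction is configurable", {
  v <- make_variants(1, fq = -30) # bcftools-style negative FQ
  expect_equal(unname(apply_hard_filters(v)$report[["surviving"]]), 1)
  flipped <- hard_filter_config(fq_direction = "greater")
  expect_equal(unname(apply_hard_filters(v, flipped)$report[["surviving"]]), 0)
})

test_that("indel proximity window is strict at 5 bp from the indel start", {
  indel <- make_variants(104, alt = "TA", is_indel = TRUE)
  near <- mask_near_indels(make_variants(100), indel)
  expect_equal(nrow(near$pass), 0) # distance 4 -> removed

  far <- mask_near_indels(make_variants(100), make_variants(105, alt = "TA", is_indel = TRUE))
  expect_equal(nrow(far$pass), 1) # distance 5 -> kept

  none <- mask_near_indels(make_variants(c(100, 200)), make_variants(integer(0)))
  expect_equal(nrow(none$pass), 2)
})

test_that("region masks use 0-based membership of pos - 1", {
  mask <- intervals(10, 20)
  inside <- apply_region_masks(make_variants(11), mask) # 0-based 10 in [10,20)
  expect_equal(nrow(inside$removed), 1)
  outside <- apply_region_masks(make_variants(21), mask) # 0-based 20 not in
  expect_equal(nrow(outside$pass), 1)
  empty <- apply_region_masks(make_variants(11), intervals(numeric(0), numeric(0)))
  expect_equal(nrow(empty$pass), 1)
})

test_that("chromosome mismatch keeps the record with a warning", {
  mask <- intervals(0, 1000, chrom = "chr2")
  expect_warning(res <- apply_region_masks(make_variants(11), mask),
                 "not covered by mask")
  expect_equal(nrow(res$pass), 1)
})

test_that("recombination mask removes tract variants and whole-genome tract removes all", {
  v <- make_variants(c(50, 500))
  res <- apply_recombination_mask(v, intervals(40, 60))
  expect_equal(res$pass$pos, 500L)
  all_gone <- apply_recombination_mask(v, intervals(0, 1e6))
  expect_equal(nrow(all_gone$pass), 0)
  identity <- apply_recombination_mask(v, intervals(numeric(0), numeric(0)))
  expect_equal(identity$pass, v)
})

test_that("cascade conserves counts and attributes first failing stage", {
  set.seed(97)
  for (rep in 1:10) {
    sets <- list(A = random_variant_set(60), B = random_variant_set(60))
    masks <- list(phage_repeat = intervals(c(100, 5000), c(600, 5400)),
                  callable = list(intervals(0, 9000), intervals(500, 10000)),
                  recombinant = intervals(8000, 8500))
    res <- suppressWarnings(run_filter_cascade(sets, masks))
    for (i in 1:2) {
      r <- res$reports[i, ]
      stage_sum <- sum(unlist(r[vertmicro:::FILTER_STAGES]))
      expect_equal(r$input, r$surviving + stage_sum)
    }
  }
})

test_that("tightening any threshold never increases survivors", {
  set.seed(131)
  for (rep in 1:10) {
    v <- list(A = random_variant_set(80))
    base <- hard_filter_config()
    n0 <- run_filter_cascade(v, cfg = base)$reports$surviving
    for (tight in list(hard_filter_config(min_qual = 200),
                       hard_filter_config(min_mq = 60),
                       hard_filter_config(min_alt_depth = 15),
                       hard_filter_config(max_fq = 0.01),
                       hard_filter_config(indel_window_bp = 50))) {
      expect_lte(run_filter_cascade(v, cfg = tight)$reports$surviving, n0)
    }
  }
})

test_that("permuting stage order changes attribution but not survivors", {
  set.seed(53)
  v <- random_variant_set(100)
  snvs <- v[!v$is_indel, ]
  indels <- v[v$is_indel, ]
  cfg <- hard_filter_config()
  masks <- intervals(c(1000, 4000), c(2000, 4800))
  recomb <- intervals(6000, 7000)

  # canonical order
  a <- apply_hard_filters(snvs, cfg)$pass
  a <- mask_near_indels(a, indels, cfg$indel_window_bp)$pass
  a <- apply_region_masks(a, masks)$pass
  a <- apply_recombination_mask(a, recomb)$pass

  # reversed order
  b <- apply_recombination_mask(snvs, recomb)$pass
  b <- apply_region_masks(b, masks)$pass
  b <- mask_near_indels(b, indels, cfg$indel_window_bp)$pass
  b <- apply_hard_filters(b, cfg)$pass

  expect_equal(dplyr::arrange(a, pos), dplyr::arrange(b, pos))
})

test_that("all-permissive config and empty masks pass raw SNV disagreements", {
  lax <- hard_filter_config(min_qual = -1e9, min_mq = -1e9,
                            min_alt_depth = 0, max_fq = 1e9)
  sets <- list(X = make_variants(c(10, 20), alt = c("T", "G")),
               Y = make_variants(c(20, 30), alt = c("G", "C")))
  res <- run_filter_cascade(sets, cfg = lax)
  expect_equal(res$distances["X", "Y"], 2L) # 10 private + 30 private, 20 shared
})
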