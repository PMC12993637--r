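test_that("BED is identity, GFF converts to 0-based half-open", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("ref\t10\t20", bed)
  expect_equal(read_intervals(bed, "bed")[, c("start", "end")],
               tibble::tibble(start = 10, end = 20), ignore_attr = TRUE)

  gff <- withr::local_tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               "ref\tsim\tmisc_feature\t11\t20\t.\t.\t.\tnote=x"), gff)
  expect_equal(read_intervals(gff, "gff")[, c("start", "end")],
               tibble::tibble(start = 10, end = 20), ignore_attr = TRUE)
})

test_that("coordinate conversion round-trips through writers", {
  iv <- intervals(c(10, 100), c(20, 150))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, bed)
  expect_equal(read_intervals(bed, "bed")[, c("chrom", "start", "end")],
               iv[, c("chrom", "start", "end")])

  gff <- withr::local_tempfile(fileext = ".gff")
  write_gff(iv, gff)
  expect_equal(read_intervals(gff, "gff")[, c("chrom", "start", "end")],
               iv[, c("chrom", "start", "end")])
})

test_that("normalisation merges overlaps and rejects inverted intervals", {
  merged <- normalize_intervals(intervals(c(0, 5), c(10, 15)))
  expect_equal(merged$start, 0)
  expect_equal(merged$end, 15)
  expect_error(normalize_intervals(intervals(10, 5)), "end < start")
})

test_that("core genome is the intersection of callable sets", {
  a <- intervals(0, 100)
  b <- intervals(50, 150)
  core <- core_genome(list(a, b))
  expect_equal(core[, c("start", "end")], tibble::tibble(start = 50, end = 100),
               ignore_attr = TRUE)

  expect_equal(core_genome(list(a))[, c("start", "end")],
               a[, c("start", "end")], ignore_attr = TRUE)

  expect_warning(core_genome(list(intervals(0, 10), intervals(20, 30))),
                 "empty")
})

test_that("three random callable sets: fold equals point-sample oracle", {
  set.seed(401)
  l <- 500
  sets <- lapply(1:3, function(i) {
    starts <- sort(sample.int(l - 20, 4))
    normalize_intervals(intervals(starts, starts + sample(5:30, 4, replace = TRUE)))
  })
  core <- suppressWarnings(core_genome(sets))
  pts <- 0:(l - 1)
  in_all <- Reduce(`&`, lapply(sets, function(s)
    vertmicro:::positions_in_intervals(rep("ref", l), pts, s)))
  in_core <- vertmicro:::positions_in_intervals(rep("ref", l), pts, core)
  expect_equal(in_core, in_all)
})

test_that("interval subtraction and total length behave as set algebra", {
  iv <- intervals(0, 100)
  expect_equal(interval_total_length(subtract_intervals(iv, intervals(20, 30))), 90)
  expect_equal(interval_total_length(normalize_intervals(intervals(c(0, 5), c(10, 15)))), 15)
})
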