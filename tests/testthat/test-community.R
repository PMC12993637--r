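toy_counts <- function() {
  tibble::tibble(sample_id = c("A", "B", "C"),
                 Otu1 = c(500, 999, 0), Otu2 = c(500, 1, 2500),
                 Otu3 = c(0, 0, 2500))
}

test_that("depth exclusion keeps the boundary sample and reports the rest", {
  tab <- tibble::tibble(sample_id = c("lo", "edge", "hi"),
                        Otu1 = c(999, 1000, 5000))
  kept <- exclude_low_depth(tab, 1000)
  expect_setequal(kept$sample_id, c("edge", "hi"))
  rep <- excluded_samples(kept)
  expect_equal(rep$sample_id, "lo")
  expect_equal(rep$total, 999)

  expect_equal(exclude_low_depth(tab, 0)$sample_id, tab$sample_id)

  none <- exclude_low_depth(tab, 10000)
  expect_equal(nrow(none), 0)
  expect_equal(nrow(excluded_samples(none)), 3)
})

test_that("relative abundances sum to one and zero totals error", {
  rel <- relative_abundance(toy_counts())
  expect_equal(unname(rowSums(otu_matrix(rel))), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(otu_matrix(rel)["A", ]), c(0.5, 0.5, 0))

  single <- tibble::tibble(sample_id = "s", Otu1 = 7)
  expect_equal(unname(otu_matrix(relative_abundance(single))[1, 1]), 1)

  zero <- tibble::tibble(sample_id = c("ok", "empty"), Otu1 = c(5, 0))
  expect_error(relative_abundance(zero), "empty")

  set.seed(42)
  rand <- tibble::tibble(sample_id = paste0("s", 1:10))
  for (k in 1:6) rand[[paste0("Otu", k)]] <- rpois(10, 20) + 1
  expect_equal(unname(rowSums(otu_matrix(relative_abundance(rand)))),
               rep(1, 10), tolerance = 1e-9)
})

test_that("display-OTU selection applies both rules jointly", {
  # Otu1: total 1499 >= 200, max relab 99.9% -> in
  # Otu2: total 3001 >= 200, max relab 83% -> in
  # Otu3: total 2500, max relab 50% -> in
  tab <- toy_counts()
  expect_equal(select_display_otus(tab), c("Otu1", "Otu2", "Otu3"))

  # abundant-but-rare: 250 reads spread thin (max relab 1%) -> out
  thin <- tibble::tibble(sample_id = paste0("s", 1:5),
                         Rare = rep(50, 5), Fill = rep(4950, 5))
  expect_equal(select_display_otus(thin), "Fill")

  # dominant-but-scarce: 150 reads at 50% -> out
  scarce <- tibble::tibble(sample_id = c("a", "b"),
                           Dom = c(150, 0), Other = c(150, 1000))
  expect_equal(select_display_otus(scarce), "Other")

  expect_setequal(select_display_otus(toy_counts(), 0, 0),
                  c("Otu1", "Otu2", "Otu3"))
})

test_that("abundance_long is a tidy sample x OTU expansion", {
  long <- abundance_long(toy_counts())
  expect_equal(nrow(long), 9)
  expect_equal(long$relab[long$sample_id == "A" & long$otu_id == "Otu1"], 0.5)
  sub <- abundance_long(toy_counts(), otus = "Otu2")
  expect_equal(unique(sub$otu_id), "Otu2")
})
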