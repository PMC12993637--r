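# Fixture builders shared across test files. Everything is generated in
# code; files go to per-test temp paths.

`%||%` <- rlang::`%||%`

write_toy_shared <- function(path = tempfile(fileext = ".shared"),
                             lines = NULL) {
  lines <- lines %||% c(
    "label\tGroup\tnumOtus\tOtu001\tOtu002\tOtu003",
    "0.03\tS1\t3\t10\t5\t0",
    "0.03\tS2\t3\t0\t2\t8")
  writeLines(lines, path)
  path
}

toy_metadata <- function(n_pairs = 2, n_weeks = 2) {
  rows <- list()
  for (p in seq_len(n_pairs)) {
    for (role in c("mother", "daughter")) {
      subject <- sprintf("P%02d%s", p, if (role == "mother") "M" else "D")
      for (w in seq_len(n_weeks) - 1L) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = sprintf("%s_w%d", subject, w), subject_id = subject,
          pair_id = sprintf("P%02d", p), role = role, week_index = w,
          birth_mode_of_daughter = if (p %% 2 == 0) "c_section" else "vaginal",
          reproductive_stage = if (role == "mother") "reproductive" else "premenarchal",
          menstruating = NA)
      }
    }
  }
  validate_sample_metadata(dplyr::bind_rows(rows))
}

write_toy_vcf <- function(path = tempfile(fileext = ".vcf"),
                          body = NULL) {
  body <- body %||% c(
    "ref\t100\t.\tA\tT\t150\t.\tDP=40;DP4=5,5,6,6;MQ=60;FQ=0.001",
    "ref\t200\t.\tC\tCA\t180\t.\tDP=40;DP4=5,5,10,10;MQ=58;FQ=0.002",
    "ref\t300\t.\tG\tT,C\t120\t.\tDP=40;DP4=2,2,12,13;MQ=55;FQ=0.01")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=ref,length=100000>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"d\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=FQ,Number=1,Type=Float,Description=\"f\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    body), path)
  path
}

# build a variant tibble row-wise with passing defaults
make_variants <- function(pos, alt = NULL, ref = NULL, qual = 200, mq = 60,
                          alt_depth = 30, fq = 0.001, is_indel = FALSE,
                          chrom = "ref") {
  n <- length(pos)
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref = rep_len(ref %||% "A", n), alt = rep_len(alt %||% "T", n),
    qual = rep_len(qual, n), mq = rep_len(mq, n),
    alt_depth = rep_len(alt_depth, n), fq = rep_len(fq, n),
    is_indel = rep_len(is_indel, n),
    unscorable = FALSE)
}

random_variant_set <- function(n, l = 10000) {
  pos <- sample.int(l, n)
  make_variants(
    pos,
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    ref = "N",
    qual = runif(n, 0, 300), mq = runif(n, 20, 70),
    alt_depth = rpois(n, 12), fq = runif(n, 0, 0.05),
    is_indel = runif(n) < 0.1)
}

intervals <- function(start, end, chrom = "ref", label = NA_character_) {
  out <- tibble::tibble(chrom = rep_len(chrom, length(start)),
                        start = as.numeric(start), end = as.numeric(end))
  attr(out, "mask_label") <- label
  out
}

# brute-force theta-YC oracle: explicit sums over the union of OTUs
theta_yc_oracle <- function(p, q) {
  cross <- 0; sp2 <- 0; sq2 <- 0
  for (k in seq_along(p)) {
    cross <- cross + p[k] * q[k]
    sp2 <- sp2 + p[k]^2
    sq2 <- sq2 + q[k]^2
  }
  1 - cross / (sp2 + sq2 - cross)
}

# double-loop pairwise-distance oracle over an abundance matrix
pairwise_oracle <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- theta_yc_oracle(mat[i, ], mat[j, ])
    }
  }
  d
}
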