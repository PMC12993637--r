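# Shared internal helpers.

# OTU tables are tibbles: first column `sample_id`, remaining columns one per
# OTU holding counts (or proportions after relative_abundance()). The mothur
# clustering label travels in attr(x, "otu_label").

otu_cols <- function(x) setdiff(names(x), "sample_id")

#' Extract the numeric sample-by-OTU matrix from an OTU tibble
#'
#' @param x An OTU tibble as returned by [read_shared()] or
#'   [simulate_pair_cohort()]: a `sample_id` column followed by one numeric
#'   column per OTU.
#' @return A numeric matrix with sample ids as row names and OTU ids as
#'   column names.
#' @export
otu_matrix <- function(x) {
  stopifnot(is.data.frame(x), "sample_id" %in% names(x))
  ids <- otu_cols(x)
  m <- as.matrix(x[, ids, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

validate_otu_table <- function(x, arg = "x") {
  if (!is.data.frame(x) || !"sample_id" %in% names(x)) {
    abort(sprintf("`%s` must be a data frame with a `sample_id` column", arg))
  }
  if (anyDuplicated(x$sample_id)) {
    abort(sprintf("duplicate sample ids in `%s`: %s", arg,
                  paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", ")))
  }
  ids <- otu_cols(x)
  if (anyDuplicated(ids)) abort(sprintf("duplicate OTU ids in `%s`", arg))
  m <- otu_matrix(x)
  if (any(is.na(m))) abort(sprintf("missing values in counts of `%s`", arg))
  if (any(m < 0)) abort(sprintf("negative counts in `%s`", arg))
  invisible(x)
}

# symmetric-matrix checks used by distance consumers
check_distance_matrix <- function(m, tol = 1e-9, arg = "dm") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix", arg))
  }
  if (is.null(rownames(m))) abort(sprintf("`%s` must have dimnames", arg))
  if (!isTRUE(all.equal(m, t(m), tolerance = tol, check.attributes = FALSE))) {
    abort(sprintf("`%s` is not symmetric", arg))
  }
  if (any(abs(diag(m)) > tol)) abort(sprintf("`%s` has a nonzero diagonal", arg))
  invisible(m)
}

# round-half-up at `digits` decimals, as humans (and the printed reports) do;
# base round() rounds half to even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Dirichlet sampler (gamma normalisation); base R has no rdirichlet.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) { # numerically possible for tiny alpha
    g[sample.int(length(g), 1)] <- 1
  }
  g / sum(g)
}
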