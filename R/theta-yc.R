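# Yue & Clayton theta: a similarity measure over relative abundances that
# weights shared and non-shared taxa. For compositions p, q over the union
# of OTUs,
#   theta = sum(p*q) / (sum(p^2) + sum(q^2) - sum(p*q))
# and the distance used throughout is 1 - theta.

#' Yue-Clayton theta distance between two abundance vectors
#'
#' Vectors may be named (OTU ids); they are aligned on the union of names
#' with missing OTUs imputed as 0. Unnamed vectors must have equal length.
#'
#' @param p,q Non-negative numeric vectors of relative abundances, each
#'   summing to 1 (within 1e-6; they are renormalised internally).
#' @return The distance `1 - theta`, in `[0, 1]`.
#' @export
theta_yc <- function(p, q) {
  if (!is.null(names(p)) || !is.null(names(q))) {
    if (is.null(names(p)) || is.null(names(q))) {
      abort("either both or neither of p, q may be named")
    }
    ids <- union(names(p), names(q))
    p <- setNames(p[ids], ids); p[is.na(p)] <- 0
    q <- setNames(q[ids], ids); q[is.na(q)] <- 0
  } else if (length(p) != length(q)) {
    abort("unnamed abundance vectors must have equal length")
  }
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 && sq <= 0) abort("both abundance vectors are all-zero")
  if (sp <= 0 || sq <= 0) return(1) # disjoint by definition
  p <- p / sp; q <- q / sq
  cross <- sum(p * q)
  denom <- sum(p^2) + sum(q^2) - cross
  d <- 1 - cross / denom
  min(max(d, 0), 1)
}

#' Pairwise Yue-Clayton distances for all samples of an abundance table
#'
#' Computes the full symmetric sample-by-sample distance matrix. The
#' vectorised computation is algebraically identical to calling
#' [theta_yc()] on every pair.
#'
#' @param x OTU tibble of relative abundances (from [relative_abundance()]);
#'   a count table is accepted and converted.
#' @return Symmetric numeric matrix (granularity: sample) with zero
#'   diagonal, sample ids as dimnames.
#' @export
theta_yc_distances <- function(x) {
  validate_otu_table(x)
  if (nrow(x) < 2) abort("need at least 2 samples for pairwise distances")
  if (!isTRUE(attr(x, "relative"))) x <- relative_abundance(x)
  p <- otu_matrix(x)
  cross <- p %*% t(p)            # cross[i,j] = sum_k p_ik p_jk
  self <- diag(cross)            # sum_k p_ik^2
  denom <- outer(self, self, "+") - cross
  d <- 1 - cross / denom
  diag(d) <- 0
  d[d < 0] <- 0
  d[d > 1] <- 1
  d <- (d + t(d)) / 2            # enforce exact symmetry against fp jitter
  dimnames(d) <- list(x$sample_id, x$sample_id)
  d
}

#' Aggregate a sample-level distance matrix to subject level
#'
#' The distance between two subjects is the arithmetic mean of all
#' cross-sample distances between them; the diagonal is zero. Subjects with
#' no usable samples are omitted with a warning.
#'
#' @param dm Sample-level symmetric distance matrix.
#' @param metadata Validated metadata covering every sample in `dm`.
#' @return Symmetric subject-level distance matrix.
#' @export
aggregate_subject_distances <- function(dm, metadata) {
  check_distance_matrix(dm)
  ids <- rownames(dm)
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("samples without metadata: %s", paste(missing, collapse = ", ")))
  }
  map <- setNames(metadata$subject_id, metadata$sample_id)
  subj_of <- map[ids]
  subjects <- unique(metadata$subject_id)
  absent <- setdiff(subjects, subj_of)
  if (length(absent) > 0) {
    warn(sprintf("subjects with no usable samples omitted: %s",
                 paste(absent, collapse = ", ")))
    subjects <- setdiff(subjects, absent)
  }
  n <- length(subjects)
  out <- matrix(0, n, n, dimnames = list(subjects, subjects))
  for (i in seq_len(n)) {
    si <- which(subj_of == subjects[i])
    for (j in seq_len(n)) {
      if (j <= i) next
      sj <- which(subj_of == subjects[j])
      out[i, j] <- out[j, i] <- mean(dm[si, sj, drop = FALSE])
    }
  }
  out
}

#' Group community distances within subject, within pair and between pairs
#'
#' The three groupings of the analysis, each summarised as per-entity means:
#' \describe{
#'   \item{within_subject}{per subject, the mean distance over all pairs of
#'     that subject's own samples (subjects with fewer than 2 samples are
#'     omitted);}
#'   \item{within_pair}{per mother/daughter pair, the subject-level distance
#'     between its mother and its daughter;}
#'   \item{between_pair}{per subject, the mean subject-level distance to all
#'     subjects outside its own pair.}
#' }
#' Pairs with a member entirely absent from `dm` are omitted and reported in
#' the `"omitted_pairs"` attribute.
#'
#' @param dm Sample-level symmetric theta-YC distance matrix.
#' @param metadata Validated metadata covering every sample in `dm`.
#' @return A tibble of class `grouped_distances` with columns `group`
#'   (ordered factor), `entity_id` and `value`, plus attributes
#'   `subject_distances` (the subject-level matrix) and `counts`.
#' @export
group_distances <- function(dm, metadata) {
  check_distance_matrix(dm)
  ids <- rownames(dm)
  meta <- metadata[metadata$sample_id %in% ids, , drop = FALSE]
  subj_dm <- aggregate_subject_distances(dm, meta)
  subjects <- rownames(subj_dm)
  sub_tbl <- subject_table(meta)
  sub_tbl <- sub_tbl[match(subjects, sub_tbl$subject_id), , drop = FALSE]

  # within subject
  map <- setNames(meta$subject_id, meta$sample_id)
  ws <- purrr::map_dfr(subjects, function(s) {
    si <- which(map[ids] == s)
    if (length(si) < 2) return(NULL)
    vals <- dm[si, si][upper.tri(diag(length(si)))]
    tibble(group = "within_subject", entity_id = s, value = mean(vals))
  })

  # within pair: subject-level mother<->daughter distance, one per pair
  pair_ids <- unique(sub_tbl$pair_id)
  omitted <- character(0)
  wp <- purrr::map_dfr(pair_ids, function(p) {
    members <- sub_tbl$subject_id[sub_tbl$pair_id == p]
    roles <- sub_tbl$role[sub_tbl$pair_id == p]
    if (length(members) < 2) { omitted <<- c(omitted, p); return(NULL) }
    mo <- members[roles == "mother"]; da <- members[roles == "daughter"]
    tibble(group = "within_pair", entity_id = p, value = subj_dm[mo, da])
  })

  # between pairs: per subject, mean distance to subjects of other pairs
  pair_of <- setNames(sub_tbl$pair_id, sub_tbl$subject_id)
  bp <- purrr::map_dfr(subjects, function(s) {
    others <- subjects[pair_of[subjects] != pair_of[s]]
    if (length(others) == 0) return(NULL)
    tibble(group = "between_pair", entity_id = s,
           value = mean(subj_dm[s, others]))
  })

  out <- dplyr::bind_rows(bp, wp, ws)
  out$group <- factor(out$group,
                      levels = c("between_pair", "within_pair", "within_subject"))
  out <- tibble::new_tibble(out, class = "grouped_distances")
  attr(out, "subject_distances") <- subj_dm
  attr(out, "omitted_pairs") <- omitted
  attr(out, "counts") <- c(
    n_subjects = length(subjects),
    n_pairs = nrow(wp),
    n_subjects_multi_sample = nrow(ws)
  )
  out
}

#' Attach pair-level covariates to within-pair distances
#'
#' Convenience for the birth-mode and reproductive-stage comparisons: the
#' `within_pair` rows of a [group_distances()] result joined with the
#' daughter's birth mode and the mother's reproductive stage.
#'
#' @param gd A `grouped_distances` tibble.
#' @param metadata The metadata used to build it.
#' @return Tibble with `pair_id`, `value`, `birth_mode_of_daughter`,
#'   `mother_stage`.
#' @export
within_pair_table <- function(gd, metadata) {
  wp <- dplyr::filter(as_tibble(gd), .data$group == "within_pair")
  sub <- subject_table(metadata)
  pairs <- dplyr::distinct(sub, .data$pair_id, .data$birth_mode_of_daughter)
  mother_stage <- dplyr::filter(sub, .data$role == "mother")
  mother_stage <- dplyr::select(mother_stage, "pair_id",
                                mother_stage = "reproductive_stage")
  out <- dplyr::left_join(
    dplyr::select(wp, pair_id = "entity_id", "value"), pairs, by = "pair_id")
  dplyr::left_join(out, mother_stage, by = "pair_id")
}

#' Box plot of grouped community distances
#'
#' @param object A `grouped_distances` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grouped_distances
#' @export
autoplot.grouped_distances <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = expression("Mean" ~ theta[YC] ~ "distance")) +
    ggplot2::theme_classic()
}
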