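# Sample metadata: one row per vaginal swab sample, linking it to a subject,
# a mother/daughter pair, a weekly time point and the covariates the analysis
# stratifies on. Vocabulary is fixed; tokens are matched case-insensitively
# and anything else is an error rather than a guess.

META_ROLES <- c("mother", "daughter")
META_BIRTH_MODES <- c("vaginal", "c_section")
META_STAGES <- c("premenarchal", "reproductive", "postmenopausal")

#' Read and validate a sample metadata table
#'
#' Expects a delimited text file (comma or tab, sniffed from the header) with
#' columns `sample_id`, `subject_id`, `pair_id`, `role`, `week_index`,
#' `birth_mode_of_daughter`, `reproductive_stage` and optionally
#' `menstruating`. Validation enforces the cohort structure: unique sample
#' ids, each subject in exactly one pair, and each pair with exactly one
#' mother and one daughter.
#'
#' @param path Path to the metadata file.
#' @return A validated tibble with normalised (lower-case) category tokens;
#'   `menstruating` is logical with `NA` for unknown.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("metadata file not found: %s", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  validate_sample_metadata(df)
}

#' Validate (and normalise) an in-memory metadata data frame
#'
#' @param df A data frame with the columns described in
#'   [read_sample_metadata()].
#' @return The normalised tibble, or an error naming the offending rows.
#' @export
validate_sample_metadata <- function(df) {
  required <- c("sample_id", "subject_id", "pair_id", "role", "week_index",
                "birth_mode_of_daughter", "reproductive_stage")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("metadata is missing columns: %s", paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (!"menstruating" %in% names(df)) df$menstruating <- NA
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample_id in metadata: %s (rows %s)",
                  paste(unique(dup), collapse = ", "),
                  paste(which(df$sample_id %in% dup), collapse = ", ")))
  }

  norm_token <- function(x, vocab, col) {
    v <- tolower(trimws(as.character(x)))
    v[v %in% c("c-section", "csection", "cesarean", "caesarean")] <- "c_section"
    bad <- which(!v %in% vocab)
    if (length(bad) > 0) {
      abort(sprintf("unknown %s token '%s' at metadata row %d (allowed: %s)",
                    col, x[bad[1]], bad[1], paste(vocab, collapse = ", ")))
    }
    v
  }
  df$role <- norm_token(df$role, META_ROLES, "role")
  df$birth_mode_of_daughter <-
    norm_token(df$birth_mode_of_daughter, META_BIRTH_MODES, "birth_mode_of_daughter")
  df$reproductive_stage <-
    norm_token(df$reproductive_stage, META_STAGES, "reproductive_stage")

  wk <- suppressWarnings(as.integer(df$week_index))
  if (any(is.na(wk)) || any(wk < 0)) {
    abort(sprintf("week_index must be a non-negative integer (row %d)",
                  which(is.na(wk) | wk < 0)[1]))
  }
  df$week_index <- wk

  mens <- tolower(trimws(as.character(df$menstruating)))
  df$menstruating <- dplyr::case_when(
    mens %in% c("true", "t", "yes", "y", "1") ~ TRUE,
    mens %in% c("false", "f", "no", "n", "0") ~ FALSE,
    TRUE ~ NA
  )

  # one subject -> one pair, one role
  sub <- dplyr::distinct(df, .data$subject_id, .data$pair_id, .data$role)
  multi <- sub$subject_id[duplicated(sub$subject_id)]
  if (length(multi) > 0) {
    abort(sprintf("subject mapped to multiple pairs or roles: %s",
                  paste(unique(multi), collapse = ", ")))
  }
  # each pair: exactly one mother and one daughter
  by_pair <- dplyr::count(sub, .data$pair_id, .data$role)
  for (p in unique(sub$pair_id)) {
    nm <- sum(by_pair$n[by_pair$pair_id == p & by_pair$role == "mother"])
    nd <- sum(by_pair$n[by_pair$pair_id == p & by_pair$role == "daughter"])
    if (nm != 1 || nd != 1) {
      abort(sprintf("pair %s must have exactly one mother and one daughter (has %d/%d)",
                    p, nm, nd))
    }
  }
  df
}

#' Subject-level view of sample metadata
#'
#' @param metadata A validated metadata tibble.
#' @return One row per subject with pair, role, birth mode and stage.
#' @export
subject_table <- function(metadata) {
  dplyr::distinct(metadata, .data$subject_id, .data$pair_id, .data$role,
                  .data$birth_mode_of_daughter, .data$reproductive_stage)
}
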