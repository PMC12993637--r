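# Within-host molecular-clock estimator. Two isolates sampled from mother
# and daughter are assumed to descend from a common ancestor at the
# daughter's birth and to accumulate non-convergent mutations independently,
# so each lineage carries half the observed pairwise SNP count. Equating
# that to (mutation rate per bp per generation) x (generations) x (genome
# length) and solving for the generation time gives
#     doubling_time = mu * age_hours * L / m,   m = s / 2,
# and the per-year mutation accumulation of one lineage is s / (2 * age).

#' Convert an age in years to hours
#'
#' Uses a 365-day year exactly (no leap-year correction):
#' `hours = years * 365 * 24`.
#'
#' @param age_years Positive age in years.
#' @return Age in hours.
#' @export
age_to_hours <- function(age_years) {
  if (any(!is.finite(age_years)) || any(age_years <= 0)) {
    abort("age_years must be positive")
  }
  age_years * 365 * 24
}

#' Mutations per lineage from a pairwise SNP count
#'
#' Under symmetric divergence from a common ancestor, each lineage accounts
#' for half the SNPs separating the two isolates.
#'
#' @param snp_count Non-negative SNP count between the two isolates.
#' @return `snp_count / 2` (non-integer allowed).
#' @export
mutations_per_lineage <- function(snp_count) {
  if (any(!is.finite(snp_count)) || any(snp_count < 0)) {
    abort("snp_count must be non-negative")
  }
  snp_count / 2
}

#' In vivo doubling time from mutation accumulation
#'
#' @param mu Mutation rate, substitutions per bp per generation.
#' @param age_hours Host age in hours (the divergence time).
#' @param genome_length Length of the compared (recombination-filtered core)
#'   genome, bp.
#' @param n_mutations Mutations accumulated per lineage (`s / 2`).
#' @return Doubling time in hours: `mu * age_hours * genome_length /
#'   n_mutations`.
#' @export
doubling_time_hours <- function(mu, age_hours, genome_length, n_mutations) {
  if (any(n_mutations == 0)) {
    abort("no mutations: doubling time unbounded (identical isolates)")
  }
  stopifnot(mu > 0, age_hours > 0, genome_length > 0, n_mutations > 0)
  mu * age_hours * genome_length / n_mutations
}

#' Mutations accumulated per lineage per year
#'
#' @param snp_count Non-negative pairwise SNP count.
#' @param age_years Positive host age in years.
#' @return `snp_count / (2 * age_years)`.
#' @export
mutations_per_year <- function(snp_count, age_years) {
  if (any(!is.finite(age_years)) || any(age_years <= 0)) {
    abort("age_years must be positive")
  }
  if (any(snp_count < 0)) abort("snp_count must be non-negative")
  snp_count / (2 * age_years)
}

#' Full transmission-plausibility estimate
#'
#' Wraps the doubling-time and mutations-per-year formulas, echoing inputs
#' and reporting both full-precision and 1-decimal (half-up) values.
#'
#' @param snp_count Pairwise recombination-filtered SNP count.
#' @param age_years Host (daughter's) age in years.
#' @param genome_length Recombination-filtered core genome length, bp.
#' @param mutation_rate Substitutions per bp per generation
#'   (default 1.0e-9).
#' @return An object of class `transmission_estimate`.
#' @export
transmission_estimate <- function(snp_count, age_years, genome_length,
                                  mutation_rate = 1e-9) {
  age_hours <- age_to_hours(age_years)
  m <- mutations_per_lineage(snp_count)
  dt <- doubling_time_hours(mutation_rate, age_hours, genome_length, m)
  mpy <- mutations_per_year(snp_count, age_years)
  structure(list(
    doubling_time_hours = dt,
    mutations_per_year = mpy,
    doubling_time_hours_rounded = round_half_up(dt, 1),
    mutations_per_year_rounded = round_half_up(mpy, 1),
    inputs = list(snp_count = snp_count, age_years = age_years,
                  age_hours = age_hours, genome_length = genome_length,
                  mutation_rate = mutation_rate, mutations_per_lineage = m)),
    class = "transmission_estimate")
}

#' @method print transmission_estimate
#' @export
print.transmission_estimate <- function(x, ...) {
  with(x$inputs, cat(sprintf(
    "Molecular-clock estimate (s = %g SNPs, age = %g y, L = %g bp, mu = %g)\n",
    snp_count, age_years, genome_length, mutation_rate)))
  cat(sprintf("  doubling time:      %.1f hours\n", x$doubling_time_hours_rounded))
  cat(sprintf("  mutations per year: %.1f\n", x$mutations_per_year_rounded))
  invisible(x)
}

#' Tidy a transmission estimate
#'
#' @param x A `transmission_estimate`.
#' @param ... Unused.
#' @return One-row tibble with full-precision and rounded values plus the
#'   echoed inputs.
#' @method tidy transmission_estimate
#' @export
tidy.transmission_estimate <- function(x, ...) {
  tibble(doubling_time_hours = x$doubling_time_hours,
         mutations_per_year = x$mutations_per_year,
         doubling_time_hours_rounded = x$doubling_time_hours_rounded,
         mutations_per_year_rounded = x$mutations_per_year_rounded,
         snp_count = x$inputs$snp_count,
         age_years = x$inputs$age_years,
         genome_length = x$inputs$genome_length,
         mutation_rate = x$inputs$mutation_rate)
}

#' @rdname tidy.transmission_estimate
#' @method glance transmission_estimate
#' @export
glance.transmission_estimate <- function(x, ...) tidy(x)
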