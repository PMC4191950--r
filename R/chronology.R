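#' Population age from lake elevation
#'
#' Post-glacial land uplift steadily lifts coastal bays out of the sea, so a
#' lake's elevation above sea level dates its isolation:
#' `age = elevation * 1000 / uplift_rate` years.
#'
#' @param elevation_m lake elevation above sea level, metres (>= 0).
#' @param uplift_rate uplift rate in mm per year (default 3.8).
#' @param round_to optional rounding granularity in years (e.g. 50 for the
#'   nearest half-century); `NULL` returns the raw value.
#' @return age in years.
#' @export
age_from_elevation <- function(elevation_m, uplift_rate = 3.8, round_to = NULL) {
  stopifnot(all(elevation_m >= 0), uplift_rate > 0)
  age <- elevation_m * 1000 / uplift_rate
  if (!is.null(round_to)) age <- round(age / round_to) * round_to
  age
}

#' Haplotype divergence time from per-site divergence
#'
#' A linear one-way molecular clock: `T = d / mu` generations, where `d` is
#' the per-site divergence between two haplotypes and `mu` the per-site,
#' per-generation mutation rate. The textbook pairwise convention
#' `T = d / (2 mu)` (divergence accumulating along both lineages) is
#' available via `pairwise = TRUE`; the one-way clock is the default.
#'
#' @param per_site_divergence fraction of differing sites, in `(0, 1)` (0
#'   allowed, giving 0).
#' @param mutation_rate per site per generation (default 1e-8).
#' @param pairwise divide by `2 mu` instead of `mu`.
#' @return divergence time in generations.
#' @export
divergence_generations <- function(per_site_divergence, mutation_rate = 1e-8,
                                   pairwise = FALSE) {
  stopifnot(all(per_site_divergence >= 0), all(per_site_divergence < 1),
            mutation_rate > 0)
  per_site_divergence / mutation_rate / (if (pairwise) 2 else 1)
}

#' Convert population age to generations
#'
#' @param age_years population age in years.
#' @param generation_time years per generation (default 2).
#' @return number of generations, rounded to the nearest integer.
#' @export
age_to_generations <- function(age_years, generation_time = 2) {
  stopifnot(generation_time > 0)
  as.integer(round(age_years / generation_time))
}
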