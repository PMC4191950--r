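#' Define sequencing pools
#'
#' A pool is one sequencing library made from the pooled DNA of several
#' individuals from one population. Each pool carries the metadata the
#' downstream filters and estimators need: habitat, the number of pooled
#' individuals (hence chromosomes), the depth cutoff used for SNP calling in
#' that pool, and -- for freshwater populations of known age -- the age in
#' years and the assumed founding frequency of freshwater alleles.
#'
#' @param name character vector of unique pool identifiers.
#' @param habitat `"marine"` or `"freshwater"`, recycled if scalar.
#' @param n_individuals positive integers, individuals pooled per library.
#' @param min_depth positive integers; a site is usable in a pool only when
#'   its read depth strictly exceeds this cutoff.
#' @param age_years population age in years, or `NA` where unknown/irrelevant
#'   (marine pools).
#' @param founder_freq assumed initial frequency of freshwater alleles at the
#'   founding of the population, in `[0, 1]`, or `NA`.
#'
#' @return A `data.frame` of class `pool_table` with one row per pool and a
#'   derived `n_chromosomes = 2 * n_individuals` column.
#' @export
pool_table <- function(name, habitat, n_individuals, min_depth,
                       age_years = NA_real_, founder_freq = NA_real_) {
  stopifnot(is.character(name), !anyDuplicated(name))
  n <- length(name)
  habitat <- rep_len(as.character(habitat), n)
  if (!all(habitat %in% c("marine", "freshwater")))
    stop("habitat must be 'marine' or 'freshwater'")
  n_individuals <- rep_len(as.integer(n_individuals), n)
  min_depth <- rep_len(as.integer(min_depth), n)
  if (any(n_individuals < 1L)) stop("n_individuals must be positive")
  if (any(min_depth < 1L)) stop("min_depth must be >= 1")
  age_years <- rep_len(as.numeric(age_years), n)
  founder_freq <- rep_len(as.numeric(founder_freq), n)
  if (any(age_years < 0, na.rm = TRUE)) stop("age_years must be non-negative")
  if (any(founder_freq < 0 | founder_freq > 1, na.rm = TRUE))
    stop("founder_freq must lie in [0, 1]")
  out <- data.frame(
    name = name, habitat = habitat, n_individuals = n_individuals,
    n_chromosomes = 2L * n_individuals, min_depth = min_depth,
    age_years = age_years, founder_freq = founder_freq,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pool_table", "data.frame")
  out
}

pool_index <- function(pools, names) {
  idx <- match(names, pools$name)
  if (anyNA(idx)) stop("unknown pool(s): ", paste(names[is.na(idx)], collapse = ", "))
  idx
}
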