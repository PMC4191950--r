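#' Nucleotide diversity from pooled frequencies
#'
#' Estimates per-site nucleotide diversity for one pool over a region as the
#' mean, over usable sites, of the expected heterozygosity
#' `2 * p * (1 - p) * n_c / (n_c - 1)`, where `p` is the pooled read-ratio
#' frequency and `n_c` the number of chromosomes in the pool (small-sample
#' correction). Monomorphic covered sites contribute 0 to the sum but count
#' in the denominator. With `depth_correction = TRUE` each site is
#' additionally scaled by `depth / (depth - 1)`, removing the downward bias
#' of order `1/depth` that read sampling induces in `2 p (1 - p)`; the raw
#' mode is the default.
#'
#' @param sf a `site_freqs` object.
#' @param pool pool name.
#' @param regions optional data.frame `chrom`, `start`, `end` restricting the
#'   sites considered; `NULL` uses all sites.
#' @param exclude if `TRUE`, use the complement: sites outside every region
#'   (the genomic background).
#' @param label region label for the output row.
#' @param depth_correction apply the `depth/(depth-1)` unbiasing factor.
#' @return data.frame `pool`, `region`, `pi`, `n_sites`.
#' @export
nucleotide_diversity <- function(sf, pool, regions = NULL, exclude = FALSE,
                                 label = if (is.null(regions)) "genome" else
                                   if (exclude) "background" else "regions",
                                 depth_correction = FALSE) {
  stopifnot(inherits(sf, "site_freqs"))
  j <- pool_index(sf$pools, pool)
  inreg <- sites_in_regions(sf$sites, regions)
  if (exclude) inreg <- !inreg
  use <- which(inreg & sf$usable[, j])
  if (length(use) == 0L)
    stop("no usable sites for pool '", pool, "' in region '", label, "'")
  p <- sf$freq[use, j]
  nc <- sf$pools$n_chromosomes[j]
  het <- 2 * p * (1 - p) * nc / (nc - 1)
  if (depth_correction) {
    d <- sf$depth[use, j]
    het <- het * d / (d - 1)
  }
  data.frame(pool = pool, region = label, pi = mean(het), n_sites = length(use),
             stringsAsFactors = FALSE)
}

sites_in_regions <- function(sites, regions) {
  if (is.null(regions)) return(rep(TRUE, nrow(sites)))
  inreg <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(regions)))
    inreg <- inreg | (sites$chrom == regions$chrom[i] &
                        sites$pos >= regions$start[i] & sites$pos <= regions$end[i])
  inreg
}

#' Diversity inside and outside divergence islands, for every pool
#'
#' Convenience wrapper computing, per pool, genome-wide diversity, diversity
#' within the DI set, and diversity of the genomic background (all covered
#' sites outside every DI).
#'
#' @param sf a `site_freqs` object.
#' @param dis a `di_set` (may be empty, in which case only `genome` rows are
#'   produced).
#' @param depth_correction see [nucleotide_diversity()].
#' @return data.frame with one row per pool x region.
#' @export
diversity_by_region <- function(sf, dis, depth_correction = FALSE) {
  rows <- lapply(sf$pools$name, function(p) {
    g <- nucleotide_diversity(sf, p, depth_correction = depth_correction)
    if (nrow(dis) == 0L) return(g)
    rbind(g,
          nucleotide_diversity(sf, p, dis, label = "DIs",
                               depth_correction = depth_correction),
          nucleotide_diversity(sf, p, dis, exclude = TRUE, label = "background",
                               depth_correction = depth_correction))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
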