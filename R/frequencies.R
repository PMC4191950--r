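#' Estimate biallelic allele frequencies from pooled counts
#'
#' For every site, the two most frequent nucleotides summed across all pools
#' define the biallelic site (ties broken alphabetically for determinism).
#' Sites where reads of a third allele exceed `max_third_frac` of the
#' combined read total are rejected as putatively triallelic or error-ridden.
#' Per pool, the frequency of the overall-major allele is the raw read-count
#' ratio `major / (major + minor)`; no pool-size shrinkage is applied. A
#' pool-site is usable only when its quality flag is set, its total depth
#' strictly exceeds the pool's `min_depth` (mirroring ">10"/">5" cutoffs read
#' literally), and at least one read supports the two site alleles.
#' Monomorphic covered sites are retained (`minor = NA`, frequency 1) so that
#' diversity denominators can count them.
#'
#' @param pc a `pool_counts` object from [read_pool_counts()] or the
#'   simulator.
#' @param max_third_frac maximum tolerated fraction of reads supporting
#'   alleles other than the two site alleles (default 0.05).
#' @return An object of class `site_freqs`: list with `sites` (data.frame
#'   `chrom`, `pos`, `major`, `minor`), matrices `freq` (major-allele
#'   frequency, `NA` where unusable), `depth`, `usable`, the `pools` table,
#'   and a `rejected` summary (data.frame `reason`, `n`).
#' @export
estimate_frequencies <- function(pc, max_third_frac = 0.05) {
  stopifnot(inherits(pc, "pool_counts"))
  pools <- pc$pools
  n <- nrow(pc$sites)
  if (n == 0L) {
    return(structure(list(
      sites = data.frame(chrom = character(), pos = integer(),
                         major = character(), minor = character()),
      freq = pc$quality_ok[0L, , drop = FALSE] + 0,
      depth = matrix(integer(), 0L, nrow(pools), dimnames = list(NULL, pools$name)),
      usable = pc$quality_ok, pools = pools,
      rejected = data.frame(reason = character(), n = integer())),
      class = "site_freqs"))
  }
  # total count per base across pools; counts from quality-failed pool-sites
  # are zero by the reader/simulator contract
  tot <- sapply(1:4, function(b) rowSums(pc$counts[, , b, drop = FALSE]))
  if (n == 1L) tot <- matrix(tot, nrow = 1L)
  # rank bases per site by count, alphabetical tie-break (BASES is sorted)
  ord <- apply(tot, 1L, order, decreasing = TRUE)  # 4 x n
  major_i <- ord[1L, ]
  minor_i <- ord[2L, ]
  cmaj <- tot[cbind(seq_len(n), major_i)]
  cmin <- tot[cbind(seq_len(n), minor_i)]
  grand <- rowSums(tot)
  third <- grand - cmaj - cmin
  reject <- grand > 0 & third > max_third_frac * grand
  nocov <- grand == 0
  keep <- which(!reject & !nocov)
  rejected <- data.frame(
    reason = c("third_allele_excess", "no_reads"),
    n = c(sum(reject), sum(nocov)), stringsAsFactors = FALSE)

  major_i <- major_i[keep]; minor_i <- minor_i[keep]
  cmin <- cmin[keep]
  npool <- nrow(pools)
  cm <- sapply(seq_len(npool), function(j)
    pc$counts[cbind(keep, j, major_i)])
  cn <- sapply(seq_len(npool), function(j)
    pc$counts[cbind(keep, j, minor_i)])
  if (length(keep) == 1L) { cm <- matrix(cm, 1L); cn <- matrix(cn, 1L) }
  depth <- sapply(1:4, function(b) pc$counts[keep, , b, drop = FALSE],
                  simplify = "array")
  depth <- matrix(rowSums(matrix(depth, nrow = length(keep) * npool)),
                  length(keep), npool)
  dimnames(depth) <- list(NULL, pools$name)
  usable <- pc$quality_ok[keep, , drop = FALSE] &
    depth > matrix(pools$min_depth, length(keep), npool, byrow = TRUE) &
    (cm + cn) > 0L
  freq <- cm / (cm + cn)
  freq[!usable] <- NA_real_
  dimnames(freq) <- list(NULL, pools$name)
  minor <- BASES[minor_i]
  minor[cmin == 0L] <- NA_character_   # monomorphic covered site
  structure(list(
    sites = data.frame(chrom = pc$sites$chrom[keep], pos = pc$sites$pos[keep],
                       major = BASES[major_i], minor = minor,
                       stringsAsFactors = FALSE),
    freq = freq, depth = depth, usable = usable, pools = pools,
    rejected = rejected), class = "site_freqs")
}

#' @export
print.site_freqs <- function(x, ...) {
  cat(sprintf("site_freqs: %d sites x %d pools; %d polymorphic; rejected: %s\n",
              nrow(x$sites), nrow(x$pools), sum(!is.na(x$sites$minor)),
              paste(sprintf("%s=%d", x$rejected$reason, x$rejected$n), collapse = ", ")))
  invisible(x)
}

subset_site_freqs <- function(sf, i) {
  structure(list(sites = sf$sites[i, , drop = FALSE],
                 freq = sf$freq[i, , drop = FALSE],
                 depth = sf$depth[i, , drop = FALSE],
                 usable = sf$usable[i, , drop = FALSE],
                 pools = sf$pools, rejected = sf$rejected),
            class = "site_freqs")
}
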