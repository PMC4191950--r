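#' Marker-SNP classification criteria
#'
#' A marker SNP is a biallelic site where every marine pool carries one
#' allele above `marine_thresh` while every freshwater pool carries the other
#' allele above `strong_thresh` ("strong" marker) or above `weak_thresh`
#' ("weak" marker). All thresholds are strict (frequency must exceed the
#' threshold), and the weak criterion relaxes only the freshwater side; the
#' marine requirement is the same for both.
#'
#' @param marine_pools,freshwater_pools names of the pools defining each
#'   habitat side (at least one each).
#' @param marine_thresh marine-side frequency threshold (default 0.8).
#' @param strong_thresh,weak_thresh freshwater-side thresholds for the strong
#'   (default 0.8) and weak (default 0.5) criteria.
#' @return An object of class `marker_criteria`.
#' @export
marker_criteria <- function(marine_pools, freshwater_pools,
                            marine_thresh = 0.8, strong_thresh = 0.8,
                            weak_thresh = 0.5) {
  stopifnot(length(marine_pools) >= 1L, length(freshwater_pools) >= 1L,
            weak_thresh >= 0.5, weak_thresh <= strong_thresh, strong_thresh < 1)
  structure(list(marine_pools = marine_pools, freshwater_pools = freshwater_pools,
                 marine_thresh = marine_thresh, strong_thresh = strong_thresh,
                 weak_thresh = weak_thresh),
            class = "marker_criteria")
}

#' Classify marker SNPs
#'
#' Applies a [marker_criteria()] to every polymorphic site of a `site_freqs`
#' object that is usable in all pools the criteria name; sites unusable in
#' any required pool are skipped rather than imputed. Because any site
#' passing the strong criterion also passes the weak one, `status = "strong"`
#' subsumes the weak criterion: the weak-criterion marker set is
#' `status %in% c("strong", "weak")`.
#'
#' @param sf a `site_freqs` object.
#' @param criteria a [marker_criteria()].
#' @return data.frame of class `marker_calls` with columns `chrom`, `pos`,
#'   `status` (`strong`/`weak`/`none`), `marine_allele`, `freshwater_allele`
#'   (`NA` for `none`), and one `fw_<pool>` column per freshwater pool with
#'   that pool's freshwater-allele frequency.
#' @export
call_markers <- function(sf, criteria) {
  stopifnot(inherits(sf, "site_freqs"), inherits(criteria, "marker_criteria"))
  mi <- pool_index(sf$pools, criteria$marine_pools)
  fi <- pool_index(sf$pools, criteria$freshwater_pools)
  req <- c(mi, fi)
  elig <- rowSums(!sf$usable[, req, drop = FALSE]) == 0L & !is.na(sf$sites$minor)
  sfe <- subset_site_freqs(sf, which(elig))
  f <- sfe$freq  # major-allele frequency
  n <- nrow(sfe$sites)

  all_above <- function(m, thr) if (n == 0L) logical() else
    rowSums(m > thr) == ncol(m)
  fm <- f[, mi, drop = FALSE]; ff <- f[, fi, drop = FALSE]
  # case 1: major allele is the marine allele, minor the freshwater allele
  m1 <- all_above(fm, criteria$marine_thresh)
  s1 <- m1 & all_above(1 - ff, criteria$strong_thresh)
  w1 <- m1 & all_above(1 - ff, criteria$weak_thresh)
  # case 2: roles swapped
  m2 <- all_above(1 - fm, criteria$marine_thresh)
  s2 <- m2 & all_above(ff, criteria$strong_thresh)
  w2 <- m2 & all_above(ff, criteria$weak_thresh)

  status <- rep("none", n)
  status[w1 | w2] <- "weak"
  status[s1 | s2] <- "strong"
  marine_allele <- rep(NA_character_, n)
  freshwater_allele <- rep(NA_character_, n)
  c1 <- w1; c2 <- w2
  marine_allele[c1] <- sfe$sites$major[c1]
  freshwater_allele[c1] <- sfe$sites$minor[c1]
  marine_allele[c2] <- sfe$sites$minor[c2]
  freshwater_allele[c2] <- sfe$sites$major[c2]

  out <- data.frame(chrom = sfe$sites$chrom, pos = sfe$sites$pos,
                    status = status, marine_allele = marine_allele,
                    freshwater_allele = freshwater_allele,
                    stringsAsFactors = FALSE)
  fwf <- ff
  fwf[c1, ] <- 1 - ff[c1, , drop = FALSE]   # freshwater allele = minor
  fwf[status == "none", ] <- NA_real_
  colnames(fwf) <- paste0("fw_", criteria$freshwater_pools)
  out <- cbind(out, as.data.frame(fwf))
  class(out) <- c("marker_calls", "data.frame")
  out
}

#' @rdname call_markers
#' @param marine_pool,freshwater_pool single pool names for single-pair
#'   classification; thresholds and dots are passed to [marker_criteria()].
#' @param ... further arguments to [marker_criteria()].
#' @export
call_markers_single_pair <- function(sf, marine_pool, freshwater_pool, ...) {
  stopifnot(length(marine_pool) == 1L, length(freshwater_pool) == 1L)
  call_markers(sf, marker_criteria(marine_pool, freshwater_pool, ...))
}

#' Freshwater-allele frequencies at marker SNPs, in every pool
#'
#' For each marker site, reports the frequency of the freshwater allele in
#' all pools of a `site_freqs` object (not just the criteria-defining ones),
#' with `NA` where the pool-site is unusable. Used to follow the freshwater
#' allele in young populations.
#'
#' @param sf a `site_freqs` object.
#' @param markers marker calls from [call_markers()]; rows with
#'   `status == "none"` are dropped.
#' @return list with `sites` (chrom, pos, status, freshwater_allele) and
#'   `freq` (matrix site x pool of freshwater-allele frequencies).
#' @export
freshwater_frequencies <- function(sf, markers) {
  mk <- markers[markers$status != "none", , drop = FALSE]
  key_sf <- paste(sf$sites$chrom, sf$sites$pos)
  idx <- match(paste(mk$chrom, mk$pos), key_sf)
  if (anyNA(idx)) stop("marker site(s) absent from site_freqs")
  f <- sf$freq[idx, , drop = FALSE]
  is_major <- mk$freshwater_allele == sf$sites$major[idx]
  fw <- ifelse(matrix(is_major, nrow(f), ncol(f)), f, 1 - f)
  fw[!sf$usable[idx, , drop = FALSE]] <- NA_real_
  dimnames(fw) <- list(NULL, sf$pools$name)
  list(sites = data.frame(chrom = mk$chrom, pos = mk$pos, status = mk$status,
                          freshwater_allele = mk$freshwater_allele,
                          stringsAsFactors = FALSE),
       freq = fw)
}
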