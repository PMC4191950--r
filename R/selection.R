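#' Deterministic allele-frequency trajectory under diploid selection
#'
#' Iterates the standard single-locus recursion
#' `p' = p (p w_FF + q w_FM) / w_bar` with
#' `w_bar = p^2 w_FF + 2 p q w_FM + q^2 w_MM`, where `p` is the frequency of
#' the freshwater allele F. Two fitness parameterizations are available:
#'
#' * `"advantage"` (default): `w_FF = 1 + s`, `w_FM = 1 + h s`, `w_MM = 1`
#'   (selective advantage of the freshwater homozygote);
#' * `"gillespie"`: `w_FF = 1`, `w_FM = 1 - h s`, `w_MM = 1 - s` (selection
#'   against the marine allele).
#'
#' For small `s` the two differ by terms of order `s^2`.
#'
#' @param p0 initial freshwater-allele frequency in `[0, 1]`.
#' @param s selection coefficient.
#' @param h dominance coefficient in `[0, 1]` (default 0.5, intermediate
#'   dominance).
#' @param generations number of generations `G >= 0`.
#' @param parameterization `"advantage"` or `"gillespie"`.
#' @return numeric vector `p_0, p_1, ..., p_G` of length `generations + 1`.
#' @export
forward_trajectory <- function(p0, s, h = 0.5, generations,
                               parameterization = c("advantage", "gillespie")) {
  parameterization <- match.arg(parameterization)
  stopifnot(p0 >= 0, p0 <= 1, h >= 0, h <= 1, generations >= 0)
  w <- fitnesses(s, h, parameterization)
  if (any(w <= 0))
    stop("fitness <= 0 for some genotype (s = ", s, ", h = ", h, ", ",
         parameterization, ")")
  p <- numeric(generations + 1L)
  p[1L] <- p0
  if (generations > 0L) for (t in seq_len(generations)) {
    pt <- p[t]; q <- 1 - pt
    wbar <- pt^2 * w[1L] + 2 * pt * q * w[2L] + q^2 * w[3L]
    p[t + 1L] <- pt * (pt * w[1L] + q * w[2L]) / wbar
  }
  p
}

fitnesses <- function(s, h, parameterization) {
  if (parameterization == "advantage") c(1 + s, 1 + h * s, 1)
  else c(1, 1 - h * s, 1 - s)
}

#' Estimate a selection coefficient from an allele-frequency change
#'
#' Solves `forward_trajectory(p0, s, h, G)[G + 1] = pt` for `s` by bisection,
#' exploiting that the final frequency is strictly increasing in `s`. For
#' `pt > p0` the search bracket is `[0, s_max]` (`s_max = 10` for the
#' advantage parameterization, just below 1 for the gillespie form so all
#' fitnesses stay positive); for `pt < p0` it is `[-0.99, 0]` and the
#' estimate is flagged `negative`. A final frequency at or above
#' `near_fixation` is flagged `near_fixation_unreliable` (the estimate is
#' still reported) because the trajectory saturates and the inversion loses
#' precision there.
#'
#' @param p0 initial frequency, strictly inside `(0, 1)`.
#' @param pt observed frequency after `generations` generations, in `[0, 1]`.
#' @param generations number of generations (>= 1).
#' @param h,parameterization as in [forward_trajectory()].
#' @param tol convergence tolerance on `|p_G - pt|` (default 1e-8).
#' @param near_fixation flag threshold on `pt` (default 0.995).
#' @return list of class `selection_estimate`: `s_hat`, `flag` (`ok`,
#'   `negative` or `near_fixation_unreliable`), `p0`, `pt`, `generations`,
#'   `h`, `parameterization`.
#' @export
estimate_s <- function(p0, pt, generations, h = 0.5,
                       parameterization = c("advantage", "gillespie"),
                       tol = 1e-8, near_fixation = 0.995) {
  parameterization <- match.arg(parameterization)
  stopifnot(p0 > 0, p0 < 1, pt >= 0, pt <= 1, generations >= 1)
  p_final <- function(s)
    forward_trajectory(p0, s, h, generations, parameterization)[generations + 1L]
  flag <- if (pt >= near_fixation) "near_fixation_unreliable"
          else if (pt < p0) "negative" else "ok"
  if (pt == p0) {
    s_hat <- 0
  } else if (pt == 1 || pt == 0) {
    # absorbing endpoints are unreachable from interior p0 in finite time
    s_hat <- NA_real_
  } else {
    if (pt > p0) {
      lo <- 0
      hi <- if (parameterization == "advantage") 10 else
        min(0.999, 0.999 / max(h, 1e-12))
    } else {
      lo <- -0.99; hi <- 0
    }
    flo <- p_final(lo) - pt; fhi <- p_final(hi) - pt
    if (flo * fhi > 0)
      stop(sprintf("pt = %.6g unreachable from p0 = %.6g in %d generations within s in [%.3g, %.3g] (p_G range [%.6g, %.6g])",
                   pt, p0, generations, lo, hi, p_final(lo), p_final(hi)))
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      fm <- p_final(mid) - pt
      if (abs(fm) <= tol && (hi - lo) < 1e-10) break
      if (fm < 0) lo <- mid else hi <- mid
    }
    s_hat <- (lo + hi) / 2
  }
  structure(list(s_hat = s_hat, flag = flag, p0 = p0, pt = pt,
                 generations = as.integer(generations), h = h,
                 parameterization = parameterization),
            class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf("s_hat = %.4f [%s]  (p0 = %.3f -> pt = %.3f over %d generations, h = %.2f, %s)\n",
              x$s_hat, x$flag, x$p0, x$pt, x$generations, x$h, x$parameterization))
  invisible(x)
}

#' Mean freshwater-allele frequency of a divergence island in one pool
#'
#' Unweighted arithmetic mean of the freshwater-allele frequencies across the
#' island's marker SNPs that are usable in the pool.
#'
#' @param fwf output of [freshwater_frequencies()].
#' @param di one row of a `di_set` (or any list with `chrom`, `start`, `end`).
#' @param pool pool name.
#' @return the mean frequency (scalar).
#' @export
di_mean_frequency <- function(fwf, di, pool) {
  j <- match(pool, colnames(fwf$freq))
  if (is.na(j)) stop("unknown pool: ", pool)
  sel <- fwf$sites$chrom == di$chrom & fwf$sites$pos >= di$start &
    fwf$sites$pos <= di$end
  v <- fwf$freq[sel, j]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no usable markers for pool '", pool, "' in island ",
                       di$chrom, ":", di$start, "-", di$end)
  mean(v)
}

#' Estimate selection coefficients for every island in aged populations
#'
#' For each divergence island and each target population of known age, takes
#' the island's mean freshwater-allele frequency as `pt`, the population's
#' assumed founding frequency as `p0`, converts age to generations at
#' `generation_time` years per generation (rounded to nearest), and inverts
#' the deterministic trajectory with [estimate_s()].
#'
#' @param fwf output of [freshwater_frequencies()].
#' @param dis a `di_set`.
#' @param pools a [pool_table()]; target populations are selected by
#'   `populations` or default to all pools with both `age_years` and
#'   `founder_freq` set.
#' @param populations optional character vector of pool names.
#' @param h,parameterization,near_fixation passed to [estimate_s()].
#' @param generation_time years per generation (default 2).
#' @return data.frame of class `selection_scan`: `di`, `population`, `p0`,
#'   `pt`, `generations`, `s_hat`, `flag` (`no_markers` rows carry `NA`
#'   estimates).
#' @export
estimate_selection <- function(fwf, dis, pools, populations = NULL, h = 0.5,
                               parameterization = "advantage",
                               generation_time = 2, near_fixation = 0.995) {
  if (is.null(populations))
    populations <- pools$name[!is.na(pools$age_years) & !is.na(pools$founder_freq)]
  rows <- list()
  for (p in populations) {
    j <- pool_index(pools, p)
    G <- as.integer(round(pools$age_years[j] / generation_time))
    p0 <- pools$founder_freq[j]
    for (i in seq_len(nrow(dis))) {
      pt <- tryCatch(di_mean_frequency(fwf, dis[i, ], p), error = function(e) NA_real_)
      if (is.na(pt)) {
        est <- list(s_hat = NA_real_, flag = "no_markers")
      } else {
        est <- estimate_s(p0, pt, G, h, parameterization, near_fixation = near_fixation)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        di = dis$id[i], population = p, p0 = p0, pt = pt, generations = G,
        s_hat = est$s_hat, flag = est$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("selection_scan", "data.frame")
  out
}

#' Summarize selection estimates across populations
#'
#' Per population, the mean of estimates flagged `ok` (estimates flagged
#' `negative` or `near_fixation_unreliable`, and missing values, are
#' excluded). Between each pair of populations, Spearman's rank correlation
#' over the islands where both estimates are usable, with average ranks for
#' ties and the two-sided P value from the t approximation on `n - 2`
#' degrees of freedom; pairs with fewer than 3 shared usable islands are
#' omitted with a notice.
#'
#' @param est a `selection_scan` data.frame (columns `di`, `population`,
#'   `s_hat`, `flag`).
#' @return list of class `selection_summary`: `mean_s` (named vector),
#'   `n_used` (named vector), `correlations` (data.frame `pop_a`, `pop_b`,
#'   `n`, `rho`, `p`), `notices` (character).
#' @export
summarize_selection <- function(est) {
  usable <- est$flag == "ok" & !is.na(est$s_hat)
  pops <- unique(est$population)
  mean_s <- vapply(pops, function(p) mean(est$s_hat[usable & est$population == p]), 0)
  n_used <- vapply(pops, function(p) sum(usable & est$population == p), 0L)
  cors <- list(); notices <- character()
  if (length(pops) > 1L) for (a in seq_len(length(pops) - 1L))
    for (b in (a + 1L):length(pops)) {
      da <- est[est$population == pops[a] & usable, c("di", "s_hat")]
      db <- est[est$population == pops[b] & usable, c("di", "s_hat")]
      m <- merge(da, db, by = "di")
      if (nrow(m) < 3L) {
        notices <- c(notices, sprintf(
          "correlation %s vs %s omitted: only %d shared usable islands",
          pops[a], pops[b], nrow(m)))
        next
      }
      sp <- spearman_t(m$s_hat.x, m$s_hat.y)
      cors[[length(cors) + 1L]] <- data.frame(
        pop_a = pops[a], pop_b = pops[b], n = nrow(m), rho = sp$rho, p = sp$p,
        stringsAsFactors = FALSE)
    }
  structure(list(mean_s = mean_s, n_used = n_used,
                 correlations = if (length(cors)) do.call(rbind, cors) else
                   data.frame(pop_a = character(), pop_b = character(),
                              n = integer(), rho = numeric(), p = numeric()),
                 notices = notices),
            class = "selection_summary")
}

# Spearman rho with average ranks, two-sided P from t approximation (n-2 df)
spearman_t <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("Mean selection coefficient per population (usable estimates only):\n")
  for (p in names(x$mean_s))
    cat(sprintf("  %-28s %.4f  (n = %d)\n", p, x$mean_s[[p]], x$n_used[[p]]))
  if (nrow(x$correlations)) {
    cat("Spearman correlations between populations:\n")
    for (i in seq_len(nrow(x$correlations)))
      cat(sprintf("  %s vs %s: rho = %.3f, p = %.3f (n = %d)\n",
                  x$correlations$pop_a[i], x$correlations$pop_b[i],
                  x$correlations$rho[i], x$correlations$p[i], x$correlations$n[i]))
  }
  for (msg in x$notices) cat("note:", msg, "\n")
  invisible(x)
}

#' @export
summary.selection_scan <- function(object, ...) summarize_selection(object)

#' @export
print.selection_scan <- function(x, ...) {
  cat(sprintf("selection_scan: %d island x population estimates (%d usable)\n",
              nrow(x), sum(x$flag == "ok", na.rm = TRUE)))
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
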