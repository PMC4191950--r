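test_that("trajectories are neutral at s = 0 and absorbing at the boundaries", {
  expect_equal(forward_trajectory(0.3, 0, 0.5, 10), rep(0.3, 11))
  expect_equal(forward_trajectory(0, 0.2, 0.5, 5), rep(0, 6))
  expect_equal(forward_trajectory(1, 0.2, 0.5, 5), rep(1, 6))
  expect_error(forward_trajectory(0.5, -1.5, 0.5, 5), "fitness")
})

test_that("one generation of selection matches direct arithmetic", {
  # advantage: w = (1.2, 1.1, 1.0); at p = 0.5, wbar = 1.10,
  # p1 = 0.5 (0.5*1.2 + 0.5*1.1) / 1.10
  p1 <- forward_trajectory(0.5, 0.2, 0.5, 1, "advantage")[2]
  expect_equal(p1, 0.5 * (0.5 * 1.2 + 0.5 * 1.1) / 1.10)
  expect_equal(p1, 0.5227273, tolerance = 1e-7)
  # gillespie: w = (1, 0.9, 0.8); wbar = 0.25 + 0.45 + 0.2 = 0.9
  g1 <- forward_trajectory(0.5, 0.2, 0.5, 1, "gillespie")[2]
  expect_equal(g1, 0.5 * (0.5 * 1 + 0.5 * 0.9) / 0.9)
})

test_that("trajectories increase in time and in s for positive selection", {
  for (s in c(0.05, 0.15, 0.3)) for (h in c(0, 0.5, 1)) for (p0 in c(0.1, 0.5)) {
    tr <- forward_trajectory(p0, s, h, 25, "advantage")
    expect_true(all(diff(tr) > 0))
  }
  pg <- vapply(seq(0.01, 0.5, 0.01),
               function(s) forward_trajectory(0.1, s, 0.5, 17)[18], 0)
  expect_true(all(diff(pg) > 0))  # monotone in s: bisection is valid
})

test_that("estimate_s inverts forward_trajectory within 1e-6 across the grid", {
  for (param in c("advantage", "gillespie"))
    for (s_true in c(0.05, 0.1, 0.2, 0.3))
      for (p0 in c(0.1, 0.5)) {
        if (param == "gillespie" && s_true >= 1) next
        pt <- forward_trajectory(p0, s_true, 0.5, 17, param)[18]
        est <- estimate_s(p0, pt, 17, 0.5, param)
        expect_lt(abs(est$s_hat - s_true), 1e-6)
        expect_equal(est$flag, "ok")
      }
})

test_that("estimate_s flags edge cases rather than failing", {
  expect_equal(estimate_s(0.1, 0.1, 17)$s_hat, 0)
  neg <- estimate_s(0.5, 0.3, 17)
  expect_equal(neg$flag, "negative")
  expect_lt(neg$s_hat, 0)
  # round trip through a negative coefficient
  ptn <- forward_trajectory(0.5, -0.2, 0.5, 17)[18]
  expect_lt(abs(estimate_s(0.5, ptn, 17)$s_hat + 0.2), 1e-6)
  nf <- estimate_s(0.1, 0.999, 17)
  expect_equal(nf$flag, "near_fixation_unreliable")
  expect_true(is.finite(nf$s_hat))
  expect_true(is.na(estimate_s(0.1, 1, 17)$s_hat))
  expect_error(estimate_s(0.999, 0.001, 1), "unreachable")
})

test_that("weak selection approximates the logit-linear growth law", {
  for (s in c(0.005, 0.01, 0.02)) {
    pG <- forward_trajectory(0.1, s, 0.5, 17, "advantage")[18]
    lhs <- log(pG / (1 - pG)) - log(0.1 / 0.9)
    rhs <- 17 * log(1 + s / 2)
    expect_lt(abs(lhs - rhs) / rhs, 0.01)
  }
})

test_that("island mean frequencies are unweighted means over usable markers", {
  pools <- two_pools()
  sf <- make_site_freqs(matrix(c(0.6, 0.4, 0.27, 0.5, 0.5, 0.5), ncol = 2),
                        pools, pos = c(10L, 20L, 500L))
  mk <- make_markers(c(10L, 20L, 500L), "strong")
  fwf <- freshwater_frequencies(sf, mk)   # freshwater allele is minor (T)
  di <- list(chrom = "chrI", start = 1L, end = 100L)
  expect_equal(di_mean_frequency(fwf, di, "sea"), mean(1 - c(0.6, 0.4)))
  expect_equal(di_mean_frequency(fwf, di, "lake"), mean(1 - c(0.5, 0.5)))
  # single marker
  expect_equal(di_mean_frequency(fwf, list(chrom = "chrI", start = 400L, end = 600L),
                                 "sea"), 0.73)
  # unusable markers are dropped; none usable is an error
  sf$usable[1, "sea"] <- FALSE
  fwf2 <- freshwater_frequencies(sf, mk)
  expect_equal(di_mean_frequency(fwf2, di, "sea"), 0.6)
  sf$usable[, "sea"] <- FALSE
  expect_error(di_mean_frequency(freshwater_frequencies(sf, mk), di, "sea"),
               "no usable markers")
  # brute-force check on random divisions
  set.seed(5)
  f <- matrix(runif(400), ncol = 2)
  sfr <- make_site_freqs(f, pools, pos = seq_len(200L) * 10L)
  fwr <- freshwater_frequencies(sfr, make_markers(seq_len(200L) * 10L, "strong"))
  for (k in 1:20) {
    lo <- sample(2000L, 1L); hi <- lo + sample(500L, 1L)
    sel <- which(sfr$sites$pos >= lo & sfr$sites$pos <= hi)
    if (!length(sel)) next
    expect_equal(di_mean_frequency(fwr, list(chrom = "chrI", start = lo, end = hi),
                                   "lake"), mean(1 - f[sel, 2]))
  }
})

test_that("published per-island coefficients reproduce the cross-population summary", {
  scan <- whitesea_selection_scan()
  s <- summarize_selection(scan)
  expect_equal(round(unname(s$mean_s["ershovskoye_residential"]), 2), 0.16)
  expect_equal(round(unname(s$mean_s["goluboy"]), 2), 0.13)
  expect_equal(unname(s$n_used), c(18L, 17L))
  expect_equal(s$correlations$n, 16L)
  expect_equal(round(s$correlations$rho, 2), 0.30)
  expect_equal(round(s$correlations$p, 2), 0.27)
  # the t-approximation with average ranks matches the standard implementation
  isl <- whitesea_islands()
  ok <- isl$flag_ershovskoye == "ok" & isl$flag_goluboy == "ok"
  ref <- suppressWarnings(stats::cor.test(isl$s_ershovskoye[ok], isl$s_goluboy[ok],
                                          method = "spearman", exact = FALSE))
  expect_equal(s$correlations$rho, unname(ref$estimate))
  expect_equal(s$correlations$p, ref$p.value, tolerance = 1e-6)
})

test_that("correlations need at least three shared usable islands", {
  scan <- data.frame(di = c("a", "b", "a", "b"),
                     population = c("p1", "p1", "p2", "p2"),
                     s_hat = c(0.1, 0.2, 0.15, 0.25), flag = "ok")
  class(scan) <- c("selection_scan", "data.frame")
  s <- summarize_selection(scan)
  expect_equal(nrow(s$correlations), 0L)
  expect_match(s$notices, "only 2 shared")
})
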