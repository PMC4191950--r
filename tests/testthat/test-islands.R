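test_that("window counts match brute-force bucketing", {
  # boundary: 10,000 is in window 1, 10,001 in window 2
  mk <- make_markers(c(1:10, 10000L, 10001L), "strong")
  w <- windows_with_markers(mk, "strong", 10000L)
  expect_equal(w$n[w$window == 1L], 11L)
  expect_equal(w$n[w$window == 2L], 1L)
  expect_equal(w$start[w$window == 2L], 10001L)
  set.seed(21)
  pos <- sort(sample.int(2e6, 500L))
  mk <- make_markers(pos, sample(c("strong", "weak"), 500L, TRUE))
  w <- windows_with_markers(mk, "weak", 10000L)
  brute <- table((pos - 1L) %/% 10000L + 1L)
  expect_equal(w$n, unname(as.integer(brute)))
  expect_equal(w$window, as.integer(names(brute)))
})

test_that("regions merge when closer than 40 kb and not otherwise", {
  # two windows of 10 markers each, trimmed regions separated by ~30 kb
  p1 <- seq(1000L, 9100L, 900L)        # 10 markers in window 1
  p2 <- p1 + 40000L                    # 10 markers in window 5
  mk <- make_markers(c(p1, p2), "strong")
  one <- detect_islands(mk, "strong", island_params())
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(min(p1), max(p2)))
  expect_equal(one$n_markers, 20L)
  # ~50 kb apart: two islands
  mk2 <- make_markers(c(p1, p1 + 60000L), "strong")
  two <- detect_islands(mk2, "strong", island_params())
  expect_equal(nrow(two), 2L)
  # gap measured between trimmed boundaries, strict <: exactly 40 kb stays split
  pa <- c(rep(9000L, 9), 10000L)       # 10 markers, trimmed end 10,000
  pb <- c(50001L, rep(51000L, 9))      # trimmed start 50,001 -> gap = 40,000
  boundary <- detect_islands(make_markers(c(pa, pb), "strong"), "strong",
                             island_params())
  expect_equal(nrow(boundary), 2L)
  # with merging disabled the island count can only grow
  off <- detect_islands(mk, "strong", island_params(merging_enabled = FALSE))
  expect_gte(nrow(off), nrow(one))
  expect_equal(nrow(off), 2L)
})

test_that("islands are trimmed to their outermost markers", {
  pos <- c(2000L, seq(2100L, 8000L, 600L), 9900L)
  di <- detect_islands(make_markers(pos, "strong"), "strong", island_params())
  expect_equal(c(di$start, di$end), c(2000L, 9900L))
})

test_that("island detection is idempotent", {
  set.seed(33)
  pos <- sort(sample.int(3e6, 4000L))
  mk <- make_markers(pos, "strong")
  d1 <- detect_islands(mk, "strong", island_params())
  inside <- mk[sites_in <- vapply(mk$pos, function(p)
    any(p >= d1$start & p <= d1$end & mk$chrom[1] == d1$chrom), TRUE), ]
  d2 <- detect_islands(inside, "strong", island_params())
  expect_equal(d1[c("chrom", "start", "end")], d2[c("chrom", "start", "end")])
})

test_that("overlay takes the union and records supporting criteria", {
  s <- data.frame(chrom = "chrIV", start = 100L, end = 200L, n_markers = 10L)
  w <- data.frame(chrom = "chrIV", start = 150L, end = 400L, n_markers = 25L)
  di <- overlay_islands(s, w)
  expect_equal(nrow(di), 1L)
  expect_equal(c(di$start, di$end), c(100L, 400L))
  expect_equal(di$criteria, "strong,weak")
  expect_equal(di$id, "IV-1")
  # weak-only interval keeps its weak label; disjoint intervals stay separate
  w2 <- data.frame(chrom = "chrIV", start = 900L, end = 1200L, n_markers = 30L)
  di2 <- overlay_islands(s, rbind(w, w2))
  expect_equal(di2$criteria, c("strong,weak", "weak"))
  expect_equal(di2$id, c("IV-1", "IV-2"))
  expect_equal(di2$length, di2$end - di2$start + 1L)
  # empty inputs
  expect_equal(nrow(overlay_islands(s[0, ], w[0, ])), 0L)
})

test_that("published island coordinates reproduce lengths and the grand total", {
  cat_ <- whitesea_islands()
  di <- divergence_islands(cat_$id, cat_$chrom, cat_$start, cat_$end, cat_$criteria)
  expect_equal(di$length[di$id == "XXI-1"], 1726757L)
  expect_equal(di$length[di$id == "I-1"], 472122L)
  expect_equal(sum(di$length), 3301948L)
})

test_that("summaries count markers inside islands and report the fraction", {
  mk <- make_markers(c(500L, 1500L, 2500L, 99000L), c("strong", "strong", "weak",
                                                      "strong"))
  di <- divergence_islands("I-1", "chrI", 400L, 3000L, "strong")
  s <- summarize_islands(di, mk)
  expect_equal(s$per_di$n_strong, 2L)
  expect_equal(s$per_di$n_weak, 3L)   # weak criterion includes strong markers
  expect_equal(s$totals$pct_strong_in_dis, round(100 * 2 / 3, 1))
  expect_equal(marker_fraction(5801, 6107), 95.0)
  # zero markers: empty but well-formed
  s0 <- summarize_islands(di[0, ], mk[0, ])
  expect_equal(s0$totals$total_length, 0L)
  expect_true(is.na(s0$totals$pct_strong_in_dis))
})
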