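crit4 <- function() marker_criteria(c("sea1", "sea2"), c("lake1", "lake2"))

test_that("strong and weak criteria classify canonical cases", {
  pools <- four_pools()
  # rows: major-allele (A) frequency per pool (sea1, sea2, lake1, lake2)
  f <- rbind(
    c(0.85, 0.90, 0.15, 0.05),  # strong: A marine, T freshwater
    c(0.85, 0.90, 0.40, 0.45),  # weak only (freshwater T at 0.60/0.55)
    c(0.80, 0.90, 0.10, 0.10),  # none: 0.80 is not above 80%
    c(0.10, 0.15, 0.90, 0.81),  # strong with roles swapped (T marine)
    c(0.90, 0.90, 0.90, 0.90))  # none: same allele everywhere
  mk <- call_markers(make_site_freqs(f, pools), crit4())
  expect_equal(mk$status, c("strong", "weak", "none", "strong", "none"))
  expect_equal(mk$marine_allele[1], "A")
  expect_equal(mk$freshwater_allele[1], "T")
  expect_equal(mk$marine_allele[4], "T")
  expect_equal(mk$freshwater_allele[4], "A")
  expect_true(all(is.na(mk$marine_allele[mk$status == "none"])))
  # freshwater-allele frequencies are reported for the freshwater pools
  expect_equal(mk$fw_lake1[1], 0.85)
  expect_equal(mk$fw_lake2[2], 0.55)
})

test_that("single-pair classification works and is a superset of two-pair", {
  pools <- four_pools()
  f <- rbind(c(0.90, 0.50, 0.19, 0.60),   # single-pair strong, two-pair none
             c(0.90, 0.90, 0.19, 0.10),   # strong under both
             c(0.90, 0.90, 0.90, 0.10))   # none under both (same allele pair1)
  sf <- make_site_freqs(f, pools)
  single <- call_markers_single_pair(sf, "sea1", "lake1")
  expect_equal(single$status, c("strong", "strong", "none"))
  both <- call_markers(sf, crit4())
  expect_equal(both$status, c("none", "strong", "none"))
  # set inclusion on simulated data: every two-pair marker is a single-pair marker
  sim <- simulate_metapopulation(small_sim_config(seed = 13), dir = tempfile())
  sfs <- estimate_frequencies(read_pool_counts(sim$paths$counts, sim$pools))
  two <- call_markers(sfs, marker_criteria(c("nilma", "ershovskoye_anadromous"),
                                           c("lobaneshskoye", "mashinnoye")))
  one <- call_markers_single_pair(sfs, "nilma", "mashinnoye")
  key <- function(m, st) paste(m$chrom, m$pos)[m$status %in% st]
  expect_true(all(key(two, "strong") %in% key(one, "strong")))
  expect_gte(sum(one$status == "strong"), sum(two$status == "strong"))
})

test_that("strong implies weak for any threshold pair and random frequencies", {
  set.seed(7)
  pools <- four_pools()
  for (wt in c(0.5, 0.65, 0.8)) {
    f <- matrix(runif(400), ncol = 4)
    sf <- make_site_freqs(f, pools)
    mk <- call_markers(sf, marker_criteria(c("sea1", "sea2"), c("lake1", "lake2"),
                                           weak_thresh = wt))
    strong_only <- call_markers(sf, marker_criteria(
      c("sea1", "sea2"), c("lake1", "lake2"), weak_thresh = 0.8))
    # every site strong under (0.8, wt) is also weak-or-better
    expect_true(all(mk$status[strong_only$status == "strong"] == "strong"))
    # weak set contains strong set by construction of the status levels
    expect_true(all(mk$status %in% c("strong", "weak", "none")))
  }
})

test_that("relabeling the tracked allele does not change marker status", {
  set.seed(8)
  pools <- four_pools()
  f <- matrix(runif(200), ncol = 4)
  sf1 <- make_site_freqs(f, pools)
  sf2 <- make_site_freqs(1 - f, pools, major = "T", minor = "A")
  m1 <- call_markers(sf1, crit4())
  m2 <- call_markers(sf2, crit4())
  expect_equal(m1$status, m2$status)
  expect_equal(m1$marine_allele, m2$marine_allele)
})

test_that("sites unusable in a required pool are skipped, not imputed", {
  pools <- four_pools()
  sf <- make_site_freqs(rbind(c(0.9, 0.9, 0.1, 0.1), c(0.9, 0.9, 0.1, 0.1)), pools)
  sf$usable[2, "lake2"] <- FALSE
  mk <- call_markers(sf, crit4())
  expect_equal(nrow(mk), 1L)
  expect_equal(mk$pos, 1L)
})
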