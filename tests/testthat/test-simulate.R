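test_that("a fixed seed reproduces byte-identical outputs", {
  cfg <- small_sim_config(seed = 23)
  s1 <- simulate_metapopulation(cfg, dir = tempfile())
  s2 <- simulate_metapopulation(cfg, dir = tempfile())
  for (f in names(s1$paths))
    expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]),
                     label = paste("file", f))
})

test_that("quarry founding frequencies are exact founder ratios", {
  pops <- sim_populations(
    c("m", "q5050", "q1090"), c("marine", "freshwater", "freshwater"),
    n_individuals = c(10L, 20L, 20L), depth_mean = 50, min_depth = 5L,
    age_years = c(NA, 0, 0), ne = c(NA, 500L, 500L),
    founding = c("marine", "quarry", "quarry"),
    quarry_marine = c(NA, 20L, 18L), quarry_fresh = c(NA, 20L, 2L))
  cfg <- sim_config(seed = 2, chromosomes = c(chrA = 100000L), n_islands = 1L,
                    island_length_range = c(20000L, 20000L),
                    background_snp_rate = 0, monomorphic_rate = 0,
                    gene_fraction = 0, n_background_genes = 0L,
                    populations = pops)
  sim <- simulate_metapopulation(cfg, dir = tempfile())
  # age 0: the founding frequency is observed directly
  expect_equal(sim$truth$islands$q_q5050, 0.5)
  expect_equal(sim$truth$islands$q_q1090, 0.1)
  expect_equal(sim$truth$islands$q_m, 0.1)  # marine standing frequency
})

test_that("neutral islands in large populations stay near the founding value", {
  pops <- sim_populations(
    c("m", "f"), c("marine", "freshwater"), n_individuals = c(10L, 20L),
    depth_mean = 50, min_depth = 5L, age_years = c(NA, 34),
    ne = c(NA, 100000L), founding = c("marine", "quarry"),
    quarry_marine = c(NA, 20L), quarry_fresh = c(NA, 20L))
  cfg <- sim_config(seed = 31, chromosomes = c(chrA = 400000L), n_islands = 4L,
                    island_length_range = c(15000L, 30000L), island_s = rep(0, 4),
                    background_snp_rate = 0, monomorphic_rate = 0,
                    gene_fraction = 0, n_background_genes = 0L, populations = pops)
  sim <- simulate_metapopulation(cfg, dir = tempfile())
  # 17 generations of drift at Ne = 1e5 from p = 0.5: sd ~ sqrt(17 p q / 2Ne)
  sd_drift <- sqrt(17 * 0.25 / 2e5)
  expect_true(all(abs(sim$truth$islands$q_f - 0.5) < 3 * sd_drift))
})

test_that("expected pooled read frequency mixes sample frequency with errors", {
  eps <- 0.01
  pops <- sim_populations("m", "marine", n_individuals = 50L, depth_mean = 60,
                          min_depth = 5L)
  cfg <- sim_config(seed = 41, chromosomes = c(chrA = 200000L), n_islands = 0L,
                    background_snp_rate = 0.25, monomorphic_rate = 0,
                    error_rate = eps, gene_fraction = 0, n_background_genes = 0L,
                    background_beta = c(2, 2), populations = pops)
  sim <- simulate_metapopulation(cfg, dir = tempfile())
  ts <- sim$truth$sites
  pc <- sim$counts
  alt_idx <- match(ts$alt, c("A", "C", "G", "T"))
  alt_reads <- pc$counts[cbind(seq_len(nrow(ts)), 1L, alt_idx)]
  depth <- rowSums(pc$counts[, 1L, ])
  f <- ts$samp_m
  expected <- f * (1 - eps) + (1 - f) * eps / 3
  # Monte-Carlo check of the mixture identity E[alt/depth] = f(1-eps)+(1-f)eps/3
  resid <- alt_reads - depth * expected
  se <- sqrt(sum(depth * expected * (1 - expected)))
  expect_lt(abs(sum(resid)) / se, 4)
})

test_that("truth_report scores detection against planted islands", {
  sim <- simulate_metapopulation(small_sim_config(seed = 47), dir = tempfile())
  truth <- sim$truth$islands
  perfect <- divergence_islands(truth$id, truth$chrom, truth$start, truth$end)
  tr <- truth_report(sim, perfect)
  expect_equal(tr$recall, 1)
  expect_equal(tr$precision, 1)
  none <- truth_report(sim, perfect[0, ])
  expect_equal(none$recall, 0)
  # an island covering less than half of the truth does not match
  shifted <- divergence_islands(truth$id[1], truth$chrom[1],
                                truth$end[1] - 99L, truth$end[1] + 500L)
  expect_equal(truth_report(sim, shifted)$recall, 0)
})

test_that("marker false positives are rare on a null simulation", {
  # equal habitats, no islands: habitats differ only by drift and sampling
  pops <- sim_populations(
    paste0("p", 1:4), c("marine", "marine", "freshwater", "freshwater"),
    n_individuals = 15L, depth_mean = 50, min_depth = 10L,
    age_years = c(NA, NA, 34, 34), ne = c(NA, NA, 500L, 500L),
    founding = c("marine", "marine", "lake", "lake"), n_founders = 100L)
  cfg <- sim_config(seed = 53, chromosomes = c(chrA = 400000L), n_islands = 0L,
                    background_snp_rate = 0.12, monomorphic_rate = 0,
                    gene_fraction = 0, n_background_genes = 0L,
                    populations = pops)
  sim <- simulate_metapopulation(cfg, dir = tempfile())
  sf <- estimate_frequencies(read_pool_counts(sim$paths$counts, sim$pools))
  mk <- call_markers(sf, marker_criteria(c("p1", "p2"), c("p3", "p4")))
  fp_rate <- sum(mk$status != "none") / nrow(mk)
  expect_lt(fp_rate, 1e-4)
})
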