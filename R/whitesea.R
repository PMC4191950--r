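#' White Sea stickleback reference tables
#'
#' Published summary tables for the eight White Sea *Gasterosteus aculeatus*
#' pools (two marine, six freshwater) that this package's pipeline was built
#' around. They serve as reference inputs for the bookkeeping arithmetic the
#' package exposes: island lengths and totals, marker fractions, NS/S
#' contingency analysis, and cross-population selection summaries.
#'
#' `whitesea_islands()` is the catalogue of 19 divergence islands: id
#' (chromosome-ordinal), 1-based inclusive coordinates, marker-SNP count,
#' supporting criteria (`weak` rows were identified only under the weak
#' criterion), and the selection coefficients estimated from Lake
#' Ershovskoye (`s_ershovskoye`) and Quarry Goluboy (`s_goluboy`) with their
#' flags: `ok`, `negative` (inferred s below 0; the value itself was not
#' reported) or `no_markers` (not inferable due to near-fixation of the
#' freshwater allele).
#'
#' `whitesea_pools()` is a [pool_table()] of the eight pools with their
#' habitat, pooled individuals, SNP-calling depth cutoffs, estimated ages and
#' assumed founding freshwater-allele frequencies (0.1 in natural lakes,
#' matching the marine standing frequency; 0.5 in the two quarries seeded
#' with equal numbers of marine and freshwater founders), plus mean coverage
#' and genome-wide nucleotide diversity as extra columns.
#'
#' `whitesea_ns_s()` is the nonsynonymous/synonymous count table for coding
#' SNPs inside and outside the islands, for marine-freshwater marker SNPs
#' (strong criterion) and for SNPs segregating within the marine population.
#'
#' @return A data.frame (`whitesea_islands`, `whitesea_ns_s`) or
#'   `pool_table` (`whitesea_pools`).
#' @name whitesea
NULL

#' @rdname whitesea
#' @export
whitesea_islands <- function() {
  df <- data.frame(
    id = c("I-1", "II-1", "IV-1", "IV-2", "IV-3", "IV-4", "IV-5", "V-1",
           "VII-1", "IX-1", "IX-2", "IX-3", "IX-4", "XI-1", "XII-1", "XII-2",
           "XIX-1", "XIX-2", "XXI-1"),
    chrom = c("chrI", "chrII", "chrIV", "chrIV", "chrIV", "chrIV", "chrIV",
              "chrV", "chrVII", "chrIX", "chrIX", "chrIX", "chrIX", "chrXI",
              "chrXII", "chrXII", "chrXIX", "chrXIX", "chrXXI"),
    start = c(21487998L, 14874366L, 12803780L, 13930002L, 19811922L, 23954634L,
              26016955L, 2482209L, 17982351L, 8521935L, 8901816L, 9208158L,
              10334101L, 5445757L, 14338229L, 16522028L, 2449903L, 14787904L,
              5759879L),
    end = c(21960119L, 14898826L, 12881296L, 13959331L, 19914666L, 23981981L,
            26166536L, 2501295L, 18002671L, 8537559L, 8910115L, 9227809L,
            10353801L, 5855124L, 14358336L, 16538810L, 2581858L, 14799088L,
            7486635L),
    n_markers = c(4186L, 73L, 285L, 168L, 209L, 48L, 252L, 65L, 84L, 44L, 20L,
                  46L, 114L, 1237L, 91L, 24L, 277L, 21L, 6900L),
    criteria = c("strong,weak", "weak", "strong,weak", "strong,weak",
                 "strong,weak", "strong,weak", "weak", "strong,weak", "weak",
                 "weak", "weak", "strong,weak", "strong,weak", "weak",
                 "strong,weak", "strong,weak", "strong,weak", "strong,weak",
                 "weak"),
    s_ershovskoye = c(0.247, 0.115, 0.188, 0.218, 0.212, 0.227, 0.196, 0.255,
                      NA, 0.062, 0.108, 0.198, 0.141, 0.054, 0.023, 0.162,
                      0.178, 0.117, 0.177),
    flag_ershovskoye = c(rep("ok", 8), "negative", rep("ok", 10)),
    s_goluboy = c(0.212, 0.146, 0.094, 0.107, 0.163, 0.100, 0.036, 0.239,
                  0.273, 0.026, 0.023, 0.131, 0.101, 0.147, 0.193, NA, 0.131,
                  0.056, NA),
    flag_goluboy = c(rep("ok", 15), "no_markers", "ok", "ok", "negative"),
    # lengths as printed in the catalogue (not derived from the coordinates)
    length = c(472122L, 24461L, 77517L, 29330L, 102745L, 27348L, 149582L,
               19087L, 20321L, 15625L, 8300L, 19652L, 19701L, 409368L, 20108L,
               16783L, 131956L, 11185L, 1726757L),
    stringsAsFactors = FALSE
  )
  df
}

#' @rdname whitesea
#' @export
whitesea_pools <- function() {
  p <- pool_table(
    name = c("nilma", "ershovskoye_anadromous", "ershovskoye_residential",
             "martsy", "goluboy", "malysh", "lobaneshskoye", "mashinnoye"),
    habitat = c("marine", "marine", "freshwater", "freshwater", "freshwater",
                "freshwater", "freshwater", "freshwater"),
    n_individuals = c(16L, 10L, 12L, 10L, 20L, 20L, 8L, 10L),
    min_depth = c(10L, 5L, 10L, 5L, 10L, 10L, 5L, 5L),
    age_years = c(NA, NA, 34, 250, 34, 34, 600, 700),
    founder_freq = c(NA, NA, 0.1, 0.1, 0.5, 0.5, 0.1, 0.1)
  )
  p$mean_coverage <- c(44L, 17L, 52L, 24L, 48L, 63L, 23L, 19L)
  p$pi <- c(0.00210, 0.00188, 0.00219, 0.00181, 0.00204, 0.00186, 0.00167, 0.00158)
  p
}

#' @rdname whitesea
#' @export
whitesea_ns_s <- function() {
  data.frame(
    comparison = rep(c("marine_freshwater_markers", "within_marine"), each = 2L),
    stratum = rep(c("within_dis", "outside_dis"), 2L),
    nonsynonymous = c(139L, 17L, 290L, 28616L),
    synonymous = c(146L, 4L, 528L, 41902L),
    stringsAsFactors = FALSE
  )
}

#' Selection estimates of the White Sea island catalogue as a selection scan
#'
#' Reshapes the `s_ershovskoye`/`s_goluboy` columns of [whitesea_islands()]
#' into the long `selection_scan` layout accepted by
#' [summarize_selection()], so the published cross-population summary (mean
#' s per population and their Spearman correlation) can be recomputed.
#'
#' @return a `selection_scan` data.frame.
#' @export
whitesea_selection_scan <- function() {
  isl <- whitesea_islands()
  out <- rbind(
    data.frame(di = isl$id, population = "ershovskoye_residential",
               p0 = 0.1, pt = NA_real_, generations = 17L,
               s_hat = isl$s_ershovskoye, flag = isl$flag_ershovskoye,
               stringsAsFactors = FALSE),
    data.frame(di = isl$id, population = "goluboy",
               p0 = 0.5, pt = NA_real_, generations = 17L,
               s_hat = isl$s_goluboy, flag = isl$flag_goluboy,
               stringsAsFactors = FALSE)
  )
  class(out) <- c("selection_scan", "data.frame")
  out
}
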