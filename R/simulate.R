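#' Simulated population definitions
#'
#' Builds the population table consumed by [sim_config()]. Each population
#' becomes one sequencing pool. Founding scenarios: `"marine"` (the ancestral
#' marine population itself; island haplotype frequencies stay at the
#' standing frequency), `"lake"` (founded by `n_founders` individuals drawn
#' binomially from marine frequencies), `"quarry"` (founded by exact counts
#' of marine and freshwater individuals, giving a founding freshwater-allele
#' frequency of `quarry_fresh / (quarry_marine + quarry_fresh)`).
#'
#' The default set mirrors the eight White Sea pools: two marine pools, two
#' old natural lakes (600 and 700 years) whose freshwater alleles have had
#' time to reach high frequency, two young natural lakes (34 and 250 years),
#' and the two quarry populations seeded in equal marine/freshwater
#' proportions (20+20 and 1+1 founders), with Table-like coverages (17-63x),
#' pool sizes (8-20) and per-pool SNP-calling depth cutoffs.
#'
#' @param name,habitat,n_individuals,depth_mean,min_depth,age_years vectors,
#'   one entry per population.
#' @param ne effective population size for Wright-Fisher drift (ignored for
#'   marine).
#' @param founding `"marine"`, `"lake"` or `"quarry"`.
#' @param n_founders lake founders (individuals).
#' @param quarry_marine,quarry_fresh quarry founder counts.
#' @return data.frame with one row per population.
#' @export
sim_populations <- function(name, habitat, n_individuals, depth_mean, min_depth,
                            age_years = NA_real_, ne = 500L,
                            founding = "marine", n_founders = 100L,
                            quarry_marine = NA_integer_, quarry_fresh = NA_integer_) {
  n <- length(name)
  data.frame(name = name, habitat = habitat,
             n_individuals = as.integer(rep_len(n_individuals, n)),
             depth_mean = as.numeric(rep_len(depth_mean, n)),
             min_depth = as.integer(rep_len(min_depth, n)),
             age_years = as.numeric(rep_len(age_years, n)),
             ne = as.integer(rep_len(ne, n)),
             founding = as.character(rep_len(founding, n)),
             n_founders = as.integer(rep_len(n_founders, n)),
             quarry_marine = as.integer(rep_len(quarry_marine, n)),
             quarry_fresh = as.integer(rep_len(quarry_fresh, n)),
             stringsAsFactors = FALSE)
}

#' @rdname sim_populations
#' @export
default_sim_populations <- function() {
  sim_populations(
    name = c("nilma", "ershovskoye_anadromous", "ershovskoye_residential",
             "martsy", "goluboy", "malysh", "lobaneshskoye", "mashinnoye"),
    habitat = c("marine", "marine", rep("freshwater", 6L)),
    n_individuals = c(16L, 10L, 12L, 10L, 20L, 20L, 8L, 10L),
    depth_mean = c(44, 17, 52, 24, 48, 63, 23, 19),
    min_depth = c(10L, 5L, 10L, 5L, 10L, 10L, 5L, 5L),
    age_years = c(NA, NA, 34, 250, 34, 34, 600, 700),
    ne = c(NA, NA, 500L, 500L, 500L, 50L, 500L, 500L),
    founding = c("marine", "marine", "lake", "lake", "quarry", "quarry",
                 "lake", "lake"),
    n_founders = c(NA, NA, 100L, 100L, NA, NA, 100L, 100L),
    quarry_marine = c(NA, NA, NA, NA, 20L, 1L, NA, NA),
    quarry_fresh = c(NA, NA, NA, NA, 20L, 1L, NA, NA)
  )
}

#' Simulation configuration
#'
#' Describes the "transporter hypothesis" metapopulation the simulator
#' emulates: ancient divergent haplotype blocks (islands) segregating at a
#' low standing frequency in the marine population, freshwater populations
#' founded from it (or seeded with known founder mixes) and evolving by
#' Wright-Fisher drift with deterministic diploid selection on each island
#' haplotype (complete linkage within an island, islands independent), a
#' neutral background SNP pool, and pooled sequencing with Poisson depth,
#' binomial read sampling and uniform base errors.
#'
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#' @param chromosomes named integer vector of chromosome lengths.
#' @param n_islands number of divergent islands to plant.
#' @param island_length_range island length range in bases.
#' @param min_island_gap minimum distance between islands (kept well above
#'   the 40 kb merge distance so planted islands stay distinct).
#' @param marker_density per-base divergence between the two island
#'   haplotypes (default 0.009, the density scale observed in real islands).
#' @param marine_standing_freq standing frequency of the freshwater haplotype
#'   in the marine population (default 0.1).
#' @param background_snp_rate per-base rate of neutral background SNPs.
#' @param background_beta `c(alpha, beta)` of the Beta distribution of marine
#'   background allele frequencies.
#' @param monomorphic_rate per-base rate of monomorphic covered sites emitted
#'   so diversity denominators include invariant sites.
#' @param s_range per-island selection coefficients are drawn uniformly from
#'   this range unless `island_s` gives them explicitly.
#' @param island_s optional explicit per-island selection coefficients.
#' @param h dominance coefficient of the freshwater haplotype (default 0.5).
#' @param error_rate per-base sequencing error rate after quality filtering.
#' @param gene_fraction fraction of islands that carry a planted
#'   protein-coding gene.
#' @param n_background_genes genes planted outside islands.
#' @param generation_time years per generation (default 2).
#' @param quality_fail_rate per pool-site probability of failing the upstream
#'   base-quality screen (emitted as `"."`).
#' @param populations a [sim_populations()] table.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = stats::setNames(rep(400000L, 10L),
                                                     paste0("chr", as.roman(1:10))),
                       n_islands = 19L,
                       island_length_range = c(10000L, 150000L),
                       min_island_gap = 60000L,
                       marker_density = 0.009,
                       marine_standing_freq = 0.1,
                       background_snp_rate = 0.002,
                       background_beta = c(0.3, 0.3),
                       monomorphic_rate = 0.01,
                       s_range = c(0.05, 0.25),
                       island_s = NULL,
                       h = 0.5,
                       error_rate = 0.001,
                       gene_fraction = 0.6,
                       n_background_genes = 2L,
                       generation_time = 2,
                       quality_fail_rate = 0,
                       populations = default_sim_populations()) {
  stopifnot(marker_density >= 0, marker_density <= 1,
            marine_standing_freq >= 0, marine_standing_freq <= 1,
            background_snp_rate >= 0, background_snp_rate <= 1,
            error_rate >= 0, error_rate < 1, all(chromosomes > 0),
            n_islands >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate pooled sequencing of a marine/freshwater metapopulation
#'
#' Generates, under a fixed seed: a random reference genome (FASTA), planted
#' protein-coding genes (GFF3), a pooled nucleotide count table in the
#' package's sync-like dialect, and ground-truth tables (island intervals
#' with true per-population selection coefficients, per-site true population
#' and pool-sample frequencies, and planted synonymous/nonsynonymous effect
#' truth).
#'
#' Per island, two divergent haplotypes differ at `Binomial(length,
#' marker_density)` sites; the marine population carries the freshwater
#' haplotype at the standing frequency. Each freshwater population is founded
#' per its scenario and then evolves for its age in generations by binomial
#' Wright-Fisher resampling of the island haplotype frequency around the
#' deterministic selection recursion of [forward_trajectory()]. Background
#' SNPs drift neutrally from Beta-distributed marine frequencies. Pooled
#' sequencing draws one haplotype sample per island per pool (the pooled
#' individuals are shared across an island's sites), Poisson depth per site,
#' binomial read counts and uniform base errors.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return object of class `metapop_sim`: list with `config`, `dir`, `paths`
#'   (counts, fasta, gff, truth tables), `pools` (a [pool_table()] matching
#'   the count-file columns) and `truth` (islands, sites, effects,
#'   trajectories).
#' @export
simulate_metapopulation <- function(config, dir = tempfile("metapop_sim_")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pops <- config$populations
  npop <- nrow(pops)
  chroms <- config$chromosomes

  islands <- place_islands(config)
  n_isl <- nrow(islands)
  islands$s <- if (!is.null(config$island_s)) {
    stopifnot(length(config$island_s) == n_isl)
    config$island_s
  } else if (n_isl) runif(n_isl, config$s_range[1L], config$s_range[2L]) else numeric()

  # random genome, then planted genes overwrite their footprint
  genome <- lapply(chroms, function(L) sample(BASES, L, replace = TRUE))
  genes <- plant_genes(config, islands, genome)
  genome <- genes$genome

  sites <- draw_sites(config, islands, genome)
  n_site <- nrow(sites)

  # per-population true frequencies -------------------------------------
  G <- ifelse(is.na(pops$age_years), 0L,
              as.integer(round(pops$age_years / config$generation_time)))
  q_island <- matrix(config$marine_standing_freq, n_isl, npop,
                     dimnames = list(NULL, pops$name))
  trajectories <- list()
  p_bg_marine <- sites$p_marine[sites$type == "background"]
  q_bg <- matrix(rep(p_bg_marine, npop), ncol = npop,
                 dimnames = list(NULL, pops$name))
  for (j in seq_len(npop)) {
    if (pops$founding[j] == "marine") next
    ne2 <- 2L * pops$ne[j]
    p0 <- switch(pops$founding[j],
      lake = NA_real_,  # drawn per island below
      quarry = pops$quarry_fresh[j] / (pops$quarry_fresh[j] + pops$quarry_marine[j]))
    nf2 <- 2L * pops$n_founders[j]
    if (n_isl) {
      traj <- matrix(NA_real_, G[j] + 1L, n_isl)
      for (i in seq_len(n_isl)) {
        p <- if (pops$founding[j] == "lake")
          rbinom(1L, nf2, config$marine_standing_freq) / nf2 else p0
        traj[1L, i] <- p
        if (G[j] > 0L) for (t in seq_len(G[j])) {
          p_sel <- forward_trajectory(p, islands$s[i], config$h, 1L)[2L]
          p <- rbinom(1L, ne2, p_sel) / ne2
          traj[t + 1L, i] <- p
        }
        q_island[i, j] <- p
      }
      trajectories[[pops$name[j]]] <- traj
    }
    # neutral background: binomial founding then neutral Wright-Fisher drift
    nb <- length(p_bg_marine)
    if (nb) {
      nf2b <- if (pops$founding[j] == "lake") nf2 else
        2L * (pops$quarry_fresh[j] + pops$quarry_marine[j])
      p <- rbinom(nb, nf2b, p_bg_marine) / nf2b
      if (G[j] > 0L) for (t in seq_len(G[j])) p <- rbinom(nb, ne2, p) / ne2
      q_bg[, j] <- p
    }
  }

  # per-pool sample frequencies ------------------------------------------
  f_samp <- matrix(0, n_site, npop, dimnames = list(NULL, pops$name))
  is_isl <- sites$type == "island"
  is_bg <- sites$type == "background"
  for (j in seq_len(npop)) {
    nc <- 2L * pops$n_individuals[j]
    if (n_isl) {
      f_isl <- rbinom(n_isl, nc, q_island[, j]) / nc  # one draw per island
      f_samp[is_isl, j] <- f_isl[sites$island_index[is_isl]]
    }
    if (any(is_bg))
      f_samp[is_bg, j] <- rbinom(sum(is_bg), nc, q_bg[, j]) / nc
  }

  # pooled reads ----------------------------------------------------------
  counts <- array(0L, dim = c(n_site, npop, 4L),
                  dimnames = list(NULL, pops$name, BASES))
  quality_ok <- matrix(TRUE, n_site, npop, dimnames = list(NULL, pops$name))
  for (j in seq_len(npop)) {
    counts[, j, ] <- sequence_pool(sites$ref_idx, sites$alt_idx, f_samp[, j],
                                   pops$depth_mean[j], config$error_rate)
    if (config$quality_fail_rate > 0) {
      fail <- runif(n_site) < config$quality_fail_rate
      quality_ok[fail, j] <- FALSE
      counts[fail, j, ] <- 0L
    }
  }

  pool_tbl <- pool_table(
    name = pops$name, habitat = pops$habitat,
    n_individuals = pops$n_individuals, min_depth = pops$min_depth,
    age_years = pops$age_years,
    founder_freq = ifelse(pops$founding == "quarry",
                          pops$quarry_fresh / (pops$quarry_fresh + pops$quarry_marine),
                          ifelse(pops$founding == "lake",
                                 config$marine_standing_freq, NA_real_)))

  pc <- structure(list(
    sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                       ref = BASES[sites$ref_idx], stringsAsFactors = FALSE),
    counts = counts, quality_ok = quality_ok, pools = pool_tbl),
    class = "pool_counts")

  # truth tables ----------------------------------------------------------
  truth_sites <- data.frame(
    chrom = sites$chrom, pos = sites$pos, type = sites$type,
    island_id = ifelse(sites$island_index > 0L,
                       islands$id[pmax(sites$island_index, 1L)], NA_character_),
    ref = BASES[sites$ref_idx],
    alt = ifelse(sites$type == "monomorphic", NA_character_, BASES[sites$alt_idx]),
    stringsAsFactors = FALSE)
  q_site <- matrix(0, n_site, npop, dimnames = list(NULL, pops$name))
  if (n_isl) q_site[is_isl, ] <- q_island[sites$island_index[is_isl], , drop = FALSE]
  if (any(is_bg)) q_site[is_bg, ] <- q_bg
  colnames(q_site) <- paste0("pop_", pops$name)
  colnames(f_samp) <- paste0("samp_", pops$name)
  truth_sites <- cbind(truth_sites, as.data.frame(q_site), as.data.frame(f_samp))

  truth_islands <- islands[c("id", "chrom", "start", "end", "length", "s")]
  for (j in seq_len(npop))
    truth_islands[[paste0("q_", pops$name[j])]] <- q_island[, j]

  effects <- sim_effect_truth(genes$table, genome, truth_sites)

  # write all artefacts ---------------------------------------------------
  paths <- list(counts = file.path(dir, "counts.tsv"),
                fasta = file.path(dir, "genome.fa"),
                gff = file.path(dir, "genes.gff3"),
                truth_islands = file.path(dir, "truth_islands.tsv"),
                truth_sites = file.path(dir, "truth_sites.tsv"),
                truth_effects = file.path(dir, "truth_effects.tsv"))
  write_pool_counts(pc, paths$counts)
  seqs <- Biostrings::DNAStringSet(vapply(genome, paste, "", collapse = ""))
  names(seqs) <- names(chroms)
  Biostrings::writeXStringSet(seqs, paths$fasta)
  write_sim_gff(genes$table, paths$gff)
  data.table::fwrite(truth_islands, paths$truth_islands, sep = "\t")
  data.table::fwrite(truth_sites, paths$truth_sites, sep = "\t")
  data.table::fwrite(effects, paths$truth_effects, sep = "\t")

  structure(list(config = config, dir = dir, paths = paths, pools = pool_tbl,
                 counts = pc,
                 truth = list(islands = truth_islands, sites = truth_sites,
                              effects = effects, trajectories = trajectories,
                              genes = genes$table)),
            class = "metapop_sim")
}

#' @export
print.metapop_sim <- function(x, ...) {
  cat(sprintf("metapop_sim: %d sites x %d pools, %d islands, %d genes (seed %d)\n  dir: %s\n",
              nrow(x$counts$sites), nrow(x$pools), nrow(x$truth$islands),
              length(unique(x$truth$genes$gene_id)), x$config$seed, x$dir))
  invisible(x)
}

# --- internal simulator pieces -------------------------------------------

place_islands <- function(config) {
  empty <- data.frame(id = character(), chrom = character(), start = integer(),
                      end = integer(), length = integer(), stringsAsFactors = FALSE)
  if (config$n_islands == 0L) return(empty)
  chroms <- config$chromosomes
  margin <- 1000L
  for (attempt in 1:200) {
    lens <- as.integer(round(runif(config$n_islands, config$island_length_range[1L],
                                   config$island_length_range[2L])))
    assign_chr <- sample(names(chroms), config$n_islands, replace = TRUE)
    ok <- TRUE
    rows <- list()
    for (cn in unique(assign_chr)) {
      li <- lens[assign_chr == cn]
      k <- length(li)
      slack <- chroms[[cn]] - sum(li) - (k - 1L) * config$min_island_gap - 2L * margin
      if (slack < 0L) { ok <- FALSE; break }
      extra <- if (k > 1L) diff(c(0, sort(runif(k - 1L, 0, slack)), slack)) else slack
      start <- margin + as.integer(floor(extra[1L]))
      for (i in seq_len(k)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cn, start = start, end = start + li[i] - 1L,
          stringsAsFactors = FALSE)
        if (i < k)
          start <- start + li[i] + config$min_island_gap +
            as.integer(floor(extra[i + 1L]))
      }
    }
    if (ok) {
      out <- do.call(rbind, rows)
      out <- out[order(match(out$chrom, names(chroms)), out$start), , drop = FALSE]
      ordinal <- stats::ave(out$start, out$chrom, FUN = seq_along)
      out$id <- paste0(sub("^chr", "", out$chrom), "-", ordinal)
      out$length <- out$end - out$start + 1L
      rownames(out) <- NULL
      return(out[c("id", "chrom", "start", "end", "length")])
    }
  }
  stop("could not place ", config$n_islands, " islands on the configured ",
       "chromosomes; increase lengths or reduce islands")
}

# standard genetic code, written out for the simulator's own truth arithmetic
SIM_CODE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
SENSE_CODONS <- names(SIM_CODE)[SIM_CODE != "*"]

plant_genes <- function(config, islands, genome) {
  table <- data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(), phase = integer(),
                      exon = integer(), stringsAsFactors = FALSE)
  spots <- list()
  n_isl <- nrow(islands)
  if (n_isl) {
    eligible <- which(islands$length >= 4000L)
    n_gene <- min(length(eligible), floor(config$gene_fraction * n_isl))
    for (i in if (n_gene) sort(sample(eligible, n_gene)) else integer())
      spots[[length(spots) + 1L]] <- list(chrom = islands$chrom[i],
                                          lo = islands$start[i],
                                          hi = islands$end[i])
  }
  # background genes go at fixed offsets in island-free space
  if (config$n_background_genes > 0L) {
    free <- free_intervals(config$chromosomes, islands, min_len = 5000L)
    for (k in seq_len(min(config$n_background_genes, nrow(free))))
      spots[[length(spots) + 1L]] <- list(chrom = free$chrom[k],
                                          lo = free$start[k], hi = free$end[k])
  }
  gid <- 0L
  for (sp in spots) {
    gid <- gid + 1L
    span <- sp$hi - sp$lo + 1L
    n_codon <- sample(100:300, 1L)
    cds_len <- 3L * n_codon
    two_exon <- runif(1) < 0.5 && span > cds_len + 1000L
    intron <- if (two_exon) sample(100:300, 1L) else 0L
    total <- cds_len + intron
    if (span < total + 200L) { two_exon <- FALSE; intron <- 0L; total <- cds_len }
    if (span < total + 200L) next
    start <- sp$lo + sample.int(span - total - 199L, 1L) + 99L
    strand <- sample(c("+", "-"), 1L)
    coding <- c("ATG", sample(SENSE_CODONS, n_codon - 2L, replace = TRUE), "TAA")
    coding <- strsplit(paste(coding, collapse = ""), "")[[1L]]
    gene_id <- sprintf("gene%02d", gid)
    if (two_exon) {
      len1 <- 3L * sample.int(n_codon - 2L, 1L) + sample(0:2, 1L)
      len1 <- min(max(len1, 1L), cds_len - 1L)
      ex <- data.frame(start = c(start, start + len1 + intron),
                       end = c(start + len1 - 1L, start + total - 1L))
    } else {
      ex <- data.frame(start = start, end = start + cds_len - 1L)
    }
    # write coding bases into the genome, reverse-complemented on minus strand
    g <- genome[[sp$chrom]]
    if (strand == "+") {
      offset <- 0L
      for (r in seq_len(nrow(ex))) {
        w <- ex$end[r] - ex$start[r] + 1L
        g[ex$start[r]:ex$end[r]] <- coding[offset + seq_len(w)]
        offset <- offset + w
      }
    } else {
      rc <- rev(unname(COMPLEMENT[coding]))
      offset <- 0L
      for (r in nrow(ex):1) {  # genomic order from the 3' end of the gene
        w <- ex$end[r] - ex$start[r] + 1L
        g[ex$start[r]:ex$end[r]] <- rc[seq(length(rc) - offset - w + 1L,
                                           length(rc) - offset)]
        offset <- offset + w
      }
    }
    genome[[sp$chrom]] <- g
    ex_tx <- if (strand == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
    phase <- 0L
    for (k in seq_along(ex_tx)) {
      r <- ex_tx[k]
      table <- rbind(table, data.frame(
        gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
        chrom = sp$chrom, strand = strand, start = ex$start[r], end = ex$end[r],
        phase = phase, exon = k, stringsAsFactors = FALSE))
      phase <- (3L - ((ex$end[r] - ex$start[r] + 1L - phase) %% 3L)) %% 3L
    }
  }
  list(table = table, genome = genome)
}

free_intervals <- function(chroms, islands, min_len) {
  rows <- list()
  for (cn in names(chroms)) {
    isl <- islands[islands$chrom == cn, , drop = FALSE]
    bounds <- c(1L, rbind(isl$start - 1L, isl$end + 1L), chroms[[cn]])
    starts <- bounds[seq(1L, length(bounds), 2L)]
    ends <- bounds[seq(2L, length(bounds), 2L)]
    keep <- ends - starts + 1L >= min_len
    if (any(keep))
      rows[[length(rows) + 1L]] <- data.frame(chrom = cn, start = starts[keep],
                                              end = ends[keep],
                                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(chrom = character(), start = integer(),
                                       end = integer()))
  do.call(rbind, rows)
}

draw_sites <- function(config, islands, genome) {
  chroms <- config$chromosomes
  rows <- list()
  # island marker sites: the two haplotypes differ here
  for (i in seq_len(nrow(islands))) {
    n <- rbinom(1L, islands$length[i], config$marker_density)
    if (n == 0L) next
    pos <- islands$start[i] + sort(sample.int(islands$length[i], n)) - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = islands$chrom[i], pos = pos, type = "island",
      island_index = i, stringsAsFactors = FALSE)
  }
  for (cn in names(chroms)) {
    nb <- rbinom(1L, chroms[[cn]], config$background_snp_rate)
    if (nb) rows[[length(rows) + 1L]] <- data.frame(
      chrom = cn, pos = sort(sample.int(chroms[[cn]], nb)), type = "background",
      island_index = 0L, stringsAsFactors = FALSE)
    nm <- rbinom(1L, chroms[[cn]], config$monomorphic_rate)
    if (nm) rows[[length(rows) + 1L]] <- data.frame(
      chrom = cn, pos = sort(sample.int(chroms[[cn]], nm)), type = "monomorphic",
      island_index = 0L, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(), pos = integer(), type = character(),
                      island_index = integer(), ref_idx = integer(),
                      alt_idx = integer(), p_marine = numeric()))
  sites <- do.call(rbind, rows)
  sites <- sites[order(match(sites$chrom, names(chroms)), sites$pos,
                       match(sites$type, c("island", "background", "monomorphic"))), ]
  sites <- sites[!duplicated(sites[c("chrom", "pos")]), ]
  rownames(sites) <- NULL
  n <- nrow(sites)
  sites$ref_idx <- vapply(seq_len(n), function(k)
    match(genome[[sites$chrom[k]]][sites$pos[k]], BASES), 0L)
  # alternate allele: a uniformly chosen different base (monomorphic sites get
  # a placeholder that never receives true reads, only errors)
  sites$alt_idx <- OTHER_BASES[cbind(sites$ref_idx, sample.int(3L, n, replace = TRUE))]
  sites$p_marine <- 0
  sites$p_marine[sites$type == "island"] <- config$marine_standing_freq
  nbg <- sum(sites$type == "background")
  sites$p_marine[sites$type == "background"] <-
    rbeta(nbg, config$background_beta[1L], config$background_beta[2L])
  sites
}

# pooled sequencing of one pool: Poisson depth, binomial allele sampling at
# the pool-sample frequency, uniform base errors; returns an n x 4 count matrix
sequence_pool <- function(ref_idx, alt_idx, f, depth_mean, error_rate) {
  n <- length(ref_idx)
  depth <- rpois(n, depth_mean)
  alt_true <- rbinom(n, depth, f)
  ref_true <- depth - alt_true
  alt_kept <- rbinom(n, alt_true, 1 - error_rate)
  ref_kept <- rbinom(n, ref_true, 1 - error_rate)
  M <- matrix(0L, n, 4L)
  idx <- seq_len(n)
  M[cbind(idx, ref_idx)] <- M[cbind(idx, ref_idx)] + ref_kept
  M[cbind(idx, alt_idx)] <- M[cbind(idx, alt_idx)] + alt_kept
  spread_errors <- function(M, err, from_idx) {
    x1 <- rbinom(n, err, 1 / 3)
    rem <- err - x1
    x2 <- rbinom(n, rem, 1 / 2)
    x3 <- rem - x2
    tgt <- OTHER_BASES[from_idx, , drop = FALSE]
    for (k in 1:3) {
      v <- list(x1, x2, x3)[[k]]
      ij <- cbind(idx, tgt[, k])
      M[ij] <- M[ij] + v
    }
    M
  }
  M <- spread_errors(M, ref_true - ref_kept, ref_idx)
  M <- spread_errors(M, alt_true - alt_kept, alt_idx)
  M
}

write_sim_gff <- function(gene_table, path) {
  lines <- "##gff-version 3"
  for (g in unique(gene_table$gene_id)) {
    seg <- gene_table[gene_table$gene_id == g, , drop = FALSE]
    lo <- min(seg$start); hi <- max(seg$end)
    tx <- seg$transcript_id[1L]
    lines <- c(lines,
      sprintf("%s\tpoolsel_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              seg$chrom[1L], lo, hi, seg$strand[1L], g),
      sprintf("%s\tpoolsel_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              seg$chrom[1L], lo, hi, seg$strand[1L], tx, g),
      sprintf("%s\tpoolsel_sim\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s;gene_id=%s",
              seg$chrom, seg$start, seg$end, seg$strand, seg$phase, tx, seg$exon,
              tx, g))
  }
  writeLines(lines, path)
  invisible(path)
}

# the simulator's own synonymous/nonsynonymous truth: rebuilds each planted
# gene's coding sequence directly from its exon layout and substitutes alleles
sim_effect_truth <- function(gene_table, genome, truth_sites) {
  out <- data.frame(chrom = character(), pos = integer(), gene_id = character(),
                    effect = character(), stringsAsFactors = FALSE)
  snp <- truth_sites[!is.na(truth_sites$alt), , drop = FALSE]
  for (tx in unique(gene_table$transcript_id)) {
    seg <- gene_table[gene_table$transcript_id == tx, , drop = FALSE]
    seg <- seg[order(seg$exon), ]
    strand <- seg$strand[1L]
    gpos <- unlist(lapply(seq_len(nrow(seg)), function(r)
      if (strand == "+") seg$start[r]:seg$end[r] else seg$end[r]:seg$start[r]))
    bases <- genome[[seg$chrom[1L]]][gpos]
    if (strand == "-") bases <- unname(COMPLEMENT[bases])
    hits <- snp[snp$chrom == seg$chrom[1L] & snp$pos >= min(seg$start) &
                  snp$pos <= max(seg$end), , drop = FALSE]
    for (r in seq_len(nrow(hits))) {
      k <- match(hits$pos[r], gpos)
      if (is.na(k)) next  # intronic
      ci <- (k - 1L) %/% 3L
      codon <- bases[ci * 3L + 1:3]
      alt_coding <- if (strand == "+") hits$alt[r] else COMPLEMENT[[hits$alt[r]]]
      codon2 <- codon
      codon2[k - ci * 3L] <- alt_coding
      eff <- if (SIM_CODE[[paste(codon, collapse = "")]] ==
                 SIM_CODE[[paste(codon2, collapse = "")]]) "synonymous"
             else "nonsynonymous"
      out <- rbind(out, data.frame(chrom = hits$chrom[r], pos = hits$pos[r],
                                   gene_id = seg$gene_id[1L], effect = eff,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Compare pipeline outputs with simulator ground truth
#'
#' @param sim a `metapop_sim` object.
#' @param dis detected islands (a `di_set` or [detect_islands()] output);
#'   matching uses at least 50 percent reciprocal overlap.
#' @param sf optional `site_freqs` to score frequency recovery: RMSE between
#'   the estimated frequency of the true alternate allele and the true
#'   pool-sample frequency, over usable pool-sites.
#' @param selection optional `selection_scan` (with `di` ids from `dis`) to
#'   tabulate estimation bias against true selection coefficients.
#' @return list with `n_truth`, `n_detected`, `recall`, `precision`,
#'   `matches` (truth id, detected interval), and optionally `freq_rmse` and
#'   `s_bias` (per island x population: `s_hat`, `s_true`, `bias`).
#' @export
truth_report <- function(sim, dis, sf = NULL, selection = NULL) {
  stopifnot(inherits(sim, "metapop_sim"))
  truth <- sim$truth$islands
  nT <- nrow(truth); nD <- nrow(dis)
  matches <- data.frame(truth_id = character(), det_id = character(),
                        overlap = integer(), stringsAsFactors = FALSE)
  det_matched <- logical(nD)
  for (i in seq_len(nT)) {
    if (nD == 0L) break
    ov <- ifelse(dis$chrom == truth$chrom[i],
                 pmax(0L, pmin(dis$end, truth$end[i]) -
                        pmax(dis$start, truth$start[i]) + 1L), 0L)
    j <- which.max(ov)
    lenD <- dis$end[j] - dis$start[j] + 1L
    if (ov[j] >= 0.5 * truth$length[i] && ov[j] >= 0.5 * lenD) {
      det_matched[j] <- TRUE
      matches <- rbind(matches, data.frame(
        truth_id = truth$id[i],
        det_id = if (!is.null(dis$id)) dis$id[j] else as.character(j),
        overlap = ov[j], stringsAsFactors = FALSE))
    }
  }
  out <- list(n_truth = nT, n_detected = nD,
              recall = if (nT) nrow(matches) / nT else NA_real_,
              precision = if (nD) sum(det_matched) / nD else NA_real_,
              matches = matches)
  if (!is.null(sf)) {
    ts <- sim$truth$sites
    key <- paste(sf$sites$chrom, sf$sites$pos)
    idx <- match(paste(ts$chrom, ts$pos), key)
    keep <- which(!is.na(idx) & !is.na(ts$alt))
    errs <- c()
    for (j in seq_len(nrow(sf$pools))) {
      pool <- sf$pools$name[j]
      f <- sf$freq[idx[keep], j]
      est_alt <- ifelse(ts$alt[keep] == sf$sites$major[idx[keep]], f,
                 ifelse(ts$alt[keep] == sf$sites$minor[idx[keep]] |
                          is.na(sf$sites$minor[idx[keep]]), 1 - f, NA_real_))
      tru <- ts[[paste0("samp_", pool)]][keep]
      ok <- !is.na(est_alt)
      errs <- c(errs, (est_alt - tru)[ok])
    }
    out$freq_rmse <- sqrt(mean(errs^2))
  }
  if (!is.null(selection)) {
    m <- matches
    sel <- merge(selection, m, by.x = "di", by.y = "det_id")
    sel <- merge(sel, truth[c("id", "s")], by.x = "truth_id", by.y = "id")
    out$s_bias <- data.frame(di = sel$truth_id, population = sel$population,
                             s_hat = sel$s_hat, s_true = sel$s,
                             bias = sel$s_hat - sel$s, flag = sel$flag,
                             stringsAsFactors = FALSE)
  }
  out
}
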