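# small in-code fixtures shared across test files

two_pools <- function(min_depth = c(10L, 5L)) {
  pool_table(c("sea", "lake"), c("marine", "freshwater"),
             n_individuals = c(10L, 10L), min_depth = min_depth)
}

four_pools <- function() {
  pool_table(c("sea1", "sea2", "lake1", "lake2"),
             c("marine", "marine", "freshwater", "freshwater"),
             n_individuals = 10L, min_depth = 5L)
}

# build a pool_counts object directly from a matrix of per-pool count strings
make_counts <- function(chrom, pos, ref, count_strings, pools) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  rows <- vapply(seq_along(pos), function(i)
    paste(c(chrom[i], pos[i], ref[i], count_strings[i, ]), collapse = "\t"), "")
  writeLines(rows, tmp)
  read_pool_counts(tmp, pools)
}

# site_freqs with prescribed major-allele frequencies, everything usable
make_site_freqs <- function(freq, pools, chrom = "chrI",
                            pos = seq_len(nrow(freq)),
                            major = "A", minor = "T", depth = 50L) {
  n <- nrow(freq)
  structure(list(
    sites = data.frame(chrom = rep_len(chrom, n), pos = pos,
                       major = rep_len(major, n), minor = rep_len(minor, n),
                       stringsAsFactors = FALSE),
    freq = `dimnames<-`(freq, list(NULL, pools$name)),
    depth = matrix(depth, n, nrow(pools), dimnames = list(NULL, pools$name)),
    usable = matrix(TRUE, n, nrow(pools), dimnames = list(NULL, pools$name)),
    pools = pools,
    rejected = data.frame(reason = character(), n = integer())),
    class = "site_freqs")
}

# marker_calls table with given statuses at given positions
make_markers <- function(pos, status, chrom = "chrI") {
  out <- data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
                    status = rep_len(status, length(pos)),
                    marine_allele = "A", freshwater_allele = "T",
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_calls", "data.frame")
  out
}

# one-gene GFF3 + FASTA pair written to temp files; seq is the full contig
write_gene_fixture <- function(seq, cds, strand = "+", chrom = "ctg1",
                               gene = "g1") {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", chrom), seq), fa)
  gff <- tempfile(fileext = ".gff3")
  phase <- 0L
  lines <- "##gff-version 3"
  ord <- if (strand == "-") rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
  for (k in ord) {
    lines <- c(lines, sprintf(
      "%s\ttest\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.t1.cds;Parent=%s.t1;gene_id=%s",
      chrom, cds$start[k], cds$end[k], strand, phase, gene, gene, gene))
    phase <- (3L - ((cds$end[k] - cds$start[k] + 1L - phase) %% 3L)) %% 3L
  }
  writeLines(lines, gff)
  list(fasta = fa, gff = gff)
}

# fast sim config used by several tests (dots override the small defaults)
small_sim_config <- function(seed = 11, ...) {
  args <- list(seed = seed,
               chromosomes = stats::setNames(rep(250000L, 3L),
                                             c("chrI", "chrII", "chrIII")),
               n_islands = 3L, island_length_range = c(15000L, 50000L),
               background_snp_rate = 0.001, monomorphic_rate = 0.002)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
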