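#' Classify SNPs as synonymous or nonsynonymous
#'
#' Maps each biallelic site into CDS coordinates of every transcript covering
#' it (respecting strand and the phase of the first coding segment), rebuilds
#' the affected codon from the reference genome, substitutes the alternate
#' allele, and translates both codons with the standard genetic code. A site
#' covered by several transcripts is called nonsynonymous if it is
#' nonsynonymous in any of them; the per-transcript calls are retained in the
#' `"per_transcript"` attribute. Sites outside all CDS are `noncoding`.
#'
#' One of the two alleles at each site must equal the reference-genome base;
#' that allele is taken as "before" and the other as "after". A mismatch
#' between both alleles and the genome is a data-integrity error.
#'
#' @param chrom,pos site coordinates (vectors, 1-based).
#' @param allele_a,allele_b the two alleles at each site (single nucleotides).
#' @param models a `gene_models` object from [read_gene_models()].
#' @return data.frame `chrom`, `pos`, `gene_id`, `effect` (`synonymous`,
#'   `nonsynonymous`, `noncoding`), `codon_before`, `codon_after`,
#'   `aa_before`, `aa_after`; coding fields are `NA` for noncoding sites.
#' @export
annotate_effects <- function(chrom, pos, allele_a, allele_b, models) {
  stopifnot(inherits(models, "gene_models"))
  n <- length(pos)
  stopifnot(length(chrom) == n, length(allele_a) == n, length(allele_b) == n)
  cds <- models$cds
  tx_ids <- unique(cds$transcript_id)
  tx_cache <- new.env(parent = emptyenv())
  code <- Biostrings::GENETIC_CODE

  per_tx <- list()
  out <- data.frame(chrom = chrom, pos = pos, gene_id = NA_character_,
                    effect = "noncoding", codon_before = NA_character_,
                    codon_after = NA_character_, aa_before = NA_character_,
                    aa_after = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    hit <- which(cds$chrom == chrom[i] & cds$start <= pos[i] & cds$end >= pos[i])
    if (!length(hit)) next
    ref_base <- substr(as.character(Biostrings::subseq(
      models$genome[[chrom[i]]], pos[i], pos[i])), 1L, 1L)
    al <- toupper(c(allele_a[i], allele_b[i]))
    if (!ref_base %in% al)
      stop(sprintf("reference base mismatch at %s:%d (genome %s, alleles %s/%s)",
                   chrom[i], pos[i], ref_base, al[1L], al[2L]))
    alt_base <- if (al[1L] == ref_base) al[2L] else al[1L]
    calls <- lapply(unique(cds$transcript_id[hit]), function(tx) {
      lay <- transcript_layout(tx, cds, models$genome, tx_cache)
      k <- match(pos[i], lay$gpos)
      if (is.na(k)) return(NULL)  # inside interval span but trimmed by phase
      ci <- (k - 1L) %/% 3L
      if ((ci + 1L) * 3L > length(lay$seq)) return(NULL)  # trailing partial codon
      idx <- ci * 3L + 1:3
      codon_before <- paste(lay$seq[idx], collapse = "")
      seq_after <- lay$seq
      seq_after[k] <- if (lay$strand == "+") alt_base else COMPLEMENT[alt_base]
      codon_after <- paste(seq_after[idx], collapse = "")
      data.frame(transcript_id = tx, gene_id = lay$gene_id,
                 codon_before = codon_before, codon_after = codon_after,
                 aa_before = code[[codon_before]], aa_after = code[[codon_after]],
                 stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, calls)
    if (is.null(calls) || nrow(calls) == 0L) next
    calls$effect <- ifelse(calls$aa_before == calls$aa_after,
                           "synonymous", "nonsynonymous")
    calls$chrom <- chrom[i]; calls$pos <- pos[i]
    per_tx[[length(per_tx) + 1L]] <- calls
    pick <- if (any(calls$effect == "nonsynonymous"))
      which(calls$effect == "nonsynonymous")[1L] else 1L
    out$gene_id[i] <- calls$gene_id[pick]
    out$effect[i] <- calls$effect[pick]
    out$codon_before[i] <- calls$codon_before[pick]
    out$codon_after[i] <- calls$codon_after[pick]
    out$aa_before[i] <- calls$aa_before[pick]
    out$aa_after[i] <- calls$aa_after[pick]
  }
  attr(out, "per_transcript") <- if (length(per_tx)) do.call(rbind, per_tx) else NULL
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# coding-strand base sequence of a transcript plus the genomic position of
# each coding base, honouring the phase of the first segment
transcript_layout <- function(tx, cds, genome, cache) {
  if (exists(tx, envir = cache, inherits = FALSE))
    return(get(tx, envir = cache, inherits = FALSE))
  seg <- cds[cds$transcript_id == tx, , drop = FALSE]  # transcription order
  strand <- seg$strand[1L]
  gpos <- unlist(lapply(seq_len(nrow(seg)), function(r)
    if (strand == "+") seg$start[r]:seg$end[r] else seg$end[r]:seg$start[r]))
  chrom_seq <- genome[[seg$chrom[1L]]]
  bases <- unlist(lapply(seq_len(nrow(seg)), function(r) {
    s <- as.character(Biostrings::subseq(chrom_seq, seg$start[r], seg$end[r]))
    v <- strsplit(s, "")[[1L]]
    if (strand == "-") rev(unname(COMPLEMENT[v])) else v
  }))
  ph <- seg$phase[1L]
  if (ph > 0L) { gpos <- gpos[-seq_len(ph)]; bases <- bases[-seq_len(ph)] }
  lay <- list(gpos = gpos, seq = bases, strand = strand, gene_id = seg$gene_id[1L])
  assign(tx, lay, envir = cache)
  lay
}

#' Nonsynonymous/synonymous contingency table and ratios
#'
#' @param inside,outside effect calls ([annotate_effects()] output restricted
#'   to coding sites) for the two strata, or length-2 numeric vectors
#'   `c(nonsynonymous, synonymous)`.
#' @return list with `table` (2x2 matrix, rows `within`/`outside`, columns
#'   `nonsynonymous`/`synonymous`), `ratios` (NS/S per stratum, rounded to 2
#'   decimals; `Inf` with an `infinite_ratio` flag when a synonymous count is
#'   zero) and `ratios_raw`.
#' @export
ns_s_table <- function(inside, outside) {
  cnt <- function(x) {
    if (is.numeric(x)) { stopifnot(length(x) == 2L); return(as.integer(x)) }
    c(sum(x$effect == "nonsynonymous"), sum(x$effect == "synonymous"))
  }
  tab <- rbind(within = cnt(inside), outside = cnt(outside))
  colnames(tab) <- c("nonsynonymous", "synonymous")
  raw <- tab[, 1L] / tab[, 2L]
  list(table = tab, ratios = round(raw, 2L), ratios_raw = raw,
       infinite_ratio = !is.finite(raw))
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Two-sided P by point-probability summation: the sum over all tables with
#' the observed margins whose hypergeometric probability does not exceed that
#' of the observed table. A table with a zero margin is degenerate and
#' returns P = 1 by convention.
#'
#' @param table a 2x2 matrix of non-negative counts.
#' @return the two-tailed P value.
#' @export
fisher_exact_two_tailed <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}
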