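#' Read a pooled nucleotide count table
#'
#' Reads the tab-separated count dialect used throughout the package: one row
#' per genomic site with columns `chrom`, `pos` (1-based), `ref`, then one
#' field per pool of colon-separated nucleotide read counts in `A:C:G:T`
#' order. Six-field variants (`A:C:G:T:N:del`) are accepted and the N and
#' deletion counts discarded, since only SNPs are analysed. A pool field of
#' `"."` marks a site that failed the per-pool base-quality screen upstream:
#' its counts are recorded as zero and `quality_ok` as `FALSE`.
#'
#' @param path path to the tab-separated count file (no header).
#' @param pools a [pool_table()]; its row order must match the per-pool column
#'   order of the file.
#' @return An object of class `pool_counts`: a list with `sites` (data.frame
#'   `chrom`, `pos`, `ref`), `counts` (integer array site x pool x base),
#'   `quality_ok` (logical matrix site x pool) and `pools`.
#' @export
read_pool_counts <- function(path, pools) {
  stopifnot(inherits(pools, "pool_table"))
  npool <- nrow(pools)
  if (!file.exists(path)) stop("count file not found: ", path)
  if (file.size(path) == 0L) return(empty_pool_counts(pools))
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", fill = TRUE)
  if (nrow(dt) == 0L) return(empty_pool_counts(pools))
  if (ncol(dt) != 3L + npool)
    stop(sprintf("count file has %d columns; expected %d (chrom, pos, ref + %d pools)",
                 ncol(dt), 3L + npool, npool))
  chrom <- dt[[1L]]
  pos <- suppressWarnings(as.integer(dt[[2L]]))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad))
    stop("malformed position field at line(s): ", paste(head(bad, 10L), collapse = ", "))
  # (chrom, pos)-sorted: positions strictly increasing within contiguous
  # chromosome blocks, and no chromosome may appear in two separate blocks
  blocks <- rle(chrom)$values
  if (anyDuplicated(blocks)) stop("input not sorted: chromosome blocks are not contiguous")
  unsorted <- which(diff(pos) <= 0L & chrom[-length(chrom)] == chrom[-1L])
  if (length(unsorted))
    stop("input not sorted by position at line(s): ",
         paste(head(unsorted + 1L, 10L), collapse = ", "))

  n <- nrow(dt)
  counts <- array(0L, dim = c(n, npool, 4L),
                  dimnames = list(NULL, pools$name, BASES))
  quality_ok <- matrix(TRUE, n, npool, dimnames = list(NULL, pools$name))
  for (j in seq_len(npool)) {
    field <- dt[[3L + j]]
    miss <- field == "."
    quality_ok[miss, j] <- FALSE
    parts <- data.table::tstrsplit(field, ":", fixed = TRUE)
    if (!(length(parts) %in% c(1L, 4L, 6L)))
      stop(sprintf("pool '%s': count fields must have 4 (A:C:G:T) or 6 (A:C:G:T:N:del) values",
                   pools$name[j]))
    if (length(parts) == 1L && !all(miss))
      stop(sprintf("pool '%s': malformed count field at line(s): %s", pools$name[j],
                   paste(head(which(!miss), 10L), collapse = ", ")))
    if (length(parts) > 1L) {
      for (b in 1:4) {
        v <- suppressWarnings(as.integer(parts[[b]]))
        badrow <- which(!miss & (is.na(v) | v < 0L))
        if (length(badrow))
          stop(sprintf("pool '%s': malformed count field at line(s): %s", pools$name[j],
                       paste(head(badrow, 10L), collapse = ", ")))
        v[miss] <- 0L
        counts[, j, b] <- v
      }
    }
  }
  structure(
    list(sites = data.frame(chrom = chrom, pos = pos, ref = toupper(dt[[3L]]),
                            stringsAsFactors = FALSE),
         counts = counts, quality_ok = quality_ok, pools = pools),
    class = "pool_counts"
  )
}

empty_pool_counts <- function(pools) {
  structure(
    list(sites = data.frame(chrom = character(), pos = integer(), ref = character(),
                            stringsAsFactors = FALSE),
         counts = array(0L, dim = c(0L, nrow(pools), 4L),
                        dimnames = list(NULL, pools$name, BASES)),
         quality_ok = matrix(TRUE, 0L, nrow(pools), dimnames = list(NULL, pools$name)),
         pools = pools),
    class = "pool_counts"
  )
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool_counts: %d sites x %d pools (%s)\n",
              nrow(x$sites), nrow(x$pools), paste(x$pools$name, collapse = ", ")))
  invisible(x)
}

#' Write a pooled nucleotide count table
#'
#' Inverse of [read_pool_counts()]; always writes the 4-field `A:C:G:T`
#' dialect, with `"."` for pool-sites whose `quality_ok` flag is `FALSE`.
#'
#' @param pc a `pool_counts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pool_counts <- function(pc, path) {
  stopifnot(inherits(pc, "pool_counts"))
  n <- nrow(pc$sites)
  cols <- list(pc$sites$chrom, pc$sites$pos, pc$sites$ref)
  for (j in seq_len(nrow(pc$pools))) {
    f <- paste(pc$counts[, j, 1L], pc$counts[, j, 2L],
               pc$counts[, j, 3L], pc$counts[, j, 4L], sep = ":")
    if (n) f[!pc$quality_ok[, j]] <- "."
    cols[[3L + j]] <- f
  }
  data.table::fwrite(cols, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert between 1-based inclusive and BED half-open coordinates
#'
#' Internal island coordinates are 1-based and inclusive, so that
#' `length = end - start + 1`. BED uses 0-based half-open intervals.
#'
#' @param start,end 1-based inclusive coordinates.
#' @return `to_bed()` returns a two-column matrix of BED start/end;
#'   `from_bed()` the inverse.
#' @export
to_bed <- function(start, end) cbind(start = start - 1L, end = end)

#' @rdname to_bed
#' @param bed_start,bed_end 0-based half-open coordinates.
#' @export
from_bed <- function(bed_start, bed_end) cbind(start = bed_start + 1L, end = bed_end)

#' Write divergence islands as BED6
#'
#' The name field encodes the island id and its supporting criteria
#' (`id|criteria`), and the score field carries the marker count (capped at
#' 1000 in the file per BED convention; the uncapped count stays in the TSV
#' report).
#'
#' @param islands a data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `id`, `criteria`, `n_markers`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, path) {
  if (nrow(islands)) {
    o <- order(islands$chrom, islands$start)
    islands <- islands[o, , drop = FALSE]
    ov <- unlist(lapply(split(islands, islands$chrom), function(d)
      if (nrow(d) > 1L) d$start[-1L] <= d$end[-nrow(d)] else logical()))
    if (any(ov))
      stop("overlapping islands on the same chromosome; merge them upstream")
  }
  id <- if (!is.null(islands$id)) islands$id else as.character(seq_len(nrow(islands)))
  crit <- if (!is.null(islands$criteria)) islands$criteria else "na"
  score <- if (!is.null(islands$n_markers)) pmin(islands$n_markers, 1000L) else 0L
  bed <- to_bed(islands$start, islands$end)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", islands$chrom, bed[, "start"],
                   bed[, "end"], paste(id, crit, sep = "|"), as.integer(score))
  writeLines(lines[seq_len(nrow(islands))], path)
  invisible(path)
}

#' Read gene models from GFF3 plus a reference genome
#'
#' CDS features are grouped per transcript (via their `Parent` attribute, or
#' `transcript_id` when present) and ordered 5' to 3' in transcription order,
#' i.e. by descending genomic coordinate for minus-strand transcripts.
#' Transcripts whose concatenated CDS length is not divisible by 3 are kept
#' but flagged incomplete, with a warning.
#'
#' @param gff_path GFF3 file with CDS features.
#' @param fasta_path reference genome FASTA covering every chromosome the CDS
#'   refer to.
#' @return An object of class `gene_models`: list with `cds` (data.frame
#'   `gene_id`, `transcript_id`, `chrom`, `strand`, `start`, `end`, `phase`,
#'   in transcription order within transcript), `genome` (a
#'   [Biostrings::DNAStringSet]) and `incomplete` (transcript ids).
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- rtracklayer::import(gff_path)
  gff <- gff[gff$type == "CDS"]
  if (!length(gff)) stop("no CDS features in ", gff_path)
  df <- as.data.frame(gff)
  parent <- if (!is.null(df$Parent)) vapply(df$Parent, function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, "") else NULL
  tx <- if (!is.null(df$transcript_id)) as.character(df$transcript_id) else parent
  if (is.null(tx) || anyNA(tx))
    stop("CDS features must carry a Parent or transcript_id attribute")
  gene <- if (!is.null(df$gene_id)) as.character(df$gene_id) else tx
  cds <- data.frame(
    gene_id = gene, transcript_id = tx,
    chrom = as.character(df$seqnames), strand = as.character(df$strand),
    start = df$start, end = df$end,
    phase = if (!is.null(df$phase)) as.integer(df$phase) else 0L,
    stringsAsFactors = FALSE
  )
  cds$phase[is.na(cds$phase)] <- 0L
  missing_chr <- setdiff(cds$chrom, names(genome))
  if (length(missing_chr))
    stop("CDS reference contig(s) absent from FASTA: ", paste(missing_chr, collapse = ", "))
  if (!all(cds$strand %in% c("+", "-"))) stop("CDS strand must be '+' or '-'")
  # transcription order within transcripts
  asc <- order(cds$transcript_id, cds$start)
  cds <- cds[asc, , drop = FALSE]
  parts <- split(seq_len(nrow(cds)), cds$transcript_id)
  ord <- unlist(lapply(parts, function(i)
    if (cds$strand[i[1L]] == "-") rev(i) else i), use.names = FALSE)
  cds <- cds[ord, , drop = FALSE]
  rownames(cds) <- NULL
  len <- vapply(split(cds$end - cds$start + 1L, cds$transcript_id), sum, 0L)
  incomplete <- names(len)[len %% 3L != 0L]
  if (length(incomplete))
    warning("CDS length not divisible by 3; flagged incomplete: ",
            paste(incomplete, collapse = ", "))
  structure(list(cds = cds, genome = genome, incomplete = incomplete),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d CDS segments, %d transcripts, %d contigs\n",
              nrow(x$cds), length(unique(x$cds$transcript_id)), length(x$genome)))
  invisible(x)
}
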