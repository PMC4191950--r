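#' Divergence-island detection parameters
#'
#' @param window window width in bases (default 10 kb); chromosomes are tiled
#'   with consecutive non-overlapping windows anchored at position 1.
#' @param min_strong,min_weak minimum marker count per window under the
#'   strong (default 10) and weak (default 20) criteria.
#' @param merge_dist regions closer than this many bases are merged (strict
#'   `<`; default 40 kb).
#' @param merging_enabled set `FALSE` to skip the merge step.
#' @return An object of class `island_params`.
#' @export
island_params <- function(window = 10000L, min_strong = 10L, min_weak = 20L,
                          merge_dist = 40000L, merging_enabled = TRUE) {
  stopifnot(window > 0L, merge_dist >= 0L, min_strong >= 1L, min_weak >= 1L)
  structure(list(window = as.integer(window), min_strong = as.integer(min_strong),
                 min_weak = as.integer(min_weak), merge_dist = as.integer(merge_dist),
                 merging_enabled = isTRUE(merging_enabled)),
            class = "island_params")
}

marker_positions <- function(markers, criterion) {
  status <- switch(criterion, strong = "strong", weak = c("strong", "weak"),
                   stop("criterion must be 'strong' or 'weak'"))
  markers[markers$status %in% status, c("chrom", "pos")]
}

#' Count markers per genomic window
#'
#' Tiles each chromosome with consecutive non-overlapping windows
#' `[1, w], [w+1, 2w], ...` and counts markers of the given criterion per
#' window. Under `criterion = "weak"` strong markers count too, since every
#' strong marker satisfies the weak criterion.
#'
#' @param markers marker calls ([call_markers()]); need not be pre-filtered.
#' @param criterion `"strong"` or `"weak"`.
#' @param window window width in bases.
#' @return data.frame `chrom`, `window` (1-based index), `start`, `end`, `n`;
#'   only windows containing at least one marker are listed.
#' @export
windows_with_markers <- function(markers, criterion = "strong", window = 10000L) {
  mk <- marker_positions(markers, criterion)
  if (nrow(mk) == 0L)
    return(data.frame(chrom = character(), window = integer(),
                      start = integer(), end = integer(), n = integer()))
  win <- (mk$pos - 1L) %/% window + 1L
  agg <- stats::aggregate(list(n = win), by = list(chrom = mk$chrom, window = win), length)
  agg <- agg[order(agg$chrom, agg$window), , drop = FALSE]
  rownames(agg) <- NULL
  data.frame(chrom = agg$chrom, window = agg$window,
             start = (agg$window - 1L) * window + 1L,
             end = agg$window * window, n = agg$n, stringsAsFactors = FALSE)
}

#' Detect divergence islands under one criterion
#'
#' Windows holding at least `min_strong` (`min_weak`) markers are flagged;
#' maximal runs of adjacent flagged windows form seed regions; each region is
#' trimmed to the outermost markers it contains; and trimmed regions whose
#' gap (`next start - previous end - 1`) is strictly less than `merge_dist`
#' are merged. Merging is idempotent: re-running on the output's markers
#' changes nothing.
#'
#' @param markers marker calls.
#' @param criterion `"strong"` or `"weak"`.
#' @param params an [island_params()].
#' @return data.frame `chrom`, `start`, `end`, `n_markers` (markers of the
#'   criterion within the island), sorted and disjoint per chromosome.
#' @export
detect_islands <- function(markers, criterion = "strong", params = island_params()) {
  stopifnot(inherits(params, "island_params"))
  min_n <- if (criterion == "strong") params$min_strong else params$min_weak
  wins <- windows_with_markers(markers, criterion, params$window)
  wins <- wins[wins$n >= min_n, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_markers = integer(), stringsAsFactors = FALSE)
  if (nrow(wins) == 0L) return(empty)
  mk <- marker_positions(markers, criterion)
  res <- lapply(split(wins, wins$chrom), function(w) {
    pos <- sort(mk$pos[mk$chrom == w$chrom[1L]])
    runs <- cumsum(c(1L, diff(w$window) != 1L))
    regs <- do.call(rbind, lapply(split(seq_len(nrow(w)), runs), function(i) {
      inside <- pos[pos >= w$start[i[1L]] & pos <= w$end[i[length(i)]]]
      c(min(inside), max(inside))  # trim to outermost markers
    }))
    regs <- regs[order(regs[, 1L]), , drop = FALSE]
    if (params$merging_enabled && nrow(regs) > 1L) {
      merged <- regs[1L, , drop = FALSE]
      for (k in 2L:nrow(regs)) {
        gap <- regs[k, 1L] - merged[nrow(merged), 2L] - 1L
        if (gap < params$merge_dist) {
          merged[nrow(merged), 2L] <- max(merged[nrow(merged), 2L], regs[k, 2L])
        } else merged <- rbind(merged, regs[k, , drop = FALSE])
      }
      regs <- merged
    }
    data.frame(chrom = w$chrom[1L], start = regs[, 1L], end = regs[, 2L],
               n_markers = vapply(seq_len(nrow(regs)), function(k)
                 sum(pos >= regs[k, 1L] & pos <= regs[k, 2L]), 0L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Overlay strong- and weak-criterion islands into the final DI set
#'
#' Takes the union of the two island sets: intervals that overlap are merged
#' into one divergence island spanning their union, with `criteria` recording
#' which criteria supported it. Ids follow the chromosome-ordinal convention
#' (`IV-2` = second island on chromosome IV), assigned in coordinate order,
#' with any `chr` prefix stripped from the chromosome name.
#'
#' @param strong_islands,weak_islands outputs of [detect_islands()] under the
#'   two criteria (each internally disjoint).
#' @return data.frame of class `di_set`: `id`, `chrom`, `start`, `end`,
#'   `length` (`end - start + 1`), `criteria` (`"strong"`, `"weak"` or
#'   `"strong,weak"`).
#' @export
overlay_islands <- function(strong_islands, weak_islands) {
  tag <- function(d, lab) if (nrow(d)) cbind(d[c("chrom", "start", "end")], crit = lab)
    else NULL
  all <- rbind(tag(strong_islands, "strong"), tag(weak_islands, "weak"))
  empty <- data.frame(id = character(), chrom = character(), start = integer(),
                      end = integer(), length = integer(), criteria = character(),
                      stringsAsFactors = FALSE)
  if (is.null(all) || nrow(all) == 0L) { class(empty) <- c("di_set", "data.frame"); return(empty) }
  all <- all[order(all$chrom, all$start, all$end), , drop = FALSE]
  out <- do.call(rbind, lapply(split(all, all$chrom), function(d) {
    cur <- d[1L, ]; crit <- d$crit[1L]; rows <- list()
    flush <- function() data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
                                   criteria = paste(sort(unique(crit)), collapse = ","),
                                   stringsAsFactors = FALSE)
    if (nrow(d) > 1L) for (k in 2L:nrow(d)) {
      if (d$start[k] <= cur$end) {  # overlapping (or touching at same base)
        cur$end <- max(cur$end, d$end[k]); crit <- c(crit, d$crit[k])
      } else { rows[[length(rows) + 1L]] <- flush(); cur <- d[k, ]; crit <- d$crit[k] }
    }
    rows[[length(rows) + 1L]] <- flush()
    do.call(rbind, rows)
  }))
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  ordinal <- stats::ave(out$start, out$chrom, FUN = seq_along)
  out$id <- paste0(sub("^chr", "", out$chrom), "-", ordinal)
  out$length <- out$end - out$start + 1L
  out <- out[c("id", "chrom", "start", "end", "length", "criteria")]
  class(out) <- c("di_set", "data.frame")
  out
}

#' Construct a divergence-island table from coordinates
#'
#' Builds a `di_set` directly from island ids and 1-based inclusive
#' coordinates (for example a published catalogue), computing
#' `length = end - start + 1` and validating that islands on a chromosome
#' are disjoint and sorted.
#'
#' @param id island labels.
#' @param chrom chromosome names.
#' @param start,end 1-based inclusive coordinates.
#' @param criteria optional criteria labels (default `"strong"`).
#' @return A `di_set` data.frame as in [overlay_islands()].
#' @export
divergence_islands <- function(id, chrom, start, end, criteria = "strong") {
  stopifnot(all(start <= end), all(start >= 1))
  out <- data.frame(id = as.character(id), chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    length = as.integer(end - start + 1),
                    criteria = rep_len(as.character(criteria), length(id)),
                    stringsAsFactors = FALSE)
  chk <- out[order(out$chrom, out$start), ]
  ov <- unlist(lapply(split(chk, chk$chrom), function(d)
    if (nrow(d) > 1L) d$start[-1L] <= d$end[-nrow(d)] else logical()))
  if (any(ov)) stop("islands on a chromosome must be disjoint")
  class(out) <- c("di_set", "data.frame")
  out
}

#' Summarize a divergence-island set against its markers
#'
#' @param dis a `di_set`.
#' @param markers marker calls.
#' @return list with `per_di` (the DI table plus `n_strong` and `n_weak`
#'   marker counts) and `totals`: number of DIs, summed length, strong-marker
#'   totals inside/overall, and `pct_strong_in_dis`, the percentage of strong
#'   markers falling inside DIs, to one decimal.
#' @export
summarize_islands <- function(dis, markers) {
  strong <- marker_positions(markers, "strong")
  weak <- marker_positions(markers, "weak")
  count_in <- function(mk, d) sum(mk$chrom == d$chrom & mk$pos >= d$start & mk$pos <= d$end)
  per <- dis
  per$n_strong <- vapply(seq_len(nrow(dis)), function(i) count_in(strong, dis[i, ]), 0L)
  per$n_weak <- vapply(seq_len(nrow(dis)), function(i) count_in(weak, dis[i, ]), 0L)
  n_strong_total <- nrow(strong)
  n_strong_in <- sum(per$n_strong)
  list(per_di = per,
       totals = list(n_dis = nrow(dis),
                     total_length = sum(per$length),
                     n_strong_total = n_strong_total,
                     n_strong_in_dis = n_strong_in,
                     pct_strong_in_dis = marker_fraction(n_strong_in, n_strong_total)))
}

#' Percentage of markers inside islands, to one decimal
#'
#' @param n_inside,n_total marker counts.
#' @return `round(100 * n_inside / n_total, 1)`, or `NA` when `n_total` is 0.
#' @export
marker_fraction <- function(n_inside, n_total) {
  if (n_total == 0) return(NA_real_)
  round(100 * n_inside / n_total, 1)
}
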