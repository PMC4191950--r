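#' Pipeline run configuration
#'
#' A declarative description of one end-to-end run: input paths, pool
#' definitions, marker criteria, island parameters and selection settings.
#' All method constants (0.8/0.5 frequency thresholds, 10 kb windows, 10/20
#' window counts, 40 kb merging, h = 0.5, 2-year generations, 3.8 mm/yr
#' uplift, 1e-8 mutation rate) are named here and surfaced in the run
#' manifest.
#'
#' @param counts path to the pooled count table.
#' @param pools a [pool_table()] matching the count-file columns.
#' @param criteria a [marker_criteria()]; defaults to all marine pools vs the
#'   two oldest freshwater pools.
#' @param gff,fasta optional gene models and reference genome for coding
#'   effects; both or neither.
#' @param islands an [island_params()].
#' @param h,parameterization,generation_time,near_fixation selection settings
#'   (see [estimate_s()]); selection is estimated for every pool with both
#'   `age_years` and `founder_freq` set.
#' @param uplift_rate,mutation_rate chronology constants.
#' @param out_dir output directory for the report bundle.
#' @param max_third_frac triallelic rejection threshold
#'   ([estimate_frequencies()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(counts, pools, criteria = NULL, gff = NULL, fasta = NULL,
                       islands = island_params(), h = 0.5,
                       parameterization = "advantage", generation_time = 2,
                       near_fixation = 0.995, uplift_rate = 3.8,
                       mutation_rate = 1e-8, out_dir = tempfile("poolsel_run_"),
                       max_third_frac = 0.05) {
  stopifnot(inherits(pools, "pool_table"))
  if (is.null(criteria)) {
    fresh <- pools[pools$habitat == "freshwater", ]
    fresh <- fresh[order(-fresh$age_years), ]
    criteria <- marker_criteria(pools$name[pools$habitat == "marine"],
                                head(fresh$name, 2L))
  }
  if (xor(is.null(gff), is.null(fasta)))
    stop("provide both gff and fasta, or neither")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes frequencies -> markers -> islands -> diversity -> coding effects
#' -> selection, writing a report bundle (TSV/BED/JSON plus a manifest with a
#' config checksum and per-stage row counts) to the configured output
#' directory. A stage failure aborts the run with the failing stage named and
#' leaves a `FAILED` marker next to any partial outputs. Given identical
#' inputs and configuration the bundle is byte-identical across runs.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the in-memory stage results and the bundle
#'   paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  counts_per_stage <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  pc <- stage("read_counts", read_pool_counts(config$counts, config$pools))
  counts_per_stage$sites_read <- nrow(pc$sites)
  say("read %d sites x %d pools", nrow(pc$sites), nrow(config$pools))

  sf <- stage("frequencies", estimate_frequencies(pc, config$max_third_frac))
  counts_per_stage$sites_kept <- nrow(sf$sites)
  say("frequencies: %d sites kept", nrow(sf$sites))

  markers <- stage("markers", call_markers(sf, config$criteria))
  counts_per_stage$markers_strong <- sum(markers$status == "strong")
  counts_per_stage$markers_weak_total <-
    sum(markers$status %in% c("strong", "weak"))
  say("markers: %d strong, %d weak-criterion",
      counts_per_stage$markers_strong, counts_per_stage$markers_weak_total)
  data.table::fwrite(markers, file.path(config$out_dir, "markers.tsv"), sep = "\t")

  dis <- stage("islands", {
    strong <- detect_islands(markers, "strong", config$islands)
    weak <- detect_islands(markers, "weak", config$islands)
    overlay_islands(strong, weak)
  })
  isl_summary <- stage("islands", summarize_islands(dis, markers))
  counts_per_stage$islands <- nrow(dis)
  say("islands: %d DIs, %s nt total", nrow(dis),
      format(isl_summary$totals$total_length, big.mark = ","))
  data.table::fwrite(isl_summary$per_di, file.path(config$out_dir, "islands.tsv"),
                     sep = "\t")
  write_islands_bed(dis, file.path(config$out_dir, "islands.bed"))

  div <- stage("diversity", diversity_by_region(sf, dis))
  data.table::fwrite(div, file.path(config$out_dir, "diversity.tsv"), sep = "\t")

  contingency <- NULL
  if (!is.null(config$gff)) {
    eff <- stage("coding", {
      models <- read_gene_models(config$gff, config$fasta)
      mk <- markers[markers$status != "none", , drop = FALSE]
      key <- paste(sf$sites$chrom, sf$sites$pos)
      idx <- match(paste(mk$chrom, mk$pos), key)
      annotate_effects(mk$chrom, mk$pos, sf$sites$major[idx], sf$sites$minor[idx],
                       models)
    })
    eff$in_di <- sites_in_regions(eff, dis)
    counts_per_stage$coding_sites <- sum(eff$effect != "noncoding")
    data.table::fwrite(eff, file.path(config$out_dir, "effects.tsv"), sep = "\t")
    coding <- eff[eff$effect != "noncoding", ]
    tab <- ns_s_table(coding[coding$in_di, ], coding[!coding$in_di, ])
    contingency <- list(table = tab$table, ratios = as.list(tab$ratios),
                        fisher_two_tailed_p = fisher_exact_two_tailed(tab$table))
    say("coding: %d coding marker SNPs, Fisher P = %.4g",
        counts_per_stage$coding_sites, contingency$fisher_two_tailed_p)
    jsonlite::write_json(contingency, file.path(config$out_dir, "contingency.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  sel <- NULL; sel_summary <- NULL
  aged <- config$pools$name[!is.na(config$pools$age_years) &
                              !is.na(config$pools$founder_freq)]
  if (nrow(dis) > 0L && length(aged)) {
    sel <- stage("selection", {
      fwf <- freshwater_frequencies(sf, markers)
      estimate_selection(fwf, dis, config$pools, aged, config$h,
                         config$parameterization, config$generation_time,
                         config$near_fixation)
    })
    sel_summary <- summarize_selection(sel)
    counts_per_stage$selection_estimates <- nrow(sel)
    data.table::fwrite(sel, file.path(config$out_dir, "selection.tsv"), sep = "\t")
    say("selection: %d estimates, mean s: %s", nrow(sel),
        paste(sprintf("%s=%.3f", names(sel_summary$mean_s), sel_summary$mean_s),
              collapse = ", "))
  }

  summary <- list(
    islands = isl_summary$totals,
    diversity = div,
    contingency = contingency,
    selection = if (!is.null(sel_summary)) list(
      mean_s = as.list(sel_summary$mean_s),
      correlations = sel_summary$correlations) else NULL,
    chronology = list(uplift_rate_mm_per_year = config$uplift_rate,
                      generation_time_years = config$generation_time,
                      mutation_rate = config$mutation_rate)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "poolsel",
    version = as.character(utils::packageVersion("poolsel")),
    config_checksum = config_checksum(config),
    parameters = list(
      marine_thresh = config$criteria$marine_thresh,
      strong_thresh = config$criteria$strong_thresh,
      weak_thresh = config$criteria$weak_thresh,
      window = config$islands$window, min_strong = config$islands$min_strong,
      min_weak = config$islands$min_weak, merge_dist = config$islands$merge_dist,
      merging_enabled = config$islands$merging_enabled,
      h = config$h, parameterization = config$parameterization,
      generation_time = config$generation_time,
      uplift_rate = config$uplift_rate, mutation_rate = config$mutation_rate),
    stage_counts = counts_per_stage)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(site_freqs = sf, markers = markers, islands = dis,
                 island_summary = isl_summary, diversity = div,
                 contingency = contingency, selection = sel,
                 selection_summary = sel_summary, out_dir = config$out_dir))
}

# deterministic checksum of the serialized configuration (manifest provenance);
# the output location is not part of the analysis identity
config_checksum <- function(config) {
  config$out_dir <- NULL
  raw <- serialize(config, NULL, version = 2L)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251L)) %% .Machine$integer.max)
}
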