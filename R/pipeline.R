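# End-to-end pipeline: simulate (or load) -> windows -> log2 -> BAF ->
# segmentation -> event classification -> SNV clonality -> progression.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated list. All
#' randomness flows from the single `seed`; two runs with equal configs
#' produce identical results.
#'
#' @param scenario `"demo"`, `"metastasis"`, or a scenario list
#'   (`tree`, `cn_events`, optionally `snvs`, `genome`, `stages`).
#' @param depth mean normal reads per window.
#' @param window_bp window size in bp.
#' @param n_sites number of germline-het SNP sites to simulate.
#' @param snp_depth mean depth per SNP site.
#' @param snv_depth mean depth per somatic variant (deep resequencing).
#' @param min_probes minimum windows per segment call.
#' @param thresholds a [cn_thresholds()] list.
#' @param bp_tol_windows event-matching tolerance in window widths.
#' @param subclonal_band,clonal_band purification-detection BAF bands.
#' @param min_site_depth BAF site depth filter.
#' @param seed integer seed.
#' @param outdir optional directory for per-stage TSV/JSON artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = "demo", depth = 1000, window_bp = 1e5,
                            n_sites = 4000, snp_depth = 120, snv_depth = 377,
                            min_probes = 10L, thresholds = cn_thresholds(),
                            bp_tol_windows = 2, subclonal_band = c(0.05, 0.25),
                            clonal_band = c(0.35, 0.55), min_site_depth = 30L,
                            seed = 1L, outdir = NULL) {
  stopifnot(depth > 0, window_bp >= 1, n_sites > 0, min_probes >= 1,
            inherits(thresholds, "cn_thresholds") || is.list(thresholds),
            length(subclonal_band) == 2, length(clonal_band) == 2)
  structure(list(scenario = scenario, depth = depth, window_bp = window_bp,
                 n_sites = n_sites, snp_depth = snp_depth,
                 snv_depth = snv_depth, min_probes = as.integer(min_probes),
                 thresholds = thresholds, bp_tol_windows = bp_tol_windows,
                 subclonal_band = subclonal_band, clonal_band = clonal_band,
                 min_site_depth = as.integer(min_site_depth),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a
#' `thresholds:` block maps onto [cn_thresholds()]. The config round-trips
#' losslessly through [write_pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- if (!is.null(y$thresholds)) do.call(cn_thresholds, y$thresholds)
  else cn_thresholds()
  y$thresholds <- NULL
  for (band in c("subclonal_band", "clonal_band")) {
    if (!is.null(y[[band]])) y[[band]] <- as.numeric(unlist(y[[band]]))
  }
  do.call(pipeline_config, c(y, list(thresholds = th)))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$thresholds <- unclass(out$thresholds)
  out$outdir <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

resolve_scenario <- function(scenario) {
  if (is.character(scenario)) {
    scenario <- switch(scenario,
                       demo = demo_scenario(),
                       metastasis = metastasis_scenario(),
                       stop("unknown scenario: ", scenario))
  }
  stopifnot(is.list(scenario), inherits(scenario$tree, "clone_tree"))
  if (is.null(scenario$genome)) scenario$genome <- mini_genome()
  if (is.null(scenario$stages)) scenario$stages <- scenario$tree$samples
  scenario
}

#' Run the full copy-number progression pipeline on a scenario
#'
#' Simulates paired counts, SNP allele counts and somatic variants from the
#' scenario's clone tree, then per sample: median-centered log2 track,
#' BAF-guided baseline correction, changepoint segmentation, BAF annotation,
#' event classification (gain territory of earlier stages feeds the OCL
#' rule), two-level loss clustering and the subclonal-HL rescue. Finally the
#' per-sample event sets are integrated into a [classify_progression()]
#' report and, when variants are available, mutation clonality is tracked
#' (presence patterns and purification between the last two stages).
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `report`, `event_sets`, `tracks`,
#'   `segments`, `somatic` (list with `calls`, `patterns`, `purified`),
#'   `scenario`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  scn <- resolve_scenario(config$scenario)
  tree <- scn$tree
  stages <- scn$stages
  sim <- simulate_counts(tree, scn$cn_events, depth = config$depth,
                         window_bp = config$window_bp, genome = scn$genome,
                         seed = config$seed)
  snp <- simulate_snp_counts(tree, scn$cn_events, n_sites = config$n_sites,
                             depth = config$snp_depth, genome = scn$genome,
                             seed = config$seed + 1L)
  tracks <- list(); segments <- list(); sets <- list()
  amplified <- NULL
  for (s in stages) {
    track <- compute_log2(sim$counts[[s]])
    sites <- select_informative_sites(snp[[s]],
                                      min_depth = config$min_site_depth)
    track <- tryCatch(
      recenter_baseline(track, sites, min_probes = config$min_probes),
      warning = function(w) track)
    segs <- segment_track(track, min_probes = config$min_probes)
    segs <- annotate_segments_baf(segs, sites)
    ev <- classify_segments(segs, purity = tree$purity[[s]],
                            thresholds = config$thresholds,
                            amplified_regions = amplified)
    ev <- detect_loss_levels(ev, config$thresholds$min_separation)
    ev <- resolve_homozygous_subclonal(ev, config$thresholds)
    gains <- ev[ev$type %in% GAIN_TYPES, c("chrom", "start", "end")]
    amplified <- if (is.null(amplified)) gains else rbind(amplified, gains)
    tracks[[s]] <- track
    segments[[s]] <- segs
    sets[[s]] <- sample_event_set(ev, s)
  }
  report <- classify_progression(sets,
                                 bp_tol = config$bp_tol_windows *
                                   config$window_bp)
  somatic <- NULL
  if (!is.null(scn$snvs) && nrow(scn$snvs)) {
    raw <- simulate_snvs(tree, scn$snvs, depth = config$snv_depth,
                         seed = config$seed + 2L)
    calls <- filter_somatic(raw)
    patterns <- presence_matrix(calls)
    purified <- if (length(stages) >= 2) {
      detect_purification(calls, stages[length(stages) - 1L],
                          stages[length(stages)],
                          subclonal_band = config$subclonal_band,
                          clonal_band = config$clonal_band)
    }
    somatic <- list(calls = calls, patterns = patterns, purified = purified)
  }
  res <- structure(list(report = report, event_sets = sets, tracks = tracks,
                        segments = segments, somatic = somatic,
                        scenario = scn, config = config),
                   class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_artifacts(res, config$outdir)
  res
}

write_pipeline_artifacts <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(res$tracks)) {
    write_log2_track(res$tracks[[s]], file.path(outdir, paste0(s, "_log2.tsv")))
    write_segments(res$segments[[s]],
                   file.path(outdir, paste0(s, "_segments.tsv")))
    utils::write.table(as.data.frame(res$event_sets[[s]]),
                       file.path(outdir, paste0(s, "_events.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_progression_json(res$report, file.path(outdir, "progression.json"))
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  if (!is.null(x$somatic)) {
    cat("\nSomatic variants:", nrow(x$somatic$calls$variants), "retained;",
        x$somatic$patterns$shared_by_all, "shared by all stages;",
        nrow(x$somatic$purified), "purified in the final stage\n")
  }
  invisible(x)
}
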