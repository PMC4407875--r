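#' Resolve a pipeline run configuration
#'
#' A run is configured by a YAML file of key-value pairs mirrored by the
#' command-line flags (flags win). Recognised keys: input paths
#' (`roster`, `map`, `markers`, `marker_meta`, `coverage` or `manifest`,
#' `fingerprints`, `depths`, `zipper`, `genetic_map`), thresholds
#' (`threshold`, `sweep` list, `max_per_dim`, `endmatch_cutoff`,
#' `tolerance`, `gel_length`, `min_depth`, `qc_max_gap`, `qc_max_cm`),
#' `seed` and `out_dir`. Referenced paths must exist before any compute
#' starts; the resolved configuration is written back into the run
#' directory.
#'
#' @param config YAML path or a named list.
#' @param overrides named list merged over the file values.
#' @return list of class `run_config`.
#' @export
run_config <- function(config = list(), overrides = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(roster = NULL, map = NULL, markers = NULL,
                   marker_meta = NULL, coverage = NULL, manifest = NULL,
                   fingerprints = NULL, depths = NULL, zipper = NULL,
                   genetic_map = NULL, threshold = 0.8,
                   sweep = seq(0.8, 0.3, by = -0.1), max_per_dim = 5L,
                   endmatch_cutoff = 1e-25, tolerance = 7,
                   gel_length = 3600, min_depth = 20, qc_max_gap = 5L,
                   qc_max_cm = 1.0, mapq_min = 1L, seed = 1L,
                   out_dir = "poolanchor_run")
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null,
                                                    logical(1))])
  cfg <- utils::modifyList(cfg, overrides[!vapply(overrides, is.null,
                                                  logical(1))])
  for (key in c("roster", "map", "markers", "marker_meta", "coverage",
                "manifest", "fingerprints", "depths", "zipper",
                "genetic_map")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("configured ", key, " file not found: ", p)
    }
  }
  for (key in c("roster", "map", "markers")) {
    if (is.null(cfg[[key]])) stop("config must provide a ", key, " path")
  }
  if (is.null(cfg$coverage) && is.null(cfg$manifest)) {
    stop("config must provide either a coverage table or an alignment manifest")
  }
  cfg$sweep <- as.numeric(unlist(cfg$sweep))   # YAML lists -> vector
  cfg$threshold <- as.numeric(cfg$threshold)
  stopifnot(cfg$threshold > 0, cfg$threshold <= 1,
            all(diff(cfg$sweep) < 0))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full anchoring pipeline
#'
#' Loads the roster, physical map and markers; computes (or ingests)
#' per-pool coverage; calls positive pools at the configured threshold
#' and across the stringency sweep; deconvolutes every threshold's calls
#' to clone/contig anchors (using end-clone Sulston matches when
#' fingerprints are supplied); compares the most and least stringent
#' anchorings; and runs the zipper-adjacency and genetic-distance QC
#' when map metadata is supplied. All tables, a machine-readable
#' `summary.json` and the resolved configuration are written to the run
#' directory; identical inputs and seed reproduce identical outputs.
#'
#' @param config a [run_config()], YAML path or named list.
#' @param overrides named list of config overrides.
#' @return invisibly, a list with the run directory, per-threshold
#'   anchor tables and the summary.
#' @export
run_pipeline <- function(config, overrides = list()) {
  cfg <- if (inherits(config, "run_config")) config
         else run_config(config, overrides)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[poolanchor] ", sprintf(...))

  log_msg("loading inputs")
  scheme <- read_roster(cfg$roster)
  map <- load_clone_contig_table(cfg$map)
  markers <- read_markers(cfg$markers, meta = cfg$marker_meta)

  if (!is.null(cfg$coverage)) {
    coverage <- coverage_from_table(cfg$coverage, markers)
  } else {
    log_msg("computing coverage from alignments")
    coverage <- coverage_from_manifest(cfg$manifest, markers,
                                       mapq_min = cfg$mapq_min)
    write_coverage(coverage, file.path(cfg$out_dir, "coverage.tsv"))
  }

  flagged <- character()
  if (!is.null(cfg$depths)) {
    depths <- utils::read.delim(cfg$depths, stringsAsFactors = FALSE)
    flagged <- flag_undersequenced_pools(depths, cfg$min_depth)$pool
    if (length(flagged)) {
      log_msg("under-sequenced pool(s): %s", paste(flagged, collapse = ", "))
    }
  }

  end_matches <- NULL
  if (!is.null(cfg$fingerprints)) {
    log_msg("matching contig end clones at cutoff %g", cfg$endmatch_cutoff)
    fps <- read_fingerprints(cfg$fingerprints)
    end_matches <- end_clone_matches(map, fps, cutoff = cfg$endmatch_cutoff,
                                     tolerance = cfg$tolerance,
                                     gel_length = cfg$gel_length)
    utils::write.table(end_matches,
                       file.path(cfg$out_dir, "end_matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  thresholds <- sort(unique(c(cfg$threshold, cfg$sweep)), decreasing = TRUE)
  sweep <- stringency_sweep(coverage, thresholds, markers = markers,
                            pools = scheme_pools(scheme))
  results <- list()
  for (t in names(sweep)) {
    log_msg("anchoring at covered-region threshold %s", t)
    res <- anchor_all(sweep[[t]], scheme, map, end_matches = end_matches,
                      max_per_dim = cfg$max_per_dim,
                      flagged_pools = flagged)
    write_anchors(res$anchors,
                  file.path(cfg$out_dir, sprintf("anchors_%s.tsv", t)))
    results[[t]] <- res
  }

  comparison <- NULL
  if (length(results) > 1L) {
    hi <- results[[1L]]$anchors
    lo <- results[[length(results)]]$anchors
    comparison <- compare_stringencies(hi, lo)
    utils::write.table(comparison$comparison,
                       file.path(cfg$out_dir, "stringency_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  main <- results[[sprintf("%g", cfg$threshold)]]
  qc <- list()
  if (!is.null(cfg$zipper)) {
    zip <- utils::read.delim(cfg$zipper, stringsAsFactors = FALSE)
    qc$zipper <- qc_zipper_adjacency(main$anchors, zip,
                                     max_gap = cfg$qc_max_gap)
    utils::write.table(qc$zipper, file.path(cfg$out_dir, "qc_zipper.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cfg$genetic_map)) {
    gm <- utils::read.delim(cfg$genetic_map, stringsAsFactors = FALSE)
    qc$genetic <- qc_genetic_distance(main$anchors, gm,
                                      max_cm = cfg$qc_max_cm)
    utils::write.table(qc$genetic, file.path(cfg$out_dir, "qc_genmap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  merge_suggestions <- unique(do.call(rbind, lapply(results, function(r) {
    a <- r$anchors
    a[a$status == "anchored" & !is.na(a$anchor_type) & a$anchor_type == 3L,
      c("marker_id", "contigs"), drop = FALSE]
  })))
  summary <- list(
    package_version = as.character(utils::packageVersion("poolanchor")),
    seed = cfg$seed,
    parameters = cfg[c("threshold", "sweep", "max_per_dim",
                       "endmatch_cutoff", "tolerance", "gel_length",
                       "min_depth", "qc_max_gap", "qc_max_cm", "mapq_min")],
    undersequenced_pools = flagged,
    thresholds = lapply(results, `[[`, "summary"),
    stringency_comparison = if (!is.null(comparison)) comparison$counts,
    merge_suggestions = if (!is.null(merge_suggestions) &&
                              nrow(merge_suggestions))
      merge_suggestions$contigs,
    qc = lapply(qc, function(tab) list(n_contigs = nrow(tab),
                                       n_flagged = sum(tab$flagged))))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  cfg_out <- unclass(cfg)
  yaml::write_yaml(cfg_out[!vapply(cfg_out, is.null, logical(1))],
                   file.path(cfg$out_dir, "config_resolved.yaml"))
  log_msg("run complete: %s", cfg$out_dir)
  invisible(list(out_dir = cfg$out_dir, results = results,
                 comparison = comparison, qc = qc, summary = summary))
}
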