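#' Configuration of a synthetic pooled-anchoring experiment
#'
#' Defaults mirror a chromosome-arm scale study: a 3,823-clone minimum
#' tiling path drawn from a physical map of ~1,300 contigs, re-arrayed
#' into ten 384-well plates and pooled in three dimensions (50 pools); 567
#' marker sequences of length 504 +/- 53 bp split into markers present
#' in a single MTP clone, markers falling in the overlap of two
#' adjacent MTP clones, repetitive markers hitting many plates, and
#' off-target markers absent from the library; per-pool sequencing
#' depths log-normally spread around ~30x so that occasional pools fall
#' below the 20x floor.
#'
#' @param n_plates,n_rows,n_cols pooling geometry.
#' @param n_clones MTP size; contigs are drawn until this many clones
#'   exist (the last contig is trimmed to fit), so the number of contigs
#'   is derived.
#' @param clones_per_contig inclusive integer range of contig sizes.
#' @param n_markers named counts per marker class: `unique_single`,
#'   `unique_two`, `repetitive`, `off_target`.
#' @param marker_length_mean,marker_length_sd marker length distribution
#'   (bp), clipped below at 100.
#' @param depth_meanlog,depth_sdlog log-normal per-pool mean depth.
#' @param false_negative_rate per-(marker, pool) probability that a truly
#'   present marker is covered below the calling threshold.
#' @param false_positive_rate per-(marker, pool) probability that an
#'   absent marker is covered above the calling threshold.
#' @param fn_below false negatives truncate the covered fraction to a
#'   uniform draw below this value (the stringent calling threshold, so
#'   part of the signal is recoverable at relaxed thresholds).
#' @param repetitive_copies clones holding each repetitive marker, in as
#'   many distinct plates (must exceed the repetitive filter, default 7).
#' @param bands_per_clone fingerprint band count per clone; adjacent
#'   clones in a contig share half their bands.
#' @param gel_length fingerprint band-value range.
#' @param roster_order `"contig"` lays MTP clones into wells in contig
#'   order (as an MTP re-array does); `"random"` scatters them.
#' @param seed integer master seed; all randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_plates = 10L, n_rows = 16L, n_cols = 24L,
                       n_clones = 3823L, clones_per_contig = c(2L, 4L),
                       n_markers = c(unique_single = 400L, unique_two = 100L,
                                     repetitive = 10L, off_target = 57L),
                       marker_length_mean = 504, marker_length_sd = 53,
                       depth_meanlog = log(30), depth_sdlog = 0.6,
                       false_negative_rate = 0, false_positive_rate = 0,
                       fn_below = 0.8, repetitive_copies = 7L,
                       bands_per_clone = 30L, gel_length = 3600,
                       roster_order = c("contig", "random"), seed = 1L) {
  roster_order <- match.arg(roster_order)
  classes <- c("unique_single", "unique_two", "repetitive", "off_target")
  full <- structure(integer(4), names = classes)
  full[names(n_markers)] <- as.integer(n_markers)
  stopifnot(all(full >= 0L), false_negative_rate >= 0,
            false_negative_rate <= 1, false_positive_rate >= 0,
            false_positive_rate <= 1, length(clones_per_contig) == 2L,
            clones_per_contig[1] >= 1L,
            clones_per_contig[2] >= clones_per_contig[1])
  structure(list(n_plates = as.integer(n_plates), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), n_clones = as.integer(n_clones),
                 clones_per_contig = as.integer(clones_per_contig),
                 n_markers = full, marker_length_mean = marker_length_mean,
                 marker_length_sd = marker_length_sd,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 false_negative_rate = false_negative_rate,
                 false_positive_rate = false_positive_rate,
                 fn_below = fn_below,
                 repetitive_copies = as.integer(repetitive_copies),
                 bands_per_clone = as.integer(bands_per_clone),
                 gel_length = gel_length, roster_order = roster_order,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a complete pooled-anchoring experiment
#'
#' Generates a contig-structured physical map with fingerprints, an MTP
#' roster over 3-D pools, marker placements per class, per-pool depths,
#' and a coverage table with configurable false-negative/-positive
#' noise, together with the ground truth needed to score recovery.
#' Deterministic under the config seed: the master seed is expanded
#' once into one sub-seed per generation stage (map, roster, markers,
#' placement, depths, coverage), so each stage draws from its own
#' reproducible stream.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, the bundle is also
#'   written as plain-text files (markers.fasta, roster.tsv, map.tsv,
#'   fingerprints.tsv, coverage.tsv, depths.tsv, truth.tsv).
#' @return list of class `sim_experiment`: `scheme`, `map`, `markers`,
#'   `sequences` (DNAStringSet), `fingerprints`, `coverage`, `depths`,
#'   `truth` (data.frame `marker_id`, `class`, `clone`, `contig`),
#'   `config`.
#' @export
simulate_experiment <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 6L)

  # --- physical map ---------------------------------------------------
  set.seed(sub[1L])
  n_clones <- config$n_clones
  capacity <- config$n_plates * config$n_rows * config$n_cols
  if (n_clones > capacity) {
    stop(sprintf("MTP of %d clones exceeds roster capacity %d",
                 n_clones, capacity))
  }
  rng <- seq(config$clones_per_contig[1L], config$clones_per_contig[2L])
  sizes <- sample(rng, ceiling(n_clones / rng[1L]), replace = TRUE)
  n_ctg <- which(cumsum(sizes) >= n_clones)[1L]
  sizes <- sizes[seq_len(n_ctg)]
  sizes[n_ctg] <- sizes[n_ctg] - (sum(sizes) - n_clones)
  if (sizes[n_ctg] == 0L) sizes <- sizes[-n_ctg]
  contig_id <- rep(sprintf("ctg%04d", seq_along(sizes)), sizes)
  clone_id <- sprintf("SIMBAC%05d", seq_len(n_clones))
  position <- unlist(lapply(sizes, seq_len))
  map_tab <- data.frame(clone_id = clone_id, contig_id = contig_id,
                        position = position, stringsAsFactors = FALSE)
  map <- load_clone_contig_table(map_tab)

  fingerprints <- simulate_fingerprints(map_tab, sizes,
                                        bands_per_clone = config$bands_per_clone,
                                        gel_length = config$gel_length)

  # --- roster ---------------------------------------------------------
  set.seed(sub[2L])
  wells <- expand.grid(column = seq_len(config$n_cols),
                       row = seq_len(config$n_rows),
                       plate = seq_len(config$n_plates))
  well_order <- if (config$roster_order == "random") {
    sample.int(nrow(wells), n_clones)
  } else {
    seq_len(n_clones)   # contig-ordered fill: plate by plate, row-major
  }
  roster <- data.frame(clone_id = clone_id,
                       plate = wells$plate[well_order],
                       row = wells$row[well_order],
                       column = wells$column[well_order],
                       stringsAsFactors = FALSE)
  scheme <- pooling_scheme(roster, n_plates = config$n_plates,
                           n_rows = config$n_rows, n_cols = config$n_cols)

  # --- markers & placements -------------------------------------------
  set.seed(sub[3L])
  n_total <- sum(config$n_markers)
  lens <- pmax(100L, as.integer(round(stats::rnorm(
    n_total, config$marker_length_mean, config$marker_length_sd))))
  marker_id <- sprintf("SIMMRK%05d", seq_len(n_total))
  class_vec <- rep(names(config$n_markers), config$n_markers)
  markers <- marker_table(marker_id, lens,
                          dataset = ifelse(class_vec == "off_target",
                                           "off_target", "target"))
  sequences <- random_dna(marker_id, lens)

  set.seed(sub[4L])
  truth <- simulate_placements(marker_id, class_vec, map_tab, roster, config)

  # --- depths & coverage ----------------------------------------------
  set.seed(sub[5L])
  pool_ids <- scheme_pools(scheme)
  depths <- data.frame(pool = pool_ids,
                       mean_depth = stats::rlnorm(length(pool_ids),
                                                  config$depth_meanlog,
                                                  config$depth_sdlog),
                       stringsAsFactors = FALSE)

  set.seed(sub[6L])
  coverage <- simulate_coverage(markers, truth, scheme, config)

  sim <- structure(list(scheme = scheme, map = map, markers = markers,
                        sequences = sequences, fingerprints = fingerprints,
                        coverage = coverage, depths = depths, truth = truth,
                        config = config),
                   class = "sim_experiment")
  if (!is.null(out_dir)) write_sim_bundle(sim, out_dir)
  sim
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "sim_experiment: %d clones / %d contigs, %d markers, %d pools, seed %d\n",
    nrow(x$scheme$roster), length(x$map$contig_ids), nrow(x$markers),
    n_pools(x$scheme), x$config$seed))
  invisible(x)
}

# contig-wise band tracks: clone j takes bands_per_clone consecutive
# fragments starting at (j-1)*bands_per_clone/2, so adjacent clones share
# half their bands and contig end clones expose unshared halves
simulate_fingerprints <- function(map_tab, sizes, bands_per_clone,
                                  gel_length) {
  fps <- vector("list", nrow(map_tab))
  names(fps) <- map_tab$clone_id
  step <- max(1L, bands_per_clone %/% 2L)
  row0 <- 0L
  for (sz in sizes) {
    n_frag <- step * (sz - 1L) + bands_per_clone
    frags <- stats::runif(n_frag, 1, gel_length)
    for (j in seq_len(sz)) {
      idx <- seq.int(step * (j - 1L) + 1L, step * (j - 1L) + bands_per_clone)
      fps[[row0 + j]] <- sort(frags[idx])
    }
    row0 <- row0 + sz
  }
  fps
}

random_dna <- function(ids, lens) {
  seqs <- vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE,
                 prob = c(0.28, 0.22, 0.22, 0.28)), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

simulate_placements <- function(marker_id, class_vec, map_tab, roster,
                                config) {
  rows <- list()
  place <- function(m, cls, clones) {
    ctg <- map_tab$contig_id[match(clones, map_tab$clone_id)]
    rows[[length(rows) + 1L]] <<- data.frame(
      marker_id = m, class = cls,
      clone = if (length(clones)) clones else NA_character_,
      contig = if (length(clones)) ctg else NA_character_,
      stringsAsFactors = FALSE)
  }
  sizes <- table(map_tab$contig_id)
  multi_ctg <- names(sizes)[sizes >= 2L]
  occupied_plates <- unique(roster$plate)
  if (any(class_vec == "repetitive") &&
      length(occupied_plates) < config$repetitive_copies) {
    stop("repetitive_copies exceeds the number of occupied plates")
  }
  for (i in seq_along(marker_id)) {
    cls <- class_vec[i]
    m <- marker_id[i]
    if (cls == "unique_single") {
      place(m, cls, sample(map_tab$clone_id, 1L))
    } else if (cls == "unique_two") {
      ctg <- sample(multi_ctg, 1L)
      mem <- map_tab[map_tab$contig_id == ctg, , drop = FALSE]
      mem <- mem[order(mem$position), , drop = FALSE]
      j <- if (nrow(mem) > 2L) sample(nrow(mem) - 1L, 1L) else 1L
      place(m, cls, mem$clone_id[c(j, j + 1L)])
    } else if (cls == "repetitive") {
      pl <- sample(occupied_plates, config$repetitive_copies)
      clones <- vapply(pl, function(p) {
        cand <- roster$clone_id[roster$plate == p]
        cand[sample.int(length(cand), 1L)]
      }, character(1))
      place(m, cls, clones)
    } else {  # off_target
      place(m, cls, character())
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simulate_coverage <- function(markers, truth, scheme, config) {
  placed <- truth[!is.na(truth$clone), , drop = FALSE]
  rows <- list()
  if (nrow(placed)) {
    pool_trip <- t(vapply(placed$clone, function(cl) {
      clone_to_pools(scheme, cl)
    }, character(3)))
    long <- data.frame(marker_id = rep(placed$marker_id, 3L),
                       pool = as.vector(pool_trip), stringsAsFactors = FALSE)
    long <- long[!duplicated(long), , drop = FALSE]
    n <- nrow(long)
    frac <- stats::runif(n, 0.9, 1.0)
    fn <- stats::runif(n) < config$false_negative_rate
    frac[fn] <- stats::runif(sum(fn), 0, config$fn_below)
    long$frac <- frac
    rows[[1L]] <- long
  }
  if (config$false_positive_rate > 0) {
    pool_ids <- scheme_pools(scheme)
    grid <- expand.grid(marker_id = markers$marker_id, pool = pool_ids,
                        stringsAsFactors = FALSE)
    true_key <- if (length(rows)) paste(rows[[1L]]$marker_id, rows[[1L]]$pool)
                else character()
    grid <- grid[!(paste(grid$marker_id, grid$pool) %in% true_key), ,
                 drop = FALSE]
    hit <- stats::runif(nrow(grid)) < config$false_positive_rate
    if (any(hit)) {
      fp <- grid[hit, , drop = FALSE]
      fp$frac <- stats::runif(nrow(fp), config$fn_below, 1.0)
      rows[[length(rows) + 1L]] <- fp
    }
  }
  if (!length(rows)) {
    return(data.frame(pool = character(), marker_id = character(),
                      covered_bases = integer(), marker_length = integer(),
                      covered_fraction = numeric(), mean_depth = numeric(),
                      stringsAsFactors = FALSE))
  }
  long <- do.call(rbind, rows)
  len <- markers$length[match(long$marker_id, markers$marker_id)]
  out <- data.frame(pool = long$pool, marker_id = long$marker_id,
                    covered_bases = as.integer(round(long$frac * len)),
                    stringsAsFactors = FALSE)
  coverage_from_table(out, markers)
}

#' Write a simulated bundle as plain-text files
#' @param sim a `sim_experiment`.
#' @param out_dir directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_sim_bundle <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(markers = file.path(out_dir, "markers.fasta"),
             roster = file.path(out_dir, "roster.tsv"),
             map = file.path(out_dir, "map.tsv"),
             fingerprints = file.path(out_dir, "fingerprints.tsv"),
             coverage = file.path(out_dir, "coverage.tsv"),
             depths = file.path(out_dir, "depths.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  Biostrings::writeXStringSet(sim$sequences, paths[["markers"]])
  wtsv <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                            row.names = FALSE)
  wtsv(sim$scheme$roster, paths[["roster"]])
  map_tab <- rbind(sim$map$members,
                   if (length(sim$map$singletons))
                     data.frame(clone_id = sim$map$singletons,
                                contig_id = "", position = NA_real_))
  wtsv(map_tab, paths[["map"]])
  fp <- data.frame(clone_id = rep(names(sim$fingerprints),
                                  lengths(sim$fingerprints)),
                   band = unlist(sim$fingerprints))
  wtsv(fp, paths[["fingerprints"]])
  wtsv(sim$coverage, paths[["coverage"]])
  wtsv(sim$depths, paths[["depths"]])
  wtsv(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Emit synthetic alignments (SAM) for one simulated pool
#'
#' Converts a pool's simulated coverage into explicit alignment records:
#' each covered region is tiled by fixed-length reads whose union
#' reproduces the simulated covered bases exactly, written as a headered
#' SAM file. This exercises the alignment-based coverage path without
#' requiring an aligner.
#'
#' @param sim a `sim_experiment`.
#' @param pool pool label.
#' @param path output SAM path.
#' @param read_length synthetic read length (default 100).
#' @return invisibly, `path`.
#' @export
write_pool_sam <- function(sim, pool, path, read_length = 100L) {
  cov <- sim$coverage[sim$coverage$pool == pool &
                        sim$coverage$covered_bases > 0L, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", sim$markers$marker_id,
                     sim$markers$length), con)
  n_read <- 0L
  for (i in seq_len(nrow(cov))) {
    m <- cov$marker_id[i]
    cb <- cov$covered_bases[i]
    seq_full <- as.character(sim$sequences[[m]])
    starts <- unique(c(seq(1L, max(1L, cb - read_length + 1L),
                           by = max(1L, read_length %/% 2L)),
                       max(1L, cb - read_length + 1L)))
    for (st in starts) {
      en <- min(st + read_length - 1L, cb)
      n_read <- n_read + 1L
      writeLines(paste(sprintf("simread%06d", n_read), 0L, m, st, 60L,
                       sprintf("%dM", en - st + 1L), "*", 0L, 0L,
                       substr(seq_full, st, en),
                       strrep("I", en - st + 1L), sep = "\t"), con)
    }
  }
  invisible(path)
}
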