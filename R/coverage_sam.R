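#' Per-pool breadth of coverage from SAM/BAM alignments
#'
#' Computes, for one sequenced pool, the covered region of every marker:
#' the number of reference positions covered by at least one retained
#' read. Retained reads are mapped, primary, non-supplementary records
#' passing the mapping-quality floor; the default `mapq_min = 1` drops
#' mapping-quality-zero records as an aligner-agnostic proxy for
#' "uniquely mapping" reads. Reference-consuming CIGAR operations (M, D,
#' =, X) count as covered; insertions and soft clips do not.
#'
#' @param path a SAM (text) or BAM file whose reference names are marker
#'   ids. SAM input is converted on the fly.
#' @param markers a [marker_table()].
#' @param pool pool label recorded in the output.
#' @param mapq_min minimal mapping quality kept (default 1, i.e. exclude
#'   MAPQ 0).
#' @return coverage data.frame as from [coverage_from_table()]; every
#'   marker appears, zero-covered markers included. `mean_depth` is the
#'   per-marker aligned-base depth.
#' @export
coverage_from_alignments <- function(path, markers, pool, mapq_min = 1L) {
  gal <- read_pool_alignments(path, mapq_min = mapq_min)
  known <- as.character(GenomicAlignments::seqnames(gal)) %in% markers$marker_id
  if (any(!known)) {
    skipped <- unique(as.character(GenomicAlignments::seqnames(gal))[!known])
    warning("skipping alignments to reference(s) not in marker set: ",
            paste(utils::head(skipped, 5L), collapse = ", "))
    gal <- gal[known]
  }
  reads <- data.frame(
    marker_id = as.character(GenomicAlignments::seqnames(gal)),
    start = GenomicAlignments::start(gal),
    end = GenomicAlignments::end(gal), stringsAsFactors = FALSE)
  breadth_from_intervals(reads, markers, pool = pool)
}

read_pool_alignments <- function(path, mapq_min = 1L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  } else {
    bam <- path
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = mapq_min)
  GenomicAlignments::readGAlignments(bam, param = param)
}

#' Breadth of coverage from explicit read intervals
#'
#' Union-of-intervals breadth: `covered_bases` is the size of the union of
#' the reads' reference spans on each marker, clipped to the marker
#' length; `mean_depth` is total aligned bases divided by marker length.
#'
#' @param reads data.frame with columns `marker_id`, `start`, `end`
#'   (1-based closed reference coordinates).
#' @param markers a [marker_table()].
#' @param pool pool label recorded in the output.
#' @return coverage data.frame, one row per marker.
#' @export
breadth_from_intervals <- function(reads, markers, pool) {
  covered <- integer(nrow(markers))
  aligned <- numeric(nrow(markers))
  if (nrow(reads)) {
    i <- match(reads$marker_id, markers$marker_id)
    if (anyNA(i)) {
      stop("reads refer to unknown marker: ",
           reads$marker_id[which(is.na(i))[1L]])
    }
    st <- pmax(1L, as.integer(reads$start))
    en <- pmin(markers$length[i], as.integer(reads$end))
    ok <- en >= st
    for (grp in split(seq_along(i)[ok], i[ok])) {
      m <- i[grp[1L]]
      ir <- IRanges::reduce(IRanges::IRanges(st[grp], en[grp]))
      covered[m] <- sum(IRanges::width(ir))
      aligned[m] <- sum(en[grp] - st[grp] + 1L)
    }
  }
  data.frame(pool = pool, marker_id = markers$marker_id,
             covered_bases = covered, marker_length = markers$length,
             covered_fraction = covered / markers$length,
             mean_depth = aligned / markers$length, stringsAsFactors = FALSE)
}

#' Coverage for many pools from an alignment manifest
#'
#' @param manifest data.frame or TSV path with columns `pool`, `path`
#'   (SAM/BAM per pool).
#' @inheritParams coverage_from_alignments
#' @return combined coverage data.frame over all pools.
#' @export
coverage_from_manifest <- function(manifest, markers, mapq_min = 1L) {
  if (is.character(manifest)) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("pool", "path") %in% names(manifest)))
  do.call(rbind, lapply(seq_len(nrow(manifest)), function(k) {
    coverage_from_alignments(manifest$path[k], markers,
                             pool = manifest$pool[k], mapq_min = mapq_min)
  }))
}

#' Depth-saturation curve for one pool
#'
#' Subsamples a pool's reads to a ladder of target depths and counts the
#' markers called positive at each depth. Positive-marker counts rise
#' with depth and plateau once every marker present in the pool is
#' breadth-covered; empirically the plateau is reached around 30x, which
#' motivates capping pool data at 30x and flooring acceptable pool depth
#' at 20x.
#'
#' @param reads read table (`marker_id`, `start`, `end`) or SAM/BAM path
#'   for one pool.
#' @param markers a [marker_table()].
#' @param depths target mean depths (x-fold over the marker set); values
#'   above the available depth are capped with a warning.
#' @param threshold covered-region call threshold.
#' @param seed integer seed making the random subsampling reproducible.
#' @return data.frame `depth`, `n_reads`, `n_positive`.
#' @export
saturation_curve <- function(reads, markers, depths = 1:50, threshold = 0.8,
                             seed = 1L) {
  if (is.character(reads)) {
    gal <- read_pool_alignments(reads)
    reads <- data.frame(
      marker_id = as.character(GenomicAlignments::seqnames(gal)),
      start = GenomicAlignments::start(gal),
      end = GenomicAlignments::end(gal), stringsAsFactors = FALSE)
  }
  stopifnot(all(depths >= 0))
  total_len <- sum(markers$length)
  full_depth <- sum(reads$end - reads$start + 1) / total_len
  capped <- depths > full_depth
  if (any(capped)) {
    warning(sprintf("requested depth %.3g exceeds available %.3g; capped",
                    max(depths), full_depth))
  }
  eff <- pmin(depths, full_depth)
  n_reads <- pmin(nrow(reads), round(nrow(reads) * eff / full_depth))
  set.seed(seed)
  n_positive <- vapply(n_reads, function(n) {
    sub <- reads[sample.int(nrow(reads), n), , drop = FALSE]
    cov <- breadth_from_intervals(sub, markers, pool = "subsample")
    sum(cov$covered_fraction >= threshold)
  }, integer(1))
  data.frame(depth = depths, n_reads = n_reads, n_positive = n_positive)
}
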