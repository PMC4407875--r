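#' Marker table constructor
#'
#' Markers are the sequences being anchored: ordered gene fragments from a
#' syntenic "zipper" build and/or genetically mapped SNP-bearing
#' sequences. Map metadata is optional and only used by the QC reports.
#'
#' @param marker_id unique marker identifiers.
#' @param length marker sequence lengths in bp (> 0).
#' @param dataset free tag, e.g. "zipper" or "snp".
#' @param zipper_rank optional integer rank in the ordered gene build.
#' @param chromosome,cm optional genetic-map position.
#' @return data.frame of class `marker_table`.
#' @export
marker_table <- function(marker_id, length, dataset = "default",
                         zipper_rank = NA_integer_, chromosome = NA_character_,
                         cm = NA_real_) {
  marker_id <- as.character(marker_id)
  length <- as.integer(length)
  if (anyDuplicated(marker_id)) {
    stop("duplicate marker_id: ", marker_id[duplicated(marker_id)][1L])
  }
  if (any(is.na(length) | length <= 0L)) stop("marker length must be > 0")
  out <- data.frame(marker_id = marker_id, length = length,
                    dataset = rep_len(as.character(dataset), length(marker_id)),
                    zipper_rank = rep_len(as.integer(zipper_rank), length(marker_id)),
                    chromosome = rep_len(as.character(chromosome), length(marker_id)),
                    cm = rep_len(as.numeric(cm), length(marker_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Read markers from FASTA, with optional metadata TSV
#'
#' @param fasta path to a marker FASTA; lengths are taken from sequences.
#' @param meta optional TSV with columns `marker_id` and any of `dataset`,
#'   `zipper_rank`, `chromosome`, `cm`.
#' @return a [marker_table()].
#' @export
read_markers <- function(fasta, meta = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  tab <- marker_table(ids, Biostrings::width(seqs))
  if (!is.null(meta)) {
    m <- utils::read.delim(meta, stringsAsFactors = FALSE)
    if (!"marker_id" %in% names(m)) stop("metadata TSV lacks marker_id column")
    i <- match(tab$marker_id, m$marker_id)
    for (col in intersect(c("dataset", "zipper_rank", "chromosome", "cm"),
                          names(m))) {
      tab[[col]][!is.na(i)] <- m[[col]][i[!is.na(i)]]
    }
  }
  tab
}

#' Per-pool breadth of coverage from a precomputed table
#'
#' Consumes a coverage table (columns `pool`, `marker_id`, `covered_bases`,
#' optionally `mean_depth`) as produced by [coverage_from_alignments()] or
#' an external per-reference coverage tool, and attaches marker lengths
#' and covered fractions. The covered region of a marker in a pool is the
#' number of its bases covered by at least one retained read (breadth).
#'
#' @param table data.frame or path to a TSV.
#' @param markers a [marker_table()] supplying marker lengths.
#' @return data.frame with columns `pool`, `marker_id`, `covered_bases`,
#'   `marker_length`, `covered_fraction`, `mean_depth`.
#' @export
coverage_from_table <- function(table, markers) {
  if (is.character(table)) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  req <- c("pool", "marker_id", "covered_bases")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop("coverage table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  i <- match(table$marker_id, markers$marker_id)
  if (anyNA(i)) {
    stop("coverage table refers to unknown marker: ",
         table$marker_id[which(is.na(i))[1L]])
  }
  len <- markers$length[i]
  cb <- as.integer(table$covered_bases)
  if (any(is.na(cb) | cb < 0L)) stop("covered_bases must be >= 0")
  over <- which(cb > len)
  if (length(over)) {
    stop(sprintf("covered_bases (%d) exceeds marker length (%d) for %s in %s",
                 cb[over[1L]], len[over[1L]], table$marker_id[over[1L]],
                 table$pool[over[1L]]))
  }
  data.frame(pool = as.character(table$pool),
             marker_id = as.character(table$marker_id),
             covered_bases = cb, marker_length = len,
             covered_fraction = cb / len,
             mean_depth = if ("mean_depth" %in% names(table))
               as.numeric(table$mean_depth) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Call positive pools at a covered-region threshold
#'
#' A pool is positive for a marker if its covered region is at least the
#' threshold fraction of the marker length (inclusive comparison; the
#' default 0.8 reproduces the standard "at least 80%" rule). Pairs absent
#' from the coverage table count as zero coverage.
#'
#' @param coverages a coverage data.frame from [coverage_from_table()] or
#'   [coverage_from_alignments()].
#' @param threshold covered-region fraction in (0, 1].
#' @param markers optional [marker_table()] fixing the marker universe;
#'   defaults to markers present in `coverages`.
#' @param pools optional character vector fixing the pool universe (e.g.
#'   [scheme_pools()]); defaults to pools present in `coverages`.
#' @return object of class `positive_call_matrix`: a logical marker x pool
#'   matrix with the threshold attached.
#' @export
call_positive_pools <- function(coverages, threshold = 0.8, markers = NULL,
                                pools = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single value in (0, 1]")
  }
  marker_ids <- if (is.null(markers)) sort(unique(coverages$marker_id))
                else markers$marker_id
  pool_ids <- if (is.null(pools)) sort(unique(coverages$pool)) else pools
  calls <- matrix(FALSE, nrow = length(marker_ids), ncol = length(pool_ids),
                  dimnames = list(marker_ids, pool_ids))
  i <- match(coverages$marker_id, marker_ids)
  j <- match(coverages$pool, pool_ids)
  keep <- !is.na(i) & !is.na(j)
  calls[cbind(i[keep], j[keep])] <- coverages$covered_fraction[keep] >= threshold
  structure(list(threshold = threshold, calls = calls),
            class = "positive_call_matrix")
}

#' @export
print.positive_call_matrix <- function(x, ...) {
  cat(sprintf("positive_call_matrix: %d markers x %d pools at threshold %.2f; %d positive calls\n",
              nrow(x$calls), ncol(x$calls), x$threshold, sum(x$calls)))
  invisible(x)
}

#' Re-call positives across a descending ladder of thresholds
#'
#' Reproduces the decreasing-stringency reanalysis: the covered-region
#' threshold is lowered from 80% to 30% of marker length in steps of 10%.
#' Calls nest monotonically — every pool positive at a threshold stays
#' positive at any lower threshold.
#'
#' @inheritParams call_positive_pools
#' @param thresholds strictly descending covered-region fractions.
#' @return named list of `positive_call_matrix`, one per threshold.
#' @export
stringency_sweep <- function(coverages, thresholds = seq(0.8, 0.3, by = -0.1),
                             markers = NULL, pools = NULL) {
  if (length(thresholds) < 1L || any(diff(thresholds) >= 0)) {
    stop("thresholds must be strictly descending")
  }
  out <- lapply(thresholds, function(t) {
    call_positive_pools(coverages, threshold = t, markers = markers,
                        pools = pools)
  })
  names(out) <- sprintf("%g", thresholds)
  out
}

#' Flag under-sequenced pools
#'
#' Pools sequenced below a minimal mean depth are prone to false-negative
#' marker detection (a marker physically present but not covered to the
#' threshold). The conventional floor is 20x; the comparison is strict,
#' so a pool at exactly 20x is not flagged.
#'
#' @param depths data.frame with columns `pool`, `mean_depth`, or a named
#'   numeric vector of per-pool mean depths.
#' @param min_depth flagging floor (default 20).
#' @return data.frame `pool`, `mean_depth` for flagged pools (zero rows if
#'   none).
#' @export
flag_undersequenced_pools <- function(depths, min_depth = 20) {
  if (is.numeric(depths) && !is.null(names(depths))) {
    depths <- data.frame(pool = names(depths), mean_depth = unname(depths),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("pool", "mean_depth") %in% names(depths)),
            all(depths$mean_depth >= 0))
  out <- depths[depths$mean_depth < min_depth, c("pool", "mean_depth"),
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a coverage table TSV
#' @param coverages coverage data.frame.
#' @param path output path.
#' @export
write_coverage <- function(coverages, path) {
  utils::write.table(coverages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Positive calls as a long table
#' @param calls a `positive_call_matrix`.
#' @return data.frame `marker_id`, `pool`, `positive`, `threshold`.
#' @export
calls_to_table <- function(calls) {
  stopifnot(inherits(calls, "positive_call_matrix"))
  m <- calls$calls
  data.frame(marker_id = rep(rownames(m), times = ncol(m)),
             pool = rep(colnames(m), each = nrow(m)),
             positive = as.vector(m), threshold = calls$threshold,
             stringsAsFactors = FALSE)
}

#' Positive pools of one marker
#' @param calls a `positive_call_matrix`.
#' @param marker_id marker to extract.
#' @return character vector of positive pool labels.
#' @export
positive_pools <- function(calls, marker_id) {
  stopifnot(inherits(calls, "positive_call_matrix"))
  row <- calls$calls[marker_id, ]
  names(row)[row]
}
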