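#' Repetitive-marker filter
#'
#' Markers hitting many pools cannot come from a single-copy locus: any
#' marker with more than `max_per_dim` positive pools in any dimension
#' (plate, row or column) is considered repetitive and is not assigned
#' to clones. The boundary is strict — exactly five positives in every
#' dimension is still deconvoluted.
#'
#' @param n_plates,n_rows,n_cols positive-pool counts per dimension.
#' @param max_per_dim maximal allowed positives per dimension (default 5).
#' @return logical: is the signature repetitive?
#' @export
filter_repetitive <- function(n_plates, n_rows, n_cols, max_per_dim = 5L) {
  stopifnot(n_plates >= 0, n_rows >= 0, n_cols >= 0)
  n_plates > max_per_dim || n_rows > max_per_dim || n_cols > max_per_dim
}

#' Deconvolute one marker's positive-pool signature
#'
#' Applies the three-tier decision cascade converting a positive-pool
#' signature into a clone/contig anchor:
#'
#' 1. more than `max_per_dim` positives in any dimension -> `repetitive`;
#' 2. no positive pool in some dimension -> `no_positive_pool`
#'    (unequivocal deconvolution impossible);
#' 3. exactly one positive pool per dimension -> anchor type 1: the
#'    single clone at that well;
#' 4. otherwise enumerate the Cartesian-product candidate clones; if
#'    candidates share a physical-map contig they corroborate each other
#'    — exactly one such group anchors the marker to all its clones
#'    (anchor type 2); several groups leave the marker `ambiguous`;
#' 5. failing that, a candidate pair of end clones from different
#'    contigs matching at the relaxed Sulston cutoff anchors both clones
#'    (anchor type 3) and suggests a contig merge;
#' 6. else `no_clone_overlap`.
#'
#' @param marker_id marker name.
#' @param pools character vector of positive pool labels.
#' @param scheme a [pooling_scheme()].
#' @param map a `physical_map` (used by types 2 and 3).
#' @param end_matches optional end-clone pair table from
#'   [end_clone_matches()].
#' @param max_per_dim repetitive filter threshold.
#' @param threshold covered-region threshold recorded in the result.
#' @param flagged_pools pools flagged under-sequenced; touching one adds
#'   an `undersequenced_pool` flag to the result.
#' @return one-row data.frame: `marker_id`, `status`, `anchor_type`,
#'   `clones`, `contigs` (semicolon-joined), `threshold`, `flags`.
#' @export
deconvolute_marker <- function(marker_id, pools, scheme, map,
                               end_matches = NULL, max_per_dim = 5L,
                               threshold = NA_real_,
                               flagged_pools = character()) {
  parsed <- if (length(pools)) parse_pool_label(pools) else
    data.frame(label = character(), dimension = character(),
               index = integer(), stringsAsFactors = FALSE)
  plates <- parsed$index[parsed$dimension == "plate"]
  rows <- parsed$index[parsed$dimension == "row"]
  cols <- parsed$index[parsed$dimension == "column"]
  flags <- character()
  if (length(intersect(pools, flagged_pools))) {
    flags <- c(flags, "undersequenced_pool")
  }

  res <- function(status, anchor_type = NA_integer_,
                  clones = character(), contigs = character(),
                  extra_flags = character()) {
    data.frame(marker_id = marker_id, status = status,
               anchor_type = anchor_type,
               clones = paste(sort(unique(clones)), collapse = ";"),
               contigs = paste(sort(unique(contigs[!is.na(contigs)])),
                               collapse = ";"),
               threshold = threshold,
               flags = paste(sort(unique(c(flags, extra_flags))),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  }

  if (filter_repetitive(length(plates), length(rows), length(cols),
                        max_per_dim = max_per_dim)) {
    return(res("repetitive"))
  }
  if (!length(plates) || !length(rows) || !length(cols)) {
    return(res("no_positive_pool"))
  }
  if (length(plates) == 1L && length(rows) == 1L && length(cols) == 1L) {
    well <- pools_to_well(scheme, pools)
    if (is.na(well$clone_id)) {
      return(res("no_clone_overlap", extra_flags = "empty_well"))
    }
    return(res("anchored", 1L, well$clone_id,
               clone_contig(map, well$clone_id)))
  }
  candidates <- enumerate_candidates(scheme, plates, rows, cols)
  if (!length(candidates)) {
    return(res("no_clone_overlap", extra_flags = "empty_well"))
  }
  groups <- same_contig_groups(candidates, map)
  if (length(groups) == 1L) {
    return(res("anchored", 2L, groups[[1L]], names(groups)))
  }
  if (length(groups) > 1L) {
    return(res("ambiguous"))
  }
  if (!is.null(end_matches) && nrow(end_matches)) {
    hit <- end_matches$clone_a %in% candidates &
      end_matches$clone_b %in% candidates
    if (sum(hit) >= 1L) {
      best <- end_matches[hit, , drop = FALSE]
      best <- best[which.min(best$score), , drop = FALSE]
      return(res("anchored", 3L, c(best$clone_a, best$clone_b),
                 c(best$contig_a, best$contig_b),
                 extra_flags = "merge_suggested"))
    }
  }
  res("no_clone_overlap")
}

#' Deconvolute every marker of a call matrix
#'
#' Runs [deconvolute_marker()] over all markers and summarises the
#' outcome: counts per status and anchor type, plus the fraction of
#' markers anchored among those detected in at least one pool.
#'
#' @param calls a `positive_call_matrix`.
#' @param scheme a [pooling_scheme()].
#' @param map a `physical_map`.
#' @param end_matches optional table from [end_clone_matches()].
#' @param max_per_dim repetitive filter threshold.
#' @param flagged_pools see [deconvolute_marker()].
#' @return list with `anchors` (data.frame, one row per marker) and
#'   `summary` (status counts, anchor-type counts, `n_detected`,
#'   `fraction_anchored_of_detected`).
#' @export
anchor_all <- function(calls, scheme, map, end_matches = NULL,
                       max_per_dim = 5L, flagged_pools = character()) {
  stopifnot(inherits(calls, "positive_call_matrix"))
  unknown <- setdiff(colnames(calls$calls), scheme_pools(scheme))
  if (length(unknown)) {
    stop("call matrix has pool label(s) not in the scheme: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  anchors <- do.call(rbind, lapply(rownames(calls$calls), function(m) {
    deconvolute_marker(m, positive_pools(calls, m), scheme, map,
                       end_matches = end_matches, max_per_dim = max_per_dim,
                       threshold = calls$threshold,
                       flagged_pools = flagged_pools)
  }))
  n_detected <- sum(rowSums(calls$calls) > 0L)
  list(anchors = anchors,
       summary = summarize_anchors(anchors, n_detected = n_detected))
}

#' Summary counts over an anchor table
#' @param anchors anchor data.frame from [anchor_all()].
#' @param n_detected number of markers with at least one positive pool;
#'   defaults to the number of markers whose status implies detection
#'   (an upper bound when the call matrix is unavailable).
#' @return list of status counts, anchor-type counts and anchored
#'   fraction among detected markers.
#' @export
summarize_anchors <- function(anchors, n_detected = NULL) {
  statuses <- c("anchored", "repetitive", "no_positive_pool",
                "no_clone_overlap", "ambiguous")
  status_counts <- vapply(statuses, function(s) sum(anchors$status == s),
                          integer(1))
  type_counts <- vapply(1:3, function(t) {
    sum(!is.na(anchors$anchor_type) & anchors$anchor_type == t)
  }, integer(1))
  names(type_counts) <- paste0("anchor_type_", 1:3)
  if (is.null(n_detected)) {
    n_detected <- sum(anchors$status != "no_positive_pool")
  }
  list(n_markers = nrow(anchors), status = as.list(status_counts),
       anchor_type = as.list(type_counts), n_detected = n_detected,
       fraction_anchored_of_detected =
         if (n_detected) unname(status_counts["anchored"]) / n_detected
         else NA_real_)
}

#' Compare anchoring at two covered-region stringencies
#'
#' Lowering the covered-region threshold recovers pools lost to false
#' negatives but can also add spurious positives. Each marker is put in
#' exactly one category: `same_contig` (anchored at both stringencies to
#' the same contig — or, for contig-less type-1 anchors, the same
#' clones), `different_contig`, `lost_unambiguity` (anchored at high
#' stringency only), `newly_anchored` (anchored at low stringency only),
#' or `unanchored_both`.
#'
#' @param results_high,results_low anchor data.frames from [anchor_all()]
#'   over the same marker universe (high = stricter threshold).
#' @return list with `comparison` (marker_id, category) and `counts`.
#' @export
compare_stringencies <- function(results_high, results_low) {
  if (!setequal(results_high$marker_id, results_low$marker_id)) {
    stop("marker universes differ between the two anchor tables")
  }
  lo <- results_low[match(results_high$marker_id, results_low$marker_id), ,
                    drop = FALSE]
  hi <- results_high
  anch_hi <- hi$status == "anchored"
  anch_lo <- lo$status == "anchored"
  key <- function(tab) ifelse(nzchar(tab$contigs), tab$contigs, tab$clones)
  category <- ifelse(!anch_hi & !anch_lo, "unanchored_both",
              ifelse(anch_hi & !anch_lo, "lost_unambiguity",
              ifelse(!anch_hi & anch_lo, "newly_anchored",
              ifelse(key(hi) == key(lo), "same_contig", "different_contig"))))
  comparison <- data.frame(marker_id = hi$marker_id, category = category,
                           stringsAsFactors = FALSE)
  cats <- c("same_contig", "different_contig", "lost_unambiguity",
            "newly_anchored", "unanchored_both")
  counts <- vapply(cats, function(cc) sum(category == cc), integer(1))
  list(comparison = comparison, counts = as.list(counts))
}

#' Write an anchor table TSV
#' @param anchors anchor data.frame.
#' @param path output path.
#' @export
write_anchors <- function(anchors, path) {
  utils::write.table(anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
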