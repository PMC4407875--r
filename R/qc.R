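#' Zipper-order adjacency QC of anchored contigs
#'
#' Markers anchored to the same physical-map contig should be neighbours
#' in the ordered gene build ("zipper"): a contig spans ~100 kbp while
#' the zipper orders genes along the whole arm. For every contig with at
#' least two anchored, ranked markers the report gives the largest
#' number of additional genes separating two rank-adjacent markers and
#' flags contigs where that separation reaches `max_gap`.
#'
#' @param anchors anchor data.frame from [anchor_all()].
#' @param zipper_order data.frame `marker_id`, `zipper_rank`, or a named
#'   integer vector of ranks.
#' @param max_gap flagging boundary: a pair separated by at least this
#'   many additional genes is suspicious (default 5).
#' @return data.frame `contig_id`, `n_markers`, `max_gap`, `flagged`.
#' @export
qc_zipper_adjacency <- function(anchors, zipper_order, max_gap = 5L) {
  ranks <- as_lookup(zipper_order, "zipper_rank")
  per <- anchored_per_contig(anchors)
  per$rank <- ranks[per$marker_id]
  per <- per[!is.na(per$rank), , drop = FALSE]
  out <- lapply(split(per, per$contig_id), function(g) {
    if (nrow(g) < 2L) return(NULL)
    gaps <- diff(sort(g$rank)) - 1L
    data.frame(contig_id = g$contig_id[1L], n_markers = nrow(g),
               max_gap = max(gaps), flagged = any(gaps >= max_gap),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(), n_markers = integer(),
                      max_gap = integer(), flagged = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Genetic-distance QC of anchored contigs
#'
#' Markers anchored to one contig should map genetically close together.
#' For every contig with at least two genetically mapped markers the
#' report gives the maximal pairwise distance in cM and flags contigs
#' where it reaches `max_cm` (default 1 cM) or where the markers sit on
#' different chromosomes.
#'
#' @param anchors anchor data.frame from [anchor_all()].
#' @param genetic_map data.frame `marker_id`, `chromosome`, `cm`.
#' @param max_cm flagging boundary in cM.
#' @return data.frame `contig_id`, `n_markers`, `max_cm`, `flagged`,
#'   `cross_chromosome`.
#' @export
qc_genetic_distance <- function(anchors, genetic_map, max_cm = 1.0) {
  stopifnot(all(c("marker_id", "chromosome", "cm") %in% names(genetic_map)))
  per <- anchored_per_contig(anchors)
  i <- match(per$marker_id, genetic_map$marker_id)
  per$chromosome <- genetic_map$chromosome[i]
  per$cm <- genetic_map$cm[i]
  per <- per[!is.na(per$cm) & !is.na(per$chromosome), , drop = FALSE]
  out <- lapply(split(per, per$contig_id), function(g) {
    if (nrow(g) < 2L) return(NULL)
    cross <- length(unique(g$chromosome)) > 1L
    span <- if (cross) NA_real_ else max(g$cm) - min(g$cm)
    data.frame(contig_id = g$contig_id[1L], n_markers = nrow(g),
               max_cm = span, flagged = cross || span >= max_cm,
               cross_chromosome = cross, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(), n_markers = integer(),
                      max_cm = numeric(), flagged = logical(),
                      cross_chromosome = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# markers anchored to exactly one contig, expanded one row per
# (marker, contig); multi-contig (type 3) anchors contribute to both
anchored_per_contig <- function(anchors) {
  a <- anchors[anchors$status == "anchored" & nzchar(anchors$contigs), ,
               drop = FALSE]
  ctg <- strsplit(a$contigs, ";", fixed = TRUE)
  data.frame(marker_id = rep(a$marker_id, lengths(ctg)),
             contig_id = unlist(ctg), stringsAsFactors = FALSE)
}

as_lookup <- function(x, col) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stopifnot(all(c("marker_id", col) %in% names(x)))
  structure(as.numeric(x[[col]]), names = as.character(x$marker_id))
}

#' False-positive rate from non-target chromosomes
#'
#' When the marker set includes sequences genetically mapped to
#' chromosomes other than the one the BAC library was made from, any
#' detection of those markers in a pool is a false positive. The
#' per-chromosome fraction of markers with at least one positive pool
#' estimates the false-positive rate; its maximum is the conservative
#' overall estimate.
#'
#' @param calls a `positive_call_matrix`.
#' @param marker_chromosomes data.frame `marker_id`, `chromosome` or a
#'   named character vector.
#' @param target_chromosome chromosome (or arm) the library derives
#'   from; excluded from the estimate.
#' @return list with `per_chromosome` (data.frame `chromosome`,
#'   `n_markers`, `n_detected`, `fraction`) and `estimate` (max
#'   non-target fraction; `NA` if there are no non-target markers).
#' @export
estimate_false_positive_rate <- function(calls, marker_chromosomes,
                                         target_chromosome) {
  stopifnot(inherits(calls, "positive_call_matrix"))
  if (is.character(marker_chromosomes) && !is.null(names(marker_chromosomes))) {
    chrom <- marker_chromosomes
  } else {
    stopifnot(all(c("marker_id", "chromosome") %in% names(marker_chromosomes)))
    chrom <- structure(as.character(marker_chromosomes$chromosome),
                       names = as.character(marker_chromosomes$marker_id))
  }
  detected <- rowSums(calls$calls) > 0L
  ch <- chrom[rownames(calls$calls)]
  keep <- !is.na(ch) & ch != target_chromosome
  per <- lapply(split(detected[keep], ch[keep]), function(d) {
    data.frame(n_markers = length(d), n_detected = sum(d),
               fraction = mean(d))
  })
  per_chromosome <- do.call(rbind, per)
  if (is.null(per_chromosome)) {
    return(list(per_chromosome = data.frame(chromosome = character(),
                                            n_markers = integer(),
                                            n_detected = integer(),
                                            fraction = numeric()),
                estimate = NA_real_))
  }
  per_chromosome <- cbind(chromosome = names(per), per_chromosome)
  rownames(per_chromosome) <- NULL
  list(per_chromosome = per_chromosome,
       estimate = max(per_chromosome$fraction))
}

#' Partition genetically mapped markers into chromosome arms
#'
#' With a genetic map of a whole chromosome but a library from one arm,
#' the physical short:long arm size ratio estimates how many of the
#' cM-ordered markers belong to the short arm: the first
#' `round(N * short / (short + long))` markers from the configured end
#' of the map (rounding half up).
#'
#' @param markers data.frame with columns `marker_id`, `cm`.
#' @param short_size,long_size physical arm sizes (e.g. Mbp; only their
#'   ratio matters — 321:449 for wheat chromosome 3D).
#' @param short_arm_end which end of the cM axis the short arm occupies:
#'   `"top"` (lowest cM first, default) or `"bottom"`.
#' @return list with `short_arm` and `long_arm` character vectors of
#'   marker ids.
#' @export
partition_markers_by_arm <- function(markers, short_size = 321,
                                     long_size = 449,
                                     short_arm_end = c("top", "bottom")) {
  short_arm_end <- match.arg(short_arm_end)
  stopifnot(short_size > 0, long_size > 0,
            all(c("marker_id", "cm") %in% names(markers)))
  ord <- order(markers$cm, decreasing = (short_arm_end == "bottom"))
  ids <- as.character(markers$marker_id)[ord]
  n <- length(ids)
  n_short <- floor(n * short_size / (short_size + long_size) + 0.5)
  list(short_arm = ids[seq_len(n_short)],
       long_arm = if (n_short < n) ids[seq(n_short + 1L, n)] else character())
}
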