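#' Physical-map model: clones organized into contigs
#'
#' A fingerprint-built physical map assigns each clone to at most one
#' contig, with a map coordinate (in band units) inside the contig.
#' Clones with no contig are singletons. End clones — those attaining the
#' minimal or maximal coordinate of their contig — are used for
#' relaxed-cutoff contig joining.
#'
#' @param table data.frame or TSV path with columns `clone_id`,
#'   `contig_id`, `position`; an empty/NA `contig_id` marks a singleton.
#' @return object of class `physical_map` with elements `members`
#'   (data.frame), `singletons` (character) and `contig_ids`.
#' @export
load_clone_contig_table <- function(table) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE,
                               colClasses = c(contig_id = "character"))
  }
  req <- c("clone_id", "contig_id", "position")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop("clone-contig table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  clone_id <- as.character(table$clone_id)
  contig_id <- as.character(table$contig_id)
  contig_id[is.na(contig_id) | contig_id == ""] <- NA_character_
  position <- as.numeric(table$position)
  if (anyDuplicated(clone_id)) {
    stop("clone assigned more than once: ",
         clone_id[duplicated(clone_id)][1L])
  }
  in_contig <- !is.na(contig_id)
  if (any(!is.finite(position[in_contig]))) {
    stop("non-finite position for contig member")
  }
  members <- data.frame(clone_id = clone_id[in_contig],
                        contig_id = contig_id[in_contig],
                        position = position[in_contig],
                        stringsAsFactors = FALSE)
  members <- members[order(members$contig_id, members$position), ,
                     drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members,
                 singletons = clone_id[!in_contig],
                 contig_ids = unique(members$contig_id)),
            class = "physical_map")
}

#' @export
print.physical_map <- function(x, ...) {
  cat(sprintf("physical_map: %d contigs, %d contig clones, %d singletons\n",
              length(x$contig_ids), nrow(x$members), length(x$singletons)))
  invisible(x)
}

#' Contig of each queried clone
#' @param map a `physical_map`.
#' @param clone_id clone names.
#' @return character vector of contig ids (`NA` for singletons/unknown).
#' @export
clone_contig <- function(map, clone_id) {
  map$members$contig_id[match(clone_id, map$members$clone_id)]
}

#' End clones of every contig
#'
#' @param map a `physical_map`.
#' @param n_end how many outermost clones per contig end count as end
#'   clones (default 1: only the coordinate extremes).
#' @return data.frame `clone_id`, `contig_id`, `end` ("left"/"right").
#' @export
contig_end_clones <- function(map, n_end = 1L) {
  out <- lapply(split(map$members, map$members$contig_id), function(m) {
    m <- m[order(m$position), , drop = FALSE]
    k <- min(n_end, nrow(m))
    left <- m[seq_len(k), c("clone_id", "contig_id"), drop = FALSE]
    right <- m[nrow(m) - seq_len(k) + 1L, c("clone_id", "contig_id"),
               drop = FALSE]
    left$end <- "left"
    right$end <- "right"
    both <- rbind(left, right)
    both[!duplicated(both$clone_id), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Candidate clones grouped by shared contig
#'
#' During deconvolution, candidate clones that lie in the same physical
#' map contig corroborate each other: all positive clones containing one
#' unique marker must overlap. Only groups of two or more clones are
#' returned.
#'
#' @param candidates character vector of clone names.
#' @param map a `physical_map`.
#' @return named list, one element per contig holding >= 2 candidates.
#' @export
same_contig_groups <- function(candidates, map) {
  candidates <- unique(candidates)
  ctg <- clone_contig(map, candidates)
  keep <- !is.na(ctg)
  groups <- split(candidates[keep], ctg[keep])
  groups[lengths(groups) >= 2L]
}

# ---- fingerprints & Sulston score ----------------------------------------

#' Read clone fingerprints (one band per row)
#' @param table data.frame or TSV path with columns `clone_id`, `band`.
#' @return named list of sorted numeric band vectors per clone.
#' @export
read_fingerprints <- function(table) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("clone_id", "band") %in% names(table)))
  lapply(split(as.numeric(table$band), as.character(table$clone_id)), sort)
}

#' Count shared fingerprint bands
#'
#' Greedy one-to-one matching of two sorted band lists: walking both
#' lists in increasing order, a pair of bands within `tolerance` of each
#' other is matched and consumed. Deterministic and order-independent.
#'
#' @param a,b numeric band vectors (migration/size units).
#' @param tolerance maximal band difference counted as a match.
#' @return integer number of matched bands.
#' @export
shared_bands <- function(a, b, tolerance = 7) {
  a <- sort(a)
  b <- sort(b)
  i <- 1L
  j <- 1L
  k <- 0L
  while (i <= length(a) && j <= length(b)) {
    d <- a[i] - b[j]
    if (abs(d) <= tolerance) {
      k <- k + 1L
      i <- i + 1L
      j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  k
}

#' Sulston fingerprint-overlap probability
#'
#' The probability that two clones share at least their observed number
#' of restriction-fragment bands by chance. With band counts
#' `n_hi >= n_lo` and `k` shared bands, each band of the smaller
#' fingerprint matches the larger one by chance with probability
#' `p = 1 - (1 - 2 * tolerance / gel_length)^n_hi`, and the score is the
#' binomial upper tail `sum_{i=k..n_lo} C(n_lo, i) p^i (1-p)^(n_lo-i)`.
#' Lower scores mean stronger evidence of a real overlap; map building
#' typically joins clones below 1e-45 and end-clone rejoining relaxes
#' the cutoff to 1e-25. The tail is evaluated through the binomial
#' distribution function so tiny cutoffs are represented exactly.
#'
#' @param a,b fingerprints: numeric band vectors.
#' @param tolerance band-matching tolerance (default 7 band units).
#' @param gel_length effective gel length in band units (default 3600).
#' @return probability in [0, 1].
#' @export
sulston_score <- function(a, b, tolerance = 7, gel_length = 3600) {
  if (!length(a) || !length(b)) stop("fingerprints must be non-empty")
  stopifnot(tolerance > 0, tolerance < gel_length)
  n_lo <- min(length(a), length(b))
  n_hi <- max(length(a), length(b))
  k <- shared_bands(a, b, tolerance = tolerance)
  p <- 1 - (1 - 2 * tolerance / gel_length)^n_hi
  stats::pbinom(k - 1L, n_lo, p, lower.tail = FALSE)
}

#' End-clone pairs matching at a relaxed cutoff
#'
#' Compares end clones of different contigs by their Sulston scores and
#' reports pairs scoring at or below the cutoff (default 1e-25, relaxed
#' relative to map building). Such a pair both resolves marker
#' deconvolution (anchor type 3) and suggests merging the two contigs.
#'
#' @param map a `physical_map`.
#' @param fingerprints named list of band vectors (see
#'   [read_fingerprints()]); end clones without fingerprints are skipped
#'   with a warning.
#' @param cutoff maximal Sulston score reported.
#' @param tolerance,gel_length see [sulston_score()].
#' @param n_end outermost clones per contig end considered (default 1).
#' @return data.frame `clone_a`, `clone_b`, `contig_a`, `contig_b`,
#'   `score`, one row per unordered pair, sorted by score.
#' @export
end_clone_matches <- function(map, fingerprints, cutoff = 1e-25,
                              tolerance = 7, gel_length = 3600, n_end = 1L) {
  ends <- contig_end_clones(map, n_end = n_end)
  empty <- data.frame(clone_a = character(), clone_b = character(),
                      contig_a = character(), contig_b = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (is.null(ends) || nrow(ends) < 2L) return(empty)
  has_fp <- ends$clone_id %in% names(fingerprints)
  if (any(!has_fp)) {
    warning("no fingerprint for end clone(s): ",
            paste(utils::head(ends$clone_id[!has_fp], 5L), collapse = ", "))
    ends <- ends[has_fp, , drop = FALSE]
  }
  n <- nrow(ends)
  if (n < 2L) return(empty)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (ends$contig_id[i] == ends$contig_id[j]) next
      s <- sulston_score(fingerprints[[ends$clone_id[i]]],
                         fingerprints[[ends$clone_id[j]]],
                         tolerance = tolerance, gel_length = gel_length)
      if (s <= cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          clone_a = ends$clone_id[i], clone_b = ends$clone_id[j],
          contig_a = ends$contig_id[i], contig_b = ends$contig_id[j],
          score = s, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$score), , drop = FALSE]
}
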