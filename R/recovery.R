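#' Score anchoring results against simulated ground truth
#'
#' A marker is counted correct when it is anchored, every reported clone
#' is a true placement, and every reported contig is a contig truly
#' holding the marker. Per class the report gives precision (correct /
#' anchored; `NA` when nothing in the class was anchored) and recall
#' (correct / class size), plus a status confusion table. For the
#' repetitive and off-target classes the expected outcome is a status
#' (`repetitive`, `no_positive_pool`), which the confusion table shows.
#'
#' @param anchors anchor data.frame from [anchor_all()].
#' @param truth truth data.frame (`marker_id`, `class`, `clone`,
#'   `contig`) from [simulate_experiment()].
#' @return list with `per_class` (data.frame `class`, `n`, `n_anchored`,
#'   `n_correct`, `precision`, `recall`) and `confusion` (class x status
#'   count table).
#' @export
evaluate_recovery <- function(anchors, truth) {
  if (!setequal(anchors$marker_id, unique(truth$marker_id))) {
    stop("anchor table and truth cover different marker universes")
  }
  true_clones <- split(truth$clone, truth$marker_id)
  true_contigs <- split(truth$contig, truth$marker_id)
  cls <- vapply(split(truth$class, truth$marker_id), `[`, character(1), 1L)

  split_field <- function(x) {
    strsplit(ifelse(nzchar(x), x, NA_character_), ";", fixed = TRUE)
  }
  rep_clones <- split_field(anchors$clones)
  rep_contigs <- split_field(anchors$contigs)
  m <- anchors$marker_id
  correct <- vapply(seq_along(m), function(i) {
    if (anchors$status[i] != "anchored") return(FALSE)
    rc <- rep_clones[[i]]
    if (anyNA(rc)) return(FALSE)
    tc <- true_clones[[m[i]]]
    if (!all(rc %in% tc)) return(FALSE)
    rg <- rep_contigs[[i]]
    all(is.na(rg) | rg %in% true_contigs[[m[i]]])
  }, logical(1))

  marker_class <- cls[m]
  per_class <- do.call(rbind, lapply(unique(truth$class), function(cc) {
    in_cls <- marker_class == cc
    n_anch <- sum(in_cls & anchors$status == "anchored")
    n_corr <- sum(in_cls & correct)
    data.frame(class = cc, n = sum(in_cls), n_anchored = n_anch,
               n_correct = n_corr,
               precision = if (n_anch) n_corr / n_anch else NA_real_,
               recall = n_corr / sum(in_cls), stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  confusion <- table(class = marker_class, status = anchors$status)
  list(per_class = per_class, confusion = confusion)
}
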