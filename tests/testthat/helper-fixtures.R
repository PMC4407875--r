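# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# fully occupied scheme with deterministic clone names BAC<p>_<r>_<c>
full_scheme <- function(n_plates = 10L, n_rows = 16L, n_cols = 24L) {
  g <- expand.grid(column = seq_len(n_cols), row = seq_len(n_rows),
                   plate = seq_len(n_plates))
  roster <- data.frame(
    clone_id = sprintf("BAC%d_%d_%d", g$plate, g$row, g$column),
    plate = g$plate, row = g$row, column = g$column,
    stringsAsFactors = FALSE)
  pooling_scheme(roster, n_plates = n_plates, n_rows = n_rows,
                 n_cols = n_cols)
}

# small physical map from parallel vectors
tiny_map <- function(clone_id, contig_id, position = NULL) {
  if (is.null(position)) {
    position <- stats::ave(seq_along(clone_id), contig_id, FUN = seq_along)
  }
  load_clone_contig_table(data.frame(clone_id = clone_id,
                                     contig_id = contig_id,
                                     position = position,
                                     stringsAsFactors = FALSE))
}

# reduced-scale simulation config: 10 plates of 8x12 wells, 800 clones
# (plates 1..7 fully occupied), so every marker class fits
small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_plates = 10L, n_rows = 8L, n_cols = 12L, n_clones = 800L,
         n_markers = c(unique_single = 80L, unique_two = 20L,
                       repetitive = 4L, off_target = 10L),
         repetitive_copies = 7L, seed = 101L),
    list(...))
  do.call(sim_config, args)
}

# two near-identical 60-band fingerprints on fresh random bands
facing_fingerprints <- function(n_bands = 60L, gel_length = 3600,
                                jitter = 0.5) {
  bands <- sort(stats::runif(n_bands, 1, gel_length - 1))
  list(a = bands, b = bands + stats::runif(n_bands, -jitter, jitter))
}
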