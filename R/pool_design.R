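#' Three-dimensional BAC pooling scheme
#'
#' An MTP (minimum tiling path) BAC library re-arrayed into `n_plates`
#' 384-well plates is pooled along three dimensions: one pool per plate,
#' one per row across all plates, and one per column across all plates.
#' Each clone therefore belongs to exactly one plate, one row and one
#' column pool, and any combination of one positive pool per dimension
#' identifies a unique well.
#'
#' @param roster data.frame with columns `clone_id`, `plate`, `row`,
#'   `column`. `row` may be given as an uppercase letter ("A".."P") or a
#'   1-based integer. Wells not listed are treated as empty; each clone
#'   and each well may appear at most once.
#' @param n_plates number of MTP plates.
#' @param n_rows,n_cols plate geometry; defaults describe a 384-well
#'   plate (16 rows A..P by 24 columns).
#' @return an object of class `pooling_scheme`.
#' @examples
#' roster <- data.frame(clone_id = "cl1", plate = 3, row = "F", column = 17)
#' sch <- pooling_scheme(roster, n_plates = 10)
#' clone_to_pools(sch, "cl1")   # p03 rF c17
#' @export
pooling_scheme <- function(roster = NULL, n_plates = 10L, n_rows = 16L,
                           n_cols = 24L) {
  n_plates <- as.integer(n_plates)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_plates >= 1L, n_rows >= 1L, n_rows <= 26L, n_cols >= 1L)
  if (is.null(roster)) {
    roster <- data.frame(clone_id = character(), plate = integer(),
                         row = integer(), column = integer(),
                         stringsAsFactors = FALSE)
  }
  req <- c("clone_id", "plate", "row", "column")
  missing_cols <- setdiff(req, names(roster))
  if (length(missing_cols)) {
    stop("roster lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  roster <- data.frame(clone_id = as.character(roster$clone_id),
                       plate = as.integer(roster$plate),
                       row = parse_row(roster$row),
                       column = as.integer(roster$column),
                       stringsAsFactors = FALSE)
  check_bounds(roster$plate, 1L, n_plates, "plate")
  check_bounds(roster$row, 1L, n_rows, "row")
  check_bounds(roster$column, 1L, n_cols, "column")
  if (anyDuplicated(roster$clone_id)) {
    stop("duplicate clone_id in roster: ",
         roster$clone_id[duplicated(roster$clone_id)][1L])
  }
  well_key <- paste(roster$plate, roster$row, roster$column)
  if (anyDuplicated(well_key)) {
    stop("well occupied by more than one clone: ",
         well_key[duplicated(well_key)][1L])
  }
  structure(list(n_plates = n_plates, n_rows = n_rows, n_cols = n_cols,
                 roster = roster),
            class = "pooling_scheme")
}

#' @export
print.pooling_scheme <- function(x, ...) {
  cat(sprintf("pooling_scheme: %d plates x %d rows x %d columns (%d pools), %d clones\n",
              x$n_plates, x$n_rows, x$n_cols, n_pools(x), nrow(x$roster)))
  invisible(x)
}

#' Total number of pools of a scheme (plates + rows + columns)
#' @param scheme a [pooling_scheme()].
#' @export
n_pools <- function(scheme) scheme$n_plates + scheme$n_rows + scheme$n_cols

parse_row <- function(row) {
  if (is.numeric(row)) return(as.integer(row))
  row <- as.character(row)
  num <- suppressWarnings(as.integer(row))
  letter <- match(toupper(row), LETTERS)
  out <- ifelse(is.na(num), letter, num)
  if (anyNA(out) & length(out)) {
    stop("unparseable row value: ", row[which(is.na(out))[1L]])
  }
  as.integer(out)
}

check_bounds <- function(x, lo, hi, what) {
  bad <- which(is.na(x) | x < lo | x > hi)
  if (length(bad)) {
    stop(sprintf("%s out of range [%d, %d]: %s", what, lo, hi,
                 paste(x[bad[seq_len(min(3L, length(bad)))]], collapse = ", ")))
  }
  invisible(x)
}

# ---- pool labels ----------------------------------------------------------

#' Construct canonical pool labels
#'
#' Pools are labelled `p01..pNN` (plates), `rA..rP` (rows) and `c01..cNN`
#' (columns); plate and column indices are zero-padded to two digits so
#' labels sort naturally.
#'
#' @param dimension one of `"plate"`, `"row"`, `"column"` (recycled).
#' @param index 1-based pool index within its dimension.
#' @return character vector of labels.
#' @export
pool_label <- function(dimension, index) {
  index <- as.integer(index)
  dimension <- rep_len(match.arg_vec(dimension, c("plate", "row", "column")),
                       length(index))
  stopifnot(all(index >= 1L))
  out <- character(length(index))
  pl <- dimension == "plate"
  ro <- dimension == "row"
  co <- dimension == "column"
  out[pl] <- sprintf("p%02d", index[pl])
  out[ro] <- paste0("r", LETTERS[index[ro]])
  out[co] <- sprintf("c%02d", index[co])
  out
}

match.arg_vec <- function(x, choices) {
  x <- choices[pmatch(x, choices, duplicates.ok = TRUE)]
  if (anyNA(x)) stop("dimension must be one of: ", paste(choices, collapse = ", "))
  x
}

#' Parse canonical pool labels
#'
#' Inverse of [pool_label()]: recovers dimension and 1-based index from
#' labels such as `"p03"`, `"rF"`, `"c17"`.
#'
#' @param label character vector of pool labels.
#' @return data.frame with columns `label`, `dimension`, `index`.
#' @export
parse_pool_label <- function(label) {
  label <- as.character(label)
  dim1 <- substr(label, 1L, 1L)
  rest <- substring(label, 2L)
  dimension <- c(p = "plate", r = "row", c = "column")[dim1]
  index <- integer(length(label))
  is_row <- !is.na(dimension) & dimension == "row"
  index[is_row] <- match(rest[is_row], LETTERS)
  index[!is_row] <- suppressWarnings(as.integer(rest[!is_row]))
  bad <- is.na(dimension) | is.na(index) | index < 1L
  if (any(bad)) stop("malformed pool label: ", label[which(bad)[1L]])
  data.frame(label = label, dimension = unname(dimension), index = index,
             stringsAsFactors = FALSE)
}

# ---- clone <-> pool arithmetic -------------------------------------------

#' Pools containing a clone or well
#'
#' Maps a well address (or a rostered clone) to the triple of pools that
#' contain it, e.g. the clone at position F17 of MTP plate 3 is present
#' in pools p03, rF and c17.
#'
#' @param scheme a [pooling_scheme()].
#' @param clone_id clone name to look up in the roster; alternatively give
#'   `plate`, `row`, `column` directly.
#' @param plate,row,column explicit well address (row as letter or integer).
#' @return named character vector with elements `plate`, `row`, `column`.
#' @export
clone_to_pools <- function(scheme, clone_id = NULL, plate = NULL, row = NULL,
                           column = NULL) {
  if (!is.null(clone_id)) {
    i <- match(clone_id, scheme$roster$clone_id)
    if (is.na(i)) stop("clone not in roster: ", clone_id)
    plate <- scheme$roster$plate[i]
    row <- scheme$roster$row[i]
    column <- scheme$roster$column[i]
  }
  plate <- as.integer(plate)
  row <- parse_row(row)
  column <- as.integer(column)
  check_bounds(plate, 1L, scheme$n_plates, "plate")
  check_bounds(row, 1L, scheme$n_rows, "row")
  check_bounds(column, 1L, scheme$n_cols, "column")
  c(plate = pool_label("plate", plate),
    row = pool_label("row", row),
    column = pool_label("column", column))
}

#' Deconvolute one pool per dimension back to a well
#'
#' Inverse of [clone_to_pools()]: a combination of a single plate, row and
#' column pool identifies one well unambiguously.
#'
#' @param scheme a [pooling_scheme()].
#' @param pools character vector of exactly three pool labels, one per
#'   dimension (any order).
#' @return list with `plate`, `row`, `column` (integers) and `clone_id`
#'   (the rostered clone, or `NA` for an empty well).
#' @export
pools_to_well <- function(scheme, pools) {
  parsed <- parse_pool_label(pools)
  if (nrow(parsed) != 3L || anyDuplicated(parsed$dimension)) {
    stop("invalid signature: need exactly one pool per dimension, got ",
         paste(pools, collapse = ", "))
  }
  idx <- structure(parsed$index, names = parsed$dimension)
  check_bounds(idx[["plate"]], 1L, scheme$n_plates, "plate")
  check_bounds(idx[["row"]], 1L, scheme$n_rows, "row")
  check_bounds(idx[["column"]], 1L, scheme$n_cols, "column")
  r <- scheme$roster
  hit <- which(r$plate == idx[["plate"]] & r$row == idx[["row"]] &
                 r$column == idx[["column"]])
  list(plate = idx[["plate"]], row = idx[["row"]], column = idx[["column"]],
       clone_id = if (length(hit)) r$clone_id[hit] else NA_character_)
}

#' Enumerate candidate clones for a multi-positive signature
#'
#' With more than one positive pool in some dimension, the candidate
#' clones are those at the Cartesian product of positive coordinates
#' (e.g. 2 plates x 2 rows x 2 columns gives eight candidate wells),
#' restricted to wells actually occupied in the roster.
#'
#' @param scheme a [pooling_scheme()].
#' @param plates,rows,cols non-empty vectors of pool labels (or bare
#'   1-based indices) per dimension.
#' @return character vector of candidate clone names (possibly empty if
#'   all product wells are unoccupied).
#' @export
enumerate_candidates <- function(scheme, plates, rows, cols) {
  p <- pool_indices(plates, "plate")
  r <- pool_indices(rows, "row")
  co <- pool_indices(cols, "column")
  if (!length(p) || !length(r) || !length(co)) {
    stop("missing dimension: each of plates/rows/cols must be non-empty")
  }
  ros <- scheme$roster
  keep <- ros$plate %in% p & ros$row %in% r & ros$column %in% co
  ros$clone_id[keep]
}

pool_indices <- function(x, dimension) {
  if (length(x) == 0L) return(integer())
  if (is.numeric(x)) return(as.integer(x))
  parsed <- parse_pool_label(x)
  bad <- parsed$dimension != dimension
  if (any(bad)) {
    stop("pool ", parsed$label[which(bad)[1L]], " is not a ", dimension,
         " pool")
  }
  parsed$index
}

#' Pool membership table
#'
#' Expands a pooling scheme into the full pool -> clone membership: every
#' clone appears in exactly three pools (its plate, row and column pool).
#' On a fully occupied 10-plate 384-well scheme the plate, row and column
#' pools hold 384, 240 and 160 clones respectively.
#'
#' @param scheme a [pooling_scheme()].
#' @return data.frame with columns `pool`, `dimension`, `clone_id`, one
#'   row per (pool, clone) incidence, ordered by dimension then pool.
#' @export
build_pool_membership <- function(scheme) {
  r <- scheme$roster
  one_dim <- function(dim, idx) {
    data.frame(pool = pool_label(dim, idx),
               dimension = rep_len(dim, nrow(r)),
               clone_id = r$clone_id, stringsAsFactors = FALSE)
  }
  out <- rbind(one_dim("plate", r$plate), one_dim("row", r$row),
               one_dim("column", r$column))
  out[order(match(out$dimension, c("plate", "row", "column")), out$pool,
            out$clone_id), , drop = FALSE]
}

#' All pool labels of a scheme
#' @param scheme a [pooling_scheme()].
#' @return character vector of length `n_pools(scheme)` in plate, row,
#'   column order.
#' @export
scheme_pools <- function(scheme) {
  c(pool_label("plate", seq_len(scheme$n_plates)),
    pool_label("row", seq_len(scheme$n_rows)),
    pool_label("column", seq_len(scheme$n_cols)))
}

#' Read a roster TSV (clone_id, plate, row, column)
#' @param path TSV file path.
#' @param ... geometry arguments passed to [pooling_scheme()].
#' @export
read_roster <- function(path, ...) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pooling_scheme(tab, ...)
}
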