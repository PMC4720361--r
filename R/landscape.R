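#' Landscapes for reserve site selection under spreading disturbance
#'
#' A landscape is a lattice of parcels with two adjacency relations: the
#' *spread* relation along which a disturbance (fire, pest, disease) moves
#' from an ignition parcel to its contiguous neighbours, and the *border*
#' relation used to measure how clustered a reserve is. On square grids the
#' spread relation is first-order queen contiguity (8 neighbours) while
#' borders are shared edges (rook, 4 neighbours); on hexagonal lattices the
#' two coincide (up to 6 neighbours).
#'
#' Square landscapes distinguish a *focal* region of parcels eligible for
#' reserve selection from an optional *buffer* ring from which fires may
#' ignite and spread inward but which cannot be selected. Focal parcels are
#' numbered 1..J row-major (left-to-right, top-to-bottom); buffer parcels get
#' ids J+1.. in row-major order over the full lattice. Hexagonal landscapes
#' have no buffer: every parcel is focal and an eligible ignition point.
#'
#' @param rows,cols number of focal rows and columns.
#' @param buffer_width width, in parcels, of the buffer ring around the focal
#'   region (0 for none).
#' @return An object of class `grid_landscape` (also `rss_landscape`) with
#'   components `J` (number of focal parcels), `focal_ids`, `ignition_domain`,
#'   per-parcel coordinates, and precomputed queen/rook adjacency lists.
#' @examples
#' ls5 <- build_square_landscape(5, 5, 1)
#' ls5$J                      # 25 focal parcels
#' length(ls5$ignition_domain) # 49 possible ignition points
#' @seealso [build_hex_landscape()], [queen_neighbors()], [shared_borders()]
#' @export
build_square_landscape <- function(rows, cols, buffer_width = 1) {
  rows <- assert_count(rows, "rows")
  cols <- assert_count(cols, "cols")
  buffer_width <- assert_count(buffer_width, "buffer_width", min = 0L)

  nr <- rows + 2L * buffer_width
  nc <- cols + 2L * buffer_width
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  focal <- row > buffer_width & row <= buffer_width + rows &
    col > buffer_width & col <= buffer_width + cols

  # ids: focal 1..J row-major over the focal region, then buffer J+1..N
  # row-major over the rest of the lattice
  n <- nr * nc
  id <- integer(n)
  id[focal] <- seq_len(sum(focal))
  id[!focal] <- sum(focal) + seq_len(sum(!focal))

  ord <- order(id)
  row <- row[ord]; col <- col[ord]; focal <- focal[ord]

  lookup <- matrix(0L, nr, nc)
  lookup[cbind(row, col)] <- seq_len(n)

  nbrs_at <- function(i, offsets) {
    rr <- row[i] + offsets[, 1L]
    cc <- col[i] + offsets[, 2L]
    keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    sort(lookup[cbind(rr[keep], cc[keep])])
  }
  queen_off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  queen_off <- queen_off[!(queen_off[, 1L] == 0 & queen_off[, 2L] == 0), ]
  rook_off <- matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L), ncol = 2L, byrow = TRUE)

  structure(list(
    type = "grid",
    rows = rows, cols = cols, buffer_width = buffer_width,
    J = sum(focal),
    n_parcels = n,
    row = row, col = col,
    focal = focal,
    focal_ids = which(focal),
    ignition_domain = seq_len(n),
    spread_nbrs = lapply(seq_len(n), nbrs_at, offsets = queen_off),
    border_nbrs = lapply(seq_len(n), nbrs_at, offsets = rook_off)
  ), class = c("grid_landscape", "rss_landscape"))
}

#' @rdname build_square_landscape
#' @param n_rows,n_cols dimensions of the axial-coordinate rhombus of
#'   hexagonal cells. `build_hex_landscape(17, 17)` gives the default
#'   289-parcel landscape.
#' @export
build_hex_landscape <- function(n_rows, n_cols) {
  n_rows <- assert_count(n_rows, "n_rows")
  n_cols <- assert_count(n_cols, "n_cols")
  n <- n_rows * n_cols

  # axial coordinates: q along columns, r along rows; ids row-major
  r <- rep(seq_len(n_rows), each = n_cols)
  q <- rep(seq_len(n_cols), times = n_rows)
  lookup <- matrix(seq_len(n), n_rows, n_cols, byrow = TRUE)
  hex_off <- matrix(c(1L, 0L, -1L, 0L, 0L, 1L, 0L, -1L, 1L, -1L, -1L, 1L),
                    ncol = 2L, byrow = TRUE) # (dq, dr)
  nbrs <- lapply(seq_len(n), function(i) {
    qq <- q[i] + hex_off[, 1L]
    rr <- r[i] + hex_off[, 2L]
    keep <- qq >= 1L & qq <= n_cols & rr >= 1L & rr <= n_rows
    sort(lookup[cbind(rr[keep], qq[keep])])
  })

  structure(list(
    type = "hex",
    rows = n_rows, cols = n_cols,
    J = n,
    n_parcels = n,
    q = q, r = r,
    focal = rep(TRUE, n),
    focal_ids = seq_len(n),
    ignition_domain = seq_len(n),
    spread_nbrs = nbrs,
    border_nbrs = nbrs
  ), class = c("hex_landscape", "rss_landscape"))
}

#' Build a hexagonal landscape from an explicit adjacency list
#'
#' Accepts the combinatorial structure of a real tessellation (e.g. extracted
#' from GIS data) as a set of parcel ids and unordered adjacent pairs,
#' bypassing the synthetic rhombus geometry.
#'
#' @param parcels vector of parcel ids `1..J`.
#' @param adjacency two-column matrix (or list of length-2 vectors) of
#'   adjacent parcel-id pairs; symmetrized internally.
#' @return A `hex_landscape` object.
#' @export
build_hex_landscape_explicit <- function(parcels, adjacency) {
  parcels <- sort(unique(as.integer(parcels)))
  n <- length(parcels)
  if (n < 1L || !identical(parcels, seq_len(n))) {
    stop("`parcels` must be the ids 1..J", call. = FALSE)
  }
  if (is.list(adjacency)) adjacency <- do.call(rbind, adjacency)
  adjacency <- matrix(as.integer(adjacency), ncol = 2L)
  if (any(adjacency < 1L | adjacency > n)) {
    stop("adjacency refers to unknown parcel ids", call. = FALSE)
  }
  if (any(adjacency[, 1L] == adjacency[, 2L])) {
    stop("adjacency must be irreflexive", call. = FALSE)
  }
  both <- rbind(adjacency, adjacency[, 2:1, drop = FALSE])
  nbrs <- lapply(seq_len(n), function(i) sort(unique(both[both[, 1L] == i, 2L])))
  if (any(lengths(nbrs) > 6L)) {
    stop("hexagonal parcels can have at most 6 neighbors", call. = FALSE)
  }

  structure(list(
    type = "hex", rows = NA_integer_, cols = NA_integer_,
    J = n, n_parcels = n,
    q = rep(NA_integer_, n), r = rep(NA_integer_, n),
    focal = rep(TRUE, n),
    focal_ids = seq_len(n),
    ignition_domain = seq_len(n),
    spread_nbrs = nbrs,
    border_nbrs = nbrs
  ), class = c("hex_landscape", "rss_landscape"))
}

check_parcel <- function(landscape, parcel) {
  parcel <- as.integer(parcel)
  if (length(parcel) != 1L || is.na(parcel) ||
      parcel < 1L || parcel > landscape$n_parcels) {
    stop(sprintf("unknown parcel id %s (landscape has parcels 1..%d)",
                 paste(parcel, collapse = ","), landscape$n_parcels),
         call. = FALSE)
  }
  parcel
}

#' Queen-contiguity neighbours of a parcel
#'
#' All parcels at Chebyshev distance 1 (up to 8) from `parcel`, restricted to
#' the represented lattice (focal plus buffer). This is the relation along
#' which a spreading disturbance moves on square grids.
#'
#' @param landscape a `grid_landscape`.
#' @param parcel a parcel id in the ignition domain.
#' @return Sorted integer vector of neighbouring parcel ids.
#' @export
queen_neighbors <- function(landscape, parcel) {
  if (!inherits(landscape, "grid_landscape")) {
    stop("`queen_neighbors()` is defined for square-grid landscapes", call. = FALSE)
  }
  landscape$spread_nbrs[[check_parcel(landscape, parcel)]]
}

#' Neighbours along the disturbance-spread relation
#'
#' Queen contiguity on square grids, 6-cell adjacency on hexagonal lattices.
#'
#' @inheritParams queen_neighbors
#' @param landscape an `rss_landscape`.
#' @export
spread_neighbors <- function(landscape, parcel) {
  landscape$spread_nbrs[[check_parcel(landscape, parcel)]]
}

#' Number of shared borders within a reserve
#'
#' Counts unordered pairs of reserve parcels that share an edge: rook
#' adjacency on square grids, the 6-cell adjacency on hexagonal lattices.
#' This is the simplest measure of how agglomerated a reserve is.
#'
#' @param landscape an `rss_landscape`.
#' @param reserve a [reserve()] or integer vector of focal parcel ids.
#' @return Integer count of adjacent pairs.
#' @export
shared_borders <- function(landscape, reserve) {
  ids <- reserve_parcels(reserve)
  if (!all(ids %in% landscape$focal_ids)) {
    stop("reserve contains parcels outside the focal landscape", call. = FALSE)
  }
  inres <- logical(landscape$n_parcels)
  inres[ids] <- TRUE
  sum(vapply(ids, function(i) sum(inres[landscape$border_nbrs[[i]]]), 0L)) %/% 2L
}

#' @export
print.rss_landscape <- function(x, ...) {
  cat(sprintf("<%s landscape: %d focal parcels, %d ignition parcels>\n",
              x$type, x$J, length(x$ignition_domain)))
  if (x$type == "grid") {
    cat(sprintf("  %d x %d focal grid, buffer width %d\n",
                x$rows, x$cols, x$buffer_width))
  }
  invisible(x)
}
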