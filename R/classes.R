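#' Reserves and species matrices
#'
#' A reserve is a set of focal parcel ids with a size budget `m`; a species
#' matrix is a J x I binary presence/absence matrix whose rows are parcels
#' and whose columns are species, with presence known with certainty.
#'
#' @param parcels integer vector of distinct focal parcel ids.
#' @param m maximum reserve size; defaults to `length(parcels)`.
#' @return `reserve()` returns a classed, sorted integer vector with
#'   attribute `m`.
#' @examples
#' r <- reserve(c(20, 7), m = 2)
#' reserve_parcels(r)
#' @export
reserve <- function(parcels, m = length(parcels)) {
  parcels <- sort(unique(as.integer(parcels)))
  m <- assert_count(m, "m", min = 0L)
  if (length(parcels) > m) {
    stop(sprintf("reserve has %d parcels but m = %d", length(parcels), m),
         call. = FALSE)
  }
  structure(parcels, m = m, class = "reserve")
}

#' @rdname reserve
#' @param x a `reserve` or plain integer vector of parcel ids.
#' @export
reserve_parcels <- function(x) {
  if (inherits(x, "reserve")) return(as.integer(unclass(x)))
  sort(unique(as.integer(x)))
}

#' @export
print.reserve <- function(x, ...) {
  cat(sprintf("<reserve: {%s}, m = %d>\n",
              paste(reserve_parcels(x), collapse = ","), attr(x, "m")))
  invisible(x)
}

#' Construct and validate a species presence/absence matrix
#'
#' @param presence J x I matrix of 0/1 values; rows are parcels in id order,
#'   columns are species.
#' @param species_names optional column names.
#' @return An integer matrix of class `species_matrix` with rownames set to
#'   parcel ids.
#' @export
species_matrix <- function(presence, species_names = NULL) {
  presence <- as.matrix(presence)
  bad <- which(!(presence %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(presence)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(presence)) + 1L
    stop(sprintf("non-binary cell at parcel row %d, species column %d: %s",
                 i, j, format(presence[i, j])), call. = FALSE)
  }
  mode(presence) <- "integer"
  empty <- which(colSums(presence) == 0L)
  if (length(empty)) {
    stop(sprintf("species column(s) %s occur on no parcel",
                 paste(empty, collapse = ",")), call. = FALSE)
  }
  rownames(presence) <- seq_len(nrow(presence))
  if (!is.null(species_names)) colnames(presence) <- species_names
  if (is.null(colnames(presence))) {
    colnames(presence) <- paste0("sp", seq_len(ncol(presence)))
  }
  class(presence) <- c("species_matrix", class(presence))
  presence
}

#' @export
print.species_matrix <- function(x, ...) {
  rich <- rowSums(unclass(x))
  cat(sprintf(
    "<species_matrix: %d parcels x %d species; richness min %d / mean %.2f / max %d>\n",
    nrow(x), ncol(x), min(rich), mean(rich), max(rich)))
  invisible(x)
}

#' @export
summary.species_matrix <- function(object, ...) {
  rich <- rowSums(unclass(object))
  list(J = nrow(object), I = ncol(object),
       richness_min = min(rich), richness_mean = mean(rich),
       richness_max = max(rich))
}

check_species_landscape <- function(species, landscape) {
  if (nrow(species) != landscape$J) {
    stop(sprintf("species matrix has %d rows but landscape has %d focal parcels",
                 nrow(species), landscape$J), call. = FALSE)
  }
  invisible(TRUE)
}
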