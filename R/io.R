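#' Species matrix CSV input/output
#'
#' The on-disk format is a table whose first column is the 1-based parcel id
#' and whose remaining columns are one species each, cells 0/1 (the same
#' shape a presence/absence matrix extracted from a biodiversity atlas takes
#' after flattening). Comma- and whitespace-delimited files are accepted,
#' with or without a header row; the reader sniffs both unless told.
#'
#' @param path file to read or write.
#' @param sep field separator; `NULL` (default) sniffs comma vs whitespace.
#' @param header logical; `NULL` (default) sniffs whether a header row is
#'   present.
#' @return `read_species_matrix()` returns a validated [species_matrix()];
#'   non-binary cells, ragged rows and duplicate parcel ids are rejected
#'   with the offending coordinates named.
#' @export
read_species_matrix <- function(path, sep = NULL, header = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  if (is.null(header)) {
    fields <- strsplit(if (sep == ",") first else trimws(first),
                       if (sep == ",") "," else "[[:space:]]+")[[1L]]
    header <- any(is.na(suppressWarnings(as.numeric(fields))))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("species matrix needs an id column plus >= 1 species column", call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate parcel id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ",")), call. = FALSE)
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(mat), dim(mat)))), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at parcel id %s, column %s",
                 ids[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]), call. = FALSE)
  }
  bad <- which(!(mat %in% c(0, 1)), arr.ind = FALSE)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(mat)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(mat)) + 1L
    stop(sprintf("non-binary cell (value %s) at parcel id %s, species column %s",
                 format(mat[i, j]), ids[i],
                 if (is.null(colnames(mat))) j else colnames(mat)[j]),
         call. = FALSE)
  }
  mat <- mat[order(ids), , drop = FALSE]
  sm <- species_matrix(mat, species_names = colnames(mat))
  message(sprintf("read %d parcels x %d species; richness min %d / mean %.2f / max %d",
                  nrow(sm), ncol(sm),
                  min(rowSums(unclass(sm))), mean(rowSums(unclass(sm))),
                  max(rowSums(unclass(sm)))))
  sm
}

#' @rdname read_species_matrix
#' @param species a [species_matrix()].
#' @export
write_species_matrix <- function(species, path) {
  df <- data.frame(parcel = seq_len(nrow(species)),
                   unclass(species)[, , drop = FALSE], check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a landscape specification file
#'
#' JSON with either `{"type": "square", "rows", "cols", "buffer_width"}`,
#' `{"type": "hex", "rows", "cols"}`, or
#' `{"type": "hex_explicit", "parcels": [...], "adjacency": [[id,id],...]}`
#' for the combinatorial structure of a real tessellation.
#'
#' @param path JSON file.
#' @return An `rss_landscape`.
#' @export
read_landscape_spec <- function(path) {
  spec <- jsonlite::fromJSON(path)
  build_landscape_from_spec(spec)
}

build_landscape_from_spec <- function(spec) {
  switch(as.character(spec$type),
    square = build_square_landscape(spec$rows, spec$cols,
                                    if (is.null(spec$buffer_width)) 1 else spec$buffer_width),
    hex = build_hex_landscape(spec$rows, spec$cols),
    hex_explicit = build_hex_landscape_explicit(unlist(spec$parcels),
                                                matrix(unlist(spec$adjacency),
                                                       ncol = 2, byrow = TRUE)),
    stop(sprintf("unknown landscape type: %s", spec$type), call. = FALSE)
  )
}

#' Export a reserve evaluation as JSON
#'
#' Writes parcels, m, expected species, the outcome distribution and the
#' secondary/dispersion metrics in one record.
#'
#' @param landscape an `rss_landscape`.
#' @param reserve a [reserve()].
#' @param result a `coverage_result` from [evaluate_reserve()].
#' @param path output file.
#' @export
write_reserve_result <- function(landscape, reserve, result, path) {
  dist <- result$outcome_distribution
  obj <- list(
    parcels = reserve_parcels(reserve),
    m = if (inherits(reserve, "reserve")) attr(reserve, "m") else length(reserve_parcels(reserve)),
    expected_species = result$expected_species,
    outcome_distribution = as.list(dist[dist > 0]),
    p_zero = result$p_zero,
    p_all = result$p_all,
    shared_borders = shared_borders(landscape, reserve),
    multi_burn_ignitions = multi_burn_ignitions(landscape, reserve)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
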