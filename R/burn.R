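#' Burn patterns and burn models
#'
#' A *burn pattern* is the set of focal parcels destroyed by a single
#' disturbance event. A *burn model* is a finite probability distribution
#' over burn patterns, in one of three representations:
#'
#' * `enumerated` — one pattern per possible ignition point, all equally
#'   probable (the spatially-correlated, spreading-fire set B1 on small
#'   landscapes);
#' * `sampled` — Monte-Carlo draws, each with weight `1/n_sims`;
#' * `closed_form` — the spatially-independent, risk-equalized null B2:
#'   conditional on `n` parcels burning, every n-subset of the J focal
#'   parcels is equally likely. This model is never materialized (for the
#'   stylized landscape it would hold 2,235,350 patterns) and is queried via
#'   hypergeometric identities instead.
#'
#' @name burn_model
NULL

new_burn_pattern <- function(burned, probability, ignitions) {
  list(burned = sort(as.integer(burned)),
       probability = probability,
       ignitions = as.integer(ignitions))
}

# Attach the J x B unburned-indicator matrix used for fast reserve
# evaluation, and check probability conservation.
finalize_burn_model <- function(patterns, kind, representation, landscape) {
  p <- vapply(patterns, `[[`, 0, "probability")
  if (abs(sum(p) - 1) > 1e-12) {
    stop("burn-pattern probabilities must sum to 1", call. = FALSE)
  }
  J <- landscape$J
  U <- matrix(1, J, length(patterns))
  for (b in seq_along(patterns)) U[patterns[[b]]$burned, b] <- 0
  structure(list(
    kind = kind, representation = representation,
    patterns = patterns, probabilities = p,
    J = J, unburned = U
  ), class = "burn_model")
}

#' @export
print.burn_model <- function(x, ...) {
  if (x$representation == "closed_form") {
    cat(sprintf("<burn_model: %s, closed form over J = %d, sizes {%s}>\n",
                x$kind, x$J, paste(names(x$sizes), collapse = ",")))
  } else {
    cat(sprintf("<burn_model: %s, %s, %d patterns>\n",
                x$kind, x$representation, length(x$patterns)))
  }
  invisible(x)
}

#' Burn pattern from a single ignition
#'
#' The fire ignites on `ignition` and spreads to every contiguous neighbour
#' (queen contiguity on square grids, the 6 adjacent cells on hexagonal
#' lattices); the resulting burn pattern is the intersection of the ignited
#' parcel and its neighbours with the focal landscape.
#'
#' @param landscape an `rss_landscape`.
#' @param ignition parcel id in the ignition domain (focal or buffer).
#' @return A burn pattern: list with `burned` (focal parcel ids),
#'   `probability` (`NA` for a standalone pattern) and `ignitions`.
#' @export
spread_burn <- function(landscape, ignition) {
  ignition <- check_parcel(landscape, ignition)
  cells <- c(ignition, landscape$spread_nbrs[[ignition]])
  burned <- sort(cells[landscape$focal[cells]])
  if (length(burned) == 0L) {
    stop(sprintf("ignition at parcel %d burns no focal parcel", ignition),
         call. = FALSE)
  }
  new_burn_pattern(burned, NA_real_, ignition)
}

#' Enumerate all spreading burn patterns
#'
#' One pattern per parcel in the ignition domain, each with probability
#' `1/|ignition domain|`. Patterns whose burned sets coincide are kept as
#' distinct equiprobable events, since probability mass belongs to the
#' ignition point. On the 5x5 focal grid with a one-parcel buffer this gives
#' the 49-pattern spatially-correlated model.
#'
#' @param landscape an `rss_landscape`.
#' @return A `burn_model` with `kind = "correlated"`,
#'   `representation = "enumerated"`.
#' @examples
#' bm <- enumerate_spread_patterns(build_square_landscape(5, 5, 1))
#' length(bm$patterns)   # 49
#' expected_burned(bm)   # 225/49 = 4.59...
#' @export
enumerate_spread_patterns <- function(landscape) {
  dom <- landscape$ignition_domain
  p <- 1 / length(dom)
  patterns <- lapply(dom, function(i) {
    bp <- spread_burn(landscape, i)
    bp$probability <- p
    bp
  })
  finalize_burn_model(patterns, "correlated", "enumerated", landscape)
}

#' Expected number of focal parcels burned
#'
#' @param model a `burn_model` in any representation.
#' @return `sum_b p_b * |burned_b|` (for closed-form models,
#'   `sum_n q_n * n`).
#' @export
expected_burned <- function(model) {
  if (model$representation == "closed_form") {
    return(sum(model$sizes * as.integer(names(model$sizes))))
  }
  sum(model$probabilities *
        vapply(model$patterns, function(b) length(b$burned), 0L))
}

#' Distribution of the number of parcels burned
#'
#' @param model an enumerated or sampled `burn_model`.
#' @return Named numeric vector `q` with `q[[as.character(n)]]` the total
#'   probability that exactly `n` parcels burn; names sorted numerically.
#' @export
size_distribution <- function(model) {
  if (model$representation == "closed_form") return(model$sizes)
  sz <- vapply(model$patterns, function(b) length(b$burned), 0L)
  q <- tapply(model$probabilities, sz, sum)
  q <- q[order(as.integer(names(q)))]
  stats::setNames(as.numeric(q), names(q))
}

#' Number of spatially-independent burn patterns
#'
#' The risk-equalized independent null draws, for each burn size `n` in the
#' support of the correlated size distribution, a uniform n-subset of the J
#' focal parcels; the number of distinct patterns is `sum_n choose(J, n)`.
#' For J = 25 and support \{1,2,3,4,6,9\} this is 2,235,350.
#'
#' @param J number of focal parcels.
#' @param sizes a size distribution (named vector as returned by
#'   [size_distribution()]) or an integer vector of supported sizes.
#' @return The pattern count (numeric, as it can exceed integer range).
#' @export
count_independent_patterns <- function(J, sizes) {
  J <- assert_count(J, "J")
  n <- if (!is.null(names(sizes))) as.integer(names(sizes)) else as.integer(sizes)
  if (any(n < 1L) || any(n > J)) {
    stop("size support must lie within 1..J", call. = FALSE)
  }
  sum(choose(J, n))
}

#' Closed-form spatially-independent burn model
#'
#' Represents the risk-equalized independent null implicitly: the burn size
#' is drawn from `sizes` and, conditional on size `n`, the burned set is a
#' uniform n-subset of the J focal parcels. Survival probabilities are
#' computed by hypergeometric identities; e.g. a fixed set of `r` parcels all
#' burn with probability `sum_n q_n * choose(J-r, n-r) / choose(J, n)`.
#'
#' @param J number of focal parcels.
#' @param sizes named probability vector over burn sizes (must sum to 1).
#' @return A `burn_model` with `representation = "closed_form"`.
#' @export
independent_model_closed_form <- function(J, sizes) {
  J <- assert_count(J, "J")
  n <- as.integer(names(sizes))
  if (is.null(names(sizes)) || any(is.na(n))) {
    stop("`sizes` must be a named vector: names are burn sizes", call. = FALSE)
  }
  if (any(n < 1L) || any(n > J)) stop("size support must lie within 1..J", call. = FALSE)
  if (abs(sum(sizes) - 1) > 1e-12) stop("`sizes` must sum to 1", call. = FALSE)
  structure(list(
    kind = "independent", representation = "closed_form",
    J = J, sizes = stats::setNames(as.numeric(sizes), names(sizes))
  ), class = "burn_model")
}

# P(all of a fixed set of r focal parcels burn) under a closed-form model.
closed_form_all_burn <- function(model, r) {
  if (r == 0L) return(1)
  n <- as.integer(names(model$sizes))
  sum(model$sizes * ifelse(n >= r,
                           choose(model$J - r, n - r) / choose(model$J, n), 0))
}

#' Monte-Carlo sample of spreading burn patterns
#'
#' Draws `n_sims` fires, each igniting on a parcel chosen uniformly from the
#' ignition domain (with replacement) and spreading to its contiguous
#' neighbours; every sampled pattern carries weight `1/n_sims`.
#'
#' @param landscape an `rss_landscape`.
#' @param n_sims number of simulated fires.
#' @param seed optional integer seed; identical seeds give identical models.
#' @return A `burn_model` with `kind = "correlated"`,
#'   `representation = "sampled"`.
#' @export
sample_spread_patterns <- function(landscape, n_sims, seed = NULL) {
  n_sims <- assert_count(n_sims, "n_sims")
  with_seed_opt(seed, {
    ign <- sample(landscape$ignition_domain, n_sims, replace = TRUE)
    patterns <- lapply(ign, function(i) {
      bp <- spread_burn(landscape, i)
      bp$probability <- 1 / n_sims
      bp
    })
    finalize_burn_model(patterns, "correlated", "sampled", landscape)
  })
}

#' Risk-equalized independent patterns matched to a correlated model
#'
#' For each pattern of the correlated model, draws one spatially-independent
#' pattern burning the same number of parcels, chosen uniformly without
#' replacement among all focal parcels; weights are copied. The expected
#' burned area of the output therefore equals the input's exactly, isolating
#' the effect of spatial correlation from total risk.
#'
#' @param landscape an `rss_landscape`.
#' @param correlated an enumerated or sampled `burn_model`.
#' @param seed optional integer seed.
#' @return A `burn_model` with `kind = "independent"`, same representation
#'   and weights as `correlated`.
#' @export
sample_matched_independent_patterns <- function(landscape, correlated, seed = NULL) {
  if (correlated$representation == "closed_form") {
    stop("`correlated` must be an enumerated or sampled model", call. = FALSE)
  }
  foc <- landscape$focal_ids
  with_seed_opt(seed, {
    patterns <- lapply(correlated$patterns, function(b) {
      s <- length(b$burned)
      burned <- if (s == length(foc)) foc else sample(foc, s)
      new_burn_pattern(burned, b$probability, integer(0))
    })
    finalize_burn_model(patterns, "independent", correlated$representation,
                        landscape)
  })
}

#' Export / import burn models as JSON
#'
#' Enumerated and sampled models are written pattern-by-pattern; closed-form
#' models are written as `{kind, representation, J, size_distribution}`.
#'
#' @param model a `burn_model`.
#' @param path file path.
#' @param landscape the landscape the model was built on (needed to
#'   reconstruct the evaluation cache on read).
#' @return `read_burn_model()` returns a `burn_model`.
#' @export
write_burn_model <- function(model, path) {
  obj <- if (model$representation == "closed_form") {
    list(kind = model$kind, representation = "closed_form", J = model$J,
         size_distribution = as.list(model$sizes))
  } else {
    list(kind = model$kind, representation = model$representation,
         patterns = lapply(model$patterns, function(b) {
           list(ignitions = b$ignitions, burned = b$burned,
                probability = b$probability)
         }))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_burn_model
#' @export
read_burn_model <- function(path, landscape = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (identical(obj$representation, "closed_form")) {
    q <- unlist(obj$size_distribution)
    return(independent_model_closed_form(obj$J, q))
  }
  if (is.null(landscape)) {
    stop("`landscape` is required to read an enumerated/sampled model",
         call. = FALSE)
  }
  patterns <- lapply(obj$patterns, function(b) {
    new_burn_pattern(unlist(b$burned), b$probability,
                     if (length(b$ignitions)) unlist(b$ignitions) else integer(0))
  })
  finalize_burn_model(patterns, obj$kind, obj$representation, landscape)
}
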