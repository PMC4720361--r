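#' Evaluating reserves under a burn model
#'
#' A species survives a burn pattern if and only if at least one *unburned*
#' reserve parcel contains it; species on non-reserve parcels, and on burned
#' parcels, do not survive. A reserve's value is the expectation, over burn
#' patterns, of the number of surviving species; the full probability
#' distribution over that number supports secondary objectives such as
#' minimizing the probability that no species survives.
#'
#' @name coverage
NULL

#' Species surviving a single burn pattern
#'
#' @param reserve a [reserve()] or integer vector of focal parcel ids.
#' @param species a [species_matrix()].
#' @param pattern a burn pattern as returned by [spread_burn()].
#' @return Integer vector of indices of surviving species.
#' @export
species_surviving <- function(reserve, species, pattern) {
  ids <- reserve_parcels(reserve)
  if (length(ids) && max(ids) > nrow(species)) {
    stop("reserve parcel ids exceed the species matrix's parcels", call. = FALSE)
  }
  keep <- setdiff(ids, pattern$burned)
  if (length(keep) == 0L) return(integer(0))
  unname(which(colSums(species[keep, , drop = FALSE]) > 0L))
}

# Fast expected surviving species for a set of parcel ids. Shared by the
# evaluator, the exact solver and the annealer; uses the model's cached
# unburned-indicator matrix and one small matrix product per call.
expected_species_ids <- function(ids, P, model) {
  if (length(ids) == 0L) return(0)
  if (model$representation == "closed_form") {
    r <- colSums(P[ids, , drop = FALSE])
    die <- vapply(unique(r), function(k) closed_form_all_burn(model, k), 0)
    names(die) <- unique(r)
    return(sum(1 - die[as.character(r)]))
  }
  alive <- crossprod(P[ids, , drop = FALSE],
                     model$unburned[ids, , drop = FALSE]) > 0 # I x B
  sum(model$probabilities * colSums(alive))
}

#' Expected number of surviving species
#'
#' @inheritParams species_surviving
#' @param model a `burn_model` in any representation.
#' @export
expected_species <- function(reserve, species, model) {
  ids <- reserve_parcels(reserve)
  P <- matrix(as.numeric(species), nrow(species), ncol(species))
  expected_species_ids(ids, P, model)
}

#' Evaluate a reserve under a burn model
#'
#' Computes the expected number of surviving species, the per-species
#' survival probabilities, and the full outcome distribution over the number
#' of species surviving. For enumerated and sampled models this is a direct
#' probability-weighted tally over patterns. For closed-form independent
#' models, per-species survival uses the hypergeometric identity
#' `P(all r reserve parcels holding the species burn) =
#' sum_n q_n choose(J-r, n-r)/choose(J, n)`, and the outcome distribution is
#' obtained exactly by enumerating the `2^|reserve|` joint burn events of the
#' reserve parcels (each event's probability again hypergeometric).
#'
#' @inheritParams expected_species
#' @return A `coverage_result`: list with `expected_species`,
#'   `outcome_distribution` (named vector over 0..I), `species_survival`,
#'   `p_zero`, `p_all`.
#' @examples
#' ls5 <- build_square_landscape(5, 5, 1)
#' bm <- enumerate_spread_patterns(ls5)
#' sp <- matrix(0L, 25, 2); sp[c(7, 8, 20), ] <- 1L  # three hotspots
#' evaluate_reserve(reserve(c(7, 20)), species_matrix(sp), bm)$expected_species
#' @export
evaluate_reserve <- function(reserve, species, model) {
  ids <- reserve_parcels(reserve)
  I <- ncol(species)
  if (model$representation != "closed_form" && length(model$patterns) == 0L) {
    stop("empty burn model", call. = FALSE)
  }
  if (model$representation != "closed_form" && nrow(species) != model$J) {
    stop(sprintf("species matrix has %d parcels but burn model has J = %d",
                 nrow(species), model$J), call. = FALSE)
  }
  P <- matrix(as.numeric(species), nrow(species), I)

  if (model$representation == "closed_form") {
    res <- closed_form_coverage(ids, P, model, I)
  } else {
    if (length(ids) == 0L) {
      alive <- matrix(FALSE, I, length(model$patterns))
    } else {
      alive <- crossprod(P[ids, , drop = FALSE],
                         model$unburned[ids, , drop = FALSE]) > 0
    }
    p <- model$probabilities
    counts <- colSums(alive)
    dist <- numeric(I + 1L)
    for (b in seq_along(p)) dist[counts[b] + 1L] <- dist[counts[b] + 1L] + p[b]
    res <- list(
      expected_species = sum(p * counts),
      outcome_distribution = stats::setNames(dist, 0:I),
      species_survival = as.numeric(alive %*% p)
    )
  }
  res$p_zero <- res$outcome_distribution[["0"]]
  res$p_all <- res$outcome_distribution[[as.character(I)]]
  class(res) <- "coverage_result"
  res
}

# Exact coverage under the implicit independent model: inclusion of the
# 2^r joint burn events of the reserve parcels. Exactness is certified
# against brute-force subset enumeration for J <= 9 in the test suite.
closed_form_coverage <- function(ids, P, model, I) {
  r <- length(ids)
  if (r > 20L) {
    stop("closed-form outcome distribution enumerates 2^|reserve| events; |reserve| > 20 unsupported",
         call. = FALSE)
  }
  J <- model$J
  n <- as.integer(names(model$sizes))
  q <- model$sizes
  # P(exactly the subset S of the reserve burns) depends only on s = |S|
  w_by_s <- vapply(0:r, function(s) {
    ok <- n >= s & (n - s) <= (J - r)
    sum(q[ok] * choose(J - r, n[ok] - s) / choose(J, n[ok]))
  }, 0)

  dist <- numeric(I + 1L)
  if (r == 0L) {
    dist[1L] <- 1
  } else {
    for (s in 0:r) {
      subs <- if (s == 0L) matrix(integer(0), 0, 1) else utils::combn(r, s)
      for (cix in seq_len(ncol(subs))) {
        keep <- ids[setdiff(seq_len(r), subs[, cix])]
        k <- if (length(keep)) sum(colSums(P[keep, , drop = FALSE]) > 0) else 0L
        dist[k + 1L] <- dist[k + 1L] + w_by_s[s + 1L]
      }
    }
  }
  ri <- if (r) colSums(P[ids, , drop = FALSE]) else numeric(I)
  surv <- vapply(ri, function(k) 1 - closed_form_all_burn(model, k), 0)
  list(
    expected_species = sum(surv),
    outcome_distribution = stats::setNames(dist, 0:I),
    species_survival = surv
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result: E[species] = %.6f, P(zero) = %.6f, P(all) = %.6f>\n",
              x$expected_species, x$p_zero, x$p_all))
  invisible(x)
}

#' Exhaustive search for optimal reserves
#'
#' Enumerates every size-m subset of focal parcels and returns *all*
#' maximizers of the expected number of surviving species (optimization on
#' these landscapes routinely has multiple optima, which are preserved, not
#' tie-broken). By survival monotonicity a reserve of size < m is never
#' strictly better, so only size-m reserves are searched.
#'
#' @param landscape an `rss_landscape`.
#' @param species a [species_matrix()].
#' @param model a `burn_model`.
#' @param m reserve size.
#' @param cap refuse instances with more than this many candidate reserves.
#' @param tol ties in expected species closer than this are co-optimal.
#' @return List of `list(reserve, result)`, sorted lexicographically by
#'   parcel ids.
#' @export
optimize_exact <- function(landscape, species, model, m, cap = 1e7,
                           tol = 1e-9) {
  check_species_landscape(species, landscape)
  m <- assert_count(m, "m")
  J <- landscape$J
  if (m > J) stop(sprintf("m = %d exceeds the %d focal parcels", m, J), call. = FALSE)
  if (choose(J, m) > cap) {
    stop(sprintf("choose(%d, %d) candidate reserves exceed the cap (%g); use anneal()",
                 J, m, cap), call. = FALSE)
  }
  cand <- utils::combn(landscape$focal_ids, m)
  P <- matrix(as.numeric(species), nrow(species), ncol(species))
  vals <- apply(cand, 2L, expected_species_ids, P = P, model = model)
  best <- max(vals)
  win <- which(vals >= best - tol)
  lapply(win, function(ix) {
    r <- reserve(cand[, ix], m = m)
    list(reserve = r, result = evaluate_reserve(r, species, model))
  })
}

#' Secondary risk metrics of a reserve
#'
#' @inheritParams expected_species
#' @return List with `p_zero` (probability no species survives) and `p_all`
#'   (probability all species survive).
#' @export
secondary_metrics <- function(reserve, species, model) {
  res <- evaluate_reserve(reserve, species, model)
  list(p_zero = res$p_zero, p_all = res$p_all)
}

#' Ignition points threatening more than one reserve parcel
#'
#' A dispersion measure complementary to [shared_borders()]: the number of
#' ignition locations from which a single spreading fire burns at least two
#' parcels of the reserve. Non-adjacent reserve parcels still count when a
#' parcel between them can ignite a fire reaching both.
#'
#' @param landscape an `rss_landscape`.
#' @param reserve a [reserve()] or integer vector of focal parcel ids.
#' @return Integer count of such ignition locations.
#' @export
multi_burn_ignitions <- function(landscape, reserve) {
  ids <- reserve_parcels(reserve)
  inres <- logical(landscape$n_parcels)
  inres[ids] <- TRUE
  sum(vapply(landscape$ignition_domain, function(ign) {
    sum(inres[spread_burn(landscape, ign)$burned]) >= 2L
  }, FALSE))
}

#' Percentage gain of the spatially-aware reserve over a naive one
#'
#' @param expected_spatial expected species of the reserve chosen with
#'   spatially-correlated risk in view.
#' @param expected_naive expected species (under the correlated model) of the
#'   reserve a non-spatial manager would choose.
#' @return `100 * (expected_spatial - expected_naive) / expected_naive`.
#' @export
percent_gain <- function(expected_spatial, expected_naive) {
  if (!is.numeric(expected_naive) || expected_naive <= 0) {
    stop("`expected_naive` must be positive", call. = FALSE)
  }
  100 * (expected_spatial - expected_naive) / expected_naive
}
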