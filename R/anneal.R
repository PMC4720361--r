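#' Simulated annealing for large landscapes
#'
#' Exhaustive search is infeasible beyond a few dozen parcels (choosing 30 of
#' 289 hexagons admits ~10^41 reserves), so large instances are solved with
#' simulated annealing: start from a random size-m reserve, repeatedly swap
#' one parcel out and one in, accept improvements always and deteriorations
#' with the Metropolis probability `exp(delta / T)`, and cool the temperature
#' geometrically. The best reserve ever visited is tracked and returned.
#'
#' @name annealing
NULL

#' Annealing configuration
#'
#' @param initial_temperature starting temperature (default 10).
#' @param cooling_rate geometric cooling factor per iteration, in (0,1)
#'   (default 0.995).
#' @param n_burn_sims fires per sampled burn model (default 500).
#' @param max_iterations number of swap proposals (default 2000; with the
#'   default schedule the end temperature is 10 * 0.995^2000 ~ 4e-4, an
#'   effectively greedy endgame).
#' @param resample_each_step if `TRUE`, and a model factory is supplied, a
#'   fresh set of fire simulations is drawn for every candidate evaluation;
#'   the default keeps one fixed burn model across the whole search (common
#'   random numbers) for variance reduction and exact reproducibility.
#' @param temperature_floor stop when the temperature falls below this.
#' @param seed integer seed governing the entire run.
#' @export
annealing_config <- function(initial_temperature = 10,
                             cooling_rate = 0.995,
                             n_burn_sims = 500,
                             max_iterations = 2000,
                             resample_each_step = FALSE,
                             temperature_floor = 1e-6,
                             seed = NULL) {
  stopifnot(initial_temperature > 0,
            cooling_rate > 0, cooling_rate < 1,
            n_burn_sims >= 1, max_iterations >= 0)
  structure(list(initial_temperature = initial_temperature,
                 cooling_rate = cooling_rate,
                 n_burn_sims = as.integer(n_burn_sims),
                 max_iterations = as.integer(max_iterations),
                 resample_each_step = isTRUE(resample_each_step),
                 temperature_floor = temperature_floor,
                 seed = seed),
            class = "annealing_config")
}

#' Random initial reserve
#'
#' @param landscape an `rss_landscape`.
#' @param m reserve size.
#' @param seed optional integer seed.
#' @return A [reserve()] of `m` parcels drawn uniformly without replacement
#'   from the focal parcels.
#' @export
initial_reserve <- function(landscape, m, seed = NULL) {
  m <- assert_count(m, "m")
  if (m > landscape$J) {
    stop(sprintf("m = %d exceeds the %d focal parcels", m, landscape$J),
         call. = FALSE)
  }
  with_seed_opt(seed, reserve(sample(landscape$focal_ids, m), m = m))
}

#' One swap move
#'
#' Removes a uniformly chosen reserve parcel and adds a uniformly chosen
#' non-reserve focal parcel; the reserve size is preserved. Uses the current
#' RNG stream (the annealer seeds it once per run).
#'
#' @param reserve a [reserve()] or integer vector of focal parcel ids.
#' @param landscape an `rss_landscape`.
#' @return A new [reserve()] differing from the input in exactly two parcels.
#' @export
swap_move <- function(reserve, landscape) {
  ids <- reserve_parcels(reserve)
  m <- if (inherits(reserve, "reserve")) attr(reserve, "m") else length(ids)
  out_pool <- setdiff(landscape$focal_ids, ids)
  if (length(ids) == 0L || length(out_pool) == 0L) {
    stop("swap requires 0 < |reserve| < J", call. = FALSE)
  }
  drop_ix <- if (length(ids) == 1L) 1L else sample.int(length(ids), 1L)
  add <- if (length(out_pool) == 1L) out_pool else sample(out_pool, 1L)
  reserve(c(ids[-drop_ix], add), m = m)
}

#' Metropolis acceptance rule
#'
#' Improvements and ties (`delta >= 0`) are always accepted; deteriorations
#' are accepted with the Boltzmann probability `exp(delta / temperature)`.
#' Accepting ties encourages traversal of the plateaus these coverage
#' objectives exhibit.
#'
#' @param delta change in the objective (candidate minus current).
#' @param temperature current temperature, > 0.
#' @return Logical flag.
#' @export
accept <- function(delta, temperature) {
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("`temperature` must be positive", call. = FALSE)
  }
  if (delta >= 0) return(TRUE)
  stats::runif(1L) < exp(delta / temperature)
}

#' Simulated annealing reserve search
#'
#' The seven-step procedure: (1) draw a random initial size-m reserve;
#' (2) evaluate its expected surviving species under the burn model;
#' (3)–(4) propose a swap of one parcel out, one in; (5) evaluate the
#' candidate (optionally on freshly simulated fires); (6) accept by the
#' Metropolis rule, tracking the best reserve so far; (7) cool and repeat.
#'
#' @param landscape an `rss_landscape`.
#' @param species a [species_matrix()].
#' @param model either a fixed `burn_model`, or a factory
#'   `function(seed) -> burn_model` (required when
#'   `config$resample_each_step` is `TRUE`; otherwise called once up front).
#' @param m reserve size.
#' @param config an [annealing_config()].
#' @return A `solve_result`: list with `best_reserve`, `best_value`,
#'   `best_result` (full [evaluate_reserve()] output under the final model),
#'   `initial_reserve`, `model`, and a per-iteration `trace` data frame
#'   (current value, best value, temperature, accepted flag).
#' @examples
#' ls5 <- build_square_landscape(5, 5, 1)
#' bm <- enumerate_spread_patterns(ls5)
#' sp <- matrix(0L, 25, 2); sp[c(7, 8, 20), ] <- 1L
#' fit <- anneal(ls5, species_matrix(sp), bm, m = 2,
#'               config = annealing_config(max_iterations = 500, seed = 1))
#' fit$best_value  # 2: both species certain to survive
#' @export
anneal <- function(landscape, species, model, m,
                   config = annealing_config()) {
  check_species_landscape(species, landscape)
  m <- assert_count(m, "m")
  P <- matrix(as.numeric(species), nrow(species), ncol(species))

  with_seed_opt(config$seed, {
    fixed_model <- if (is.function(model)) model(child_seed()) else model
    evalfun <- function(ids) {
      mod <- if (config$resample_each_step && is.function(model)) {
        model(child_seed())
      } else {
        fixed_model
      }
      expected_species_ids(ids, P, mod)
    }

    cur <- initial_reserve(landscape, m)
    cur_val <- evalfun(reserve_parcels(cur))
    best <- cur
    best_val <- cur_val
    init <- cur

    n_it <- config$max_iterations
    trace <- data.frame(iteration = integer(n_it), current = numeric(n_it),
                        best = numeric(n_it), temperature = numeric(n_it),
                        accepted = logical(n_it))
    temp <- config$initial_temperature
    it <- 0L
    while (it < n_it && temp >= config$temperature_floor) {
      it <- it + 1L
      cand <- swap_move(cur, landscape)
      cand_val <- evalfun(reserve_parcels(cand))
      acc <- accept(cand_val - cur_val, temp)
      if (acc) {
        cur <- cand
        cur_val <- cand_val
        if (cand_val > best_val) {
          best <- cand
          best_val <- cand_val
        }
      }
      trace[it, ] <- list(it, cur_val, best_val, temp, acc)
      temp <- temp * config$cooling_rate
    }
    trace <- trace[seq_len(it), , drop = FALSE]

    # full outcome distribution is infeasible for closed-form models with
    # large reserves (2^m events); fall back to the expectation
    best_result <- tryCatch(evaluate_reserve(best, species, fixed_model),
                            error = function(e) {
                              structure(list(expected_species = best_val,
                                             outcome_distribution = NULL,
                                             species_survival = NULL,
                                             p_zero = NA_real_, p_all = NA_real_),
                                        class = "coverage_result")
                            })
    structure(list(
      best_reserve = best,
      best_value = best_val,
      best_result = best_result,
      initial_reserve = init,
      model = fixed_model,
      config = config,
      trace = trace
    ), class = "solve_result")
  })
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("<solve_result: best E[species] = %.4f over %d iterations>\n",
              x$best_value, nrow(x$trace)))
  cat(sprintf("  best reserve: {%s}\n",
              paste(reserve_parcels(x$best_reserve), collapse = ",")))
  invisible(x)
}
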