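test_that("species survive iff an unburned reserve parcel holds them", {
  sp <- hotspot_species()
  both <- spread_burn(stylized_landscape(), 7L) # burns 7 and 8, not 20
  expect_equal(species_surviving(reserve(c(7L, 20L)), sp, both), c(1L, 2L))
  allburn <- list(burned = c(7L, 20L), probability = 1, ignitions = integer(0))
  expect_length(species_surviving(reserve(c(7L, 20L)), sp, allburn), 0L)
  expect_length(species_surviving(integer(0), sp, both), 0L)
})

test_that("no-hotspot pair reserves reproduce the three printed configurations", {
  ls5 <- stylized_landscape()
  bm <- stylized_model(ls5)
  cases <- list(
    adjacent = list(pair = c(12L, 13L), dist = c(6, 6, 37) / 49),
    separated_by_one = list(pair = c(11L, 13L), dist = c(3, 12, 34) / 49),
    separated_by_more = list(pair = c(11L, 15L), dist = c(0, 18, 31) / 49)
  )
  for (case in cases) {
    res <- evaluate_reserve(reserve(case$pair), pair_species(case$pair), bm)
    expect_equal(unname(res$outcome_distribution), case$dist, tolerance = 1e-12)
    expect_equal(res$expected_species, 80 / 49, tolerance = 1e-12)
    # linearity: expectation equals the sum of per-species survival
    expect_equal(sum(res$species_survival), res$expected_species, tolerance = 1e-12)
    sm <- secondary_metrics(reserve(case$pair), pair_species(case$pair), bm)
    expect_equal(sm$p_zero, case$dist[1L], tolerance = 1e-12)
    expect_equal(sm$p_all, case$dist[3L], tolerance = 1e-12)
  }
})

test_that("expected species is invariant to pair placement for no-hotspot reserves", {
  ls5 <- stylized_landscape()
  bm <- stylized_model(ls5)
  set.seed(101)
  for (rep in 1:25) {
    pair <- sample(25L, 2L)
    res <- evaluate_reserve(reserve(pair), pair_species(pair), bm)
    expect_equal(res$expected_species, 80 / 49, tolerance = 1e-12)
  }
})

test_that("hotspot-pair reserves reproduce the printed values", {
  bm <- stylized_model()
  sp <- hotspot_species()
  r720 <- evaluate_reserve(reserve(c(7L, 20L)), sp, bm)
  expect_equal(r720$expected_species, 2, tolerance = 1e-12)
  expect_equal(r720$p_all, 1, tolerance = 1e-12)
  expect_equal(r720$p_zero, 0, tolerance = 1e-12)

  r78 <- evaluate_reserve(reserve(c(7L, 8L)), sp, bm)
  expect_equal(r78$expected_species, 86 / 49, tolerance = 1e-12)   # 1.755102
  expect_equal(r78$p_all, 43 / 49, tolerance = 1e-12)              # 0.877551
  expect_equal(r78$p_zero, 6 / 49, tolerance = 1e-12)              # 0.122449

  r820 <- evaluate_reserve(reserve(c(8L, 20L)), sp, bm)
  expect_equal(r820$expected_species, 96 / 49, tolerance = 1e-12)  # 1.959184
  expect_equal(r820$p_all, 48 / 49, tolerance = 1e-12)
  expect_equal(r820$p_zero, 1 / 49, tolerance = 1e-12)
})

test_that("exact solver finds the unique correlated optimum and all independent ties", {
  ls5 <- stylized_landscape()
  bm <- stylized_model(ls5)
  sp <- hotspot_species()

  oc <- optimize_exact(ls5, sp, bm, 2)
  expect_length(oc, 1L)
  expect_equal(reserve_parcels(oc[[1L]]$reserve), c(7L, 20L))
  expect_equal(oc[[1L]]$result$expected_species, 2, tolerance = 1e-12)

  ind <- independent_model_closed_form(25, size_distribution(bm))
  oi <- optimize_exact(ls5, sp, ind, 2)
  expect_equal(lapply(oi, function(o) reserve_parcels(o$reserve)),
               list(c(7L, 8L), c(7L, 20L), c(8L, 20L)))
  vals <- vapply(oi, function(o) o$result$expected_species, 0)
  expect_true(all(abs(vals - vals[1L]) < 1e-12))

  # single species on one parcel: that parcel is optimal at m = 1
  sp1 <- species_matrix(matrix(as.integer(1:25 == 9L), 25L, 1L))
  o1 <- optimize_exact(ls5, sp1, bm, 1)
  expect_equal(reserve_parcels(o1[[1L]]$reserve), 9L)

  expect_error(optimize_exact(ls5, sp, bm, 26), "exceeds")
  expect_error(optimize_exact(ls5, sp, bm, 2, cap = 10), "cap")
})

test_that("closed-form evaluation equals brute-force subset enumeration (J <= 9)", {
  for (dims in list(c(3, 3), c(2, 4))) {
    ls <- build_square_landscape(dims[1], dims[2], 1)
    q <- size_distribution(enumerate_spread_patterns(ls))
    ind <- independent_model_closed_form(ls$J, q)
    brute <- brute_force_independent(ls, q)
    set.seed(7)
    for (rep in 1:10) {
      sp <- random_species_distribution(ls, n_species = 3,
                                        parcels_per_species = min(3L, ls$J))
      r <- reserve(sample(ls$focal_ids, min(3L, ls$J)))
      a <- evaluate_reserve(r, sp, ind)
      b <- evaluate_reserve(r, sp, brute)
      expect_equal(a$expected_species, b$expected_species, tolerance = 1e-12)
      expect_equal(a$outcome_distribution, b$outcome_distribution, tolerance = 1e-12)
      expect_equal(a$species_survival, b$species_survival, tolerance = 1e-12)
    }
  }
})

test_that("adding a parcel never decreases expected species", {
  ls5 <- stylized_landscape()
  bm <- stylized_model(ls5)
  ind <- independent_model_closed_form(25, size_distribution(bm))
  set.seed(33)
  for (rep in 1:10) {
    sp <- random_species_distribution(ls5, 2, 5)
    base <- sample(25L, 3L)
    extra <- sample(setdiff(1:25, base), 1L)
    for (model in list(bm, ind)) {
      expect_gte(expected_species(c(base, extra), sp, model),
                 expected_species(base, sp, model) - 1e-12)
    }
  }
})

test_that("expected species is invariant under grid symmetry", {
  ls5 <- stylized_landscape()
  bm <- stylized_model(ls5)
  # 180-degree rotation maps focal id j to 26 - j
  rot <- function(ids) 26L - ids
  set.seed(44)
  for (rep in 1:10) {
    sp <- random_species_distribution(ls5, 2, 5)
    spr <- species_matrix(unclass(sp)[rot(1:25), , drop = FALSE])
    r <- sample(25L, 2L)
    expect_equal(expected_species(r, sp, bm),
                 expected_species(sort(rot(r)), spr, bm), tolerance = 1e-12)
  }
})

test_that("multi-burn ignition counts match the pairwise burn probabilities", {
  ls5 <- stylized_landscape()
  expect_equal(multi_burn_ignitions(ls5, c(12L, 13L)), 6L)
  expect_equal(multi_burn_ignitions(ls5, c(11L, 13L)), 3L)
  expect_equal(multi_burn_ignitions(ls5, c(11L, 15L)), 0L)
  # consistency: count/49 equals P(zero) for one-species-per-parcel pairs
  bm <- stylized_model(ls5)
  for (pair in list(c(12L, 13L), c(11L, 13L), c(11L, 15L))) {
    res <- evaluate_reserve(reserve(pair), pair_species(pair), bm)
    expect_equal(multi_burn_ignitions(ls5, pair) / 49, res$p_zero, tolerance = 1e-12)
  }
})

test_that("percent gain recovers the printed 14% and rejects bad baselines", {
  expect_equal(percent_gain(2, 86 / 49), 700 / 43 * 6 / 7, tolerance = 1e-9)
  expect_equal(round(percent_gain(2, 86 / 49)), 14)
  expect_equal(percent_gain(1.5, 1.5), 0)
  expect_equal(percent_gain(96 / 49, 86 / 49), 100 * 10 / 86, tolerance = 1e-12)
  expect_error(percent_gain(2, 0), "positive")
})
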