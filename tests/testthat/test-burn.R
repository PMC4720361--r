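test_that("spread burns are the ignition's focal queen neighborhood", {
  ls5 <- stylized_landscape()
  corner <- which(ls5$row == 1L & ls5$col == 1L)    # outer buffer corner
  expect_length(spread_burn(ls5, corner)$burned, 1L)
  midside <- which(ls5$row == 1L & ls5$col == 4L)   # center of a buffer side
  expect_length(spread_burn(ls5, midside)$burned, 3L)
  expect_length(spread_burn(ls5, 13L)$burned, 9L)   # focal center
  expect_equal(spread_burn(ls5, 13L)$burned, c(7L, 8L, 9L, 12L, 13L, 14L, 17L, 18L, 19L))
})

test_that("enumeration gives the 49-pattern correlated model", {
  bm <- stylized_model()
  expect_length(bm$patterns, 49L)
  expect_true(all(abs(bm$probabilities - 1 / 49) < 1e-15))
  expect_equal(sum(bm$probabilities), 1, tolerance = 1e-12)

  sizes <- vapply(bm$patterns, function(b) length(b$burned), 0L)
  expect_equal(sum(sizes), 225L)
  expect_equal(as.vector(table(sizes)), c(4L, 8L, 12L, 4L, 12L, 9L))
  expect_equal(sort(unique(sizes)), c(1L, 2L, 3L, 4L, 6L, 9L))

  expect_equal(expected_burned(bm), 225 / 49)

  tiny <- build_square_landscape(1, 1, 0)
  bt <- enumerate_spread_patterns(tiny)
  expect_length(bt$patterns, 1L)
  expect_equal(bt$patterns[[1L]]$burned, 1L)
})

test_that("burn-size multiset is invariant under the grid's symmetries", {
  # the size distribution from row-major enumeration must match the one from
  # a transposed landscape (reflection) and from re-enumeration
  q <- size_distribution(stylized_model())
  q2 <- size_distribution(enumerate_spread_patterns(build_square_landscape(5, 5, 1)))
  expect_equal(q, q2)
  qr <- size_distribution(enumerate_spread_patterns(build_square_landscape(3, 5, 1)))
  qc <- size_distribution(enumerate_spread_patterns(build_square_landscape(5, 3, 1)))
  expect_equal(qr, qc)
})

test_that("size distribution matches the enumerated pattern counts", {
  q <- size_distribution(stylized_model())
  expect_equal(q[["1"]], 4 / 49)
  expect_equal(q[["2"]], 8 / 49)
  expect_equal(q[["3"]], 12 / 49)
  expect_equal(q[["4"]], 4 / 49)
  expect_equal(q[["6"]], 12 / 49)
  expect_equal(q[["9"]], 9 / 49)
  expect_false("7" %in% names(q))
  expect_false("8" %in% names(q))
  expect_equal(sum(q), 1, tolerance = 1e-12)

  single <- firereserve:::finalize_burn_model(
    list(list(burned = c(1L, 2L, 3L), probability = 1, ignitions = 1L)),
    "correlated", "enumerated", build_square_landscape(2, 2, 0))
  expect_equal(size_distribution(single), c("3" = 1))
  expect_equal(expected_burned(single), 3)
})

test_that("independent pattern counting uses binomial sums", {
  q <- size_distribution(stylized_model())
  expect_equal(count_independent_patterns(25, q), 2235350)
  expect_equal(count_independent_patterns(25, c("1" = 1)), 25)
  expect_equal(count_independent_patterns(9, c("1" = 0.5, "2" = 0.5)), 45)
  expect_error(count_independent_patterns(5, c("6" = 1)), "1..J")
})

test_that("closed-form independent model matches hypergeometric identities", {
  q <- size_distribution(stylized_model())
  ind <- independent_model_closed_form(25, q)
  # risk equalization: same expected burned area as the correlated model
  expect_equal(expected_burned(ind), 225 / 49, tolerance = 1e-12)
  # P(a fixed parcel burns) = E[burned]/J
  expect_equal(1 - firereserve:::closed_form_all_burn(ind, 0L), 0)
  expect_equal(firereserve:::closed_form_all_burn(ind, 1L), 9 / 49, tolerance = 1e-12)
  # P(two fixed parcels both burn), hypergeometric
  n <- as.integer(names(q))
  expect_equal(firereserve:::closed_form_all_burn(ind, 2L),
               sum(q * choose(23, n - 2) / choose(25, n)), tolerance = 1e-15)
  expect_error(independent_model_closed_form(25, unname(q)), "named")
})

test_that("sampled models are reproducible and size-consistent", {
  hx <- build_hex_landscape(17, 17)
  bm1 <- sample_spread_patterns(hx, 500, seed = 11)
  bm2 <- sample_spread_patterns(hx, 500, seed = 11)
  expect_identical(bm1, bm2)
  expect_length(bm1$patterns, 500L)
  sizes <- vapply(bm1$patterns, function(b) length(b$burned), 0L)
  expect_true(all(sizes >= 3L & sizes <= 7L))
  expect_equal(sum(bm1$probabilities), 1, tolerance = 1e-12)

  one <- sample_spread_patterns(hx, 1, seed = 2)
  expect_length(one$patterns, 1L)
  expect_equal(one$patterns[[1L]]$probability, 1)
})

test_that("matched independent sampling equalizes risk exactly", {
  hx <- build_hex_landscape(17, 17)
  corr <- sample_spread_patterns(hx, 200, seed = 5)
  ind <- sample_matched_independent_patterns(hx, corr, seed = 6)
  expect_length(ind$patterns, 200L)
  sz <- function(m) sort(vapply(m$patterns, function(b) length(b$burned), 0L))
  expect_equal(sz(ind), sz(corr))
  expect_equal(expected_burned(ind), expected_burned(corr))
  expect_identical(ind, sample_matched_independent_patterns(hx, corr, seed = 6))

  # whole-landscape burn has a unique matched pattern
  tiny <- build_square_landscape(1, 2, 0)
  full <- firereserve:::finalize_burn_model(
    list(list(burned = 1:2, probability = 1, ignitions = 1L)),
    "correlated", "enumerated", tiny)
  m <- sample_matched_independent_patterns(tiny, full, seed = 1)
  expect_equal(m$patterns[[1L]]$burned, 1:2)
})

test_that("burn models round-trip through JSON", {
  ls3 <- build_square_landscape(3, 3, 1)
  bm <- enumerate_spread_patterns(ls3)
  path <- withr::local_tempfile(fileext = ".json")
  write_burn_model(bm, path)
  back <- read_burn_model(path, ls3)
  expect_equal(back$patterns, bm$patterns)
  expect_equal(back$unburned, bm$unburned)

  ind <- independent_model_closed_form(9, size_distribution(bm))
  write_burn_model(ind, path)
  back <- read_burn_model(path)
  expect_equal(back$sizes, ind$sizes)
  expect_equal(expected_burned(back), expected_burned(bm), tolerance = 1e-12)
})
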