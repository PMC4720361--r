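# Shared fixtures: the stylized 5x5 landscape with one-parcel buffer, its
# enumerated correlated model, and the three-hotspot species layout.

stylized_landscape <- function() build_square_landscape(5, 5, 1)

stylized_model <- function(landscape = stylized_landscape()) {
  enumerate_spread_patterns(landscape)
}

# both species on parcels 7, 8 and 20 (three hotspots, 7-8 adjacent)
hotspot_species <- function() {
  sp <- matrix(0L, 25L, 2L)
  sp[c(7L, 8L, 20L), ] <- 1L
  species_matrix(sp)
}

# two species, one on each of a pair of parcels (no hotspot)
pair_species <- function(pair, J = 25L) {
  sp <- matrix(0L, J, 2L)
  sp[pair[1L], 1L] <- 1L
  sp[pair[2L], 2L] <- 1L
  species_matrix(sp)
}

# brute-force independent model: every size-n subset materialized with
# weight q_n / choose(J, n) -- the oracle for closed-form evaluation
brute_force_independent <- function(landscape, sizes) {
  J <- landscape$J
  pats <- list()
  for (n in as.integer(names(sizes))) {
    subs <- utils::combn(J, n)
    w <- sizes[[as.character(n)]] / ncol(subs)
    for (cix in seq_len(ncol(subs))) {
      pats[[length(pats) + 1L]] <-
        list(burned = subs[, cix], probability = w, ignitions = integer(0))
    }
  }
  firereserve:::finalize_burn_model(pats, "independent", "enumerated", landscape)
}
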