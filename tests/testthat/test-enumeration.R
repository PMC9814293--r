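small_selected <- function() {
  memo("small_selected", {
    sys <- get_small()
    designs <- grow_all(init_edesigns(sys$headpieces, sys$ontology),
                        sys$reactions, sys$bbts, sys$matrices, n_cycles = 2L)
    designs <- finalize_designs(designs, sys$ontology$disallowed_final)
    libs <- group_libdesigns(designs, sys$reactions)
    select_libdesigns(libs, sys$proc, sys$reactions, min_size = 5,
                      target_median = 29L)
  })
}

test_that("enumeration configs respect caps and round-trip through JSON", {
  sys <- get_small()
  sel <- small_selected()
  lib <- sel[[1]]
  cfg <- enum_config(lib, sys$proc, sys$reactions, sys$ontology)
  # every listed building block obeys its node's heavy-atom cap
  for (ci in seq_along(cfg$steps))
    expect_true(all(cfg$steps[[ci]]$bbs$eff_ha <= lib$selection[ci]))
  # a tightened cap excludes the heaviest building blocks
  tight <- lib
  tight$selection <- pmax(lib$selection - 3L, 5L)
  cfg_tight <- enum_config(tight, sys$proc, sys$reactions, sys$ontology)
  for (ci in seq_along(cfg_tight$steps)) {
    expect_true(all(cfg_tight$steps[[ci]]$bbs$eff_ha <= tight$selection[ci]))
    expect_lte(nrow(cfg_tight$steps[[ci]]$bbs), nrow(cfg$steps[[ci]]$bbs))
  }
  # round trip
  path <- tempfile(fileext = ".json")
  write_enum_config(cfg, path)
  back <- read_enum_config(path)
  expect_identical(back$libdesign_id, cfg$libdesign_id)
  expect_identical(back$ha_shift, cfg$ha_shift)
  expect_identical(length(back$steps), length(cfg$steps))
  for (ci in seq_along(cfg$steps)) {
    expect_identical(back$steps[[ci]]$bbs, cfg$steps[[ci]]$bbs)
    expect_identical(back$steps[[ci]]$deprot_rxn, cfg$steps[[ci]]$deprot_rxn)
  }
  # an unpopulated node is an error naming the cycle
  starved <- lib
  starved$selection <- c(1L, 1L)
  expect_error(enum_config(starved, sys$proc, sys$reactions, sys$ontology),
               "cycle 1")
})

test_that("single transforms reproduce worked synthesis steps", {
  rx <- get_reactions()
  # amidation of the headpiece amine with acetic acid: 4 + (4 - 1) atoms
  p <- apply_transform("NCCO", rx["amide_amine_on_design_prim", ], "CC(=O)O")
  expect_identical(attr(p, "natoms"), 7L)
  expect_identical(standardize_smiles(p)$canonical_smiles,
                   standardize_smiles("CC(=O)NCCO")$canonical_smiles)
  # Boc removal frees the amine, 7 atoms lighter
  p2 <- apply_transform("CC(C)(C)OC(=O)NCCO", rx["boc_removal", ])
  expect_identical(attr(p2, "natoms"), 4L)
  # cyanuric chloride capping: amine -> dichlorotriazine, +8 atoms
  p3 <- apply_transform("NCCO", rx["triazine_scaffold", ])
  expect_identical(attr(p3, "natoms"), 12L)
  # the triazine cap is annotated (plus the weakly basic triazinyl N-H)
  expect_true(deldesign:::fg_id(get_ontology(), "dichlorotriazine") %in%
                annotate_fgs(c(x = p3), get_ontology())[[1]])
  # no matching site is a failure
  expect_error(apply_transform("CCCC", rx["boc_removal", ]), "no_match")
})

test_that("sampling is seeded, uniform and exhaustive at full size", {
  sys <- get_small()
  cfg <- enum_config(small_selected()[[1]], sys$proc, sys$reactions,
                     sys$ontology)
  N <- deldesign:::library_size(cfg)
  # full enumeration: every provenance tuple exactly once
  expect_warning(full <- sample_products(cfg, N + 5L, seed = 2L), "full library")
  expect_identical(nrow(full), as.integer(N))
  expect_identical(anyDuplicated(full$provenance), 0L)
  # byte-identical under one seed, different under another
  a <- sample_products(cfg, 10L, seed = 5L)
  b <- sample_products(cfg, 10L, seed = 5L)
  cc <- sample_products(cfg, 10L, seed = 6L)
  expect_identical(a, b)
  expect_false(identical(a$provenance, cc$provenance))
  # provenance-only sampling agrees with the structure path on predictions
  fast <- sample_products(cfg, 10L, seed = 5L, structures = FALSE)
  expect_identical(fast$provenance, a$provenance)
  expect_identical(fast$predicted_ha, a$predicted_ha)
})

test_that("replacement-free batches draw each product uniformly", {
  # synthetic 100-product two-node config; no chemistry needed
  cfg <- structure(list(
    libdesign_id = "U", key = "u", ha_shift = 4L,
    headpiece = list(fg = "x", smiles = "NCCO", atoms = 4L),
    steps = list(
      list(cycle = 1L, deprot_rxn = NA_character_,
           deprot_transform = NA_character_,
           bbs = data.frame(bb_id = sprintf("a%02d", 1:10), smiles = "",
                            bbt = "3.0.0", eff_ha = 5L, conn_rxn = "r",
                            transform = "", stringsAsFactors = FALSE)),
      list(cycle = 2L, deprot_rxn = NA_character_,
           deprot_transform = NA_character_,
           bbs = data.frame(bb_id = sprintf("b%02d", 1:10), smiles = "",
                            bbt = "6.0.0", eff_ha = 6L, conn_rxn = "r",
                            transform = "", stringsAsFactors = FALSE)))),
    class = "del_enum_config")
  counts <- integer(100)
  n_batches <- 200L
  for (k in seq_len(n_batches)) {
    s <- sample_products(cfg, 10L, seed = 1000L + k, structures = FALSE)
    expect_identical(anyDuplicated(s$provenance), 0L)
    idx <- match(s$provenance,
                 as.vector(outer(sprintf("a%02d", 1:10),
                                 sprintf("b%02d", 1:10),
                                 function(x, y) paste(x, y, sep = ";"))))
    counts[idx] <- counts[idx] + 1L
  }
  # chi-square goodness of fit against uniform occupancy
  expected <- n_batches * 10L / 100L
  chi2 <- sum((counts - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 99))
  # and no product starved or flooded beyond binomial 4-sigma
  sd4 <- 4 * sqrt(n_batches * 0.1 * 0.9)
  expect_true(all(abs(counts - expected) < sd4))
})

test_that("every sampled product matches the convolution model's atom count", {
  sys <- get_small()
  sel <- small_selected()
  for (lib in sel) {
    cfg <- enum_config(lib, sys$proc, sys$reactions, sys$ontology)
    xs <- sample_products(cfg, min(30L, deldesign:::library_size(cfg)),
                          seed = 11L)
    expect_identical(xs$heavy_atoms, xs$predicted_ha)
    # and the sampled sizes live inside the convolved histogram's support
    h <- lib$ha_histogram
    expect_true(all(xs$predicted_ha %in% deldesign:::hist_values(h)))
  }
})
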