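test_that("designs sharing topology and enum indices merge into one library", {
  rx <- get_reactions()
  acid <- 6L; prim <- 3L; sec <- 4L
  hp <- deldesign:::new_edesign(acid)
  d_prim <- apply_connection(hp, rx["amide_acid_on_design_prim", ], c(prim, 0L, 0L))
  d_sec <- apply_connection(hp, rx["amide_acid_on_design_sec", ], c(sec, 0L, 0L))
  libs <- group_libdesigns(list(d_prim, d_sec), rx)
  # same enum index -> one libDESIGN with two BBTs at the node
  expect_length(libs, 1L)
  expect_identical(nrow(libs[[1]]$nodes[[1]]), 2L)
  # a different enum index separates
  d_other <- apply_connection(deldesign:::new_edesign(prim),
                              rx["amide_amine_on_design_prim", ], c(acid, 0L, 0L))
  libs2 <- group_libdesigns(list(d_prim, d_sec, d_other), rx)
  expect_length(libs2, 2L)
})

test_that("grouping is a partition of the design set", {
  sys <- get_small()
  designs <- grow_all(init_edesigns(sys$headpieces, sys$ontology),
                      sys$reactions, sys$bbts, sys$matrices, n_cycles = 2L)
  libs <- group_libdesigns(designs, sys$reactions)
  members <- unlist(lapply(libs, `[[`, "members"))
  expect_identical(sort(members),
                   sort(vapply(designs, `[[`, character(1), "trace")))
  expect_identical(anyDuplicated(members), 0L)
  expect_lte(length(libs), length(designs))
})

test_that("BBT histograms count effective heavy atoms", {
  rx <- get_reactions()
  bbs <- mk_bbs(c("a", "b", "c"), rep("3.0.0", 3), c(5L, 5L, 8L))
  h <- bbt_ha_histogram("3.0.0", bbs, rx["amide_acid_on_design_prim", ])
  expect_identical(h, c(`5` = 2, `8` = 1))
  expect_identical(sum(h), 3)      # conservation
  # bb-side delta shifts the histogram (acid loses its hydroxyl)
  h2 <- bbt_ha_histogram("6.0.0", mk_bbs("d", "6.0.0", 10L),
                         rx["amide_amine_on_design_prim", ])
  expect_identical(h2, c(`9` = 1))
  expect_identical(bbt_ha_histogram("9.0.0", bbs, rx[1, ]), numeric(0))
})

test_that("convolution obeys the product rule and matches enumeration", {
  rx <- get_reactions()
  bi_sizes <- c(6L, 7L, 7L, 9L, 12L)
  mono_sizes <- c(4L, 5L, 8L, 8L, 10L, 11L)
  bbs <- two_cycle_bbs(bi_sizes, mono_sizes)
  lib <- two_cycle_amide_lib(rx)
  h <- convolve_design_ha(lib, bbs, rx, headpiece_atoms = 4L)
  # totals: product of per-cycle counts
  expect_identical(sum(h), 5 * 6)
  # exact equality with exhaustive enumeration of all size pairs:
  # each acid loses one atom on coupling; headpiece contributes 4
  want <- table(outer(bi_sizes - 1L, mono_sizes - 1L, `+`) + 4L)
  expect_identical(as.numeric(h[names(want)]), as.numeric(want))
  expect_identical(sum(h), sum(want) * 1.0)
  # single-cycle library: node histogram shifted by headpiece + deltas
  hp <- deldesign:::new_edesign(3L)
  d1 <- apply_connection(hp, rx["amide_amine_on_design_prim", ], c(3L, 6L, 0L))
  lib1 <- group_libdesigns(list(d1), rx)[[1]]
  h1 <- convolve_design_ha(lib1, bbs, rx, headpiece_atoms = 4L)
  node <- bbt_ha_histogram("3.6.0", bbs, rx["amide_amine_on_design_prim", ])
  expect_identical(h1, deldesign:::hist_shift(node, 4L))
  # empty node flagged
  h0 <- convolve_design_ha(lib, bbs[0, ], rx)
  expect_length(h0, 0L)
  expect_identical(attr(h0, "empty_node"), 1:2)
})

test_that("random toy libraries convolve exactly like brute force", {
  rx <- get_reactions()
  set.seed(99)
  for (rep in 1:4) {
    s1 <- sample(5:20, sample(3:12, 1), replace = TRUE)
    s2 <- sample(5:20, sample(3:12, 1), replace = TRUE)
    bbs <- two_cycle_bbs(s1, s2)
    lib <- two_cycle_amide_lib(rx)
    h <- convolve_design_ha(lib, bbs, rx, headpiece_atoms = 4L)
    want <- table(oracle_product_sizes(list(s1 - 1L, s2 - 1L), 4L))
    expect_identical(as.numeric(h[names(want)]), as.numeric(want))
    expect_identical(sum(h), sum(want) * 1.0)
  }
})

test_that("size maximization is exact on the cap lattice and monotone", {
  rx <- get_reactions()
  set.seed(7)
  for (rep in 1:4) {
    s1 <- sample(6:24, 18, replace = TRUE)
    s2 <- sample(6:24, 15, replace = TRUE)
    bbs <- two_cycle_bbs(s1, s2)
    lib <- two_cycle_amide_lib(rx)
    sized <- maximize_size(lib, bbs, rx, target_median = 28L,
                           headpiece_atoms = 4L)
    want <- oracle_max_size(list(s1 - 1L, s2 - 1L), 4L, 28L)
    expect_identical(sized$max_size, as.numeric(want$max_size))
    if (sized$feasible) {
      expect_lte(sized$median_ha, 28L)
      expect_identical(sized$median_ha, as.integer(want$median))
      expect_identical(sum(sized$ha_histogram), sized$max_size)
    }
    # tightening the target never increases the achievable size
    tighter <- maximize_size(lib, bbs, rx, target_median = 24L,
                             headpiece_atoms = 4L)
    expect_lte(tighter$max_size, sized$max_size)
    # an unrestrictive target keeps the whole library
    loose <- maximize_size(lib, bbs, rx, target_median = 60L,
                           headpiece_atoms = 4L)
    expect_identical(loose$max_size, length(s1) * length(s2) * 1.0)
  }
})

test_that("greedy cap descent is feasible and near the exact optimum", {
  rx <- get_reactions()
  set.seed(21)
  s1 <- sample(8:20, 30, replace = TRUE)
  s2 <- sample(8:20, 30, replace = TRUE)
  bbs <- two_cycle_bbs(s1, s2)
  lib <- two_cycle_amide_lib(rx)
  exact <- maximize_size(lib, bbs, rx, target_median = 27L, headpiece_atoms = 4L)
  greedy <- maximize_size(lib, bbs, rx, target_median = 27L,
                          headpiece_atoms = 4L, exact_limit = 1)
  expect_true(greedy$feasible)
  expect_lte(greedy$median_ha, 27L)
  expect_lte(greedy$max_size, exact$max_size)
  # the documented approximation stays close to the optimum here
  expect_gte(greedy$max_size, 0.9 * exact$max_size)
})

test_that("selection filters by achievable size and sorts decreasingly", {
  rx <- get_reactions()
  lib_a <- two_cycle_amide_lib(rx); lib_a$id <- "A"
  bbs_a <- two_cycle_bbs(rep(8L, 10), rep(8L, 10), tag = "a")   # 100 products
  lib_b <- two_cycle_amide_lib(rx); lib_b$id <- "B"
  bbs_b <- two_cycle_bbs(rep(8L, 4), rep(8L, 4), tag = "b")     # 16 products
  sel_a <- select_libdesigns(list(lib_a), bbs_a, rx, min_size = 50,
                             target_median = 40L)
  expect_length(sel_a, 1L)
  expect_identical(sel_a[[1]]$max_size, 100)
  expect_length(select_libdesigns(list(lib_b), bbs_b, rx, min_size = 50,
                                  target_median = 40L), 0L)
  # survivor set equals the brute-force filter over both instances
  sizes <- c(A = 100, B = 16)
  for (min_size in c(1, 20, 1000)) {
    got_a <- length(select_libdesigns(list(lib_a), bbs_a, rx, min_size,
                                      target_median = 40L))
    got_b <- length(select_libdesigns(list(lib_b), bbs_b, rx, min_size,
                                      target_median = 40L))
    expect_identical(c(got_a, got_b),
                     as.integer(c(sizes["A"] >= min_size, sizes["B"] >= min_size)))
  }
})
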