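test_that("initialization creates one design per distinct headpiece FG", {
  ont <- get_ontology()
  d <- init_edesigns("amine_aliphatic_primary", ont)
  expect_length(d, 1L)
  expect_identical(d[[1]]$live, deldesign:::fg_id(ont, "amine_aliphatic_primary"))
  expect_length(init_edesigns(c(3L, 6L, 7L), ont), 3L)
  expect_warning(d2 <- init_edesigns(c(3L, 3L), ont), "duplicate")
  expect_length(d2, 1L)
  expect_error(init_edesigns(999L, ont), "999")
})

test_that("deprotections rewrite live FGs and record scaffold atoms", {
  ont <- get_ontology(); rx <- get_reactions()
  boc <- deldesign:::fg_id(ont, "boc_amine")
  prim <- deldesign:::fg_id(ont, "amine_aliphatic_primary")
  dct <- deldesign:::fg_id(ont, "dichlorotriazine")
  d <- deldesign:::new_edesign(boc)
  d2 <- apply_deprotection(d, rx["boc_removal", ])
  expect_identical(d2$live, prim)
  expect_identical(d2$edges[[1]]$scaffold, 0L)
  # the original design is untouched (pure operation)
  expect_identical(d$live, boc)
  # cyanuric chloride capping: amine -> dichlorotriazine, 8 scaffold atoms
  d3 <- apply_deprotection(deldesign:::new_edesign(prim),
                           rx["triazine_scaffold", ])
  expect_identical(d3$live, dct)
  expect_identical(d3$edges[[1]]$scaffold, 8L)
  expect_error(apply_deprotection(d3, rx["boc_removal", ]), "fg_not_available")
})

test_that("connections consume FGs and inherit spectators and outputs", {
  ont <- get_ontology(); rx <- get_reactions()
  acid <- deldesign:::fg_id(ont, "carboxylic_acid")
  prim <- deldesign:::fg_id(ont, "amine_aliphatic_primary")
  dct <- deldesign:::fg_id(ont, "dichlorotriazine")
  mct <- deldesign:::fg_id(ont, "monochlorotriazine")
  phe <- deldesign:::fg_id(ont, "phenol")
  # amide formation consumes both sides; the amide is not a tracked FG
  d <- apply_connection(deldesign:::new_edesign(acid),
                        rx["amide_acid_on_design_prim", ], c(prim, 0L, 0L))
  expect_identical(d$live, integer(0))
  # SNAr on a dichlorotriazine emits a monochlorotriazine
  d2 <- apply_connection(deldesign:::new_edesign(dct),
                         rx["snar_triazine_phenol", ], c(phe, 0L, 0L))
  expect_identical(d2$live, mct)
  # a bifunctional BB leaves its spectator FG live
  d3 <- apply_connection(deldesign:::new_edesign(acid),
                         rx["amide_acid_on_design_prim", ],
                         canonical_bbt(c(prim, acid), ont))
  expect_identical(d3$live, acid)
})

test_that("reaction-FG matrices veto on- and off-DNA contexts asymmetrically", {
  ont <- get_ontology(); rx <- get_reactions()
  acid <- deldesign:::fg_id(ont, "carboxylic_acid")
  prim <- deldesign:::fg_id(ont, "amine_aliphatic_primary")
  thiol <- deldesign:::fg_id(ont, "thiol")
  r <- rx["snar_triazine_amine", ]
  dct <- deldesign:::fg_id(ont, "dichlorotriazine")
  d <- deldesign:::new_edesign(dct)
  # empty matrices: always ok
  expect_true(check_compatibility(d, r, c(prim, thiol, 0L)))
  mat <- get_matrices()
  # thiol blocked when riding in on the BB (off-DNA) ...
  expect_match(check_compatibility(d, r, c(prim, thiol, 0L), mat), "off_dna")
  # ... but a live thiol on the design is tolerated by this reaction
  d_thiol <- d; d_thiol$live <- sort(c(d_thiol$live, thiol))
  expect_true(check_compatibility(d_thiol, r, c(prim, 0L, 0L), mat))
  # live spectator rule: a second primary amine during scaffold capping
  d2 <- deldesign:::new_edesign(prim); d2$live <- c(prim, prim)
  expect_match(check_compatibility(d2, rx["triazine_scaffold", ], NULL, mat),
               "on_dna")
  expect_error(apply_connection(d, r, c(prim, thiol, 0L), mat),
               "off_dna")
})

test_that("single-cycle growth counts BBTs x applicable reactions", {
  ont <- get_ontology()
  rx <- mk_rxns(list(list(rxn_id = "amide", kind = "connecting",
                          design_fg = 3L, bb_fg = 6L, bd = -1L)))
  k <- 4L
  bbts <- cbind(6L, 0L, 0L)[rep(1, k), ]
  bbts[, 2] <- c(0L, 9L, 12L, 13L)  # distinct spectator FGs keep BBTs distinct
  designs <- grow_all(init_edesigns(3L, ont), rx, bbts, n_cycles = 1L)
  expect_length(designs, k)
})

test_that("growth equals brute-force recursion on toy systems", {
  ont <- get_ontology(); mat <- get_matrices()
  sys <- get_small()
  for (nc in 1:3) {
    got <- grow_all(init_edesigns(sys$headpieces, ont), sys$reactions,
                    sys$bbts, sys$matrices, n_cycles = nc)
    want <- oracle_grow(deldesign:::fg_id(ont, sys$headpieces), sys$reactions,
                        sys$bbts, sys$matrices, nc)
    expect_setequal(vapply(got, `[[`, character(1), "trace"), want)
  }
  # richer rule set: matrices active, multiple reactions and headpieces
  rx <- get_reactions()[c("amide_acid_on_design_prim", "amide_amine_on_design_prim",
                          "snar_triazine_amine", "snar_triazine_phenol",
                          "triazine_scaffold", "boc_removal"), ]
  bbts <- rbind(c(3L, 0L, 0L), c(6L, 0L, 0L), c(3L, 6L, 0L), c(9L, 0L, 0L),
                c(6L, 17L, 0L), c(6L, 9L, 0L))
  for (hp in list(3L, 6L, c(3L, 6L))) {
    got <- grow_all(init_edesigns(hp, ont), rx, bbts, mat, n_cycles = 2L)
    want <- oracle_grow(hp, rx, bbts, mat, 2L)
    expect_setequal(vapply(got, `[[`, character(1), "trace"), want)
  }
})

test_that("at most one deprotection is attempted per cycle", {
  ont <- get_ontology()
  # A -> B -> C deprotection chain; only C can connect
  rx <- mk_rxns(list(
    list(rxn_id = "dep1", kind = "deprotection", design_fg = 17L,
         outputs = 18L, enum_index = 101L),
    list(rxn_id = "dep2", kind = "deprotection", design_fg = 18L,
         outputs = 3L, enum_index = 102L),
    list(rxn_id = "conn", kind = "connecting", design_fg = 3L, bb_fg = 6L)))
  bbts <- matrix(c(6L, 0L, 0L), ncol = 3)
  designs <- grow_all(init_edesigns(17L, ont), rx, bbts, n_cycles = 1L)
  expect_length(designs, 0L)  # would need two chained deprotections
})

test_that("adding reactions or BBTs never shrinks the design space", {
  ont <- get_ontology(); mat <- get_matrices()
  rx_full <- get_reactions()
  rx_sub <- rx_full[c("amide_acid_on_design_prim", "amide_amine_on_design_prim"), ]
  bbts_small <- rbind(c(3L, 0L, 0L), c(6L, 0L, 0L))
  bbts_big <- rbind(bbts_small, c(3L, 6L, 0L), c(7L, 0L, 0L))
  n <- function(rx, bbts) length(grow_all(init_edesigns(c(3L, 6L), ont), rx,
                                          bbts, mat, n_cycles = 2L))
  expect_lte(n(rx_sub, bbts_small), n(rx_full, bbts_small))
  expect_lte(n(rx_sub, bbts_small), n(rx_sub, bbts_big))
})

test_that("replaying a trace reproduces the design exactly", {
  sys <- get_small()
  designs <- grow_all(init_edesigns(sys$headpieces, sys$ontology),
                      sys$reactions, sys$bbts, sys$matrices, n_cycles = 2L)
  for (d in designs) {
    r <- deldesign:::replay_edesign(d$trace, sys$reactions, sys$matrices)
    expect_identical(r$live, d$live)
    expect_identical(r$trace, d$trace)
  }
})

test_that("FG accounting balances at every step", {
  sys <- get_small()
  designs <- grow_all(init_edesigns(sys$headpieces, sys$ontology),
                      sys$reactions, sys$bbts, sys$matrices, n_cycles = 2L)
  rx <- sys$reactions
  for (d in designs) {
    n <- 1L  # headpiece FG
    for (e in d$edges) {
      r <- rx[e$rxn, ]
      if (e$kind == "deprotection") n <- n - 1L + length(unlist(r$outputs))
      else {
        bbt <- deldesign:::bbt_from_key(e$bbt)
        n <- n - 1L + length(unlist(r$outputs)) + sum(bbt != 0L) - 1L
      }
    }
    expect_identical(length(d$live), n)
  }
})

test_that("designs ending in disallowed FGs are eliminated", {
  ont <- get_ontology()
  designs <- list(deldesign:::new_edesign(3L),
                  deldesign:::new_edesign(15L))  # live sulfonyl chloride
  kept <- finalize_designs(designs, ont$disallowed_final)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$live, 3L)
  expect_length(finalize_designs(designs, integer(0)), 2L)
})
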