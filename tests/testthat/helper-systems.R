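# shared fixtures, built once per test session

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

get_ontology <- function() memo("ont", load_ontology())

get_reactions <- function() memo("rxns",
  load_reactions(ontology = get_ontology()))

get_matrices <- function() memo("mat",
  load_reaction_fg_incompat(ontology = get_ontology()))

get_small <- function() memo("small", {
  sys <- make_toy_system("small", seed = 7)
  sys$proc <- process_bbs(sys$bbs, sys$ontology)
  sys$bbts <- do.call(rbind, lapply(sort(unique(
    sys$proc$bbt[sys$proc$status == "ok"])), deldesign:::bbt_from_key))
  sys
})

get_medium <- function() memo("medium", {
  sys <- make_toy_system("medium", seed = 11)
  sys$proc <- process_bbs(sys$bbs, sys$ontology)
  sys$bbts <- do.call(rbind, lapply(sort(unique(
    sys$proc$bbt[sys$proc$status == "ok"])), deldesign:::bbt_from_key))
  sys
})

# a truncated copy of the default ontology holding the first n FGs
# (null included) with no incompatibilities unless kept
mini_ontology <- function(n_fgs, keep_incompat = FALSE) {
  ont <- get_ontology()
  ont$fgs <- ont$fgs[seq_len(n_fgs), , drop = FALSE]
  ont$fgs$parent_id[!ont$fgs$parent_id %in% ont$fgs$id] <- NA_integer_
  if (!keep_incompat)
    ont$incompatible_pairs <- matrix(integer(0), ncol = 2,
                                     dimnames = list(NULL, c("fg1", "fg2")))
  else {
    keep <- ont$incompatible_pairs[, 1] %in% ont$fgs$id &
            ont$incompatible_pairs[, 2] %in% ont$fgs$id
    ont$incompatible_pairs <- ont$incompatible_pairs[keep, , drop = FALSE]
  }
  ont
}

# hand-built reaction tables for engine tests
mk_rxns <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) data.frame(
    rxn_id = r$rxn_id, kind = r$kind,
    enum_index = r$enum_index %||% 1L,
    design_side_atom_delta = r$dd %||% 0L,
    bb_side_atom_delta = r$bd %||% 0L,
    scaffold_atoms = r$scaffold %||% 0L,
    transform = r$transform %||% "",
    production_status = r$status %||% "production",
    design_fg = r$design_fg,
    bb_fg = r$bb_fg %||% NA_integer_,
    stringsAsFactors = FALSE)))
  df$outputs <- lapply(rows, function(r) as.integer(r$outputs %||% integer(0)))
  df <- df[order(df$rxn_id), ]
  rownames(df) <- df$rxn_id
  class(df) <- c("del_reactions", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built processed-BB frames for histogram/sizing tests
mk_bbs <- function(bb_id, bbt, heavy_atoms, source = "internal",
                   smiles = NA_character_) {
  n <- length(bb_id)
  source <- rep_len(source, n); smiles <- rep_len(smiles, n)
  df <- data.frame(bb_id = bb_id, smiles = smiles, source = source,
                   canonical_smiles = smiles, heavy_atoms = heavy_atoms,
                   rotatable_bonds = rep_len(0L, n), bbt = bbt,
                   multiplicity = vapply(strsplit(bbt, ".", fixed = TRUE),
                                         function(p) sum(p != "0"), integer(1)),
                   status = rep_len("ok", n), reject_reason = rep_len("", n),
                   stringsAsFactors = FALSE)
  df$fgs <- lapply(strsplit(bbt, ".", fixed = TRUE), function(p) {
    v <- as.integer(p); v[v != 0L]
  })
  class(df) <- c("del_bbs", "data.frame")
  df
}

# two-cycle amidation chain used throughout: headpiece amine, cycle 1
# couples a bifunctional acid BB (amine spectator survives), cycle 2 caps
# the regenerated amine with a monofunctional acid BB; both acids lose the
# hydroxyl (-1) on their own side, the design side is delta-free
two_cycle_amide_lib <- function(rx) {
  hp <- deldesign:::new_edesign(3L)
  d <- apply_connection(hp, rx["amide_amine_on_design_prim", ], c(3L, 6L, 0L))
  d <- apply_connection(d, rx["amide_amine_on_design_prim", ], c(6L, 0L, 0L))
  group_libdesigns(list(d), rx)[[1]]
}

two_cycle_bbs <- function(bi_sizes, mono_sizes, tag = "") {
  mk_bbs(c(sprintf("%sx%02d", tag, seq_along(bi_sizes)),
           sprintf("%sy%02d", tag, seq_along(mono_sizes))),
         c(rep("3.6.0", length(bi_sizes)), rep("6.0.0", length(mono_sizes))),
         as.integer(c(bi_sizes, mono_sizes)))
}

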