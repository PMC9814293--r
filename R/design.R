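# The design engine: grows synthesis designs (graphs of BBT nodes joined by
# reaction edges) cycle by cycle from a DNA headpiece FG.  A design is
# characterized by its multiset of live FGs; each cycle applies at most one
# deprotection/scaffold addition followed by exactly one connection to a new
# BBT, subject to reaction-FG compatibility on both sides of the DNA.

new_edesign <- function(headpiece_fg) {
  structure(list(headpiece = as.integer(headpiece_fg),
                 live = as.integer(headpiece_fg),
                 edges = list(),
                 trace = paste0("hp:", headpiece_fg)),
            class = "del_edesign")
}

#' @export
print.del_edesign <- function(x, ...) {
  cat("eDESIGN", x$trace, "\n  live FGs:", paste(x$live, collapse = ","), "\n")
  invisible(x)
}

edesign_n_cycles <- function(d)
  sum(vapply(d$edges, function(e) e$kind == "connecting", logical(1)))

#' Initialize designs from headpiece FGs
#'
#' One zero-cycle design per distinct headpiece FG; the design's live FG
#' multiset starts as that single FG.
#'
#' @param headpieces FG ids or names.
#' @param ontology a \code{del_ontology}.
#' @return list of \code{del_edesign} objects.
#' @export
init_edesigns <- function(headpieces, ontology) {
  if (is.character(headpieces)) headpieces <- fg_id(ontology, headpieces)
  unknown <- setdiff(headpieces, ontology$fgs$id)
  if (length(unknown)) stop("unknown headpiece FG id(s): ",
                            paste(unknown, collapse = ", "))
  if (anyDuplicated(headpieces)) {
    warning("duplicate headpiece FGs collapsed")
    headpieces <- unique(headpieces)
  }
  lapply(as.integer(headpieces), new_edesign)
}

#' Apply a deprotection or scaffold addition
#'
#' Replaces one live instance of the reaction's input FG by its outputs;
#' scaffold atoms (e.g. the 8 heavy atoms of the dichlorotriazine cap that
#' cyanuric chloride leaves on a primary amine) are recorded on the edge for
#' heavy-atom accounting.  Pure: the input design is not modified.
#'
#' @param d a \code{del_edesign}.
#' @param r one row of a \code{del_reactions} frame with kind deprotection.
#' @return the transformed design.
#' @export
apply_deprotection <- function(d, r) {
  if (r$kind != "deprotection") stop("reaction is not a deprotection")
  live <- ms_remove_one(d$live, r$design_fg)
  d$live <- ms_add(live, unlist(r$outputs))
  d$edges <- c(d$edges, list(list(kind = "deprotection", rxn = r$rxn_id,
                                  scaffold = r$scaffold_atoms,
                                  delta = r$design_side_atom_delta)))
  d$trace <- paste0(d$trace, "|d:", r$rxn_id)
  d
}

#' Apply a connecting reaction to a building-block type
#'
#' Consumes the reaction's design FG from the live multiset and its bb FG
#' from the incoming BBT; the reaction outputs plus the BBT's unconsumed
#' non-null FGs are inherited by the grown design.
#'
#' @param d a \code{del_edesign}.
#' @param r one row of a \code{del_reactions} frame with kind connecting.
#' @param bbt integer triple (canonical BBT).
#' @param matrices reaction-FG incompatibility matrices
#'   (\code{del_rxn_fg_incompat}); defaults to none.
#' @return the grown design.
#' @export
apply_connection <- function(d, r, bbt, matrices = empty_rxn_fg_incompat()) {
  if (r$kind != "connecting") stop("reaction is not a connecting reaction")
  if (!r$bb_fg %in% bbt[bbt != 0L])
    stop("fg_not_available: BBT ", bbt_key(bbt), " lacks FG ", r$bb_fg)
  viol <- check_compatibility(d, r, bbt, matrices)
  if (!isTRUE(viol)) stop("incompatibility violation: ", viol)
  live <- ms_remove_one(d$live, r$design_fg)
  spectators <- bbt[bbt != 0L]
  spectators <- spectators[-match(r$bb_fg, spectators)]
  d$live <- ms_add(live, c(unlist(r$outputs), spectators))
  d$edges <- c(d$edges, list(list(kind = "connecting", rxn = r$rxn_id,
                                  bbt = bbt_key(bbt),
                                  delta = r$design_side_atom_delta)))
  d$trace <- paste0(d$trace, "|c:", r$rxn_id, ":", bbt_key(bbt))
  d
}

#' Check reaction-FG compatibility for a step
#'
#' A step is vetoed when any live FG on the design other than the consumed
#' instance is on-DNA-incompatible with the reaction, or any FG of the
#' incoming BBT other than the consumed instance is off-DNA-incompatible
#' with it.
#'
#' @param d a \code{del_edesign}.
#' @param r a reaction row.
#' @param bbt canonical BBT triple, or NULL for deprotections.
#' @param matrices a \code{del_rxn_fg_incompat}.
#' @return \code{TRUE}, or a string naming the violated rule.
#' @export
check_compatibility <- function(d, r, bbt = NULL,
                                matrices = empty_rxn_fg_incompat()) {
  rest <- d$live
  i <- match(r$design_fg, rest)
  if (!is.na(i)) rest <- rest[-i]
  bad <- rest[paste(r$rxn_id, rest, sep = "|") %in% matrices$on_dna]
  if (length(bad))
    return(paste0("on_dna:", r$rxn_id, "|", bad[1L]))
  if (!is.null(bbt) && !is.na(r$bb_fg)) {
    side <- bbt[bbt != 0L]
    j <- match(r$bb_fg, side)
    if (!is.na(j)) side <- side[-j]
    bad <- side[paste(r$rxn_id, side, sep = "|") %in% matrices$off_dna]
    if (length(bad))
      return(paste0("off_dna:", r$rxn_id, "|", bad[1L]))
  }
  TRUE
}

#' Grow all designs for a number of cycles
#'
#' Exhaustive breadth-first expansion: per cycle and per design, branch over
#' \{no deprotection\} plus every applicable deprotection, then over every
#' applicable (connecting reaction x BBT) pair, adding exactly one BBT per
#' design per cycle.  Chained deprotections within one cycle are not
#' attempted.  Iteration order (designs in list order, deprotections and
#' reactions by rxn_id, BBTs in canonical order) is fixed, so the output
#' list is reproducible.
#'
#' @param designs list of \code{del_edesign} (typically from
#'   \code{init_edesigns}).
#' @param reactions a \code{del_reactions} frame.
#' @param bbts integer matrix of canonical BBTs (rows), e.g. populated BBTs
#'   of a processed collection.
#' @param matrices a \code{del_rxn_fg_incompat}.
#' @param n_cycles number of synthesis cycles.
#' @param max_designs hard cap; growth aborts cleanly beyond it.
#' @return list of grown designs after \code{n_cycles}.
#' @export
grow_all <- function(designs, reactions, bbts, matrices = empty_rxn_fg_incompat(),
                     n_cycles = 2L, max_designs = 1e8) {
  stopifnot(n_cycles >= 1L)
  if (is.null(dim(bbts))) bbts <- matrix(bbts, ncol = 3L)
  bbts <- bbts[order(bbts[, 1L], bbts[, 2L], bbts[, 3L]), , drop = FALSE]
  deprots <- reactions[reactions$kind == "deprotection", , drop = FALSE]
  conns <- reactions[reactions$kind == "connecting", , drop = FALSE]
  # BBT candidates per connecting reaction (by its bb-side FG)
  cand <- lapply(conns$bb_fg, function(fg)
    which(bbts[, 1L] == fg | bbts[, 2L] == fg | bbts[, 3L] == fg))

  for (cycle in seq_len(n_cycles)) {
    res <- vector("list", 0L); seen <- new.env(hash = TRUE, parent = emptyenv())
    n_out <- 0L
    for (d in designs) {
      variants <- list(d)
      for (k in seq_len(nrow(deprots))) {
        r <- deprots[k, ]
        if (r$design_fg %in% d$live &&
            isTRUE(check_compatibility(d, r, NULL, matrices)))
          variants <- c(variants, list(apply_deprotection(d, r)))
      }
      for (v in variants) {
        for (k in seq_len(nrow(conns))) {
          r <- conns[k, ]
          if (!r$design_fg %in% v$live) next
          for (bi in cand[[k]]) {
            bbt <- bbts[bi, ]
            if (!isTRUE(check_compatibility(v, r, bbt, matrices))) next
            nd <- apply_connection(v, r, bbt, matrices)
            if (is.null(seen[[nd$trace]])) {
              seen[[nd$trace]] <- TRUE
              n_out <- n_out + 1L
              res[[n_out]] <- nd
              if (n_out > max_designs)
                stop("design cap exceeded (", max_designs,
                     "); raise max_designs or restrict the system")
            }
          }
        }
      }
    }
    designs <- res
  }
  designs
}

#' Remove designs with disallowed terminal FGs
#'
#' @param designs list of grown designs.
#' @param disallowed_final_fgs FG ids not allowed live on a finished design
#'   (e.g. sulfonyl chloride).
#' @return filtered list.
#' @export
finalize_designs <- function(designs, disallowed_final_fgs) {
  keep <- vapply(designs, function(d)
    !any(d$live %in% disallowed_final_fgs), logical(1))
  designs[keep]
}

# serialize designs one replay trace per line
write_edesigns <- function(designs, path) {
  writeLines(vapply(designs, `[[`, character(1), "trace"), path)
  invisible(path)
}

# rebuild a design by replaying its trace (used for the replay-determinism
# invariant and for reading design lists back)
replay_edesign <- function(trace, reactions, matrices = empty_rxn_fg_incompat()) {
  toks <- strsplit(trace, "|", fixed = TRUE)[[1L]]
  stopifnot(grepl("^hp:", toks[1L]))
  d <- new_edesign(as.integer(sub("^hp:", "", toks[1L])))
  for (tk in toks[-1L]) {
    p <- strsplit(tk, ":", fixed = TRUE)[[1L]]
    if (p[1L] == "d") d <- apply_deprotection(d, reactions[p[2L], ])
    else d <- apply_connection(d, reactions[p[2L], ], bbt_from_key(p[3L]),
                               matrices)
  }
  d
}
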