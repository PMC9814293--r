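#' Load the reaction set
#'
#' Reads the YAML reaction file.  Connecting reactions consume one FG on the
#' growing design and one on the incoming building block and may emit new
#' FGs (e.g. SNAr on a dichlorotriazine leaves a monochlorotriazine);
#' deprotections transform a single design FG, optionally adding scaffold
#' atoms (cyanuric chloride capping turns a primary amine into a
#' dichlorotriazine).  Heavy-atom deltas are split into a design-side and a
#' building-block-side contribution so that effective atom counts are
#' well-defined per BB.  Reactions sharing an \code{enum_index} can be run
#' in one experimental step and are merged at the libDESIGN stage.
#'
#' @param path reaction YAML; defaults to the set shipped with the package.
#' @param ontology a \code{del_ontology} used to resolve FG names.
#' @param scope \code{"both"} (default) or \code{"production"} to restrict
#'   to reactions already used in library production.
#' @return object of class \code{del_reactions}: a data frame with one row
#'   per reaction (outputs held as a list column of FG ids).
#' @export
load_reactions <- function(path = NULL, ontology, scope = c("both", "production")) {
  scope <- match.arg(scope)
  if (is.null(path)) path <- path_pkg_file("extdata", "reactions.yaml")
  raw <- yaml::read_yaml(path)$reactions
  rx <- data.frame(
    rxn_id = vapply(raw, function(r) as.character(r$rxn_id), character(1)),
    kind = vapply(raw, function(r) as.character(r$kind), character(1)),
    enum_index = vapply(raw, function(r) as.integer(r$enum_index), integer(1)),
    design_side_atom_delta = vapply(raw, function(r)
      as.integer(r$design_side_atom_delta), integer(1)),
    bb_side_atom_delta = vapply(raw, function(r)
      as.integer(r$bb_side_atom_delta), integer(1)),
    scaffold_atoms = vapply(raw, function(r) as.integer(r$scaffold_atoms), integer(1)),
    transform = vapply(raw, function(r) as.character(r$transform), character(1)),
    production_status = vapply(raw, function(r)
      as.character(r$production_status), character(1)),
    stringsAsFactors = FALSE)
  ins <- lapply(raw, function(r) fg_id(ontology, unlist(r$inputs)))
  n_in <- lengths(ins)
  if (any(rx$kind == "connecting" & n_in != 2L) ||
      any(rx$kind == "deprotection" & n_in != 1L))
    stop("connecting reactions need 2 input FGs, deprotections exactly 1")
  if (any(rx$scaffold_atoms > 0L & rx$kind != "deprotection"))
    stop("scaffold_atoms > 0 is only meaningful for deprotections")
  rx$design_fg <- vapply(ins, `[`, integer(1), 1L)
  rx$bb_fg <- vapply(ins, function(x) if (length(x) > 1L) x[2L] else NA_integer_,
                     integer(1))
  rx$outputs <- lapply(raw, function(r) {
    o <- unlist(r$outputs)
    if (length(o)) fg_id(ontology, o) else integer(0)
  })
  if (anyDuplicated(rx$rxn_id)) stop("duplicate rxn_id")
  check_enum_groups(rx)
  if (scope == "production") rx <- rx[rx$production_status == "production", ]
  rx <- rx[order(rx$rxn_id), ]
  rownames(rx) <- rx$rxn_id
  class(rx) <- c("del_reactions", "data.frame")
  rx
}

# reactions pooled under one enum_index must be experimentally combinable:
# same kind and identical heavy-atom bookkeeping on the design side
check_enum_groups <- function(rx) {
  for (e in unique(rx$enum_index)) {
    g <- rx[rx$enum_index == e, ]
    if (length(unique(g$kind)) > 1L)
      stop("enum_index ", e, " mixes connecting and deprotection reactions")
    if (length(unique(g$design_side_atom_delta)) > 1L ||
        length(unique(g$scaffold_atoms)) > 1L)
      stop("enum_index ", e, " mixes design-side atom deltas")
  }
  invisible(rx)
}

#' @export
print.del_reactions <- function(x, ...) {
  cat("Reaction set:", sum(x$kind == "connecting"), "connecting,",
      sum(x$kind == "deprotection"), "deprotection reactions;",
      length(unique(x$enum_index)), "enum groups\n")
  invisible(x)
}

#' Load reaction-by-FG incompatibility matrices
#'
#' Some FGs cannot survive a reaction's conditions: the on-DNA matrix rules
#' out live FGs on the growing design (beyond the instance the reaction
#' consumes), the off-DNA matrix rules out FGs arriving on the incoming
#' building block.  The same FG may be allowed in one context and not the
#' other.
#'
#' @param path CSV with columns rxn_id, fg_name, context (on_dna/off_dna);
#'   defaults to the matrix shipped with the package.
#' @param ontology a \code{del_ontology}.
#' @return list with character-key sets \code{on_dna} and \code{off_dna}
#'   ("rxn_id|fg_id"), class \code{del_rxn_fg_incompat}.
#' @export
load_reaction_fg_incompat <- function(path = NULL, ontology) {
  if (is.null(path)) path <- path_pkg_file("extdata", "reaction_fg_incompat.csv")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("rxn_id", "fg_name", "context") %in% names(df)))
  if (!all(df$context %in% c("on_dna", "off_dna")))
    stop("context must be on_dna or off_dna")
  key <- paste(df$rxn_id, fg_id(ontology, df$fg_name), sep = "|")
  structure(list(on_dna = unique(key[df$context == "on_dna"]),
                 off_dna = unique(key[df$context == "off_dna"])),
            class = "del_rxn_fg_incompat")
}

empty_rxn_fg_incompat <- function() {
  structure(list(on_dna = character(0), off_dna = character(0)),
            class = "del_rxn_fg_incompat")
}
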