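#' Load a functional-group ontology
#'
#' Reads the YAML ontology describing the functional groups (FGs) available
#' to the design engine: reactive handles and protected precursors, each with
#' a SMARTS pattern, an optional parent in the annotation hierarchy (e.g.
#' amine > aliphatic amine > primary aliphatic amine), and class tags used to
#' expand pairwise incompatibilities (strong electrophiles and strong
#' nucleophiles are mutually incompatible within and across classes, since
#' such combinations would make a building block unstable or a reaction
#' non-selective).  The null FG (id 0) used to pad building-block types is
#' added automatically.
#'
#' @param path path to an ontology YAML file; defaults to the ontology
#'   shipped with the package.
#' @return an object of class \code{del_ontology}: a list with elements
#'   \code{fgs} (data frame: id, name, smarts, parent_id, protected),
#'   \code{class_tags}, \code{incompatible_pairs} (two-column integer matrix
#'   of mutually incompatible FG ids), \code{disallowed_final} and
#'   \code{unwanted} (integer id vectors).
#' @export
load_ontology <- function(path = NULL) {
  if (is.null(path)) path <- path_pkg_file("extdata", "fg_ontology.yaml")
  raw <- yaml::read_yaml(path)
  ent <- raw$fgs
  fgs <- data.frame(
    id = vapply(ent, function(e) as.integer(e$id), integer(1)),
    name = vapply(ent, function(e) as.character(e$name), character(1)),
    smarts = vapply(ent, function(e) as.character(e$smarts), character(1)),
    parent = vapply(ent, function(e) as.character(e$parent %||% NA_character_),
                    character(1)),
    protected = vapply(ent, function(e) isTRUE(e$protected), logical(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(fgs$id) || any(fgs$id == 0L))
    stop("FG ids must be unique and non-zero (0 is the null FG)")
  fgs$parent_id <- fgs$id[match(fgs$parent, fgs$name)]
  if (any(!is.na(fgs$parent) & is.na(fgs$parent_id)))
    stop("unknown parent FG name in ontology")
  # null FG row
  fgs <- rbind(data.frame(id = 0L, name = "null", smarts = "", parent = NA,
                          protected = FALSE, parent_id = NA_integer_,
                          stringsAsFactors = FALSE), fgs)
  check_acyclic_parents(fgs)
  tags <- lapply(ent, function(e) as.character(unlist(e$class_tags)))
  names(tags) <- as.character(vapply(ent, function(e) as.integer(e$id), integer(1)))

  name2id <- function(nm) {
    id <- fgs$id[match(nm, fgs$name)]
    if (any(is.na(id))) stop("unknown FG name(s): ",
                             paste(nm[is.na(id)], collapse = ", "))
    id
  }
  extra <- raw$extra_incompatible_pairs %||% list()
  extra <- if (length(extra))
    t(vapply(extra, function(p) sort(name2id(unlist(p))), integer(2)))
  else matrix(integer(0), ncol = 2)

  ont <- structure(list(
    fgs = fgs,
    class_tags = tags,
    incompatible_pairs = expand_class_incompat(fgs, tags, extra),
    disallowed_final = name2id(unlist(raw$disallowed_final_fgs %||% list())),
    unwanted = name2id(unlist(raw$unwanted_fgs %||% list())),
    source = path), class = "del_ontology")
  ont
}

check_acyclic_parents <- function(fgs) {
  for (i in seq_len(nrow(fgs))) {
    seen <- integer(0); cur <- fgs$id[i]
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle in FG parent chain at id ", fgs$id[i])
      seen <- c(seen, cur)
      cur <- fgs$parent_id[match(cur, fgs$id)]
    }
  }
}

# all unordered pairs of FGs carrying a strong electrophile/nucleophile tag
# are incompatible (within and across the two classes), plus explicit pairs
expand_class_incompat <- function(fgs, tags, extra) {
  strong <- as.integer(names(tags)[vapply(tags, function(tg)
    any(tg %in% c("strong_electrophile", "strong_nucleophile")), logical(1))])
  pairs <- if (length(strong) >= 2L) t(utils::combn(sort(strong), 2L))
           else matrix(integer(0), ncol = 2)
  pairs <- rbind(pairs, extra)
  pairs <- unique(pairs)
  storage.mode(pairs) <- "integer"
  if (any(pairs == 0L)) stop("null FG cannot appear in incompatibilities")
  colnames(pairs) <- c("fg1", "fg2")
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' @export
print.del_ontology <- function(x, ...) {
  cat("FG ontology:", nrow(x$fgs) - 1L, "functional groups (+ null FG)\n")
  cat("  incompatible pairs:", nrow(x$incompatible_pairs), "\n")
  cat("  protected FGs:",
      paste(x$fgs$name[x$fgs$protected], collapse = ", "), "\n")
  invisible(x)
}

fg_id <- function(ontology, name) {
  id <- ontology$fgs$id[match(name, ontology$fgs$name)]
  if (any(is.na(id))) stop("unknown FG name(s): ",
                           paste(name[is.na(id)], collapse = ", "))
  id
}

fg_name <- function(ontology, id) {
  nm <- ontology$fgs$name[match(id, ontology$fgs$id)]
  if (any(is.na(nm))) stop("unknown FG id(s): ",
                           paste(id[is.na(nm)], collapse = ", "))
  nm
}

#' Canonical building-block type
#'
#' A building-block type (BBT) is a canonical triple of FG ids padded with
#' the null FG (id 0): non-null ids sorted ascending and nulls at the end,
#' so that any two FG multisets with the same distinct FGs map to the same
#' BBT.  A building block carrying the same FG twice is typed by that FG
#' once.
#'
#' @param fg_ids 1-3 non-null FG ids (duplicates collapsed).
#' @param ontology a \code{del_ontology}.
#' @return integer vector of length 3.
#' @export
canonical_bbt <- function(fg_ids, ontology) {
  ids <- unique(sort(as.integer(fg_ids)))
  ids <- ids[ids != 0L]
  unknown <- setdiff(ids, ontology$fgs$id)
  if (length(unknown)) stop("unknown FG id(s): ", paste(unknown, collapse = ", "))
  if (length(ids) == 0L) stop("a BBT needs at least one non-null FG")
  if (length(ids) > 3L)
    stop("too_many_fgs: more than 3 distinct FGs cannot be typed as a BBT")
  c(ids, rep(0L, 3L - length(ids)))
}

bbt_key <- function(bbt) paste(bbt, collapse = ".")

bbt_from_key <- function(key) as.integer(strsplit(key, ".", fixed = TRUE)[[1L]])

bbt_multiplicity <- function(bbt) sum(bbt != 0L)

#' Enumerate the building-block-type space
#'
#' Generates all canonical BBTs as 3-subsets of the FG list with the null FG
#' treated as an ordinary element: pairs of distinct reactive FGs plus the
#' null (bifunctional) and triples of distinct reactive FGs (trifunctional).
#' For an ontology of n FGs including the null this yields choose(n, 3)
#' combinations before pruning.  Every BBT containing a pair of mutually
#' incompatible FGs is then removed.  Monofunctional BBTs (one FG, two
#' nulls) arise from building-block assignment rather than enumeration, but
#' can be included with \code{include_monofunctional}.
#'
#' @param ontology a \code{del_ontology}.
#' @param incompat two-column matrix of incompatible FG-id pairs; defaults
#'   to the ontology's expanded pairs.  Use a zero-row matrix for none.
#' @param include_monofunctional also emit one BBT per single FG.
#' @return integer matrix with 3 columns, one canonical BBT per row.
#' @export
enumerate_bbt_space <- function(ontology,
                                incompat = ontology$incompatible_pairs,
                                include_monofunctional = FALSE) {
  ids <- sort(ontology$fgs$id[ontology$fgs$id != 0L])
  if (length(ids) < 2L) stop("ontology must hold at least 2 reactive FGs")
  bi <- t(utils::combn(ids, 2L))
  bi <- cbind(bi, 0L)
  tri <- if (length(ids) >= 3L) t(utils::combn(ids, 3L))
         else matrix(integer(0), ncol = 3)
  space <- rbind(bi, tri)
  if (include_monofunctional)
    space <- rbind(cbind(ids, 0L, 0L), space)
  storage.mode(space) <- "integer"
  colnames(space) <- c("fg1", "fg2", "fg3")
  keep <- !apply(space, 1L, has_incompatible_pair, incompat = incompat)
  space[keep, , drop = FALSE]
}

has_incompatible_pair <- function(bbt, incompat) {
  ids <- bbt[bbt != 0L]
  if (length(ids) < 2L || nrow(incompat) == 0L) return(FALSE)
  prs <- utils::combn(sort(ids), 2L)
  keys <- paste(prs[1L, ], prs[2L, ])
  any(keys %in% paste(incompat[, 1L], incompat[, 2L]))
}

#' Resolve FG matches through the annotation hierarchy
#'
#' When an ancestor FG and one of its descendants match the same site of a
#' molecule (every primary aliphatic amine is also an aliphatic amine and an
#' amine), only the most specific FG is retained for that site.  Matches of
#' related FGs at distinct sites are all kept: the per-FG resolved count is
#' the raw match count minus the match counts of its direct children, which
#' is exact whenever each child match site is also a parent match site (the
#' contract the shipped ontology patterns obey).
#'
#' @param matches vector of FG ids, one entry per SMARTS match site
#'   (multiplicity allowed).
#' @param ontology a \code{del_ontology}.
#' @return integer vector of leaf-resolved FG ids with multiplicity.
#' @export
resolve_fg_hierarchy <- function(matches, ontology) {
  matches <- as.integer(matches)
  if (length(matches) == 0L) return(integer(0))
  counts <- table(matches)
  ids <- as.integer(names(counts))
  resolved <- as.integer(counts)
  names(resolved) <- names(counts)
  for (i in seq_along(ids)) {
    kids <- ontology$fgs$id[!is.na(ontology$fgs$parent_id) &
                            ontology$fgs$parent_id == ids[i]]
    kid_total <- sum(counts[as.character(kids)], na.rm = TRUE)
    resolved[i] <- max(0L, resolved[i] - as.integer(kid_total))
  }
  out <- rep(ids, resolved)
  sort(out)
}
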