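#' Filtering policy for building blocks
#'
#' @param max_heavy_atoms maximum heavy atoms per building block.
#' @param max_rotatable_bonds maximum rotatable bonds.
#' @param unwanted_fg_ids FG ids whose presence disqualifies a building
#'   block; default \code{NULL} means the ontology's unwanted list.
#' @return object of class \code{del_filter_policy}.
#' @export
filter_policy <- function(max_heavy_atoms = 30L, max_rotatable_bonds = 10L,
                          unwanted_fg_ids = NULL) {
  stopifnot(max_heavy_atoms > 0L, max_rotatable_bonds > 0L)
  structure(list(max_heavy_atoms = as.integer(max_heavy_atoms),
                 max_rotatable_bonds = as.integer(max_rotatable_bonds),
                 unwanted_fg_ids = unwanted_fg_ids),
            class = "del_filter_policy")
}

#' Read a building-block collection
#'
#' Accepts a CSV with columns \code{bb_id}, \code{smiles}, \code{source}
#' or a SMILES file (one record per line: smiles, id, optional source).
#'
#' @param path input file.
#' @param source default source label when the file carries none.
#' @return data frame with columns bb_id, smiles, source.
#' @export
read_bb_collection <- function(path, source = "external") {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
    stopifnot(all(c("bb_id", "smiles") %in% names(df)))
    if (is.null(df$source)) df$source <- source
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    df <- data.frame(
      bb_id = vapply(parts, function(p) p[2] %||% NA_character_, character(1)),
      smiles = vapply(parts, `[`, character(1), 1L),
      source = vapply(parts, function(p) p[3] %||% source, character(1)),
      stringsAsFactors = FALSE)
    df$bb_id[is.na(df$bb_id)] <- sprintf("bb%06d", which(is.na(df$bb_id)))
  }
  df[, c("bb_id", "smiles", "source")]
}

#' Process a building-block collection
#'
#' Runs the curation pipeline: standardization (salt stripping,
#' neutralization, canonicalization), deduplication of identical canonical
#' structures, FG annotation with hierarchy resolution, policy filtering
#' (unwanted FGs, heavy atoms, rotatable bonds; all failing rules are
#' recorded, the first is the primary reason) and BBT assignment.  A BB is
#' assigned iff it carries 1-3 distinct leaf FGs whose combination survives
#' pairwise incompatibility pruning.
#'
#' @param bbs data frame with columns bb_id, smiles, source.
#' @param ontology a \code{del_ontology}.
#' @param policy a \code{del_filter_policy}.
#' @return object of class \code{del_bbs}: data frame with columns bb_id,
#'   smiles, source, canonical_smiles, heavy_atoms, rotatable_bonds, fgs
#'   (list column of leaf FG ids), bbt (key string or NA), multiplicity,
#'   status, reject_reason; attribute \code{merged} logs deduplications.
#' @export
process_bbs <- function(bbs, ontology, policy = filter_policy()) {
  stopifnot(all(c("bb_id", "smiles", "source") %in% names(bbs)))
  if (anyDuplicated(bbs$bb_id)) stop("duplicate bb_id in input")
  unwanted <- policy$unwanted_fg_ids %||% ontology$unwanted

  std <- standardize_smiles(bbs$smiles)
  out <- bbs
  out$canonical_smiles <- std$canonical_smiles
  out$heavy_atoms <- NA_integer_
  out$rotatable_bonds <- NA_integer_
  out$fgs <- vector("list", nrow(out))
  out$bbt <- NA_character_
  out$multiplicity <- NA_integer_
  out$status <- ifelse(std$status == "ok", "ok", "rejected")
  out$reject_reason <- std$reason

  # deduplicate identical canonical forms, keeping the first id in
  # lexicographic order
  merged <- data.frame(kept = character(0), dropped = character(0))
  ok <- which(out$status == "ok")
  if (length(ok)) {
    ord <- ok[order(out$canonical_smiles[ok], out$bb_id[ok])]
    dup <- ord[duplicated(out$canonical_smiles[ord])]
    if (length(dup)) {
      first <- ord[!duplicated(out$canonical_smiles[ord])]
      keep_of <- first[match(out$canonical_smiles[dup], out$canonical_smiles[first])]
      merged <- data.frame(kept = out$bb_id[keep_of], dropped = out$bb_id[dup],
                           stringsAsFactors = FALSE)
      out$status[dup] <- "rejected"
      out$reject_reason[dup] <- "duplicate"
    }
  }

  live <- which(out$status == "ok")
  if (length(live)) {
    smi <- out$canonical_smiles[live]
    names(smi) <- out$bb_id[live]
    sdf <- smiles_to_sdf(smi)
    counts <- fg_match_counts(sdf, ontology)
    ids <- as.integer(colnames(counts))
    out$heavy_atoms[live] <- sdf_heavy_atoms(sdf)
    out$rotatable_bonds[live] <- as.integer(
      ChemmineR::smartsSearchOB(sdf, ROTATABLE_SMARTS, uniqueMatches = TRUE))

    for (k in seq_along(live)) {
      i <- live[k]
      raw <- rep(ids, counts[k, ])
      leaf <- resolve_fg_hierarchy(raw, ontology)
      out$fgs[[i]] <- leaf
      reasons <- character(0)
      if (any(unwanted %in% raw)) reasons <- c(reasons, "unwanted_fg")
      if (out$heavy_atoms[i] > policy$max_heavy_atoms)
        reasons <- c(reasons, "heavy_atoms")
      if (out$rotatable_bonds[i] > policy$max_rotatable_bonds)
        reasons <- c(reasons, "rotatable_bonds")
      if (length(reasons) == 0L) {
        distinct <- unique(leaf)
        if (length(distinct) == 0L) reasons <- "no_fg"
        else if (length(distinct) > 3L) reasons <- "too_many_fgs"
        else if (has_incompatible_pair(distinct, ontology$incompatible_pairs))
          reasons <- "incompatible"
        else {
          bbt <- canonical_bbt(distinct, ontology)
          out$bbt[i] <- bbt_key(bbt)
          out$multiplicity[i] <- bbt_multiplicity(bbt)
        }
      }
      if (length(reasons)) {
        out$status[i] <- "rejected"
        out$reject_reason[i] <- paste(reasons, collapse = ";")
      }
    }
  }
  attr(out, "merged") <- merged
  class(out) <- c("del_bbs", "data.frame")
  out
}

#' @export
print.del_bbs <- function(x, ...) {
  cat("Building blocks:", nrow(x), "input,", sum(x$status == "ok"),
      "assigned to", length(unique(x$bbt[x$status == "ok"])), "BBTs\n")
  rej <- x$reject_reason[x$status == "rejected"]
  if (length(rej)) {
    primary <- vapply(strsplit(rej, ";"), `[`, character(1), 1L)
    print(table(primary))
  }
  invisible(x)
}

#' Effective heavy atoms of a building block
#'
#' Number of heavy atoms a building block contributes to the final product:
#' its own heavy atoms plus the building-block-side atom delta of the
#' connecting reaction that consumes it (e.g. -1 for the hydroxyl an acid
#' loses in amidation), composed with the design-side deltas of any
#' deprotections applied to it afterwards (e.g. -7 for Boc removal).
#'
#' @param bb one row of a \code{del_bbs} frame (or any list with
#'   \code{heavy_atoms} and \code{fgs}).
#' @param reaction one row of a \code{del_reactions} frame; its bb-side
#'   input FG must be present on the building block.
#' @param deprotections optional list of deprotection reaction rows applied
#'   to this building block's FGs after incorporation.
#' @return integer heavy-atom count.
#' @export
effective_heavy_atoms <- function(bb, reaction, deprotections = list()) {
  fgs <- unlist(bb$fgs)
  if (!reaction$bb_fg %in% fgs)
    stop("reaction ", reaction$rxn_id, " does not consume any FG of this BB")
  ha <- bb$heavy_atoms + reaction$bb_side_atom_delta
  for (d in deprotections)
    ha <- ha + d$design_side_atom_delta + d$scaffold_atoms
  as.integer(ha)
}

#' Collection summary report
#'
#' Summarizes a processed collection per source and per multiplicity
#' (mono/bi/trifunctional): number of populated BBTs, number of building
#' blocks, and the heavy-atom histogram of members.
#'
#' @param bbs a \code{del_bbs} frame.
#' @return list with elements \code{table} (data frame) and
#'   \code{histograms} (named list "source/multiplicity"), class
#'   \code{del_bb_report}.
#' @export
bb_collection_report <- function(bbs) {
  acc <- bbs[bbs$status == "ok", , drop = FALSE]
  sources <- sort(unique(bbs$source))
  rows <- list(); hists <- list()
  for (s in sources) for (m in 1:3) {
    sub <- acc[acc$source == s & acc$multiplicity == m, , drop = FALSE]
    rows[[paste(s, m)]] <- data.frame(
      source = s, multiplicity = m,
      n_bbts = length(unique(sub$bbt)), n_bbs = nrow(sub),
      stringsAsFactors = FALSE)
    hists[[paste(s, m, sep = "/")]] <- hist_from_values(sub$heavy_atoms)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(source = character(0),
                                      multiplicity = integer(0),
                                      n_bbts = integer(0), n_bbs = integer(0))
  rownames(tab) <- NULL
  structure(list(table = tab, histograms = hists), class = "del_bb_report")
}

#' @export
print.del_bb_report <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Write a processed collection to CSV
#'
#' @param bbs a \code{del_bbs} frame.
#' @param path output CSV path.
#' @export
write_processed_bbs <- function(bbs, path) {
  df <- as.data.frame(bbs)
  df$fgs <- vapply(df$fgs, function(f) paste(f, collapse = ";"), character(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
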