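# Profiling: molecular property profiles, Tanimoto diversity against
# reference collections, near-neighbor distributions and spread-design
# ranking of library samples.

as_smiles_vec <- function(x) {
  if (inherits(x, "del_xset")) {
    smi <- x$smiles
    names(smi) <- x$product_id
    smi
  } else {
    smi <- as.character(x)
    if (is.null(names(smi))) names(smi) <- sprintf("s%06d", seq_along(smi))
    smi
  }
}

#' Property profile of a compound set
#'
#' Per-compound heavy atoms, cLogP, fraction Csp3, topological polar
#' surface area and rotatable bonds, plus per-set means.  Unparseable
#' structures are skipped and counted.
#'
#' @param x SMILES vector or a \code{del_xset}.
#' @return list with \code{records} (data frame), \code{means} (named
#'   numeric) and \code{n_skipped}; class \code{del_profile}.
#' @export
profile_set <- function(x) {
  smi <- as_smiles_vec(x)
  std <- standardize_smiles(smi)
  ok <- std$status == "ok"
  keep <- std$canonical_smiles[ok]
  names(keep) <- names(smi)[ok]
  rec <- mol_descriptors(smiles_to_sdf(keep))
  means <- c(heavy_atoms = mean(rec$heavy_atoms), clogp = mean(rec$clogp),
             fraction_csp3 = mean(rec$fraction_csp3), tpsa = mean(rec$tpsa),
             rotatable_bonds = mean(rec$rotatable_bonds))
  structure(list(records = rec, means = means, n_skipped = sum(!ok)),
            class = "del_profile")
}

#' @export
print.del_profile <- function(x, ...) {
  cat("Property profile of", nrow(x$records), "compounds",
      if (x$n_skipped) paste0("(", x$n_skipped, " skipped)"), "\n")
  print(round(x$means, 2))
  invisible(x)
}

#' Average pairwise Tanimoto distance between two sets
#'
#' Mean over all |A| x |B| pairs of (1 - Tanimoto similarity) on path
#' fingerprints; symmetric in its arguments.
#'
#' @param a,b SMILES vectors, \code{del_xset}s, or precomputed fingerprint
#'   matrices from \code{path_fingerprints}.
#' @return number in [0, 1].
#' @export
avg_pairwise_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty compound set")
  fa <- if (is.matrix(a)) a else path_fingerprints(as_smiles_vec(a))
  fb <- if (is.matrix(b)) b else path_fingerprints(as_smiles_vec(b))
  if (nrow(fa) == 0L || nrow(fb) == 0L) stop("empty compound set")
  mean(1 - tanimoto_matrix(fa, fb))
}

#' Near-neighbor distances to a reference set
#'
#' For each compound, the distance (1 - Tanimoto) to its nearest neighbor
#' in the reference collection.
#'
#' @param x SMILES/\code{del_xset}/fingerprint matrix of the library sample.
#' @param reference the reference collection in any of the same forms.
#' @return numeric vector, one value per compound of \code{x}.
#' @export
nn_distances <- function(x, reference) {
  if (length(reference) == 0L) stop("empty reference set")
  fx <- if (is.matrix(x)) x else path_fingerprints(as_smiles_vec(x))
  fr <- if (is.matrix(reference)) reference
        else path_fingerprints(as_smiles_vec(reference))
  if (nrow(fr) == 0L) stop("empty reference set")
  sim <- tanimoto_matrix(fx, fr)
  1 - apply(sim, 1L, max)
}

# library-level diversity measure: mean near-neighbor distance of the
# library's compounds to the (current) reference union
lib_measure <- function(fp, ref_fp) mean(nn_distances(fp, ref_fp))

#' Spread-design ranking of libraries
#'
#' Greedy maximal-diversity ordering: the library with the largest mean
#' near-neighbor distance to the reference union is selected first and its
#' compounds are added to the reference; subsequent libraries are ranked
#' against the updated reference.  With no reference sets, the first
#' selection uses the union of all other libraries as reference.  Ties are
#' broken by larger library size, then lexicographic id.
#'
#' @param libraries named list of library samples (SMILES vectors or
#'   \code{del_xset}s).
#' @param references list of reference collections (may be empty).
#' @param n_select stop after this many selections (default: all).
#' @param threshold stop once the selected spread value drops below it.
#' @return data frame (rank, library, spread, size), class
#'   \code{del_spread}.
#' @export
spread_rank <- function(libraries, references = list(), n_select = NULL,
                        threshold = NULL) {
  stopifnot(length(libraries) >= 1L)
  if (is.null(names(libraries)))
    names(libraries) <- sprintf("lib%03d", seq_along(libraries))
  fps <- lapply(libraries, function(l)
    if (is.matrix(l)) l else path_fingerprints(as_smiles_vec(l)))
  ref_fp <- if (length(references))
    do.call(rbind, lapply(references, function(r)
      if (is.matrix(r)) r else path_fingerprints(as_smiles_vec(r))))
  else NULL
  remaining <- names(fps)
  out <- list()
  while (length(remaining) > 0L) {
    vals <- vapply(remaining, function(nm) {
      ref <- ref_fp
      if (is.null(ref)) {
        others <- setdiff(names(fps), nm)
        ref <- do.call(rbind, fps[others])
      }
      lib_measure(fps[[nm]], ref)
    }, numeric(1))
    sizes <- vapply(remaining, function(nm) nrow(fps[[nm]]), integer(1))
    ord <- order(-vals, -sizes, remaining)
    pick <- remaining[ord[1L]]
    out[[length(out) + 1L]] <- data.frame(
      rank = length(out) + 1L, library = pick,
      spread = vals[pick], size = sizes[pick], stringsAsFactors = FALSE)
    if (!is.null(threshold) && vals[pick] < threshold) {
      remaining <- character(0)
    } else {
      ref_fp <- rbind(ref_fp, fps[[pick]])
      remaining <- setdiff(remaining, pick)
      if (!is.null(n_select) && length(out) >= n_select)
        remaining <- character(0)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("del_spread", "data.frame")
  res
}

#' Building-block usage across selected libDESIGNs
#'
#' For every building block, the number of selected libDESIGNs whose
#' cap-compliant node lists include it, aggregated by heavy-atom count and
#' BBT multiplicity.
#'
#' @param selected_libs list of sized \code{del_libdesign}s.
#' @param bbs a \code{del_bbs} frame.
#' @param reactions a \code{del_reactions} frame.
#' @param sources source labels considered; NULL = all.
#' @return list with \code{per_bb} (data frame bb_id, usage) and
#'   \code{by_atoms} (data frame heavy_atoms, multiplicity, n_bbs_used,
#'   total_usage, mean_usage).
#' @export
bb_usage_report <- function(selected_libs, bbs, reactions, sources = NULL) {
  pool <- bbs[bbs$status == "ok", , drop = FALSE]
  if (!is.null(sources)) pool <- pool[pool$source %in% sources, , drop = FALSE]
  usage <- stats::setNames(numeric(nrow(pool)), pool$bb_id)
  for (lib in selected_libs) {
    used <- character(0)
    for (ci in seq_len(lib$n_cycles)) {
      node <- lib$nodes[[ci]]
      cap <- if (!is.null(lib$selection)) lib$selection[ci] else Inf
      for (i in seq_len(nrow(node))) {
        r <- reactions[node$conn_rxn[i], ]
        mem <- pool[!is.na(pool$bbt) & pool$bbt == node$bbt[i], , drop = FALSE]
        eff <- mem$heavy_atoms + r$bb_side_atom_delta
        used <- c(used, mem$bb_id[eff <= cap])
      }
    }
    used <- unique(used)
    usage[used] <- usage[used] + 1
  }
  per_bb <- data.frame(bb_id = names(usage), usage = as.numeric(usage),
                       stringsAsFactors = FALSE)
  key <- interaction(pool$heavy_atoms, pool$multiplicity, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(pool)), key), function(ix)
    data.frame(heavy_atoms = pool$heavy_atoms[ix[1L]],
               multiplicity = pool$multiplicity[ix[1L]],
               n_bbs_used = sum(usage[ix] > 0),
               total_usage = sum(usage[ix]),
               mean_usage = mean(usage[ix]))))
  agg <- agg[order(agg$multiplicity, agg$heavy_atoms), ]
  rownames(agg) <- NULL
  list(per_bb = per_bb, by_atoms = agg)
}
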