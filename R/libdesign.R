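# libDESIGNs: merged designs that can be produced in one experimental
# campaign.  Designs sharing topology (headpiece, cycle count) and the
# per-cycle enum indices of their reactions are pooled; each node then holds
# the union of member BBTs.  Library size under a heavy-atom constraint is
# computed by histogram convolution, never by enumeration.

#' Group designs into libDESIGNs
#'
#' Partition of the design list by (headpiece, number of cycles, per-cycle
#' deprotection enum index or none, per-cycle connection enum index).  Two
#' designs that differ only in equivalent reactions (e.g. amidation of a
#' primary vs a secondary amine, which share an enum index) and in their
#' BBTs fall into the same libDESIGN.
#'
#' @param designs list of \code{del_edesign}.
#' @param reactions a \code{del_reactions} frame.
#' @return list of \code{del_libdesign} objects: each holds the topology
#'   key, per-cycle nodes (data frame bbt/conn_rxn), per-cycle deprotection
#'   id sets, and its member traces.
#' @export
group_libdesigns <- function(designs, reactions) {
  if (length(designs) == 0L) return(list())
  enum_of <- function(rid) reactions[rid, "enum_index"]
  parsed <- lapply(designs, function(d) {
    cycles <- list(); cur_dep <- NA_character_
    for (e in d$edges) {
      if (e$kind == "deprotection") cur_dep <- e$rxn
      else {
        cycles[[length(cycles) + 1L]] <-
          list(deprot = cur_dep, conn = e$rxn, bbt = e$bbt)
        cur_dep <- NA_character_
      }
    }
    key <- paste0("hp:", d$headpiece, "|", paste(vapply(cycles, function(cy)
      paste0(if (is.na(cy$deprot)) "-" else enum_of(cy$deprot), ">",
             enum_of(cy$conn)), character(1)), collapse = "|"))
    list(key = key, headpiece = d$headpiece, cycles = cycles, trace = d$trace)
  })
  keys <- vapply(parsed, `[[`, character(1), "key")
  groups <- split(parsed, factor(keys, levels = unique(keys)))
  out <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    n_cycles <- length(g[[1L]]$cycles)
    nodes <- lapply(seq_len(n_cycles), function(ci) {
      df <- unique(data.frame(
        bbt = vapply(g, function(p) p$cycles[[ci]]$bbt, character(1)),
        conn_rxn = vapply(g, function(p) p$cycles[[ci]]$conn, character(1)),
        stringsAsFactors = FALSE))
      # one histogram entry per BBT: same-enum reactions share bb-side deltas
      df[!duplicated(df$bbt), , drop = FALSE]
    })
    deprots <- lapply(seq_len(n_cycles), function(ci)
      sort(unique(stats::na.omit(vapply(g, function(p)
        p$cycles[[ci]]$deprot, character(1))))))
    structure(list(id = sprintf("LD%05d", gi), key = g[[1L]]$key,
                   headpiece = g[[1L]]$headpiece, n_cycles = n_cycles,
                   nodes = nodes, deprots = deprots,
                   members = vapply(g, `[[`, character(1), "trace")),
              class = "del_libdesign")
  })
  out
}

#' @export
print.del_libdesign <- function(x, ...) {
  cat("libDESIGN", x$id, "(", x$key, ")\n")
  cat("  members:", length(x$members), "designs;",
      paste(vapply(x$nodes, nrow, integer(1)), collapse = "x"),
      "BBTs per cycle\n")
  if (!is.null(x$max_size))
    cat("  max size:", format(x$max_size, big.mark = ","),
        " median HA:", x$median_ha, "\n")
  invisible(x)
}

#' Effective heavy-atom histogram of one BBT under one reaction
#'
#' Histogram of the atoms each member building block contributes to the
#' product when consumed by the given connecting reaction.
#'
#' @param bbt_key canonical BBT key string (e.g. "3.6.0").
#' @param bbs a \code{del_bbs} frame (pre-filtered to the sizing source).
#' @param reaction the consuming reaction row.
#' @return named numeric histogram (names = heavy-atom value).
#' @export
bbt_ha_histogram <- function(bbt_key, bbs, reaction) {
  mem <- bbs[bbs$status == "ok" & !is.na(bbs$bbt) & bbs$bbt == bbt_key, ,
             drop = FALSE]
  if (nrow(mem) == 0L) return(numeric(0))
  hist_from_values(mem$heavy_atoms + reaction$bb_side_atom_delta)
}

# per-cycle node histogram: union over the node's BBTs
libdesign_node_hist <- function(lib, cycle, bbs, reactions) {
  node <- lib$nodes[[cycle]]
  h <- numeric(0)
  for (i in seq_len(nrow(node))) {
    hi <- bbt_ha_histogram(node$bbt[i], bbs, reactions[node$conn_rxn[i], ])
    h <- merge_hists(h, hi)
  }
  h
}

merge_hists <- function(h1, h2) {
  if (length(h1) == 0L) return(h2)
  if (length(h2) == 0L) return(h1)
  vals <- sort(unique(c(hist_values(h1), hist_values(h2))))
  out <- numeric(length(vals)); names(out) <- vals
  out[names(h1)] <- out[names(h1)] + h1
  out[names(h2)] <- out[names(h2)] + h2
  out
}

# fixed heavy-atom shift of a libDESIGN: headpiece plus per-cycle
# design-side reaction deltas and deprotection scaffold atoms
libdesign_shift <- function(lib, reactions, headpiece_atoms) {
  shift <- headpiece_atoms
  for (ci in seq_len(lib$n_cycles)) {
    shift <- shift + reactions[lib$nodes[[ci]]$conn_rxn[1L],
                               "design_side_atom_delta"]
    dep <- lib$deprots[[ci]]
    if (length(dep)) {
      r <- reactions[dep[1L], ]
      shift <- shift + r$design_side_atom_delta + r$scaffold_atoms
    }
  }
  shift
}

#' Product heavy-atom histogram by convolution
#'
#' The heavy-atom distribution of all products of a libDESIGN is the
#' discrete convolution across cycles of the per-node effective heavy-atom
#' histograms, shifted by the headpiece atom count plus all design-side
#' reaction deltas and scaffold atoms.  Its total equals the product of the
#' per-cycle building-block counts: library size and size distribution are
#' obtained without enumerating a single compound.
#'
#' @param lib a \code{del_libdesign}.
#' @param bbs a \code{del_bbs} frame (sizing source).
#' @param reactions a \code{del_reactions} frame.
#' @param headpiece_atoms heavy atoms contributed by the DNA headpiece
#'   linker (default 4).
#' @return named numeric histogram; empty (with attribute
#'   \code{empty_node}) when some node has no building blocks.
#' @export
convolve_design_ha <- function(lib, bbs, reactions, headpiece_atoms = 4L) {
  hists <- lapply(seq_len(lib$n_cycles), libdesign_node_hist,
                  lib = lib, bbs = bbs, reactions = reactions)
  if (any(lengths(hists) == 0L)) {
    out <- numeric(0); attr(out, "empty_node") <- which(lengths(hists) == 0L)
    return(out)
  }
  h <- Reduce(hist_convolve, hists)
  hist_shift(h, libdesign_shift(lib, reactions, headpiece_atoms))
}

#' Maximize library size under a median heavy-atom constraint
#'
#' Finds per-node heavy-atom caps (building blocks above a node's cap are
#' excluded) maximizing the number of products subject to the product
#' histogram's lower median not exceeding \code{target_median}.  Caps are
#' monotone truncations from above: any median-constrained selection closed
#' under replacing a building block by a lighter one is cap-representable.
#' The cap lattice is searched exhaustively when the number of combinations
#' of distinct per-node sizes is at most \code{exact_limit}; otherwise a
#' greedy coordinate descent lowers, at each step, the cap whose reduction
#' preserves the largest library, which is approximate.
#'
#' @param lib a \code{del_libdesign}.
#' @param bbs sizing building blocks (\code{del_bbs}).
#' @param reactions a \code{del_reactions} frame.
#' @param target_median largest admissible median product heavy-atom count.
#' @param headpiece_atoms headpiece contribution (default 4).
#' @param exact_limit lattice size bound for the exact search.
#' @return the libDESIGN with fields \code{selection} (per-cycle caps),
#'   \code{max_size}, \code{median_ha}, \code{ha_histogram} and
#'   \code{feasible} filled in.
#' @export
maximize_size <- function(lib, bbs, reactions, target_median,
                          headpiece_atoms = 4L, exact_limit = 1e5) {
  hists <- lapply(seq_len(lib$n_cycles), libdesign_node_hist,
                  lib = lib, bbs = bbs, reactions = reactions)
  shift <- libdesign_shift(lib, reactions, headpiece_atoms)
  if (any(lengths(hists) == 0L)) {
    lib$selection <- NULL; lib$max_size <- 0; lib$median_ha <- NA_integer_
    lib$ha_histogram <- numeric(0); lib$feasible <- FALSE
    return(lib)
  }
  # per node: censored histograms for every distinct-size cap
  caps <- lapply(hists, hist_values)            # ascending distinct sizes
  pref <- lapply(hists, function(h)
    lapply(seq_along(h), function(i) h[seq_len(i)]))
  eval_combo <- function(idx) {
    sel <- mapply(function(p, i) p[[i]], pref, idx, SIMPLIFY = FALSE)
    h <- hist_shift(Reduce(hist_convolve, sel), shift)
    list(size = hist_total(h), median = hist_median(h), hist = h)
  }
  m <- vapply(caps, length, integer(1))
  best <- NULL; best_idx <- NULL
  if (prod(m) <= exact_limit) {
    grid <- as.matrix(expand.grid(lapply(m, seq_len)))
    for (g in seq_len(nrow(grid))) {
      ev <- eval_combo(grid[g, ])
      if (ev$median <= target_median &&
          (is.null(best) || ev$size > best$size)) {
        best <- ev; best_idx <- grid[g, ]
      }
    }
  } else {
    idx <- m
    repeat {
      ev <- eval_combo(idx)
      if (ev$median <= target_median) { best <- ev; best_idx <- idx; break }
      cand_j <- which(idx > 1L)
      if (length(cand_j) == 0L) break
      sizes <- vapply(cand_j, function(j) {
        idx2 <- idx; idx2[j] <- idx2[j] - 1L
        eval_combo(idx2)$size
      }, numeric(1))
      j <- cand_j[which.max(sizes)]
      idx[j] <- idx[j] - 1L
    }
  }
  if (is.null(best)) {
    lib$selection <- NULL; lib$max_size <- 0; lib$median_ha <- NA_integer_
    lib$ha_histogram <- numeric(0); lib$feasible <- FALSE
  } else {
    lib$selection <- mapply(function(cp, i) cp[i], caps, best_idx)
    lib$max_size <- best$size
    lib$median_ha <- best$median
    lib$ha_histogram <- best$hist
    lib$feasible <- TRUE
  }
  lib
}

#' Select libDESIGNs by achievable size
#'
#' Runs \code{maximize_size} on every libDESIGN using the sizing source
#' (by default only internal building blocks, mirroring production
#' practice) and keeps those that can reach \code{min_size} products while
#' holding the median heavy-atom constraint, sorted by achievable size.
#'
#' @param libs list of \code{del_libdesign}.
#' @param bbs a \code{del_bbs} frame.
#' @param reactions a \code{del_reactions} frame.
#' @param min_size minimum library size.
#' @param target_median median heavy-atom cap.
#' @param headpiece_atoms headpiece contribution.
#' @param sizing_source source label used for sizing; NULL for all sources.
#' @return list of surviving libDESIGNs (fields filled by
#'   \code{maximize_size}), sorted by decreasing \code{max_size}.
#' @export
select_libdesigns <- function(libs, bbs, reactions, min_size, target_median,
                              headpiece_atoms = 4L, sizing_source = "internal") {
  sizing <- if (is.null(sizing_source)) bbs
            else bbs[bbs$source == sizing_source, , drop = FALSE]
  libs <- lapply(libs, maximize_size, bbs = sizing, reactions = reactions,
                 target_median = target_median,
                 headpiece_atoms = headpiece_atoms)
  keep <- vapply(libs, function(l) l$max_size >= min_size, logical(1))
  libs <- libs[keep]
  ord <- order(-vapply(libs, `[[`, numeric(1), "max_size"),
               vapply(libs, `[[`, character(1), "id"))
  libs[ord]
}

# JSON-serializable record of a sized libDESIGN
libdesign_record <- function(lib) {
  list(id = lib$id, key = lib$key, headpiece = lib$headpiece,
       n_cycles = lib$n_cycles,
       nodes = lapply(seq_len(lib$n_cycles), function(ci)
         list(bbts = lib$nodes[[ci]]$bbt, conn_rxns = lib$nodes[[ci]]$conn_rxn,
              deprots = lib$deprots[[ci]],
              cap = if (!is.null(lib$selection)) lib$selection[ci] else NA)),
       n_members = length(lib$members),
       max_size = lib$max_size %||% NA,
       median_ha = lib$median_ha %||% NA,
       ha_histogram = if (!is.null(lib$ha_histogram))
         as.list(lib$ha_histogram) else NULL)
}
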