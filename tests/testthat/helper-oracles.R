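# Independent brute-force oracles.  These deliberately re-derive results
# with the simplest possible code (recursion, double loops, exhaustive
# enumeration) and never call the implementation paths they check.

# --- design generation: recursive expansion over the same rule set --------
oracle_grow <- function(headpieces, reactions, bbts, matrices, n_cycles) {
  deprots <- reactions[reactions$kind == "deprotection", , drop = FALSE]
  conns <- reactions[reactions$kind == "connecting", , drop = FALSE]
  on_bad <- function(rxn, live, consumed) {
    i <- match(consumed, live); if (!is.na(i)) live <- live[-i]
    any(paste(rxn, live, sep = "|") %in% matrices$on_dna)
  }
  off_bad <- function(rxn, side, consumed) {
    i <- match(consumed, side); if (!is.na(i)) side <- side[-i]
    any(paste(rxn, side, sep = "|") %in% matrices$off_dna)
  }
  recurse <- function(live, trace, cycles_left) {
    if (cycles_left == 0L) return(trace)
    out <- character(0)
    states <- list(list(live = live, trace = trace))
    for (k in seq_len(nrow(deprots))) {
      r <- deprots[k, ]
      if (r$design_fg %in% live && !on_bad(r$rxn_id, live, r$design_fg)) {
        lv <- live[-match(r$design_fg, live)]
        lv <- sort(c(lv, unlist(r$outputs)))
        states[[length(states) + 1L]] <-
          list(live = lv, trace = paste0(trace, "|d:", r$rxn_id))
      }
    }
    for (st in states) {
      for (k in seq_len(nrow(conns))) {
        r <- conns[k, ]
        if (!r$design_fg %in% st$live) next
        for (b in seq_len(nrow(bbts))) {
          bbt <- bbts[b, ]
          side <- bbt[bbt != 0L]
          if (!r$bb_fg %in% side) next
          if (on_bad(r$rxn_id, st$live, r$design_fg)) next
          if (off_bad(r$rxn_id, side, r$bb_fg)) next
          lv <- st$live[-match(r$design_fg, st$live)]
          spect <- side[-match(r$bb_fg, side)]
          lv <- sort(c(lv, unlist(r$outputs), spect))
          out <- c(out, recurse(lv, paste0(st$trace, "|c:", r$rxn_id, ":",
                                           paste(bbt, collapse = ".")),
                                cycles_left - 1L))
        }
      }
    }
    unique(out)
  }
  unique(unlist(lapply(headpieces, function(hp)
    recurse(as.integer(hp), paste0("hp:", hp), n_cycles))))
}

# --- heavy atoms: exhaustive sum over all BB combinations -----------------
oracle_product_sizes <- function(node_values, shift) {
  grid <- do.call(expand.grid, node_values)
  rowSums(as.matrix(grid)) + shift
}

# --- size maximization: exhaustive search over the cap lattice ------------
oracle_max_size <- function(node_values, shift, target_median) {
  lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
  caps <- lapply(node_values, function(v) sort(unique(v)))
  grid <- do.call(expand.grid, caps)
  best <- 0; best_median <- NA
  for (g in seq_len(nrow(grid))) {
    sel <- lapply(seq_along(node_values), function(j)
      node_values[[j]][node_values[[j]] <= grid[g, j]])
    if (any(lengths(sel) == 0L)) next
    sizes <- oracle_product_sizes(sel, shift)
    if (lower_median(sizes) <= target_median && length(sizes) > best) {
      best <- length(sizes); best_median <- lower_median(sizes)
    }
  }
  list(max_size = best, median = best_median)
}

# --- diversity: double-loop Tanimoto on raw fingerprint vectors -----------
oracle_avg_pairwise <- function(fa, fb) {
  tot <- 0
  for (i in seq_len(nrow(fa))) for (j in seq_len(nrow(fb))) {
    a <- fa[i, ]; b <- fb[j, ]
    inter <- sum(a & b); uni <- sum(a | b)
    tot <- tot + (1 - if (uni > 0) inter / uni else 1)
  }
  tot / (nrow(fa) * nrow(fb))
}

oracle_nn <- function(fx, fr) {
  vapply(seq_len(nrow(fx)), function(i) {
    min(vapply(seq_len(nrow(fr)), function(j) {
      inter <- sum(fx[i, ] & fr[j, ]); uni <- sum(fx[i, ] | fr[j, ])
      1 - if (uni > 0) inter / uni else 1
    }, numeric(1)))
  }, numeric(1))
}

# greedy spread recomputed from scratch at every step
oracle_spread <- function(lib_fps, ref_fps) {
  ref <- do.call(rbind, ref_fps)
  remaining <- names(lib_fps)
  out <- NULL
  while (length(remaining)) {
    vals <- vapply(remaining, function(nm) mean(oracle_nn(lib_fps[[nm]], ref)),
                   numeric(1))
    sizes <- vapply(remaining, function(nm) nrow(lib_fps[[nm]]), integer(1))
    pick <- remaining[order(-vals, -sizes, remaining)[1]]
    out <- rbind(out, data.frame(library = pick, spread = vals[pick],
                                 stringsAsFactors = FALSE))
    ref <- rbind(ref, lib_fps[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  rownames(out) <- NULL
  out
}

# all 3-subsets (null as ordinary element) filtered by pairwise rules
oracle_bbt_space <- function(fg_ids_with_null, incompat) {
  tri <- t(utils::combn(sort(fg_ids_with_null), 3L))
  ok <- apply(tri, 1L, function(s) {
    s <- s[s != 0L]
    if (length(s) < 2L) return(TRUE)
    prs <- utils::combn(s, 2L)
    !any(paste(prs[1, ], prs[2, ]) %in% paste(incompat[, 1], incompat[, 2]))
  })
  tri[ok, , drop = FALSE]
}
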