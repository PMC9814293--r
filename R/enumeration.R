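# Enumeration: translate a sized libDESIGN into an executable config and
# draw random product samples (X-Sets) of any size, without ever
# enumerating the full library.

#' Default headpiece surrogate fragments
#'
#' The DNA headpiece and its linker are represented by a small surrogate
#' fragment carrying the headpiece FG; each default surrogate has exactly 4
#' heavy atoms, the headpiece contribution used in heavy-atom accounting.
#'
#' @return data frame with columns fg_name, smiles, atoms.
#' @export
default_headpieces <- function() {
  data.frame(
    fg_name = c("amine_aliphatic_primary", "carboxylic_acid", "aldehyde",
                "azide", "thiol"),
    smiles = c("NCCO", "CC(=O)O", "CCC=O", "CN=[N+]=[N-]", "OCCS"),
    atoms = c(4L, 4L, 4L, 4L, 4L),
    stringsAsFactors = FALSE)
}

#' Build an enumeration config for a libDESIGN
#'
#' Collects, per cycle, the cap-compliant building blocks of every BBT at
#' that node together with the reaction transform that consumes them, plus
#' the headpiece surrogate, into a self-contained instruction object the
#' sampler executes.
#'
#' @param lib a sized \code{del_libdesign} (after \code{maximize_size}).
#' @param bbs a \code{del_bbs} frame; building blocks above a node's
#'   heavy-atom cap are excluded.
#' @param reactions a \code{del_reactions} frame.
#' @param ontology a \code{del_ontology}.
#' @param headpieces surrogate table as \code{default_headpieces()}.
#' @param sources source labels to draw building blocks from; NULL = all.
#' @return object of class \code{del_enum_config}.
#' @export
enum_config <- function(lib, bbs, reactions, ontology,
                        headpieces = default_headpieces(), sources = NULL) {
  hp_name <- fg_name(ontology, lib$headpiece)
  hp <- headpieces[headpieces$fg_name == hp_name, , drop = FALSE]
  if (nrow(hp) == 0L) stop("no headpiece surrogate for FG ", hp_name)
  pool <- bbs[bbs$status == "ok", , drop = FALSE]
  if (!is.null(sources)) pool <- pool[pool$source %in% sources, , drop = FALSE]
  steps <- lapply(seq_len(lib$n_cycles), function(ci) {
    node <- lib$nodes[[ci]]
    cap <- if (!is.null(lib$selection)) lib$selection[ci] else Inf
    dep <- lib$deprots[[ci]]
    bb_tab <- do.call(rbind, lapply(seq_len(nrow(node)), function(i) {
      r <- reactions[node$conn_rxn[i], ]
      mem <- pool[!is.na(pool$bbt) & pool$bbt == node$bbt[i], , drop = FALSE]
      eff <- mem$heavy_atoms + r$bb_side_atom_delta
      mem <- mem[eff <= cap, , drop = FALSE]
      if (nrow(mem) == 0L) return(NULL)
      data.frame(bb_id = mem$bb_id, smiles = mem$canonical_smiles,
                 bbt = mem$bbt, eff_ha = eff[eff <= cap],
                 conn_rxn = r$rxn_id, transform = r$transform,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(bb_tab) || nrow(bb_tab) == 0L)
      stop("empty building-block list at cycle ", ci, " of ", lib$id)
    bb_tab <- bb_tab[order(bb_tab$bb_id), , drop = FALSE]
    rownames(bb_tab) <- NULL
    list(cycle = ci,
         deprot_rxn = if (length(dep)) dep[1L] else NA_character_,
         deprot_transform = if (length(dep)) reactions[dep[1L], "transform"]
                            else NA_character_,
         bbs = bb_tab)
  })
  structure(list(libdesign_id = lib$id, key = lib$key,
                 headpiece = list(fg = hp_name, smiles = hp$smiles[1L],
                                  atoms = hp$atoms[1L]),
                 ha_shift = libdesign_shift(lib, reactions, hp$atoms[1L]),
                 steps = steps),
            class = "del_enum_config")
}

#' @export
print.del_enum_config <- function(x, ...) {
  sizes <- vapply(x$steps, function(s) nrow(s$bbs), integer(1))
  cat("Enumeration config for", x$libdesign_id, "\n  headpiece:",
      x$headpiece$fg, paste0("(", x$headpiece$smiles, ")"),
      "\n  cycle BB counts:", paste(sizes, collapse = " x "),
      "=", format(prod(sizes), big.mark = ","), "products\n")
  invisible(x)
}

#' Write / read an enumeration config (JSON)
#'
#' @param cfg a \code{del_enum_config}.
#' @param path JSON file path.
#' @return \code{read_enum_config} returns the config; the writer returns
#'   the path invisibly.  \code{read_enum_config(write_enum_config(cfg, p))}
#'   reproduces \code{cfg}.
#' @export
write_enum_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_enum_config
#' @export
read_enum_config <- function(path) {
  raw <- jsonlite::read_json(path)
  steps <- lapply(raw$steps, function(s) {
    bbs <- data.frame(lapply(s$bbs, function(col) unlist(col)),
                      stringsAsFactors = FALSE)
    bbs$eff_ha <- as.integer(bbs$eff_ha)
    list(cycle = as.integer(s$cycle),
         deprot_rxn = as.character(s$deprot_rxn %||% NA_character_),
         deprot_transform = as.character(s$deprot_transform %||% NA_character_),
         bbs = bbs)
  })
  structure(list(libdesign_id = raw$libdesign_id, key = raw$key,
                 headpiece = list(fg = raw$headpiece$fg,
                                  smiles = raw$headpiece$smiles,
                                  atoms = as.integer(raw$headpiece$atoms)),
                 ha_shift = as.integer(raw$ha_shift), steps = steps),
            class = "del_enum_config")
}

library_size <- function(cfg)
  prod(vapply(cfg$steps, function(s) nrow(s$bbs), integer(1)))

# decode 0-based flat indices into per-node 1-based row indices
decode_tuples <- function(idx0, sizes) {
  k <- length(sizes)
  out <- matrix(0L, nrow = length(idx0), ncol = k)
  rest <- idx0
  for (j in k:1) {
    out[, j] <- as.integer(rest %% sizes[j]) + 1L
    rest <- floor(rest / sizes[j])
  }
  out
}

#' Sample products from a libDESIGN
#'
#' Draws provenance tuples uniformly without replacement from the Cartesian
#' product of the per-cycle building-block lists, then virtually
#' synthesizes each product by replaying the deprotection and connection
#' transforms from the headpiece surrogate.  Results are byte-reproducible
#' under a fixed seed.  Tuples whose transforms fail are logged and
#' resampled; a failure rate above \code{failure_threshold} is an error.
#'
#' @param cfg a \code{del_enum_config}.
#' @param n sample size; capped at the library size (with a warning).
#' @param seed integer seed.
#' @param structures synthesize structures via the rewrite backend
#'   (\code{TRUE}) or return provenance and model heavy atoms only
#'   (\code{FALSE}), which is exact for heavy-atom statistics and fast.
#' @param failure_threshold maximum tolerated transform failure rate.
#' @return object of class \code{del_xset}: data frame with product id,
#'   provenance (bb ids per cycle), predicted heavy atoms and, when
#'   \code{structures}, the product SMILES and its actual heavy atoms.
#' @export
sample_products <- function(cfg, n, seed = 1L, structures = TRUE,
                            failure_threshold = 0.05) {
  stopifnot(n >= 1L)
  sizes <- vapply(cfg$steps, function(s) nrow(s$bbs), integer(1))
  N <- prod(sizes)
  if (n > N) {
    warning("requested ", n, " > library size ", N, "; returning full library")
    n <- N
  }
  set.seed(seed)
  if (N <= .Machine$integer.max) {
    idx0 <- sample.int(N, n) - 1
  } else {
    # rejection sampling on 53-bit uniforms for astronomically large spaces
    idx0 <- numeric(0)
    while (length(idx0) < n)
      idx0 <- unique(c(idx0, floor(stats::runif(n) * N)))
    idx0 <- idx0[seq_len(n)]
  }
  tup <- decode_tuples(idx0, sizes)
  prov <- vapply(seq_len(n), function(i) paste(vapply(seq_along(sizes),
    function(j) cfg$steps[[j]]$bbs$bb_id[tup[i, j]], character(1)),
    collapse = ";"), character(1))
  pred <- cfg$ha_shift + rowSums(vapply(seq_along(sizes), function(j)
    cfg$steps[[j]]$bbs$eff_ha[tup[, j]], numeric(n)))
  out <- data.frame(product_id = sprintf("%s_p%06d", cfg$libdesign_id, seq_len(n)),
                    provenance = prov, predicted_ha = as.integer(pred),
                    stringsAsFactors = FALSE)
  if (structures) {
    jobs <- lapply(seq_len(n), function(i) {
      steps <- list()
      for (j in seq_along(sizes)) {
        st <- cfg$steps[[j]]
        if (!is.na(st$deprot_transform))
          steps[[length(steps) + 1L]] <- list(transform = st$deprot_transform,
                                              bb = NULL)
        steps[[length(steps) + 1L]] <-
          list(transform = st$bbs$transform[tup[i, j]],
               bb = st$bbs$smiles[tup[i, j]])
      }
      list(id = out$product_id[i], start = cfg$headpiece$smiles, steps = steps)
    })
    res <- rdkit_transform_batch(jobs)
    res <- res[match(out$product_id, res$id), ]
    fail <- res$status != "ok"
    if (mean(fail) > failure_threshold)
      stop("transform failure rate ", round(mean(fail), 3),
           " exceeds threshold ", failure_threshold)
    out$smiles <- res$smiles
    out$heavy_atoms <- res$natoms
    out$transform_status <- res$status
    out <- out[!fail, , drop = FALSE]
  }
  attr(out, "seed") <- seed
  attr(out, "libdesign_id") <- cfg$libdesign_id
  class(out) <- c("del_xset", "data.frame")
  out
}

#' Apply one reaction transform to one structure
#'
#' @param current SMILES of the growing design.
#' @param step reaction SMARTS (or a reaction row, whose transform is used).
#' @param bb building-block SMILES for connecting steps, NULL for
#'   deprotections.
#' @return product SMILES with attributes \code{natoms} and \code{alts}
#'   (number of distinct products at ambiguous sites; the lowest canonical
#'   SMILES is kept).
#' @export
apply_transform <- function(current, step, bb = NULL) {
  smarts <- if (is.character(step)) step else step$transform
  res <- rdkit_transform_batch(list(list(id = "x", start = current,
                                         steps = list(list(transform = smarts,
                                                           bb = bb)))))
  if (res$status != "ok") stop("transform failed: ", res$status)
  structure(res$smiles, natoms = res$natoms, alts = res$alts)
}

#' Write an X-Set as a SMILES table
#'
#' @param xset a \code{del_xset} with structures.
#' @param path output file.
#' @export
write_xset <- function(xset, path) {
  utils::write.csv(as.data.frame(xset), path, row.names = FALSE)
  invisible(path)
}
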