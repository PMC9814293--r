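# Synthetic-data generators: building-block collections with known ground
# truth, reference compound collections, and complete toy systems, so every
# pipeline stage is testable without proprietary catalogs.  Structures are
# assembled from a vetted table of FG substituent templates attached to a
# compact branched-alkane skeleton, which guarantees chemical validity and
# makes the intended BBT assignment recoverable by annotation.

fg_fragment_table <- function() {
  data.frame(
    fg_name = c("amine_aliphatic_primary", "amine_aliphatic_secondary",
                "amine_aromatic", "carboxylic_acid", "aldehyde", "ketone",
                "phenol", "thiol", "azide", "alkyne_terminal", "aryl_halide",
                "boronate", "sulfonyl_chloride", "isocyanate", "boc_amine",
                "nitro_aromatic", "fluoronitroarene_ortho", "acyl_chloride",
                "ester"),
    fragment = c("N", "NC", "c1ccc(N)cc1", "C(=O)O", "C=O", "C(C)=O",
                 "c1ccc(O)cc1", "S", "N=[N+]=[N-]", "C#C", "c1ccc(Br)cc1",
                 "c1ccc(B(O)O)cc1", "S(Cl)(=O)=O", "N=C=O", "NC(=O)OC(C)(C)C",
                 "c1ccc([N+](=O)[O-])cc1", "c1ccc(F)c([N+](=O)[O-])c1",
                 "C(=O)Cl", "C(=O)OC"),
    atoms = c(1L, 2L, 7L, 3L, 2L, 3L, 7L, 1L, 3L, 2L, 7L, 9L, 4L, 3L, 8L,
              9L, 10L, 2L, 4L),
    stringsAsFactors = FALSE)
}

# assemble a branched-alkane skeleton of `n_skel` carbons carrying the FG
# substituents; methyl branches (non-rotatable) absorb atoms so rotatable
# bonds stay within curation limits
build_bb_smiles <- function(frags, n_skel) {
  n_skel <- max(n_skel, 1L)
  # random chain length within the feasible window gives structural variety
  lo <- max(1L, ceiling(n_skel / 3))
  chain <- if (lo >= min(n_skel, 6L)) min(n_skel, 6L)
           else sample(lo:min(n_skel, 6L), 1L)
  repeat {
    # substituents at the ends (middle for trifunctional); on tiny skeletons
    # several may stack on one carbon, within carbon valence
    pos <- switch(length(frags), 1L, c(1L, chain),
                  c(1L, max(2L, chain %/% 2L + 1L), chain))
    pos <- pmin(pos, chain)
    nsub <- tabulate(pos, chain)
    chain_bonds <- if (chain == 1L) 0L else
      ifelse(seq_len(chain) %in% c(1L, chain), 1L, 2L)
    cap <- pmax(0L, 4L - chain_bonds - nsub)   # methyl capacity per carbon
    extra <- n_skel - chain
    if (extra <= sum(cap) || chain >= n_skel) break
    chain <- chain + 1L                        # lengthen when branches overflow
  }
  branches <- integer(chain)
  open <- which(cap > 0L)
  while (extra > 0L) {
    j <- if (length(open) == 1L) open else sample(open, 1L)
    branches[j] <- branches[j] + 1L
    extra <- extra - 1L
    if (branches[j] >= cap[j]) open <- setdiff(open, j)
  }
  subs <- vector("list", chain)
  for (k in seq_along(frags)) subs[[pos[k]]] <- c(subs[[pos[k]]], frags[k])
  paste(vapply(seq_len(chain), function(j) {
    att <- c(unlist(subs[[j]]), rep("C", branches[j]))
    paste0("C", paste0(vapply(att, function(a) paste0("(", a, ")"),
                              character(1)), collapse = ""))
  }, character(1)), collapse = "")
}

#' Generate a synthetic building-block collection
#'
#' Each request row asks for \code{n} building blocks of one intended BBT
#' (FG names separated by "+"), with heavy atoms drawn from a truncated
#' normal distribution, tagged with a source.  The generator records the
#' ground truth (intended BBT and atom count per BB) in a manifest;
#' regenerating with the same seed reproduces the collection exactly.
#'
#' @param requests data frame with columns \code{fgs} (e.g.
#'   "carboxylic_acid" or "boc_amine+carboxylic_acid"), \code{n},
#'   \code{mean_atoms}, \code{sd_atoms}, \code{source}.
#' @param ontology a \code{del_ontology}.
#' @param seed integer seed.
#' @param salt_fraction fraction of emitted SMILES decorated with an HCl
#'   salt fragment (exercises standardization; default 0).
#' @return list with \code{bbs} (data frame bb_id, smiles, source) and
#'   \code{manifest} (adds intended_bbt, intended_atoms).
#' @export
make_bb_collection <- function(requests, ontology, seed = 1L,
                               salt_fraction = 0) {
  frag_tab <- fg_fragment_table()
  set.seed(seed)
  rows <- list()
  for (q in seq_len(nrow(requests))) {
    fg_names <- strsplit(requests$fgs[q], "+", fixed = TRUE)[[1L]]
    miss <- setdiff(fg_names, frag_tab$fg_name)
    if (length(miss)) stop("no fragment template for FG(s): ",
                           paste(miss, collapse = ", "))
    ids <- fg_id(ontology, fg_names)
    if (has_incompatible_pair(ids, ontology$incompatible_pairs))
      stop("requested FG combination is incompatible: ", requests$fgs[q])
    fr <- frag_tab[match(fg_names, frag_tab$fg_name), ]
    base <- sum(fr$atoms)
    n <- requests$n[q]
    target <- rtrunc_norm_int(n, requests$mean_atoms[q], requests$sd_atoms[q],
                              lower = base + 1L, upper = base + 18L)
    for (i in seq_len(n)) {
      smi <- build_bb_smiles(fr$fragment, target[i] - base)
      if (salt_fraction > 0 && stats::runif(1) < salt_fraction)
        smi <- paste0(smi, ".Cl")
      rows[[length(rows) + 1L]] <- data.frame(
        bb_id = sprintf("%s_%s_%03d", substr(requests$source[q], 1, 3),
                        paste(sprintf("f%02d", ids), collapse = ""), i),
        smiles = smi, source = requests$source[q],
        intended_bbt = bbt_key(canonical_bbt(ids, ontology)),
        intended_atoms = target[i],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$bb_id <- make.unique(manifest$bb_id, sep = "_")
  list(bbs = manifest[, c("bb_id", "smiles", "source")], manifest = manifest)
}

#' Generate a synthetic reference compound collection
#'
#' Drug-like reference sets (screening-deck surrogates) for diversity
#' analysis: each compound combines one or two substituent templates on a
#' branched skeleton, with heavy atoms centered on \code{mean_atoms}
#' (default 25, a typical screening-collection mean).
#'
#' @param n number of compounds.
#' @param mean_atoms,sd_atoms heavy-atom distribution parameters.
#' @param seed integer seed.
#' @return named character vector of SMILES.
#' @export
make_reference_collection <- function(n, mean_atoms = 25, sd_atoms = 4,
                                      seed = 1L) {
  frag_tab <- fg_fragment_table()
  # aromatic-rich, benign templates for drug-likeness
  pool <- frag_tab[frag_tab$fg_name %in%
    c("phenol", "amine_aromatic", "ketone", "ester", "aryl_halide",
      "amine_aliphatic_secondary", "nitro_aromatic", "carboxylic_acid"), ]
  set.seed(seed)
  out <- character(n)
  for (i in seq_len(n)) {
    k <- sample(1:2, 1L)
    fr <- pool[sample(nrow(pool), k), ]
    base <- sum(fr$atoms)
    target <- rtrunc_norm_int(1L, mean_atoms, sd_atoms,
                              lower = base + 2L, upper = base + 18L)
    out[i] <- build_bb_smiles(fr$fragment, target - base)
  }
  names(out) <- sprintf("ref%05d", seq_len(n))
  out
}

#' Generate a complete toy design system
#'
#' \code{small}: a hand-checkable system (one headpiece, 3 reactions,
#' ~30 building blocks over 4 BBTs) on which design generation can be
#' verified against brute-force recursion.  \code{medium}: the full default
#' ontology and reaction set with a few hundred building blocks over ~18
#' BBTs in two sources (internal skewed heavier, as production collections
#' are) plus two synthetic reference collections; supports 2-cycle
#' triazine and SNAr/benzimidazole routes end to end.
#'
#' @param scale "small" or "medium".
#' @param seed integer seed.
#' @return list with ontology, reactions, matrices, bb_requests, bbs
#'   (raw data frame), manifest, references (list of SMILES vectors),
#'   headpieces (FG names) and params defaults.
#' @export
make_toy_system <- function(scale = c("small", "medium"), seed = 1L) {
  scale <- match.arg(scale)
  ontology <- load_ontology()
  if (scale == "small") {
    reactions <- load_reactions(ontology = ontology)
    reactions <- reactions[reactions$rxn_id %in%
      c("amide_amine_on_design_prim", "amide_acid_on_design_prim",
        "boc_removal"), ]
    req <- data.frame(
      fgs = c("carboxylic_acid", "amine_aliphatic_primary",
              "boc_amine+carboxylic_acid", "amine_aliphatic_primary+carboxylic_acid"),
      n = c(10L, 8L, 6L, 6L),
      mean_atoms = c(10, 9, 14, 12), sd_atoms = c(2, 2, 2, 2),
      source = "internal", stringsAsFactors = FALSE)
    coll <- make_bb_collection(req, ontology, seed = derive_seed(seed, 1L))
    refs <- list(screening = make_reference_collection(
      40L, mean_atoms = 18, sd_atoms = 3, seed = derive_seed(seed, 2L)))
    headpieces <- "amine_aliphatic_primary"
  } else {
    reactions <- load_reactions(ontology = ontology)
    req <- data.frame(
      fgs = c("carboxylic_acid", "carboxylic_acid",
              "amine_aliphatic_primary", "amine_aliphatic_primary",
              "amine_aliphatic_secondary", "amine_aliphatic_secondary",
              "aldehyde", "aldehyde", "phenol", "phenol",
              "carboxylic_acid+fluoronitroarene_ortho",
              "carboxylic_acid+fluoronitroarene_ortho",
              "boc_amine+carboxylic_acid",
              "amine_aliphatic_primary+carboxylic_acid",
              "carboxylic_acid+phenol", "aldehyde+carboxylic_acid",
              "sulfonyl_chloride", "isocyanate", "azide", "alkyne_terminal",
              "aryl_halide", "boronate",
              "boc_amine+carboxylic_acid+phenol",
              "amine_aliphatic_primary+carboxylic_acid+phenol"),
      n = c(45L, 30L, 45L, 30L, 18L, 12L, 18L, 14L, 15L, 10L,
            18L, 8L, 18L, 14L, 10L, 8L, 8L, 6L, 6L, 8L, 8L, 8L, 8L, 6L),
      # building blocks span roughly 5-25 heavy atoms, with the internal
      # source skewed heavier than the external one
      mean_atoms = rep(c(14, 12), length.out = 24L),
      sd_atoms = rep(c(4, 4), length.out = 24L),
      source = rep(c("internal", "external"), length.out = 24L),
      stringsAsFactors = FALSE)
    # keep bifunctional/trifunctional rows mostly internal
    req$source[11:24] <- c("internal", "external", "internal", "internal",
                           "internal", "internal", "internal", "internal",
                           "internal", "internal", "internal", "internal",
                           "internal", "internal")
    req$mean_atoms[11:24] <- c(16, 14, 16, 15, 15, 15, 12, 11, 11, 12,
                               13, 14, 18, 17)
    req$sd_atoms[11:24] <- 3
    coll <- make_bb_collection(req, ontology, seed = derive_seed(seed, 1L))
    refs <- list(
      screening = make_reference_collection(120L, mean_atoms = 25,
                                            sd_atoms = 4,
                                            seed = derive_seed(seed, 2L)),
      prior_del = make_reference_collection(80L, mean_atoms = 30,
                                            sd_atoms = 5,
                                            seed = derive_seed(seed, 3L)))
    headpieces <- c("amine_aliphatic_primary", "carboxylic_acid")
  }
  list(ontology = ontology, reactions = reactions,
       matrices = load_reaction_fg_incompat(ontology = ontology),
       bbs = coll$bbs, manifest = coll$manifest, references = refs,
       headpieces = headpieces,
       params = list(n_cycles = 2L, min_library_size = if (scale == "small") 10
                     else 1000,
                     target_median_atoms = 29L, headpiece_atoms = 4L,
                     sample_size = if (scale == "small") 50L else 1000L,
                     seed = seed))
}

#' Pad an ontology with placeholder FGs
#'
#' Extends an ontology to a given total FG count (null included) with inert
#' placeholder entries, for combinatorial studies of the BBT space at the
#' scale of a full production ontology.
#'
#' @param ontology a \code{del_ontology}.
#' @param n_total desired FG count including the null FG.
#' @return a \code{del_ontology} with placeholder FGs appended.
#' @export
pad_ontology <- function(ontology, n_total) {
  have <- nrow(ontology$fgs)            # includes the null row
  need <- n_total - have
  if (need < 0L) stop("ontology already has more than ", n_total, " FGs")
  if (need == 0L) return(ontology)
  nxt <- max(ontology$fgs$id) + seq_len(need)
  pad <- data.frame(id = nxt, name = sprintf("placeholder_%02d", seq_len(need)),
                    smarts = "[#6]", parent = NA, protected = FALSE,
                    parent_id = NA_integer_, stringsAsFactors = FALSE)
  ontology$fgs <- rbind(ontology$fgs, pad)
  ontology
}
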