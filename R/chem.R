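# Chemistry backend: structure standardization via the OpenBabel CLI,
# SMARTS annotation / descriptors / path fingerprints via ChemmineR and
# ChemmineOB, and reaction-SMARTS rewrites via a batched RDKit helper.

find_obabel <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("the 'obabel' executable (Open Babel 3) is required")
  p
}

find_python <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("a 'python' executable with RDKit is required")
  p
}

#' Standardize raw structures
#'
#' Cleans raw SMILES the way building-block collections are curated before
#' typing: salt and solvent fragments are stripped (largest contiguous
#' fragment retained), common free base / acid forms are consolidated by
#' charge neutralization, and the survivor is emitted as a canonical
#' SMILES.  The operation is idempotent on its own output.
#'
#' @param smiles character vector of raw SMILES.
#' @return data frame with columns \code{input}, \code{canonical_smiles}
#'   (NA on failure), \code{status} ("ok" or "rejected") and \code{reason}
#'   ("parse", "no_organic_fragment" or "").
#' @export
standardize_smiles <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(input = smiles,
                    canonical_smiles = NA_character_,
                    status = "rejected", reason = "parse",
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  ids <- sprintf("m%08d", seq_len(n))
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, ids, sep = "\t"), fin)
  suppressWarnings(system2(find_obabel(),
    c("-ismi", fin, "-ocan", "-O", fout, "-r", "--neutralize", "-e"),
    stdout = FALSE, stderr = FALSE))
  if (file.exists(fout)) {
    res <- readLines(fout)
    res <- res[nzchar(res)]
    parts <- strsplit(res, "\t", fixed = TRUE)
    got_id <- vapply(parts, function(p) trimws(p[2] %||% ""), character(1))
    got_smi <- vapply(parts, function(p) trimws(p[1]), character(1))
    idx <- match(ids, got_id)
    hit <- !is.na(idx) & nzchar(got_smi[ifelse(is.na(idx), 1L, idx)])
    out$canonical_smiles[hit] <- got_smi[idx[hit]]
    # an organic building block must retain at least one carbon atom
    carbon <- grepl("C(?![a-z])|c", out$canonical_smiles, perl = TRUE)
    carbon[is.na(carbon)] <- FALSE
    ok <- hit & carbon
    out$status[ok] <- "ok"; out$reason[ok] <- ""
    out$reason[hit & !carbon] <- "no_organic_fragment"
    out$canonical_smiles[!ok] <- NA_character_
  }
  out
}

# parse a named character vector of (clean) SMILES into an SDFset
smiles_to_sdf <- function(smiles) {
  if (is.null(names(smiles))) names(smiles) <- sprintf("m%06d", seq_along(smiles))
  ChemmineR::smiles2sdf(smiles)
}

# heavy atoms per molecule (hydrogens in the connection table excluded)
sdf_heavy_atoms <- function(sdf) {
  vapply(ChemmineR::atomblock(sdf), function(ab) {
    sym <- sub("_.*$", "", rownames(ab))
    sum(sym != "H")
  }, integer(1))
}

# unique SMARTS match counts for each ontology FG; rows = molecules
fg_match_counts <- function(sdf, ontology) {
  fgs <- ontology$fgs[ontology$fgs$id != 0L, ]
  m <- vapply(seq_len(nrow(fgs)), function(i)
    ChemmineR::smartsSearchOB(sdf, fgs$smarts[i], uniqueMatches = TRUE),
    numeric(length(ChemmineR::cid(sdf))))
  m <- matrix(m, nrow = length(ChemmineR::cid(sdf)),
              dimnames = list(ChemmineR::cid(sdf), fgs$id))
  m
}

#' Annotate molecules with leaf functional groups
#'
#' Matches every ontology SMARTS against each molecule and resolves the
#' hierarchy so that only the most specific FG is kept per matched site.
#'
#' @param smiles named character vector of clean SMILES.
#' @param ontology a \code{del_ontology}.
#' @return list (one element per molecule) of leaf FG id vectors with
#'   site multiplicity.
#' @export
annotate_fgs <- function(smiles, ontology) {
  sdf <- smiles_to_sdf(smiles)
  counts <- fg_match_counts(sdf, ontology)
  ids <- as.integer(colnames(counts))
  out <- lapply(seq_len(nrow(counts)), function(i) {
    raw <- rep(ids, counts[i, ])
    resolve_fg_hierarchy(raw, ontology)
  })
  names(out) <- rownames(counts)
  out
}

ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"

# physchem descriptors for profiling: heavy atoms, cLogP, fraction Csp3,
# TPSA and rotatable bonds
mol_descriptors <- function(sdf) {
  pr <- ChemmineR::propOB(sdf)
  csp3 <- ChemmineR::smartsSearchOB(sdf, "[CX4]", uniqueMatches = TRUE)
  ctot <- ChemmineR::smartsSearchOB(sdf, "[#6]", uniqueMatches = TRUE)
  rot <- ChemmineR::smartsSearchOB(sdf, ROTATABLE_SMARTS, uniqueMatches = TRUE)
  data.frame(
    id = ChemmineR::cid(sdf),
    heavy_atoms = sdf_heavy_atoms(sdf),
    clogp = pr$logP,
    fraction_csp3 = ifelse(ctot > 0, csp3 / ctot, 0),
    tpsa = pr$TPSA,
    rotatable_bonds = as.integer(rot),
    stringsAsFactors = FALSE)
}

#' Path-based fingerprints
#'
#' Computes Open Babel FP2 fingerprints (hashed linear paths of up to seven
#' atoms, 1024 bits) used for all Tanimoto diversity calculations.
#'
#' @param smiles named character vector of SMILES.
#' @return logical matrix, one row per molecule, 1024 columns.
#' @export
path_fingerprints <- function(smiles) {
  sdf <- smiles_to_sdf(smiles)
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  m <- methods::slot(fp, "fpma")
  storage.mode(m) <- "logical"
  m
}

# Tanimoto similarity between two fingerprint matrices (rows = molecules)
tanimoto_matrix <- function(a, b) {
  am <- matrix(as.numeric(a), nrow = nrow(a))
  bm <- matrix(as.numeric(b), nrow = nrow(b))
  inter <- am %*% t(bm)
  na <- rowSums(am); nb <- rowSums(bm)
  denom <- outer(na, nb, `+`) - inter
  sim <- ifelse(denom > 0, inter / denom, 1)
  sim
}

# run the RDKit rewrite helper on a batch of jobs
# jobs: list of list(id=, start=, steps=list(list(transform, bb_smiles or NULL)))
rdkit_transform_batch <- function(jobs) {
  if (length(jobs) == 0L)
    return(data.frame(id = character(0), status = character(0),
                      smiles = character(0), natoms = integer(0),
                      alts = integer(0), stringsAsFactors = FALSE))
  lines <- vapply(jobs, function(j) {
    steps <- lapply(j$steps, function(s)
      if (is.null(s$bb)) list(s$transform) else list(s$transform, s$bb))
    jsonlite::toJSON(list(id = j$id, start = j$start, steps = steps),
                     auto_unbox = TRUE, null = "null")
  }, character(1))
  fin <- tempfile(fileext = ".jsonl")
  on.exit(unlink(fin), add = TRUE)
  writeLines(lines, fin)
  script <- path_pkg_file("python", "rxn_apply.py")
  res <- system2(find_python(), shQuote(script), stdin = fin, stdout = TRUE,
                 stderr = FALSE)
  recs <- lapply(res, jsonlite::fromJSON)
  data.frame(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    status = vapply(recs, function(r) as.character(r$status), character(1)),
    smiles = vapply(recs, function(r) as.character(r$smiles %||% NA_character_),
                    character(1)),
    natoms = vapply(recs, function(r) as.integer(r$natoms %||% NA_integer_),
                    integer(1)),
    alts = vapply(recs, function(r) as.integer(r$alts %||% 1L), integer(1)),
    stringsAsFactors = FALSE)
}
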