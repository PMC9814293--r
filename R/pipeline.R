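#' Run parameters
#'
#' Bundles the knobs of a full design run.  Defaults follow production
#' practice for DNA-encoded libraries: 4 headpiece atoms, a target median
#' of 29 product heavy atoms (screening-collection-like molecules once the
#' headpiece is counted) and 10,000-compound profiling samples.
#'
#' @param n_cycles number of synthesis cycles (2 or 3 typical).
#' @param reaction_scope "production" or "both" (production + validated).
#' @param min_library_size smallest acceptable library (products from the
#'   sizing source alone).
#' @param target_median_atoms median heavy-atom cap for products.
#' @param headpiece_atoms heavy atoms attributed to the DNA headpiece.
#' @param sample_size X-Set size for profiling.
#' @param n_profile number of top libDESIGNs to enumerate and profile.
#' @param seed integer seed for all randomness.
#' @return list of class \code{del_run_params}.
#' @export
run_params <- function(n_cycles = 2L, reaction_scope = c("both", "production"),
                       min_library_size = 1000, target_median_atoms = 29L,
                       headpiece_atoms = 4L, sample_size = 10000L,
                       n_profile = 6L, seed = 1L) {
  reaction_scope <- match.arg(reaction_scope)
  stopifnot(n_cycles >= 1L, min_library_size > 0, target_median_atoms > 0L,
            headpiece_atoms > 0L, sample_size > 0L)
  structure(list(n_cycles = as.integer(n_cycles),
                 reaction_scope = reaction_scope,
                 min_library_size = min_library_size,
                 target_median_atoms = as.integer(target_median_atoms),
                 headpiece_atoms = as.integer(headpiece_atoms),
                 sample_size = as.integer(sample_size),
                 n_profile = as.integer(n_profile),
                 seed = as.integer(seed)),
            class = "del_run_params")
}

#' Run the full design pipeline
#'
#' Executes the staged workflow: building-block processing and BBT
#' assignment, exhaustive design generation, merging into libDESIGNs,
#' size maximization under the median heavy-atom constraint, selection,
#' X-Set sampling of the top libDESIGNs, property profiling and
#' spread-design ranking against the reference collections.
#'
#' @param bbs raw building blocks (data frame bb_id, smiles, source) or a
#'   processed \code{del_bbs}.
#' @param references named list of reference SMILES vectors (may be empty).
#' @param params a \code{del_run_params}.
#' @param ontology,reactions,matrices system definition; defaults load the
#'   packaged ontology, reaction set and reaction-FG matrices (reactions are
#'   restricted to \code{params$reaction_scope}).
#' @param headpieces headpiece FG names; default: all FGs with a surrogate.
#' @param out_dir optional directory for per-stage outputs and the run
#'   manifest.
#' @return object of class \code{del_run}.
#' @export
run_pipeline <- function(bbs, references = list(), params = run_params(),
                         ontology = NULL, reactions = NULL, matrices = NULL,
                         headpieces = NULL, out_dir = NULL) {
  t0 <- Sys.time()
  if (is.null(ontology)) ontology <- load_ontology()
  if (is.null(reactions))
    reactions <- load_reactions(ontology = ontology,
                                scope = params$reaction_scope)
  else if (params$reaction_scope == "production")
    reactions <- reactions[reactions$production_status == "production", ]
  if (is.null(matrices)) matrices <- load_reaction_fg_incompat(ontology = ontology)
  if (is.null(headpieces))
    headpieces <- intersect(default_headpieces()$fg_name,
                            ontology$fgs$name)
  log_stage <- function(...) message(sprintf("[deldesign %s] ",
                                             format(Sys.time(), "%H:%M:%S")), ...)

  log_stage("stage bbts: processing ", nrow(bbs), " building blocks")
  proc <- if (inherits(bbs, "del_bbs")) bbs else process_bbs(bbs, ontology)
  bbt_keys <- sort(unique(proc$bbt[proc$status == "ok"]))
  bbts <- do.call(rbind, lapply(bbt_keys, bbt_from_key))

  log_stage("stage designs: growing ", params$n_cycles, " cycles from ",
            length(headpieces), " headpieces")
  designs <- init_edesigns(headpieces, ontology)
  designs <- grow_all(designs, reactions, bbts, matrices,
                      n_cycles = params$n_cycles)
  designs <- finalize_designs(designs, ontology$disallowed_final)
  log_stage("  ", length(designs), " designs")

  log_stage("stage libdesigns: grouping")
  libs <- group_libdesigns(designs, reactions)
  log_stage("  ", length(libs), " libDESIGNs")

  log_stage("stage select: sizing at median <= ", params$target_median_atoms)
  selected <- select_libdesigns(libs, proc, reactions,
                                min_size = params$min_library_size,
                                target_median = params$target_median_atoms,
                                headpiece_atoms = params$headpiece_atoms)
  log_stage("  ", length(selected), " selected")

  top <- utils::head(selected, params$n_profile)
  xsets <- list(); profiles <- list()
  if (length(top)) {
    log_stage("stage enumerate: sampling ", params$sample_size,
              " products from ", length(top), " libDESIGNs")
    for (i in seq_along(top)) {
      cfg <- enum_config(top[[i]], proc, reactions, ontology)
      xsets[[top[[i]]$id]] <- sample_products(
        cfg, params$sample_size, seed = derive_seed(params$seed, i))
    }
    log_stage("stage profile")
    profiles <- lapply(xsets, profile_set)
  }

  distances <- NULL; spread <- NULL
  if (length(xsets) && length(references)) {
    log_stage("stage spread")
    ref_fps <- lapply(references, function(r) path_fingerprints(r))
    lib_fps <- lapply(xsets, function(x) path_fingerprints(as_smiles_vec(x)))
    distances <- do.call(rbind, lapply(names(lib_fps), function(nm) {
      d <- vapply(ref_fps, function(rf) avg_pairwise_distance(lib_fps[[nm]], rf),
                  numeric(1))
      data.frame(library = nm, reference = names(ref_fps), distance = d,
                 stringsAsFactors = FALSE)
    }))
    rownames(distances) <- NULL
    spread <- spread_rank(lib_fps, ref_fps)
  }

  summary_counts <- data.frame(
    n_cycles = params$n_cycles, reaction_scope = params$reaction_scope,
    min_library_size = params$min_library_size,
    target_median_atoms = params$target_median_atoms,
    n_bbs_assigned = sum(proc$status == "ok"),
    n_bbts_populated = length(bbt_keys),
    n_edesigns = length(designs), n_libdesigns = length(libs),
    n_selected = length(selected), stringsAsFactors = FALSE)

  run <- structure(list(params = params, headpieces = headpieces,
                        bbs = proc, bbts = bbts, designs = designs,
                        libdesigns = libs, selected = selected,
                        xsets = xsets, profiles = profiles,
                        distances = distances, spread = spread,
                        summary = summary_counts,
                        elapsed = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))),
                   class = "del_run")
  if (!is.null(out_dir)) write_run_dir(run, reactions, out_dir)
  run
}

write_run_dir <- function(run, reactions, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_edesigns(run$designs, file.path(out_dir, "edesigns.txt"))
  jsonlite::write_json(lapply(run$selected, libdesign_record),
                       file.path(out_dir, "libdesigns_selected.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_processed_bbs(run$bbs, file.path(out_dir, "bbs_processed.csv"))
  for (nm in names(run$xsets))
    write_xset(run$xsets[[nm]], file.path(out_dir, paste0("xset_", nm, ".csv")))
  if (!is.null(run$spread))
    utils::write.csv(run$spread, file.path(out_dir, "spread.csv"),
                     row.names = FALSE)
  if (!is.null(run$distances))
    utils::write.csv(run$distances, file.path(out_dir, "distances.csv"),
                     row.names = FALSE)
  utils::write.csv(run$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(params = unclass(run$params),
                   headpieces = run$headpieces,
                   counts = as.list(run$summary),
                   elapsed_sec = round(run$elapsed, 2))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.del_run <- function(x, ...) {
  cat("DEL design run (", x$params$n_cycles, "cycles, scope",
      x$params$reaction_scope, ")\n")
  print(x$summary)
  invisible(x)
}

#' @export
summary.del_run <- function(object, ...) {
  cat("Design run summary\n")
  print(object$summary)
  if (length(object$selected)) {
    cat("\nTop selected libDESIGNs:\n")
    for (l in utils::head(object$selected, 5L))
      cat(sprintf("  %s  size=%s  median_ha=%d  key=%s\n", l$id,
                  format(l$max_size, big.mark = ","), l$median_ha, l$key))
  }
  if (!is.null(object$spread)) {
    cat("\nSpread ranking:\n")
    print(object$spread)
  }
  invisible(object)
}
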