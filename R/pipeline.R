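## End-to-end orchestration: curate -> encode -> search -> consensus ->
## support -> summaries, with every intermediate written to disk and a
## machine-readable run log.  Stage outputs are pure functions of (inputs,
## config, seed), so a rerun with identical inputs is byte-identical.

#' Build a pipeline configuration
#'
#' @param out_dir directory for all artifacts (created if absent).
#' @param seed integer seed for the parsimony search (mandatory).
#' @param replicates random-addition replicates for the search.
#' @param maxtrees cap on stored most-parsimonious trees.
#' @param consensus `"strict"` or `"mast"`.
#' @param exact_limit exact-MAST leaf-count limit (see [mast_k()]).
#' @param mast_cap tree-subsampling cap for [mast_k()].
#' @param min_shared minimum shared taxa for the overlap check.
#' @param format matrix serialisation format, `"tnt"` or `"nexus"`.
#' @param outgroup reserved all-zero outgroup name.
#' @param auto_remove_disconnected drop records outside the largest overlap
#'   component instead of halting.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed, replicates = 20L,
                            maxtrees = 200L,
                            consensus = c("strict", "mast"),
                            exact_limit = 8L, mast_cap = 100L,
                            min_shared = 2L, format = c("tnt", "nexus"),
                            outgroup = "MRP_Outgroup",
                            auto_remove_disconnected = FALSE) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 replicates = as.integer(replicates),
                 maxtrees = as.integer(maxtrees),
                 consensus = match.arg(consensus),
                 exact_limit = as.integer(exact_limit),
                 mast_cap = as.integer(mast_cap),
                 min_shared = as.integer(min_shared),
                 format = match.arg(format),
                 outgroup = outgroup,
                 auto_remove_disconnected = isTRUE(auto_remove_disconnected)),
            class = "pipeline_config")
}

#' Run the full supertree construction protocol
#'
#' Executes, in order: name standardisation, higher-taxon substitution,
#' independence weighting/removal, taxonomic-overlap check, Baum-Ragan MRP
#' encoding, heuristic parsimony search, consensus (strict or MAST), V/V+
#' node support and novel-clade detection, and dataset summaries.  Every
#' stage's output is written under `config$out_dir` along with
#' `run_log.json` recording the configuration, seed, versions and stage
#' outcomes.
#'
#' @param dataset a `"supertree_dataset"`, or a path to a dataset bundle
#'   directory readable by [read_dataset()].
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the curated dataset, matrix, search
#'   result, consensus tree, support table and summaries, plus the paths of
#'   all written artifacts.
#' @export
run_pipeline <- function(dataset, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  stopifnot(inherits(dataset, "supertree_dataset"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline halted at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }

  std <- run_stage("standardize", function() standardize_names(dataset))
  stages$standardize <- nrow(std$log)
  sub <- run_stage("substitute", function()
    substitute_higher_taxa(std$dataset))
  stages$substitute <- nrow(sub$log)
  ind <- run_stage("independence", function()
    apply_independence(sub$dataset))
  stages$independence <- nrow(ind$report)
  curated <- ind$dataset

  ov <- run_stage("overlap", function()
    check_overlap(curated, min_shared = config$min_shared))
  if (!ov$pass) {
    if (!config$auto_remove_disconnected)
      stop("pipeline halted at stage 'overlap': overlap graph has ",
           ov$n_components, " components; disconnected records: ",
           paste(ov$removal_candidates, collapse = ", "), call. = FALSE)
    keep <- !(record_ids(curated) %in% ov$removal_candidates)
    curated$records <- curated$records[keep]
    stages$overlap_removed <- sum(!keep)
  }
  stages$records_curated <- length(curated$records)

  bundle_dir <- file.path(config$out_dir, "curated_bundle")
  write_dataset(curated, bundle_dir)
  curation_log <- rbind(std$log, sub$log, ind$report)
  utils::write.csv(curation_log,
                   file.path(config$out_dir, "curation_log.csv"),
                   row.names = FALSE)

  m <- run_stage("encode", function()
    encode_brs(curated, outgroup_name = config$outgroup))
  matrix_file <- file.path(config$out_dir,
                           paste0("mrp_matrix.",
                                  ifelse(config$format == "tnt", "tnt",
                                         "nex")))
  write_matrix(m, format = config$format, file = matrix_file)
  stages$characters <- n_characters(m)

  sr <- run_stage("search", function()
    heuristic_search(m, replicates = config$replicates, seed = config$seed,
                     maxtrees = config$maxtrees))
  mpt_file <- file.path(config$out_dir, "mpts.nwk")
  writeLines(vapply(sr$mpts, write_newick, character(1L)), mpt_file)
  stages$best_length <- sr$best_length
  stages$n_mpts <- length(sr$mpts)

  ingroup_mpts <- lapply(sr$mpts, function(t)
    restrict_tree(t, setdiff(t$tip.label, config$outgroup)))
  cons <- run_stage("consensus", function() {
    if (config$consensus == "strict") strict_consensus(ingroup_mpts)
    else mast_k(ingroup_mpts, exact_limit = config$exact_limit,
                cap = config$mast_cap, seed = config$seed)$tree
  })
  cons_file <- file.path(config$out_dir,
                         paste0(config$consensus, "_tree.nwk"))
  write_newick(cons, file = cons_file)

  ns <- run_stage("support", function()
    v_indices(cons, curated, outgroup = config$outgroup))
  write_support_csv(ns, file.path(config$out_dir, "support.csv"))
  write_support_tree(ns, file.path(config$out_dir, "support_tree.nwk"))
  nc <- novel_clades(cons, curated, outgroup = config$outgroup)
  stages$novel_clades <- nrow(nc$novel)

  summaries <- run_stage("summary", function() dataset_summary(curated))
  for (nm in names(summaries))
    utils::write.csv(summaries[[nm]],
                     file.path(config$out_dir, paste0("summary_", nm,
                                                      ".csv")),
                     row.names = FALSE)

  log <- list(package = "mrptree",
              version = as.character(utils::packageVersion("mrptree")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              config = unclass(config),
              stages = stages)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dataset = curated, matrix = m, search = sr,
                 consensus = cons, support = ns, novel = nc,
                 summaries = summaries,
                 paths = list(bundle = bundle_dir, matrix = matrix_file,
                              mpts = mpt_file, consensus = cons_file,
                              run_log = file.path(config$out_dir,
                                                  "run_log.json"))))
}
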