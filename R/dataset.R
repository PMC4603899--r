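## Source-tree records, dataset container, and bundle input/output.
## A dataset bundle on disk is a directory with trees/ (one Newick file per
## source tree), metadata.csv, synonyms.csv and taxonomy.csv; a single-file
## XML bundle is also supported as an alternative import/export path.

#' Create a source-tree record
#'
#' Bundles one rooted source tree with the study meta-data used by the
#' curation rules: bibliographic key, publication year, the character
#' classes the tree was inferred from, the inference method, and an
#' analysis weight (down-weighted later when trees are non-independent).
#'
#' @param tree a `"phylo"` object (rooted; polytomies allowed).
#' @param study_key bibliographic identifier, e.g. `"Palero_2009"`.
#' @param year publication year (>= 1980).
#' @param character_types nonempty character vector of character-class tags
#'   (e.g. `"morphology"`, `"16S"`, `"COI"`).
#' @param method inference-method tag (e.g. `"parsimony"`, `"bayesian"`).
#' @param weight analysis weight in (0, 1], stored as an exact rational
#'   `weight_num / weight_den`.
#' @param id optional unique record id; defaults to `study_key` plus a
#'   suffix assigned when the record joins a dataset.
#' @return an object of class `"source_record"`.
#' @export
source_record <- function(tree, study_key, year, character_types,
                          method = "unspecified", weight = 1, id = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(character_types) == 0L)
    stop("character_types must be nonempty")
  year <- as.integer(year)
  if (is.na(year) || year < 1980L)
    stop("year must be a publication year >= 1980")
  if (weight <= 0 || weight > 1) stop("weight must be in (0, 1]")
  structure(list(tree = tree, study_key = as.character(study_key),
                 year = year,
                 character_types = sort(as.character(character_types)),
                 method = as.character(method),
                 weight_num = 1L,
                 weight_den = as_weight_den(weight),
                 id = id),
            class = "source_record")
}

## weights only ever arise as 1/k; reject anything else early
as_weight_den <- function(w) {
  d <- 1 / w
  if (abs(d - round(d)) > 1e-9)
    stop("weight must be the reciprocal of a positive integer")
  as.integer(round(d))
}

record_weight <- function(rec) rec$weight_num / rec$weight_den

#' Assemble a supertree dataset
#'
#' @param records list of [source_record()] objects.
#' @param synonyms named character vector mapping names to accepted names
#'   (accepted names may map to themselves; the map must be idempotent).
#' @param taxonomy named list mapping higher-taxon names to character
#'   vectors of constituent species names.
#' @return an object of class `"supertree_dataset"`.
#' @export
supertree_dataset <- function(records, synonyms = character(0),
                              taxonomy = list()) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, logical(1L), "source_record")))
  ## assign unique ids where missing
  for (i in seq_along(records)) {
    if (is.null(records[[i]]$id))
      records[[i]]$id <- sprintf("%s_t%02d", records[[i]]$study_key, i)
  }
  ids <- vapply(records, `[[`, character(1L), "id")
  if (anyDuplicated(ids))
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "))
  synonyms <- validate_synonyms(synonyms)
  structure(list(records = records, synonyms = synonyms,
                 taxonomy = taxonomy),
            class = "supertree_dataset")
}

validate_synonyms <- function(syn) {
  if (length(syn) == 0L) return(character(0))
  stopifnot(!is.null(names(syn)))
  ## idempotence: accepted names must not themselves be remapped elsewhere
  resolved <- unname(syn[match(syn, names(syn))])
  chained <- !is.na(resolved) & resolved != syn
  if (any(chained))
    stop("synonym map is not idempotent; chained entries: ",
         paste(unique(syn[chained]), collapse = ", "))
  syn
}

#' @export
print.supertree_dataset <- function(x, ...) {
  nt <- length(x$records)
  taxa <- dataset_taxa(x)
  cat("Supertree dataset:", nt, "source tree(s),", length(taxa),
      "taxa\n")
  cat("  synonym entries:", length(x$synonyms),
      " higher taxa:", length(x$taxonomy), "\n")
  invisible(x)
}

#' All taxa occurring in a dataset
#' @param dataset a `"supertree_dataset"`.
#' @return sorted character vector of leaf labels over all source trees.
#' @export
dataset_taxa <- function(dataset) {
  sort(unique(unlist(lapply(dataset$records,
                            function(r) r$tree$tip.label))),
       method = "radix")
}

record_ids <- function(dataset)
  vapply(dataset$records, `[[`, character(1L), "id")

#' Write a dataset bundle to a directory
#'
#' Lays out `trees/<record id>.nwk` (canonical Newick), `metadata.csv`,
#' `synonyms.csv` and `taxonomy.csv`.  Output is byte-deterministic for a
#' given dataset.
#'
#' @param dataset a `"supertree_dataset"`.
#' @param dir target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(
    id = record_ids(dataset),
    study_key = vapply(dataset$records, `[[`, character(1L), "study_key"),
    year = vapply(dataset$records, `[[`, integer(1L), "year"),
    character_types = vapply(dataset$records, function(r)
      paste(r$character_types, collapse = ";"), character(1L)),
    method = vapply(dataset$records, `[[`, character(1L), "method"),
    weight_num = vapply(dataset$records, `[[`, integer(1L), "weight_num"),
    weight_den = vapply(dataset$records, `[[`, integer(1L), "weight_den"),
    tree_file = paste0("trees/", record_ids(dataset), ".nwk"),
    stringsAsFactors = FALSE)
  for (i in seq_along(dataset$records))
    write_newick(dataset$records[[i]]$tree,
                 file.path(dir, meta$tree_file[i]))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  syn <- data.frame(name = names(dataset$synonyms),
                    accepted = unname(dataset$synonyms),
                    stringsAsFactors = FALSE)
  utils::write.csv(syn, file.path(dir, "synonyms.csv"), row.names = FALSE)
  tax <- data.frame(
    higher_taxon = rep(names(dataset$taxonomy),
                       lengths(dataset$taxonomy)),
    member = unlist(dataset$taxonomy, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(tax) == 0L)
    tax <- data.frame(higher_taxon = character(0), member = character(0))
  utils::write.csv(tax, file.path(dir, "taxonomy.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset bundle from a directory
#'
#' @param dir a directory written by [write_dataset()] (or assembled by
#'   hand with the same layout).
#' @return a `"supertree_dataset"`.
#' @export
read_dataset <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(meta)), function(i) {
    source_record(tree = read_newick(file = file.path(dir, meta$tree_file[i])),
                  study_key = meta$study_key[i], year = meta$year[i],
                  character_types = strsplit(meta$character_types[i],
                                             ";", fixed = TRUE)[[1L]],
                  method = meta$method[i],
                  weight = meta$weight_num[i] / meta$weight_den[i],
                  id = meta$id[i])
  })
  synonyms <- character(0)
  sp <- file.path(dir, "synonyms.csv")
  if (file.exists(sp)) {
    s <- utils::read.csv(sp, stringsAsFactors = FALSE)
    if (nrow(s)) synonyms <- stats::setNames(s$accepted, s$name)
  }
  taxonomy <- list()
  tp <- file.path(dir, "taxonomy.csv")
  if (file.exists(tp)) {
    t <- utils::read.csv(tp, stringsAsFactors = FALSE)
    if (nrow(t)) taxonomy <- split(t$member, t$higher_taxon)
  }
  supertree_dataset(records, synonyms, taxonomy)
}

#' Write a dataset as a single XML bundle
#'
#' A compact single-file alternative to the directory bundle, mirroring the
#' layout of supertree-toolkit data files: one `<source>` element per source
#' tree carrying its Newick string and meta-data, plus `<synonym>` and
#' `<higher_taxon>` elements for the two maps.
#'
#' @param dataset a `"supertree_dataset"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_dataset_xml <- function(dataset, file) {
  doc <- xml2::xml_new_root("supertree_data")
  for (r in dataset$records) {
    src <- xml2::xml_add_child(doc, "source", id = r$id,
                               study_key = r$study_key,
                               year = as.character(r$year),
                               method = r$method,
                               weight_num = as.character(r$weight_num),
                               weight_den = as.character(r$weight_den))
    for (ch in r$character_types)
      xml2::xml_add_child(src, "character", type = ch)
    xml2::xml_add_child(src, "tree", write_newick(r$tree))
  }
  for (i in seq_along(dataset$synonyms))
    xml2::xml_add_child(doc, "synonym",
                        name = names(dataset$synonyms)[i],
                        accepted = unname(dataset$synonyms[i]))
  for (i in seq_along(dataset$taxonomy))
    for (m in dataset$taxonomy[[i]])
      xml2::xml_add_child(doc, "higher_taxon",
                          name = names(dataset$taxonomy)[i], member = m)
  xml2::write_xml(doc, file)
  invisible(file)
}

#' Read a dataset from a single XML bundle
#' @param file path to a file written by [write_dataset_xml()].
#' @return a `"supertree_dataset"`.
#' @export
read_dataset_xml <- function(file) {
  doc <- xml2::read_xml(file)
  srcs <- xml2::xml_find_all(doc, "./source")
  records <- lapply(srcs, function(s) {
    source_record(
      tree = read_newick(xml2::xml_text(xml2::xml_find_first(s, "./tree"))),
      study_key = xml2::xml_attr(s, "study_key"),
      year = as.integer(xml2::xml_attr(s, "year")),
      character_types = xml2::xml_attr(
        xml2::xml_find_all(s, "./character"), "type"),
      method = xml2::xml_attr(s, "method"),
      weight = as.integer(xml2::xml_attr(s, "weight_num")) /
        as.integer(xml2::xml_attr(s, "weight_den")),
      id = xml2::xml_attr(s, "id"))
  })
  syns <- xml2::xml_find_all(doc, "./synonym")
  synonyms <- stats::setNames(xml2::xml_attr(syns, "accepted"),
                              xml2::xml_attr(syns, "name"))
  if (length(synonyms) == 0L) synonyms <- character(0)
  hts <- xml2::xml_find_all(doc, "./higher_taxon")
  taxonomy <- list()
  if (length(hts))
    taxonomy <- split(xml2::xml_attr(hts, "member"),
                      xml2::xml_attr(hts, "name"))
  supertree_dataset(records, synonyms, taxonomy)
}
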