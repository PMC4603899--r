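## Baum-Ragan matrix representation with parsimony: every nontrivial,
## non-root clade of every source tree becomes one binary group-inclusion
## character (members 1, other taxa of that tree 0, absent taxa ?), the
## matrix is rooted by a hypothetical all-zero outgroup, and characters
## inherit their record's analysis weight as an exact rational.

#' Encode a curated dataset as an MRP matrix
#'
#' @param dataset a curated `"supertree_dataset"` (names standardised,
#'   higher taxa substituted, overlap checked).
#' @param outgroup_name reserved name for the hypothetical all-zero
#'   outgroup; must not collide with a real taxon.
#' @return an object of class `"mrp_matrix"`: a list with `taxa` (outgroup
#'   first), `mat` (taxa x characters integer matrix over 0/1/`NA`, `NA`
#'   encoding "?"), `w_num`/`w_den` (exact rational character weights),
#'   `provenance` (record id and source node id per character) and
#'   `outgroup`.
#' @export
encode_brs <- function(dataset, outgroup_name = "MRP_Outgroup") {
  taxa <- dataset_taxa(dataset)
  if (outgroup_name %in% taxa)
    stop("outgroup name '", outgroup_name, "' collides with a real taxon")
  all_taxa <- c(outgroup_name, taxa)
  cols <- list()
  wn <- integer(0)
  wd <- integer(0)
  prov_rec <- character(0)
  prov_node <- integer(0)
  for (rec in dataset$records) {
    tr <- rec$tree
    cl <- clades_preorder(tr)
    if (length(cl) == 0L) next
    present <- all_taxa %in% tr$tip.label
    for (k in seq_along(cl)) {
      col <- rep(NA_integer_, length(all_taxa))
      col[present] <- 0L
      col[match(cl[[k]], all_taxa)] <- 1L
      col[1L] <- 0L                      # outgroup is all-zero
      cols[[length(cols) + 1L]] <- col
      wn <- c(wn, rec$weight_num)
      wd <- c(wd, rec$weight_den)
      prov_rec <- c(prov_rec, rec$id)
      prov_node <- c(prov_node, as.integer(names(cl)[k]))
    }
  }
  if (length(cols) == 0L)
    stop("empty matrix: no source tree contributes an informative clade")
  mat <- do.call(cbind, cols)
  rownames(mat) <- all_taxa
  colnames(mat) <- sprintf("c%04d", seq_along(cols))
  structure(list(taxa = all_taxa, mat = mat, w_num = wn, w_den = wd,
                 provenance = data.frame(record = prov_rec,
                                         node = prov_node,
                                         stringsAsFactors = FALSE),
                 outgroup = outgroup_name),
            class = "mrp_matrix")
}

## clades in pre-order node order (order of first appearance as a parent in
## the cladewise edge list), root excluded
clades_preorder <- function(tree) {
  cl <- clades(tree)
  if (length(cl) == 0L) return(cl)
  e <- ape::reorder.phylo(tree, "cladewise")$edge
  ord <- unique(e[, 1L])
  cl[order(match(as.integer(names(cl)), ord))]
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat("MRP matrix:", length(x$taxa), "taxa x", ncol(x$mat),
      "characters (outgroup:", x$outgroup, ")\n")
  invisible(x)
}

n_characters <- function(m) ncol(m$mat)

## least common multiple of the weight denominators
weight_scale <- function(m) {
  Reduce(function(a, b) a * b / gcd_int(a, b), unique(m$w_den), accumulate = FALSE)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

## integer character weights after scaling by the common denominator
integer_weights <- function(m) {
  L <- weight_scale(m)
  as.integer(round(m$w_num * (L / m$w_den)))
}

#' Serialise an MRP matrix
#'
#' TNT output uses an `xread` block with `?` for missing entries and
#' integer `ccode` weights obtained by scaling all rational weights by
#' their least common denominator.  NEXUS output uses a DATA block plus an
#' ASSUMPTIONS block with a WTSET; non-integer weights are written as
#' exact fractions (`num/den`), an extension accepted by [read_matrix()].
#'
#' @param matrix an `"mrp_matrix"`.
#' @param format `"tnt"` or `"nexus"`.
#' @param file optional output path.
#' @return the serialised text (one string), invisibly when `file` given.
#' @export
write_matrix <- function(matrix, format = c("tnt", "nexus"), file = NULL) {
  format <- match.arg(format)
  m <- matrix
  txt <- if (format == "tnt") format_tnt(m) else format_nexus(m)
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

matrix_rows <- function(m, quote_spaces) {
  bad <- grepl("[\t\n';()\\[\\]]", m$taxa) |
    (!quote_spaces & grepl(" ", m$taxa))
  if (any(bad))
    stop("taxon label(s) not serialisable in this format: ",
         paste(m$taxa[bad], collapse = ", "))
  labs <- m$taxa
  if (quote_spaces) {
    sp <- grepl("[ ]", labs)
    labs[sp] <- paste0("'", labs[sp], "'")
  }
  states <- apply(m$mat, 1L, function(r)
    paste(ifelse(is.na(r), "?", as.character(r)), collapse = ""))
  paste(formatC(labs, width = max(nchar(labs)) + 2L, flag = "-"), states)
}

format_tnt <- function(m) {
  rows <- matrix_rows(m, quote_spaces = FALSE)
  wint <- integer_weights(m)
  ccode <- vapply(sort(unique(wint)), function(w)
    paste0("ccode /", w, " ",
           paste(which(wint == w) - 1L, collapse = " "), ";"),
    character(1L))
  paste0("xread\n'MRP matrix'\n", ncol(m$mat), " ", length(m$taxa), "\n",
         paste(rows, collapse = "\n"), "\n;\n",
         paste(ccode, collapse = "\n"), "\nproc /;\n")
}

format_weight_frac <- function(num, den) {
  ifelse(den == 1L, as.character(num), paste0(num, "/", den))
}

format_nexus <- function(m) {
  rows <- matrix_rows(m, quote_spaces = TRUE)
  wkey <- format_weight_frac(m$w_num, m$w_den)
  parts <- vapply(unique(wkey), function(w)
    paste0(w, ": ", paste(which(wkey == w), collapse = " ")),
    character(1L))
  paste0("#NEXUS\nBEGIN DATA;\nDIMENSIONS NTAX=", length(m$taxa),
         " NCHAR=", ncol(m$mat), ";\n",
         "FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;\nMATRIX\n",
         paste(rows, collapse = "\n"),
         "\n;\nEND;\nBEGIN ASSUMPTIONS;\nWTSET * mrp_weights = ",
         paste(parts, collapse = ", "), ";\nEND;\n")
}

#' Read an MRP matrix written by [write_matrix()]
#'
#' The format is auto-detected (`#NEXUS` header vs `xread`).  TNT `ccode`
#' weights are integers, so reading a TNT file recovers weights up to the
#' common scaling applied at write time; NEXUS files round-trip weights
#' exactly via the fraction extension.
#'
#' @param file path, or `text` a single string.
#' @param text optional literal matrix text instead of a file.
#' @return an `"mrp_matrix"` (provenance is not stored in the formats and
#'   comes back empty).
#' @export
read_matrix <- function(file = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE),
                                   collapse = "\n")
  if (grepl("^\\s*#NEXUS", text)) read_matrix_nexus(text)
  else if (grepl("xread", text)) read_matrix_tnt(text)
  else stop("unrecognised matrix format (expected NEXUS or TNT xread)")
}

parse_matrix_rows <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  taxa <- character(0)
  rows <- list()
  for (ln in lines) {
    mlab <- regmatches(ln, regexec("^'([^']+)'\\s+(\\S+)$", ln))[[1L]]
    if (length(mlab) == 3L) {
      lab <- mlab[2L]; st <- mlab[3L]
    } else {
      sp <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)$", ln))[[1L]]
      if (length(sp) != 3L) stop("cannot parse matrix row: ", ln)
      lab <- sp[2L]; st <- sp[3L]
    }
    v <- strsplit(st, "", fixed = TRUE)[[1L]]
    row <- rep(NA_integer_, length(v))
    row[v != "?"] <- as.integer(v[v != "?"])
    taxa <- c(taxa, lab)
    rows[[length(rows) + 1L]] <- row
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- taxa
  colnames(mat) <- sprintf("c%04d", seq_len(ncol(mat)))
  mat
}

new_mrp_matrix <- function(mat, w_num, w_den, outgroup) {
  structure(list(taxa = rownames(mat), mat = mat,
                 w_num = as.integer(w_num), w_den = as.integer(w_den),
                 provenance = data.frame(record = character(0),
                                         node = integer(0)),
                 outgroup = outgroup),
            class = "mrp_matrix")
}

read_matrix_tnt <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  hdr <- grep("^\\s*\\d+\\s+\\d+\\s*$", lines)[1L]
  dims <- as.integer(strsplit(trimws(lines[hdr]), "\\s+")[[1L]])
  nchar_ <- dims[1L]; ntax <- dims[2L]
  body <- lines[(hdr + 1L):(hdr + ntax)]
  mat <- parse_matrix_rows(body)
  stopifnot(ncol(mat) == nchar_)
  w <- rep(1L, nchar_)
  for (cc in grep("^ccode", lines, value = TRUE)) {
    mm <- regmatches(cc, regexec("^ccode\\s+/(\\d+)\\s+([0-9 ]+);", cc))[[1L]]
    if (length(mm) == 3L) {
      idx <- as.integer(strsplit(trimws(mm[3L]), "\\s+")[[1L]]) + 1L
      w[idx] <- as.integer(mm[2L])
    }
  }
  new_mrp_matrix(mat, w, rep(1L, nchar_), rownames(mat)[1L])
}

read_matrix_nexus <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  mstart <- grep("^\\s*MATRIX\\s*$", toupper(lines))[1L]
  mend <- mstart + which(grepl("^\\s*;\\s*$", lines[(mstart + 1L):length(lines)]))[1L]
  mat <- parse_matrix_rows(lines[(mstart + 1L):(mend - 1L)])
  nchar_ <- ncol(mat)
  wn <- rep(1L, nchar_); wd <- rep(1L, nchar_)
  wl <- grep("WTSET", toupper(lines))
  if (length(wl)) {
    spec <- sub(".*=\\s*", "", sub(";\\s*$", "", lines[wl[1L]]))
    for (part in strsplit(spec, ",")[[1L]]) {
      kv <- strsplit(trimws(part), ":")[[1L]]
      frac <- strsplit(trimws(kv[1L]), "/", fixed = TRUE)[[1L]]
      idx <- as.integer(strsplit(trimws(kv[2L]), "\\s+")[[1L]])
      wn[idx] <- as.integer(frac[1L])
      wd[idx] <- if (length(frac) == 2L) as.integer(frac[2L]) else 1L
    }
  }
  new_mrp_matrix(mat, wn, wd, rownames(mat)[1L])
}
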