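## File and text I/O for the formats the pipeline touches: newick trees,
## aligned FASTA, and TSV tables (reference annotations, community tables,
## sample metadata, distance matrices), plus cross-reference validation.

#' Parse a newick string into a rooted tree
#'
#' Thin wrapper around ape's newick reader with the package's validation
#' rules: unique non-empty tip labels, non-negative branch lengths (missing
#' lengths default to 0), quoted labels supported, internal node labels
#' preserved but ignored by analyses.
#'
#' @param text a newick string (single tree, terminated by `;`).
#' @return a `phylo` object.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1)
    stop("'text' must be a single newick string")
  np <- sum(utf8ToInt(text) == utf8ToInt("(")) -
        sum(utf8ToInt(text) == utf8ToInt(")"))
  if (np != 0)
    stop(sprintf("malformed newick: unbalanced parentheses (offset %d)",
                 nchar(text)))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: no tree found")
  validate_tree(tree)
}

#' Validate tree invariants
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly usable, with missing branch lengths set to 0.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  tl <- tree$tip.label
  if (any(!nzchar(tl))) stop("empty tip label")
  dup <- unique(tl[duplicated(tl)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) not allowed")
  tree
}

#' Write a tree as a newick string
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Read a rooted tree from a newick file
#' @param path path to a newick file.
#' @return a `phylo` object.
#' @export
read_tree <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Read an aligned FASTA file
#'
#' Sequences are uppercased and checked for equal length; characters outside
#' `{A,C,G,T,N,-}` are tolerated but treated as `N` by downstream identity
#' computations.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of equal-length aligned sequences, with
#'   class `alignment_set`.
#' @export
read_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("FASTA must start with a '>' header line")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  names(seqs) <- ids[as.integer(names(seqs))]
  as_alignment(seqs)
}

#' Build a validated alignment from named sequences
#' @param seqs named character vector of aligned sequences.
#' @return an `alignment_set` object.
#' @export
as_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment sequences must be named")
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup)) stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  len <- nchar(seqs)
  if (any(len == 0)) stop("zero-length sequence(s)")
  if (length(unique(len)) > 1) {
    off <- names(seqs)[len != stats::median(len)]
    stop("ragged alignment: sequences with deviating length: ",
         paste(off, collapse = ", "))
  }
  structure(toupper(seqs), class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n",
              length(x), nchar(x[[1]])))
  invisible(x)
}

#' Read a reference annotation table
#'
#' Expects a UTF-8 TSV with header columns `id`, `category` and `chemotype`.
#' `category` must be `spore_pigment` or `antibiotic`; a chemotype label is
#' required for (and only meaningful for) antibiotic rows. The distinct
#' category and chemotype counts are reported via `message()`.
#'
#' @param path path to the TSV file.
#' @return a data frame with class `reference_annotations`.
#' @export
read_reference_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "category", "chemotype")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  as_reference_annotations(df[need])
}

#' Validate a reference annotation data frame
#' @param df data frame with columns `id`, `category`, `chemotype`.
#' @param quiet suppress the summary message.
#' @return the validated data frame (class `reference_annotations`).
#' @export
as_reference_annotations <- function(df, quiet = FALSE) {
  df$id <- trimws(df$id); df$category <- trimws(df$category)
  df$chemotype <- trimws(df$chemotype)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) stop("duplicate annotation id(s): ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(df$category), c("spore_pigment", "antibiotic"))
  if (length(bad)) stop("unknown category token(s): ", paste(bad, collapse = ", "))
  mis <- df$id[df$category == "antibiotic" & !nzchar(df$chemotype)]
  if (length(mis))
    stop("antibiotic row(s) with missing chemotype: ", paste(mis, collapse = ", "))
  df$chemotype[df$category == "spore_pigment"] <- NA_character_
  if (!quiet)
    message(sprintf(
      "reference annotations: %d ids (%d spore_pigment, %d antibiotic), %d distinct chemotypes",
      nrow(df), sum(df$category == "spore_pigment"),
      sum(df$category == "antibiotic"),
      length(unique(stats::na.omit(df$chemotype)))))
  structure(df, class = c("reference_annotations", "data.frame"))
}

#' Read a sample-by-unit community table
#'
#' TSV with first column the sample id and remaining columns unit ids;
#' integer, non-negative cells. Empty samples (all-zero rows) are dropped
#' with a warning.
#'
#' @param path path to the TSV file.
#' @param unit_kind one of `"sequence"`, `"group"`, `"trait"`.
#' @return an integer (or numeric for `"trait"`) matrix, samples as rows,
#'   with attribute `unit_kind`.
#' @export
read_community_table <- function(path, unit_kind = "sequence") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("community table needs >= 1 unit column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "numeric"
  as_community_table(m, unit_kind = unit_kind)
}

#' Validate a community matrix
#' @param m numeric matrix, samples as rows, units as columns.
#' @param unit_kind one of `"sequence"`, `"group"`, `"trait"`.
#' @param drop_empty drop all-zero samples (with a warning)?
#' @return the validated matrix with attribute `unit_kind`.
#' @export
as_community_table <- function(m, unit_kind = "sequence", drop_empty = TRUE) {
  unit_kind <- match.arg(unit_kind, c("sequence", "group", "trait"))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("community table must have sample and unit ids")
  if (anyDuplicated(rownames(m))) stop("duplicate sample id(s)")
  if (anyDuplicated(colnames(m))) stop("duplicate unit id(s)")
  if (any(!is.finite(m))) stop("non-finite cell(s) in community table")
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative count at row '%s', column '%s'",
                 rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  if (unit_kind != "trait" && any(m != round(m))) {
    ni <- which(m != round(m), arr.ind = TRUE)
    stop(sprintf("non-integer count at row '%s', column '%s'",
                 rownames(m)[ni[1, 1]], colnames(m)[ni[1, 2]]))
  }
  empty <- rowSums(m) == 0
  if (any(empty) && drop_empty) {
    warning("dropping empty sample(s): ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  if (!nrow(m)) stop("community table has no non-empty samples")
  attr(m, "unit_kind") <- unit_kind
  m
}

#' Write a community table as TSV
#' @param m community matrix.
#' @param path output path.
#' @export
write_community_table <- function(m, path) {
  df <- data.frame(sample = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample`, coordinates, `continent`, and optional
#' environmental / plant-presence columns. Coordinates are either planar
#' meters (columns `x`, `y`; `coord_system = "xy_m"`) or decimal degrees
#' (columns `lon`, `lat`; `coord_system = "lonlat"`). Plant columns are
#' those prefixed `plant_` (0/1); remaining numeric columns are treated as
#' environmental variables.
#'
#' @param path path to the TSV file.
#' @return a list with elements `samples`, `coords` (n x 2), `coord_system`,
#'   `continent`, `env` (matrix), `plants` (0/1 matrix), of class
#'   `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample" %in% names(df)) stop("metadata needs a 'sample' column")
  if (all(c("x", "y") %in% names(df))) {
    coord_system <- "xy_m"; coords <- as.matrix(df[, c("x", "y")])
  } else if (all(c("lon", "lat") %in% names(df))) {
    coord_system <- "lonlat"; coords <- as.matrix(df[, c("lon", "lat")])
  } else stop("metadata needs coordinate columns 'x','y' (xy_m) or 'lon','lat' (lonlat)")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  rownames(coords) <- df$sample
  cont <- if ("continent" %in% names(df)) df$continent else rep("all", nrow(df))
  names(cont) <- df$sample
  rest <- setdiff(names(df), c("sample", "x", "y", "lon", "lat", "continent"))
  pl <- rest[startsWith(rest, "plant_")]
  ev <- setdiff(rest, pl)
  ev <- ev[vapply(df[ev], is.numeric, TRUE)]
  env <- if (length(ev)) as.matrix(df[, ev, drop = FALSE]) else
    matrix(numeric(0), nrow(df), 0)
  plants <- if (length(pl)) as.matrix(df[, pl, drop = FALSE]) else
    matrix(numeric(0), nrow(df), 0)
  rownames(env) <- rownames(plants) <- df$sample
  structure(list(samples = df$sample, coords = coords,
                 coord_system = coord_system, continent = cont,
                 env = env, plants = plants),
            class = "sample_metadata")
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("Sample metadata: %d samples (%s), %d env vars, %d plant taxa\n",
              length(x$samples), x$coord_system, ncol(x$env), ncol(x$plants)))
  invisible(x)
}

#' Read / write a square distance matrix (TSV with id header)
#' @param path file path.
#' @return a validated symmetric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "numeric"
  validate_distance_matrix(m)
}

#' @rdname read_distance_matrix
#' @param m a distance matrix.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate distance-matrix invariants
#' @param m square numeric matrix with matching id dimnames.
#' @param tol symmetry tolerance.
#' @return the matrix, diagonal forced to exact zero.
#' @export
validate_distance_matrix <- function(m, tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("not a square matrix")
  if (is.null(rownames(m))) stop("distance matrix must carry ids")
  if (!identical(rownames(m), colnames(m))) stop("row/column ids differ")
  if (any(!is.finite(m))) stop("non-finite distances")
  if (any(m < 0)) stop("negative distances")
  if (max(abs(m - t(m))) > tol) stop("matrix not symmetric within tolerance")
  if (max(abs(diag(m))) > tol) stop("nonzero diagonal")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Cross-validate a loaded input bundle
#'
#' Checks id consistency across the tree, alignment, reference annotations,
#' community table and metadata: every annotated id and community unit must be
#' a tree tip (and an alignment member when an alignment is given), and every
#' community sample must have metadata when metadata are supplied. All missing
#' ids are collected and reported in a single error.
#'
#' @param tree `phylo`; required.
#' @param aln optional `alignment_set`.
#' @param refs optional `reference_annotations`.
#' @param community optional community matrix.
#' @param meta optional `sample_metadata`.
#' @return `TRUE` (invisibly) on success.
#' @export
validate_bundle <- function(tree, aln = NULL, refs = NULL, community = NULL,
                            meta = NULL) {
  tree <- validate_tree(tree)
  probs <- character(0)
  add <- function(what, ids) if (length(ids))
    sprintf("%s not found: %s", what, paste(ids, collapse = ", "))
  if (!is.null(refs))
    probs <- c(probs, add("annotation id(s) absent from tree",
                          setdiff(refs$id, tree$tip.label)))
  if (!is.null(community)) {
    probs <- c(probs, add("community unit(s) absent from tree",
                          setdiff(colnames(community), tree$tip.label)))
    if (!is.null(aln))
      probs <- c(probs, add("community unit(s) absent from alignment",
                            setdiff(colnames(community), names(aln))))
    if (!is.null(meta))
      probs <- c(probs, add("sample(s) without metadata",
                            setdiff(rownames(community), meta$samples)))
  }
  if (!is.null(aln) && !is.null(refs))
    probs <- c(probs, add("annotation id(s) absent from alignment",
                          setdiff(refs$id, names(aln))))
  probs <- probs[!vapply(probs, is.null, TRUE)]
  if (length(probs)) stop(paste(probs, collapse = "; "))
  invisible(TRUE)
}
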