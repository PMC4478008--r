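## Sequence-group binning from the tree, rarefaction, and construction of
## group-level and trait pseudo-abundance community matrices.

#' Pairwise percent identity of an alignment
#'
#' Identity is computed on the given alignment as
#' `matches / compared columns * 100`, where columns in which both sequences
#' have a gap are excluded, columns in which exactly one has a gap count as
#' mismatches (switchable via `single_gap`), and `N` (or any non-ACGT
#' character) matches nothing.
#'
#' @param aln an `alignment_set` (named, equal-length sequences).
#' @param single_gap `"mismatch"` (default) counts single-gap columns as
#'   compared mismatches; `"exclude"` removes them from the comparison.
#' @return symmetric percent-identity matrix (diagonal 100) of class
#'   `identity_matrix`.
#' @export
pairwise_identity <- function(aln, single_gap = c("mismatch", "exclude")) {
  single_gap <- match.arg(single_gap)
  if (length(aln) < 2) stop("need >= 2 sequences")
  ids <- names(aln)
  L <- nchar(aln[[1]])
  M <- matrix(unlist(strsplit(unname(unlist(aln)), "")), ncol = L, byrow = TRUE)
  n <- nrow(M)
  matches <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    I <- (M == b) * 1
    matches <- matches + tcrossprod(I)
  }
  G <- (M == "-") * 1
  bothgap <- tcrossprod(G)
  compared <- L - bothgap
  if (single_gap == "exclude") {
    rg <- rowSums(G)
    singlegap <- outer(rg, rg, "+") - 2 * bothgap
    compared <- compared - singlegap
  }
  ident <- matrix(0, n, n)
  ok <- compared > 0
  ident[ok] <- matches[ok] / compared[ok] * 100
  if (any(!ok[upper.tri(ok)]))
    warning("sequence pair(s) with no comparable columns: identity set to 0")
  diag(ident) <- 100
  dimnames(ident) <- list(ids, ids)
  structure(ident, class = c("identity_matrix", "matrix"))
}

#' Bin sequences into similarity groups by tree collapse
#'
#' Traverses the tree from the tips to the root and collapses every node for
#' which all descendant sequences are at least `cutoff_pct` percent identical
#' (i.e. the minimum pairwise identity within the clade reaches the cutoff) —
#' the furthest-neighbor clustering criterion restricted to complete clades.
#' Groups are the maximal collapsible clades; tips outside any collapsible
#' clade form singleton groups.
#'
#' @param tree rooted `phylo` whose tips are all present in `ident`.
#' @param ident an `identity_matrix` (percent identities).
#' @param cutoff_pct percent identity cutoff x in (0, 100].
#' @return named character vector: tip label -> group id, with attribute
#'   `cutoff`.
#' @export
bin_by_tree <- function(tree, ident, cutoff_pct) {
  if (!is.numeric(cutoff_pct) || cutoff_pct <= 0 || cutoff_pct > 100)
    stop("cutoff must be in (0, 100]")
  miss <- setdiff(tree$tip.label, rownames(ident))
  if (length(miss)) stop("tip(s) missing from identity matrix: ",
                         paste(miss, collapse = ", "))
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  tipsets <- vector("list", M)
  for (i in seq_len(n)) tipsets[[i]] <- i
  minid <- rep(Inf, M)  # min pairwise identity within the clade below a node
  labs <- tree$tip.label
  # postorder guarantees each child's subtree is complete before its edge;
  # accumulate cross-child minima incrementally per edge
  for (r in seq_len(nrow(po$edge))) {
    pa <- po$edge[r, 1]; ch <- po$edge[r, 2]
    cross <- if (is.null(tipsets[[pa]])) Inf else
      min(ident[labs[tipsets[[pa]]], labs[tipsets[[ch]]], drop = FALSE])
    minid[pa] <- min(minid[pa], minid[ch], cross)
    tipsets[[pa]] <- c(tipsets[[pa]], tipsets[[ch]])
  }
  collapsible <- minid >= cutoff_pct  # tips trivially collapsible (Inf)
  # maximal collapsible clades by preorder descent
  group <- integer(n)
  gid <- 0L
  stack <- n + 1L
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (collapsible[nd]) {
      gid <- gid + 1L
      group[tipsets[[nd]]] <- gid
    } else {
      stack <- c(stack, kids[[as.character(nd)]])
    }
  }
  out <- paste0("g", formatC(group, width = nchar(max(group)), flag = "0"))
  names(out) <- tree$tip.label
  attr(out, "cutoff") <- cutoff_pct
  out
}

#' Smallest cutoff with chemotype-pure reference groups
#'
#' Reporting utility for choosing the binning threshold: over a grid of
#' cutoffs, checks whether every group containing reference sequences
#' contains references of at most one chemotype, and reports the smallest
#' pure cutoff along with per-cutoff group counts.
#'
#' @param tree rooted `phylo`.
#' @param ident an `identity_matrix`.
#' @param refs `reference_annotations`.
#' @param grid cutoffs to scan (descending order recommended).
#' @return data frame with columns `cutoff`, `n_groups`, `pure`.
#' @export
chemotype_purity_scan <- function(tree, ident, refs,
                                  grid = c(100, 95, 90, 85, 80, 70, 60, 50)) {
  anti <- refs[refs$category == "antibiotic", ]
  out <- lapply(grid, function(x) {
    g <- bin_by_tree(tree, ident, x)
    gr <- g[anti$id[anti$id %in% names(g)]]
    pure <- all(vapply(split(anti$chemotype[anti$id %in% names(g)], gr),
                       function(z) length(unique(z)) == 1, TRUE))
    data.frame(cutoff = x, n_groups = length(unique(g)), pure = pure)
  })
  do.call(rbind, out)
}

## deterministic per-sample RNG substream: hash the sample id so results do
## not depend on sample order
.sample_seed <- function(seed, id) {
  h <- sum(utf8ToInt(id) * (seq_len(nchar(id)) %% 31 + 1))
  as.integer((as.numeric(seed) + 7919 * h) %% 2147483647)
}

#' Rarefy a community table to fixed depth
#'
#' Samples with fewer than `depth` sequences are dropped (with a warning);
#' the rest are subsampled without replacement to exactly `depth` sequences.
#' Each sample uses an RNG substream derived from `seed` and a hash of the
#' sample id, so results are independent of sample order.
#'
#' @param table community matrix (samples x units, counts).
#' @param depth target depth (>= 1).
#' @param seed integer seed.
#' @return rarefied community matrix (same unit kind).
#' @export
rarefy <- function(table, depth, seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  rs <- rowSums(table)
  drop <- rs < depth
  if (any(drop))
    warning("dropping sample(s) below depth: ",
            paste(rownames(table)[drop], collapse = ", "))
  keep <- rownames(table)[!drop]
  if (!length(keep)) stop("all samples below rarefaction depth")
  out <- matrix(0L, length(keep), ncol(table),
                dimnames = list(keep, colnames(table)))
  for (s in keep) {
    counts <- table[s, ]
    pool <- rep(seq_along(counts), counts)
    set.seed(.sample_seed(seed, s))
    take <- if (length(pool) == depth) pool else sample(pool, depth)
    tab <- tabulate(take, nbins = ncol(table))
    out[s, ] <- tab
  }
  attr(out, "unit_kind") <- attr(table, "unit_kind")
  out
}

#' Collapse a sequence-level community table to similarity groups
#'
#' @param table community matrix with sequence units.
#' @param assignment named vector sequence id -> group id (see
#'   [bin_by_tree()]).
#' @return community matrix with group units; per-sample totals preserved.
#' @export
collapse_to_groups <- function(table, assignment) {
  un <- setdiff(colnames(table), names(assignment))
  if (length(un)) stop("unassigned unit(s): ", paste(un, collapse = ", "))
  g <- assignment[colnames(table)]
  groups <- sort(unique(g))
  out <- vapply(groups, function(gr)
    rowSums(table[, g == gr, drop = FALSE]), numeric(nrow(table)))
  out <- matrix(out, nrow = nrow(table),
                dimnames = list(rownames(table), groups))
  attr(out, "unit_kind") <- "group"
  out
}

#' Trait pseudo-abundance community matrix
#'
#' Multiplies the sample x sequence community matrix with the sequence x
#' trait probability matrix: pseudo-abundance(sample, trait) =
#' sum over sequences of count * P(sequence codes for trait). Row sums equal
#' each sample's total sequence count.
#'
#' @param table community matrix (sequence units).
#' @param probs a `trait_probs` object (or plain probability matrix with
#'   sequence rownames).
#' @return real-valued community matrix with trait units.
#' @export
build_trait_matrix <- function(table, probs) {
  P <- unclass(probs)
  miss <- setdiff(colnames(table), rownames(P))
  if (length(miss))
    stop("no trait probability row for sequence(s): ",
         paste(miss, collapse = ", "))
  out <- table %*% P[colnames(table), , drop = FALSE]
  attr(out, "unit_kind") <- "trait"
  out
}
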