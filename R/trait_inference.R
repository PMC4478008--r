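## Probabilistic trait assignment for uncharacterized tips: prune the global
## phylogeny to the query plus annotated references, reroot at the query's
## parent, fit the ER rate on the reference states (query missing), take the
## marginal root-state distribution, and propagate it across the query's
## pendant branch.

.trait_labels <- function(refs, trait_field) {
  trait_field <- match.arg(trait_field, c("category", "chemotype"))
  if (trait_field == "category") {
    lab <- sort(unique(refs$category))
    states <- match(refs$category, lab)
  } else {
    anti <- refs$category == "antibiotic"
    lab <- sort(unique(refs$chemotype[anti]))
    states <- ifelse(anti, match(refs$chemotype, lab), NA_integer_)
  }
  if (length(lab) < 2)
    stop("need >= 2 distinct trait labels among references (found ",
         length(lab), ")")
  names(states) <- refs$id
  list(labels = lab, states = states[!is.na(states)])
}

## Reference-only ML rate for a given trait field. A missing query tip
## contributes a vector of ones and marginalises out of the likelihood, so
## the per-query fit with the query missing equals this reference-only fit;
## batch callers compute it once and reuse it.
.fit_field_rate <- function(tree, refs, trait_field, bounds = c(1e-8, 100)) {
  enc <- .trait_labels(refs, trait_field)
  reftree <- ape::keep.tip(tree, names(enc$states))
  fit <- fit_er_rate(reftree, enc$states, k = length(enc$labels),
                     bounds = bounds)
  list(fit = fit, labels = enc$labels, states = enc$states)
}

#' Estimate the trait probability vector of a single uncharacterized tip
#'
#' Implements the hidden-state prediction at the heart of the package:
#' (1) prune the tree to the query tip plus all annotated reference tips
#' (unifurcations suppressed, merged branch lengths summed); (2) reroot the
#' pruned tree at the parent node of the query (the ancestor of the query and
#' its closest reference relative); (3) fit the ER transition rate by maximum
#' likelihood on the reference states with the query treated as missing data;
#' (4) compute the marginal state probabilities at the new root from the
#' reference data; (5) propagate them over the query's pendant branch.
#' Under the time-reversible ER model with uniform root prior this equals the
#' missing-data marginal at the query tip, independent of the rooting.
#'
#' @param tree rooted `phylo` containing the query and all reference tips.
#' @param refs a `reference_annotations` data frame (columns `id`,
#'   `category`, `chemotype`).
#' @param query_id tip label of the uncharacterized sequence.
#' @param trait_field `"category"` (spore pigment vs antibiotic) or
#'   `"chemotype"`.
#' @param q optional fixed ER rate; when `NULL` the rate is fitted (step 3).
#' @param bounds rate search bounds passed to [fit_er_rate()].
#' @return named probability vector over the trait labels (sums to 1), with
#'   attributes `q` and `at_bound`.
#' @export
estimate_tip_trait <- function(tree, refs, query_id,
                               trait_field = c("chemotype", "category"),
                               q = NULL, bounds = c(1e-8, 100)) {
  trait_field <- match.arg(trait_field)
  if (!query_id %in% tree$tip.label) stop("query '", query_id, "' not in tree")
  if (query_id %in% refs$id) stop("query '", query_id, "' is itself annotated")
  enc <- .trait_labels(refs, trait_field)
  k <- length(enc$labels)
  missing_refs <- setdiff(names(enc$states), tree$tip.label)
  if (length(missing_refs))
    stop("reference tip(s) absent from tree: ",
         paste(missing_refs, collapse = ", "))
  pruned <- ape::keep.tip(tree, c(names(enc$states), query_id))
  at_bound <- FALSE
  if (is.null(q)) {
    fit <- fit_er_rate(pruned, enc$states, k = k, bounds = bounds)
    q <- fit$q_hat
    at_bound <- fit$at_bound
    if (at_bound)
      warning("ER rate estimate at search bound (q = ", signif(q, 6), ")")
  }
  p <- .query_marginal(pruned, enc$states, k, q, query_id)
  names(p) <- enc$labels
  attr(p, "q") <- q
  attr(p, "at_bound") <- at_bound
  p
}

## Reroot at the query's parent, take the reference-only marginal at that
## root, and push it through the query's pendant branch.
.query_marginal <- function(pruned, ref_states, k, q, query_id) {
  u <- if (ape::is.rooted(pruned)) ape::unroot(pruned) else pruned
  qi <- match(query_id, u$tip.label)
  erow <- which(u$edge[, 2] == qi)
  parent <- u$edge[erow, 1]
  t_pend <- u$edge.length[erow]
  rootnode <- length(u$tip.label) + 1L
  ph <- if (parent == rootnode) u else
    ape::root(u, node = parent, resolve.root = FALSE)
  # after rerooting the query's parent is the root; pendant length unchanged
  qi2 <- match(query_id, ph$tip.label)
  st <- ref_states[names(ref_states) %in% ph$tip.label]
  model <- er_model(k, q)
  m <- marginal_root_probabilities(ph, st, model)
  p <- as.vector(m %*% er_transition_matrix(k, q, t_pend))
  p / sum(p)
}

#' Two-state spore-pigment classification with exclusion set
#'
#' Runs [estimate_tip_trait()] with `trait_field = "category"` for each query
#' and flags queries whose probability of encoding spore pigmentation exceeds
#' the exclusion threshold; those sequences are removed before chemotype
#' analyses since the interest is antibiotic production.
#'
#' @param tree rooted `phylo`.
#' @param refs `reference_annotations` containing both categories.
#' @param query_ids character vector of unannotated tip labels.
#' @param threshold exclusion threshold on P(spore_pigment); default 0.5.
#' @return a `trait_probs` object over `{antibiotic, spore_pigment}` with an
#'   `excluded` attribute (character vector of excluded query ids).
#' @export
classify_spore_pigment <- function(tree, refs, query_ids, threshold = 0.5) {
  if (!all(c("spore_pigment", "antibiotic") %in% refs$category))
    stop("references must contain both 'spore_pigment' and 'antibiotic' rows")
  fr <- .fit_field_rate(tree, refs, "category")
  P <- t(vapply(query_ids, function(id)
    estimate_tip_trait(tree, refs, id, "category", q = fr$fit$q_hat),
    numeric(length(fr$labels))))
  colnames(P) <- fr$labels
  tp <- trait_probs(P, field = "category", q = fr$fit$q_hat,
                    at_bound = fr$fit$at_bound)
  attr(tp, "excluded") <- query_ids[P[, "spore_pigment"] > threshold]
  tp
}

#' Assign chemotype probability vectors to queries
#'
#' Per-query chemotype probability vectors via [estimate_tip_trait()] with
#' `trait_field = "chemotype"`. The rate is fitted once on the reference-only
#' tree (exactly the per-query fit with the query missing). A query is a
#' "confident" assignment when its modal probability reaches `confidence`
#' (default 0.75).
#'
#' @inheritParams classify_spore_pigment
#' @param confidence modal-probability threshold for a confident assignment.
#' @return a `trait_probs` object over chemotype labels.
#' @export
assign_chemotypes <- function(tree, refs, query_ids, confidence = 0.75) {
  fr <- .fit_field_rate(tree, refs, "chemotype")
  P <- t(vapply(query_ids, function(id)
    estimate_tip_trait(tree, refs, id, "chemotype", q = fr$fit$q_hat),
    numeric(length(fr$labels))))
  colnames(P) <- fr$labels
  trait_probs(P, field = "chemotype", q = fr$fit$q_hat,
              at_bound = fr$fit$at_bound, confidence = confidence)
}

#' Trait probability container
#'
#' @param P matrix of probabilities, queries as rows, trait labels as
#'   columns; each row must sum to 1 (within 1e-9).
#' @param field trait field the probabilities refer to.
#' @param q ER rate used.
#' @param at_bound was the rate fit at a search bound?
#' @param confidence modal-probability threshold recorded for `confident`.
#' @return the matrix with class `trait_probs` and cached `modal`,
#'   `modal_prob` and `confident` attributes.
#' @export
trait_probs <- function(P, field = "chemotype", q = NA_real_,
                        at_bound = FALSE, confidence = 0.75) {
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) stop("probabilities outside [0,1]")
  if (any(abs(rowSums(P) - 1) > 1e-9)) stop("trait probability rows must sum to 1")
  mi <- max.col(P, ties.method = "first")
  structure(P, class = c("trait_probs", "matrix"),
            field = field, q = q, at_bound = at_bound,
            modal = colnames(P)[mi],
            modal_prob = P[cbind(seq_len(nrow(P)), mi)],
            confident = P[cbind(seq_len(nrow(P)), mi)] >= confidence)
}

#' @export
print.trait_probs <- function(x, ...) {
  cat(sprintf("Trait probabilities (%s): %d queries x %d labels; %d confident assignments\n",
              attr(x, "field"), nrow(x), ncol(x), sum(attr(x, "confident"))))
  invisible(x)
}

#' @export
summary.trait_probs <- function(object, ...) {
  data.frame(query = rownames(object),
             modal = attr(object, "modal"),
             modal_prob = attr(object, "modal_prob"),
             confident = attr(object, "confident"),
             row.names = NULL)
}

#' @export
as.data.frame.trait_probs <- function(x, ...) {
  cbind(data.frame(query = rownames(x), row.names = NULL),
        as.data.frame(unclass(x), row.names = NULL),
        summary(x)[-1])
}

#' Faith's phylogenetic diversity of a tip set
#'
#' Sum of the branch lengths of the minimal subtree connecting `tip_set`,
#' measured below (and excluding branches above) the most recent common
#' ancestor of the set. A singleton set has PD 0 by convention.
#'
#' @param tree rooted `phylo`.
#' @param tip_set character vector of tip labels.
#' @param include_root_path also count the path from the MRCA up to the root?
#'   Default `FALSE`.
#' @return a scalar PD value.
#' @export
faith_pd <- function(tree, tip_set, include_root_path = FALSE) {
  tip_set <- unique(tip_set)
  idx <- match(tip_set, tree$tip.label)
  if (anyNA(idx)) stop("unknown tip(s): ",
                       paste(tip_set[is.na(idx)], collapse = ", "))
  m <- length(idx)
  if (m == 0) stop("empty tip set")
  if (m == 1) return(0)
  counts <- .edge_tip_counts(tree, idx)
  pd <- sum(tree$edge.length[counts >= 1 & counts <= m - 1])
  if (include_root_path) {
    # stem edges: all m tips below, between MRCA and root
    pd <- pd + sum(tree$edge.length[counts == m])
  }
  pd
}

## number of tips from `idx` descending from each edge's child end
.edge_tip_counts <- function(tree, idx) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  cnt <- numeric(n + tree$Nnode)
  cnt[idx] <- 1
  for (r in seq_len(nrow(po$edge)))
    cnt[po$edge[r, 1]] <- cnt[po$edge[r, 1]] + cnt[po$edge[r, 2]]
  cnt[tree$edge[, 2]]
}

#' Randomization test of phylogenetic trait clustering
#'
#' Compares the Faith's PD spanned by the tips carrying a trait to the PD of
#' `n_draws` uniform random draws (without replacement) of the same number of
#' tips. The reported quantile is the rank of the observed PD among the draws
#' (ties counted as at or below the observed value; rank 1 when the observed
#' PD is below all draws) divided by `n_draws + 1`; a low quantile indicates
#' phylogenetic clustering. Reported under the field's customary "z-score"
#' label although it is a rank quantile.
#'
#' @param tree rooted `phylo`.
#' @param trait_tips tips carrying the trait (1 < size < number of tips,
#'   except for the degenerate all-tips case which returns quantile 1 with a
#'   warning).
#' @param n_draws number of random draws (the reference analysis uses 10,000).
#' @param seed integer RNG seed.
#' @return list with `observed_pd`, `quantile`, `n_draws`, `draw_pd`.
#' @export
trait_clustering_score <- function(tree, trait_tips, n_draws = 10000,
                                   seed = 1) {
  trait_tips <- unique(trait_tips)
  n <- length(tree$tip.label)
  m <- length(trait_tips)
  if (m < 2) stop("need at least 2 trait tips")
  if (n_draws < 1) stop("n_draws must be >= 1")
  obs <- faith_pd(tree, trait_tips)
  if (m >= n) {
    warning("trait set covers all tips; clustering quantile degenerate (1)")
    return(list(observed_pd = obs, quantile = 1, n_draws = n_draws,
                draw_pd = rep(obs, n_draws)))
  }
  # vectorised PD over draws: edge x tip incidence times tip x draw indicator
  po <- ape::reorder.phylo(tree, "postorder")
  set.seed(as.integer(seed %% .Machine$integer.max))
  draws <- replicate(n_draws, sample.int(n, m))
  ind <- matrix(0, n, n_draws)
  ind[cbind(as.vector(draws), rep(seq_len(n_draws), each = m))] <- 1
  cnt <- rbind(ind, matrix(0, tree$Nnode, n_draws))
  for (r in seq_len(nrow(po$edge)))
    cnt[po$edge[r, 1], ] <- cnt[po$edge[r, 1], ] + cnt[po$edge[r, 2], ]
  ecnt <- cnt[tree$edge[, 2], , drop = FALSE]
  draw_pd <- colSums(tree$edge.length * (ecnt >= 1 & ecnt <= m - 1))
  rank_obs <- 1 + sum(draw_pd <= obs)
  list(observed_pd = obs, quantile = rank_obs / (n_draws + 1),
       n_draws = n_draws, draw_pd = draw_pd)
}

#' Robustness of chemotype assignment across alternative trees
#'
#' Runs [assign_chemotypes()] on each tree of a set (e.g. a Bayesian
#' posterior sample or NNI-perturbed replicates) sharing the same tip set.
#' Per query, the agreement fraction is the share of trees whose modal label
#' equals the overall most common modal label; per tree, sequences are
#' counted per modal chemotype with a `"none"` bucket for modal probability
#' at or below `none_threshold`.
#'
#' @param trees list of `phylo` trees with identical tip sets.
#' @param refs `reference_annotations`.
#' @param query_ids queries to assign on every tree.
#' @param none_threshold modal probability at or below which a query counts
#'   as unassigned; default 0.5.
#' @param confidence passed to [assign_chemotypes()].
#' @return list with `per_query` (data frame: query, modal label, agreement)
#'   and `per_tree_counts` (trees x chemotype-labels-plus-none matrix).
#' @export
assignment_consistency <- function(trees, refs, query_ids,
                                   none_threshold = 0.5, confidence = 0.75) {
  if (length(trees) < 2) stop("need >= 2 trees")
  tipset <- sort(trees[[1]]$tip.label)
  for (tr in trees[-1])
    if (!identical(sort(tr$tip.label), tipset))
      stop("trees do not share the same tip set")
  runs <- lapply(trees, assign_chemotypes, refs = refs,
                 query_ids = query_ids, confidence = confidence)
  labels <- colnames(runs[[1]])
  modal <- vapply(runs, function(r) attr(r, "modal"), character(length(query_ids)))
  mprob <- vapply(runs, function(r) attr(r, "modal_prob"), numeric(length(query_ids)))
  modal <- matrix(modal, nrow = length(query_ids))
  mprob <- matrix(mprob, nrow = length(query_ids))
  consensus <- apply(modal, 1, function(z) names(sort(table(z), decreasing = TRUE))[1])
  agreement <- rowMeans(modal == consensus)
  eff <- ifelse(mprob <= none_threshold, "none", modal)
  counts <- t(apply(eff, 2, function(z)
    table(factor(z, levels = c(labels, "none")))))
  rownames(counts) <- paste0("tree", seq_along(trees))
  list(per_query = data.frame(query = query_ids, modal = consensus,
                              agreement = agreement, row.names = NULL),
       per_tree_counts = counts)
}
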