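# Independent oracles used across tests: brute-force likelihood enumeration
# over internal-node states, enumeration-based tip marginals, and small
# random-instance generators. These deliberately avoid the package's pruning
# code paths.

rand_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
  tr
}

# Brute-force likelihood: enumerate states of every internal node and every
# missing tip; multiply edge transition probabilities explicitly.
enum_likelihood <- function(tree, states, k, q, prior = rep(1 / k, k)) {
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  fixed <- rep(NA_integer_, M)
  fixed[seq_len(n)] <- states[tree$tip.label]
  free <- which(is.na(fixed))
  P <- lapply(seq_len(nrow(tree$edge)), function(r)
    er_transition_matrix(k, q, tree$edge.length[r]))
  total <- 0
  grid <- rep(1L, length(free))
  repeat {
    s <- fixed
    s[free] <- grid
    term <- prior[s[n + 1L]]
    for (r in seq_len(nrow(tree$edge)))
      term <- term * P[[r]][s[tree$edge[r, 1]], s[tree$edge[r, 2]]]
    total <- total + term
    j <- 1L
    while (j <= length(free)) {
      grid[j] <- grid[j] + 1L
      if (grid[j] <= k) break
      grid[j] <- 1L
      j <- j + 1L
    }
    if (j > length(free)) break
  }
  total
}

# Enumeration-based marginal for one query tip: P(query = j) over labels by
# fixing the query to each state in turn.
enum_tip_marginal <- function(tree, ref_states, k, q, query_id,
                              prior = rep(1 / k, k)) {
  L <- vapply(seq_len(k), function(j) {
    st <- c(ref_states, stats::setNames(j, query_id))
    enum_likelihood(tree, st, k, q, prior)
  }, 0)
  L / sum(L)
}

# Random reference/query instance on a small tree with clustered labels.
rand_instance <- function(n_tips, k, seed, q_sim = 0.4) {
  tr <- rand_tree(n_tips, seed)
  sim <- simulate_er_traits(tr, k, q_sim, seed = seed + 1000)
  query <- sample(tr$tip.label, 1)
  refs_ids <- setdiff(tr$tip.label, query)
  # ensure at least 2 labels among references
  st <- sim$tip_states[refs_ids]
  if (length(unique(st)) < 2) st[1] <- (st[1] %% k) + 1L
  labels <- sprintf("L%02d", seq_len(k))
  refs <- as_reference_annotations(data.frame(
    id = refs_ids, category = "antibiotic",
    chemotype = labels[st], stringsAsFactors = FALSE), quiet = TRUE)
  list(tree = tr, refs = refs, query = query,
       ref_states = st, labels = labels)
}

make_star_tree <- function(n, pendant = 0.3) {
  edge <- cbind(rep(n + 1L, n), seq_len(n))
  structure(list(edge = edge, edge.length = rep(pendant, n),
                 tip.label = sprintf("t%04d", seq_len(n)), Nnode = 1L),
            class = "phylo", order = "cladewise")
}

tmp_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
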