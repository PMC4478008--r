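## Synthetic trees, trait histories, reference subsets, and spatially
## structured communities with the statistical structure the analyses assume:
## a clock-ish gene tree with phylogenetically clustered chemotypes, a
## minority of annotated reference tips, samples grouped into continents,
## distance-decay of community composition, and trait convergence (several
## distinct sequence groups encoding the same chemotype).

.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 1299721 * offset) %% 2147483647)
}

#' Simulate a pure-birth gene tree of unit height
#'
#' Yule (pure-birth) tree with exponential waiting times, rescaled so the
#' root-to-tip height equals 1. Tips are labelled `seq0001`, `seq0002`, ...
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @return a rooted binary `phylo` of height 1.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  set.seed(.sub_seed(seed, 1))
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / h
  tr$tip.label <- sprintf("seq%04d", seq_len(n_tips))
  tr
}

#' Simulate a discrete trait along a tree under the ER Mk model
#'
#' The root state is uniform on `1..k`; each branch transitions according to
#' [er_transition_matrix()]. Both tip and internal-node states are returned
#' so the simulation can serve as ground truth for reconstruction oracles.
#'
#' @param tree rooted `phylo`.
#' @param k number of states.
#' @param q per-pair transition rate.
#' @param seed integer seed.
#' @return list with `tip_states` (named integer vector) and `node_states`
#'   (states of all nodes, tips first).
#' @export
simulate_er_traits <- function(tree, k, q, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (q < 0) stop("q must be >= 0")
  set.seed(.sub_seed(seed, 2))
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  pre <- ape::reorder.phylo(tree, "postorder")
  states <- integer(M)
  states[n + 1L] <- sample.int(k, 1)
  # preorder = reverse postorder edge traversal
  for (r in rev(seq_len(nrow(pre$edge)))) {
    pa <- pre$edge[r, 1]; ch <- pre$edge[r, 2]
    P <- er_transition_matrix(k, q, pre$edge.length[r])
    states[ch] <- sample.int(k, 1, prob = P[states[pa], ])
  }
  tips <- states[seq_len(n)]
  names(tips) <- tree$tip.label
  list(tip_states = tips, node_states = states)
}

#' Simulate an alignment along the tree (Jukes-Cantor)
#'
#' Optional explicit sequence evolution (a 4-state ER model per site) for
#' when a real alignment, rather than the tree-distance identity map, is
#' needed.
#'
#' @param tree rooted `phylo`.
#' @param n_sites alignment length.
#' @param rate per-pair substitution rate.
#' @param seed integer seed.
#' @return an `alignment_set`.
#' @export
simulate_alignment <- function(tree, n_sites = 300, rate = 0.2, seed = 1) {
  set.seed(.sub_seed(seed, 3))
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  S <- matrix(0L, M, n_sites)
  S[n + 1L, ] <- sample.int(4, n_sites, replace = TRUE)
  for (r in rev(seq_len(nrow(po$edge)))) {
    pa <- po$edge[r, 1]; ch <- po$edge[r, 2]
    e <- exp(-4 * rate * po$edge.length[r])
    stay <- stats::runif(n_sites) < 0.25 + 0.75 * e
    child <- S[pa, ]
    nm <- sum(!stay)
    if (nm) {
      shift <- sample.int(3, nm, replace = TRUE)
      child[!stay] <- (child[!stay] - 1L + shift) %% 4L + 1L
    }
    S[ch, ] <- child
  }
  bases <- c("A", "C", "G", "T")
  seqs <- apply(S[seq_len(n), , drop = FALSE], 1,
                function(z) paste(bases[z], collapse = ""))
  names(seqs) <- tree$tip.label
  as_alignment(seqs)
}

#' Landscape generator configuration
#'
#' Defaults mirror the sampling design the package's analyses assume: three
#' continents with 50 samples each, within-continent extent 170 km,
#' intercontinental separation thousands of kilometers, 20 chemotypes with a
#' spore-pigment clade, a minority of annotated reference tips, exponential
#' distance-decay of sequence occurrence, and trait convergence (each
#' chemotype spread over several 90%-identity sequence groups).
#'
#' @param n_continents number of continents.
#' @param samples_per_continent samples per continent.
#' @param within_extent_m within-continent extent (meters).
#' @param between_separation_m separation between continent centers (meters).
#' @param n_sequences number of environmental sequences (tree tips).
#' @param n_chemotypes number of antibiotic chemotypes.
#' @param q_sim ER rate used when `trait_mode = "mk"`.
#' @param trait_mode `"clade"` (chemotypes assigned to similarity-group
#'   clades; the convergence structure) or `"mk"` (traits simulated under
#'   the ER model at rate `q_sim`).
#' @param reference_fraction fraction of tips annotated as references.
#' @param decay_lambda per-meter turnover of occurrence probability.
#' @param continent_effect occurrence weight of a sequence outside its home
#'   continent (1 = no continent structure).
#' @param convergence_factor mean number of distinct 90%-level groups per
#'   chemotype.
#' @param sequences_per_sample sequences observed per sample (presence 0/1).
#' @param pigment_fraction approximate fraction of tips in the spore-pigment
#'   clade.
#' @param binning_cutoff percent-identity cutoff used for group structure.
#' @param n_env,n_plants numbers of environmental variables and plant taxa.
#' @param seed integer seed.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(n_continents = 3, samples_per_continent = 50,
                             within_extent_m = 170000,
                             between_separation_m = 8e6,
                             n_sequences = 400, n_chemotypes = 20,
                             q_sim = 0.5, trait_mode = c("clade", "mk"),
                             reference_fraction = 0.2, decay_lambda = 3e-5,
                             continent_effect = 0.05, convergence_factor = 3,
                             sequences_per_sample = 80,
                             pigment_fraction = 0.05, binning_cutoff = 90,
                             n_env = 15, n_plants = 30, seed = 1) {
  cfg <- list(n_continents = n_continents,
              samples_per_continent = samples_per_continent,
              within_extent_m = within_extent_m,
              between_separation_m = between_separation_m,
              n_sequences = n_sequences, n_chemotypes = n_chemotypes,
              q_sim = q_sim, trait_mode = match.arg(trait_mode),
              reference_fraction = reference_fraction,
              decay_lambda = decay_lambda,
              continent_effect = continent_effect,
              convergence_factor = convergence_factor,
              sequences_per_sample = sequences_per_sample,
              pigment_fraction = pigment_fraction,
              binning_cutoff = binning_cutoff,
              n_env = n_env, n_plants = n_plants, seed = seed)
  stopifnot(n_continents >= 1, samples_per_continent >= 1, n_sequences >= 4,
            n_chemotypes >= 2, reference_fraction > 0, reference_fraction <= 1,
            decay_lambda >= 0, sequences_per_sample >= 1)
  structure(cfg, class = "landscape_config")
}

#' Simulate a full synthetic landscape
#'
#' Generates a coherent bundle: gene tree, percent-identity structure,
#' reference annotations, true per-sequence traits, a presence/absence
#' community table with continent structure and exponential distance-decay,
#' and sample metadata with spatially structured environmental variables and
#' plant presences. Fully deterministic per `cfg$seed`.
#'
#' @param cfg a [landscape_config()].
#' @return list with `tree`, `identity`, `refs`, `truth`, `groups`,
#'   `community`, `meta`, `cfg`.
#' @export
simulate_landscape <- function(cfg = landscape_config()) {
  stopifnot(inherits(cfg, "landscape_config"))
  n <- cfg$n_sequences
  tree <- simulate_tree(n, seed = cfg$seed)
  D <- ape::cophenetic.phylo(tree)
  ident <- 100 * exp(-D / 2)   # monotone map of patristic distance, in (0,100]
  diag(ident) <- 100
  class(ident) <- c("identity_matrix", "matrix")

  set.seed(.sub_seed(cfg$seed, 10))
  ## spore-pigment clade: internal clade with tip share closest to target
  cnt <- .edge_tip_counts(tree, seq_len(n))
  target <- max(3, round(cfg$pigment_fraction * n))
  internal <- tree$edge[, 2] > n
  pick <- which(internal)[which.min(abs(cnt[internal] - target))]
  pig_tips <- tree$tip.label[ape::prop.part(tree)[[tree$edge[pick, 2] - n]]]

  ## chemotypes over similarity groups (trait convergence) or by Mk process
  groups <- bin_by_tree(tree, ident, cfg$binning_cutoff)
  truth <- stats::setNames(rep(NA_character_, n), tree$tip.label)
  truth[pig_tips] <- "pigment"
  anti_tips <- setdiff(tree$tip.label, pig_tips)
  labels <- sprintf("ct%02d", seq_len(cfg$n_chemotypes))
  if (cfg$trait_mode == "mk") {
    sim <- simulate_er_traits(tree, cfg$n_chemotypes, cfg$q_sim,
                              seed = .sub_seed(cfg$seed, 11))
    truth[anti_tips] <- labels[sim$tip_states[anti_tips]]
  } else {
    agroups <- unique(groups[anti_tips])
    sizes <- vapply(agroups, function(g) sum(groups[anti_tips] == g), 0L)
    agroups <- agroups[order(-sizes)]
    n_use <- min(length(agroups),
                 max(cfg$n_chemotypes,
                     round(cfg$n_chemotypes * cfg$convergence_factor)))
    lab_of_group <- stats::setNames(rep(NA_character_, length(agroups)), agroups)
    lab_of_group[seq_len(n_use)] <-
      sample(rep_len(labels, n_use))
    if (n_use < length(agroups)) {
      # small leftover groups inherit the chemotype of the nearest seeded group
      rep_tip <- vapply(agroups, function(g)
        names(groups)[groups == g & names(groups) %in% anti_tips][1], "")
      seeded <- seq_len(n_use)
      for (j in (n_use + 1L):length(agroups)) {
        dnear <- D[rep_tip[j], rep_tip[seeded]]
        lab_of_group[j] <- lab_of_group[seeded[which.min(dnear)]]
      }
    }
    truth[anti_tips] <- lab_of_group[groups[anti_tips]]
  }

  ## reference subset: stratified so every chemotype and both categories are
  ## represented (at least one reference per label, two for pigment)
  set.seed(.sub_seed(cfg$seed, 12))
  refs_ids <- character(0)
  for (lab in unique(truth)) {
    tips <- names(truth)[truth == lab]
    need <- max(if (lab == "pigment") 2L else 1L,
                round(cfg$reference_fraction * length(tips)))
    refs_ids <- c(refs_ids, sample(tips, min(need, length(tips))))
  }
  refs <- as_reference_annotations(data.frame(
    id = refs_ids,
    category = ifelse(truth[refs_ids] == "pigment", "spore_pigment",
                      "antibiotic"),
    chemotype = ifelse(truth[refs_ids] == "pigment", "",
                       truth[refs_ids]),
    stringsAsFactors = FALSE), quiet = TRUE)

  ## sample coordinates: continent centers far apart; within a continent,
  ## cluster centers with lognormal jitter give pair distances spanning
  ## sub-meter to the full extent
  set.seed(.sub_seed(cfg$seed, 13))
  n_samp <- cfg$n_continents * cfg$samples_per_continent
  continent <- rep(sprintf("C%d", seq_len(cfg$n_continents)),
                   each = cfg$samples_per_continent)
  coords <- matrix(0, n_samp, 2)
  for (ci in seq_len(cfg$n_continents)) {
    idx <- which(continent == sprintf("C%d", ci))
    ncl <- max(2, ceiling(length(idx) / 10))
    centers <- matrix(stats::runif(2 * ncl, 0, cfg$within_extent_m), ncl, 2)
    asg <- sample.int(ncl, length(idx), replace = TRUE)
    jit <- matrix(stats::rlnorm(2 * length(idx), log(50), 2), ncol = 2) *
      sample(c(-1, 1), 2 * length(idx), replace = TRUE)
    coords[idx, ] <- centers[asg, , drop = FALSE] + jit
    coords[idx, 1] <- coords[idx, 1] + (ci - 1) * cfg$between_separation_m
  }
  sample_ids <- sprintf("%s_s%02d", continent,
                        stats::ave(seq_len(n_samp), continent, FUN = seq_along))
  rownames(coords) <- sample_ids

  ## sequence home locations: per similarity group, then tip-level jitter
  set.seed(.sub_seed(cfg$seed, 14))
  gids <- unique(groups)
  ghome_cont <- sample(seq_len(cfg$n_continents), length(gids), replace = TRUE)
  names(ghome_cont) <- gids
  ghome_xy <- cbind(stats::runif(length(gids), 0, cfg$within_extent_m) +
                      (ghome_cont - 1) * cfg$between_separation_m,
                    stats::runif(length(gids), 0, cfg$within_extent_m))
  rownames(ghome_xy) <- gids
  home_xy <- ghome_xy[groups[tree$tip.label], , drop = FALSE] +
    matrix(stats::rnorm(2 * n, 0, cfg$within_extent_m / 20), n, 2)
  home_cont <- ghome_cont[groups[tree$tip.label]]

  ## occurrence draws: weight decays with distance from home, reduced off the
  ## home continent
  set.seed(.sub_seed(cfg$seed, 15))
  comm <- matrix(0L, n_samp, n, dimnames = list(sample_ids, tree$tip.label))
  cont_idx <- as.integer(factor(continent, levels = sprintf("C%d", seq_len(cfg$n_continents))))
  for (s in seq_len(n_samp)) {
    d <- sqrt((home_xy[, 1] - coords[s, 1])^2 + (home_xy[, 2] - coords[s, 2])^2)
    w <- exp(-cfg$decay_lambda * d) *
      ifelse(home_cont == cont_idx[s], 1, cfg$continent_effect)
    w <- w + 1e-12
    take <- sample.int(n, min(cfg$sequences_per_sample, n), prob = w)
    comm[s, take] <- 1L
  }

  ## environment and plants share the spatial gradient so their
  ## dissimilarities correlate with community turnover
  set.seed(.sub_seed(cfg$seed, 16))
  gx <- coords[, 1] / max(abs(coords[, 1]))
  gy <- coords[, 2] / max(abs(coords[, 2]))
  env <- vapply(seq_len(cfg$n_env), function(j)
    stats::rnorm(1) * gx + stats::rnorm(1) * gy + stats::rnorm(n_samp, 0, 0.3),
    numeric(n_samp))
  colnames(env) <- sprintf("env%02d", seq_len(cfg$n_env))
  ph <- cbind(stats::runif(cfg$n_plants, min(coords[, 1]), max(coords[, 1])),
              stats::runif(cfg$n_plants, 0, cfg$within_extent_m))
  range_m <- cfg$between_separation_m / 4
  plants <- vapply(seq_len(cfg$n_plants), function(j) {
    d <- sqrt((coords[, 1] - ph[j, 1])^2 + (coords[, 2] - ph[j, 2])^2)
    as.numeric(stats::runif(n_samp) < exp(-d / range_m))
  }, numeric(n_samp))
  colnames(plants) <- sprintf("plant_%02d", seq_len(cfg$n_plants))
  rownames(env) <- rownames(plants) <- sample_ids

  meta <- structure(list(samples = sample_ids, coords = coords,
                         coord_system = "xy_m",
                         continent = stats::setNames(continent, sample_ids),
                         env = env, plants = plants),
                    class = "sample_metadata")
  list(tree = tree, identity = ident, refs = refs, truth = truth,
       groups = groups, community = as_community_table(comm, "sequence"),
       meta = meta, cfg = cfg)
}
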