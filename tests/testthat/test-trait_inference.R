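# Toy tree used in several cases: a tight clade of "A" references next to the
# query, with "B" references far away.
toy_bundle <- function(pendant = 0) {
  txt <- sprintf(
    "(((q:%g,a1:0.01):0.01,(a2:0.01,a3:0.01):0.01):2,(b1:0.05,b2:0.05):2);",
    pendant)
  tree <- parse_newick(txt)
  refs <- as_reference_annotations(data.frame(
    id = c("a1", "a2", "a3", "b1", "b2"), category = "antibiotic",
    chemotype = c("A", "A", "A", "B", "B")), quiet = TRUE)
  list(tree = tree, refs = refs)
}

test_that("zero-distance attachment to a monolabel clade is near-certain", {
  tb <- toy_bundle(pendant = 0)
  p <- suppressWarnings(estimate_tip_trait(tb$tree, tb$refs, "q", "chemotype"))
  expect_gte(p[["A"]], 0.99)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("an infinite pendant branch returns the uniform stationary vector", {
  tb <- toy_bundle(pendant = 500)
  p <- suppressWarnings(estimate_tip_trait(tb$tree, tb$refs, "q", "chemotype"))
  expect_equal(as.numeric(p), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("probabilities move monotonically toward uniform with pendant length", {
  dists <- numeric(0)
  for (pend in c(0, 0.1, 0.5, 1, 2, 5, 20)) {
    tb <- toy_bundle(pendant = pend)
    p <- suppressWarnings(
      estimate_tip_trait(tb$tree, tb$refs, "q", "chemotype", q = 0.3))
    dists <- c(dists, max(abs(p - 0.5)))
  }
  expect_true(all(diff(dists) <= 1e-12))
})

test_that("tip imputation equals the enumeration marginal on random instances", {
  for (i in 1:10) {
    inst <- rand_instance(8, 3, seed = 3000 + i)
    p <- suppressWarnings(
      estimate_tip_trait(inst$tree, inst$refs, inst$query, "chemotype"))
    ul <- sort(unique(inst$labels[inst$ref_states]))
    k_eff <- length(ul)
    st_eff <- stats::setNames(match(inst$labels[inst$ref_states], ul),
                              names(inst$ref_states))
    pe <- enum_tip_marginal(inst$tree, st_eff, k_eff, attr(p, "q"), inst$query)
    expect_lt(max(abs(as.numeric(p) - pe)), 1e-8)
  }
})

test_that("relabelling chemotypes permutes the output columns exactly", {
  inst <- rand_instance(8, 3, seed = 77)
  p1 <- suppressWarnings(
    estimate_tip_trait(inst$tree, inst$refs, inst$query, "chemotype", q = 0.4))
  refs2 <- inst$refs
  perm <- c(L01 = "ZZ", L02 = "AA", L03 = "MM")
  refs2$chemotype <- unname(perm[refs2$chemotype])
  p2 <- suppressWarnings(
    estimate_tip_trait(inst$tree, refs2, inst$query, "chemotype", q = 0.4))
  for (old in names(perm)[names(perm) %in% names(p1)])
    expect_equal(p2[[perm[[old]]]], p1[[old]], tolerance = 1e-12)
})

test_that("a query equidistant from two single-label references is symmetric", {
  tree <- parse_newick("(q:1,a:2,b:2);")
  refs <- as_reference_annotations(data.frame(
    id = c("a", "b"), category = "antibiotic", chemotype = c("A", "B")),
    quiet = TRUE)
  p <- estimate_tip_trait(tree, refs, "q", "chemotype", q = 0.5)
  expect_equal(p[["A"]], p[["B"]], tolerance = 1e-9)
})

test_that("chemotype assignment requires at least two labels", {
  tree <- parse_newick("((q:1,a:1):1,b:2);")
  refs <- as_reference_annotations(data.frame(
    id = c("a", "b"), category = "antibiotic", chemotype = c("A", "A")),
    quiet = TRUE)
  expect_error(assign_chemotypes(tree, refs, "q"), ">= 2 distinct trait labels")
})

test_that("spore-pigment classification excludes and retains glued queries", {
  tree <- parse_newick(
    "(((qpig:0,p1:0.01):0.02,p2:0.03):2,((qant:0,a1:0.01):0.02,a2:0.03):2);")
  refs <- as_reference_annotations(data.frame(
    id = c("p1", "p2", "a1", "a2"),
    category = c("spore_pigment", "spore_pigment", "antibiotic", "antibiotic"),
    chemotype = c("", "", "A", "A")), quiet = TRUE)
  cl <- suppressWarnings(
    classify_spore_pigment(tree, refs, c("qpig", "qant")))
  expect_identical(attr(cl, "excluded"), "qpig")
  expect_gt(cl["qpig", "spore_pigment"], 0.5)
  expect_lt(cl["qant", "spore_pigment"], 0.5)
})

test_that("pigment/antibiotic separation reaches high balanced accuracy", {
  L <- simulate_landscape(landscape_config(
    n_sequences = 200, samples_per_continent = 4, pigment_fraction = 0.15,
    reference_fraction = 0.25, seed = 88))
  queries <- setdiff(names(L$truth), L$refs$id)
  cl <- suppressWarnings(classify_spore_pigment(L$tree, L$refs, queries))
  truth_pig <- L$truth[queries] == "pigment"
  pred_pig <- queries %in% attr(cl, "excluded")
  sens <- mean(pred_pig[truth_pig])
  spec <- mean(!pred_pig[!truth_pig])
  expect_gte((sens + spec) / 2, 0.9)
})

test_that("confident chemotype assignments are mostly correct on simulation", {
  L <- simulate_landscape(landscape_config(
    n_sequences = 250, samples_per_continent = 4, seed = 42))
  queries <- setdiff(names(L$truth)[L$truth != "pigment"], L$refs$id)
  ch <- suppressWarnings(assign_chemotypes(L$tree, L$refs, queries))
  conf <- attr(ch, "confident")
  expect_gt(sum(conf), 5)
  acc <- mean(attr(ch, "modal")[conf] == L$truth[queries][conf])
  expect_gte(acc, 0.70)
})

test_that("Faith's PD matches manual path sums and picante", {
  tr <- parse_newick("((a:1,b:2):1,(c:3,d:1):2);")
  expect_equal(faith_pd(tr, c("a", "b")), 3)
  expect_equal(faith_pd(tr, c("a", "c")), 7)
  expect_equal(faith_pd(tr, "a"), 0)
  expect_error(faith_pd(tr, c("a", "nope")), "unknown tip")
  skip_if_not_installed("picante")
  tr2 <- rand_tree(12, 6)
  comm <- matrix(0, 1, 12, dimnames = list("s", tr2$tip.label))
  tips <- sample(tr2$tip.label, 5)
  comm[, tips] <- 1
  pp <- picante::pd(comm, tr2, include.root = FALSE)
  expect_equal(faith_pd(tr2, tips), pp$PD, tolerance = 1e-10)
})

test_that("PD clustering quantile follows the rank definition", {
  # plant near-zero pendant tips: their PD is below any other same-size draw
  tree <- make_star_tree(20, pendant = 1)
  tree$edge.length[1:3] <- 0.001
  z <- trait_clustering_score(tree, tree$tip.label[1:3], n_draws = 200, seed = 3)
  expect_equal(z$observed_pd, 0.003)
  expect_gt(min(z$draw_pd), z$observed_pd)
  expect_equal(z$quantile, 1 / 201)
  # star tree: all draws tie the observed value, tie convention gives 1
  star <- make_star_tree(10, pendant = 1)
  zs <- trait_clustering_score(star, star$tip.label[1:4], n_draws = 50, seed = 1)
  expect_equal(zs$quantile, 1)
  expect_warning(
    trait_clustering_score(star, star$tip.label, n_draws = 10, seed = 1),
    "degenerate")
})

test_that("PD clustering quantile is uniform under the null", {
  tr <- rand_tree(40, 17)
  qs <- vapply(1:300, function(i) {
    set.seed(9000 + i)
    tips <- sample(tr$tip.label, 8)
    trait_clustering_score(tr, tips, n_draws = 99, seed = 50000 + i)$quantile
  }, 0)
  ks <- suppressWarnings(stats::ks.test(qs, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("certainty in the correct label grows with reference density", {
  densities <- c(10, 25, 45)
  res <- expand.grid(rep = 1:40, density = densities)
  res$p_correct <- NA_real_
  for (r in seq_len(nrow(res))) {
    seed <- 7000 + res$rep[r]
    tr <- simulate_tree(50, seed = seed)
    sim <- simulate_er_traits(tr, 3, 0.5, seed = seed)
    set.seed(seed)
    query <- sample(tr$tip.label, 1)
    pool <- sample(setdiff(tr$tip.label, query))  # nested reference sets
    ids <- pool[seq_len(res$density[r])]
    st <- sim$tip_states[ids]
    if (length(unique(st)) < 2) next
    refs <- as_reference_annotations(data.frame(
      id = ids, category = "antibiotic",
      chemotype = sprintf("L%02d", st)), quiet = TRUE)
    p <- suppressWarnings(
      estimate_tip_trait(tr, refs, query, "chemotype"))
    lab <- sprintf("L%02d", sim$tip_states[query])
    res$p_correct[r] <- if (lab %in% names(p)) p[[lab]] else 0
  }
  res <- res[!is.na(res$p_correct), ]
  means <- tapply(res$p_correct, res$density, mean)
  # one-sided trend: more references must not reduce certainty
  tt <- stats::cor.test(res$density, res$p_correct, method = "kendall",
                        alternative = "greater")
  expect_lt(tt$p.value, 0.05)
  expect_gt(means[[length(means)]], means[[1]])
})

test_that("assignment agreement is 1 for identical trees and drops under swaps", {
  inst <- rand_instance(10, 3, seed = 55)
  trees <- rep(list(inst$tree), 5)
  cons <- suppressWarnings(
    assignment_consistency(trees, inst$refs, inst$query))
  expect_equal(cons$per_query$agreement, 1)
  expect_equal(nrow(cons$per_tree_counts), 5)
  expect_error(
    assignment_consistency(list(inst$tree, rand_tree(4, 1)), inst$refs,
                           inst$query),
    "tip set")
})

test_that("assignment is robust to modest topology perturbation", {
  skip_if_not_installed("phangorn")
  L <- simulate_landscape(landscape_config(
    n_sequences = 120, samples_per_continent = 4, n_chemotypes = 6,
    reference_fraction = 0.4, seed = 19))
  queries <- sample(setdiff(names(L$truth)[L$truth != "pigment"], L$refs$id), 8)
  set.seed(31)
  trees <- c(list(L$tree), lapply(1:7, function(i) {
    tr <- phangorn::rNNI(L$tree, moves = 3)
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
  }))
  cons <- suppressWarnings(assignment_consistency(trees, L$refs, queries))
  expect_gte(stats::median(cons$per_query$agreement), 0.8)
})
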