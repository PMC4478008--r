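mk_dm <- function(n, seed, ids = paste0("s", seq_len(n))) {
  set.seed(seed)
  m <- as.matrix(stats::dist(matrix(stats::runif(2 * n), n, 2)))
  dimnames(m) <- list(ids, ids)
  m
}

test_that("Bray-Curtis matches hand computation and its bounds", {
  m <- rbind(s1 = c(9L, 1L, 5L, 0L), s2 = c(0L, 2L, 8L, 0L),
             s3 = c(9L, 1L, 5L, 0L), s4 = c(0L, 0L, 0L, 7L))
  colnames(m) <- c("u1", "u2", "u3", "u4")
  m <- as_community_table(m)
  d <- bray_curtis(m)
  expect_equal(d["s1", "s2"], 13 / 25)              # = 0.52
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s4"], 1)                    # disjoint supports
  expect_true(all(d >= 0 & d <= 1))
  bad <- rbind(s1 = c(1L, 0L), s2 = c(0L, 0L))
  colnames(bad) <- c("u1", "u2")
  expect_error(bray_curtis(suppressWarnings(
    as_community_table(bad, drop_empty = FALSE))), "all-zero")
})

test_that("weighted UniFrac equals a branch-by-branch hand sum", {
  # 2-tip tree, fully disjoint samples: normalized distance is 1
  tr2 <- parse_newick("(a:1,b:1);")
  m2 <- rbind(s1 = c(5L, 0L), s2 = c(0L, 3L))
  colnames(m2) <- c("a", "b"); m2 <- as_community_table(m2)
  expect_equal(weighted_unifrac(m2, tr2)["s1", "s2"], 1)
  # identical relative abundances: 0
  m2b <- rbind(s1 = c(4L, 2L), s2 = c(2L, 1L))
  colnames(m2b) <- c("a", "b"); m2b <- as_community_table(m2b)
  expect_equal(weighted_unifrac(m2b, tr2)["s1", "s2"], 0)
  # 3-tip toy, hand-summed branch contributions
  tr3 <- parse_newick("((a:0.4,b:0.6):0.3,c:1.2);")
  m3 <- rbind(s1 = c(2L, 1L, 1L), s2 = c(0L, 2L, 2L))
  colnames(m3) <- c("a", "b", "c"); m3 <- as_community_table(m3)
  A <- c(a = 0.5, b = 0.25, c = 0.25); B <- c(a = 0, b = 0.5, c = 0.5)
  raw <- 0.4 * abs(A["a"] - B["a"]) + 0.6 * abs(A["b"] - B["b"]) +
    1.2 * abs(A["c"] - B["c"]) + 0.3 * abs(A["a"] + A["b"] - B["a"] - B["b"])
  depth <- c(a = 0.7, b = 0.9, c = 1.2)
  denom <- sum(depth * A) + sum(depth * B)
  expect_equal(weighted_unifrac(m3, tr3)["s1", "s2"], unname(raw / denom),
               tolerance = 1e-10)
  expect_equal(weighted_unifrac(m3, tr3, normalized = FALSE)["s1", "s2"],
               unname(raw), tolerance = 1e-10)
  # random tables stay within [0, 1]
  set.seed(12)
  tr <- rand_tree(10, 31)
  mm <- matrix(rpois(50, 2), 5, 10,
               dimnames = list(paste0("s", 1:5), tr$tip.label))
  mm[, 1] <- mm[, 1] + 1
  d <- weighted_unifrac(as_community_table(mm), tr)
  expect_true(all(d >= -1e-12 & d <= 1 + 1e-12))
})

test_that("Mantel statistics behave on constructed inputs", {
  dx <- mk_dm(10, 1)
  r1 <- mantel(dx, dx, n_perm = 99, seed = 2)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_equal(r1$p, 1 / 100)
  # exact power-law construction: log-log slope 1/2
  dy <- dx^0.5
  r2 <- mantel(dx, dy, n_perm = 99, seed = 2, loglog_slope = TRUE,
               distance_floor = 1e-12)
  expect_equal(r2$slope, 0.5, tolerance = 1e-10)
  expect_true(r2$slope_ci[1] <= 0.5 && 0.5 <= r2$slope_ci[2])
  expect_error(mantel(dx * 0 + 1 - diag(10), dx), "zero variance")
})

test_that("Mantel r agrees with vegan and is reproducible under a seed", {
  dx <- mk_dm(12, 5); dy <- mk_dm(12, 6)
  mine <- mantel(dx, dy, n_perm = 199, seed = 7)
  ref <- vegan::mantel(stats::as.dist(dx), stats::as.dist(dy),
                       permutations = 199)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
  expect_identical(mine$p, mantel(dx, dy, n_perm = 199, seed = 7)$p)
  # reordering the samples changes nothing
  ids <- sample(rownames(dx))
  expect_equal(mantel(dx[ids, ids], dy[ids, ids], n_perm = 199, seed = 7)$r,
               mine$r, tolerance = 1e-12)
})

test_that("partial Mantel removes a shared driver", {
  set.seed(9)
  z <- mk_dm(15, 10)
  noise1 <- mk_dm(15, 11); noise2 <- mk_dm(15, 12)
  dx <- z + 0.05 * noise1
  dy <- z + 0.05 * noise2
  full <- mantel(dx, dy, n_perm = 99, seed = 1)
  part <- mantel(dx, dy, n_perm = 99, seed = 1, conditioning = z)
  expect_gt(full$r, 0.9)
  expect_lt(abs(part$r), 0.5)
})

test_that("ANOSIM equals a hand-ranked computation and its extremes", {
  # two tight groups, all between-pairs larger than within-pairs: R = 1
  ids <- paste0("s", 1:6)
  d <- matrix(10, 6, 6, dimnames = list(ids, ids))
  d[1:3, 1:3] <- 1; d[4:6, 4:6] <- 1
  diag(d) <- 0
  grp <- stats::setNames(rep(c("g1", "g2"), each = 3), ids)
  res <- anosim(d, grp, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)
  expect_lte(res$p, 0.1)   # only C(6,3) = 20 distinct label permutations
  # hand-ranked asymmetric 6-sample example
  set.seed(21)
  dh <- mk_dm(6, 33)
  v <- dh[lower.tri(dh)]
  rk <- rank(v)
  within <- (row(dh) <= 3 & col(dh) <= 3) | (row(dh) > 3 & col(dh) > 3)
  wl <- within[lower.tri(dh)]
  R_hand <- (mean(rk[!wl]) - mean(rk[wl])) / (6 * 5 / 4)
  expect_equal(anosim(dh, grp, n_perm = 49, seed = 1)$R, R_hand,
               tolerance = 1e-10)
  expect_error(anosim(d, stats::setNames(c("a", rep("b", 5)), ids)),
               "singleton")
})

test_that("ANOSIM R is centered at zero under label shuffling", {
  d <- mk_dm(12, 40)
  ids <- rownames(d)
  Rs <- vapply(1:200, function(i) {
    set.seed(i)
    grp <- stats::setNames(sample(rep(c("a", "b"), each = 6)), ids)
    anosim(d, grp, n_perm = 1, seed = i)$R
  }, 0)
  expect_lt(abs(mean(Rs)), 0.05)
})

test_that("MRM recovers exact linear constructions and flags collinearity", {
  P1 <- mk_dm(12, 50); P2 <- mk_dm(12, 51)
  resp <- 2 * P1 + 3 * P2
  fit <- mrm(resp, list(a = P1, b = P2), n_perm = 49, seed = 1)
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(mrm(resp, list(a = P1, b = P1 * 2), n_perm = 9, seed = 1),
               "collinear")
})

test_that("MRM separates a real predictor from pure noise", {
  hits_p1 <- 0; miss_p2 <- 0
  for (i in 1:100) {
    P1 <- mk_dm(14, 600 + i); P2 <- mk_dm(14, 900 + i)
    set.seed(1200 + i)
    E <- matrix(stats::rnorm(14 * 14, 0, 0.03), 14, 14); E <- abs(E + t(E)); diag(E) <- 0
    dimnames(E) <- dimnames(P1)
    resp <- P1 + E
    fit <- mrm(resp, list(p1 = P1, p2 = P2), n_perm = 99, seed = i)
    hits_p1 <- hits_p1 + (fit$p_values[["p1"]] <= 0.05)
    miss_p2 <- miss_p2 + (fit$p_values[["p2"]] > 0.05)
  }
  expect_gte(hits_p1, 90)
  expect_gte(miss_p2, 90)
})

test_that("bioenv recovers the variables generating the community distance", {
  set.seed(77)
  env <- matrix(stats::runif(30 * 5), 30, 5,
                dimnames = list(paste0("s", 1:30), paste0("v", 1:5)))
  sc <- apply(env, 2, function(v) (v - min(v)) / diff(range(v)))
  dcomm <- as.matrix(stats::dist(sc[, c(1, 3)]))
  res <- bioenv(dcomm, env)
  expect_setequal(res$best_subset, c("v1", "v3"))
  expect_equal(res$correlation, 1, tolerance = 1e-9)
  one <- bioenv(dcomm, env[, "v1", drop = FALSE])
  expect_equal(one$best_subset, "v1")
  envc <- cbind(env, vconst = 1)
  expect_warning(bioenv(dcomm, envc), "constant")
})

test_that("bioenv recovers a planted pair against noise variables", {
  ok <- 0
  for (i in 1:60) {
    set.seed(2000 + i)
    env <- matrix(stats::runif(30 * 5), 30, 5,
                  dimnames = list(paste0("s", 1:30), paste0("v", 1:5)))
    sc <- apply(env, 2, function(v) (v - min(v)) / diff(range(v)))
    dcomm <- as.matrix(stats::dist(sc[, c(2, 4)]))
    dcomm <- dcomm + as.matrix(stats::dist(matrix(stats::rnorm(30, 0, 0.05), 30)))
    res <- bioenv(dcomm, env)
    ok <- ok + setequal(res$best_subset, c("v2", "v4"))
  }
  expect_gte(ok / 60, 0.8)
})

test_that("environmental pre-filtering drops later members of collinear pairs", {
  set.seed(3)
  clay <- stats::runif(40)
  env <- cbind(clay = clay, sand = -clay + stats::rnorm(40, 0, 0.05),
               ph = stats::runif(40))
  out <- env_prefilter(env, r2 = 0.7)
  expect_setequal(colnames(out), c("clay", "ph"))
  expect_equal(attr(out, "dropped"), "sand")
})

test_that("driver analysis reports raw and Bonferroni-adjusted p-values", {
  set.seed(64)
  geo <- mk_dm(12, 80) * 1000 + 1
  diag(geo) <- 0
  comm <- (geo / max(geo))^0.3
  diag(comm) <- 0
  env_d <- mk_dm(12, 81)
  drv <- driver_analysis(comm, geo, env_d = env_d, n_perm = 99, seed = 5)
  expect_s3_class(drv$decay, "mantel_result")
  expect_true(all(drv$p_table$p_bonferroni >= drv$p_table$p))
  expect_true(all(drv$p_table$p_bonferroni <= 1))
  expect_equal(nrow(drv$p_table), 1 + 2 + 2)  # decay + partials + mrm coefs
})
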