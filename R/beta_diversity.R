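## The three dissimilarity layers (Bray-Curtis on sequence groups and traits,
## weighted UniFrac on the phylogeny) and the spatial/driver statistics:
## Mantel / partial Mantel with log-log distance-decay slope and randomization
## CI, ANOSIM, multiple regression on distance matrices, and bioenv variable
## selection.

.as_dm <- function(m, ids = NULL) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  validate_distance_matrix(m, tol = 1e-8)
}

.lower <- function(m) m[lower.tri(m)]

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum |x_u - y_u| / sum (x_u + y_u)` over units, computed via
#' vegan. Accepts the real-valued trait pseudo-abundance matrices as well as
#' integer count tables.
#'
#' @param table community matrix (samples x units).
#' @return symmetric dissimilarity matrix in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  if (nrow(table) < 2) stop("need >= 2 samples")
  if (any(rowSums(table) <= 0)) stop("all-zero sample row(s)")
  .as_dm(vegan::vegdist(table, method = "bray"))
}

#' Weighted UniFrac dissimilarity
#'
#' For each branch `b` of length `l_b`, the raw score accumulates
#' `l_b * |A_b - B_b|` where `A_b`, `B_b` are the fractions of each sample's
#' total counts descending from the branch. With `normalized = TRUE`
#' (default) the raw score is divided by the score of fully disjoint
#' communities with the same tip depths, so values lie in `[0, 1]`.
#'
#' @param table community matrix whose units are tips of `tree`.
#' @param tree rooted `phylo` with branch lengths.
#' @param normalized normalise to `[0, 1]`?
#' @return symmetric dissimilarity matrix.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  miss <- setdiff(colnames(table), tree$tip.label)
  if (length(miss)) stop("unit(s) not in tree: ", paste(miss, collapse = ", "))
  if (any(rowSums(table) <= 0)) stop("all-zero sample row(s)")
  rel <- table / rowSums(table)
  n <- length(tree$tip.label)
  # relative abundance aligned to tip order (absent tips are zero)
  R <- matrix(0, nrow(table), n, dimnames = list(rownames(table), tree$tip.label))
  R[, colnames(rel)] <- rel
  po <- ape::reorder.phylo(tree, "postorder")
  B <- rbind(t(R), matrix(0, tree$Nnode, nrow(table)))  # node x sample
  for (r in seq_len(nrow(po$edge)))
    B[po$edge[r, 1], ] <- B[po$edge[r, 1], ] + B[po$edge[r, 2], ]
  eb <- B[tree$edge[, 2], , drop = FALSE] * tree$edge.length
  raw <- as.matrix(stats::dist(t(eb), method = "manhattan"))
  if (normalized) {
    depth <- ape::node.depth.edgelength(tree)[seq_len(n)]
    s <- as.vector(R %*% depth)
    denom <- outer(s, s, "+")
    ok <- denom > 0
    raw[ok] <- raw[ok] / denom[ok]
  }
  .as_dm(raw, rownames(table))
}

#' Mantel test with distance-decay slope and randomization CI
#'
#' Correlation between the lower triangles of two distance matrices with a
#' permutation test (simultaneous row/column permutation of `dy`). With
#' `loglog_slope = TRUE` both triangles are log10-transformed (the
#' distance-decay convention), the least-squares slope of
#' `log10(dy) ~ log10(dx)` is reported, and a 95% randomization confidence
#' interval on the slope is computed by residual randomization drawn from the
#' same permutation stream. Pairs at geographic distance 0 are excluded from
#' log-log fits and positive distances below `distance_floor` are floored.
#' With `conditioning` given, a partial Mantel test is performed on the
#' residuals of both triangles regressed on the conditioning triangle.
#'
#' @param dx,dy distance matrices with matching ids (`dx` is permuted as the
#'   "explanatory" matrix, e.g. geographic distance).
#' @param n_perm number of permutations (the reference analysis uses 999).
#' @param seed integer seed.
#' @param conditioning optional third distance matrix (partial Mantel).
#' @param loglog_slope log10-transform both matrices and fit the decay slope?
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @param distance_floor floor (same units as `dx`) applied to positive
#'   `dx` entries under the log transform; default 0.01.
#' @return an object of class `mantel_result`: `r`, `p`, `n_perm`, and (for
#'   log-log fits) `slope`, `slope_ci`.
#' @export
mantel <- function(dx, dy, n_perm = 999, seed = 1, conditioning = NULL,
                   loglog_slope = FALSE, method = c("pearson", "spearman"),
                   distance_floor = 0.01) {
  method <- match.arg(method)
  dx <- .as_dm(dx); dy <- .as_dm(dy)
  if (!identical(rownames(dx), rownames(dy))) {
    if (!setequal(rownames(dx), rownames(dy))) stop("id sets differ")
    dy <- dy[rownames(dx), rownames(dx)]
  }
  if (!is.null(conditioning)) {
    conditioning <- .as_dm(conditioning)
    conditioning <- conditioning[rownames(dx), rownames(dx)]
  }
  n <- nrow(dx)
  tx_mat <- dx; ty_mat <- dy
  if (loglog_slope) {
    tx_mat[dx > 0 & dx < distance_floor] <- distance_floor
    tx_mat <- suppressWarnings(log10(tx_mat))
    ty_mat <- suppressWarnings(log10(dy))
  }
  lt <- lower.tri(dx)
  pair_ok <- if (loglog_slope) is.finite(tx_mat) & is.finite(ty_mat) & lt else lt
  x <- tx_mat[pair_ok]
  if (stats::var(x) == 0) stop("zero variance in explanatory triangle")
  tz <- if (!is.null(conditioning)) conditioning[pair_ok] else NULL
  resfun <- function(xv, yv) {
    ok <- is.finite(yv)        # permuted log-dissimilarities can hit log10(0)
    xv <- xv[ok]; yv <- yv[ok]
    if (!is.null(tz)) {
      zz <- tz[ok]
      xv <- stats::lm.fit(cbind(1, zz), xv)$residuals
      yv <- stats::lm.fit(cbind(1, zz), yv)$residuals
    }
    stats::cor(xv, yv, method = method)
  }
  y0 <- ty_mat[pair_ok]
  if (stats::var(y0) == 0) stop("zero variance in response triangle")
  r_obs <- resfun(x, y0)
  set.seed(as.integer(seed %% .Machine$integer.max))
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    yp <- ty_mat[pm, pm][pair_ok]
    r_perm[b] <- resfun(x, yp)
  }
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  out <- list(r = r_obs, p = p, n_perm = n_perm, method = method,
              partial = !is.null(conditioning), loglog = loglog_slope)
  if (loglog_slope) {
    fit <- stats::lm.fit(cbind(1, x), y0)
    slope <- fit$coefficients[2]
    e <- fit$residuals; fv <- fit$fitted.values
    sl_perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      ystar <- fv + sample(e)
      sl_perm[b] <- stats::lm.fit(cbind(1, x), ystar)$coefficients[2]
    }
    out$slope <- unname(slope)
    out$slope_ci <- unname(stats::quantile(sl_perm, c(0.025, 0.975)))
    out$n_pairs <- length(x)
  }
  structure(out, class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%sMantel test (%s): r = %.4f, p = %.4g (%d permutations)\n",
              if (x$partial) "Partial " else "", x$method, x$r, x$p, x$n_perm))
  if (x$loglog)
    cat(sprintf("  log10-log10 decay slope = %.4f [%.4f, %.4f] (95%% randomization CI, %d pairs)\n",
                x$slope, x$slope_ci[1], x$slope_ci[2], x$n_pairs))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group ones; `R = (mean between-rank - mean within-rank) / (N(N-1)/4)`
#' with significance by label permutation (delegated to vegan).
#'
#' @param d distance matrix.
#' @param groups named vector sample -> group label.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list with `R` and `p`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1) {
  d <- .as_dm(d)
  g <- groups[rownames(d)]
  if (anyNA(g)) stop("missing group label(s)")
  tab <- table(g)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("singleton group(s): ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  set.seed(as.integer(seed %% .Machine$integer.max))
  a <- vegan::anosim(stats::as.dist(d), grouping = factor(g),
                     permutations = n_perm)
  list(R = unname(a$statistic), p = a$signif)
}

#' Multiple regression on distance matrices (MRM)
#'
#' OLS of the unfolded lower triangle of the response on the unfolded lower
#' triangles of the predictors; per-coefficient significance by simultaneous
#' row/column permutation of the response matrix with coefficients refit,
#' two-sided on |coefficient| with +1 smoothing.
#'
#' @param response distance matrix.
#' @param predictors named list of distance matrices.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return an object of class `mrm_result`: `coefficients`, `r_squared`,
#'   `p_values`, `n_perm`.
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = 1) {
  if (!length(predictors)) stop("need >= 1 predictor")
  if (is.null(names(predictors)))
    names(predictors) <- paste0("X", seq_along(predictors))
  response <- .as_dm(response)
  ids <- rownames(response)
  predictors <- lapply(predictors, function(p) .as_dm(p)[ids, ids])
  lt <- lower.tri(response)
  X <- cbind(intercept = 1,
             vapply(predictors, function(p) p[lt], numeric(sum(lt))))
  # scale-invariant collinearity check (units of the predictor matrices differ)
  Xs <- scale(X[, -1, drop = FALSE])
  kap <- kappa(crossprod(cbind(1, Xs)), exact = TRUE)
  if (!is.finite(kap) || kap > 1e10) {
    cc <- stats::cor(X[, -1, drop = FALSE])
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop("collinear predictors: ", paste(colnames(cc)[worst], collapse = " ~ "))
  }
  y <- response[lt]
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  n <- nrow(response)
  set.seed(as.integer(seed %% .Machine$integer.max))
  exceed <- numeric(length(beta))
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    yp <- response[pm, pm][lt]
    bp <- stats::lm.fit(X, yp)$coefficients
    exceed <- exceed + (abs(bp) >= abs(beta))
  }
  pv <- (1 + exceed) / (n_perm + 1)
  names(pv) <- names(beta)
  structure(list(coefficients = beta[-1], intercept = beta[1],
                 r_squared = r2, p_values = pv[-1], n_perm = n_perm),
            class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("Multiple regression on distance matrices (R^2 = %.4f, %d permutations)\n",
              x$r_squared, x$n_perm))
  print(data.frame(coefficient = x$coefficients, p = x$p_values))
  invisible(x)
}

#' bioenv environmental variable selection
#'
#' Exhaustive search over subsets of (min-max scaled) environmental
#' variables: for each subset the Euclidean inter-sample distance is rank
#' correlated (Spearman) with the community dissimilarity; the subset with
#' the highest correlation is returned. Constant variables are dropped with
#' a warning.
#'
#' @param community_d community distance matrix.
#' @param env samples x variables numeric matrix (rownames = sample ids).
#' @param max_subset largest subset size examined.
#' @return list with `best_subset`, `correlation`, and a per-subset `table`.
#' @export
bioenv <- function(community_d, env, max_subset = ncol(env)) {
  community_d <- .as_dm(community_d)
  env <- as.matrix(env)[rownames(community_d), , drop = FALSE]
  if (!ncol(env)) stop("need >= 1 environmental variable")
  rng <- apply(env, 2, function(v) diff(range(v)))
  if (any(rng == 0)) {
    warning("dropping constant variable(s): ",
            paste(colnames(env)[rng == 0], collapse = ", "))
    env <- env[, rng > 0, drop = FALSE]
    rng <- rng[rng > 0]
  }
  if (!ncol(env)) stop("no non-constant environmental variables")
  scaled <- sweep(sweep(env, 2, apply(env, 2, min)), 2, rng, "/")
  yv <- .lower(community_d)
  max_subset <- min(max_subset, ncol(env))
  rows <- list()
  for (sz in seq_len(max_subset)) {
    for (ss in utils::combn(ncol(env), sz, simplify = FALSE)) {
      dv <- .lower(as.matrix(stats::dist(scaled[, ss, drop = FALSE])))
      rows[[length(rows) + 1L]] <- data.frame(
        subset = paste(colnames(env)[ss], collapse = "+"),
        size = sz,
        correlation = stats::cor(dv, yv, method = "spearman"))
    }
  }
  tab <- do.call(rbind, rows)
  best <- which.max(tab$correlation)
  list(best_subset = strsplit(tab$subset[best], "+", fixed = TRUE)[[1]],
       correlation = tab$correlation[best], table = tab)
}

#' Drop one of each highly correlated variable pair
#'
#' Pre-filtering rule used before bioenv: for every variable pair with
#' squared correlation at or above `r2`, the later variable in input order is
#' dropped (mirrors dropping sand/silt fractions collinear with clay).
#'
#' @param env samples x variables matrix.
#' @param r2 squared-correlation threshold; default 0.7.
#' @return the filtered matrix, with attribute `dropped`.
#' @export
env_prefilter <- function(env, r2 = 0.7) {
  env <- as.matrix(env)
  keep <- rep(TRUE, ncol(env))
  if (ncol(env) > 1) {
    cc <- suppressWarnings(stats::cor(env))^2
    for (j in 2:ncol(env)) {
      if (any(cc[seq_len(j - 1), j][keep[seq_len(j - 1)]] >= r2, na.rm = TRUE))
        keep[j] <- FALSE
    }
  }
  out <- env[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(env)[!keep]
  out
}

#' Geographic distance matrix from sample metadata
#'
#' Planar Euclidean distances for `xy_m` coordinates; great-circle
#' (haversine) distances in meters for `lonlat` coordinates.
#'
#' @param meta a `sample_metadata` object.
#' @return distance matrix in meters.
#' @export
geo_distance <- function(meta) {
  if (meta$coord_system == "xy_m") {
    m <- as.matrix(stats::dist(meta$coords))
  } else {
    m <- geosphere::distm(meta$coords, fun = geosphere::distHaversine)
    dimnames(m) <- list(meta$samples, meta$samples)
  }
  .as_dm(m, meta$samples)
}

#' Plant-community dissimilarity (Jaccard on presence/absence)
#' @param meta a `sample_metadata` object with plant columns.
#' @return distance matrix.
#' @export
plant_distance <- function(meta) {
  if (!ncol(meta$plants)) stop("no plant presence columns in metadata")
  keep <- rowSums(meta$plants) > 0
  if (!all(keep)) warning("sample(s) with no plants present get NA-free Jaccard via drop: ",
                          paste(meta$samples[!keep], collapse = ", "))
  .as_dm(vegan::vegdist(meta$plants[keep, , drop = FALSE],
                        method = "jaccard", binary = TRUE))
}

#' Driver analysis: distance decay plus MRM with Bonferroni correction
#'
#' Convenience wrapper reproducing one driver-analysis run: a log-log
#' distance-decay Mantel test of community dissimilarity against geographic
#' distance, partial Mantel tests conditioning on the other predictors, and
#' an MRM of the community dissimilarity on geography plus any environmental
#' and plant dissimilarities, with Bonferroni-adjusted p-values across the
#' family of tests in the run.
#'
#' @param community_d community distance matrix.
#' @param geo_d geographic distance matrix (meters).
#' @param env_d optional environmental distance matrix.
#' @param plant_d optional plant-community distance matrix.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @return list with `decay` (mantel_result), `partial` (list), `mrm`
#'   (mrm_result) and a `p_table` with raw and Bonferroni-adjusted p-values.
#' @export
driver_analysis <- function(community_d, geo_d, env_d = NULL, plant_d = NULL,
                            n_perm = 999, seed = 1) {
  decay <- mantel(geo_d, community_d, n_perm = n_perm, seed = seed,
                  loglog_slope = TRUE)
  partial <- list()
  preds <- list(geography = geo_d)
  if (!is.null(env_d)) preds$environment <- env_d
  if (!is.null(plant_d)) preds$vegetation <- plant_d
  if (length(preds) > 1) {
    for (nm in names(preds)) {
      others <- preds[setdiff(names(preds), nm)]
      cond <- Reduce(`+`, others) / length(others)
      partial[[nm]] <- mantel(preds[[nm]], community_d, n_perm = n_perm,
                              seed = seed, conditioning = cond)
    }
  }
  fit <- mrm(community_d, preds, n_perm = n_perm, seed = seed)
  p_raw <- c(decay = decay$p,
             stats::setNames(vapply(partial, `[[`, 0, "p"),
                             paste0("partial_", names(partial))),
             stats::setNames(fit$p_values, paste0("mrm_", names(fit$p_values))))
  p_table <- data.frame(test = names(p_raw), p = unname(p_raw),
                        p_bonferroni = pmin(1, unname(p_raw) * length(p_raw)))
  list(decay = decay, partial = partial, mrm = fit, p_table = p_table)
}
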