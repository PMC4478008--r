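#' Equal-rates Mk transition probability matrix
#'
#' Transition probabilities of the k-state equal-rates ("ER") continuous-time
#' Markov model over a branch of length `t`. The rate matrix Q has all
#' off-diagonal entries equal to `q` and diagonal entries `-(k-1)q`, so the
#' matrix exponential has the closed form
#' \deqn{P_{ii}(t) = 1/k + (k-1)/k \, e^{-kqt}, \qquad
#'       P_{ij}(t) = (1 - e^{-kqt})/k \; (i \ne j).}
#'
#' @param k number of states (integer >= 2).
#' @param q per-ordered-pair transition rate (>= 0), the off-diagonal of Q.
#' @param t branch length, expected substitutions per site (>= 0).
#' @return a `k x k` row-stochastic matrix.
#' @examples
#' er_transition_matrix(2, 0.5, 1)
#' @export
er_transition_matrix <- function(k, q, t) {
  if (!is.finite(k) || k < 2 || k != round(k)) stop("'k' must be an integer >= 2")
  if (!is.finite(q) || q < 0) stop("'q' must be a finite non-negative rate")
  if (!is.finite(t) || t < 0) stop("'t' must be a finite non-negative branch length")
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

#' Construct an equal-rates Mk model
#'
#' @param k number of states.
#' @param q per-pair transition rate.
#' @param prior root prior over the k states; default uniform (the ER
#'   stationary distribution).
#' @return an object of class `er_model`.
#' @export
er_model <- function(k, q, prior = rep(1 / k, k)) {
  if (length(prior) != k) stop("root prior must have length k")
  if (abs(sum(prior) - 1) > 1e-12) stop("root prior must sum to 1")
  if (any(prior < 0)) stop("root prior must be non-negative")
  er_transition_matrix(k, q, 0)  # argument validation
  structure(list(k = as.integer(k), q = q, prior = prior), class = "er_model")
}

#' @export
print.er_model <- function(x, ...) {
  cat(sprintf("Equal-rates Mk model: k = %d states, q = %g per ordered pair\n",
              x$k, x$q))
  invisible(x)
}

## Encode tip states: named integer vector in 1..k, NA for missing (a missing
## tip contributes a vector of ones to the pruning recursion).
.check_states <- function(tree, tip_states, k) {
  if (is.null(names(tip_states))) stop("'tip_states' must be named by tip label")
  unknown <- setdiff(names(tip_states), tree$tip.label)
  if (length(unknown))
    stop("tip_states name(s) not in tree: ", paste(unknown, collapse = ", "))
  st <- rep(NA_integer_, length(tree$tip.label))
  names(st) <- tree$tip.label
  st[names(tip_states)] <- as.integer(tip_states)
  bad <- !is.na(st) & (st < 1L | st > k)
  if (any(bad)) stop("state index out of range 1..k for tip(s): ",
                     paste(names(st)[bad], collapse = ", "))
  if (all(is.na(st))) stop("all tips missing: likelihood is uninformative")
  st
}

## Post-order pruning pass. Returns the (rescaled) partial likelihoods at the
## root and the accumulated log scaling factor. Polytomies and zero-length
## branches (P = I) are handled; per-node rescaling guards against underflow
## on large trees.
.prune <- function(tree, st, k, q) {
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- po$edge
  olen <- po$edge.length
  if (is.null(olen)) olen <- rep(0, nrow(ord))
  L <- matrix(1, M, k)
  for (i in seq_len(n)) if (!is.na(st[i])) {
    L[i, ] <- 0
    L[i, st[i]] <- 1
  }
  logsc <- numeric(M)
  for (r in seq_len(nrow(ord))) {
    pa <- ord[r, 1]; ch <- ord[r, 2]
    P <- er_transition_matrix(k, q, olen[r])
    v <- as.vector(P %*% L[ch, ])
    w <- L[pa, ] * v
    s <- sum(w)
    if (s <= 0) {
      # impossible configuration under q = 0 on some branch
      return(list(root = rep(0, k), logsc = -Inf, rootnode = n + 1L))
    }
    L[pa, ] <- w / s
    logsc[pa] <- logsc[pa] + log(s) + logsc[ch]
  }
  list(root = L[n + 1L, ], logsc = logsc[n + 1L], rootnode = n + 1L)
}

#' Pruning log-likelihood of tip states under an ER Mk model
#'
#' Felsenstein's post-order pruning algorithm:
#' `log( sum_s prior(s) L_root(s) )`, where partial likelihoods are propagated
#' tipward-to-rootward with the closed-form ER transition matrices. Missing
#' tips contribute a vector of ones (they are marginalised out).
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param tip_states named integer vector of states in `1..k`; `NA` (or
#'   omitted tips) are treated as missing.
#' @param model an [er_model()].
#' @return the log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(tree, tip_states, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "er_model"))
  st <- .check_states(tree, tip_states, model$k)
  pr <- .prune(tree, st, model$k, model$q)
  val <- sum(model$prior * pr$root)
  if (val <= 0 || !is.finite(pr$logsc)) return(-Inf)
  log(val) + pr$logsc
}

#' Marginal root-state probabilities
#'
#' Posterior probability of each state at the root given the observed tip
#' states: proportional to `prior(s) * L_root(s)`, normalised to sum to 1.
#'
#' @inheritParams tree_log_likelihood
#' @return a probability vector of length `k`.
#' @export
marginal_root_probabilities <- function(tree, tip_states, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "er_model"))
  st <- .check_states(tree, tip_states, model$k)
  pr <- .prune(tree, st, model$k, model$q)
  w <- model$prior * pr$root
  s <- sum(w)
  if (s <= 0) stop("zero likelihood: tip states impossible under this model")
  w / s
}

#' Maximum-likelihood estimate of the ER transition rate
#'
#' One-dimensional bounded maximisation of the pruning log-likelihood over the
#' rate `q` (deterministic golden-section/parabolic search, tolerance 1e-8).
#' The bound endpoints are evaluated explicitly, so monotone likelihoods land
#' exactly on a bound and are flagged.
#'
#' @inheritParams tree_log_likelihood
#' @param k number of states.
#' @param bounds search interval for `q`; default `c(1e-8, 100)`.
#' @param prior root prior (default uniform).
#' @return an object of class `er_fit` with elements `q_hat`, `log_likelihood`,
#'   `converged` and `at_bound`.
#' @export
fit_er_rate <- function(tree, tip_states, k, bounds = c(1e-8, 100),
                        prior = rep(1 / k, k)) {
  stopifnot(inherits(tree, "phylo"))
  if (length(bounds) != 2 || bounds[1] < 0 || bounds[2] <= bounds[1])
    stop("'bounds' must be an increasing non-negative pair")
  st <- .check_states(tree, tip_states, k)
  if (sum(!is.na(st)) < 2) stop("need >= 2 tips with observed states")
  f <- function(q) tree_log_likelihood(tree, st, er_model(k, q, prior))
  opt <- stats::optimize(f, interval = bounds, maximum = TRUE, tol = 1e-8)
  cand <- c(bounds, opt$maximum)
  ll <- c(f(bounds[1]), f(bounds[2]), opt$objective)
  # prefer an exact endpoint when the likelihood there ties the interior
  # optimum (monotone likelihoods converge to a bound)
  best <- which(ll >= max(ll) - 1e-10)[1]
  q_hat <- cand[best]
  at_bound <- min(abs(q_hat - bounds)) < 1e-6
  structure(list(q_hat = q_hat, log_likelihood = ll[best],
                 converged = is.finite(ll[best]), at_bound = at_bound,
                 k = as.integer(k), bounds = bounds),
            class = "er_fit")
}

#' @export
print.er_fit <- function(x, ...) {
  cat(sprintf("ML equal-rates Mk fit: q_hat = %.6g (logL = %.4f, k = %d)%s\n",
              x$q_hat, x$log_likelihood, x$k,
              if (x$at_bound) " [at search bound]" else ""))
  invisible(x)
}
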