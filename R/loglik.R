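# Likelihood of a tree + tip states under the compound-state model.

# Build the S x n_tip matrix of tip initial conditions D = rho * 1[compatible].
tip_D_matrix <- function(tree, tips, n_states, sampling_fraction) {
  n_tip <- length(tree$tip.label)
  D <- matrix(0, n_states, n_tip)
  missing <- setdiff(tree$tip.label, names(tips))
  if (length(missing))
    stop("tip data missing for: ", paste(missing, collapse = ", "))
  for (t in seq_len(n_tip)) {
    idx <- tips[[tree$tip.label[t]]]
    if (length(idx) == 0L || anyNA(idx) || any(idx < 1L) || any(idx > n_states))
      stop("invalid state set for tip ", tree$tip.label[t])
    D[idx, t] <- sampling_fraction
  }
  D
}

check_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be nonnegative")
  if (!ape::is.binary(tree)) stop("tree must be strictly binary")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}

# Postorder pruning pass; returns all partials needed for stochastic mapping.
classe_pruning <- function(tree, tips, gen, sampling_fraction = 1,
                           rtol = 1e-8, atol = 1e-10) {
  check_tree(tree)
  S <- gen$n_states
  tipD <- tip_D_matrix(tree, tips, S, sampling_fraction)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  e0 <- rep(1 - sampling_fraction, S)
  pr <- cpp_tree_prune(tree_po$edge, tree_po$edge.length,
                       length(tree$tip.label), tipD, e0,
                       gen$Q, gen$clad$parent, gen$clad$left, gen$clad$right,
                       gen$clad$rate, gen$mu, rtol, atol)
  pr$edge <- tree_po$edge
  pr$edge.length <- tree_po$edge.length
  pr$n_tip <- length(tree$tip.label)
  pr$root <- length(tree$tip.label) + 1L
  pr
}

# conditioning factor: probability that a lineage in state i speciates and
# both daughters survive to be sampled
survival_condition <- function(gen, E_root) {
  cond <- numeric(gen$n_states)
  cl <- gen$clad
  for (c in seq_len(nrow(cl))) {
    i <- cl$parent[c]; j <- cl$left[c]; k <- cl$right[c]
    mult <- if (j == k) 1 else 2
    cond[i] <- cond[i] + cl$rate[c] * mult * (1 - E_root[j]) * (1 - E_root[k])
  }
  cond
}

#' Log-likelihood under the compound-state ClaSSE model
#'
#' Integrates the coupled extinction/likelihood ODE system tip-to-root along
#' every branch, combines daughters through the cladogenetic tensor at nodes,
#' and applies the chosen root treatment.  Incomplete sampling enters through
#' the tip conditions `D = sampling_fraction` on compatible states and
#' `E(0) = 1 - sampling_fraction`; unobserved speciation and extinction are
#' accounted for by the extinction trajectory `E(t)`.
#'
#' @param tree a rooted, binary, time-calibrated `phylo` (branch lengths Ma).
#' @param tips named list mapping each tip label to the integer state indices
#'   compatible with it (singleton when fully observed).
#' @param gen a [generator_set()].
#' @param sampling_fraction probability that an extant species is sampled;
#'   defaults to the value carried by `gen$params` if present, else 1.
#' @param condition_on_survival condition the likelihood on the root lineage
#'   speciating and both daughter clades surviving (default `TRUE`).
#' @param root one of `"fitzjohn"` (likelihood-proportional state weights, the
#'   default), `"flat"` (uniform weights), or `"fixed"` (weights supplied in
#'   `root_weights`).
#' @param root_weights numeric vector of state weights when `root = "fixed"`.
#' @param rtol,atol relative/absolute ODE tolerances.
#' @return the log-likelihood (finite scalar).
#' @export
classe_loglik <- function(tree, tips, gen, sampling_fraction = NULL,
                          condition_on_survival = TRUE,
                          root = c("fitzjohn", "flat", "fixed"),
                          root_weights = NULL, rtol = 1e-8, atol = 1e-10) {
  root <- match.arg(root)
  if (is.null(sampling_fraction))
    sampling_fraction <- if (!is.null(gen$params)) gen$params$sampling_fraction else 1
  pr <- classe_pruning(tree, tips, gen, sampling_fraction, rtol, atol)
  D <- pr$nodeD[, pr$root]
  E <- pr$nodeE[, pr$root]
  lg <- pr$nodeLog[pr$root]
  if (all(D <= 0)) stop("all root partial likelihoods are zero")
  w <- switch(root,
    fitzjohn = D / sum(D),
    flat = rep(1 / gen$n_states, gen$n_states),
    fixed = {
      if (is.null(root_weights) || length(root_weights) != gen$n_states)
        stop("root_weights must have one entry per state")
      root_weights / sum(root_weights)
    })
  terms <- w * D
  if (condition_on_survival) {
    cond <- survival_condition(gen, E)
    ok <- terms > 0
    if (any(cond[ok] <= 0)) stop("survival conditioning factor is zero")
    terms[ok] <- terms[ok] / cond[ok]
  }
  ll <- log(sum(terms)) + lg
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

#' Marginal root-state weights used by the likelihood
#'
#' Returns the likelihood-proportional (FitzJohn-style) root-state
#' distribution, which is also the marginal conditional distribution the
#' stochastic mapper draws the root state from.
#'
#' @inheritParams classe_loglik
#' @return numeric vector of probabilities over states.
#' @export
root_state_weights <- function(tree, tips, gen, sampling_fraction = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  if (is.null(sampling_fraction))
    sampling_fraction <- if (!is.null(gen$params)) gen$params$sampling_fraction else 1
  pr <- classe_pruning(tree, tips, gen, sampling_fraction, rtol, atol)
  D <- pr$nodeD[, pr$root]
  D / sum(D)
}
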