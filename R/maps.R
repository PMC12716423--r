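# Stochastic character mapping: joint history replicates conditional on the
# tree, the tip states and the model.
#
# Node states are drawn root-to-tip from their joint conditional distribution
# using the stored per-branch partials of the likelihood pass; each branch is
# then filled by rejection sampling of the anagenetic process augmented with
# hidden-cladogenesis transitions (a speciation whose other daughter leaves no
# sampled descendants, at rate lambda_{i,jk} * E_k(t)), with paths rejected if
# they die or miss the branch-end state.

#' Extinction probabilities E_i(t) on an age grid
#'
#' @param gen a [generator_set()].
#' @param ages nondecreasing ages (Ma) starting near 0.
#' @param sampling_fraction tip sampling probability.
#' @param rtol,atol ODE tolerances.
#' @return matrix (state x age) of extinction probabilities.
#' @export
extinction_grid <- function(gen, ages, sampling_fraction = 1,
                            rtol = 1e-8, atol = 1e-10) {
  e0 <- rep(1 - sampling_fraction, gen$n_states)
  cpp_E_grid(ages, e0, gen$Q, gen$clad$parent, gen$clad$left, gen$clad$right,
             gen$clad$rate, gen$mu, rtol, atol)
}

# linear interpolation of an extinction grid at age a
e_lookup <- function(Egrid, ages, a) {
  n <- length(ages)
  if (a <= ages[1]) return(Egrid[, 1])
  if (a >= ages[n]) return(Egrid[, n])
  i <- findInterval(a, ages)
  w <- (a - ages[i]) / (ages[i + 1] - ages[i])
  Egrid[, i] * (1 - w) + Egrid[, i + 1] * w
}

clad_event_class <- function(space, parent, d1, d2) {
  if (is.null(space)) return(NA_character_)
  st <- space$states
  if (st$range_mask[d1] != st$range_mask[parent] &&
      st$range_mask[d2] != st$range_mask[parent] &&
      bitwOr(st$range_mask[d1], st$range_mask[d2]) == st$range_mask[parent])
    "BETWEEN_REGION" else "WITHIN_REGION"
}

#' Sample one augmented history along a single branch
#'
#' Simulates the anagenetic process plus hidden speciations from `start_age`
#' down to `end_age`, starting in `start_state`, by thinning against the
#' constant bound `q_total + 2*lambda_total + mu`.  A path is rejected if the
#' lineage dies, or (when `end_weights` is given) with probability
#' `1 - end_weights[end]/max(end_weights)` at the branch end, which conditions
#' the endpoint on the subtended data.
#'
#' @param gen a [generator_set()].
#' @param start_state state index at the rootward end.
#' @param start_age,end_age branch interval, `start_age > end_age`, Ma.
#' @param Egrid,ages extinction grid from [extinction_grid()] and its ages.
#' @param end_weights optional nonnegative endpoint weights over states.
#' @param max_attempts rejection-sampling cap; at the default 10000 attempts
#'   the acceptance floor is 1e-4 per branch, below which an error advises
#'   reviewing parameters or tolerances.
#' @return list with `end_state`, `events` (oldest first), and `attempts`.
#' @export
sample_branch_history <- function(gen, start_state, start_age, end_age,
                                  Egrid, ages, end_weights = NULL,
                                  max_attempts = 10000L) {
  if (start_age < end_age) stop("start_age must not be younger than end_age")
  space <- gen$space
  clad <- gen$clad
  wmax <- if (!is.null(end_weights)) max(end_weights) else 1
  if (!is.null(end_weights) && wmax <= 0)
    stop("end_weights must contain a positive entry")
  for (attempt in seq_len(max_attempts)) {
    a <- start_age
    s <- start_state
    events <- list()
    failed <- FALSE
    repeat {
      B <- gen$q_total[s] + 2 * gen$lambda_total[s] + gen$mu[s]
      a_next <- if (B > 0) a - stats::rexp(1, B) else -Inf
      if (a_next <= end_age) break
      E <- e_lookup(Egrid, ages, a_next)
      rows <- which(clad$parent == s)
      # hidden-speciation candidates: continue as one daughter, the sibling
      # (weighted by its extinction probability) leaves no descendants
      h_to <- c(clad$left[rows], clad$right[rows])
      h_sib <- c(clad$right[rows], clad$left[rows])
      h_rate <- c(clad$rate[rows] * E[clad$right[rows]],
                  clad$rate[rows] * E[clad$left[rows]])
      total <- gen$q_total[s] + sum(h_rate) + gen$mu[s]
      if (stats::runif(1) * B > total) { a <- a_next; next }  # phantom event
      u <- stats::runif(1) * total
      if (u < gen$mu[s]) { failed <- TRUE; break }            # unobservable death
      if (u < gen$mu[s] + gen$q_total[s]) {
        to <- sample.int(gen$n_states, 1L, prob = gen$Q[s, ])
        events[[length(events) + 1L]] <-
          new_event(a_next, "ANAGENETIC",
                    if (!is.null(space)) move_class_between(space, s, to)
                    else NA_character_, s, to)
        s <- to
      } else {
        k <- if (length(h_rate) == 1L) 1L
             else sample.int(length(h_rate), 1L, prob = h_rate)
        events[[length(events) + 1L]] <-
          new_event(a_next, "CLADOGENETIC_HIDDEN",
                    clad_event_class(space, s, h_to[k], h_sib[k]),
                    s, h_to[k], sibling_state = h_sib[k])
        s <- h_to[k]
      }
      a <- a_next
    }
    if (failed) next
    if (!is.null(end_weights)) {
      if (end_weights[s] <= 0) next
      if (stats::runif(1) > end_weights[s] / wmax) next
    }
    return(list(end_state = s, events = events, attempts = attempt))
  }
  stop("branch rejection sampling fell below the acceptance floor (",
       max_attempts, " attempts); review model parameters or the ",
       "branch's endpoint constraints")
}

#' Draw replicate joint histories by stochastic mapping
#'
#' @param tree rooted binary ultrametric `phylo` (branch lengths in Ma).
#' @param tips named list mapping tip labels to compatible state indices.
#' @param gen a [generator_set()] (its `space`, when present, enriches event
#'   records with move classes).
#' @param n_maps number of replicate histories.
#' @param seed optional integer; map `m` is drawn under `seed + m`, so any
#'   single replicate can be regenerated independently.
#' @param sampling_fraction tip sampling probability (defaults to
#'   `gen$params`).
#' @param grid_points_per_ma resolution of the extinction-probability grid
#'   used for the time-inhomogeneous hidden-speciation rates (default 100
#'   points per Ma).
#' @param max_attempts per-branch rejection cap (see
#'   [sample_branch_history()]).
#' @param rtol,atol ODE tolerances for the likelihood pass.
#' @return list of [mapped_history()] objects; branch indices follow the
#'   tree's edge matrix (cladewise order), node ids follow ape numbering, and
#'   each internal branch ends with the `CLADOGENETIC_NODE` event of its child
#'   node (the root's own event is stored as `root_event`).
#' @export
stochastic_maps <- function(tree, tips, gen, n_maps = 1L, seed = NULL,
                            sampling_fraction = NULL, grid_points_per_ma = 100,
                            max_attempts = 10000L, rtol = 1e-8, atol = 1e-10) {
  if (is.null(sampling_fraction))
    sampling_fraction <- if (!is.null(gen$params)) gen$params$sampling_fraction else 1
  pr <- classe_pruning(tree, tips, gen, sampling_fraction, rtol, atol)
  S <- gen$n_states
  n_tip <- pr$n_tip
  root <- pr$root
  depths <- ape::node.depth.edgelength(tree)
  root_age <- max(depths)
  node_age <- pmax(root_age - depths, 0)
  grid_ages <- seq(0, root_age, length.out = max(51, ceiling(grid_points_per_ma * root_age) + 1))
  Egrid <- extinction_grid(gen, grid_ages, sampling_fraction, rtol, atol)

  # per-node child edges (postorder indexing), and postorder -> cladewise map
  edge_po <- pr$edge
  child_edges <- vector("list", n_tip + tree$Nnode)
  for (e in seq_len(nrow(edge_po)))
    child_edges[[edge_po[e, 1]]] <- c(child_edges[[edge_po[e, 1]]], e)
  orig_index <- match(paste(edge_po[, 1], edge_po[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))
  tipD <- tip_D_matrix(tree, tips, S, sampling_fraction)
  root_w <- pr$nodeD[, root] / sum(pr$nodeD[, root])
  clad <- gen$clad

  sample_node_outcome <- function(state, eL, eR) {
    rows <- which(clad$parent == state)
    if (!length(rows)) stop("node in a state with no cladogenetic outcome")
    wLR <- clad$rate[rows] * pr$topD[clad$left[rows], eL] * pr$topD[clad$right[rows], eR]
    wRL <- clad$rate[rows] * pr$topD[clad$right[rows], eL] * pr$topD[clad$left[rows], eR]
    w <- c(wLR, wRL)
    if (sum(w) <= 0) stop("zero-probability node outcome; inconsistent partials")
    k <- sample.int(length(w), 1L, prob = w)
    if (k <= length(rows)) c(clad$left[rows[k]], clad$right[rows[k]])
    else c(clad$right[rows[k - length(rows)]], clad$left[rows[k - length(rows)]])
  }

  draw_one <- function() {
    branches <- vector("list", nrow(edge_po))
    root_state <- sample.int(S, 1L, prob = root_w)
    eL <- child_edges[[root]][1]; eR <- child_edges[[root]][2]
    d <- sample_node_outcome(root_state, eL, eR)
    root_event <- new_event(root_age, "CLADOGENETIC_NODE",
                            clad_event_class(gen$space, root_state, d[1], d[2]),
                            root_state, d)
    stack <- list(list(edge = eL, state = d[1]), list(edge = eR, state = d[2]))
    while (length(stack)) {
      item <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      e <- item$edge
      child <- edge_po[e, 2]
      parent <- edge_po[e, 1]
      a_top <- node_age[parent]; a_bot <- node_age[child]
      is_tip <- child <= n_tip
      end_w <- if (is_tip) tipD[, child] else pr$nodeD[, child]
      fill <- sample_branch_history(gen, item$state, a_top, a_bot, Egrid,
                                    grid_ages, end_w, max_attempts)
      events <- fill$events
      if (!is_tip) {
        cl <- child_edges[[child]]
        dd <- sample_node_outcome(fill$end_state, cl[1], cl[2])
        events[[length(events) + 1L]] <-
          new_event(a_bot, "CLADOGENETIC_NODE",
                    clad_event_class(gen$space, fill$end_state, dd[1], dd[2]),
                    fill$end_state, dd)
        stack[[length(stack) + 1L]] <- list(edge = cl[1], state = dd[1])
        stack[[length(stack) + 1L]] <- list(edge = cl[2], state = dd[2])
      }
      branches[[e]] <- list(branch_index = orig_index[e],
                            parent_node = parent, child_node = child,
                            start_age = a_top, end_age = a_bot,
                            start_state = as.integer(item$state),
                            end_state = as.integer(fill$end_state),
                            events = events)
    }
    branches <- branches[order(vapply(branches, `[[`, integer(1), "branch_index"))]
    mapped_history(branches, root_state = root_state, root_age = root_age,
                   root_event = root_event, space = gen$space)
  }

  lapply(seq_len(n_maps), function(m) {
    if (!is.null(seed)) set.seed(as.integer(seed) + m)
    draw_one()
  })
}
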