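# Independent oracles, deliberately written against different machinery than
# the package: a fixed-step classical Runge-Kutta integrator in pure R for the
# likelihood system, a matrix-exponential pruning pass for pure character
# evolution, a uniformization series for conditioned CTMC event counts, and
# exhaustive path enumeration for least-cost distances and connectivity.

oracle_deriv <- function(y, Q, clad, mu) {
  S <- length(mu)
  E <- y[1:S]; D <- y[S + 1:S]
  lam <- numeric(S)
  for (r in seq_len(nrow(clad)))
    lam[clad$parent[r]] <- lam[clad$parent[r]] + clad$rate[r]
  tot <- lam + rowSums(Q) + mu
  dE <- mu - tot * E + as.numeric(Q %*% E)
  dD <- -tot * D + as.numeric(Q %*% D)
  for (r in seq_len(nrow(clad))) {
    i <- clad$parent[r]; j <- clad$left[r]; k <- clad$right[r]; rt <- clad$rate[r]
    dE[i] <- dE[i] + rt * E[j] * E[k]
    dD[i] <- dD[i] + rt * (D[j] * E[k] + D[k] * E[j])
  }
  c(dE, dD)
}

oracle_branch <- function(y, len, Q, clad, mu, nstep = 2000) {
  h <- len / nstep
  for (s in seq_len(nstep)) {
    k1 <- oracle_deriv(y, Q, clad, mu)
    k2 <- oracle_deriv(y + h / 2 * k1, Q, clad, mu)
    k3 <- oracle_deriv(y + h / 2 * k2, Q, clad, mu)
    k4 <- oracle_deriv(y + h * k3, Q, clad, mu)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# brute-force tree likelihood: postorder over ape edges, no rescaling
oracle_loglik <- function(tree, tipstates, gen, rho = 1,
                          root = c("fitzjohn", "flat"), condition = FALSE,
                          nstep = 2000) {
  root <- match.arg(root)
  Q <- gen$Q; clad <- gen$clad; mu <- gen$mu
  S <- length(mu)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  EE <- matrix(0, S, nn); DD <- matrix(0, S, nn)
  for (t in seq_len(ntip)) {
    EE[, t] <- 1 - rho
    DD[tipstates[[tree$tip.label[t]]], t] <- rho
  }
  first_edge <- integer(nn)
  tops <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]; pa <- tree$edge[e, 1]
    tops[[e]] <- oracle_branch(c(EE[, ch], DD[, ch]), tree$edge.length[e],
                               Q, clad, mu, nstep)
    if (first_edge[pa] == 0L) {
      first_edge[pa] <- e
    } else {
      yL <- tops[[first_edge[pa]]]; yR <- tops[[e]]
      Dn <- numeric(S)
      for (r in seq_len(nrow(clad))) {
        i <- clad$parent[r]; j <- clad$left[r]; k <- clad$right[r]; rt <- clad$rate[r]
        Dn[i] <- Dn[i] + if (j == k) rt * yL[S + j] * yR[S + j]
                 else rt * (yL[S + j] * yR[S + k] + yL[S + k] * yR[S + j])
      }
      EE[, pa] <- yL[1:S]
      DD[, pa] <- Dn
    }
  }
  D <- DD[, ntip + 1]; E <- EE[, ntip + 1]
  w <- if (root == "fitzjohn") D / sum(D) else rep(1 / S, S)
  terms <- w * D
  if (condition) {
    cond <- numeric(S)
    for (r in seq_len(nrow(clad))) {
      i <- clad$parent[r]; j <- clad$left[r]; k <- clad$right[r]
      cond[i] <- cond[i] + clad$rate[r] * (if (j == k) 1 else 2) *
        (1 - E[j]) * (1 - E[k])
    }
    terms[terms > 0] <- terms[terms > 0] / cond[terms > 0]
  }
  log(sum(terms))
}

# CTMC character log-likelihood by matrix-exponential pruning (flat root)
oracle_ctmc_loglik <- function(tree, tipstates, Q) {
  S <- nrow(Q)
  Qg <- Q; diag(Qg) <- -rowSums(Q)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  L <- matrix(0, S, nn)
  for (t in seq_len(ntip)) L[tipstates[[tree$tip.label[t]]], t] <- 1
  first <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]; pa <- tree$edge[e, 1]
    P <- as.matrix(Matrix::expm(Qg * tree$edge.length[e]))
    v <- as.numeric(P %*% L[, ch])
    if (is.null(first[[pa]])) first[[pa]] <- v else L[, pa] <- first[[pa]] * v
  }
  log(sum(L[, ntip + 1] / S))
}

# E[#changes | X_0 = X_T = same state] for the symmetric 2-state CTMC with
# rate q, by the uniformization series (every virtual jump is a real flip)
oracle_conditioned_changes <- function(q, Tlen, nmax = 400) {
  n <- 0:nmax
  pn <- stats::dpois(n, q * Tlen)
  even <- n %% 2 == 0
  sum(n[even] * pn[even]) / sum(pn[even])
}

# exhaustive least-cost distance between two pixel sets on a tiny lattice:
# enumerates all simple paths (grids of <= ~12 passable pixels)
oracle_lcp <- function(resistance, from_pixels, to_pixels, neighborhood = 8) {
  nr <- nrow(resistance); nc <- ncol(resistance)
  pass <- which(is.finite(resistance))
  stopifnot(length(pass) <= 14)
  idx_rc <- cbind((pass - 1) %% nr + 1, (pass - 1) %/% nr + 1)
  nbr <- function(a, b) {
    dr <- abs(idx_rc[a, 1] - idx_rc[b, 1]); dc <- abs(idx_rc[a, 2] - idx_rc[b, 2])
    if (neighborhood == 4) (dr + dc) == 1 else max(dr, dc) == 1
  }
  step_cost <- function(a, b) {
    len <- sqrt((idx_rc[a, 1] - idx_rc[b, 1])^2 + (idx_rc[a, 2] - idx_rc[b, 2])^2)
    (resistance[pass[a]] + resistance[pass[b]]) / 2 * len
  }
  from <- which(pass %in% from_pixels)
  to <- which(pass %in% to_pixels)
  best <- Inf
  dfs <- function(node, visited, cost) {
    if (cost >= best) return()
    if (node %in% to) { best <<- min(best, cost); return() }
    for (m in seq_along(pass)) {
      if (!visited[m] && nbr(node, m)) {
        visited[m] <- TRUE
        dfs(m, visited, cost + step_cost(node, m))
        visited[m] <- FALSE
      }
    }
  }
  for (f in from) {
    visited <- logical(length(pass)); visited[f] <- TRUE
    dfs(f, visited, 0)
  }
  best
}

# maximum path product over a small patch network by path enumeration
oracle_pstar <- function(edges, n_nodes, k) {
  p <- matrix(0, n_nodes, n_nodes); diag(p) <- 1
  adj <- vector("list", n_nodes)
  if (nrow(edges))
    for (e in seq_len(nrow(edges))) {
      adj[[edges$from[e]]] <- rbind(adj[[edges$from[e]]], c(edges$to[e], edges$cost[e]))
      adj[[edges$to[e]]] <- rbind(adj[[edges$to[e]]], c(edges$from[e], edges$cost[e]))
    }
  for (s in seq_len(n_nodes)) {
    dfs <- function(node, visited, prob) {
      p[s, node] <<- max(p[s, node], prob)
      if (!is.null(adj[[node]]))
        for (r in seq_len(nrow(adj[[node]]))) {
          nxt <- adj[[node]][r, 1]
          if (!visited[nxt]) {
            visited[nxt] <- TRUE
            dfs(nxt, visited, prob * exp(-k * adj[[node]][r, 2]))
            visited[nxt] <- FALSE
          }
        }
    }
    visited <- logical(n_nodes); visited[s] <- TRUE
    dfs(s, visited, 1)
  }
  p
}

# event counts aggregated by region x process (weighted for colonization)
tally_counts <- function(events) {
  if (!nrow(events))
    return(data.frame(region = character(0), process = character(0),
                      weight = numeric(0)))
  agg <- stats::aggregate(weight ~ region + process, events, sum)
  agg[order(agg$region, agg$process), ]
}
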