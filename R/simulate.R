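# Forward (Gillespie) simulation of a clade under the compound-state model.

# classify a single anagenetic move by comparing states
move_class_between <- function(space, from, to) {
  st <- space$states
  if (st$range_mask[from] != st$range_mask[to]) {
    if (st$range_size[to] > st$range_size[from]) "RANGE_EXPANSION" else "RANGE_CONTRACTION"
  } else "BIOME_SHIFT"
}

new_event <- function(age, kind, move_class, from_state, to_states,
                      sibling_state = NULL) {
  ev <- list(age = age, kind = kind, move_class = move_class,
             from_state = as.integer(from_state),
             to_states = as.integer(to_states),
             state_changed = any(to_states != from_state))
  if (!is.null(sibling_state)) ev$sibling_state <- as.integer(sibling_state)
  ev
}

# event-table row(s) for the simulator's own assembly tally; independent of
# classify_events(), which re-derives the same processes from the history
tally_clado <- function(space, age, parent, d1, d2) {
  st <- space$states
  n <- length(space$regions$labels)
  rows <- list()
  alp <- function(s, r) {
    biome_is_alpine(st$biome[s]) && r %in% mask_bits(st$range_mask[s], n)
  }
  for (r in mask_bits(bitwOr(st$range_mask[d1], st$range_mask[d2]), n)) {
    delta <- alp(d1, r) + alp(d2, r) - alp(parent, r)
    if (delta != 1L) next
    endemic_alpine <- st$range_mask[parent] == bits_mask(r) && st$biome[parent] == 2L
    rows[[length(rows) + 1L]] <- data.frame(
      age = age, region = space$regions$labels[r],
      process = if (endemic_alpine) "IN_SITU_SPECIATION" else "SUBSET_SPECIATION",
      source = NA_character_, weight = 1, stringsAsFactors = FALSE)
  }
  rows
}

tally_anagenetic <- function(space, age, from, to) {
  st <- space$states
  n <- length(space$regions$labels)
  labels <- space$regions$labels
  rows <- list()
  add <- function(region, process, source = NA_character_, weight = 1)
    rows[[length(rows) + 1L]] <<- data.frame(age = age, region = region,
                                             process = process, source = source,
                                             weight = weight,
                                             stringsAsFactors = FALSE)
  mf <- st$range_mask[from]; mt <- st$range_mask[to]
  bf <- st$biome[from]; bt <- st$biome[to]
  if (mf != mt) {
    if (st$range_size[to] > st$range_size[from]) {
      if (biome_is_alpine(bt)) {
        gained <- labels[mask_bits(bitwAnd(mt, bitwNot(mf)), n)]
        src <- labels[mask_bits(mf, n)]
        for (s in src) add(gained, "COLONIZATION", s, 1 / length(src))
      }
    } else {
      if (biome_is_alpine(bf))
        add(labels[mask_bits(bitwAnd(mf, bitwNot(mt)), n)], "LOCAL_EXTINCTION")
    }
  } else if (bf == 1L && bt == 3L) {
    for (r in labels[mask_bits(mf, n)]) add(r, "NICHE_EXPANSION")
  } else if (bf == 3L && bt == 1L) {
    for (r in labels[mask_bits(mf, n)]) add(r, "NICHE_CONTRACTION")
  }
  rows
}

tally_death <- function(space, age, state) {
  st <- space$states
  n <- length(space$regions$labels)
  if (!biome_is_alpine(st$biome[state])) return(list())
  lapply(space$regions$labels[mask_bits(st$range_mask[state], n)], function(r)
    data.frame(age = age, region = r, process = "LOCAL_EXTINCTION",
               source = NA_character_, weight = 1, stringsAsFactors = FALSE))
}

#' Simulate a clade forward in time under the compound-state model
#'
#' Runs a Gillespie simulation from a single root lineage at age `max_age`
#' down to the present: each lineage carries competing exponential clocks for
#' every anagenetic move in `Q`, every cladogenetic outcome in `Lambda`, and
#' lineage extinction `mu`.  The returned tree is pruned of extinct lineages;
#' the full history (all lineages, extinct included, with every typed and
#' timed event) is retained in the mapped history, together with the
#' simulator's own assembly-event tally.
#'
#' @param gen a [generator_set()] built over a `state_space`.
#' @param root_state integer index of the root lineage's state.
#' @param max_age crown age of the simulation, in Ma.
#' @param seed optional integer seed for reproducibility.
#' @param max_lineages guard against runaway growth (default 20000).
#' @param min_survivors if the number of extant lineages at the present is
#'   below this (default 1), the simulation signals a condition of class
#'   `"alpassembly_extinct"` rather than returning silently.
#' @return a list with `tree` (pruned extant `phylo`, `NULL` if fewer than two
#'   survivors), `tips` (named list tip -> state index), `history` (a
#'   [mapped_history()] over the complete tree), `tally` (the simulator's
#'   assembly-event table), and `n_extant`.
#' @export
simulate_clade <- function(gen, root_state, max_age, seed = NULL,
                           max_lineages = 20000L, min_survivors = 1L) {
  space <- gen$space
  if (is.null(space)) stop("generator set must carry its state space")
  if (!is.null(seed)) set.seed(seed)
  if (max_age <= 0) stop("max_age must be positive")
  if (root_state < 1L || root_state > gen$n_states) stop("root_state not in space")

  S <- gen$n_states
  total_rate <- gen$q_total + gen$lambda_total + gen$mu
  clad_by_parent <- split(seq_len(nrow(gen$clad)), gen$clad$parent)

  lineages <- list()   # each: parent, start_age, start_state plus fate fields
  tally <- list()
  # stack of lineages waiting to be simulated: (id)
  lineages[[1L]] <- list(id = 1L, parent = 0L, start_age = max_age,
                         start_state = as.integer(root_state))
  stack <- 1L
  next_id <- 2L
  while (length(stack)) {
    id <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ln <- lineages[[id]]
    age <- ln$start_age
    s <- ln$start_state
    events <- list()
    repeat {
      rt <- total_rate[s]
      age_next <- if (rt > 0) age - stats::rexp(1, rt) else -Inf
      if (age_next <= 0) {
        lineages[[id]] <- c(ln, list(end_age = 0, end_state = s, fate = "extant",
                                     events = events))
        break
      }
      u <- stats::runif(1) * rt
      if (u < gen$q_total[s]) {
        to <- sample.int(S, 1L, prob = gen$Q[s, ])
        events[[length(events) + 1L]] <-
          new_event(age_next, "ANAGENETIC", move_class_between(space, s, to), s, to)
        tally <- c(tally, tally_anagenetic(space, age_next, s, to))
        s <- to
        age <- age_next
      } else if (u < gen$q_total[s] + gen$lambda_total[s]) {
        rows <- clad_by_parent[[as.character(s)]]
        row <- rows[sample.int(length(rows), 1L, prob = gen$clad$rate[rows])]
        d <- c(gen$clad$left[row], gen$clad$right[row])
        if (stats::runif(1) < 0.5) d <- rev(d)
        events[[length(events) + 1L]] <-
          new_event(age_next, "CLADOGENETIC_NODE", NA_character_, s, d)
        tally <- c(tally, tally_clado(space, age_next, s, d[1], d[2]))
        lineages[[id]] <- c(ln, list(end_age = age_next, end_state = s,
                                     fate = "speciation", events = events))
        if (next_id + 1L > max_lineages)
          stop("simulation exceeded max_lineages; lower rates or max_age")
        for (k in 1:2) {
          lineages[[next_id]] <- list(id = next_id, parent = id,
                                      start_age = age_next, start_state = d[k])
          stack <- c(stack, next_id)
          next_id <- next_id + 1L
        }
        break
      } else {
        tally <- c(tally, tally_death(space, age_next, s))
        lineages[[id]] <- c(ln, list(end_age = age_next, end_state = s,
                                     fate = "extinct", events = events))
        break
      }
    }
  }

  tally <- if (length(tally)) {
    tb <- do.call(rbind, tally)
    rownames(tb) <- NULL
    tb[order(-tb$age, tb$region, tb$process), , drop = FALSE]
  } else data.frame(age = numeric(0), region = character(0),
                    process = character(0), source = character(0),
                    weight = numeric(0))

  extant <- vapply(lineages, function(l) l$fate == "extant", logical(1))
  n_extant <- sum(extant)
  if (n_extant < min_survivors) {
    cond <- structure(class = c("alpassembly_extinct", "error", "condition"),
                      list(message = sprintf(
                        "clade extinct before the present (%d survivors)", n_extant),
                        call = sys.call()))
    stop(cond)
  }

  history <- history_from_lineages(lineages, space, max_age)
  tip_states <- lapply(lineages[extant], function(l) l$end_state)
  names(tip_states) <- paste0("t", vapply(lineages[extant], function(l) l$id, integer(1)))
  tree <- prune_extant_tree(lineages)
  list(tree = tree, tips = tip_states, history = history, tally = tally,
       n_extant = n_extant)
}

# full-history container from the simulator's lineage records
history_from_lineages <- function(lineages, space, max_age) {
  branches <- lapply(lineages, function(l) {
    list(branch_index = l$id, parent_node = l$parent, child_node = l$id,
         start_age = l$start_age, end_age = l$end_age,
         start_state = as.integer(l$start_state),
         end_state = as.integer(l$end_state),
         extinct = identical(l$fate, "extinct"),
         events = l$events)
  })
  mapped_history(branches, root_state = lineages[[1L]]$start_state,
                 root_age = max_age, space = space)
}

# Build the extant-only phylo by recursive reduction; NULL if < 2 survivors.
prune_extant_tree <- function(lineages) {
  children <- lapply(seq_along(lineages), function(i) integer(0))
  for (l in lineages) if (l$parent > 0L)
    children[[l$parent]] <- c(children[[l$parent]], l$id)
  surv <- logical(length(lineages))
  # lineages are created parents-first, so a reverse pass settles survivorship
  for (i in rev(seq_along(lineages))) {
    l <- lineages[[i]]
    surv[i] <- l$fate == "extant" ||
      (l$fate == "speciation" && any(surv[children[[i]]]))
  }
  if (sum(vapply(lineages, function(l) l$fate == "extant", logical(1))) < 2L)
    return(NULL)
  newick <- function(id, top_age) {
    l <- lineages[[id]]
    if (l$fate == "extant")
      return(sprintf("t%d:%.12g", id, top_age))
    kids <- children[[id]][surv[children[[id]]]]
    if (length(kids) == 2L)
      return(sprintf("(%s,%s):%.12g",
                     newick(kids[1], l$end_age), newick(kids[2], l$end_age),
                     top_age - l$end_age))
    newick(kids[1], top_age)   # single surviving daughter: splice through
  }
  root_surv <- which(surv)
  # the crown starts at the first speciation on the surviving spine
  id <- 1L
  repeat {
    l <- lineages[[id]]
    kids <- children[[id]][surv[children[[id]]]]
    if (l$fate == "extant" || length(kids) == 2L) break
    id <- kids[1]
  }
  l <- lineages[[id]]
  if (l$fate == "extant") return(NULL)
  kids <- children[[id]][surv[children[[id]]]]
  txt <- sprintf("(%s,%s);", newick(kids[1], l$end_age), newick(kids[2], l$end_age))
  ape::read.tree(text = txt)
}
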