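# Compound range x biome state space.
#
# A lineage's state couples a geographic range (a nonempty, adjacency-connected
# set of regions, held as a bitmask) with a biome-occupancy flag: NONALPINE,
# ALPINE, or BOTH.  Biome occupancy is uniform across the occupied regions, so
# a biome shift applies to the whole range at once.

BIOME_LEVELS <- c("NONALPINE", "ALPINE", "BOTH")

#' Define a set of biogeographic regions with an adjacency relation
#'
#' @param labels character vector of unique region names.
#' @param adjacency either a symmetric logical/0-1 matrix with empty diagonal
#'   (rows/columns in the order of `labels`), a two-column matrix/data.frame of
#'   adjacent label pairs, or `NULL` for complete adjacency.
#' @return an object of class `region_set` with elements `labels` and
#'   `adjacency` (logical matrix).
#' @examples
#' region_set(c("X", "Y", "Z"), cbind(c("X", "Y"), c("Y", "Z")))
#' @export
region_set <- function(labels, adjacency = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n == 0L) stop("at least one region is required")
  if (anyDuplicated(labels)) stop("region labels must be unique")
  if (n > 16L) stop("at most 16 regions are supported")
  if (is.null(adjacency)) {
    adj <- matrix(TRUE, n, n)
  } else if (is.matrix(adjacency) && nrow(adjacency) == n && ncol(adjacency) == n &&
             (is.logical(adjacency) || is.numeric(adjacency))) {
    adj <- matrix(as.logical(adjacency), n, n)
  } else {
    pairs <- as.matrix(adjacency)
    if (ncol(pairs) != 2L) stop("adjacency pairs must have two columns")
    adj <- matrix(FALSE, n, n)
    i <- match(pairs[, 1L], labels)
    j <- match(pairs[, 2L], labels)
    if (anyNA(i) || anyNA(j)) stop("adjacency pair refers to unknown region label")
    adj[cbind(i, j)] <- TRUE
    adj[cbind(j, i)] <- TRUE
  }
  diag(adj) <- FALSE
  if (!isSymmetric(adj)) stop("adjacency matrix must be symmetric")
  dimnames(adj) <- list(labels, labels)
  structure(list(labels = labels, adjacency = adj), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set with", length(x$labels), "regions:",
      paste(x$labels, collapse = ", "), "\n")
  npair <- sum(x$adjacency) / 2
  cat("Adjacency:", npair, "pairs\n")
  invisible(x)
}

#' Default six-region configuration
#'
#' A plausible adjacency for the five major Northern Hemisphere mountain
#' systems plus the boreal-arctic ecozone: the boreal-arctic region touches all
#' five mountain systems; the Eurasian systems form a chain
#' THH -- TianshanPamir -- IranoTuranianCaucasus -- EuropeanAlps; western North
#' America connects only through the boreal-arctic region.  The real adjacency
#' used in any given study is a modelling choice; this constructor is a
#' convenience default and every entry can be overridden via [region_set()].
#'
#' @return a `region_set` over six regions.
#' @export
northern_hemisphere_regions <- function() {
  labels <- c("THH", "TianshanPamir", "IranoTuranianCaucasus",
              "EuropeanAlps", "WesternNorthAmerica", "BorealArctic")
  pairs <- rbind(
    c("BorealArctic", "THH"),
    c("BorealArctic", "TianshanPamir"),
    c("BorealArctic", "IranoTuranianCaucasus"),
    c("BorealArctic", "EuropeanAlps"),
    c("BorealArctic", "WesternNorthAmerica"),
    c("THH", "TianshanPamir"),
    c("TianshanPamir", "IranoTuranianCaucasus"),
    c("IranoTuranianCaucasus", "EuropeanAlps")
  )
  region_set(labels, pairs)
}

# -- bitmask helpers ----------------------------------------------------------

mask_bits <- function(mask, n) which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)

bits_mask <- function(bits) {
  if (length(bits) == 0L) return(0L)
  Reduce(bitwOr, bitwShiftL(1L, as.integer(bits) - 1L))
}

popcount <- function(mask) vapply(mask, function(m) length(mask_bits(m, 31L)), integer(1))

# connectedness of the subgraph induced by the regions in `bits`
mask_connected <- function(bits, adj) {
  k <- length(bits)
  if (k <= 1L) return(TRUE)
  seen <- logical(k)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (f in frontier) {
      nb <- which(adj[bits[f], bits] & !seen)
      seen[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  all(seen)
}

# -- state space --------------------------------------------------------------

#' Build the compound range x biome state space
#'
#' Enumerates every legal compound state: a nonempty range of at most
#' `max_range_size` regions that induces a connected subgraph of the adjacency
#' matrix, combined with one of the three biome-occupancy values.  States are
#' deterministically ordered: ranges by size then ascending bitmask, with
#' biomes in the fixed order NONALPINE < ALPINE < BOTH within each range.
#'
#' @param regions a [region_set()].
#' @param max_range_size maximum number of regions a lineage may occupy
#'   (default 4).
#' @return an object of class `state_space`: a list with `regions`,
#'   `max_range_size`, `n_states`, and a data frame `states` with columns
#'   `index`, `range_mask`, `range_size`, `biome` (integer codes into
#'   `BIOME_LEVELS`), and `label`.
#' @examples
#' sp <- build_state_space(region_set(c("X", "Y", "Z"),
#'                                    cbind(c("X", "Y"), c("Y", "Z"))), 2)
#' sp$n_states  # 15
#' @export
build_state_space <- function(regions, max_range_size = 4L) {
  stopifnot(inherits(regions, "region_set"))
  max_range_size <- as.integer(max_range_size)
  if (max_range_size < 1L) stop("max_range_size must be at least 1")
  n <- length(regions$labels)
  max_range_size <- min(max_range_size, n)
  adj <- regions$adjacency
  masks <- integer(0)
  for (m in seq_len(2^n - 1)) {
    bits <- mask_bits(m, n)
    if (length(bits) > max_range_size) next
    if (!mask_connected(bits, adj)) next
    masks <- c(masks, as.integer(m))
  }
  ord <- order(popcount(masks), masks)
  masks <- masks[ord]
  range_mask <- rep(masks, each = 3L)
  biome <- rep(1:3, times = length(masks))
  labels <- vapply(seq_along(range_mask), function(i) {
    paste0(paste(regions$labels[mask_bits(range_mask[i], n)], collapse = "+"),
           "|", BIOME_LEVELS[biome[i]])
  }, character(1))
  states <- data.frame(index = seq_along(range_mask),
                       range_mask = range_mask,
                       range_size = popcount(range_mask),
                       biome = biome,
                       label = labels,
                       stringsAsFactors = FALSE)
  key <- setNames(states$index, paste0(states$range_mask, ".", states$biome))
  structure(list(regions = regions, max_range_size = max_range_size,
                 n_states = nrow(states), states = states, .key = key),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("Compound state space:", x$n_states, "states (",
      x$n_states / 3, "ranges x 3 biomes ) over",
      length(x$regions$labels), "regions, max range size",
      x$max_range_size, "\n")
  invisible(x)
}

#' Look up the canonical index of a compound state
#'
#' @param space a `state_space`.
#' @param range region labels or a range bitmask.
#' @param biome one of `"NONALPINE"`, `"ALPINE"`, `"BOTH"` (or integer code).
#' @return integer state index, or `NA` if the state is not in the space.
#' @export
state_index <- function(space, range, biome) {
  mask <- if (is.character(range)) {
    i <- match(range, space$regions$labels)
    if (anyNA(i)) stop("unknown region label")
    bits_mask(i)
  } else as.integer(range)
  b <- if (is.character(biome)) match(biome, BIOME_LEVELS) else as.integer(biome)
  if (is.na(b)) stop("unknown biome value")
  unname(space$.key[paste0(mask, ".", b)])
}

state_range_mask <- function(space, index) space$states$range_mask[index]
state_biome <- function(space, index) space$states$biome[index]

#' Human-readable label(s) for state indices
#' @param space a `state_space`.
#' @param index integer state indices.
#' @export
state_label <- function(space, index) space$states$label[index]

# alpine occupancy indicator: biome ALPINE (2) or BOTH (3)
biome_is_alpine <- function(biome) biome >= 2L

#' Enumerate legal cladogenetic outcomes of a compound state
#'
#' Two event classes exist.  `WITHIN_REGION(r)`: one daughter keeps the parent
#' state, the other becomes an endemic of one occupied region `r`; from a
#' single-biome parent the new daughter inherits that biome, from a BOTH
#' parent it may be BOTH, ALPINE, or NONALPINE (the subset-speciation
#' pathway).  `BETWEEN_REGION`: the range splits into two connected, nonempty
#' subranges, both daughters inheriting the parent biome.  Outcomes are
#' unordered in the daughters and listed in canonical order (within-region by
#' region then daughter state index; between-region by smaller daughter mask).
#'
#' @param state integer state index.
#' @param space a `state_space`.
#' @return data frame with columns `left`, `right` (state indices),
#'   `event_class` (`"WITHIN_REGION"`/`"BETWEEN_REGION"`) and `region`
#'   (label for within-region outcomes, `NA` otherwise).
#' @export
cladogenetic_outcomes <- function(state, space) {
  st <- space$states
  if (length(state) != 1L || is.na(state) || state < 1L || state > space$n_states)
    stop("state not in state space")
  mask <- st$range_mask[state]
  biome <- st$biome[state]
  n <- length(space$regions$labels)
  bits <- mask_bits(mask, n)
  out <- list()
  daughter_biomes <- if (biome == 3L) c(3L, 2L, 1L) else biome
  for (r in bits) {
    for (b in sort(daughter_biomes)) {
      d <- state_index(space, bits_mask(r), b)
      pair <- sort(c(state, d))
      out[[length(out) + 1L]] <- data.frame(
        left = pair[1], right = pair[2], event_class = "WITHIN_REGION",
        region = space$regions$labels[r], stringsAsFactors = FALSE)
    }
  }
  if (length(bits) >= 2L) {
    # unordered bipartitions into two connected nonempty subranges
    sub <- setdiff(seq_len(2^length(bits) - 1), 2^length(bits) - 1)
    seen <- integer(0)
    for (s in sub) {
      a_bits <- bits[mask_bits(s, length(bits))]
      b_bits <- setdiff(bits, a_bits)
      a_mask <- bits_mask(a_bits); b_mask <- bits_mask(b_bits)
      lo <- min(a_mask, b_mask)
      if (lo %in% seen) next
      seen <- c(seen, lo)
      ia <- state_index(space, a_mask, biome)
      ib <- state_index(space, b_mask, biome)
      if (is.na(ia) || is.na(ib)) next   # disconnected or oversized subrange
      pair <- sort(c(ia, ib))
      out[[length(out) + 1L]] <- data.frame(
        left = pair[1], right = pair[2], event_class = "BETWEEN_REGION",
        region = NA_character_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  within <- res$event_class == "WITHIN_REGION"
  res <- rbind(
    res[within, ][order(match(res$region[within], space$regions$labels),
                        res$left[within], res$right[within]), ],
    res[!within, ][order(res$left[!within], res$right[!within]), ])
  rownames(res) <- NULL
  res
}

#' Enumerate legal anagenetic moves from a compound state
#'
#' Move classes: `RANGE_EXPANSION` (gain one region adjacent to the current
#' range, if the result is still a legal range), `RANGE_CONTRACTION` (lose one
#' region, if the remainder is nonempty and connected), and `BIOME_SHIFT`
#' (NONALPINE <-> BOTH or ALPINE <-> BOTH; a direct ALPINE <-> NONALPINE jump
#' is impossible, since a shift between pure biomes requires two steps through
#' the BOTH state).  Range moves and biome moves never combine: each target
#' differs from the source in exactly one of range or biome.
#'
#' @param state integer state index.
#' @param space a `state_space`.
#' @return data frame with columns `target` (state index), `move_class`, and
#'   `region` (the gained/lost region for range moves, `NA` for biome shifts).
#' @export
anagenetic_neighbors <- function(state, space) {
  st <- space$states
  if (length(state) != 1L || is.na(state) || state < 1L || state > space$n_states)
    stop("state not in state space")
  mask <- st$range_mask[state]
  biome <- st$biome[state]
  n <- length(space$regions$labels)
  bits <- mask_bits(mask, n)
  adj <- space$regions$adjacency
  out <- list()
  add <- function(target, move_class, region)
    out[[length(out) + 1L]] <<- data.frame(target = target,
                                           move_class = move_class,
                                           region = region,
                                           stringsAsFactors = FALSE)
  if (length(bits) < space$max_range_size) {
    gainable <- setdiff(which(colSums(adj[bits, , drop = FALSE]) > 0), bits)
    for (g in sort(gainable)) {
      tgt <- state_index(space, bitwOr(mask, bits_mask(g)), biome)
      if (!is.na(tgt)) add(tgt, "RANGE_EXPANSION", space$regions$labels[g])
    }
  }
  if (length(bits) >= 2L) {
    for (r in bits) {
      rem <- setdiff(bits, r)
      if (!mask_connected(rem, adj)) next
      add(state_index(space, bits_mask(rem), biome),
          "RANGE_CONTRACTION", space$regions$labels[r])
    }
  }
  shift_to <- switch(biome, `1` = 3L, `2` = 3L, `3` = c(1L, 2L))
  for (b in shift_to)
    add(state_index(space, mask, b), "BIOME_SHIFT", NA_character_)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
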