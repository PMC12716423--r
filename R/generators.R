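# Model parameters and the generator set (Q, Lambda, mu) they imply.

#' Parameters of the compound-state diversification model
#'
#' @param lambda_within per-region within-region speciation rates
#'   (events/lineage/Ma); recycled to the number of regions.
#' @param lambda_between single rate shared by all between-region (vicariant)
#'   speciation outcomes of a state.
#' @param dispersal base range-expansion rate per occupied source region
#'   adjacent to the gained region.
#' @param biome_rate rate of each allowed biome shift
#'   (NONALPINE<->BOTH, ALPINE<->BOTH).
#' @param extirpation per-region local extinction rate (scalar = shared across
#'   regions, the default reading; a vector gives region-specific rates).
#' @param sampling_fraction probability in (0, 1] that an extant species is
#'   sampled in the tree.
#' @return an object of class `classe_parameters`.
#' @export
classe_parameters <- function(lambda_within, lambda_between = 0, dispersal = 0,
                              biome_rate = 0, extirpation = 0,
                              sampling_fraction = 1) {
  p <- list(lambda_within = as.numeric(lambda_within),
            lambda_between = as.numeric(lambda_between),
            dispersal = as.numeric(dispersal),
            biome_rate = as.numeric(biome_rate),
            extirpation = as.numeric(extirpation),
            sampling_fraction = as.numeric(sampling_fraction))
  rates <- unlist(p[c("lambda_within", "lambda_between", "dispersal",
                      "biome_rate", "extirpation")])
  if (any(rates < 0)) stop("all rates must be nonnegative")
  if (p$sampling_fraction <= 0 || p$sampling_fraction > 1)
    stop("sampling_fraction must be in (0, 1]")
  structure(p, class = "classe_parameters")
}

#' Assemble a generator set by hand
#'
#' Low-level constructor used by [build_generators()] and available for custom
#' models (e.g. state-independent limiting cases).  The cladogenetic tensor is
#' held sparsely as one row per unordered daughter pair.
#'
#' @param Q square matrix of anagenetic rates (diagonal ignored).
#' @param clad data frame with integer columns `parent`, `left`, `right`
#'   (`left <= right`) and numeric `rate`; one row per unordered outcome.
#' @param mu per-state lineage-extinction rates.
#' @param space optional `state_space` the indices refer to.
#' @return an object of class `generator_set` with elements `Q`, `clad`, `mu`,
#'   `lambda_total` (total cladogenetic rate per state), `q_total`, `n_states`,
#'   and `space`.
#' @export
generator_set <- function(Q, clad, mu, space = NULL) {
  S <- nrow(Q)
  stopifnot(ncol(Q) == S, length(mu) == S)
  Q <- as.matrix(Q)
  diag(Q) <- 0
  if (any(Q < 0)) stop("off-diagonal Q entries must be nonnegative")
  if (is.null(clad) || nrow(clad) == 0L) {
    clad <- data.frame(parent = integer(0), left = integer(0),
                       right = integer(0), rate = numeric(0))
  }
  stopifnot(all(clad$left <= clad$right), all(clad$rate >= 0),
            all(clad$parent >= 1L & clad$parent <= S),
            all(clad$left >= 1L & clad$right <= S))
  lambda_total <- numeric(S)
  if (nrow(clad))
    lambda_total <- as.numeric(rowsum(c(clad$rate, numeric(S)),
                                      c(clad$parent, seq_len(S))))
  structure(list(Q = Q, clad = clad, mu = as.numeric(mu),
                 lambda_total = lambda_total, q_total = rowSums(Q),
                 n_states = S, space = space),
            class = "generator_set")
}

#' @export
print.generator_set <- function(x, ...) {
  cat("ClaSSE generator set over", x$n_states, "states:",
      nrow(x$clad), "cladogenetic outcomes,",
      sum(x$Q > 0), "anagenetic moves,",
      sum(x$mu > 0), "states with extinction\n")
  invisible(x)
}

#' Build the model generators over a compound state space
#'
#' Translates [classe_parameters()] into concrete rate structures:
#'
#' * `Q` (anagenetic): range expansion gaining region `j` proceeds at
#'   `dispersal` times the number of occupied regions adjacent to `j`;
#'   contraction dropping `r` at `extirpation[r]`; each allowed biome shift at
#'   `biome_rate`.
#' * `Lambda` (cladogenetic): the within-region rate `lambda_within[r]` is
#'   split equally among region `r`'s distinct within-region outcomes (one for
#'   a single-biome parent, three for a BOTH parent); `lambda_between` is
#'   split equally among the valid bipartitions of the range.
#' * `mu` (lineage extinction): `extirpation[r]` for the endemic state of
#'   region `r`; zero for multi-region states, whose local extinctions are
#'   range contractions in `Q`.
#'
#' @param params a `classe_parameters`.
#' @param space a `state_space`.
#' @return a [generator_set()].
#' @export
build_generators <- function(params, space) {
  stopifnot(inherits(params, "classe_parameters"), inherits(space, "state_space"))
  n <- length(space$regions$labels)
  lw <- rep_len(params$lambda_within, n)
  ex <- rep_len(params$extirpation, n)
  S <- space$n_states
  Q <- matrix(0, S, S)
  mu <- numeric(S)
  clad_rows <- vector("list", S)
  for (i in seq_len(S)) {
    an <- anagenetic_neighbors(i, space)
    for (k in seq_len(nrow(an))) {
      rate <- switch(an$move_class[k],
        RANGE_EXPANSION = {
          g <- match(an$region[k], space$regions$labels)
          occ <- mask_bits(space$states$range_mask[i], n)
          params$dispersal * sum(space$regions$adjacency[occ, g])
        },
        RANGE_CONTRACTION = ex[match(an$region[k], space$regions$labels)],
        BIOME_SHIFT = params$biome_rate)
      Q[i, an$target[k]] <- Q[i, an$target[k]] + rate
    }
    co <- cladogenetic_outcomes(i, space)
    co$rate <- 0
    for (r in unique(stats::na.omit(co$region))) {
      sel <- which(!is.na(co$region) & co$region == r)
      co$rate[sel] <- lw[match(r, space$regions$labels)] / length(sel)
    }
    btw <- which(co$event_class == "BETWEEN_REGION")
    if (length(btw)) co$rate[btw] <- params$lambda_between / length(btw)
    clad_rows[[i]] <- data.frame(parent = i, left = co$left, right = co$right,
                                 rate = co$rate)
    if (space$states$range_size[i] == 1L)
      mu[i] <- ex[mask_bits(space$states$range_mask[i], n)]
  }
  clad <- do.call(rbind, clad_rows)
  clad <- clad[clad$rate > 0, , drop = FALSE]
  rownames(clad) <- NULL
  gen <- generator_set(Q, clad, mu, space)
  gen$params <- params
  gen
}
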