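# Classify raw state changes in a mapped history into assembly processes.

ASSEMBLY_PROCESSES <- c("IN_SITU_SPECIATION", "SUBSET_SPECIATION", "COLONIZATION",
                        "NICHE_EXPANSION", "NICHE_CONTRACTION", "LOCAL_EXTINCTION")

empty_event_table <- function() {
  data.frame(age = numeric(0), region = character(0), process = character(0),
             source = character(0), weight = numeric(0), detail = character(0),
             event_id = integer(0), stringsAsFactors = FALSE)
}

#' Classify a mapped history into assembly events
#'
#' Walks every branch of a joint range-biome history and emits one record per
#' region-level assembly event:
#'
#' * `IN_SITU_SPECIATION` — a cladogenetic event whose parent is the alpine
#'   endemic of region `r` and that adds an alpine daughter in `r`.
#' * `SUBSET_SPECIATION` — a cladogenetic event adding an alpine-occupying
#'   daughter in `r` from a parent whose state strictly contains `r`'s alpine
#'   occupancy (wider range and/or BOTH biome); the `detail` column breaks the
#'   case down (`range_subset`, `biome_subset`, `range_biome_subset`).
#' * `COLONIZATION` — a range expansion adding `r` while the biome is ALPINE
#'   or BOTH; one record per source region (the regions occupied just before
#'   the event), with weights summing to 1 per event (equal by default,
#'   restricted to sources adjacent to `r` with `sources = "adjacent"`).
#' * `NICHE_EXPANSION` / `NICHE_CONTRACTION` — a NONALPINE->BOTH (resp.
#'   BOTH->NONALPINE) shift, one record per occupied region.
#' * `LOCAL_EXTINCTION` — a range contraction dropping `r` while the biome is
#'   ALPINE or BOTH, or death of an (alpine-occupying) endemic lineage
#'   (branches flagged `extinct`).
#'
#' Hidden cladogenetic events are real speciations whose sibling lineage left
#' no sampled descendants and are classified exactly like node events; set
#' `include_hidden = FALSE` to exclude them for sensitivity checks.
#'
#' @param history a [mapped_history()].
#' @param space the `state_space` the history's state indices refer to.
#' @param focal_biome biome whose assembly is being tracked (currently only
#'   `"ALPINE"`, the default: occupancy means biome ALPINE or BOTH).
#' @param include_hidden count hidden speciation events (default `TRUE`).
#' @param sources `"all"` (equal weights over the occupied range, default) or
#'   `"adjacent"` (equal weights over occupied regions adjacent to the gained
#'   region).
#' @return a data frame with columns `age`, `region`, `process`, `source`,
#'   `weight`, `detail`, `event_id`, ordered oldest first.  Colonization
#'   events span one row per source region; all other events are single rows
#'   of weight 1.
#' @export
classify_events <- function(history, space, focal_biome = "ALPINE",
                            include_hidden = TRUE, sources = c("all", "adjacent")) {
  sources <- match.arg(sources)
  focal_biome <- match.arg(focal_biome, "ALPINE")
  validate_history(history, space)
  st <- space$states
  n <- length(space$regions$labels)
  labels <- space$regions$labels
  out <- list()
  eid <- 0L
  emit <- function(age, region, process, source = NA_character_, weight = 1,
                   detail = NA_character_) {
    out[[length(out) + 1L]] <<- data.frame(age = age, region = region,
                                           process = process, source = source,
                                           weight = weight, detail = detail,
                                           event_id = eid, stringsAsFactors = FALSE)
  }
  alp <- function(s, r) biome_is_alpine(st$biome[s]) && r %in% mask_bits(st$range_mask[s], n)

  classify_node <- function(age, parent, d1, d2) {
    eid <<- eid + 1L
    for (r in mask_bits(bitwOr(st$range_mask[d1], st$range_mask[d2]), n)) {
      delta <- alp(d1, r) + alp(d2, r) - alp(parent, r)
      if (delta != 1L) next
      if (st$range_mask[parent] == bits_mask(r) && st$biome[parent] == 2L) {
        emit(age, labels[r], "IN_SITU_SPECIATION")
      } else {
        wider <- st$range_size[parent] > 1L
        both <- st$biome[parent] == 3L
        detail <- if (wider && both) "range_biome_subset"
                  else if (wider) "range_subset" else "biome_subset"
        emit(age, labels[r], "SUBSET_SPECIATION", detail = detail)
      }
    }
  }
  classify_anagenetic <- function(age, from, to) {
    eid <<- eid + 1L
    mf <- st$range_mask[from]; mt <- st$range_mask[to]
    bf <- st$biome[from]; bt <- st$biome[to]
    if (mf != mt) {
      if (st$range_size[to] > st$range_size[from]) {
        if (biome_is_alpine(bt)) {
          gained <- mask_bits(bitwAnd(mt, bitwNot(mf)), n)
          occ <- mask_bits(mf, n)
          src <- if (sources == "adjacent") {
            adj <- occ[space$regions$adjacency[occ, gained]]
            if (length(adj)) adj else occ
          } else occ
          for (s in src)
            emit(age, labels[gained], "COLONIZATION", labels[s], 1 / length(src))
        }
      } else if (biome_is_alpine(bf)) {
        emit(age, labels[mask_bits(bitwAnd(mf, bitwNot(mt)), n)], "LOCAL_EXTINCTION")
      }
    } else if (bf == 1L && bt == 3L) {
      for (r in mask_bits(mf, n)) emit(age, labels[r], "NICHE_EXPANSION")
    } else if (bf == 3L && bt == 1L) {
      for (r in mask_bits(mf, n)) emit(age, labels[r], "NICHE_CONTRACTION")
    }
  }

  if (!is.null(history$root_event)) {
    ev <- history$root_event
    classify_node(ev$age, ev$from_state, ev$to_states[1], ev$to_states[2])
  }
  for (b in history$branches) {
    for (ev in b$events) {
      if (ev$kind == "ANAGENETIC") {
        classify_anagenetic(ev$age, ev$from_state, ev$to_states)
      } else if (ev$kind == "CLADOGENETIC_NODE") {
        classify_node(ev$age, ev$from_state, ev$to_states[1], ev$to_states[2])
      } else if (ev$kind == "CLADOGENETIC_HIDDEN") {
        if (include_hidden) {
          sib <- if (!is.null(ev$sibling_state)) ev$sibling_state else ev$to_states
          classify_node(ev$age, ev$from_state, ev$to_states, sib)
        }
      }
    }
    if (isTRUE(b$extinct)) {
      eid <- eid + 1L
      s <- b$end_state
      if (biome_is_alpine(st$biome[s]))
        for (r in mask_bits(st$range_mask[s], n))
          emit(b$end_age, labels[r], "LOCAL_EXTINCTION")
    }
  }
  if (!length(out)) return(empty_event_table())
  res <- do.call(rbind, out)
  res <- res[order(-res$age, res$region, res$process), , drop = FALSE]
  rownames(res) <- NULL
  res
}
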