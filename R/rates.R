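# Binned per-capita rate series, quantile envelopes, interchange matrices and
# assembly-proportion summaries over replicate event tables.
#
# Bin convention: count bins are half-open age intervals (t-1, t] labeled by
# their older edge t (an event at exactly an integer age belongs to the
# younger bin); lineage counts n(a) are evaluated at integer boundary ages a
# and include every event strictly older than a.  The per-capita rate of bin t
# is then s(t) / n(t): events in the bin divided by the lineage count standing
# at the bin's older edge, i.e. at the end of the previous 1-Ma period.

# events with age > a (strictly) are "before" boundary age a
bin_of <- function(age) ceiling(age)

#' Alpine lineage count through time for one region
#'
#' Running balance of classified assembly events: in situ speciation, subset
#' speciation, niche expansion, and colonization add an alpine-occupying
#' lineage; local extinction and niche contraction remove one.  The balance is
#' reported at integer boundary ages from `max_age` down to 0; at the present
#' it equals the census of extant alpine lineages in the region.
#'
#' @param events a classified event table (see [classify_events()]) for one
#'   replicate.
#' @param region region label.
#' @param max_age oldest boundary age (Ma); defaults to the oldest event,
#'   rounded up.
#' @param initial lineage count standing at the oldest boundary (default 0).
#'   The event balance cannot see lineages that were never created by an
#'   event: when the root lineage itself occupies the alpine biome in
#'   `region`, set `initial = 1` to make the present-day balance equal the
#'   census of extant alpine lineages.
#' @return data frame with columns `age` (boundary ages, oldest first) and `n`.
#' @export
lineage_count_series <- function(events, region, max_age = NULL, initial = 0) {
  bad <- setdiff(unique(events$process), ASSEMBLY_PROCESSES)
  if (length(bad)) stop("unclassified process labels: ", paste(bad, collapse = ", "))
  ev <- events[events$region == region, , drop = FALSE]
  if (is.null(max_age))
    max_age <- if (nrow(ev)) ceiling(max(ev$age)) else 0
  ages <- seq(from = max_age, to = 0)
  sign <- ifelse(ev$process %in% c("LOCAL_EXTINCTION", "NICHE_CONTRACTION"), -1, 1)
  # colonization rows are split per source with weights summing to 1 per
  # event, so summing sign * weight counts each event exactly once
  contrib <- sign * ifelse(ev$process == "COLONIZATION", ev$weight, 1)
  n <- initial + vapply(ages, function(a) sum(contrib[ev$age > a]), numeric(1))
  if (any(n < -1e-9))
    warning("lineage count dropped below zero in region ", region, "; floored at 0")
  n <- pmax(round(n, 9), 0)
  data.frame(age = ages, n = n)
}

#' Per-capita rates from counts and lagged lineage counts
#'
#' `lambda(t) = s(t) / n(t-1)`: the number of events in a 1-Ma period divided
#' by the lineage count at the end of the previous period.  Bins where the
#' lagged count is zero get rate 0 (not `NaN`), matching the masking intent of
#' suppressing pre-origin noise.
#'
#' @param s event counts per bin.
#' @param n_lag lineage counts at each bin's older edge (same length as `s`).
#' @return numeric vector of rates (events/lineage/Ma).
#' @export
per_capita_rates <- function(s, n_lag) {
  if (length(s) != length(n_lag)) stop("bin misalignment: lengths differ")
  rate <- ifelse(n_lag > 0, s / n_lag, 0)
  as.numeric(rate)
}

#' Binned event counts for one region and process
#'
#' @param events classified event table for one replicate.
#' @param region region label.
#' @param process one of the assembly process names.
#' @param bins vector of bin labels (older edges, oldest first).
#' @return numeric vector of counts aligned with `bins` (colonization counts
#'   are weighted, so multi-source events still count once).
#' @export
event_counts <- function(events, region, process, bins) {
  ev <- events[events$region == region & events$process == process, , drop = FALSE]
  w <- if (nrow(ev) && process == "COLONIZATION") ev$weight else rep(1, nrow(ev))
  vapply(bins, function(t) sum(w[ev$age > t - 1 & ev$age <= t]), numeric(1))
}

#' Per-replicate, per-region rate series with quantile envelopes
#'
#' Full pipeline: per replicate, bins the focal process's events, builds the
#' alpine lineage-count balance, forms per-capita rates, and summarizes the
#' replicate ensemble with binwise median and 25/75% quantile envelopes
#' (optionally masked with [mask_leading()]).
#'
#' @param replicates list of classified event tables (one per replicate
#'   history).
#' @param region region label.
#' @param process assembly process to rate (default `"IN_SITU_SPECIATION"`).
#' @param max_age oldest bin edge; defaults to the oldest event over all
#'   replicates.
#' @param initial root-standing lineage count per replicate (recycled; see
#'   [lineage_count_series()]).
#' @param mask apply leading-zero masking to each quantile trajectory
#'   (default `TRUE`).
#' @return an object of class `rate_series`: list with `bins` (older edges,
#'   oldest first), `counts`, `n_lag` and `rates` (replicate x bin matrices),
#'   and `envelope` (data frame `bin`, `q25`, `median`, `q75`).
#' @export
rate_series <- function(replicates, region, process = "IN_SITU_SPECIATION",
                        max_age = NULL, initial = 0, mask = TRUE) {
  if (length(replicates) < 1L) stop("at least one replicate is required")
  if (is.null(max_age)) {
    ages <- unlist(lapply(replicates, function(e) e$age))
    max_age <- if (length(ages)) ceiling(max(ages)) else 1
  }
  initial <- rep_len(initial, length(replicates))
  bins <- seq(from = max_age, to = 1)
  counts <- t(vapply(replicates, function(e) event_counts(e, region, process, bins),
                     numeric(length(bins))))
  n_lag <- t(vapply(seq_along(replicates), function(m) {
    lineage_count_series(replicates[[m]], region, max_age,
                         initial = initial[m])$n[seq_along(bins)]
  }, numeric(length(bins))))
  rates <- matrix(per_capita_rates(as.numeric(counts), as.numeric(n_lag)),
                  nrow = nrow(counts))
  env <- if (nrow(rates) >= 2L) quantile_envelope(rates)
         else data.frame(q25 = rates[1, ], median = rates[1, ], q75 = rates[1, ])
  if (mask) env[] <- lapply(env, mask_leading)
  structure(list(bins = bins, counts = counts, n_lag = n_lag, rates = rates,
                 envelope = data.frame(bin = bins, env)),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat("Rate series:", nrow(x$rates), "replicates x", length(x$bins),
      "1-Ma bins (", max(x$bins), "-", min(x$bins) - 1, "Ma )\n")
  invisible(x)
}

#' Binwise quantile envelopes across replicates
#'
#' Linear-interpolation (type-7) quantiles, the definition stated here because
#' replicate counts can be small in tests.
#'
#' @param rates replicate x bin matrix.
#' @return data frame with columns `q25`, `median`, `q75` (one row per bin);
#'   the ordering `q25 <= median <= q75` holds binwise.
#' @export
quantile_envelope <- function(rates) {
  rates <- as.matrix(rates)
  if (nrow(rates) < 2L) stop("at least two replicates are required")
  qs <- apply(rates, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE, type = 7)
  qs <- matrix(qs, nrow = 3)
  data.frame(q25 = qs[1, ], median = qs[2, ], q75 = qs[3, ])
}

#' Mask a rate trajectory before its last zero
#'
#' Sets all values strictly older than the last zero-valued bin to zero.
#' Intended to be applied independently to each quantile trajectory, it
#' suppresses noise from early, weakly informed parts of ancestral
#' reconstructions.  Idempotent; series with no zeros are unchanged.
#'
#' @param x numeric vector ordered oldest to present.
#' @return the masked vector.
#' @export
mask_leading <- function(x) {
  zeros <- which(x == 0)
  if (!length(zeros)) return(x)
  last <- max(zeros)
  if (last > 1L) x[seq_len(last - 1L)] <- 0
  x
}

#' Biotic interchange totals between regions over a period
#'
#' Sums colonization events into each region, attributed to their source
#' regions, over all 1-Ma windows in `[age_old, age_young]`, then takes the
#' median across replicates.
#'
#' @param replicates list of classified event tables.
#' @param period numeric `c(age_old, age_young)` in Ma, `age_old > age_young`.
#' @param regions character vector of region labels defining matrix order.
#' @param weighting `"fractional"` (each event contributes its source weights,
#'   summing to 1 per event; default) or `"unit"` (each contributing source
#'   counts a full event).
#' @return square matrix (source i, destination j) of median cumulative
#'   colonization counts; the diagonal is zero.
#' @export
interchange_totals <- function(replicates, period, regions,
                               weighting = c("fractional", "unit")) {
  weighting <- match.arg(weighting)
  if (length(period) != 2L || period[1] <= period[2])
    stop("period must be c(age_old, age_young) with age_old > age_young")
  k <- length(regions)
  acc <- array(0, dim = c(k, k, length(replicates)),
               dimnames = list(regions, regions, NULL))
  for (m in seq_along(replicates)) {
    ev <- replicates[[m]]
    ev <- ev[ev$process == "COLONIZATION" & !is.na(ev$source) &
             ev$age <= period[1] & ev$age > period[2], , drop = FALSE]
    if (!nrow(ev)) next
    w <- if (weighting == "fractional") ev$weight else rep(1, nrow(ev))
    i <- match(ev$source, regions)
    j <- match(ev$region, regions)
    ok <- !is.na(i) & !is.na(j)
    for (r in which(ok)) acc[i[r], j[r], m] <- acc[i[r], j[r], m] + w[r]
  }
  out <- apply(acc, c(1, 2), stats::median)
  diag(out) <- 0
  out
}

#' Relative contribution of assembly processes in a region
#'
#' Median cumulative event counts per process across replicates, normalized to
#' shares over the three assembly routes (cladogenesis = in situ + subset
#' speciation, colonization, niche expansion), with the cladogenesis breakdown
#' reported separately.
#'
#' @param replicates list of classified event tables.
#' @param region region label.
#' @return list with `counts` (median cumulative counts per process), `shares`
#'   (named proportions over cladogenesis/colonization/niche expansion,
#'   summing to 1), `cladogenesis_breakdown` (in situ and subset shares of
#'   cladogenesis) and `defined` (`FALSE`, with `NA` shares, when no assembly
#'   events occurred).
#' @export
assembly_proportions <- function(replicates, region) {
  if (length(replicates) < 1L) stop("at least one replicate is required")
  procs <- c("IN_SITU_SPECIATION", "SUBSET_SPECIATION", "COLONIZATION",
             "NICHE_EXPANSION")
  per_rep <- vapply(replicates, function(ev) {
    ev <- ev[ev$region == region & ev$process %in% procs, , drop = FALSE]
    vapply(procs, function(p) {
      sel <- ev$process == p
      if (p == "COLONIZATION") sum(ev$weight[sel]) else sum(sel)
    }, numeric(1))
  }, numeric(length(procs)))
  counts <- apply(matrix(per_rep, nrow = length(procs)), 1, stats::median)
  names(counts) <- procs
  clad <- counts["IN_SITU_SPECIATION"] + counts["SUBSET_SPECIATION"]
  total <- clad + counts["COLONIZATION"] + counts["NICHE_EXPANSION"]
  if (total <= 0) {
    return(list(counts = counts,
                shares = c(cladogenesis = NA_real_, colonization = NA_real_,
                           niche_expansion = NA_real_),
                cladogenesis_breakdown = c(in_situ = NA_real_, subset = NA_real_),
                defined = FALSE))
  }
  shares <- c(cladogenesis = unname(clad / total),
              colonization = unname(counts["COLONIZATION"] / total),
              niche_expansion = unname(counts["NICHE_EXPANSION"] / total))
  breakdown <- if (clad > 0)
    c(in_situ = unname(counts["IN_SITU_SPECIATION"] / clad),
      subset = unname(counts["SUBSET_SPECIATION"] / clad))
  else c(in_situ = NA_real_, subset = NA_real_)
  list(counts = counts, shares = shares, cladogenesis_breakdown = breakdown,
       defined = TRUE)
}
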