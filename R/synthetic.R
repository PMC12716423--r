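# Synthetic inputs: paleo-temperature grid sequences with a latitudinal
# gradient, mountain massifs and a cooling trend; simulated clades under named
# rate regimes; and occurrence tables with known alpine fractions.

#' Describe a synthetic paleo-temperature scenario
#'
#' Temperature is built as
#' `base - gradient * (row - 1) - lapse_rate * elevation + offset(t) + noise`,
#' where elevation comes from conical massifs (peak height decaying linearly
#' to zero at the massif radius), `offset` is a per-time-step global shift (a
#' monotone decreasing sequence emulates long-term cooling), and the noise is
#' a seeded smooth random field (truncated spectral synthesis: a small sum of
#' random cosine modes with wavelengths no shorter than the correlation
#' length).
#'
#' @param nrow,ncol grid extent in cells.
#' @param cell_size cell edge length, km (default 50).
#' @param base_temp temperature at row 1 with no massif/offset/noise (degC).
#' @param gradient latitudinal cooling, degC per cell row (default 0.5,
#'   i.e. 1 degC per 100 km).
#' @param massifs data frame with columns `row`, `col`, `radius` (cells),
#'   `peak_elevation` (km); `NULL` for none.
#' @param lapse_rate free-air cooling with elevation, degC/km (default 6.5).
#' @param offsets numeric vector of per-time-step global offsets (degC);
#'   monotone nonincreasing for cooling scenarios.
#' @param noise_amplitude standard amplitude of the smooth noise field, degC
#'   (default 0.5; 0 disables noise).
#' @param noise_correlation correlation length of the noise, cells (default 5).
#' @param seed integer seed; all generated fields are reproducible under it.
#' @return an object of class `grid_scenario`.
#' @export
grid_scenario <- function(nrow = 40, ncol = 40, cell_size = 50,
                          base_temp = 18, gradient = 0.5, massifs = NULL,
                          lapse_rate = 6.5, offsets = c(0, -2, -4, -6, -8),
                          noise_amplitude = 0.5, noise_correlation = 5,
                          seed = 1L) {
  if (nrow < 1 || ncol < 1) stop("degenerate grid extent")
  if (!is.null(massifs))
    stopifnot(all(c("row", "col", "radius", "peak_elevation") %in% names(massifs)))
  structure(list(nrow = nrow, ncol = ncol, cell_size = cell_size,
                 base_temp = base_temp, gradient = gradient, massifs = massifs,
                 lapse_rate = lapse_rate, offsets = offsets,
                 noise_amplitude = noise_amplitude,
                 noise_correlation = noise_correlation, seed = as.integer(seed)),
            class = "grid_scenario")
}

# smooth seeded field: sum of random cosine modes, wavelengths >= corr length
smooth_noise_field <- function(nr, nc, amplitude, corr_len, n_modes = 24L) {
  if (amplitude <= 0) return(matrix(0, nr, nc))
  kmax <- 2 * pi / max(corr_len, 1)
  theta <- stats::runif(n_modes, 0, 2 * pi)
  kmag <- stats::runif(n_modes, kmax / 8, kmax)
  phase <- stats::runif(n_modes, 0, 2 * pi)
  amp <- stats::rnorm(n_modes)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  f <- matrix(0, nr, nc)
  for (m in seq_len(n_modes))
    f <- f + amp[m] * cos(kmag[m] * (cos(theta[m]) * rows + sin(theta[m]) * cols) + phase[m])
  f * amplitude / stats::sd(as.numeric(f))
}

massif_elevation <- function(nr, nc, massifs) {
  elev <- matrix(0, nr, nc)
  if (is.null(massifs)) return(elev)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (m in seq_len(nrow(massifs))) {
    d <- sqrt((rows - massifs$row[m])^2 + (cols - massifs$col[m])^2)
    elev <- pmax(elev, massifs$peak_elevation[m] * pmax(0, 1 - d / massifs$radius[m]))
  }
  elev
}

#' Generate a sequence of synthetic paleo-temperature grids
#'
#' One [temperature_grid()] per offset in the scenario, oldest first; with
#' monotone decreasing offsets the alpine window starts confined to massif
#' tops and high-latitude rows and expands step by step.  Noise is drawn once
#' (a fixed topographic/climatic texture) so that with zero noise the alpine
#' area grows exactly monotonically under a monotone cooling sequence.
#'
#' @param scenario a [grid_scenario()].
#' @param time_steps ages (Ma) to attach, oldest first; defaults to
#'   `length(offsets)-1, ..., 0`.
#' @return list of `temperature_grid` objects.
#' @export
make_paleo_grids <- function(scenario, time_steps = NULL) {
  stopifnot(inherits(scenario, "grid_scenario"))
  set.seed(scenario$seed)
  nr <- scenario$nrow; nc <- scenario$ncol
  elev <- massif_elevation(nr, nc, scenario$massifs)
  noise <- smooth_noise_field(nr, nc, scenario$noise_amplitude,
                              scenario$noise_correlation)
  rows <- matrix(seq_len(nr), nr, nc)
  baseline <- scenario$base_temp - scenario$gradient * (rows - 1) -
    scenario$lapse_rate * elev + noise
  if (is.null(time_steps))
    time_steps <- rev(seq_along(scenario$offsets)) - 1
  stopifnot(length(time_steps) == length(scenario$offsets))
  lapply(seq_along(scenario$offsets), function(i)
    temperature_grid(baseline + scenario$offsets[i],
                     cell_size = scenario$cell_size,
                     time_step = time_steps[i]))
}

#' Named clade scenarios with contrasting assembly regimes
#'
#' Presets emulate regional contrasts in how alpine floras assemble:
#' `SPECIATION_ENGINE` (high within-region speciation in the focal region, so
#' in situ speciation dominates), `RECRUITMENT` (high biome-transition rate,
#' so niche expansion dominates), and `CROSSROADS` (high dispersal, so
#' colonization dominates).
#'
#' @param preset one of `"SPECIATION_ENGINE"`, `"RECRUITMENT"`,
#'   `"CROSSROADS"`.
#' @param n_regions number of regions in a chain adjacency (default 3).
#' @param max_range_size maximum range size (default 2).
#' @param max_age crown age, Ma (default 15).
#' @param seed integer seed.
#' @return an object of class `clade_scenario` with the fully specified
#'   [classe_parameters()], the `state_space`, root state and simulation
#'   settings.
#' @export
clade_scenario <- function(preset = c("SPECIATION_ENGINE", "RECRUITMENT",
                                      "CROSSROADS"),
                           n_regions = 3L, max_range_size = 2L, max_age = 15,
                           seed = 1L) {
  preset <- match.arg(preset)
  labels <- paste0("R", seq_len(n_regions))
  pairs <- if (n_regions > 1)
    cbind(labels[-n_regions], labels[-1]) else NULL
  regions <- region_set(labels, pairs)
  space <- build_state_space(regions, max_range_size)
  params <- switch(preset,
    SPECIATION_ENGINE = classe_parameters(
      lambda_within = c(0.45, rep(0.08, n_regions - 1)),
      lambda_between = 0.02, dispersal = 0.02, biome_rate = 0.03,
      extirpation = 0.02),
    RECRUITMENT = classe_parameters(
      lambda_within = rep(0.12, n_regions),
      lambda_between = 0.02, dispersal = 0.02, biome_rate = 0.35,
      extirpation = 0.02),
    CROSSROADS = classe_parameters(
      lambda_within = c(0.25, rep(0.05, n_regions - 1)),
      lambda_between = 0.02, dispersal = 0.4, biome_rate = 0.03,
      extirpation = 0.15))
  # the focal region is where the preset's signature process should dominate:
  # the root region for a speciation engine, the root region (starting
  # nonalpine) for local recruitment, and a region that must be reached by
  # dispersal for a biogeographic crossroads
  root_state <- switch(preset,
    SPECIATION_ENGINE = state_index(space, labels[1], "ALPINE"),
    RECRUITMENT = state_index(space, labels[1], "NONALPINE"),
    CROSSROADS = state_index(space, labels[1], "ALPINE"))
  focal_region <- if (preset == "CROSSROADS" && n_regions > 1) labels[2] else labels[1]
  structure(list(preset = preset, params = params, space = space,
                 regions = regions, root_state = root_state,
                 focal_region = focal_region, max_age = max_age,
                 seed = as.integer(seed)),
            class = "clade_scenario")
}

#' Simulate a clade under a named scenario
#'
#' Wraps [simulate_clade()]; the generating parameters travel with the result
#' for parameter-recovery tests.  Re-draws (advancing the seed deterministically)
#' if the clade dies before the present, up to `max_tries`.
#'
#' @param scenario a [clade_scenario()].
#' @param min_survivors smallest acceptable number of extant species
#'   (default 5).
#' @param max_tries attempts before giving up (default 50).
#' @return the [simulate_clade()] result plus `scenario`.
#' @export
make_scenario_clade <- function(scenario, min_survivors = 5L, max_tries = 50L) {
  stopifnot(inherits(scenario, "clade_scenario"))
  gen <- build_generators(scenario$params, scenario$space)
  for (try in seq_len(max_tries)) {
    res <- tryCatch(
      simulate_clade(gen, scenario$root_state, scenario$max_age,
                     seed = scenario$seed + (try - 1L) * 1009L,
                     min_survivors = min_survivors),
      alpassembly_extinct = function(e) NULL)
    if (!is.null(res)) {
      res$scenario <- scenario
      res$gen <- gen
      return(res)
    }
  }
  stop("no simulation with >= ", min_survivors, " survivors in ",
       max_tries, " tries")
}

# -- occurrence tables and biome classification -------------------------------

#' Generate a synthetic occurrence table
#'
#' Species records with elevations drawn around each species' characteristic
#' elevation, plus a local treeline elevation per site, so that each species
#' has a known expected fraction of alpine records.
#'
#' @param species character vector of species names.
#' @param alpine_fraction per-species probability that a record lies above the
#'   local treeline (recycled).
#' @param n_records records per species (recycled).
#' @param treeline_mean,treeline_sd distribution of local treeline elevations,
#'   m (defaults 2300, 150).
#' @param seed integer seed.
#' @return data frame with columns `species`, `site`, `elevation`,
#'   `treeline_elevation`, `alpine_flag`.
#' @export
make_occurrences <- function(species, alpine_fraction = 0.5, n_records = 40L,
                             treeline_mean = 2300, treeline_sd = 150,
                             seed = 1L) {
  set.seed(seed)
  alpine_fraction <- rep_len(alpine_fraction, length(species))
  n_records <- rep_len(n_records, length(species))
  rows <- lapply(seq_along(species), function(s) {
    n <- n_records[s]
    tl <- stats::rnorm(n, treeline_mean, treeline_sd)
    above <- stats::runif(n) < alpine_fraction[s]
    elev <- ifelse(above, tl + stats::rexp(n, 1 / 200), tl - stats::rexp(n, 1 / 400) - 1)
    data.frame(species = species[s], site = paste0("s", seq_len(n)),
               elevation = elev, treeline_elevation = tl,
               alpine_flag = elev >= tl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag alpine occurrence records by treeline distance
#'
#' A record is alpine when its elevation reaches the local climatic treeline
#' (the lower boundary of the alpine biome); ties count as alpine.
#'
#' @param occ occurrence table with columns `elevation` and
#'   `treeline_elevation`.
#' @return logical vector, one flag per record.
#' @export
classify_by_treeline <- function(occ) {
  stopifnot(all(c("elevation", "treeline_elevation") %in% names(occ)))
  if (anyNA(occ$treeline_elevation)) stop("missing treeline elevation")
  occ$elevation >= occ$treeline_elevation
}

#' Classify species into biomes from occurrence fractions
#'
#' With `f` the fraction of a species' records flagged alpine:
#' `f >= alpine_threshold` (default 25%) classifies the species ALPINE;
#' `both_threshold <= f < alpine_threshold` (default 5%) classifies it BOTH;
#' otherwise NONALPINE.  Thresholds are inclusive at the stated minima.
#'
#' @param occ occurrence table with columns `species` and `alpine_flag` (or
#'   the columns needed by [classify_by_treeline()], used as a fallback).
#' @param alpine_threshold minimum alpine fraction for ALPINE (default 0.25).
#' @param both_threshold minimum alpine fraction for BOTH (default 0.05).
#' @return named character vector species -> `"ALPINE"`, `"BOTH"`, or
#'   `"NONALPINE"`.
#' @export
classify_species_biome <- function(occ, alpine_threshold = 0.25,
                                   both_threshold = 0.05) {
  stopifnot("species" %in% names(occ))
  if (!"alpine_flag" %in% names(occ))
    occ$alpine_flag <- classify_by_treeline(occ)
  if (!nrow(occ)) stop("empty occurrence table")
  f <- tapply(occ$alpine_flag, occ$species, mean)
  out <- ifelse(f >= alpine_threshold, "ALPINE",
                ifelse(f >= both_threshold, "BOTH", "NONALPINE"))
  setNames(as.character(out), names(f))
}
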