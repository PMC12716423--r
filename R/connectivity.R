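# Arctic-alpine habitat connectivity from gridded temperature fields.
#
# Pipeline per time step: classify alpine pixels (rounded annual mean
# temperature in [0, 6] degC), label habitat patches, derive a resistance
# surface from the temperature deviation outside that window, compute
# least-cost distances between patches over the pixel lattice, threshold them
# into a patch network, and summarize the network with the probability of
# connectivity (PC).

#' Create a temperature grid
#'
#' @param values numeric matrix of annual mean temperatures (degC); `NA` marks
#'   nodata.  Rows are grid rows (north at row 1 by convention), columns grid
#'   columns; cells are assumed equal-area.
#' @param cell_size cell edge length in km (default 50).
#' @param time_step age of the reconstruction in Ma (default `NA`).
#' @return an object of class `temperature_grid`.
#' @export
temperature_grid <- function(values, cell_size = 50, time_step = NA_real_) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(dim(values) < 1L)) stop("values must be a numeric matrix")
  if (cell_size <= 0) stop("cell_size must be positive")
  structure(list(values = values, cell_size = cell_size, time_step = time_step),
            class = "temperature_grid")
}

#' @export
print.temperature_grid <- function(x, ...) {
  cat("Temperature grid:", nrow(x$values), "x", ncol(x$values), "cells of",
      x$cell_size, "km;", sum(is.na(x$values)), "nodata\n")
  invisible(x)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Classify alpine pixels
#'
#' A pixel belongs to the alpine biome when its temperature, rounded to whole
#' degrees (half away from zero), lies in the closed interval \[0, 6\] degC.
#' Nodata pixels are never alpine.
#'
#' @param grid a [temperature_grid()].
#' @return logical matrix.
#' @export
classify_alpine <- function(grid) {
  stopifnot(inherits(grid, "temperature_grid"))
  if (all(is.na(grid$values))) stop("all-nodata grid")
  t_round <- round_half_away(grid$values)
  mask <- !is.na(t_round) & t_round >= 0 & t_round <= 6
  mask
}

#' Label connected habitat patches
#'
#' Connected-component labeling of a boolean mask under the 8- (default) or
#' 4-neighborhood; patch ids are deterministic by scan order (column-major,
#' the first-seen pixel of each patch).
#'
#' @param mask logical matrix.
#' @param neighborhood 8 or 4.
#' @param cell_size cell edge length (km) used for patch areas.
#' @return list of patches, each a list with `id`, `pixels` (two-column
#'   matrix of row/col indices), `n_pixels`, and `area` (km^2).
#' @export
label_patches <- function(mask, neighborhood = 8, cell_size = 50) {
  stopifnot(is.logical(mask), neighborhood %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (neighborhood == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  nextid <- 0L
  patches <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nextid <- nextid + 1L
    queue <- matrix(c(i, j), 1, 2)
    lab[i, j] <- nextid
    pix <- queue
    while (nrow(queue)) {
      p <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        ri <- p[1] + offs[k, 1]; cj <- p[2] + offs[k, 2]
        if (ri < 1 || ri > nr || cj < 1 || cj > nc) next
        if (mask[ri, cj] && lab[ri, cj] == 0L) {
          lab[ri, cj] <- nextid
          queue <- rbind(queue, c(ri, cj))
          pix <- rbind(pix, c(ri, cj))
        }
      }
    }
    patches[[nextid]] <- list(id = nextid, pixels = unname(pix),
                              n_pixels = nrow(pix),
                              area = nrow(pix) * cell_size^2)
  }
  patches
}

#' Resistance surface from temperature deviation
#'
#' Per-pixel movement cost: the distance of the rounded temperature from the
#' alpine window \[0, 6\] degC, i.e. `max(0, T - 6, -T)`; zero on alpine
#' pixels; nodata pixels are impassable (`Inf`).
#'
#' @param grid a [temperature_grid()].
#' @return numeric matrix of costs.
#' @export
resistance_surface <- function(grid) {
  stopifnot(inherits(grid, "temperature_grid"))
  t_round <- round_half_away(grid$values)
  cost <- pmax(t_round - 6, -t_round, 0)   # distance from the [0, 6] window
  cost[is.na(cost)] <- Inf
  dim(cost) <- dim(grid$values)
  cost
}

# lattice graph over passable pixels; step cost = mean endpoint resistance x
# step length (1 orthogonal, sqrt(2) diagonal, in cell units)
lattice_graph <- function(resistance, neighborhood = 8) {
  nr <- nrow(resistance); nc <- ncol(resistance)
  idx <- function(i, j) (j - 1L) * nr + i
  pass <- is.finite(resistance)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  steps <- list(list(di = 1, dj = 0, len = 1), list(di = 0, dj = 1, len = 1))
  if (neighborhood == 8)
    steps <- c(steps, list(list(di = 1, dj = 1, len = sqrt(2)),
                           list(di = 1, dj = -1, len = sqrt(2))))
  for (s in steps) {
    i1 <- seq_len(nr); j1 <- seq_len(nc)
    ii <- rep(i1, times = nc); jj <- rep(j1, each = nr)
    i2 <- ii + s$di; j2 <- jj + s$dj
    ok <- i2 >= 1 & i2 <= nr & j2 >= 1 & j2 <= nc
    ok[ok] <- pass[cbind(ii[ok], jj[ok])] & pass[cbind(i2[ok], j2[ok])]
    if (!any(ok)) next
    a <- idx(ii[ok], jj[ok]); b <- idx(i2[ok], j2[ok])
    cost <- (resistance[cbind(ii[ok], jj[ok])] + resistance[cbind(i2[ok], j2[ok])]) / 2 * s$len
    from <- c(from, a); to <- c(to, b); w <- c(w, cost)
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  g
}

#' Least-cost distances between habitat patches
#'
#' Multi-source Dijkstra over the pixel lattice: the cost between two adjacent
#' pixels is the mean of their resistances times the step length (1
#' orthogonal, sqrt(2) diagonal, in cell units), and the patch-to-patch
#' distance is the minimal accumulated cost over any pair of member pixels.
#' Patch-internal movement is free (alpine resistance is zero).
#'
#' @param patches patch list from [label_patches()].
#' @param resistance matrix from [resistance_surface()].
#' @param neighborhood lattice neighborhood for movement, 8 (default) or 4.
#' @return symmetric matrix of least-cost distances (`Inf` when unreachable).
#' @export
patch_cost_distances <- function(patches, resistance, neighborhood = 8) {
  np <- length(patches)
  d <- matrix(0, np, np)
  if (np <= 1L) return(d)
  nr <- nrow(resistance)
  g <- lattice_graph(resistance, neighborhood)
  members <- lapply(patches, function(p) (p$pixels[, 2] - 1L) * nr + p$pixels[, 1])
  # virtual zero-cost hub per patch makes this multi-source/multi-target
  nv <- igraph::vcount(g)
  g <- igraph::add_vertices(g, np)
  for (p in seq_len(np)) {
    hub <- nv + p
    g <- igraph::add_edges(g, rbind(rep(hub, length(members[[p]])), members[[p]]))
  }
  igraph::E(g)$weight[is.na(igraph::E(g)$weight)] <- 0
  dm <- igraph::distances(g, v = nv + seq_len(np), to = nv + seq_len(np),
                          weights = igraph::E(g)$weight, algorithm = "dijkstra")
  dm <- unname(as.matrix(dm))
  diag(dm) <- 0
  dm
}

#' Threshold least-cost links into a patch network
#'
#' Retains every patch pair whose least-cost distance is strictly below
#' `cost_threshold` (the network may be disconnected).
#'
#' @param patches patch list.
#' @param distances matrix from [patch_cost_distances()].
#' @param cost_threshold maximum allowed cumulative resistance (default 250).
#' @param decay_cost,decay_p calibration of the movement-probability decay:
#'   probability `decay_p` at cost `decay_cost` (defaults 0.05 at 150), giving
#'   `k = -log(decay_p)/decay_cost`.
#' @return object of class `patch_network`: list with `patches`, `areas`,
#'   `edges` (data frame `from`, `to`, `cost`), `cost_threshold`, `k`.
#' @export
build_network <- function(patches, distances, cost_threshold = 250,
                          decay_cost = 150, decay_p = 0.05) {
  np <- length(patches)
  edges <- data.frame(from = integer(0), to = integer(0), cost = numeric(0))
  if (np >= 2L) {
    pairs <- which(upper.tri(distances), arr.ind = TRUE)
    keep <- is.finite(distances[pairs]) & distances[pairs] < cost_threshold
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                        cost = distances[pairs][keep])
  }
  structure(list(patches = patches,
                 areas = vapply(patches, `[[`, numeric(1), "area"),
                 edges = edges, cost_threshold = cost_threshold,
                 k = -log(decay_p) / decay_cost),
            class = "patch_network")
}

#' @export
print.patch_network <- function(x, ...) {
  cat("Patch network:", length(x$patches), "patches,", nrow(x$edges),
      "least-cost links (threshold", x$cost_threshold, ")\n")
  invisible(x)
}

#' Movement probability of a least-cost link
#'
#' Exponential decay `p = exp(-k * cost)`; with the default
#' `k = log(20)/150`, the probability is exactly 0.05 at cost 150.
#'
#' @param cost nonnegative cost distance(s).
#' @param k decay constant.
#' @return probabilities in (0, 1].
#' @export
edge_probability <- function(cost, k = log(20) / 150) {
  if (any(cost < 0)) stop("cost must be nonnegative")
  exp(-k * cost)
}

#' Probability of connectivity of a patch network
#'
#' `PC = sum_ij a_i a_j p*_ij / A^2` over all ordered patch pairs (including
#' `i = j`, with `p*_ii = 1`), where `p*_ij` is the maximum-probability path
#' product over the retained links — equivalently `exp(-k d_ij)` with `d_ij`
#' the shortest-path cost over the network — and `A` the total alpine area.
#' Under this normalization PC is the probability that two alpine pixels drawn
#' at random are interconnected; unreachable pairs contribute zero.  Set
#' `total_area` to a landscape area to recover the classical PC denominator.
#'
#' @param network a [build_network()] result.
#' @param total_area normalizing area; defaults to the summed patch areas.
#' @return PC in \[0, 1\] (under the default normalization).
#' @export
probability_of_connectivity <- function(network, total_area = NULL) {
  np <- length(network$patches)
  if (np < 1L) stop("network must contain at least one patch")
  a <- network$areas
  A <- if (is.null(total_area)) sum(a) else total_area
  if (A <= 0) stop("zero alpine area")
  if (np == 1L) return(a[1]^2 / A^2)
  g <- igraph::make_empty_graph(n = np, directed = FALSE)
  if (nrow(network$edges)) {
    g <- igraph::add_edges(g, rbind(network$edges$from, network$edges$to))
    igraph::E(g)$weight <- network$edges$cost
  }
  d <- igraph::distances(g, algorithm = "dijkstra")
  pstar <- exp(-network$k * d)      # Inf distance -> 0 probability
  diag(pstar) <- 1
  sum(outer(a, a) * pstar) / A^2
}

#' PC time series over a sequence of temperature grids
#'
#' Applies the full chain (alpine classification, patch labeling, resistance,
#' least-cost distances, thresholding, PC) to each time step.
#'
#' @param grids list of [temperature_grid()] objects.
#' @param cost_threshold,decay_cost,decay_p see [build_network()].
#' @param neighborhood patch/movement neighborhood (default 8).
#' @return data frame with one row per grid: `time`, `n_patches`,
#'   `alpine_area` (km^2), `n_edges`, `pc` (`NA` with a warning for steps with
#'   no alpine pixels).
#' @export
pc_time_series <- function(grids, cost_threshold = 250, decay_cost = 150,
                           decay_p = 0.05, neighborhood = 8) {
  if (!length(grids)) stop("at least one grid is required")
  rows <- lapply(grids, function(g) {
    stopifnot(inherits(g, "temperature_grid"))
    mask <- tryCatch(classify_alpine(g), error = function(e) NULL)
    if (is.null(mask) || !any(mask)) {
      warning("no alpine pixels at time step ", g$time_step, "; PC undefined")
      return(data.frame(time = g$time_step, n_patches = 0L, alpine_area = 0,
                        n_edges = 0L, pc = NA_real_))
    }
    patches <- label_patches(mask, neighborhood, g$cell_size)
    res <- resistance_surface(g)
    d <- patch_cost_distances(patches, res, neighborhood)
    net <- build_network(patches, d, cost_threshold, decay_cost, decay_p)
    data.frame(time = g$time_step, n_patches = length(patches),
               alpine_area = sum(net$areas), n_edges = nrow(net$edges),
               pc = probability_of_connectivity(net))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# -- ESRI ASCII grid IO -------------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' Plain-text raster format: a header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by `nrows` rows
#' of values, northernmost row first.
#'
#' @param path file path.
#' @param cell_size_km cell size in km for the returned grid; defaults to the
#'   header `cellsize` (useful when the file is already in km units).
#' @param time_step age (Ma) to attach.
#' @return a [temperature_grid()].
#' @export
read_ascii_grid <- function(path, cell_size_km = NULL, time_step = NA_real_) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  for (f in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[f]])) stop("missing header field: ", f)
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("value count does not match ncols x nrows")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  temperature_grid(m, cell_size = if (is.null(cell_size_km)) hdr$cellsize else cell_size_km,
                   time_step = time_step)
}

#' Write a temperature grid as an ESRI ASCII grid
#'
#' @param grid a [temperature_grid()].
#' @param path output path.
#' @param nodata value encoding `NA` (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "temperature_grid"))
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           "xllcorner 0", "yllcorner 0",
           paste("cellsize", grid$cell_size),
           paste("NODATA_value", nodata))
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
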