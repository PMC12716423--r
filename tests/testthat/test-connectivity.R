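test_that("alpine classification rounds half away from zero on [0, 6]", {
  g <- temperature_grid(matrix(c(3.2, 6.4, 6.6, -0.4, -0.6, 6.5), 2, 3),
                        cell_size = 1)
  expect_equal(as.logical(classify_alpine(g)),
               c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  withna <- temperature_grid(matrix(c(3, NA), 1, 2), cell_size = 1)
  expect_equal(as.logical(classify_alpine(withna)), c(TRUE, FALSE))
  expect_error(classify_alpine(temperature_grid(matrix(NA_real_, 2, 2))),
               "all-nodata")
})

test_that("resistance is the deviation from the alpine window", {
  g <- temperature_grid(matrix(c(3, 9, -4, NA), 2, 2), cell_size = 1)
  r <- resistance_surface(g)
  expect_equal(as.numeric(r), c(0, 3, 4, Inf))
  expect_equal(dim(r), c(2L, 2L))
})

test_that("patch labeling honors the neighborhood", {
  expect_length(label_patches(matrix(FALSE, 3, 3)), 0)
  diagm <- matrix(FALSE, 2, 2); diagm[1, 1] <- diagm[2, 2] <- TRUE
  expect_length(label_patches(diagm, 8), 1)
  expect_length(label_patches(diagm, 4), 2)
  cb <- outer(1:3, 1:3, function(i, j) (i + j) %% 2 == 0)
  expect_length(label_patches(cb, 8), 1)
  p <- label_patches(matrix(TRUE, 2, 3), 8, cell_size = 50)
  expect_equal(p[[1]]$area, 6 * 50^2)
})

test_that("patch cost distances match hand computations", {
  # one gap pixel of resistance 2 between two alpine pixels
  res <- matrix(c(0, 2, 0), 1, 3)
  p <- label_patches(res == 0, 8, 1)
  expect_equal(patch_cost_distances(p, res)[1, 2], 2)

  # 1x5 row with resistances [0,2,4,2,0]: 1 + 3 + 3 + 1
  res2 <- matrix(c(0, 2, 4, 2, 0), 1, 5)
  p2 <- label_patches(res2 == 0, 8, 1)
  expect_equal(patch_cost_distances(p2, res2)[1, 2], 8)

  # a free corridor gives zero cost even between distant patches
  res3 <- matrix(5, 3, 4)
  res3[2, ] <- 0
  res3[2, 2] <- Inf       # block the middle: detour through cost-5 cells
  mask3 <- res3 == 0
  mask3[2, 2] <- FALSE
  p3 <- label_patches(mask3, 4, 1)
  d3 <- patch_cost_distances(p3, res3, neighborhood = 8)
  expect_equal(length(p3), 2)
  expect_gt(d3[1, 2], 0)

  # any path through only alpine (zero-resistance) pixels costs nothing
  res4 <- matrix(0, 1, 6)
  res4[1, 4] <- 3
  p4 <- label_patches(res4 == 0, 8, 1)
  expect_equal(length(p4), 2)
  expect_equal(patch_cost_distances(p4, res4)[1, 2], 3)  # (0+3)/2 + (3+0)/2
})

test_that("lattice least-cost distances agree with exhaustive enumeration", {
  set.seed(77)
  for (rep in 1:8) {
    nr <- sample(2:3, 1); nc <- sample(2:4, 1)
    res <- matrix(sample(c(0, 0, 1, 3, 7), nr * nc, replace = TRUE), nr, nc)
    while (sum(res == 0) < 2) res[sample(length(res), 1)] <- 0
    mask <- res == 0
    p <- label_patches(mask, 8, 1)
    if (length(p) < 2) next
    d <- patch_cost_distances(p, res, 8)
    for (i in 1:(length(p) - 1)) for (j in (i + 1):length(p)) {
      pix <- function(q) (q$pixels[, 2] - 1) * nr + q$pixels[, 1]
      expect_equal(d[i, j], oracle_lcp(res, pix(p[[i]]), pix(p[[j]]), 8),
                   tolerance = 1e-12)
    }
  }
})

test_that("network thresholding is strict and edge probabilities calibrate", {
  p <- list(list(id = 1, pixels = cbind(1, 1), n_pixels = 1, area = 1),
            list(id = 2, pixels = cbind(1, 2), n_pixels = 1, area = 1),
            list(id = 3, pixels = cbind(1, 3), n_pixels = 1, area = 1))
  d <- matrix(c(0, 249.9, 250, 249.9, 0, 300, 250, 300, 0), 3, 3)
  net <- build_network(p, d, cost_threshold = 250)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$cost, 249.9)
  expect_equal(nrow(build_network(p, d, cost_threshold = 0)$edges), 0)
  expect_equal(nrow(build_network(p, d, cost_threshold = Inf)$edges), 3)

  expect_equal(edge_probability(150), 0.05)
  expect_equal(edge_probability(0), 1)
  expect_equal(edge_probability(300), 0.05^2)
  expect_error(edge_probability(-1), "nonnegative")
})

test_that("PC matches closed forms and the path-product oracle", {
  one <- list(list(id = 1, pixels = cbind(1, 1:4), n_pixels = 4, area = 4))
  net1 <- build_network(one, matrix(0, 1, 1))
  expect_equal(probability_of_connectivity(net1), 1)

  two <- list(list(id = 1, pixels = cbind(1, 1), n_pixels = 2, area = 2),
              list(id = 2, pixels = cbind(1, 9), n_pixels = 2, area = 2))
  net2 <- build_network(two, matrix(c(0, Inf, Inf, 0), 2, 2))
  expect_equal(probability_of_connectivity(net2), 0.5)

  # three patches on a line: Dijkstra-based p* equals exhaustive enumeration
  p3 <- lapply(1:3, function(i) list(id = i, pixels = cbind(1, i), n_pixels = 1,
                                     area = c(2, 1, 3)[i]))
  d3 <- matrix(c(0, 60, 200, 60, 0, 90, 200, 90, 0), 3, 3)
  net3 <- build_network(p3, d3, cost_threshold = 100)
  pstar <- oracle_pstar(net3$edges, 3, net3$k)
  a <- net3$areas
  expect_equal(probability_of_connectivity(net3),
               sum(outer(a, a) * pstar) / sum(a)^2, tolerance = 1e-12)
  expect_lte(probability_of_connectivity(net3), 1)

  # adding an edge (or cheapening one) never decreases PC
  pc0 <- probability_of_connectivity(net3)
  net_more <- build_network(p3, d3, cost_threshold = 300)
  expect_gte(probability_of_connectivity(net_more), pc0)
  d_cheap <- d3; d_cheap[1, 2] <- d_cheap[2, 1] <- 10
  net_cheap <- build_network(p3, d_cheap, cost_threshold = 100)
  expect_gte(probability_of_connectivity(net_cheap), pc0)
})

test_that("the PC time series handles constant, warming and cooling sequences", {
  sc <- grid_scenario(nrow = 25, ncol = 25,
                      massifs = data.frame(row = 13, col = 13, radius = 7,
                                           peak_elevation = 4),
                      base_temp = 24, offsets = c(0, -5, -10),
                      noise_amplitude = 0, seed = 3)
  grids <- make_paleo_grids(sc)
  pcs <- pc_time_series(grids)
  expect_equal(nrow(pcs), 3)
  expect_true(all(diff(pcs$alpine_area) >= 0))
  expect_true(all(pcs$pc >= 0 & pcs$pc <= 1, na.rm = TRUE))

  same <- pc_time_series(list(grids[[2]], grids[[2]]))
  expect_equal(same$pc[1], same$pc[2])

  warm <- temperature_grid(matrix(25, 4, 4), cell_size = 50, time_step = 0)
  expect_warning(pw <- pc_time_series(list(warm)), "PC undefined")
  expect_true(is.na(pw$pc))
})

test_that("ASCII grids round-trip through files", {
  g <- temperature_grid(matrix(c(1.5, -3.25, NA, 7), 2, 2), cell_size = 50,
                        time_step = 4)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, f)
  g2 <- read_ascii_grid(f, time_step = 4)
  expect_equal(g2$values, g$values)
  expect_equal(g2$cell_size, 50)

  f2 <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 50", "1 2 3"), f2)
  expect_error(read_ascii_grid(f2), "value count")
})
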