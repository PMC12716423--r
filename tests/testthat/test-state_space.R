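test_that("state counts match exhaustive enumeration", {
  expect_equal(space_1region()$n_states, 3)

  # X - Y - Z chain, max 2: {X},{Y},{Z},{XY},{YZ} x 3 biomes; {XZ} disconnected
  sp <- space_chain3()
  expect_equal(sp$n_states, 15)
  masks <- unique(sp$states$range_mask)
  expect_false(bitwOr(1L, 4L) %in% masks)  # {X,Z} excluded

  # complete adjacency: sum of binomial coefficients
  sp6 <- build_state_space(region_set(paste0("r", 1:6)), 4)
  expect_equal(sp6$n_states, 3 * (choose(6, 1) + choose(6, 2) + choose(6, 3) + choose(6, 4)))

  # complete adjacency with max_range_size = n: all nonempty subsets
  for (n in 2:4) {
    spn <- build_state_space(region_set(paste0("r", seq_len(n))), n)
    expect_equal(spn$n_states, 3 * (2^n - 1))
  }
})

test_that("state ordering and indexing are deterministic and bijective", {
  sp <- space_chain3()
  expect_equal(sp$states$index, seq_len(sp$n_states))
  # ranges by size then bitmask; biomes NONALPINE < ALPINE < BOTH within range
  expect_true(all(diff(sp$states$range_size) >= 0))
  expect_equal(sp$states$biome[1:3], 1:3)
  for (i in seq_len(sp$n_states))
    expect_equal(state_index(sp, sp$states$range_mask[i], sp$states$biome[i]), i)
})

test_that("region_set validates its inputs", {
  expect_error(region_set(character(0)), "at least one")
  expect_error(region_set(c("A", "A")), "unique")
  bad <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  expect_error(region_set(c("A", "B"), bad), "symmetric")
  expect_error(build_state_space(region_set("A"), 0), "at least 1")
})

test_that("cladogenetic outcomes follow the inheritance rules", {
  sp <- space_chain3()
  iXA <- state_index(sp, "X", "ALPINE")
  co <- cladogenetic_outcomes(iXA, sp)
  expect_equal(nrow(co), 1)
  expect_equal(co$left, iXA)
  expect_equal(co$right, iXA)
  expect_equal(co$event_class, "WITHIN_REGION")

  # BOTH parent: daughter endemics in all three biomes (subset pathway)
  iXB <- state_index(sp, "X", "BOTH")
  co <- cladogenetic_outcomes(iXB, sp)
  expect_equal(nrow(co), 3)
  daughters <- setdiff(c(co$left, co$right), iXB)
  expect_setequal(c(daughters, iXB),
                  c(state_index(sp, "X", "NONALPINE"), state_index(sp, "X", "ALPINE"), iXB))

  # adjacent two-region range: vicariant split present, daughters keep biome
  iXYA <- state_index(sp, c("X", "Y"), "ALPINE")
  co <- cladogenetic_outcomes(iXYA, sp)
  btw <- co[co$event_class == "BETWEEN_REGION", ]
  expect_equal(nrow(btw), 1)
  expect_setequal(c(btw$left, btw$right),
                  c(state_index(sp, "X", "ALPINE"), state_index(sp, "Y", "ALPINE")))

  expect_error(cladogenetic_outcomes(999L, sp), "not in state space")
})

test_that("anagenetic moves change exactly one of range or biome", {
  sp <- space_chain3()
  iXA <- state_index(sp, "X", "ALPINE")
  an <- anagenetic_neighbors(iXA, sp)
  expect_setequal(an$target[an$move_class == "RANGE_EXPANSION"],
                  state_index(sp, c("X", "Y"), "ALPINE"))
  expect_false("RANGE_CONTRACTION" %in% an$move_class)
  expect_setequal(an$target[an$move_class == "BIOME_SHIFT"],
                  state_index(sp, "X", "BOTH"))

  # no direct ALPINE <-> NONALPINE jump, ever
  for (i in seq_len(sp$n_states)) {
    an <- anagenetic_neighbors(i, sp)
    shifted <- an$target[an$move_class == "BIOME_SHIFT"]
    for (t in shifted)
      expect_true(sp$states$biome[i] == 3L || sp$states$biome[t] == 3L)
    for (t in an$target) {
      same_range <- sp$states$range_mask[t] == sp$states$range_mask[i]
      same_biome <- sp$states$biome[t] == sp$states$biome[i]
      expect_true(xor(same_range, same_biome))
    }
  }

  # chain {X,Y,Z} cannot contract to the disconnected {X,Z}
  sp3 <- space_chain3(3)
  iAll <- state_index(sp3, c("X", "Y", "Z"), "BOTH")
  an <- anagenetic_neighbors(iAll, sp3)
  contr <- an$target[an$move_class == "RANGE_CONTRACTION"]
  expect_setequal(contr, c(state_index(sp3, c("X", "Y"), "BOTH"),
                           state_index(sp3, c("Y", "Z"), "BOTH")))
})

test_that("moves are closed over the space and expansion/contraction are dual", {
  for (sp in list(space_chain3(), space_chain3(3),
                  build_state_space(northern_hemisphere_regions(), 3))) {
    exp_pairs <- list()
    for (i in seq_len(sp$n_states)) {
      an <- anagenetic_neighbors(i, sp)
      co <- cladogenetic_outcomes(i, sp)
      expect_false(anyNA(an$target))
      expect_false(anyNA(c(co$left, co$right)))
      for (k in which(an$move_class == "RANGE_EXPANSION"))
        exp_pairs[[length(exp_pairs) + 1L]] <- c(i, an$target[k])
    }
    # t is an expansion target of s iff s is a contraction target of t
    for (p in exp_pairs) {
      back <- anagenetic_neighbors(p[2], sp)
      expect_true(p[1] %in% back$target[back$move_class == "RANGE_CONTRACTION"])
    }
  }
})
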