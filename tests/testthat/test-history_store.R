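make_two_branch_history <- function(sp) {
  iXa <- state_index(sp, "X", "NONALPINE")
  iXb <- state_index(sp, "X", "BOTH")
  ev1 <- list(age = 6.5, kind = "ANAGENETIC", move_class = "BIOME_SHIFT",
              from_state = iXa, to_states = iXb, state_changed = TRUE)
  ev2 <- list(age = 5, kind = "CLADOGENETIC_NODE", move_class = "WITHIN_REGION",
              from_state = iXb, to_states = c(iXb, iXb), state_changed = FALSE)
  b1 <- list(branch_index = 1L, parent_node = 0L, child_node = 1L,
             start_age = 8, end_age = 5, start_state = iXa, end_state = iXb,
             extinct = FALSE, events = list(ev1, ev2))
  b2 <- list(branch_index = 2L, parent_node = 1L, child_node = 2L,
             start_age = 5, end_age = 0, start_state = iXb, end_state = iXb,
             extinct = FALSE, events = list())
  mapped_history(list(b1, b2), root_state = iXa, root_age = 8, space = sp)
}

test_that("histories round-trip through JSON exactly", {
  sp <- space_1region()
  h <- make_two_branch_history(sp)
  f <- withr::local_tempfile(fileext = ".json")
  write_histories(h, f)
  back <- read_histories(f, space = sp)
  expect_length(back, 1)
  expect_identical(back[[1]], h)

  # empty event lists and several replicates round-trip too
  h0 <- mapped_history(list(list(branch_index = 1L, parent_node = 0L,
                                 child_node = 1L, start_age = 3, end_age = 0,
                                 start_state = 1L, end_state = 1L,
                                 events = list())),
                       root_state = 1L, root_age = 3)
  write_histories(list(h0, h), f)
  back2 <- read_histories(f)
  expect_identical(back2, list(h0, h))
})

test_that("simulated full histories round-trip bit-identically", {
  res <- make_scenario_clade(clade_scenario("SPECIATION_ENGINE", seed = 11,
                                            max_age = 8), min_survivors = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_histories(res$history, f)
  expect_identical(read_histories(f)[[1]], res$history)
})

test_that("schema violations are rejected with branch coordinates", {
  sp <- space_1region()
  h <- make_two_branch_history(sp)
  broken <- h
  broken$branches[[1]]$events[[1]]$to_states <- state_index(sp, "X", "ALPINE")
  expect_error(validate_history(broken, sp), "branch 1.*chaining|chaining.*branch 1")
  f <- withr::local_tempfile(fileext = ".json")
  write_histories(h, f)
  payload <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  payload$histories[[1]]$branches[[2]]$end_state <- 1L
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17)), f)
  expect_error(read_histories(f), "branch 2")

  # flag inconsistency and out-of-space states are caught
  broken2 <- h
  broken2$branches[[1]]$events[[1]]$state_changed <- FALSE
  expect_error(validate_history(broken2, sp), "state_changed")
  expect_error(validate_history(h, space_chain3()), NA)  # larger space is fine
})

test_that("unknown fields survive a round-trip (extensible format)", {
  h <- make_two_branch_history(space_1region())
  h$posterior_sample <- 42L
  h$branches[[1]]$note <- "hand-built"
  f <- withr::local_tempfile(fileext = ".json")
  write_histories(h, f)
  back <- read_histories(f)[[1]]
  expect_identical(back$posterior_sample, 42L)
  expect_identical(back$branches[[1]]$note, "hand-built")
})

test_that("event classification matches the worked definitions", {
  sp <- space_chain3()
  iXA <- state_index(sp, "X", "ALPINE")
  iXB <- state_index(sp, "X", "BOTH")
  iXYA <- state_index(sp, c("X", "Y"), "ALPINE")

  # in situ: alpine endemic parent, both daughters alpine in X
  h1 <- mapped_history(list(list(
    branch_index = 1L, parent_node = 0L, child_node = 1L, start_age = 4,
    end_age = 2, start_state = iXA, end_state = iXA,
    events = list(list(age = 2, kind = "CLADOGENETIC_NODE",
                       move_class = "WITHIN_REGION", from_state = iXA,
                       to_states = c(iXA, iXA), state_changed = FALSE)))),
    root_state = iXA, root_age = 4, space = sp)
  ev <- classify_events(h1, sp)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$process, "IN_SITU_SPECIATION")
  expect_equal(ev$region, "X")

  # subset: BOTH parent spawning an alpine endemic
  h2 <- h1
  h2$branches[[1]]$start_state <- iXB
  h2$branches[[1]]$end_state <- iXB
  h2$branches[[1]]$events[[1]]$from_state <- iXB
  h2$branches[[1]]$events[[1]]$to_states <- c(iXB, iXA)
  h2$branches[[1]]$events[[1]]$state_changed <- TRUE
  h2$root_state <- iXB
  ev2 <- classify_events(h2, sp)
  expect_equal(ev2$process, "SUBSET_SPECIATION")
  expect_equal(ev2$detail, "biome_subset")

  # colonization: ({X},A) -> ({X,Y},A), source X with weight 1
  h3 <- mapped_history(list(list(
    branch_index = 1L, parent_node = 0L, child_node = 1L, start_age = 4,
    end_age = 0, start_state = iXA, end_state = iXYA,
    events = list(list(age = 1.5, kind = "ANAGENETIC",
                       move_class = "RANGE_EXPANSION", from_state = iXA,
                       to_states = iXYA, state_changed = TRUE)))),
    root_state = iXA, root_age = 4, space = sp)
  ev3 <- classify_events(h3, sp)
  expect_equal(ev3$process, "COLONIZATION")
  expect_equal(ev3$region, "Y")
  expect_equal(ev3$source, "X")
  expect_equal(ev3$weight, 1)
})

test_that("classification reproduces the simulator tally and ignores branch order", {
  res <- make_scenario_clade(clade_scenario("RECRUITMENT", seed = 21,
                                            max_age = 12), min_survivors = 5)
  sp <- res$scenario$space
  ev <- classify_events(res$history, sp)
  expect_identical(tally_counts(ev), tally_counts(res$tally))

  shuffled <- res$history
  set.seed(1)
  shuffled$branches <- shuffled$branches[sample(length(shuffled$branches))]
  ev_sh <- classify_events(shuffled, sp)
  expect_identical(tally_counts(ev_sh), tally_counts(ev))
})

test_that("hidden events classify like node events and can be excluded", {
  sp <- space_chain3()
  iXB <- state_index(sp, "X", "BOTH")
  iXA <- state_index(sp, "X", "ALPINE")
  h <- mapped_history(list(list(
    branch_index = 1L, parent_node = 0L, child_node = 1L, start_age = 4,
    end_age = 0, start_state = iXB, end_state = iXA,
    events = list(list(age = 2, kind = "CLADOGENETIC_HIDDEN",
                       move_class = "WITHIN_REGION", from_state = iXB,
                       to_states = iXA, state_changed = TRUE,
                       sibling_state = iXB)))),
    root_state = iXB, root_age = 4, space = sp)
  ev <- classify_events(h, sp)
  expect_equal(ev$process, "SUBSET_SPECIATION")
  expect_equal(nrow(classify_events(h, sp, include_hidden = FALSE)), 0)
})
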