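event_row <- function(age, region, process, source = NA_character_, weight = 1,
                      event_id = 1L) {
  data.frame(age = age, region = region, process = process, source = source,
             weight = weight, detail = NA_character_, event_id = event_id,
             stringsAsFactors = FALSE)
}

test_that("the lineage balance reproduces the worked bookkeeping", {
  ev <- rbind(event_row(10.5, "A", "COLONIZATION", source = "B"),
              event_row(9.5, "A", "IN_SITU_SPECIATION", event_id = 2L),
              event_row(8.5, "A", "LOCAL_EXTINCTION", event_id = 3L))
  n <- lineage_count_series(ev, "A", max_age = 12)
  expect_equal(n$age, 12:0)
  expect_equal(n$n[n$age %in% c(10, 9, 8)], c(1, 2, 1))
  expect_equal(n$n[n$age == 0], 1)

  # no events: identically zero
  n0 <- lineage_count_series(empty <- ev[0, ], "A", max_age = 3)
  expect_true(all(n0$n == 0))

  # unknown labels are rejected
  bad <- event_row(1, "A", "SOMETHING_ELSE")
  expect_error(lineage_count_series(bad, "A"), "unclassified")
})

test_that("the balance floors at zero with a warning", {
  ev <- event_row(5.5, "A", "LOCAL_EXTINCTION")
  expect_warning(n <- lineage_count_series(ev, "A", max_age = 6), "floored")
  expect_true(all(n$n >= 0))
})

test_that("per-capita rates follow s/n with a zero-count convention", {
  expect_equal(per_capita_rates(2, 8), 0.25)
  expect_equal(per_capita_rates(0, 5), 0)
  expect_equal(per_capita_rates(3, 0), 0)   # defined as 0, not NaN
  expect_error(per_capita_rates(c(1, 2), 1), "misalignment")
})

test_that("quantile envelopes use type-7 quantiles and stay ordered", {
  # identical replicates collapse onto the series
  r <- matrix(rep(c(0.1, 0.4, 0), 3), nrow = 3, byrow = TRUE)
  env <- quantile_envelope(r)
  expect_equal(env$median, c(0.1, 0.4, 0))
  expect_equal(env$q25, env$q75)

  env2 <- quantile_envelope(matrix(0:4, ncol = 1))
  expect_equal(unlist(env2), c(q25 = 1, median = 2, q75 = 3))

  set.seed(8)
  renv <- quantile_envelope(matrix(rexp(200), 20, 10))
  expect_true(all(renv$q25 <= renv$median & renv$median <= renv$q75))
})

test_that("leading-zero masking matches the rule and is idempotent", {
  expect_equal(mask_leading(c(0.1, 0, 0.3, 0.4)), c(0, 0, 0.3, 0.4))
  expect_equal(mask_leading(c(0.2, 0.3)), c(0.2, 0.3))
  expect_equal(mask_leading(rep(0, 4)), rep(0, 4))
  set.seed(2)
  x <- round(rexp(30) - 0.5, 2) * (runif(30) > 0.3)
  expect_equal(mask_leading(mask_leading(x)), mask_leading(x))
})

test_that("interchange totals attribute sources and take medians", {
  one <- event_row(5.5, "Y", "COLONIZATION", source = "X")
  m <- interchange_totals(list(one), c(10, 0), c("X", "Y", "Z"))
  expect_equal(m["X", "Y"], 1)
  expect_equal(sum(m), 1)
  expect_equal(diag(m), setNames(rep(0, 3), c("X", "Y", "Z")))

  # replicates {0,1,2} events -> median 1
  two <- rbind(one, event_row(4.5, "Y", "COLONIZATION", source = "X", event_id = 2L))
  m3 <- interchange_totals(list(one[0, ], one, two), c(10, 0), c("X", "Y"))
  expect_equal(m3["X", "Y"], 1)

  # split attribution: colonization from range {X,Y} adds 0.5 to each source
  split <- rbind(event_row(3.5, "Z", "COLONIZATION", source = "X", weight = 0.5),
                 event_row(3.5, "Z", "COLONIZATION", source = "Y", weight = 0.5))
  mf <- interchange_totals(list(split), c(10, 0), c("X", "Y", "Z"))
  expect_equal(unname(mf[c("X", "Y"), "Z"]), c(0.5, 0.5))
  mu <- interchange_totals(list(split), c(10, 0), c("X", "Y", "Z"),
                           weighting = "unit")
  expect_equal(unname(mu[c("X", "Y"), "Z"]), c(1, 1))

  # period filtering is [old, young) in age
  expect_equal(sum(interchange_totals(list(one), c(5, 0), c("X", "Y"))), 0)
  expect_error(interchange_totals(list(one), c(0, 10), c("X", "Y")), "age_old")
})

test_that("assembly proportions normalize over the three routes", {
  ev <- rbind(
    do.call(rbind, lapply(1:6, function(i) event_row(i, "A", "IN_SITU_SPECIATION", event_id = i))),
    event_row(7, "A", "SUBSET_SPECIATION", event_id = 7L),
    event_row(7.5, "A", "SUBSET_SPECIATION", event_id = 8L),
    event_row(8, "A", "COLONIZATION", source = "B", event_id = 9L),
    event_row(9, "A", "NICHE_EXPANSION", event_id = 10L))
  ap <- assembly_proportions(list(ev), "A")
  expect_true(ap$defined)
  expect_equal(sum(ap$shares), 1)
  expect_equal(ap$shares[["cladogenesis"]], 0.8)
  expect_equal(ap$cladogenesis_breakdown[["in_situ"]], 0.75)

  single <- list(event_row(2, "A", "NICHE_EXPANSION"))
  ap1 <- assembly_proportions(single, "A")
  expect_equal(ap1$shares[["niche_expansion"]], 1)

  apz <- assembly_proportions(list(event_row(2, "B", "NICHE_EXPANSION")), "A")
  expect_false(apz$defined)
  expect_true(all(is.na(apz$shares)))
})

test_that("the full rate pipeline reconstructs counts and matches the census", {
  res <- make_scenario_clade(clade_scenario("SPECIATION_ENGINE", seed = 42),
                             min_survivors = 50)
  sp <- res$scenario$space
  ev <- classify_events(res$history, sp)
  st <- sp$states
  root <- res$history$root_state
  init <- as.numeric(st$biome[root] >= 2 &&
                     bitwAnd(st$range_mask[root], 1L) > 0)
  # census identity at the present
  n <- lineage_count_series(ev, "R1", max_age = 15, initial = init)
  census <- sum(vapply(res$tips, function(s)
    st$biome[s] >= 2 && bitwAnd(st$range_mask[s], 1L) > 0, logical(1)))
  expect_equal(n$n[n$age == 0], census)

  # exact reconstruction: rates x lagged n return the counts
  rs <- rate_series(list(ev, ev), "R1", initial = init)
  expect_lt(max(abs(rs$rates * rs$n_lag - rs$counts)), 1e-12)
  expect_true(all(rs$envelope$q25 <= rs$envelope$median + 1e-12))
  expect_true(all(rs$envelope$median <= rs$envelope$q75 + 1e-12))
})

test_that("mean pipeline rate recovers the generating speciation rate", {
  # pooled in situ events over replicate simulated clades against the known
  # within-region rate (the per-capita estimator is unbiased given n > 0)
  # modest rates keep the within-bin growth bias of the 1-Ma discretization
  # well below the Monte-Carlo tolerance
  sp <- space_1region()
  lam <- 0.15
  gen <- build_generators(classe_parameters(lambda_within = lam,
                                            extirpation = 0.02), sp)
  set.seed(14)
  tot_ev <- 0; tot_exposure <- 0
  for (i in 1:40) {
    res <- tryCatch(simulate_clade(gen, 2L, 12),
                    alpassembly_extinct = function(e) NULL)
    if (is.null(res)) next
    ev <- classify_events(res$history, sp)
    n <- lineage_count_series(ev, "X", max_age = 12, initial = 1)
    s <- event_counts(ev, "X", "IN_SITU_SPECIATION", 12:1)
    tot_ev <- tot_ev + sum(s)
    tot_exposure <- tot_exposure + sum(n$n[seq_len(12)])
  }
  est <- tot_ev / tot_exposure
  expect_gt(tot_ev, 100)
  expect_lt(abs(est - lam) / lam, 0.15)
})
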