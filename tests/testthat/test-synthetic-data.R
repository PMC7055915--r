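test_that("evolving at zero divergence returns the ancestor unchanged", {
  anc <- strrep("ACGT", 250)
  expect_identical(evolve_sequence(anc, evolution_params(0, 2, seed = 1)),
                   anc)
})

test_that("realized K2P divergence matches the requested distance", {
  set.seed(10)
  anc <- random_dna(1000)
  one <- evolve_sequence(anc, evolution_params(0.10, 2, seed = 7))
  expect_lt(abs(k2p_distance(anc, one)$distance - 0.10), 0.03)
  mean_d <- mean(vapply(1:100, function(s) {
    ev <- evolve_sequence(anc, evolution_params(0.10, 2, seed = s))
    k2p_distance(anc, ev)$distance
  }, numeric(1)))
  expect_lt(abs(mean_d - 0.10), 0.005)
})

test_that("the transitions-only limit produces no transversions", {
  set.seed(3)
  anc <- random_dna(1000)
  ev <- evolve_sequence(anc, evolution_params(0.10, Inf, seed = 3))
  counts <- count_ts_tv(anc, ev)
  expect_gt(counts$ts, 0)
  expect_identical(counts$tv, 0L)
  expect_equal(k2p_distance(anc, ev)$Q, 0)
})

test_that("evolve_sequence validates its inputs", {
  expect_error(evolve_sequence("", evolution_params(0.1)), "empty")
  expect_error(evolve_sequence("ACGN", evolution_params(0.1)), "non-ACGT")
  expect_error(evolution_params(-1), "divergence")
  expect_error(evolution_params(0.1, kappa = 0), "kappa")
})

test_that("recombinants are exact segment mosaics of their parents", {
  set.seed(4)
  A <- random_dna(400)
  B <- random_dna(400)
  expect_identical(build_recombinant(A, B)$sequence, A)
  half <- build_recombinant(A, B, 200)$sequence
  expect_identical(substr(half, 1, 200), substr(A, 1, 200))
  expect_identical(substr(half, 201, 400), substr(B, 201, 400))
  # string-slicing oracle for two breakpoints
  p <- 57
  q <- 311
  two <- build_recombinant(A, B, c(p, q))$sequence
  expect_identical(two, paste0(substr(A, 1, p), substr(B, p + 1, q),
                               substr(A, q + 1, 400)))
  expect_error(build_recombinant(A, B, c(300, 100)), "increasing")
  expect_error(build_recombinant(A, B, 400), "inside")
})

test_that("a minimal planted layout emits the expected fragments", {
  cfg <- ty_sim_config(
    elements = data.frame(
      family = "Ty1",
      subfamily = c("canonical", NA),
      structural_class = c("full_length", "solo_ltr"),
      strand = "+"))
  gt <- plant_genome(cfg, seed = 1)
  expect_equal(nrow(gt$raw_hits), 4)  # LTR, internal, LTR, solo LTR
  expect_identical(gt$truth_counts$by_family$n_full, 1L)
  expect_identical(gt$truth_counts$by_family$n_solo, 1L)
  expect_true(all(!gt$raw_hits$is_fp))
  # every non-false-positive hit overlaps a planted element
  for (i in seq_len(nrow(gt$raw_hits))) {
    h <- gt$raw_hits[i, ]
    expect_true(any(h$query_start - 1 < gt$elements$end &
                      h$query_end > gt$elements$start))
  }
})

test_that("a forced-merge tandem array shares one hit-group id", {
  cfg <- ty_sim_config(
    elements = data.frame(family = character(0), subfamily = character(0),
                          structural_class = character(0),
                          strand = character(0)),
    tandem_arrays = list(list(n = 2, family = "Ty1",
                              subfamily = "canonical")),
    errors = error_modes(p_merge_tandem = 1))
  gt <- plant_genome(cfg, seed = 2)
  expect_equal(nrow(gt$raw_hits), 5)  # L-I-L-I-L
  expect_length(unique(gt$raw_hits$hit_group_id), 1)
  expect_identical(gt$truth_counts$by_family$n_full, 2L)
})

test_that("false-positive hits always exceed the divergence cutoff", {
  cfg <- ty_sim_config(
    elements = data.frame(family = "Ty1", subfamily = "canonical",
                          structural_class = "full_length", strand = "+"),
    errors = error_modes(fp_rate = 20))
  gt <- plant_genome(cfg, seed = 5)
  fps <- gt$raw_hits[gt$raw_hits$is_fp, ]
  expect_gt(nrow(fps), 0)
  expect_true(all(fps$pct_divergence > 20))
})

test_that("identical config and seed give byte-identical output", {
  cfg <- random_ty_config(11)
  a <- plant_genome(cfg, seed = 99)
  b <- plant_genome(cfg, seed = 99)
  expect_identical(a$genome, b$genome)
  expect_identical(a$raw_hits, b$raw_hits)
  expect_identical(a$elements, b$elements)
})

test_that("overlapping explicit placements are rejected", {
  cfg <- ty_sim_config(
    elements = data.frame(
      family = "Ty1", subfamily = "canonical",
      structural_class = "full_length", strand = "+",
      trunc_kind = NA_character_, start = c(1000L, 3000L)))
  expect_error(plant_genome(cfg, seed = 1), "overlap")
})

test_that("simulated mobility counts follow the Poisson law", {
  zero <- simulate_mobility_counts(0, n_replicates = 4, seed = 1)
  expect_identical(zero$replicate_events, rep(0L, 4))
  sim <- simulate_mobility_counts(1e-6, n_replicates = 1000,
                                  cells_per_ml = 1e7, seed = 5)
  # mean 10, SE = sqrt(10/1000)
  expect_lt(abs(mean(sim$replicate_events) - 10), 3 * sqrt(10 / 1000))
})

test_that("mobility frequency is recovered from large simulations", {
  sim <- simulate_mobility_counts(1e-6, n_replicates = 10000,
                                  cells_per_ml = 1e7, seed = 8)
  est <- mobility_frequency(sim$replicate_events, sim$uraplus_per_ml)
  expect_lt(abs(est$frequency - 1e-6) / 1e-6, 0.05)
})
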