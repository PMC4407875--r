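# true positive-pool signature of a marker: union of its clones' pools
truth_signature <- function(sim, marker) {
  clones <- sim$truth$clone[sim$truth$marker_id == marker]
  clones <- clones[!is.na(clones)]
  sort(unique(as.vector(vapply(clones, function(cl) {
    clone_to_pools(sim$scheme, cl)
  }, character(3)))))
}

test_that("noise-free coverage reproduces the truth signatures exactly", {
  sim <- simulate_experiment(small_sim_config(seed = 51L))
  calls <- call_positive_pools(sim$coverage, 0.8, markers = sim$markers,
                               pools = scheme_pools(sim$scheme))
  for (m in sim$markers$marker_id) {
    expect_equal(sort(positive_pools(calls, m)), truth_signature(sim, m),
                 info = m)
  }
  # and at any lower threshold too (simulated fractions are >= 0.9)
  calls3 <- call_positive_pools(sim$coverage, 0.3, markers = sim$markers,
                                pools = scheme_pools(sim$scheme))
  expect_identical(calls3$calls, calls$calls)
})

test_that("the simulation is byte-deterministic under its seed", {
  cfg <- small_sim_config(false_negative_rate = 0.1, seed = 77L)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$coverage, s2$coverage)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$scheme$roster, s2$scheme$roster)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  s3 <- simulate_experiment(small_sim_config(false_negative_rate = 0.1,
                                             seed = 78L))
  expect_false(identical(s1$coverage, s3$coverage))
})

test_that("marker classes are placed as configured", {
  sim <- simulate_experiment(small_sim_config(seed = 52L))
  tt <- sim$truth
  per <- table(tt$marker_id[!is.na(tt$clone)])
  singles <- unique(tt$marker_id[tt$class == "unique_single"])
  expect_true(all(per[singles] == 1L))
  twos <- unique(tt$marker_id[tt$class == "unique_two"])
  expect_true(all(per[twos] == 2L))
  for (m in twos) {
    rows <- tt[tt$marker_id == m, ]
    expect_equal(length(unique(rows$contig)), 1L)  # one contig, two clones
  }
  reps <- unique(tt$marker_id[tt$class == "repetitive"])
  for (m in reps) {
    clones <- tt$clone[tt$marker_id == m]
    plates <- sim$scheme$roster$plate[
      match(clones, sim$scheme$roster$clone_id)]
    expect_gte(length(unique(plates)), 6L)  # exceeds the 5-per-dim filter
  }
  offs <- unique(tt$marker_id[tt$class == "off_target"])
  expect_true(all(is.na(tt$clone[tt$marker_id %in% offs])))
})

test_that("false negatives drop covered fractions at the configured rate", {
  rate <- 0.1
  sim <- simulate_experiment(small_sim_config(
    n_markers = c(unique_single = 1000L, unique_two = 0L, repetitive = 0L,
                  off_target = 0L),
    n_clones = 800L, false_negative_rate = rate, seed = 53L))
  # every unique-single marker truly covers 3 pools; dropped rows fall
  # below the 0.8 calling threshold
  n_pairs <- nrow(sim$coverage)
  expect_equal(n_pairs, 3000L)
  dropped <- mean(sim$coverage$covered_fraction < 0.8)
  se <- sqrt(rate * (1 - rate) / n_pairs)
  expect_lt(abs(dropped - rate), 3 * se)
})

test_that("recovery is perfect on noise-free runs and degrades under dropout", {
  sim <- simulate_experiment(small_sim_config(seed = 54L))
  calls <- call_positive_pools(sim$coverage, 0.8, markers = sim$markers,
                               pools = scheme_pools(sim$scheme))
  res <- anchor_all(calls, sim$scheme, sim$map)
  rec <- evaluate_recovery(res$anchors, sim$truth)
  pc <- rec$per_class
  expect_equal(pc$precision[pc$class == "unique_single"], 1.0)
  expect_equal(pc$recall[pc$class == "unique_single"], 1.0)
  expect_equal(pc$recall[pc$class == "unique_two"], 1.0)
  expect_equal(unname(rec$confusion["repetitive", "repetitive"]), 4L)
  expect_equal(unname(rec$confusion["off_target", "no_positive_pool"]), 10L)

  noisy <- simulate_experiment(small_sim_config(
    false_negative_rate = 0.2, seed = 54L))
  ncalls <- call_positive_pools(noisy$coverage, 0.8, markers = noisy$markers,
                                pools = scheme_pools(noisy$scheme))
  nres <- anchor_all(ncalls, noisy$scheme, noisy$map)
  nrec <- evaluate_recovery(nres$anchors, noisy$truth)
  expect_lt(nrec$per_class$recall[nrec$per_class$class == "unique_single"],
            1.0)
})

test_that("forcing one dimension negative turns a marker into no_positive_pool", {
  sim <- simulate_experiment(small_sim_config(seed = 55L))
  calls <- call_positive_pools(sim$coverage, 0.8, markers = sim$markers,
                               pools = scheme_pools(sim$scheme))
  m <- sim$truth$marker_id[sim$truth$class == "unique_single"][1L]
  sig <- positive_pools(calls, m)
  plate_pool <- sig[parse_pool_label(sig)$dimension == "plate"]
  calls$calls[m, plate_pool] <- FALSE
  res <- anchor_all(calls, sim$scheme, sim$map)
  row <- res$anchors[res$anchors$marker_id == m, ]
  expect_equal(row$status, "no_positive_pool")
})

test_that("recovery reports not-applicable precision when nothing anchors", {
  sim <- simulate_experiment(small_sim_config(
    n_markers = c(unique_single = 5L, unique_two = 0L, repetitive = 0L,
                  off_target = 0L), seed = 56L))
  calls <- call_positive_pools(sim$coverage, 0.8, markers = sim$markers,
                               pools = scheme_pools(sim$scheme))
  res <- anchor_all(calls, sim$scheme, sim$map)
  res$anchors$status <- "no_positive_pool"   # pretend total dropout
  res$anchors$anchor_type <- NA_integer_
  res$anchors$clones <- ""
  rec <- evaluate_recovery(res$anchors, sim$truth)
  expect_true(is.na(rec$per_class$precision))
  expect_equal(rec$per_class$recall, 0)
  expect_error(evaluate_recovery(res$anchors[-1, ], sim$truth),
               "different marker universes")
})

test_that("the written bundle round-trips into identical objects", {
  dir <- withr::local_tempdir()
  sim <- simulate_experiment(small_sim_config(seed = 57L), out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "markers.fasta", "roster.tsv", "map.tsv", "fingerprints.tsv",
    "coverage.tsv", "depths.tsv", "truth.tsv")))))
  sch <- read_roster(file.path(dir, "roster.tsv"), n_plates = 10,
                     n_rows = 8, n_cols = 12)
  expect_equal(sch$roster, sim$scheme$roster)
  map <- load_clone_contig_table(file.path(dir, "map.tsv"))
  expect_equal(map$members, sim$map$members)
  markers <- read_markers(file.path(dir, "markers.fasta"))
  expect_equal(markers$length, sim$markers$length)
  cov <- coverage_from_table(file.path(dir, "coverage.tsv"), markers)
  calls1 <- call_positive_pools(sim$coverage, 0.8, markers = sim$markers)
  calls2 <- call_positive_pools(cov, 0.8, markers = markers)
  expect_identical(calls1$calls, calls2$calls)
})

test_that("marker classes exceeding the map are a configuration error", {
  expect_error(simulate_experiment(sim_config(
    n_clones = 5000L, n_plates = 10L)), "exceeds roster capacity")
  expect_error(simulate_experiment(small_sim_config(
    n_clones = 200L, repetitive_copies = 7L)),
    "occupied plates")
})
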