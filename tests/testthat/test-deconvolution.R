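test_that("repetitive filter is strict at more-than-five per dimension", {
  expect_true(filter_repetitive(6, 1, 1))
  expect_false(filter_repetitive(5, 5, 5))
  expect_true(filter_repetitive(10, 16, 24))   # all fifty pools positive
  expect_false(filter_repetitive(0, 0, 0))
  expect_true(filter_repetitive(1, 1, 7, max_per_dim = 5))
  expect_false(filter_repetitive(6, 1, 1, max_per_dim = 6))
})

test_that("a 1-1-1 signature anchors immediately (type 1)", {
  sch <- full_scheme()
  map <- tiny_map("BAC3_6_17", "ctg042")
  res <- deconvolute_marker("m", c("p03", "rF", "c17"), sch, map)
  expect_equal(res$status, "anchored")
  expect_equal(res$anchor_type, 1L)
  expect_equal(res$clones, "BAC3_6_17")
  expect_equal(res$contigs, "ctg042")
})

test_that("missing dimensions and empty wells fall through the cascade", {
  sch <- full_scheme()
  map <- tiny_map("BAC1_1_1", "ctg1")
  # positive in plate and row dimensions only
  res <- deconvolute_marker("m", c("p01", "rA"), sch, map)
  expect_equal(res$status, "no_positive_pool")
  expect_equal(deconvolute_marker("m", character(), sch, map)$status,
               "no_positive_pool")
  # 1-1-1 pointing at an unoccupied well
  roster <- sch$roster[sch$roster$clone_id != "BAC1_1_1", , drop = FALSE]
  sch2 <- pooling_scheme(roster, n_plates = 10)
  res2 <- deconvolute_marker("m", c("p01", "rA", "c01"), sch2, map)
  expect_equal(res2$status, "no_clone_overlap")
  expect_match(res2$flags, "empty_well")
})

test_that("co-contig candidates resolve multi-positive signatures (type 2)", {
  sch <- full_scheme()
  # 2x2x2 signature; exactly two of the eight candidates share ctg328
  map <- tiny_map(c("BAC2_3_5", "BAC4_7_9", "BAC1_1_1"),
                  c("ctg328", "ctg328", "ctg999"))
  pools <- c("p02", "p04", "rC", "rG", "c05", "c09")
  res <- deconvolute_marker("m", pools, sch, map)
  expect_equal(res$status, "anchored")
  expect_equal(res$anchor_type, 2L)
  expect_setequal(strsplit(res$clones, ";")[[1]],
                  c("BAC2_3_5", "BAC4_7_9"))
  expect_equal(res$contigs, "ctg328")
})

test_that("several co-contig groups leave the marker ambiguous", {
  sch <- full_scheme()
  map <- tiny_map(c("BAC2_3_5", "BAC4_7_9", "BAC2_3_9", "BAC4_7_5"),
                  c("ctgA", "ctgA", "ctgB", "ctgB"))
  pools <- c("p02", "p04", "rC", "rG", "c05", "c09")
  res <- deconvolute_marker("m", pools, sch, map)
  expect_equal(res$status, "ambiguous")
  expect_equal(res$clones, "")
})

test_that("end-clone matches rescue candidates from different contigs (type 3)", {
  sch <- full_scheme()
  map <- tiny_map(c("BAC2_3_5", "BAC4_7_9"), c("ctgL", "ctgR"))
  pools <- c("p02", "p04", "rC", "rG", "c05", "c09")
  em <- data.frame(clone_a = "BAC2_3_5", clone_b = "BAC4_7_9",
                   contig_a = "ctgL", contig_b = "ctgR", score = 1e-30,
                   stringsAsFactors = FALSE)
  res <- deconvolute_marker("m", pools, sch, map, end_matches = em)
  expect_equal(res$status, "anchored")
  expect_equal(res$anchor_type, 3L)
  expect_setequal(strsplit(res$contigs, ";")[[1]], c("ctgL", "ctgR"))
  expect_match(res$flags, "merge_suggested")
  # without the end-match table the same signature has no clone overlap
  res2 <- deconvolute_marker("m", pools, sch, map)
  expect_equal(res2$status, "no_clone_overlap")
})

test_that("a shared contig takes precedence over an end-clone match", {
  sch <- full_scheme()
  map <- tiny_map(c("BAC2_3_5", "BAC4_7_9", "BAC2_3_9", "BAC4_7_5"),
                  c("ctgA", "ctgA", "ctgL", "ctgR"))
  em <- data.frame(clone_a = "BAC2_3_9", clone_b = "BAC4_7_5",
                   contig_a = "ctgL", contig_b = "ctgR", score = 1e-30,
                   stringsAsFactors = FALSE)
  res <- deconvolute_marker("m", c("p02", "p04", "rC", "rG", "c05", "c09"),
                            sch, map, end_matches = em)
  expect_equal(res$anchor_type, 2L)
  expect_equal(res$contigs, "ctgA")
})

test_that("repetitive signatures are never assigned clones", {
  sch <- full_scheme()
  map <- tiny_map("BAC1_1_1", "ctg1")
  pools <- c(pool_label("plate", 1:6), "rA", "c01")
  res <- deconvolute_marker("m", pools, sch, map)
  expect_equal(res$status, "repetitive")
  expect_equal(res$clones, "")
})

test_that("deleting one dimension from an anchored signature loses the marker", {
  sim <- simulate_experiment(small_sim_config(seed = 17L))
  calls <- call_positive_pools(sim$coverage, 0.8, markers = sim$markers,
                               pools = scheme_pools(sim$scheme))
  res <- anchor_all(calls, sim$scheme, sim$map)
  anchored <- res$anchors$marker_id[res$anchors$status == "anchored"]
  for (m in anchored[seq_len(min(25L, length(anchored)))]) {
    pools <- positive_pools(calls, m)
    dims <- parse_pool_label(pools)$dimension
    for (d in unique(dims)) {
      mut <- deconvolute_marker(m, pools[dims != d], sim$scheme, sim$map)
      expect_equal(mut$status, "no_positive_pool")
    }
  }
})

test_that("anchor_all summarises statuses over the simulated experiment", {
  sim <- simulate_experiment(small_sim_config(seed = 23L))
  calls <- call_positive_pools(sim$coverage, 0.8, markers = sim$markers,
                               pools = scheme_pools(sim$scheme))
  res <- anchor_all(calls, sim$scheme, sim$map)
  s <- res$summary
  expect_equal(s$n_markers, nrow(sim$markers))
  expect_equal(Reduce(`+`, s$status), s$n_markers)  # cascade is total
  expect_equal(s$status$repetitive, 4L)
  expect_equal(s$status$no_positive_pool, 10L)      # off-target markers
  expect_equal(s$n_detected, s$n_markers - 10L)
  expect_equal(s$status$anchored,
               s$anchor_type$anchor_type_1 + s$anchor_type$anchor_type_2 +
                 s$anchor_type$anchor_type_3)
  bad <- calls
  colnames(bad$calls)[1] <- "zz9"
  expect_error(anchor_all(bad, sim$scheme, sim$map), "pool label")
})

test_that("undersequenced-pool involvement is flagged on results", {
  sch <- full_scheme()
  map <- tiny_map("BAC3_6_17", "ctg042")
  res <- deconvolute_marker("m", c("p03", "rF", "c17"), sch, map,
                            flagged_pools = "p03")
  expect_match(res$flags, "undersequenced_pool")
  res2 <- deconvolute_marker("m", c("p03", "rF", "c17"), sch, map,
                             flagged_pools = "p09")
  expect_false(grepl("undersequenced_pool", res2$flags))
})

test_that("stringency comparison partitions the marker universe", {
  sim <- simulate_experiment(small_sim_config(
    false_negative_rate = 0.2, seed = 31L))
  sweep <- stringency_sweep(sim$coverage, markers = sim$markers,
                            pools = scheme_pools(sim$scheme))
  hi <- anchor_all(sweep[["0.8"]], sim$scheme, sim$map)$anchors
  lo <- anchor_all(sweep[["0.3"]], sim$scheme, sim$map)$anchors
  cmp <- compare_stringencies(hi, lo)
  expect_equal(Reduce(`+`, cmp$counts), nrow(sim$markers))
  expect_equal(sort(unique(cmp$comparison$category)),
               sort(names(cmp$counts)[unlist(cmp$counts) > 0]))
  # identical inputs: every anchored marker is same_contig
  self <- compare_stringencies(hi, hi)
  expect_equal(self$counts$same_contig, sum(hi$status == "anchored"))
  expect_equal(self$counts$different_contig, 0L)
  expect_error(compare_stringencies(hi, lo[-1, ]), "universes differ")
})

test_that("constructed stringency transitions hit the right categories", {
  sch <- full_scheme()
  map <- tiny_map(c("BAC2_3_5", "BAC4_7_9", "BAC2_3_9", "BAC4_7_5"),
                  c("ctgA", "ctgA", "ctgB", "ctgB"))
  # high: clean 1-1-1; low: extra pools create two co-contig groups
  hi <- deconvolute_marker("m1", c("p02", "rC", "c05"), sch, map,
                           threshold = 0.8)
  lo <- deconvolute_marker("m1", c("p02", "p04", "rC", "rG", "c05", "c09"),
                           sch, map, threshold = 0.3)
  cmp <- compare_stringencies(hi, lo)
  expect_equal(cmp$comparison$category, "lost_unambiguity")
  # high: missing row pool; low: row pool recovered
  hi2 <- deconvolute_marker("m1", c("p02", "c05"), sch, map)
  lo2 <- deconvolute_marker("m1", c("p02", "rC", "c05"), sch, map)
  cmp2 <- compare_stringencies(hi2, lo2)
  expect_equal(cmp2$comparison$category, "newly_anchored")
})
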