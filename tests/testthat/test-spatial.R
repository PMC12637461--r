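test_that("follicle-count histogram tabulates distinct follicles with sqrt errors", {
  rec <- make_records(3, lineage_id = 0:2, follicle_id = c(1L, 2L, 3L))
  h <- follicle_count_histogram(rec)
  expect_equal(h$counts[h$k == 1], 3L)
  expect_equal(h$errors[h$k == 1], sqrt(3))
  # distinctness: follicles {2,2,5} -> k = 2
  rec2 <- make_records(3, lineage_id = 0L, follicle_id = c(2L, 2L, 5L))
  h2 <- follicle_count_histogram(rec2)
  expect_equal(h2$k[h2$counts > 0], 2L)
  # ASC/extrafollicular records are not counted
  rec3 <- rbind(rec, make_records(1, umi_id = "A1", lineage_id = 0L,
                                  follicle_id = EXTRAFOLLICULAR,
                                  compartment = "ASC"))
  expect_equal(follicle_count_histogram(rec3)$n_lineages, 3L)
  expect_error(follicle_count_histogram(rec3[4, ]), "intrafollicular")
})

test_that("truncated geometric MLE: degenerate case, grid-search oracle, recovery", {
  expect_equal(fit_truncated_geometric(rep(1L, 10)), 0)
  # oracle: grid search at 1e-4 resolution on counts {1:3, 2:1}
  ks <- c(1L, 1L, 1L, 2L)
  grid <- seq(1e-4, 0.9999, by = 1e-4)
  ll <- vapply(grid, function(p)
    sum((ks - 1) * log(p) + log(1 - p) - log(1 - p^4)), 0)
  p_grid <- grid[which.max(ll)]
  expect_equal(fit_truncated_geometric(ks), p_grid, tolerance = 1e-3)
  # sampling consistency: draws from truncated geometric with p = 0.25
  set.seed(7)
  p0 <- 0.25
  probs <- p0^(0:3) * (1 - p0); probs <- probs / sum(probs)
  draws <- sample(1:4, 1e5, replace = TRUE, prob = probs)
  expect_equal(fit_truncated_geometric(draws), 0.25, tolerance = 0.04)
})

test_that("well-mixed shuffle preserves follicle sizes and totals", {
  sim <- small_sim()
  rec <- sim$records
  wm <- well_mixed_shuffle(rec, n_reps = 5, seed = 1)
  intra <- rec[is_intrafollicular(rec), ]
  expect_equal(sum(wm$observed_counts), length(unique(intra$lineage_id)))
  # every shuffle keeps the total lineage count (histogram sum invariant)
  expect_true(all(rowSums(wm$shuffled_counts) == sum(wm$observed_counts)))
  # n_reps = 0: observed only
  wm0 <- well_mixed_shuffle(rec, n_reps = 0)
  expect_null(wm0$shuffled_mean)
  # single-follicle data: shuffle is the identity
  rec1 <- make_records(6, lineage_id = rep(0:2, 2), follicle_id = 1L)
  wm1 <- well_mixed_shuffle(rec1, n_reps = 3, seed = 1)
  expect_true(all(wm1$shuffled_counts[, 1] == wm1$observed_counts[1]))
})

test_that("shuffle direction: local migration leaves more monofollicular lineages", {
  sim <- small_sim()
  wm <- well_mixed_shuffle(sim$records, n_reps = 30, seed = 3)
  z <- (wm$observed_counts[1] - wm$shuffled_mean[1]) / wm$shuffled_sem[1]
  expect_gt(z, 3)
})

test_that("related pair distances: bookkeeping on tiny hand-built cases", {
  # two related UMIs at identical coordinates in different follicles
  rec <- make_records(6, lineage_id = c(0L, 0L, 1L, 1L, 2L, 2L),
                      follicle_id = c(1L, 2L, 1L, 1L, 2L, 2L),
                      x = c(5, 5, 0, 1, 10, 11), y = 0)
  dd <- related_pair_distances(rec, seed = 1)
  expect_equal(dd$n_related, 1L)
  expect_equal(dd$related, 0)
  # exactly one cross-follicle related pair at distance == intra_median
  rec2 <- make_records(6, lineage_id = c(0L, 0L, 1L, 1L, 2L, 2L),
                       follicle_id = c(1L, 2L, 1L, 1L, 2L, 2L),
                       x = c(0, 1, 0, 1, 10, 11), y = 0)
  dd2 <- related_pair_distances(rec2, seed = 1)
  expect_equal(dd2$related, 1)  # normalized to intra-median 1
  expect_true(dd2$tail_fraction %in% c(0, 1))
  # no qualifying pairs: flagged, not an error
  rec3 <- make_records(4, lineage_id = c(0L, 0L, 1L, 1L),
                       follicle_id = c(1L, 1L, 2L, 2L), x = c(0, 1, 5, 6), y = 0)
  dd3 <- related_pair_distances(rec3, seed = 1)
  expect_equal(dd3$n_related, 0L)
  expect_true(is.na(dd3$tail_fraction))
})

test_that("clonal_only restricts to identical diverged sequences", {
  g <- strrep("ACGT", 25L)
  s <- flip_sites(g, 1:3)  # 3% diverged
  rec <- make_records(4, lineage_id = 0L, v_sequence = c(s, s, g, g),
                      germline_v = g, follicle_id = c(1L, 2L, 1L, 2L),
                      x = c(0, 3, 0, 50), y = 0, root_divergence = c(.03, .03, 0, 0))
  # also needs >=2 records per follicle for a finite normalizer
  rec <- rbind(rec, make_records(2, umi_id = c("Z1", "Z2"), lineage_id = 1L,
                                 follicle_id = c(1L, 2L), x = c(1, 4), y = 0,
                                 germline_v = g, v_sequence = g,
                                 root_divergence = 0))
  dd <- related_pair_distances(rec, clonal_only = TRUE, min_root_div = 0.01,
                               seed = 1)
  expect_equal(dd$n_related, 1L)  # only the s-s cross-follicle pair qualifies
})

test_that("locality vs reentry: related pairs are closer only under the kernel", {
  p <- sim_params(n_follicles = 15, arena_size = 3000, n_lineages = 50,
                  generations = 12, division_prob = 0.6,
                  follicle_capacity = 4000, sample_prob = 0.15,
                  migration_prob = 0.03, locality_scale = 150,
                  burst_prob = 0, asc_prob = 0.01)
  siml <- simulate_tonsil(p, seed = 31)
  simr <- reentry_variant(p, seed = 31)
  ddl <- related_pair_distances(siml$records, seed = 1)
  ddr <- related_pair_distances(simr$records, seed = 1)
  expect_lt(median(ddl$related), median(ddl$background))
  expect_lt(ddl$tail_fraction, 0.25)
  # reentry: related distribution matches background closely
  ks_r <- suppressWarnings(ks.test(ddr$related, ddr$background)$statistic)
  expect_lt(as.numeric(ks_r), 0.35)
})

test_that("cross-section filter drops same-section pairs", {
  rec <- make_records(4, lineage_id = 0L, follicle_id = c(1L, 2L, 1L, 2L),
                      x = c(0, 1, 0, 1), y = c(0, 0, 2, 2),
                      section = c(1L, 1L, 1L, 2L))
  dd_all <- related_pair_distances(rec, seed = 1)
  dd_cs <- related_pair_distances(rec, cross_section_only = TRUE, seed = 1)
  expect_gt(dd_all$n_related, dd_cs$n_related)
  expect_equal(dd_cs$n_related, 2L)  # pairs (1,4) and (2,3)
})
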