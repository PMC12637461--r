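test_that("exponential divergence fit is the sample mean", {
  expect_equal(fit_exponential_divergence(c(0.02, 0.04)), 0.03)
  expect_warning(a <- fit_exponential_divergence(c(0, 0)), "degenerate")
  expect_equal(a, 0)
  expect_error(fit_exponential_divergence(numeric(0)))
  set.seed(3)
  draws <- rexp(1e5, rate = 1 / 0.027)
  expect_equal(fit_exponential_divergence(draws), 0.027, tolerance = 0.02)
})

test_that("pairwise migration curve: closed-form MLE and sentinels", {
  # two independent pairs, both at x = 0.05 (1 mismatch over 20 sites),
  # one cross-follicle: beta = x / ln 2
  g <- strrep("ACGTACGTACGTACGTACGT", 1L)
  s2 <- flip_sites(g, 1)
  rec <- make_records(4, lineage_id = c(0L, 0L, 1L, 1L),
                      v_sequence = c(g, s2, g, s2),
                      follicle_id = c(1L, 2L, 1L, 1L), germline_v = g)
  mc <- pairwise_migration_curve(rec)
  expect_equal(mc$n_pairs, 2L)
  expect_equal(mc$beta, 0.05 / log(2), tolerance = 1e-6)
  # all same-follicle: beta unidentified sentinel
  rec0 <- make_records(2, lineage_id = 0L, v_sequence = c(g, s2),
                       follicle_id = 1L, germline_v = g)
  expect_warning(mc0 <- pairwise_migration_curve(rec0), "Inf|unidentified")
  expect_identical(mc0$beta, Inf)
  # all cross-follicle: lower bound sentinel
  rec1 <- make_records(2, lineage_id = 0L, v_sequence = c(g, s2),
                       follicle_id = c(1L, 2L), germline_v = g)
  expect_warning(mc1 <- pairwise_migration_curve(rec1), "lower")
})

test_that("pairwise curve dedups to unique (sequence, follicle) and distinct pairs", {
  g <- strrep("ACGT", 5L)
  s2 <- flip_sites(g, 1)
  # 3 UMIs of g in follicle 1 + 1 of s2: dedup leaves one pair
  rec <- make_records(4, lineage_id = 0L, v_sequence = c(g, g, g, s2),
                      follicle_id = 1L, germline_v = g)
  mc <- suppressWarnings(pairwise_migration_curve(rec))  # all y = 0 here
  expect_equal(mc$n_pairs, 1L)
  # identical sequences in two follicles form no pair (they are the burst signal)
  rec2 <- make_records(2, lineage_id = 0L, v_sequence = g,
                       follicle_id = c(1L, 2L), germline_v = g)
  mc2 <- pairwise_migration_curve(rec2)
  expect_equal(mc2$n_pairs, 0L)
})

test_that("burst analysis: closed forms and aggregate identity", {
  g <- strrep("ACGT", 25L)
  b1 <- flip_sites(g, 1:3); b2 <- flip_sites(g, 4:6)
  # two size-2 groups, one multifollicular: MLE p solves 1-(1-p)^2 = 1/2
  rec <- make_records(4, lineage_id = c(0L, 0L, 1L, 1L),
                      v_sequence = c(b1, b1, b2, b2), germline_v = g,
                      follicle_id = c(1L, 2L, 3L, 3L),
                      root_divergence = 0.03)
  ba <- clonal_burst_analysis(rec)
  expect_equal(nrow(ba$groups), 2L)
  expect_equal(ba$p_burst, 1 - sqrt(0.5), tolerance = 1e-6)
  expect_equal(ba$aggregate_multifollicular, 0.5)
  # neither multifollicular: p = 0
  rec0 <- make_records(4, lineage_id = c(0L, 0L, 1L, 1L),
                       v_sequence = c(b1, b1, b2, b2), germline_v = g,
                       follicle_id = c(1L, 1L, 3L, 3L), root_divergence = 0.03)
  expect_equal(clonal_burst_analysis(rec0)$p_burst, 0)
  # below-threshold groups are excluded; empty result is flagged
  rec_low <- make_records(2, v_sequence = b1, germline_v = g,
                          follicle_id = 1L, root_divergence = 0.005)
  ba_low <- clonal_burst_analysis(rec_low)
  expect_equal(nrow(ba_low$groups), 0L)
  expect_true(is.na(ba_low$p_burst))
  # aggregate equals the group-count-weighted mean of the per-size curve
  sim <- small_sim()
  bs <- clonal_burst_analysis(sim$records)
  if (nrow(bs$groups) > 0) {
    expect_equal(bs$aggregate_multifollicular,
                 sum(bs$curve$p_multi * bs$curve$n) / sum(bs$curve$n))
  }
})

test_that("bursts inflate the near-zero intercept; burst-free stays near zero", {
  base <- list(n_follicles = 12, n_lineages = 40, generations = 10,
               division_prob = 0.6, follicle_capacity = 3000,
               sample_prob = 0.2, shm_per_division = 0.004,
               migration_prob = 0.05, asc_prob = 0.01, stagger_entry = FALSE)
  p_burst <- do.call(sim_params, c(base, list(burst_prob = 0.1, burst_divisions = 3)))
  p_free <- do.call(sim_params, c(base, list(burst_prob = 0)))
  mcb <- pairwise_migration_curve(simulate_tonsil(p_burst, seed = 17)$records, seed = 1)
  mcf <- pairwise_migration_curve(simulate_tonsil(p_free, seed = 17)$records, seed = 1)
  expect_gt(mcb$intercept_excess, mcf$intercept_excess)
})

test_that("asc_age_trend: ties give 0, monotone gives 1, flags tiny input", {
  rec <- do.call(rbind, lapply(0:3, function(l) {
    r <- make_records(2, umi_id = sprintf("L%d_%d", l, 1:2), lineage_id = l,
                      root_divergence = 0.01 * (l + 1))
    r$follicle_id[2] <- EXTRAFOLLICULAR; r$compartment[2] <- "ASC"
    r
  }))
  # identical ASC fraction everywhere -> correlation 0 by tie convention
  tr <- asc_age_trend(rec)
  expect_equal(tr$rho, 0)
  # monotone: more ASCs for older lineages
  rec2 <- do.call(rbind, lapply(0:3, function(l) {
    n_asc <- l
    r <- make_records(1 + n_asc, umi_id = sprintf("M%d_%d", l, 1:(1 + n_asc)),
                      lineage_id = l, root_divergence = 0.01 * (l + 1))
    if (n_asc > 0) {
      r$follicle_id[-1] <- EXTRAFOLLICULAR; r$compartment[-1] <- "ASC"
    }
    r
  }))
  expect_equal(asc_age_trend(rec2)$rho, 1)
  expect_true(is.na(asc_age_trend(rec[1:4, ])$rho) ||
              length(unique(rec$lineage_id[1:4])) >= 3)
})

test_that("older lineages accumulate more ASC relatives in the simulator", {
  hits <- 0L
  for (s in 1:5) {
    p <- sim_params(n_follicles = 8, n_lineages = 60, generations = 16,
                    division_prob = 0.6, follicle_capacity = 600,
                    sample_prob = 0.25, asc_prob = 0.04, burst_prob = 0,
                    stagger_entry = TRUE)
    sim <- simulate_tonsil(p, seed = 40 + s)
    tr <- asc_age_trend(sim$records)
    if (!is.na(tr$rho) && tr$rho > 0) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
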