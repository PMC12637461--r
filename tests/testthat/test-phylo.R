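test_that("parsimony counts on canonical 4-leaf trees", {
  phy <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(parsimony_labels(
    lineage_tree(0L, phy, c(a = 1L, b = 1L, c = 1L, d = 1L)))$n_migrations, 0L)
  ps1 <- parsimony_labels(lineage_tree(0L, phy, c(a = 1L, b = 1L, c = 2L, d = 2L)))
  expect_equal(ps1$n_migrations, 1L)
  ps2 <- parsimony_labels(lineage_tree(0L, phy, c(a = 1L, b = 2L, c = 1L, d = 2L)))
  expect_equal(ps2$n_migrations, 2L)
  # root tie-break: leaf-majority then smallest follicle id
  ps3 <- parsimony_labels(lineage_tree(0L, phy, c(a = 2L, b = 2L, c = 2L, d = 1L)))
  expect_equal(ps3$root_label, 2L)
  expect_equal(ps2$root_label, 1L)  # 2-2 leaf tie -> smallest id
})

test_that("parsimony equals the exhaustive oracle on random trees", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:8, 1); k <- sample(2:4, 1)
    phy <- ape::rtree(n)
    lf <- setNames(sample.int(k, n, replace = TRUE), phy$tip.label)
    ps <- parsimony_labels(lineage_tree(0L, phy, lf))
    expect_equal(ps$n_migrations, oracle_parsimony(phy, as.integer(lf[phy$tip.label])),
                 info = paste("tree", i))
  }
})

test_that("parsimony count is invariant to child order and branch rescaling", {
  set.seed(12)
  for (i in 1:20) {
    phy <- ape::rtree(7)
    lf <- setNames(sample.int(3, 7, replace = TRUE), phy$tip.label)
    n0 <- parsimony_labels(lineage_tree(0L, phy, lf))$n_migrations
    phy2 <- ape::rotateConstr(phy, rev(phy$tip.label))
    expect_equal(parsimony_labels(lineage_tree(0L, phy2, lf))$n_migrations, n0)
    phy3 <- phy; phy3$edge.length <- phy$edge.length * 7.3
    expect_equal(parsimony_labels(lineage_tree(0L, phy3, lf))$n_migrations, n0)
  }
})

test_that("parsimony errors on unlabeled leaves", {
  phy <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  expect_error(lineage_tree(0L, phy, c(a = 1L, b = 2L)), "unlabeled")
})

test_that("build_tree: cherries, import fidelity, eligibility gates", {
  g <- strrep("ACGT", 25L)
  s1 <- flip_sites(g, 1:2); s2 <- flip_sites(g, 51:54)
  rec <- make_records(2, v_sequence = c(s1, s2), germline_v = g,
                      follicle_id = c(1L, 2L))
  tr <- build_tree(rec, mode = "nj")
  expect_s3_class(tr, "lineage_tree")
  expect_equal(length(tr$phy$tip.label), 2L)
  # cherry branch lengths: la = (d_ab + d_ag - d_bg)/2 etc.
  expect_equal(tr$total_divergence, 0.06, tolerance = 1e-9)
  # import: leaf set and T match the file exactly
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((U1:0.01,U2:0.02):0.005,(U3:0.01,U4:0.03):0.001);", nwk)
  rec4 <- make_records(4, v_sequence = c(flip_sites(g, 1), flip_sites(g, 2),
                                         flip_sites(g, 3), flip_sites(g, 4)),
                       germline_v = g, follicle_id = c(1L, 1L, 2L, 2L))
  ti <- build_tree(rec4, mode = "import", import_phy = nwk)
  expect_setequal(ti$phy$tip.label, rec4$umi_id)
  expect_equal(ti$total_divergence, 0.076)
  # fewer than two distinct sequences: skipped with reason
  rec_same <- make_records(3, v_sequence = g, germline_v = g,
                           follicle_id = c(1L, 2L, 3L))
  sk <- build_tree(rec_same, mode = "nj")
  expect_s3_class(sk, "skipped_lineage")
  expect_match(attr(sk, "skip_reason"), "distinct")
})

test_that("NJ recovers the true topology with ample divergence", {
  set.seed(6)
  wins <- 0L
  for (i in 1:50) {
    true <- ape::rtree(5)
    true$edge.length <- rep(0.08, nrow(true$edge))  # ~8 substitutions / edge
    g <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    # evolve sequences down the tree
    seqs <- character(5 + true$Nnode)
    seqs[6] <- g
    pe <- reorder(true, "postorder")$edge
    for (e in rev(seq_len(nrow(pe)))) {
      parent_seq <- strsplit(seqs[pe[e, 1]], "")[[1]]
      k <- rpois(1, 0.08 * 100)
      seqs[pe[e, 2]] <- paste(gcmigrate:::mutate_sequence(parent_seq, k), collapse = "")
    }
    rec <- make_records(5, umi_id = true$tip.label,
                        v_sequence = seqs[1:5], germline_v = g,
                        follicle_id = seq_len(5))
    rec$sequence <- rec$v_sequence
    built <- build_tree(rec, mode = "nj", germline = g)
    rf <- ape::dist.topo(ape::unroot(built$phy), ape::unroot(true))
    if (rf == 0) wins <- wins + 1L
  }
  expect_gte(wins, 40L)
})

test_that("identical (sequence, follicle) UMIs collapse into weighted leaves", {
  g <- strrep("ACGT", 25L)
  s1 <- flip_sites(g, 1); s2 <- flip_sites(g, 2)
  rec <- make_records(5, v_sequence = c(s1, s1, s1, s2, s1),
                      germline_v = g, follicle_id = c(1L, 1L, 1L, 2L, 2L))
  tr <- build_tree(rec, mode = "nj")
  # s1@f1 (weight 3), s2@f2, s1@f2: 3 leaves
  expect_equal(length(tr$phy$tip.label), 3L)
  expect_setequal(as.integer(tr$leaf_weight), c(3L, 1L, 1L))
})

test_that("extract_migrations: midpoint depth and early flag", {
  phy <- ape::read.tree(text = "((a:0.02,b:0.02):0.02,c:0.001);")
  tr <- lineage_tree(0L, phy, c(a = 1L, b = 2L, c = 1L))
  ps <- parsimony_labels(tr)
  ev <- extract_migrations(tr, ps, early_threshold = 0.01)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$child_label, 2L)
  expect_equal(ev$depth, (0.02 + 0.04) / 2)  # midpoint of b's terminal branch
  expect_false(ev$is_early)
  ev2 <- extract_migrations(tr, ps, depth_at = "child")
  expect_equal(ev2$depth, 0.04)
})

test_that("estimate_rates arithmetic and degenerate cases", {
  mk <- function(n_mig, tot) {
    phy <- ape::read.tree(text = sprintf("(a:%f,b:%f);", tot / 2, tot / 2))
    tr <- lineage_tree(0L, phy, c(a = 1L, b = 2L))
    tr$n_migrations <- n_mig
    tr$events <- data.frame(edge = integer(0))
    tr
  }
  re <- estimate_rates(list(mk(1L, 0.1), mk(2L, 0.1)))
  expect_equal(re$m_global, 15)
  re0 <- estimate_rates(list(mk(0L, 0.1)))
  expect_equal(re0$m_global, 0)
  expect_equal(nrow(re0$per_lineage), 0L)
  tr_zero <- mk(0L, 0); tr_zero$total_divergence <- 0
  expect_error(estimate_rates(list(tr_zero)), "zero")
})

test_that("true-genealogy parsimony reproduces truth event branches when counts agree", {
  sim <- small_sim()
  trees <- small_sim_trees()
  checked <- 0L
  for (tr in trees) {
    entry <- sim$truth$lineages[[tr$lineage_id + 1L]]
    # lineages where the analysis tree is the full truth tree (all leaves
    # intrafollicular, no collapsing) and parsimony count equals truth count
    if (length(tr$phy$tip.label) != length(entry$phy$tip.label)) next
    if (tr$n_migrations != nrow(entry$edge_events)) next
    # node numbering is preserved by the pruning (tips in order, internals
    # ascending, root first), but edge rows may be ordered differently:
    # compare the child nodes of the label-changing edges
    true_children <- sort(entry$phy$edge[unique(entry$edge_events$edge), 2L])
    obs_children <- sort(tr$phy$edge[tr$events$edge, 2L])
    expect_equal(obs_children, true_children)
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("depth stratification conserves branch length and events exactly", {
  trees <- small_sim_trees()
  sr <- stratify_rates(trees, "depth", depth_bin_width = 0.004)
  expect_equal(sum(sr$branch_length),
               sum(vapply(trees, function(t) t$total_divergence, 0)))
  expect_equal(sum(sr$n_events),
               sum(vapply(trees, function(t) t$n_migrations, 0)))
  # single tree with all branch length in one bin
  phy <- ape::read.tree(text = "(a:0.001,b:0.001);")
  tr <- lineage_tree(0L, phy, c(a = 1L, b = 2L))
  tr <- analyze_trees(list(tr))[[1]]
  s1 <- stratify_rates(list(tr), "depth", depth_bin_width = 0.01)
  expect_equal(s1$rate[1], tr$n_migrations / tr$total_divergence)
})

test_that("size strata report per-lineage mean rates with empty strata as NA", {
  trees <- small_sim_trees()
  ss <- stratify_rates(trees, "size", size_breaks = c(2, 4, 8, 16, Inf))
  expect_true(all(is.na(ss$rate[ss$n_lineages == 0])))
  expect_true(all(ss$rate[ss$n_lineages > 0] >= 0))
})

test_that("early filter removes sub-threshold events from downstream stats", {
  trees <- small_sim_trees()
  s_all <- stratify_rates(trees, "depth", depth_bin_width = 0.005)
  s_filt <- stratify_rates(trees, "depth", depth_bin_width = 0.005,
                           early_filter = TRUE)
  n_early <- sum(vapply(trees, function(t) sum(t$events$is_early), 0))
  expect_equal(sum(s_all$n_events) - sum(s_filt$n_events), n_early)
})

test_that("multi-follicle seeding elevates only the shallow depth bins", {
  p <- sim_params(n_follicles = 10, n_lineages = 60, generations = 10,
                  division_prob = 0.6, follicle_capacity = 3000,
                  sample_prob = 0.2, migration_prob = 0.005,
                  shm_per_division = 0.003, burst_prob = 0, asc_prob = 0,
                  pre_gc_expansion = 3L, stagger_entry = FALSE)
  sim <- simulate_tonsil(p, seed = 77)
  bt <- build_lineage_trees(sim$records, "true", truth = sim$truth)
  at <- analyze_trees(bt$trees)
  sr <- stratify_rates(at, "depth", depth_bin_width = 0.01)
  # the sub-1% bin contains the pre-GC seeding signal
  expect_gt(sr$rate[1], 2 * max(0, sr$rate[3], na.rm = TRUE))
})
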