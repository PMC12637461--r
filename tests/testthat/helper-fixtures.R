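# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from disk.

# Hand-built repertoire rows with sensible defaults for unused columns.
make_records <- function(n, umi_id = sprintf("U%d", seq_len(n)),
                         sequence = strrep("ACGT", 5L),
                         v_sequence = sequence, germline_v = sequence,
                         v_call = "V1", j_call = "J1",
                         junction = strrep("TGC", 5L),
                         follicle_id = 1L, compartment = "GC",
                         x = 0, y = 0, section = 1L,
                         lineage_id = 0L, root_divergence = NA_real_) {
  data.frame(umi_id = umi_id, sequence = rep_len(sequence, n),
             v_sequence = rep_len(v_sequence, n),
             germline_v = rep_len(germline_v, n),
             v_call = rep_len(v_call, n), j_call = rep_len(j_call, n),
             junction = rep_len(junction, n),
             follicle_id = rep_len(as.integer(follicle_id), n),
             compartment = rep_len(compartment, n),
             x = rep_len(x, n), y = rep_len(y, n),
             section = rep_len(as.integer(section), n),
             lineage_id = rep_len(as.integer(lineage_id), n),
             root_divergence = rep_len(root_divergence, n),
             stringsAsFactors = FALSE)
}

# Mutate a sequence at specific 1-based positions (cycles A->C->G->T->A).
flip_sites <- function(seq, sites) {
  v <- strsplit(seq, "")[[1L]]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  v[sites] <- nxt[v[sites]]
  paste(v, collapse = "")
}

# A small simulated tonsil reused by several test files (built once per run).
.fixture_env <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    p <- sim_params(n_follicles = 12, n_lineages = 50, generations = 12,
                    division_prob = 0.6, follicle_capacity = 4000,
                    sample_prob = 0.15, migration_prob = 0.02,
                    burst_prob = 0.01, asc_prob = 0.02)
    .fixture_env$sim <- simulate_tonsil(p, seed = 2024)
  }
  .fixture_env$sim
}
small_sim_trees <- function() {
  if (is.null(.fixture_env$trees)) {
    sim <- small_sim()
    bt <- build_lineage_trees(sim$records, "true", truth = sim$truth)
    .fixture_env$trees <- analyze_trees(bt$trees)
  }
  .fixture_env$trees
}

# Exhaustive minimum-cost labelling oracle (vectorized over all internal
# label assignments); independent of the Sankoff/Fitch implementation.
oracle_parsimony <- function(phy, leaf_lab) {
  states <- sort(unique(leaf_lab))
  ntip <- length(phy$tip.label)
  grid <- as.matrix(expand.grid(rep(list(states), phy$Nnode)))
  full <- cbind(matrix(leaf_lab, nrow(grid), ntip, byrow = TRUE), grid)
  changes <- rowSums(full[, phy$edge[, 1L], drop = FALSE] !=
                     full[, phy$edge[, 2L], drop = FALSE])
  min(changes)
}
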