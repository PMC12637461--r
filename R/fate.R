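# Stage 5: post-migration diversification (single-follicle subtree
# decomposition + migration shuffling) and migrant composition of follicles.

#' Decompose a labelled tree into single-follicle subtrees
#'
#' Cuts the tree at every branch whose endpoint labels differ (the migration
#' branches). Each connected component is then local to one follicle; its
#' divergence is the sum of branch lengths strictly inside it (the cut
#' branch's length belongs to neither side, making the conservation identity
#' `sum(subtree divergences) + sum(cut branch lengths) = T` exact).
#' `follows_migration` marks components whose rootward attachment is a cut
#' branch, i.e. the expansion of a lineage in a follicle it migrated into.
#'
#' @param tree a `lineage_tree`.
#' @param labels result of [parsimony_labels()].
#' @return data frame, one row per subtree: `follicle`, `divergence`,
#'   `n_leaves`, `follows_migration`.
#' @export
decompose_subtrees <- function(tree, labels) {
  phy <- tree$phy
  ntot <- length(phy$tip.label) + phy$Nnode
  lab <- labels$labels
  cut <- lab[phy$edge[, 1L]] != lab[phy$edge[, 2L]]
  comp <- seq_len(ntot)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (e in which(!cut)) {
    a <- find(phy$edge[e, 1L]); b <- find(phy$edge[e, 2L])
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(ntot), find, 0L)
  div <- tapply(c(phy$edge.length[!cut]), roots[phy$edge[!cut, 2L]], sum)
  ntips <- length(phy$tip.label)
  leaf_cnt <- table(factor(roots[seq_len(ntips)], levels = unique(roots)))
  comps <- unique(roots)
  root_comp <- roots[ntips + 1L]
  out <- data.frame(
    lineage_id = rep(tree$lineage_id, length(comps)),
    follicle = lab[comps],
    divergence = as.numeric(ifelse(as.character(comps) %in% names(div),
                                   div[as.character(comps)], 0)),
    n_leaves = as.integer(leaf_cnt[as.character(comps)]),
    follows_migration = comps != root_comp)
  out$n_leaves[is.na(out$n_leaves)] <- 0L
  rownames(out) <- NULL
  out
}

#' Shuffle migration-event locations along a tree
#'
#' Places `n_events` cut points uniformly along the tree's total branch length
#' (branch chosen with probability proportional to its length; at most one
#' event per branch, by rejection) and recomputes the divergences of the
#' post-migration components, giving a null in which migration location is
#' independent of subsequent diversification.
#'
#' @param tree a `lineage_tree`.
#' @param n_events number of events to place (>= 1).
#' @param n_reps shuffle replicates.
#' @param seed RNG seed.
#' @return list: `divergences` (list per rep of post-migration component
#'   divergences), `zero_fraction` (fraction of post-migration components
#'   with zero divergence, pooled over reps), `edges_chosen` (matrix).
#' @export
shuffle_migrations <- function(tree, n_events, n_reps = 100L, seed = NULL) {
  phy <- tree$phy
  ne <- nrow(phy$edge)
  if (n_events < 1L) stop("n_events must be >= 1")
  if (n_events > ne) stop("more events (", n_events, ") than branches (", ne, ")")
  with_seed(seed, {
    lens <- phy$edge.length
    divs <- vector("list", n_reps)
    chosen <- matrix(NA_integer_, n_reps, n_events)
    for (r in seq_len(n_reps)) {
      picked <- integer(0)
      while (length(picked) < n_events) {
        e <- sample.int(ne, 1L, prob = lens)
        if (!(e %in% picked)) picked <- c(picked, e)
      }
      chosen[r, ] <- picked
      divs[[r]] <- component_divergences(phy, picked)
    }
    zero_fraction <- mean(unlist(divs) == 0)
    list(divergences = divs, zero_fraction = zero_fraction,
         edges_chosen = chosen)
  })
}

# Divergence of every component that lies below a cut edge (follows a
# migration), cutting the tree at the given edges.
component_divergences <- function(phy, cut_edges) {
  ntot <- length(phy$tip.label) + phy$Nnode
  cut <- logical(nrow(phy$edge)); cut[cut_edges] <- TRUE
  comp <- seq_len(ntot)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (e in which(!cut)) {
    a <- find(phy$edge[e, 1L]); b <- find(phy$edge[e, 2L])
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(ntot), find, 0L)
  comps <- unique(roots)
  div <- setNames(rep(0, length(comps)), comps)
  agg <- tapply(phy$edge.length[!cut], roots[phy$edge[!cut, 2L]], sum)
  div[names(agg)] <- agg
  root_comp <- roots[length(phy$tip.label) + 1L]
  as.numeric(div[names(div) != as.character(root_comp)])
}

#' Observed vs shuffled post-migration divergence distributions
#'
#' Pools, over all trees with at least one migration, the divergences of
#' single-follicle subtrees that immediately follow a migration, for the
#' observed labelling and for migration locations shuffled along each tree.
#'
#' @param trees analyzed trees.
#' @param n_reps shuffle replicates per tree.
#' @param seed RNG seed.
#' @param early_filter drop `is_early` events before decomposing (robustness
#'   variant).
#' @return class `fate_shuffle`: `observed` divergences, `shuffled` (pooled),
#'   per-rep shuffled list, zero-divergence fractions, and the max gap between
#'   the two survival functions with its permutation band.
#' @export
post_migration_divergence <- function(trees, n_reps = 100L, seed = NULL,
                                      early_filter = FALSE) {
  with_seed(seed, {
    obs <- numeric(0)
    shuf_by_rep <- vector("list", n_reps)
    for (tr in trees) {
      ev <- tr$events
      if (early_filter && nrow(ev) > 0L) ev <- ev[!ev$is_early, , drop = FALSE]
      n_ev <- nrow(ev)
      if (n_ev == 0L) next
      if (early_filter) {
        obs_d <- component_divergences(tr$phy, ev$edge)
      } else {
        dec <- decompose_subtrees(tr, tr$parsimony)
        obs_d <- dec$divergence[dec$follows_migration]
      }
      obs <- c(obs, obs_d)
      n_place <- min(n_ev, nrow(tr$phy$edge))
      sh <- shuffle_migrations(tr, n_place, n_reps = n_reps, seed = NULL)
      for (r in seq_len(n_reps))
        shuf_by_rep[[r]] <- c(shuf_by_rep[[r]], sh$divergences[[r]])
    }
    if (length(obs) == 0L) stop("no migration events in any tree")
    shuffled <- unlist(shuf_by_rep)
    grid <- sort(unique(c(obs, shuffled)))
    obs_sf <- survival_on_grid(obs, grid)
    rep_sf <- t(vapply(shuf_by_rep, function(v) survival_on_grid(v, grid),
                       numeric(length(grid))))
    mean_sf <- colMeans(rep_sf)
    rep_gaps <- apply(rep_sf, 1L, function(v) max(abs(v - mean_sf)))
    obs_gap <- max(abs(obs_sf - mean_sf))
    structure(list(observed = obs, shuffled = shuffled,
                   shuffled_by_rep = shuf_by_rep,
                   observed_zero_fraction = mean(obs == 0),
                   shuffled_zero_fraction = mean(shuffled == 0),
                   observed_gap = obs_gap,
                   gap_band_95 = quantile(rep_gaps, 0.95, names = FALSE),
                   grid = grid), class = "fate_shuffle")
  })
}

#' Migrant composition of each follicle
#'
#' A UMI is a migrant when its follicle differs from the parsimony root label
#' of its lineage's tree and, if `min_migration_root_div > 0`, at least one
#' label change on the path from the root to its leaf occurs at depth >= the
#' threshold (robustness variant ignoring apparent migrations that predate
#' GC entry). Lineages without trees are never migrants. Fractions are over
#' intrafollicular UMIs only.
#'
#' @param records repertoire data frame.
#' @param trees analyzed trees.
#' @param min_migration_root_div depth threshold (default 0).
#' @return data frame, one row per follicle: `follicle_id`, `n_umis`,
#'   `migrant_umi_fraction`, `migrant_lineage_fraction`, `top_lineage_freq`,
#'   `top_migrant_freq` (NA when the follicle hosts no migrant lineage).
#' @export
migrant_composition <- function(records, trees, min_migration_root_div = 0) {
  intra <- records[is_intrafollicular(records), , drop = FALSE]
  if (nrow(intra) == 0L) stop("no intrafollicular records")
  intra$migrant <- FALSE
  root_of <- list()
  for (tr in trees) {
    phy <- tr$phy
    lab <- tr$parsimony$labels
    ntot <- length(phy$tip.label) + phy$Nnode
    d <- ape::node.depth.edgelength(phy)
    # qualifying label change anywhere on the root-to-node path
    qual <- logical(ntot)
    E <- reorder(phy, "postorder")$edge
    for (e in rev(seq_len(nrow(E)))) {
      pa <- E[e, 1L]; ch <- E[e, 2L]
      changed <- lab[pa] != lab[ch]
      depth_ok <- (d[pa] + d[ch]) / 2 >= min_migration_root_div
      qual[ch] <- qual[pa] || (changed && depth_ok)
    }
    root_lab <- tr$root_label
    root_of[[as.character(tr$lineage_id)]] <- root_lab
    mig_leaf <- qual[seq_along(phy$tip.label)] &
      tr$leaf_follicle[phy$tip.label] != root_lab
    mig_tips <- phy$tip.label[mig_leaf]
    # every UMI collapsed into a leaf shares its (sequence, follicle), hence
    # its migrant status
    sel <- intra$lineage_id == tr$lineage_id
    key_leaf <- paste(intra$v_sequence, intra$follicle_id, sep = "\r")
    leaf_key <- paste(intra$v_sequence[match(phy$tip.label, intra$umi_id)],
                      tr$leaf_follicle[phy$tip.label], sep = "\r")
    intra$migrant[sel] <- key_leaf[sel] %in% leaf_key[mig_leaf]
  }
  out <- lapply(sort(unique(intra$follicle_id)), function(f) {
    sub <- intra[intra$follicle_id == f, , drop = FALSE]
    lin_tab <- sort(table(sub$lineage_id), decreasing = TRUE)
    lins <- as.integer(names(lin_tab))
    roots <- vapply(lins, function(l) {
      r <- root_of[[as.character(l)]]
      if (is.null(r)) NA_integer_ else as.integer(r)
    }, 0L)
    is_mig_lin <- !is.na(roots) & roots != f
    top_mig <- if (any(is_mig_lin)) max(lin_tab[is_mig_lin]) / nrow(sub) else NA_real_
    data.frame(follicle_id = f, n_umis = nrow(sub),
               migrant_umi_fraction = mean(sub$migrant),
               migrant_lineage_fraction = mean(is_mig_lin),
               top_lineage_freq = as.numeric(lin_tab[1L]) / nrow(sub),
               top_migrant_freq = top_mig)
  })
  do.call(rbind, out)
}
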