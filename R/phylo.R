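# Stage 3: lineage trees, maximum-parsimony follicle labelling, migration
# events, and migration-rate estimation.

#' Construct a lineage tree object
#'
#' @param lineage_id integer id.
#' @param phy rooted `ape::phylo` with branch lengths in substitutions/site.
#' @param leaf_follicle named integer vector: follicle id per tip label.
#' @param leaf_weight named integer vector: UMIs collapsed into each tip
#'   (default 1 each).
#' @return class `lineage_tree` with `total_divergence` precomputed.
#' @export
lineage_tree <- function(lineage_id, phy, leaf_follicle, leaf_weight = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(leaf_weight))
    leaf_weight <- setNames(rep(1L, length(phy$tip.label)), phy$tip.label)
  miss <- setdiff(phy$tip.label, names(leaf_follicle))
  if (length(miss) > 0L)
    stop("unlabeled leaves: ", paste(head(miss, 5L), collapse = ", "))
  structure(list(lineage_id = lineage_id, phy = phy,
                 leaf_follicle = leaf_follicle[phy$tip.label],
                 leaf_weight = leaf_weight[phy$tip.label],
                 total_divergence = sum(phy$edge.length)),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("lineage_tree", x$lineage_id, ":", length(x$phy$tip.label), "leaves,",
      length(unique(x$leaf_follicle)), "follicles, T =",
      format(x$total_divergence, digits = 4), "\n")
  invisible(x)
}

# Convert a phylo to per-node parent/edge-length arrays (0 = root parent).
phylo_arrays <- function(phy) {
  ntot <- length(phy$tip.label) + phy$Nnode
  par <- integer(ntot); elen <- numeric(ntot); eidx <- integer(ntot)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  elen[phy$edge[, 2L]] <- phy$edge.length
  eidx[phy$edge[, 2L]] <- seq_len(nrow(phy$edge))
  list(parent = par, elen = elen, edge_index = eidx,
       n_tip = length(phy$tip.label), root = length(phy$tip.label) + 1L)
}

# Prune a rooted phylo to a subset of tips, keeping the original root and
# collapsing unary internal nodes (summing branch lengths). `node_payload`
# optionally maps old node ids to lists merged onto collapsed edges.
prune_phylo <- function(phy, keep_tips) {
  arr <- phylo_arrays(phy)
  tips <- match(keep_tips, phy$tip.label)
  stopifnot(!anyNA(tips))
  ntot <- length(arr$parent)
  visited <- logical(ntot)
  for (l in tips) {
    i <- l
    while (i != 0L && !visited[i]) { visited[i] <- TRUE; i <- arr$parent[i] }
  }
  vis <- which(visited)
  pv <- arr$parent[vis]; pv <- pv[pv != 0L]
  cc <- table(pv)
  branch_nodes <- as.integer(names(cc)[cc >= 2L])
  keep <- sort(unique(c(tips, branch_nodes, arr$root)))
  inK <- logical(ntot); inK[keep] <- TRUE

  n_tip <- length(tips)
  internal <- c(arr$root, setdiff(setdiff(keep, tips), arr$root))
  node_num <- integer(ntot)
  node_num[tips] <- seq_len(n_tip)
  node_num[internal] <- n_tip + seq_along(internal)

  ne <- length(keep) - 1L
  em <- matrix(0L, ne, 2L); el <- numeric(ne); old_child <- integer(ne)
  r <- 0L
  for (k in setdiff(keep, arr$root)) {
    len <- arr$elen[k]
    i <- arr$parent[k]
    while (!inK[i]) { len <- len + arr$elen[i]; i <- arr$parent[i] }
    r <- r + 1L
    em[r, ] <- c(node_num[i], node_num[k]); el[r] <- len; old_child[r] <- k
  }
  new_phy <- structure(list(edge = em, edge.length = el,
                            tip.label = phy$tip.label[tips],
                            Nnode = length(internal)), class = "phylo")
  list(phy = new_phy, old_child_of_edge = old_child, kept_old_ids = keep)
}

#' Build a lineage tree
#'
#' Builds the rooted phylogeny of one lineage's intrafollicular records, with
#' the germline as rooting outgroup. Leaves are unique (sequence, follicle)
#' combinations (duplicate UMIs collapse into a weighted leaf); lineages with
#' fewer than two genetically distinct intrafollicular sequences are not
#' treeable and return `NULL` with a reason attribute.
#'
#' Modes: `"nj"` reconstructs by neighbor joining on pairwise Hamming
#' divergence (negative branch lengths clamped to 0, rooted by the germline
#' outgroup, which is then removed so its attachment point becomes the root);
#' `"true"` prunes a known genealogy (e.g. from [simulate_tonsil()] truth) to
#' the intrafollicular leaves; `"import"` takes a user-supplied rooted newick
#' tree whose tip labels are `umi_id`s.
#'
#' @param records repertoire rows of one lineage.
#' @param mode `"nj"`, `"true"`, or `"import"`.
#' @param germline germline V sequence (required for `"nj"`).
#' @param true_phy `ape::phylo` genealogy over this lineage's `umi_id`s
#'   (required for `"true"`).
#' @param import_phy rooted `ape::phylo` (or path to a newick file) for
#'   `"import"`.
#' @return a `lineage_tree`, or `NULL` (attribute `"skip_reason"` set).
#' @export
build_tree <- function(records, mode = c("nj", "true", "import"),
                       germline = NULL, true_phy = NULL, import_phy = NULL) {
  mode <- match.arg(mode)
  lid <- records$lineage_id[1L]
  intra <- records[is_intrafollicular(records), , drop = FALSE]
  if (nrow(intra) < 2L) return(structure(list(), class = "skipped_lineage",
                                         skip_reason = "fewer than 2 intrafollicular UMIs",
                                         lineage_id = lid))
  if (length(unique(intra$v_sequence)) < 2L)
    return(structure(list(), class = "skipped_lineage",
                    skip_reason = "fewer than 2 genetically distinct sequences",
                    lineage_id = lid))

  key <- paste(intra$v_sequence, intra$follicle_id, sep = "\r")
  rep_ix <- which(!duplicated(key))
  weight <- as.integer(table(key)[key[rep_ix]])
  tipnames <- intra$umi_id[rep_ix]
  leaf_follicle <- setNames(intra$follicle_id[rep_ix], tipnames)
  leaf_weight <- setNames(weight, tipnames)

  if (mode == "nj") {
    if (is.null(germline) || germline == "") {
      g <- intra$germline_v[1L]
      if (is.na(g) || g == "") stop("germline sequence required for NJ rooting")
      germline <- g
    }
    seqs <- c(intra$v_sequence[rep_ix], germline)
    dm <- divergence_matrix(seqs)
    n <- length(rep_ix)
    if (n == 2L) {
      la <- max(0, (dm[1L, 2L] + dm[1L, 3L] - dm[2L, 3L]) / 2)
      lb <- max(0, (dm[1L, 2L] + dm[2L, 3L] - dm[1L, 3L]) / 2)
      phy <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                            edge.length = c(la, lb),
                            tip.label = tipnames, Nnode = 1L),
                       class = "phylo")
    } else {
      dimnames(dm) <- list(c(tipnames, "__germline__"), c(tipnames, "__germline__"))
      nj <- ape::nj(as.dist(dm))
      nj$edge.length[nj$edge.length < 0] <- 0
      rooted <- ape::root(nj, outgroup = "__germline__", resolve.root = TRUE)
      phy <- ape::drop.tip(rooted, "__germline__")
    }
  } else if (mode == "true") {
    if (is.null(true_phy)) stop("true_phy required for mode 'true'")
    pruned <- prune_phylo(true_phy, tipnames)
    phy <- pruned$phy
  } else {
    phy <- if (is.character(import_phy)) ape::read.tree(import_phy) else import_phy
    if (is.null(phy)) stop("import_phy required for mode 'import'")
    if (!ape::is.rooted(phy)) stop("imported tree must be rooted")
    present <- intersect(phy$tip.label, tipnames)
    if (length(present) < 2L)
      return(structure(list(), class = "skipped_lineage",
                      skip_reason = "imported tree covers <2 treeable leaves",
                      lineage_id = lid))
    if (length(present) < length(phy$tip.label))
      phy <- prune_phylo(phy, present)$phy
  }
  lineage_tree(lid, phy, leaf_follicle, leaf_weight)
}

#' Build trees for every treeable lineage
#'
#' @param records repertoire data frame with `lineage_id`.
#' @param mode tree mode; see [build_tree()].
#' @param truth a `sim_truth` object (required for mode `"true"`).
#' @param import_trees named list of `phylo` objects (or newick paths), names
#'   = lineage ids, for mode `"import"`.
#' @return list with `trees` (lineage_tree list) and `skipped`
#'   (data frame of lineage_id, reason).
#' @export
build_lineage_trees <- function(records, mode = c("nj", "true", "import"),
                                truth = NULL, import_trees = NULL) {
  mode <- match.arg(mode)
  trees <- list(); skipped <- list()
  for (lr in split(records, records$lineage_id)) {
    lid <- lr$lineage_id[1L]
    tp <- NULL; ip <- NULL
    if (mode == "true") {
      if (is.null(truth)) stop("mode 'true' needs a sim_truth object")
      entry <- truth$lineages[[lid + 1L]]
      if (is.null(entry$phy)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(lineage_id = lid, reason = "no genealogy (fewer than 2 sampled)")
        next
      }
      tp <- entry$phy
    }
    if (mode == "import") {
      ip <- import_trees[[as.character(lid)]]
      if (is.null(ip)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(lineage_id = lid, reason = "no imported tree")
        next
      }
    }
    tr <- build_tree(lr, mode = mode, true_phy = tp, import_phy = ip)
    if (inherits(tr, "skipped_lineage")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(lineage_id = lid, reason = attr(tr, "skip_reason"))
    } else {
      trees[[length(trees) + 1L]] <- tr
    }
  }
  list(trees = trees,
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(lineage_id = integer(0), reason = character(0)))
}

#' Maximum-parsimony follicle labels for internal nodes
#'
#' Uniform-cost Sankoff dynamic program (identical to Fitch on binary trees):
#' the migration count `n_migrations` is the minimum number of label changes
#' over all internal labellings. The returned labelling attains the minimum
#' deterministically: the root takes the minimum-cost label (ties broken by
#' most leaves carrying the label, then smallest follicle id) and each child
#' keeps its parent's label whenever that is optimal, otherwise the smallest
#' optimal label.
#'
#' @param tree a `lineage_tree`.
#' @return list: `labels` (follicle id per node, tips first), `n_migrations`,
#'   `root_label`.
#' @export
parsimony_labels <- function(tree) {
  phy <- tree$phy
  leaf_lab <- tree$leaf_follicle[phy$tip.label]
  if (anyNA(leaf_lab))
    stop("unlabeled leaf: ",
         paste(phy$tip.label[is.na(leaf_lab)][1L], collapse = ", "))
  states <- sort(unique(as.integer(leaf_lab)))
  K <- length(states)
  ntip <- length(phy$tip.label); ntot <- ntip + phy$Nnode
  E <- reorder(phy, "postorder")$edge

  cost <- matrix(0, ntot, K)
  cost[seq_len(ntip), ] <- Inf
  cost[cbind(seq_len(ntip), match(leaf_lab, states))] <- 0
  for (e in seq_len(nrow(E))) {
    cc <- cost[E[e, 2L], ]
    cost[E[e, 1L], ] <- cost[E[e, 1L], ] + pmin(cc, min(cc) + 1)
  }
  root <- ntip + 1L
  min_cost <- min(cost[root, ])
  cand <- which(cost[root, ] == min_cost)
  if (length(cand) > 1L) {
    leaf_counts <- tabulate(match(leaf_lab, states), nbins = K)
    cand <- cand[order(-leaf_counts[cand], states[cand])]
  }
  assign <- integer(ntot)
  assign[root] <- cand[1L]
  for (e in rev(seq_len(nrow(E)))) {
    s <- assign[E[e, 1L]]
    opts <- cost[E[e, 2L], ] + (seq_len(K) != s)
    mo <- min(opts)
    assign[E[e, 2L]] <- if (opts[s] == mo) s else which(opts == mo)[1L]
  }
  n_mig <- sum(assign[phy$edge[, 1L]] != assign[phy$edge[, 2L]])
  stopifnot(n_mig == min_cost)  # the constructed labelling is minimum-cost
  list(labels = states[assign], n_migrations = as.integer(min_cost),
       root_label = states[cand[1L]])
}

#' Extract migration events from a labelled tree
#'
#' One event per branch whose endpoint labels differ. Event depth is the
#' divergence from the root to the branch midpoint (the change point within a
#' branch is unidentifiable; the midpoint is the unbiased convention;
#' `depth_at = "child"` uses the child node instead).
#'
#' @param tree a `lineage_tree`.
#' @param labels result of [parsimony_labels()].
#' @param early_threshold depth below which an event is flagged `is_early`
#'   (default 0.01, the pre-GC-entry regime).
#' @param depth_at `"midpoint"` or `"child"`.
#' @return data frame: `edge`, `parent_label`, `child_label`, `depth`,
#'   `is_early`, `branch_length`.
#' @export
extract_migrations <- function(tree, labels, early_threshold = 0.01,
                               depth_at = c("midpoint", "child")) {
  depth_at <- match.arg(depth_at)
  phy <- tree$phy
  d <- ape::node.depth.edgelength(phy)
  lab <- labels$labels
  chg <- which(lab[phy$edge[, 1L]] != lab[phy$edge[, 2L]])
  depth <- if (depth_at == "midpoint")
    (d[phy$edge[chg, 1L]] + d[phy$edge[chg, 2L]]) / 2
  else d[phy$edge[chg, 2L]]
  data.frame(lineage_id = rep(tree$lineage_id, length(chg)),
             edge = chg,
             parent_label = lab[phy$edge[chg, 1L]],
             child_label = lab[phy$edge[chg, 2L]],
             depth = depth, is_early = depth < early_threshold,
             branch_length = phy$edge.length[chg])
}

#' Run parsimony + event extraction on a list of trees
#'
#' @param trees list of `lineage_tree`.
#' @param early_threshold see [extract_migrations()].
#' @return the list with `$parsimony` (labels), `$n_migrations`,
#'   `$root_label`, `$events` attached to each tree.
#' @export
analyze_trees <- function(trees, early_threshold = 0.01) {
  lapply(trees, function(tr) {
    ps <- parsimony_labels(tr)
    tr$parsimony <- ps
    tr$n_migrations <- ps$n_migrations
    tr$root_label <- ps$root_label
    tr$events <- extract_migrations(tr, ps, early_threshold = early_threshold)
    tr
  })
}

#' Global and per-lineage migration-rate estimates
#'
#' `m_global = sum(N_i) / sum(T_i)` is the Poisson MLE of the through-origin
#' line N = m T; per-lineage rates `m_hat_i = N_i / T_i` are reported for
#' lineages with at least one inferred migration. The binned mean-migration
#' curve over the dense region of T comes with the Poisson envelope
#' `mT +/- sqrt(mT)`.
#'
#' @param trees analyzed trees (see [analyze_trees()]).
#' @param n_bins bins for the mean curve.
#' @param dense_quantile upper T quantile defining the dense region.
#' @return class `rate_estimates`: `m_global`, `per_lineage` (data frame),
#'   `curve`, `n_trees`, totals.
#' @export
estimate_rates <- function(trees, n_bins = 8L, dense_quantile = 0.95) {
  if (length(trees) == 0L) stop("no trees supplied")
  N <- vapply(trees, function(t) t$n_migrations, 0L)
  Tv <- vapply(trees, function(t) t$total_divergence, 0)
  lid <- vapply(trees, function(t) t$lineage_id, 0L)
  if (sum(Tv) == 0) stop("total phylogenetic divergence is zero")
  m_global <- sum(N) / sum(Tv)
  sel <- N >= 1L
  per_lineage <- data.frame(lineage_id = lid[sel], n_migrations = N[sel],
                            total_divergence = Tv[sel],
                            m_hat = N[sel] / Tv[sel])
  tmax <- quantile(Tv, dense_quantile, names = FALSE)
  edges <- seq(0, max(tmax, min(Tv) + 1e-9), length.out = n_bins + 1L)
  bin <- findInterval(Tv, edges, rightmost.closed = TRUE)
  curve <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    ix <- which(bin == b)
    if (length(ix) == 0L) return(NULL)
    tm <- mean(Tv[ix])
    data.frame(t_mid = (edges[b] + edges[b + 1L]) / 2, t_mean = tm,
               n_trees = length(ix), mean_migrations = mean(N[ix]),
               poisson_mean = m_global * tm,
               poisson_sd = sqrt(m_global * tm))
  }))
  structure(list(m_global = m_global, per_lineage = per_lineage,
                 curve = curve, n_trees = length(trees),
                 total_migrations = sum(N), total_divergence = sum(Tv)),
            class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat("rate_estimates:", x$n_trees, "trees;", x$total_migrations,
      "migrations over T =", format(x$total_divergence, digits = 4),
      "; m =", format(x$m_global, digits = 4),
      sprintf("= (%.2f%%)^-1\n", 100 / x$m_global))
  invisible(x)
}

#' Migration rates stratified by lineage size or event depth
#'
#' Size strata average per-lineage rates `N_i / T_i` over lineages in each
#' size bin. Depth strata divide the migration events falling in each
#' root-depth bin by the total branch length residing in that bin (branch
#' lengths apportioned to bins by overlap), which conserves both totals
#' exactly. `early_filter` removes events below the early threshold before
#' any statistics.
#'
#' @param trees analyzed trees.
#' @param by `"size"` or `"depth"`.
#' @param size_breaks breaks for UMI-count strata (default powers of 2).
#' @param depth_bin_width width of depth bins in divergence units.
#' @param early_filter drop `is_early` events first.
#' @return data frame of strata with rates and counting errors; empty strata
#'   are reported with `NA` rates, not zero.
#' @export
stratify_rates <- function(trees, by = c("size", "depth"),
                           size_breaks = NULL, depth_bin_width = 0.005,
                           early_filter = FALSE) {
  by <- match.arg(by)
  get_events <- function(tr) {
    ev <- tr$events
    if (early_filter && nrow(ev) > 0L) ev <- ev[!ev$is_early, , drop = FALSE]
    ev
  }
  if (by == "size") {
    size <- vapply(trees, function(t) sum(t$leaf_weight), 0)
    if (is.null(size_breaks))
      size_breaks <- c(2^(1:ceiling(log2(max(size) + 1))), Inf)
    m_hat <- vapply(trees, function(t) nrow(get_events(t)) / t$total_divergence, 0)
    bin <- findInterval(size, size_breaks, left.open = FALSE)
    out <- do.call(rbind, lapply(seq_len(length(size_breaks) - 1L), function(b) {
      ix <- which(bin == b)
      data.frame(stratum = sprintf("[%g,%g)", size_breaks[b], size_breaks[b + 1L]),
                 n_lineages = length(ix),
                 rate = if (length(ix)) mean(m_hat[ix]) else NA_real_,
                 se = if (length(ix) > 1L) sd(m_hat[ix]) / sqrt(length(ix)) else NA_real_)
    }))
    return(out)
  }
  # depth strata
  max_depth <- max(vapply(trees, function(t)
    max(ape::node.depth.edgelength(t$phy)), 0))
  edges <- seq(0, max_depth + depth_bin_width, by = depth_bin_width)
  nb <- length(edges) - 1L
  len_in_bin <- numeric(nb); ev_in_bin <- numeric(nb)
  for (tr in trees) {
    d <- ape::node.depth.edgelength(tr$phy)
    dp <- d[tr$phy$edge[, 1L]]; dc <- d[tr$phy$edge[, 2L]]
    for (b in seq_len(nb)) {
      lo <- edges[b]; hi <- edges[b + 1L]
      ov <- pmax(0, pmin(dc, hi) - pmax(dp, lo))
      len_in_bin[b] <- len_in_bin[b] + sum(ov)
    }
    ev <- get_events(tr)
    if (nrow(ev) > 0L) {
      bv <- pmin(findInterval(ev$depth, edges, rightmost.closed = TRUE), nb)
      bv[bv < 1L] <- 1L
      ev_in_bin <- ev_in_bin + tabulate(bv, nbins = nb)
    }
  }
  data.frame(depth_lo = edges[-length(edges)], depth_hi = edges[-1L],
             branch_length = len_in_bin, n_events = ev_in_bin,
             rate = ifelse(len_in_bin > 0, ev_in_bin / len_in_bin, NA_real_),
             se = ifelse(len_in_bin > 0, sqrt(ev_in_bin) / len_in_bin, NA_real_))
}
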