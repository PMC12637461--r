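# Agent-based synthetic tonsil: germinal-center lineages that divide, mutate,
# migrate between follicles, burst, and differentiate to ASCs, with full
# ground truth (genealogies + migration event log) for parameter recovery.

#' Simulation parameters for the synthetic tonsil
#'
#' Defaults describe the stated world the analysis is validated against:
#' 37 follicles in a 3 mm arena, an SHM rate of 1e-3 substitutions per site
#' per division, and a per-daughter migration probability of 0.02 per division
#' (one migration per 50 divisions, i.e. (5%)^-1 per unit divergence at
#' delta = 1e-3). Lineage founding generations are staggered uniformly so the
#' sampled germline-divergence distribution is an exponential-like mixture of
#' ages, as in real tonsil repertoires.
#'
#' @param n_follicles number of follicles.
#' @param arena_size side of the square arena, micrometres.
#' @param n_lineages number of independent lineages to simulate.
#' @param generations number of synchronous generations G.
#' @param division_prob per-cell per-generation division probability.
#' @param shm_per_division expected substitutions per site per division (delta).
#' @param migration_prob per-division per-daughter migration probability (q).
#' @param locality_scale distance kernel scale for migration destinations
#'   (micrometres); destinations are drawn proportional to
#'   `exp(-distance / locality_scale)` over the other follicles.
#' @param burst_prob per-daughter probability of entering a clonal burst.
#' @param burst_divisions SHM-suppressed divisions per burst.
#' @param asc_prob per-cell per-generation ASC differentiation probability.
#' @param pre_gc_expansion founder cells seeded per lineage (each founder's
#'   follicle drawn uniformly; >1 gives multi-follicle seeding before GC entry).
#' @param sample_prob per-cell detection (sampling) probability.
#' @param v_length simulated V-segment length in sites.
#' @param follicle_capacity carrying capacity (live cells) per follicle per
#'   lineage; excess culled uniformly.
#' @param follicle_radius follicle disk radius, micrometres (coordinate jitter).
#' @param min_separation minimum centroid separation when placing follicles.
#' @param stagger_entry stagger lineage founding generations uniformly on
#'   `0:(generations-1)` so lineage ages vary (default TRUE).
#' @param migration_rate_cv coefficient of variation of a per-lineage gamma
#'   multiplier on `migration_prob` (0 = rate-homogeneous world).
#' @param fitness_cv coefficient of variation of a per-lineage multiplier on
#'   `division_prob` (off by default; the inference never needs it).
#' @param migration_kernel `"local"` (distance kernel) or `"uniform"`
#'   (memory-reentry-like: destination uniform over other follicles).
#' @param junction_length length of the lineage-defining junction segment.
#' @param n_sections number of tissue z-sections to assign UMIs to.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_follicles = 37L, arena_size = 3000, n_lineages = 200L,
                       generations = 30L, division_prob = 0.7,
                       shm_per_division = 0.001, migration_prob = 0.02,
                       locality_scale = 300, burst_prob = 0.02,
                       burst_divisions = 3L, asc_prob = 0.02,
                       pre_gc_expansion = 1L, sample_prob = 0.02,
                       v_length = 300L, follicle_capacity = 2000L,
                       follicle_radius = 100, min_separation = 250,
                       stagger_entry = TRUE, migration_rate_cv = 0,
                       fitness_cv = 0, migration_kernel = c("local", "uniform"),
                       junction_length = 45L, n_sections = 6L) {
  p <- list(n_follicles = as.integer(n_follicles), arena_size = arena_size,
            n_lineages = as.integer(n_lineages),
            generations = as.integer(generations),
            division_prob = division_prob,
            shm_per_division = shm_per_division,
            migration_prob = migration_prob, locality_scale = locality_scale,
            burst_prob = burst_prob, burst_divisions = as.integer(burst_divisions),
            asc_prob = asc_prob, pre_gc_expansion = as.integer(pre_gc_expansion),
            sample_prob = sample_prob, v_length = as.integer(v_length),
            follicle_capacity = as.integer(follicle_capacity),
            follicle_radius = follicle_radius, min_separation = min_separation,
            stagger_entry = isTRUE(stagger_entry),
            migration_rate_cv = migration_rate_cv, fitness_cv = fitness_cv,
            migration_kernel = match.arg(migration_kernel),
            junction_length = as.integer(junction_length),
            n_sections = as.integer(n_sections))
  probs <- c("division_prob", "shm_per_division", "migration_prob",
             "burst_prob", "asc_prob", "sample_prob")
  for (nm in setdiff(probs, "shm_per_division"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  if (p$shm_per_division < 0) stop("shm_per_division must be >= 0")
  if (p$generations < 1L) stop("generations must be >= 1")
  if (p$n_follicles < 1L) stop("n_follicles must be >= 1")
  class(p) <- "sim_params"
  p
}

# Evaluate expr under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Place follicle centroids in the arena
#'
#' Centroids are drawn uniformly with minimum-separation rejection; the result
#' is deterministic per seed.
#'
#' @param n_follicles number of follicles to place.
#' @param arena_size arena side length (micrometres).
#' @param seed RNG seed (optional).
#' @param min_separation minimum pairwise centroid distance.
#' @param max_tries placement attempts per follicle before giving up.
#' @return a `follicle_map` with equispaced ids `1:n_follicles` and
#'   `intra_median = NA` (no member UMIs yet).
#' @export
make_follicle_map <- function(n_follicles, arena_size, seed = NULL,
                              min_separation = 250, max_tries = 5000L) {
  stopifnot(n_follicles >= 1L)
  with_seed(seed, {
    pts <- matrix(NA_real_, n_follicles, 2L)
    for (i in seq_len(n_follicles)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- runif(2L, 0, arena_size)
        if (i == 1L || all(sqrt(rowSums((pts[seq_len(i - 1L), , drop = FALSE] -
                                         matrix(cand, i - 1L, 2L, byrow = TRUE))^2)) >=
                           min_separation)) {
          pts[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place ", n_follicles, " follicles with separation ",
             min_separation, "; increase arena_size")
    }
    structure(list(follicle_ids = seq_len(n_follicles),
                   centroids = cbind(x = pts[, 1L], y = pts[, 2L]),
                   intra_median = NA_real_),
              class = "follicle_map")
  })
}

# Per-source cumulative destination distributions over the other follicles.
destination_cdfs <- function(fmap, locality_scale, kernel) {
  n <- length(fmap$follicle_ids)
  d <- as.matrix(dist(fmap$centroids))
  lapply(seq_len(n), function(s) {
    if (n == 1L) return(numeric(0))
    w <- if (kernel == "local") exp(-d[s, ] / locality_scale) else rep(1, n)
    w[s] <- 0
    cumsum(w / sum(w))
  })
}

# random sequence / mutation helpers -----------------------------------------

.BASES <- c("A", "C", "G", "T")

random_sequence <- function(L) sample(.BASES, L, replace = TRUE)

# Apply k point mutations at uniformly chosen sites (multiple hits allowed).
mutate_sequence <- function(seq_vec, k) {
  if (k == 0L) return(seq_vec)
  sites <- sample.int(length(seq_vec), k, replace = TRUE)
  for (s in sites) seq_vec[s] <- sample(.BASES[.BASES != seq_vec[s]], 1L)
  seq_vec
}

#' Simulate a single B cell lineage
#'
#' Discrete synchronous generations. Each surviving GC cell divides with
#' probability `division_prob`; each daughter acquires
#' `Poisson(shm_per_division * v_length)` substitutions, migrates with
#' probability `migration_prob` to a follicle drawn from the distance kernel,
#' and enters a clonal burst with probability `burst_prob` (then performs
#' `burst_divisions` SHM-free divisions, each daughter still migrating with
#' probability `migration_prob`). Cells differentiate to ASCs with probability
#' `asc_prob` (move to extrafollicular space, stop dividing). Surviving cells
#' are sampled with `sample_prob` into UMI records; the sampled genealogy is
#' returned pruned, with true migration events attached to its edges.
#'
#' @param params a [sim_params()] object.
#' @param fmap a `follicle_map` (see [make_follicle_map()]).
#' @param lineage_id integer id stamped on the output records.
#' @param seed RNG seed (optional; use `NULL` to continue the current stream).
#' @param n_generations override the number of generations (used internally
#'   for staggered entry).
#' @param rate_mult multiplier on `migration_prob` for this lineage.
#' @param fitness_mult multiplier on `division_prob` for this lineage.
#' @return a list: `records` (repertoire rows for sampled cells, or NULL),
#'   `phy` (pruned true genealogy, `ape::phylo`, or NULL if <2 leaves),
#'   `leaf_follicle`, `edge_events` (true migrations on pruned edges),
#'   `true_events` (all migration events in the full genealogy),
#'   `founder_follicles`, `germline` (V-segment germline string),
#'   `n_sampled`.
#' @export
simulate_lineage <- function(params, fmap, lineage_id = 0L, seed = NULL,
                             n_generations = NULL, rate_mult = 1,
                             fitness_mult = 1) {
  with_seed(seed, {
    p <- params
    nF <- length(fmap$follicle_ids)
    cdfs <- destination_cdfs(fmap, p$locality_scale, p$migration_kernel)
    q <- min(1, p$migration_prob * rate_mult)
    if (nF == 1L) q <- 0
    pdiv <- min(1, p$division_prob * fitness_mult)
    lamb <- p$shm_per_division * p$v_length
    G <- if (is.null(n_generations)) p$generations else n_generations

    # genealogy arrays (grow by doubling)
    cap <- 1024L
    par_ <- integer(cap); muts_ <- integer(cap); foll_ <- integer(cap)
    genb_ <- integer(cap); migsrc_ <- rep(NA_integer_, cap)
    n_nodes <- 0L
    grow <- function(need) {
      while (n_nodes + need > cap) {
        cap <<- cap * 2L
        length(par_) <<- cap; length(muts_) <<- cap; length(foll_) <<- cap
        length(genb_) <<- cap
        migsrc_ <<- c(migsrc_, rep(NA_integer_, cap - length(migsrc_)))
      }
    }
    add_nodes <- function(parent, muts, foll, gen, migsrc) {
      k <- length(parent); grow(k)
      ix <- n_nodes + seq_len(k)
      par_[ix] <<- parent; muts_[ix] <<- muts; foll_[ix] <<- foll
      genb_[ix] <<- gen; migsrc_[ix] <<- migsrc
      n_nodes <<- n_nodes + k
      ix
    }

    pick_dest <- function(src) {
      # one uniform draw per migration, inverted through the kernel CDF, so
      # the local and uniform variants consume identical RNG streams
      u <- runif(length(src))
      vapply(seq_along(src), function(j) {
        cdf <- cdfs[[src[j]]]
        min(findInterval(u[j], cdf) + 1L, nF)
      }, 0L)
    }

    # node 1 is a virtual germline root; founder cells are its children, so a
    # sampled leaf is never the root node
    root_foll <- sample.int(nF, 1L)
    root <- add_nodes(0L, 0L, root_foll, 0L, NA_integer_)
    founder_follicles <- root_foll
    if (p$pre_gc_expansion > 1L)
      founder_follicles <- c(root_foll,
                             sample.int(nF, p$pre_gc_expansion - 1L, replace = TRUE))
    alive <- add_nodes(rep(root, p$pre_gc_expansion), 0L, founder_follicles,
                       0L, NA_integer_)
    ascs <- integer(0)
    ev_cell <- integer(0); ev_src <- integer(0); ev_dst <- integer(0); ev_gen <- integer(0)

    spawn <- function(parents, muts, gen) {
      # common daughter bookkeeping: migration + event log
      k <- length(parents)
      src <- foll_[parents]
      mig <- runif(k) < q
      dest <- src
      if (any(mig)) dest[mig] <- pick_dest(src[mig])
      ids <- add_nodes(parents, muts, dest, gen,
                       ifelse(mig & dest != src, src, NA_integer_))
      real <- mig & dest != src
      if (any(real)) {
        ev_cell <<- c(ev_cell, ids[real]); ev_src <<- c(ev_src, src[real])
        ev_dst <<- c(ev_dst, dest[real]); ev_gen <<- c(ev_gen, rep(gen, sum(real)))
      }
      ids
    }

    for (g in seq_len(G)) {
      if (length(alive) == 0L) break
      # 1. ASC differentiation
      to_asc <- runif(length(alive)) < p$asc_prob
      if (any(to_asc)) {
        ascs <- c(ascs, alive[to_asc])
        alive <- alive[!to_asc]
      }
      if (length(alive) == 0L) break
      # 2. division
      divides <- runif(length(alive)) < pdiv
      keep <- alive[!divides]
      parents <- alive[divides]
      new_cells <- integer(0)
      if (length(parents) > 0L) {
        dp <- rep(parents, each = 2L)
        muts <- rpois(length(dp), lamb)
        daughters <- spawn(dp, muts, g)
        # 3. burst entry per daughter
        burst <- runif(length(daughters)) < p$burst_prob
        plain <- daughters[!burst]
        cohort <- daughters[burst]
        if (length(cohort) > 0L && p$burst_divisions > 0L) {
          for (r in seq_len(p$burst_divisions)) {
            bp <- rep(cohort, each = 2L)
            cohort <- spawn(bp, 0L, g)
          }
        }
        new_cells <- c(plain, cohort)
      }
      alive <- c(keep, new_cells)
      # 4. carrying capacity per follicle
      if (length(alive) > p$follicle_capacity) {
        occ <- foll_[alive]
        tab <- table(occ)
        over <- as.integer(names(tab)[tab > p$follicle_capacity])
        if (length(over) > 0L) {
          keep_mask <- rep(TRUE, length(alive))
          for (f in sort(over)) {
            ix <- which(occ == f)
            drop_n <- length(ix) - p$follicle_capacity
            keep_mask[sample(ix, drop_n)] <- FALSE
          }
          alive <- alive[keep_mask]
        }
      }
    }

    # 5. sampling
    samp_gc <- alive[runif(length(alive)) < p$sample_prob]
    samp_asc <- ascs[runif(length(ascs)) < p$sample_prob]
    leaves <- c(samp_gc, samp_asc)
    is_asc_leaf <- c(rep(FALSE, length(samp_gc)), rep(TRUE, length(samp_asc)))
    n_sampled <- length(leaves)

    true_events <- data.frame(lineage_id = rep(lineage_id, length(ev_cell)),
                              cell_id = ev_cell, source = ev_src,
                              destination = ev_dst, generation = ev_gen)
    germline <- random_sequence(p$v_length)
    junction <- paste(random_sequence(p$junction_length), collapse = "")
    v_call <- sprintf("SIMV%02d", sample.int(25L, 1L))
    j_call <- sprintf("SIMJ%d", sample.int(6L, 1L))

    if (n_sampled == 0L) {
      return(list(records = NULL, phy = NULL, leaf_follicle = NULL,
                  edge_events = NULL, true_events = true_events,
                  founder_follicles = founder_follicles,
                  germline = paste(germline, collapse = ""), n_sampled = 0L))
    }

    pruned <- prune_true_genealogy(par_, muts_, migsrc_, foll_, genb_,
                                   leaves, lineage_id)
    umi_ids <- sprintf("L%d_U%d", lineage_id, seq_len(n_sampled))

    # sequences along the pruned genealogy (root = germline)
    seqs <- assign_sequences(pruned, germline)
    leaf_seq <- seqs[seq_len(n_sampled)]

    # coordinates
    foll_leaf <- foll_[leaves]
    xs <- numeric(n_sampled); ys <- numeric(n_sampled)
    gc_ix <- which(!is_asc_leaf)
    if (length(gc_ix) > 0L) {
      ctr <- fmap$centroids[foll_leaf[gc_ix], , drop = FALSE]
      xs[gc_ix] <- ctr[, 1L] + rnorm(length(gc_ix), 0, p$follicle_radius / 2)
      ys[gc_ix] <- ctr[, 2L] + rnorm(length(gc_ix), 0, p$follicle_radius / 2)
    }
    for (i in which(is_asc_leaf)) {
      repeat {
        cand <- runif(2L, 0, p$arena_size)
        dd <- sqrt(rowSums((fmap$centroids -
                            matrix(cand, nrow(fmap$centroids), 2L, byrow = TRUE))^2))
        if (all(dd > p$follicle_radius)) { xs[i] <- cand[1L]; ys[i] <- cand[2L]; break }
      }
    }

    follicle_out <- ifelse(is_asc_leaf, EXTRAFOLLICULAR, foll_leaf)
    records <- data.frame(
      umi_id = umi_ids, sequence = paste0(leaf_seq, junction),
      v_sequence = leaf_seq, germline_v = paste(germline, collapse = ""),
      v_call = v_call, j_call = j_call, junction = junction,
      follicle_id = as.integer(follicle_out),
      compartment = ifelse(is_asc_leaf, "ASC", "GC"),
      x = round(xs, 2L), y = round(ys, 2L),
      section = sample.int(p$n_sections, n_sampled, replace = TRUE),
      lineage_id = lineage_id, root_divergence = NA_real_,
      stringsAsFactors = FALSE)
    records <- compute_root_divergence(records)

    leaf_follicle <- setNames(as.integer(follicle_out), umi_ids)
    phy <- NULL; edge_events <- NULL
    if (n_sampled >= 2L) {
      phy <- pruned$phy
      phy$tip.label <- umi_ids
      phy$edge.length <- pruned$elen_muts / p$v_length
      edge_events <- pruned$edge_events
    }
    list(records = records, phy = phy, leaf_follicle = leaf_follicle,
         edge_events = edge_events, true_events = true_events,
         founder_follicles = founder_follicles,
         germline = paste(germline, collapse = ""), n_sampled = n_sampled)
  })
}

# Prune the full genealogy to the sampled leaves: keep leaves, branch points
# and the root; collapse unary chains, summing mutation counts and carrying
# migration events onto the collapsed edge.
prune_true_genealogy <- function(par_, muts_, migsrc_, foll_, genb_,
                                 leaves, lineage_id) {
  visited <- logical(length(par_))
  for (l in leaves) {
    i <- l
    while (i != 0L && !visited[i]) { visited[i] <- TRUE; i <- par_[i] }
  }
  vis_ids <- which(visited)
  pvec <- par_[vis_ids]
  pvec <- pvec[pvec != 0L]
  child_count <- table(pvec)
  branch_nodes <- as.integer(names(child_count)[child_count >= 2L])
  keep <- sort(unique(c(leaves, branch_nodes, 1L)))
  inK <- logical(length(par_)); inK[keep] <- TRUE

  n_tip <- length(leaves)
  # ape numbering: tips 1..n_tip in 'leaves' order, root n_tip+1, internals after
  internal <- setdiff(keep, leaves)
  internal <- c(1L, setdiff(internal, 1L))  # root (genealogy id 1) first
  # NB: a leaf id could theoretically equal 1 only if the root itself was
  # sampled, which cannot happen (the root always divides or goes unsampled
  # as a non-leaf); guard anyway
  node_num <- integer(length(par_))
  node_num[leaves] <- seq_len(n_tip)
  node_num[internal] <- n_tip + seq_along(internal)

  edges <- matrix(0L, 0L, 2L); elen_muts <- integer(0)
  ev_edge <- integer(0); ev_src <- integer(0); ev_dst <- integer(0); ev_gen <- integer(0)
  for (k in setdiff(keep, 1L)) {
    m <- muts_[k]
    evs_s <- integer(0); evs_d <- integer(0); evs_g <- integer(0)
    if (!is.na(migsrc_[k])) {
      evs_s <- migsrc_[k]; evs_d <- foll_[k]; evs_g <- genb_[k]
    }
    i <- par_[k]
    while (!inK[i]) {
      m <- m + muts_[i]
      if (!is.na(migsrc_[i])) {
        evs_s <- c(evs_s, migsrc_[i]); evs_d <- c(evs_d, foll_[i])
        evs_g <- c(evs_g, genb_[i])
      }
      i <- par_[i]
    }
    edges <- rbind(edges, c(node_num[i], node_num[k]))
    elen_muts <- c(elen_muts, m)
    if (length(evs_s) > 0L) {
      eidx <- nrow(edges)
      # events were collected child-upward; report rootward-first
      ord <- rev(seq_along(evs_s))
      ev_edge <- c(ev_edge, rep(eidx, length(evs_s)))
      ev_src <- c(ev_src, evs_s[ord]); ev_dst <- c(ev_dst, evs_d[ord])
      ev_gen <- c(ev_gen, evs_g[ord])
    }
  }

  phy <- NULL
  if (n_tip >= 2L) {
    phy <- structure(list(edge = edges,
                          edge.length = as.numeric(elen_muts),
                          tip.label = as.character(seq_len(n_tip)),
                          Nnode = length(internal)),
                     class = "phylo")
    attr(phy, "order") <- NULL
  }
  list(phy = phy, edges = edges, elen_muts = elen_muts, n_tip = n_tip,
       n_internal = length(internal),
       root_follicle = foll_[1L],
       edge_events = data.frame(lineage_id = rep(lineage_id, length(ev_edge)),
                                edge = ev_edge,
                                source = ev_src, destination = ev_dst,
                                generation = ev_gen))
}

# Generate sequences for all pruned-tree nodes; returns character vector
# indexed by ape node number (tips first). Root sequence is the germline.
assign_sequences <- function(pruned, germline) {
  n_tot <- pruned$n_tip + pruned$n_internal
  seq_store <- vector("list", n_tot)
  root_num <- pruned$n_tip + 1L
  seq_store[[root_num]] <- germline
  if (nrow(pruned$edges) > 0L) {
    # edges were appended child-by-child in increasing genealogy id, so a
    # parent's edge always precedes its children's edges
    for (e in seq_len(nrow(pruned$edges))) {
      pa <- pruned$edges[e, 1L]; ch <- pruned$edges[e, 2L]
      seq_store[[ch]] <- mutate_sequence(seq_store[[pa]], pruned$elen_muts[e])
    }
  }
  vapply(seq_store, function(s) if (is.null(s)) NA_character_ else paste(s, collapse = ""), "")
}

#' Simulate a full synthetic tonsil
#'
#' Runs `n_lineages` independent lineage simulations on one follicle map and
#' assembles the repertoire table plus a ground-truth object.
#'
#' @param params a [sim_params()] object.
#' @param seed RNG seed.
#' @return a list with `records` (repertoire data frame), `fmap`
#'   (`follicle_map`), and `truth` (class `sim_truth`): per-lineage pruned
#'   genealogies with edge-attached migration events, the full migration event
#'   log, founder follicles, per-lineage rate multipliers and the parameters.
#' @export
simulate_tonsil <- function(params, seed = NULL) {
  with_seed(seed, {
    p <- params
    fmap <- make_follicle_map(p$n_follicles, p$arena_size, seed = NULL,
                              min_separation = p$min_separation)
    g0 <- if (p$stagger_entry && p$generations > 1L)
      sample.int(p$generations, p$n_lineages, replace = TRUE) - 1L
    else rep(0L, p$n_lineages)
    rate_mult <- if (p$migration_rate_cv > 0)
      rgamma(p$n_lineages, shape = 1 / p$migration_rate_cv^2,
             rate = 1 / p$migration_rate_cv^2)
    else rep(1, p$n_lineages)
    fit_mult <- if (p$fitness_cv > 0)
      rgamma(p$n_lineages, shape = 1 / p$fitness_cv^2, rate = 1 / p$fitness_cv^2)
    else rep(1, p$n_lineages)

    sims <- vector("list", p$n_lineages)
    for (i in seq_len(p$n_lineages)) {
      sims[[i]] <- simulate_lineage(p, fmap, lineage_id = i - 1L, seed = NULL,
                                    n_generations = p$generations - g0[i],
                                    rate_mult = rate_mult[i],
                                    fitness_mult = fit_mult[i])
    }
    rec_list <- Filter(Negate(is.null), lapply(sims, `[[`, "records"))
    if (length(rec_list) == 0L)
      stop("no cells sampled in any lineage; increase sample_prob")
    records <- do.call(rbind, rec_list)
    rownames(records) <- NULL

    truth <- structure(list(
      lineages = lapply(sims, function(s)
        list(phy = s$phy, leaf_follicle = s$leaf_follicle,
             edge_events = s$edge_events, founder_follicles = s$founder_follicles,
             germline = s$germline, n_sampled = s$n_sampled)),
      events = do.call(rbind, lapply(sims, `[[`, "true_events")),
      rate_mult = rate_mult, entry_generation = g0, params = p),
      class = "sim_truth")
    list(records = records, fmap = fmap, truth = truth)
  })
}

#' Memory-reentry variant of the tonsil simulation
#'
#' Identical dynamics to [simulate_tonsil()] except migration destinations are
#' drawn uniformly over the other follicles (no locality kernel), emulating
#' apparent migration driven by re-entry from the circulating memory pool.
#' With the same seed and non-binding carrying capacity, genealogies and
#' sequences are identical to the local-kernel run; only migration
#' destinations differ.
#'
#' @inheritParams simulate_tonsil
#' @return as [simulate_tonsil()].
#' @export
reentry_variant <- function(params, seed = NULL) {
  params$migration_kernel <- "uniform"
  simulate_tonsil(params, seed = seed)
}
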