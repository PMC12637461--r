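# Stage 4: is a single Poisson migration rate consistent with the observed
# per-lineage rates? Resampling envelopes, burst filtering, a CV upper bound,
# and the predicted follicle-count distribution.

# Survival function S(x) = fraction of values >= x, evaluated on a grid.
survival_on_grid <- function(values, grid) {
  if (length(values) == 0L) return(rep(NA_real_, length(grid)))
  vapply(grid, function(g) mean(values >= g), 0)
}

#' Poisson resampling envelope for per-lineage migration rates
#'
#' Tests rate homogeneity: migrations are resampled along the observed trees
#' as a Poisson process with a single rate. Following the observed statistic's
#' definition, resampled lineages are kept only if they draw at least one
#' migration; the survival function of their `N_i / T_i` values is tabulated
#' on the grid of observed rates, and the envelope is the mean +/- sd over
#' `n_boot` resamplings. The resampling rate is refit by a fixed point
#' matching the resampled mean total migration count to the observed total
#' (which reduces to `sum(N)/sum(T)` analytically, since conditioning does not
#' change the expected count).
#'
#' @param trees analyzed trees (see [analyze_trees()]); all with `T > 0`.
#' @param n_boot resampling replicates (default 100).
#' @param seed RNG seed.
#' @param tol relative fixed-point tolerance for the rate refit.
#' @return class `homogeneity_result`: `grid`, `observed_survival`,
#'   `envelope_mean`, `envelope_sd`, `m_refit`, `n_boot`,
#'   `fraction_inside` (of grid points with observed inside mean +/- 2 sd),
#'   `observed_rates`.
#' @export
poisson_resample <- function(trees, n_boot = 100L, seed = NULL, tol = 1e-3) {
  N <- vapply(trees, function(t) t$n_migrations, 0L)
  Tv <- vapply(trees, function(t) t$total_divergence, 0)
  keep <- Tv > 0
  N <- N[keep]; Tv <- Tv[keep]
  if (sum(N) == 0L) stop("zero observed migrations: nothing to resample")
  obs_rates <- (N / Tv)[N >= 1L]
  grid <- sort(unique(obs_rates))

  with_seed(seed, {
    # fixed point: resampled E[total N] = m * sum(T) must equal observed total
    m_refit <- sum(N) / sum(Tv)
    for (it in seq_len(50L)) {
      m_new <- m_refit * sum(N) / (m_refit * sum(Tv))
      if (abs(m_new - m_refit) <= tol * m_refit) { m_refit <- m_new; break }
      m_refit <- m_new
    }
    sf <- matrix(NA_real_, n_boot, length(grid))
    for (b in seq_len(n_boot)) {
      Nb <- rpois(length(Tv), m_refit * Tv)
      rb <- (Nb / Tv)[Nb >= 1L]
      sf[b, ] <- survival_on_grid(rb, grid)
    }
    env_mean <- colMeans(sf, na.rm = TRUE)
    env_sd <- apply(sf, 2L, sd, na.rm = TRUE)
    obs_sf <- survival_on_grid(obs_rates, grid)
    # half a survival step of slack absorbs the discreteness of the observed
    # step function at tail grid points where the envelope sd collapses
    eps <- 0.5 / length(obs_rates)
    inside <- obs_sf >= env_mean - 2 * env_sd - eps &
              obs_sf <= env_mean + 2 * env_sd + eps
    structure(list(grid = grid, observed_survival = obs_sf,
                   envelope_mean = env_mean, envelope_sd = env_sd,
                   m_refit = m_refit, n_boot = n_boot,
                   fraction_inside = mean(inside),
                   observed_rates = obs_rates),
              class = "homogeneity_result")
  })
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat("homogeneity_result:", length(x$observed_rates),
      "lineages with >=1 migration; refit m =", format(x$m_refit, digits = 4),
      "; observed survival inside mean+/-2sd at",
      sprintf("%.0f%%", 100 * x$fraction_inside), "of grid points\n")
  invisible(x)
}

#' Filter lineages with putative clonal bursts
#'
#' Excludes lineages that (i) contain a multifollicular clonal group (same V
#' sequence in several follicles; see [clonal_burst_analysis()]) or (ii) have
#' exactly one inferred migration lying on a branch shorter than
#' `short_branch`: both signatures of migration during a burst, which inflates
#' the apparent per-divergence rate.
#'
#' @param trees analyzed trees.
#' @param records repertoire data frame (for the clonal-group criterion).
#' @param min_root_div clonal-group divergence threshold (default 0.01).
#' @param short_branch branch-length threshold (default 0.002
#'   substitutions/site).
#' @return list: `trees` (kept), `excluded` (data frame lineage_id, reason).
#' @export
burst_filter <- function(trees, records, min_root_div = 0.01,
                         short_branch = 0.002) {
  ba <- clonal_burst_analysis(records, min_root_div = min_root_div)
  burst_lineages <- integer(0)
  if (nrow(ba$groups) > 0L) {
    intra <- records[is_intrafollicular(records), , drop = FALSE]
    sp <- split(intra, intra$v_sequence)
    burst_lineages <- unique(unlist(lapply(sp, function(g) {
      if (nrow(g) >= 2L && length(unique(g$follicle_id)) >= 2L &&
          !is.na(g$root_divergence[1L]) && g$root_divergence[1L] >= min_root_div)
        unique(g$lineage_id) else NULL
    })))
  }
  keep <- logical(length(trees)); reason <- character(length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (tr$lineage_id %in% burst_lineages) {
      reason[i] <- "multifollicular clonal group"
    } else if (tr$n_migrations == 1L &&
               tr$events$branch_length[1L] < short_branch) {
      reason[i] <- "single migration on short branch"
    } else keep[i] <- TRUE
  }
  if (!any(keep)) stop("burst filter removed all lineages")
  list(trees = trees[keep],
       excluded = data.frame(
         lineage_id = vapply(trees[!keep], function(t) t$lineage_id, 0L),
         reason = reason[!keep]))
}

#' Upper bound on migration-rate variability across lineages
#'
#' For each coefficient of variation c in `cv_grid`, per-lineage rates are
#' drawn from a gamma law with mean `m_refit` and CV c, migrations resampled
#' as Poisson on the observed trees (conditioned on >= 1), and a
#' Kolmogorov-Smirnov-type maximum gap (standardized pointwise by the
#' simulation spread) computed between each simulated survival function and
#' the mean simulated survival at that c. A value of c
#' is accepted when the observed gap (observed survival vs that mean curve)
#' falls within the central 95% of the simulated gap distribution;
#' `cv_upper` is the largest accepted c.
#'
#' @param trees analyzed trees (>= 20 lineages with a migration recommended).
#' @param cv_grid CVs to test (default `c(0, 0.25, 0.5, 1, 1.5)`).
#' @param n_sim simulations per grid value.
#' @param seed RNG seed.
#' @return class `cv_bound`: `cv_upper`, per-grid table (`cv`, `observed_gap`,
#'   `gap_lo`, `gap_hi`, `accepted`). If accepted values do not bracket
#'   cleanly (non-monotone acceptance), `cv_upper` is still the largest
#'   accepted c and a warning records the bracketing interval.
#' @export
cv_upper_bound <- function(trees, cv_grid = c(0, 0.25, 0.5, 1, 1.5),
                           n_sim = 200L, seed = NULL) {
  N <- vapply(trees, function(t) t$n_migrations, 0L)
  Tv <- vapply(trees, function(t) t$total_divergence, 0)
  keep <- Tv > 0
  N <- N[keep]; Tv <- Tv[keep]
  if (sum(N >= 1L) < 2L) stop("too few lineages with migrations")
  obs_rates <- (N / Tv)[N >= 1L]
  grid <- sort(unique(obs_rates))
  obs_sf <- survival_on_grid(obs_rates, grid)
  m_refit <- sum(N) / sum(Tv)

  with_seed(seed, {
    rows <- lapply(cv_grid, function(cv) {
      sf <- matrix(NA_real_, n_sim, length(grid))
      for (s in seq_len(n_sim)) {
        rates <- if (cv <= 0) rep(m_refit, length(Tv))
        else rgamma(length(Tv), shape = 1 / cv^2, rate = 1 / (cv^2 * m_refit))
        Nb <- rpois(length(Tv), rates * Tv)
        rb <- (Nb / Tv)[Nb >= 1L]
        sf[s, ] <- survival_on_grid(rb, grid)
      }
      mean_sf <- colMeans(sf, na.rm = TRUE)
      # KS-type max gap, standardized pointwise by the simulation spread so
      # tail deviations carry their proper weight
      sd_sf <- pmax(apply(sf, 2L, sd, na.rm = TRUE), 1e-3)
      gaps <- apply(sf, 1L, function(v) max(abs(v - mean_sf) / sd_sf, na.rm = TRUE))
      obs_gap <- max(abs(obs_sf - mean_sf) / sd_sf)
      hi <- quantile(gaps, 0.975, names = FALSE)
      lo <- quantile(gaps, 0.025, names = FALSE)
      data.frame(cv = cv, observed_gap = obs_gap, gap_lo = lo, gap_hi = hi,
                 accepted = obs_gap <= hi)
    })
    tab <- do.call(rbind, rows)
    acc <- tab$cv[tab$accepted]
    if (length(acc) == 0L) {
      warning("no CV value on the grid accepted; grid may be too coarse")
      cv_upper <- NA_real_
    } else {
      cv_upper <- max(acc)
      if (any(!tab$accepted & tab$cv < cv_upper))
        warning("non-monotone acceptance across the CV grid; bracketing interval [",
                min(acc), ", ", cv_upper, "]")
    }
    structure(list(cv_upper = cv_upper, table = tab, m_refit = m_refit),
              class = "cv_bound")
  })
}

#' @export
print.cv_bound <- function(x, ...) {
  cat("cv_bound: largest CV consistent with the data =",
      format(x$cv_upper, digits = 3), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Predicted follicle-count distribution under homogeneous Poisson migration
#'
#' Each treeable lineage draws `N ~ Poisson(m * T)` migrations, each assumed
#' to reach a new follicle, so its predicted follicle count is `N + 1`;
#' lineages without trees (fewer than two unique sequences) contribute count
#' 1. Averaged over `n_boot` replicates with SEM. The number of lineages is
#' conserved exactly in every replicate.
#'
#' @param records repertoire data frame with `lineage_id` (defines the full
#'   lineage set, including untreeable ones).
#' @param trees analyzed trees.
#' @param m_hat Poisson rate (migrations per unit divergence).
#' @param n_boot replicates.
#' @param seed RNG seed.
#' @param k_cap largest follicle count tracked separately.
#' @return class `predicted_follicle_counts`: `k`, `mean_counts`, `sem`,
#'   `n_lineages`, plus the observed histogram for comparison.
#' @export
predict_follicle_counts <- function(records, trees, m_hat, n_boot = 100L,
                                    seed = NULL, k_cap = 10L) {
  intra <- records[is_intrafollicular(records), , drop = FALSE]
  all_lineages <- unique(intra$lineage_id)
  tree_lid <- vapply(trees, function(t) t$lineage_id, 0L)
  Tv <- vapply(trees, function(t) t$total_divergence, 0)
  n_no_tree <- length(setdiff(all_lineages, tree_lid))
  with_seed(seed, {
    counts <- matrix(0, n_boot, k_cap)
    for (b in seq_len(n_boot)) {
      k_tree <- pmin(rpois(length(Tv), m_hat * Tv) + 1L, k_cap)
      tab <- tabulate(k_tree, nbins = k_cap)
      tab[1L] <- tab[1L] + n_no_tree
      counts[b, ] <- tab
    }
    obs <- follicle_count_histogram(records)
    obs_counts <- rep(0L, k_cap)
    kk <- pmin(obs$k, k_cap)
    for (i in seq_along(obs$k)) obs_counts[kk[i]] <- obs_counts[kk[i]] + obs$counts[i]
    structure(list(k = seq_len(k_cap),
                   mean_counts = colMeans(counts),
                   sem = apply(counts, 2L, sd) / sqrt(n_boot),
                   n_lineages = length(all_lineages),
                   observed_counts = obs_counts,
                   per_rep_total = rowSums(counts)),
              class = "predicted_follicle_counts")
  })
}
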