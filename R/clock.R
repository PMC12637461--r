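# Stage 2: the somatic-hypermutation clock -- divergence distributions, the
# pairwise migration-vs-divergence curve, and clonal-burst multifollicularity.

#' Exponential fit to a divergence distribution
#'
#' MLE of the exponential scale alpha (the sample mean) for germline
#' divergences of intrafollicular cells.
#'
#' @param divs numeric vector of divergences, all `>= 0`.
#' @return alpha-hat. All-zero input returns 0 with a warning (degenerate fit).
#' @export
fit_exponential_divergence <- function(divs) {
  if (length(divs) == 0L) stop("no divergences supplied")
  if (any(divs < 0)) stop("divergences must be >= 0")
  a <- mean(divs)
  if (a == 0) warning("all divergences are zero: degenerate exponential fit")
  a
}

# Bernoulli MLE of P(y=1 | x) = 1 - exp(-x / beta).
fit_beta_mle <- function(x, y, lower = 1e-6, upper = 5) {
  if (all(y == 0)) {
    warning("no cross-follicle pairs: beta is unidentified (returning Inf)")
    return(Inf)
  }
  if (all(y == 1)) {
    warning("all pairs cross-follicle: beta at lower search bound")
    return(lower)
  }
  nll <- function(beta) {
    p <- -expm1(-x / beta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * (-x / beta))
  }
  optimize(nll, c(lower, upper), tol = 1e-10)$minimum
}

#' Pairwise migration probability as a function of divergence
#'
#' For every pair of distinct unique V(D)J sequences within the same lineage
#' (intrafollicular records, deduplicated to unique (sequence, follicle)
#' combinations before pairing), records the pairwise V-gene divergence x and
#' whether the two sequences lie in different follicles. A Bernoulli MLE fits
#' `P(different follicle) = 1 - exp(-x / beta)`; `intercept_excess` is the
#' migration probability among near-zero-divergence pairs, which a pure
#' Poisson clock would send to 0 and clonal bursts inflate.
#'
#' @param records repertoire data frame with `lineage_id`.
#' @param near_zero_edge divergence below which pairs count toward the
#'   intercept (default 0.005).
#' @param bin_width width of display bins (default 0.005).
#' @param max_pairs_per_lineage cap on pairs drawn per lineage (seeded
#'   subsample above the cap).
#' @param fit_mode `"mle"` (Bernoulli MLE on raw pairs, default) or
#'   `"binned_ls"` (least squares on the binned curve, for comparison).
#' @param seed RNG seed for subsampling.
#' @return class `migration_curve`: raw pair table (`x`, `y`), `beta`,
#'   `intercept_excess`, binned curve with counting errors, `n_pairs`.
#' @export
pairwise_migration_curve <- function(records, near_zero_edge = 0.005,
                                     bin_width = 0.005,
                                     max_pairs_per_lineage = 1e4,
                                     fit_mode = c("mle", "binned_ls"),
                                     seed = NULL) {
  fit_mode <- match.arg(fit_mode)
  with_seed(seed, {
    intra <- records[is_intrafollicular(records), , drop = FALSE]
    if (nrow(intra) == 0L) stop("no intrafollicular records")
    xs <- numeric(0); ys <- integer(0)
    for (ix in split(seq_len(nrow(intra)), intra$lineage_id)) {
      # dedup to unique (sequence, follicle) combinations
      key <- paste(intra$v_sequence[ix], intra$follicle_id[ix], sep = "\r")
      ix <- ix[!duplicated(key)]
      if (length(ix) < 2L) next
      seqs <- intra$v_sequence[ix]
      dm <- divergence_matrix(seqs)
      cmb <- which(upper.tri(dm), arr.ind = TRUE)
      # pairs of *distinct* sequences only
      distinct <- seqs[cmb[, 1L]] != seqs[cmb[, 2L]]
      cmb <- cmb[distinct, , drop = FALSE]
      if (nrow(cmb) == 0L) next
      if (nrow(cmb) > max_pairs_per_lineage)
        cmb <- cmb[sample.int(nrow(cmb), max_pairs_per_lineage), , drop = FALSE]
      xs <- c(xs, dm[cmb])
      ys <- c(ys, as.integer(intra$follicle_id[ix][cmb[, 1L]] !=
                             intra$follicle_id[ix][cmb[, 2L]]))
    }
    if (length(xs) == 0L) {
      return(structure(list(x = xs, y = ys, beta = NA_real_,
                            intercept_excess = NA_real_, curve = NULL,
                            n_pairs = 0L), class = "migration_curve"))
    }
    edges <- seq(0, max(xs) + bin_width, by = bin_width)
    bin <- findInterval(xs, edges, rightmost.closed = TRUE)
    nb <- tabulate(bin, nbins = length(edges) - 1L)
    kb <- vapply(seq_len(length(edges) - 1L), function(b) sum(ys[bin == b]), 0)
    curve <- data.frame(x_mid = (edges[-1L] + edges[-length(edges)]) / 2,
                        n = nb, k = kb,
                        p = ifelse(nb > 0L, kb / nb, NA_real_),
                        err = ifelse(nb > 0L, sqrt(pmax(kb, 1)) / nb, NA_real_))
    beta <- if (fit_mode == "mle") {
      fit_beta_mle(xs, ys)
    } else {
      cc <- curve[curve$n > 0L, ]
      optimize(function(b) sum((cc$p - (-expm1(-cc$x_mid / b)))^2),
               c(1e-6, 5), tol = 1e-10)$minimum
    }
    near <- xs < near_zero_edge
    intercept_excess <- if (any(near)) mean(ys[near]) else NA_real_
    structure(list(x = xs, y = ys, beta = beta,
                   intercept_excess = intercept_excess, curve = curve,
                   n_pairs = length(xs)), class = "migration_curve")
  })
}

#' @export
print.migration_curve <- function(x, ...) {
  cat("migration_curve:", x$n_pairs, "same-lineage pairs; beta =",
      format(x$beta, digits = 4), "; intercept excess =",
      format(x$intercept_excess, digits = 3), "\n")
  invisible(x)
}

# Bernoulli MLE of P(multifollicular | size s) = 1 - (1-p)^s.
fit_pburst_mle <- function(size, multi) {
  if (all(multi == 0)) return(0)
  if (all(multi == 1)) {
    warning("all clonal groups multifollicular: p_burst at upper bound")
    return(1 - 1e-9)
  }
  nll <- function(p) {
    pm <- 1 - (1 - p)^size
    pm <- pmin(pmax(pm, 1e-12), 1 - 1e-12)
    -sum(multi * log(pm) + (1 - multi) * size * log(1 - p))
  }
  optimize(nll, c(1e-9, 1 - 1e-9), tol = 1e-10)$minimum
}

#' Clonal bursts and their multifollicularity
#'
#' A clonal burst group is a V sequence, at least `min_root_div` diverged from
#' its germline ancestor, appearing at least twice among intrafollicular UMIs.
#' The per-size probability of spanning multiple follicles is fit with the
#' independent-migration model `P(multi | size) = 1 - (1-p)^size`, whose MLE
#' `p_burst` estimates the per-UMI migration probability during a burst.
#'
#' @param records repertoire data frame.
#' @param min_root_div minimum germline divergence for a group (default 0.01).
#' @return class `burst_analysis`: `groups` (one row per clonal group: size,
#'   number of follicles, multifollicular flag, root divergence), per-size
#'   curve, `p_burst`, `aggregate_multifollicular`. No qualifying groups is
#'   flagged by zero rows, not an error.
#' @export
clonal_burst_analysis <- function(records, min_root_div = 0.01) {
  intra <- records[is_intrafollicular(records), , drop = FALSE]
  if (nrow(intra) == 0L) stop("no intrafollicular records")
  sp <- split(seq_len(nrow(intra)), intra$v_sequence)
  rows <- lapply(sp, function(ix) {
    if (length(ix) < 2L) return(NULL)
    rd <- intra$root_divergence[ix[1L]]
    if (is.na(rd) || rd < min_root_div) return(NULL)
    nf <- length(unique(intra$follicle_id[ix]))
    data.frame(size = length(ix), n_follicles = nf,
               multifollicular = nf >= 2L, root_div = rd)
  })
  groups <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(groups))
    groups <- data.frame(size = integer(0), n_follicles = integer(0),
                         multifollicular = logical(0), root_div = numeric(0))
  rownames(groups) <- NULL
  if (nrow(groups) == 0L) {
    return(structure(list(groups = groups, curve = NULL, p_burst = NA_real_,
                          aggregate_multifollicular = NA_real_),
                     class = "burst_analysis"))
  }
  sizes <- sort(unique(groups$size))
  curve <- data.frame(
    size = sizes,
    n = vapply(sizes, function(s) sum(groups$size == s), 0L),
    p_multi = vapply(sizes, function(s) mean(groups$multifollicular[groups$size == s]), 0))
  p_burst <- fit_pburst_mle(groups$size, as.integer(groups$multifollicular))
  structure(list(groups = groups, curve = curve, p_burst = p_burst,
                 aggregate_multifollicular = mean(groups$multifollicular)),
            class = "burst_analysis")
}

#' @export
print.burst_analysis <- function(x, ...) {
  cat("burst_analysis:", nrow(x$groups), "clonal groups; p_burst =",
      format(x$p_burst, digits = 3), "; aggregate multifollicular fraction =",
      format(x$aggregate_multifollicular, digits = 3), "\n")
  invisible(x)
}

# Spearman rank correlation implemented from first principles (rank transform
# with average ties, then product-moment).
rank_correlation <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  if (sd(ra) == 0 || sd(rb) == 0) return(0)
  cor(ra, rb)
}

#' Lineage age versus ASC output
#'
#' For each lineage with at least one intrafollicular member, pairs the median
#' intrafollicular germline divergence (an age proxy) with the fraction of the
#' lineage's sampled cells that are extrafollicular ASCs; older lineages are
#' expected to have terminally differentiated more.
#'
#' @param records repertoire data frame with `lineage_id`.
#' @return class `asc_age_trend`: per-lineage data frame (`median_div`,
#'   `asc_fraction`) and `rho` (rank correlation; `NA` with <3 lineages).
#' @export
asc_age_trend <- function(records) {
  stopifnot(!anyNA(records$lineage_id))
  intra_mask <- is_intrafollicular(records)
  lins <- sort(unique(records$lineage_id[intra_mask]))
  rows <- lapply(lins, function(l) {
    sel <- records$lineage_id == l
    n_intra <- sum(sel & intra_mask)
    n_asc <- sum(sel & records$compartment == "ASC")
    data.frame(lineage_id = l,
               median_div = median(records$root_divergence[sel & intra_mask]),
               asc_fraction = n_asc / (n_asc + n_intra))
  })
  df <- do.call(rbind, rows)
  rho <- if (nrow(df) < 3L) NA_real_ else rank_correlation(df$median_div, df$asc_fraction)
  structure(list(lineages = df, rho = rho), class = "asc_age_trend")
}
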