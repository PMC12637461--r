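# Stage 1: lineage sharing across follicles, well-mixed null, and spatial
# locality of related pairs.

#' Distribution of follicles per lineage
#'
#' Tabulates, over intrafollicular records only, how many distinct follicles
#' each lineage is detected in. Bin errors are counting errors (sqrt of the
#' bin count).
#'
#' @param records repertoire data frame with `lineage_id` assigned.
#' @return class `follicle_count_histogram`: `k` (follicle counts), `counts`,
#'   `errors`, `n_lineages`.
#' @export
follicle_count_histogram <- function(records) {
  intra <- records[is_intrafollicular(records), , drop = FALSE]
  if (nrow(intra) == 0L) stop("no intrafollicular records")
  per_lin <- tapply(intra$follicle_id, intra$lineage_id,
                    function(f) length(unique(f)))
  tab <- table(factor(per_lin, levels = seq_len(max(per_lin))))
  structure(list(k = as.integer(names(tab)), counts = as.integer(tab),
                 errors = sqrt(as.integer(tab)),
                 n_lineages = length(per_lin)),
            class = "follicle_count_histogram")
}

#' Truncated geometric fit to the follicle-count distribution
#'
#' Conditional maximum-likelihood fit of `P(k) ~ p^(k-1) (1-p)` restricted to
#' `k <= k_max` (the exponential-decay regime, before the heavy tail of very
#' widespread lineages).
#'
#' @param hist a `follicle_count_histogram`, or a vector of per-lineage
#'   follicle counts.
#' @param k_max truncation point (default 4, the fit range used for tonsil
#'   data).
#' @return the MLE of `p`.
#' @export
fit_truncated_geometric <- function(hist, k_max = 4L) {
  if (inherits(hist, "follicle_count_histogram")) {
    keep <- hist$k <= k_max
    ks <- hist$k[keep]; ns <- hist$counts[keep]
  } else {
    ks0 <- hist[hist <= k_max]
    if (length(ks0) == 0L) stop("no lineages with k <= k_max")
    tb <- table(ks0); ks <- as.integer(names(tb)); ns <- as.integer(tb)
  }
  if (sum(ns) == 0L) stop("no lineages with k <= k_max")
  if (all(ks[ns > 0L] == 1L)) return(0)
  nll <- function(p) {
    # truncated likelihood: P(k | k <= k_max) = p^(k-1)(1-p) / (1 - p^k_max)
    -sum(ns * ((ks - 1) * log(p) + log(1 - p) - log(1 - p^k_max)))
  }
  opt <- optimize(nll, c(1e-9, 1 - 1e-9), tol = 1e-9)
  opt$minimum
}

#' Well-mixed shuffle null for lineage-follicle association
#'
#' Permutes follicle labels uniformly among intrafollicular UMIs (follicle
#' sizes preserved exactly) and tabulates, for the observed data and each
#' shuffle, the per-lineage follicle-count histogram and the distribution of
#' per-lineage UMI counts conditioned on follicle count k.
#'
#' @param records repertoire data frame with `lineage_id`.
#' @param n_reps number of shuffles (0 = observed only).
#' @param seed RNG seed.
#' @param k_cap largest follicle count tracked separately (higher pooled).
#' @return class `well_mixed_shuffle`: observed histogram, matrix of shuffled
#'   histograms (`n_reps` x k), their mean and SEM, and conditional UMI-count
#'   summaries (mean UMI count per lineage given k, observed and shuffled).
#' @export
well_mixed_shuffle <- function(records, n_reps = 100L, seed = NULL, k_cap = 10L) {
  with_seed(seed, {
    intra <- records[is_intrafollicular(records), , drop = FALSE]
    if (nrow(intra) == 0L) stop("no intrafollicular records")
    lin <- intra$lineage_id
    foll <- intra$follicle_id

    tab_k <- function(f) {
      per_lin_k <- tapply(f, lin, function(x) length(unique(x)))
      per_lin_n <- tapply(f, lin, length)
      kk <- pmin(per_lin_k, k_cap)
      counts <- tabulate(kk, nbins = k_cap)
      mean_n <- vapply(seq_len(k_cap), function(k) {
        v <- per_lin_n[kk == k]
        if (length(v) == 0L) NA_real_ else mean(v)
      }, 0)
      list(counts = counts, mean_umis = mean_n)
    }

    obs <- tab_k(foll)
    shuf_counts <- matrix(NA_real_, n_reps, k_cap)
    shuf_mean_umis <- matrix(NA_real_, n_reps, k_cap)
    if (n_reps > 0L) {
      for (r in seq_len(n_reps)) {
        s <- tab_k(sample(foll))
        shuf_counts[r, ] <- s$counts
        shuf_mean_umis[r, ] <- s$mean_umis
      }
    }
    sem <- function(m) apply(m, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))
    })
    structure(list(
      k = seq_len(k_cap),
      observed_counts = obs$counts,
      observed_mean_umis = obs$mean_umis,
      shuffled_counts = shuf_counts,
      shuffled_mean = if (n_reps > 0L) colMeans(shuf_counts) else NULL,
      shuffled_sem = if (n_reps > 0L) sem(shuf_counts) else NULL,
      shuffled_mean_umis = if (n_reps > 0L) colMeans(shuf_mean_umis, na.rm = TRUE) else NULL,
      n_reps = n_reps), class = "well_mixed_shuffle")
  })
}

#' Distances between related cross-follicle pairs
#'
#' Collects XY Euclidean distances for pairs of UMIs in the same lineage but
#' different follicles, normalized by the median within-follicle pair distance,
#' and compares them to a background of all cross-follicle pairs regardless of
#' lineage. `tail_fraction` is the fraction of related pairs at least as far
#' apart as the median background (unrelated) pair -- the statistic that
#' separates local migration from memory-cell re-entry.
#'
#' @param records repertoire data frame with coordinates and `lineage_id`.
#' @param min_root_div with `clonal_only`, minimum germline divergence of the
#'   identical sequence (default 0).
#' @param clonal_only restrict related pairs to identical sequences (clonal
#'   pairs) with `root_divergence >= min_root_div`.
#' @param background_cap maximum number of background pairs sampled.
#' @param cross_section_only restrict both related and background pairs to
#'   records on different tissue sections (robustness control).
#' @param seed RNG seed for the background subsample.
#' @return class `distance_distribution`: `related` and `background`
#'   normalized distances, `normalizer` (intra-follicle median, micrometres),
#'   `tail_fraction`, `n_related`. Empty related set is flagged via
#'   `n_related = 0`, not an error.
#' @export
related_pair_distances <- function(records, min_root_div = 0,
                                   clonal_only = FALSE,
                                   background_cap = 1e6,
                                   cross_section_only = FALSE, seed = NULL) {
  with_seed(seed, {
    intra <- records[is_intrafollicular(records), , drop = FALSE]
    if (nrow(intra) == 0L) stop("no intrafollicular records")
    fmap <- compute_follicle_map(intra)
    normalizer <- fmap$intra_median

    pair_ok <- function(i, j) {
      keep <- intra$follicle_id[i] != intra$follicle_id[j]
      if (cross_section_only) keep <- keep & intra$section[i] != intra$section[j]
      keep
    }
    pd <- function(i, j) sqrt((intra$x[i] - intra$x[j])^2 + (intra$y[i] - intra$y[j])^2)

    # related pairs: same lineage, different follicles
    rel <- numeric(0)
    for (ix in split(seq_len(nrow(intra)), intra$lineage_id)) {
      if (length(ix) < 2L) next
      if (clonal_only) {
        ix <- ix[intra$root_divergence[ix] >= min_root_div]
        if (length(ix) < 2L) next
      }
      cmb <- combn(ix, 2L)
      i <- cmb[1L, ]; j <- cmb[2L, ]
      if (clonal_only) {
        same_seq <- intra$v_sequence[i] == intra$v_sequence[j]
        i <- i[same_seq]; j <- j[same_seq]
      }
      keep <- pair_ok(i, j)
      rel <- c(rel, pd(i[keep], j[keep]))
    }

    # background: subsampled cross-follicle pairs, any lineage
    n <- nrow(intra)
    want <- min(background_cap, n * (n - 1) / 2)
    bg <- numeric(0)
    tries <- 0L
    while (length(bg) < want && tries < 20L) {
      m <- ceiling((want - length(bg)) * 1.6)
      i <- sample.int(n, m, replace = TRUE)
      j <- sample.int(n, m, replace = TRUE)
      ok <- i != j & pair_ok(i, j)
      bg <- c(bg, pd(i[ok], j[ok]))
      tries <- tries + 1L
    }
    if (length(bg) > want) bg <- bg[seq_len(want)]

    rel_n <- rel / normalizer
    bg_n <- bg / normalizer
    tail_fraction <- if (length(rel_n) > 0L && length(bg_n) > 0L)
      mean(rel_n >= median(bg_n)) else NA_real_
    structure(list(related = rel_n, background = bg_n,
                   normalizer = normalizer, tail_fraction = tail_fraction,
                   n_related = length(rel_n)),
              class = "distance_distribution")
  })
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("distance_distribution:", x$n_related, "related cross-follicle pairs;",
      "tail fraction", format(x$tail_fraction, digits = 3),
      "(vs 0.5 under re-entry)\n")
  invisible(x)
}
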