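#' gcmigrate: B cell migration between germinal-center follicles
#'
#' Tools to quantify B cell migration between germinal-center (GC) follicles
#' from spatially resolved BCR heavy-chain repertoires. The package covers the
#' full analysis chain: lineage clustering, somatic-hypermutation divergence
#' clocks, maximum-parsimony migration inference on lineage phylogenies,
#' Poisson rate-homogeneity testing, post-migration fate analysis, and an
#' agent-based synthetic tonsil simulator with complete ground truth.
#'
#' @importFrom stats median optimize quantile rbinom rpois rnorm runif rgamma
#'   rexp sd cor setNames aggregate rmultinom dist reorder
#' @importFrom utils read.delim write.table head tail combn
#' @importFrom ape nj root drop.tip read.tree write.tree is.rooted
#'   node.depth.edgelength
#' @keywords internal
"_PACKAGE"

#' Sentinel follicle id for extrafollicular records
#'
#' Records located outside all follicles (including antibody-secreting cells,
#' ASCs) carry this follicle id. In the on-disk TSV dialect it is written as
#' the token `"EF"`; an empty cell means *missing*, which is different.
#' @export
EXTRAFOLLICULAR <- -1L

.EF_TOKEN <- "EF"

.REPERTOIRE_COLS <- c("umi_id", "sequence", "v_sequence", "germline_v",
                      "v_call", "j_call", "junction", "follicle_id",
                      "compartment", "x", "y", "section", "lineage_id",
                      "root_divergence")

.COMPARTMENTS <- c("GC", "ASC", "OTHER")

#' Is a record intrafollicular?
#'
#' @param records repertoire data frame.
#' @return logical vector: `TRUE` for records inside a follicle.
#' @export
is_intrafollicular <- function(records) {
  !is.na(records$follicle_id) & records$follicle_id != EXTRAFOLLICULAR
}

#' Read a repertoire table
#'
#' Reads the tab-separated UMI-level repertoire dialect: one row per sequenced
#' molecule (UMI) with heavy-chain V(D)J sequence, V-segment sequence, germline
#' V, V/J gene calls, junction, follicle assignment (`"EF"` for
#' extrafollicular), compartment (`GC`/`ASC`/`OTHER`), XY coordinates in
#' micrometres, tissue-section index and optional lineage id / precomputed
#' germline divergence.
#'
#' @param path path to a tab-separated file with a header row.
#' @return a `data.frame` with one row per UMI. Rows lacking both `germline_v`
#'   and `root_divergence` are counted in `attr(, "n_missing_germline")`.
#' @export
read_repertoire_table <- function(path) {
  if (!file.exists(path)) stop("repertoire table not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    na.strings = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "")
  if (nrow(raw) == 0L) stop("empty repertoire table: ", path)
  missing_cols <- setdiff(c("umi_id", "sequence", "follicle_id", "compartment",
                            "x", "y"), names(raw))
  if (length(missing_cols) > 0L)
    stop("repertoire table missing required columns: ",
         paste(missing_cols, collapse = ", "))

  n <- nrow(raw)
  out <- data.frame(umi_id = raw$umi_id, sequence = toupper(raw$sequence),
                    stringsAsFactors = FALSE)
  get_chr <- function(col) if (col %in% names(raw)) raw[[col]] else rep("", n)
  out$v_sequence <- toupper(get_chr("v_sequence"))
  out$germline_v <- toupper(get_chr("germline_v"))
  out$v_call <- get_chr("v_call")
  out$j_call <- get_chr("j_call")
  out$junction <- toupper(get_chr("junction"))

  parse_num <- function(col, what) {
    v <- get_chr(col)
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad) > 0L)
      stop(sprintf("row %d: malformed value '%s' in column '%s'",
                   bad[1L], v[bad[1L]], what))
    num
  }
  out$x <- parse_num("x", "x")
  out$y <- parse_num("y", "y")
  sec <- parse_num("section", "section")
  out$section <- ifelse(is.na(sec), 1L, as.integer(sec))

  fid <- get_chr("follicle_id")
  foll <- rep(NA_integer_, n)
  is_ef <- fid == .EF_TOKEN
  foll[is_ef] <- EXTRAFOLLICULAR
  rest <- !is_ef & fid != ""
  fnum <- suppressWarnings(as.integer(fid[rest]))
  if (anyNA(fnum))
    stop(sprintf("row %d: malformed value '%s' in column 'follicle_id'",
                 which(rest)[which(is.na(fnum))[1L]],
                 fid[rest][which(is.na(fnum))[1L]]))
  foll[rest] <- fnum
  out$follicle_id <- foll

  comp <- get_chr("compartment")
  bad_comp <- which(!(comp %in% .COMPARTMENTS))
  if (length(bad_comp) > 0L)
    stop(sprintf("row %d: unknown compartment '%s'",
                 bad_comp[1L], comp[bad_comp[1L]]))
  out$compartment <- comp

  lin <- get_chr("lineage_id")
  out$lineage_id <- suppressWarnings(as.integer(ifelse(lin == "", NA, lin)))
  rd <- get_chr("root_divergence")
  out$root_divergence <- suppressWarnings(as.numeric(ifelse(rd == "", NA, rd)))
  if (any(!is.na(out$root_divergence) &
          (out$root_divergence < 0 | out$root_divergence > 1)))
    stop("root_divergence outside [0, 1]")

  attr(out, "n_missing_germline") <-
    sum(out$germline_v == "" & is.na(out$root_divergence))
  out
}

#' Write a repertoire table
#'
#' Inverse of [read_repertoire_table()]: deterministic formatting (coordinates
#' with 2 decimals, divergences with 6), so read-then-write round-trips
#' byte-identically.
#'
#' @param records repertoire data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repertoire_table <- function(records, path) {
  fmt_num <- function(v, digits) ifelse(is.na(v), "", sprintf(paste0("%.", digits, "f"), v))
  fid <- ifelse(is.na(records$follicle_id), "",
                ifelse(records$follicle_id == EXTRAFOLLICULAR, .EF_TOKEN,
                       as.character(records$follicle_id)))
  out <- data.frame(
    umi_id = records$umi_id,
    sequence = records$sequence,
    v_sequence = records$v_sequence,
    germline_v = records$germline_v,
    v_call = records$v_call,
    j_call = records$j_call,
    junction = records$junction,
    follicle_id = fid,
    compartment = records$compartment,
    x = fmt_num(records$x, 2L),
    y = fmt_num(records$y, 2L),
    section = ifelse(is.na(records$section), "", as.character(records$section)),
    lineage_id = ifelse(is.na(records$lineage_id), "", as.character(records$lineage_id)),
    root_divergence = fmt_num(records$root_divergence, 6L),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "")
  invisible(path)
}

#' Pairwise nucleotide divergence between two aligned sequences
#'
#' Hamming divergence over positions where both sequences carry an unambiguous
#' base (A/C/G/T). Positions with ambiguity codes (including N and gaps) are
#' excluded from numerator and denominator.
#'
#' @param a,b equal-length pre-aligned nucleotide strings.
#' @return fraction of mismatching comparable positions.
#' @export
pairwise_divergence <- function(a, b) {
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (length(av) != length(bv))
    stop("pairwise_divergence: sequences have different lengths (",
         length(av), " vs ", length(bv), ")")
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("pairwise_divergence: zero comparable positions")
  sum(av[ok] != bv[ok]) / sum(ok)
}

# Divergence matrix over a character vector of equal-length sequences.
# Vectorized via one-hot crossproducts; ambiguous bases drop out of both the
# match count and the comparable-site count.
divergence_matrix <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) stop("divergence_matrix: unequal sequence lengths")
  m <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
              nrow = n, ncol = L, byrow = TRUE)
  onehot <- matrix(0L, n, 4L * L)
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(bases)) {
    idx <- which(m == bases[k], arr.ind = TRUE)
    onehot[cbind(idx[, 1L], (idx[, 2L] - 1L) * 4L + k)] <- 1L
  }
  valid <- matrix(as.integer(m %in% bases), n, L)
  matches <- tcrossprod(onehot)
  comparable <- tcrossprod(valid)
  if (any(comparable == 0))
    stop("divergence_matrix: a sequence pair has zero comparable positions")
  d <- 1 - matches / comparable
  d[d < 0] <- 0
  d
}

#' Divergence of each record from its inferred germline ancestor
#'
#' Returns the precomputed `root_divergence` when present; otherwise computes
#' [pairwise_divergence()] between `v_sequence` and `germline_v` and stores it
#' on the record. This is the somatic-hypermutation clock reading used
#' throughout the analysis.
#'
#' @param records repertoire data frame.
#' @return `records` with `root_divergence` filled in.
#' @export
compute_root_divergence <- function(records) {
  todo <- which(is.na(records$root_divergence))
  if (length(todo) == 0L) return(records)
  missing <- todo[records$germline_v[todo] == "" | records$v_sequence[todo] == ""]
  if (length(missing) > 0L)
    stop("no germline_v or root_divergence for UMIs: ",
         paste(head(records$umi_id[missing], 5L), collapse = ", "))
  records$root_divergence[todo] <- vapply(
    todo, function(i) pairwise_divergence(records$v_sequence[i],
                                          records$germline_v[i]), 0)
  records
}

#' Cluster records into clonal lineages
#'
#' Single-linkage clonal grouping in the style standard for heavy-chain-only
#' repertoires: two records are linked iff they share V gene, J gene and
#' junction length, and their junction Hamming identity is at least
#' `junction_identity_min`. Lineage ids are dense from 0 and invariant to input
#' row order (records are canonically sorted before union-find).
#'
#' @param records repertoire data frame with `v_call`, `j_call`, `junction`.
#' @param junction_identity_min minimum junction identity to link (default 0.85).
#' @param require_same_vj gate linkage on identical V and J calls (default TRUE).
#' @return `records` with `lineage_id` assigned; records missing a junction are
#'   given singleton lineages and counted in `attr(, "n_missing_junction")`.
#' @export
cluster_lineages <- function(records, junction_identity_min = 0.85,
                             require_same_vj = TRUE) {
  n <- nrow(records)
  key_order <- order(records$v_call, records$j_call, nchar(records$junction),
                     records$junction, records$sequence, records$umi_id)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }

  has_junction <- !is.na(records$junction) & records$junction != ""
  idx <- key_order[has_junction[key_order]]
  if (length(idx) > 1L) {
    grp_key <- if (require_same_vj)
      paste(records$v_call[idx], records$j_call[idx], nchar(records$junction[idx]), sep = "\r")
    else as.character(nchar(records$junction[idx]))
    for (members in split(idx, grp_key)) {
      m <- length(members)
      if (m < 2L) next
      juncs <- records$junction[members]
      # exact duplicates first: link identical junctions trivially
      dup_of <- match(juncs, juncs)
      for (k in which(dup_of != seq_len(m))) union_(members[k], members[dup_of[k]])
      uniq <- which(dup_of == seq_len(m))
      if (length(uniq) > 1L) {
        L <- nchar(juncs[1L])
        cm <- matrix(unlist(strsplit(juncs[uniq], "", fixed = TRUE)),
                     nrow = length(uniq), byrow = TRUE)
        for (i in seq_len(length(uniq) - 1L)) {
          same <- colSums(t(cm[(i + 1L):length(uniq), , drop = FALSE]) == cm[i, ]) / L
          hits <- which(same >= junction_identity_min)
          for (h in hits) union_(members[uniq[i]], members[uniq[i + h]])
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  # dense ids, numbered in canonical order for order-invariance
  first_seen <- roots[key_order]
  ids <- setNames(seq_along(unique(first_seen)) - 1L, unique(first_seen))
  records$lineage_id <- as.integer(ids[as.character(roots)])
  attr(records, "n_missing_junction") <- sum(!has_junction)
  records
}

#' Summarize lineages
#'
#' @param records repertoire data frame with `lineage_id`.
#' @return data frame with one row per lineage: member counts, number of
#'   distinct follicles among intrafollicular members, ASC count.
#' @export
lineage_summary <- function(records) {
  stopifnot(!anyNA(records$lineage_id))
  intra <- is_intrafollicular(records)
  lin <- sort(unique(records$lineage_id))
  n_umis <- as.integer(table(factor(records$lineage_id, levels = lin)))
  n_intra <- as.integer(table(factor(records$lineage_id[intra], levels = lin)))
  n_asc <- as.integer(table(factor(records$lineage_id[records$compartment == "ASC"],
                                   levels = lin)))
  nf <- integer(length(lin))
  sp <- split(records$follicle_id[intra], factor(records$lineage_id[intra], levels = lin))
  nf <- vapply(sp, function(f) length(unique(f)), 0L)
  data.frame(lineage_id = lin, n_umis = n_umis, n_umis_intra = n_intra,
             n_follicles = as.integer(nf), n_asc = n_asc)
}

#' Build a follicle map from observed records
#'
#' Centroid of each follicle is the mean of its members' XY coordinates; the
#' normalizer `intra_median` is the median Euclidean distance between all pairs
#' of UMIs lying in the same follicle.
#'
#' @param records repertoire data frame.
#' @return an object of class `follicle_map`: `follicle_ids`, `centroids`
#'   (matrix), `intra_median` (micrometres).
#' @export
compute_follicle_map <- function(records) {
  intra <- records[is_intrafollicular(records), , drop = FALSE]
  if (nrow(intra) == 0L) stop("no intrafollicular records")
  ids <- sort(unique(intra$follicle_id))
  cx <- tapply(intra$x, factor(intra$follicle_id, levels = ids), mean)
  cy <- tapply(intra$y, factor(intra$follicle_id, levels = ids), mean)
  d_all <- unlist(lapply(split(seq_len(nrow(intra)), intra$follicle_id), function(ix) {
    if (length(ix) < 2L) return(numeric(0))
    as.numeric(dist(cbind(intra$x[ix], intra$y[ix])))
  }))
  structure(list(follicle_ids = ids,
                 centroids = cbind(x = as.numeric(cx), y = as.numeric(cy)),
                 intra_median = if (length(d_all)) median(d_all) else NA_real_),
            class = "follicle_map")
}

#' @export
print.follicle_map <- function(x, ...) {
  cat("follicle_map:", length(x$follicle_ids), "follicles; intra-follicle median distance",
      format(x$intra_median, digits = 4), "um\n")
  invisible(x)
}
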