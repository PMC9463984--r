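#' Inter-subject correlation of temporal features
#'
#' For each atom, how consistent its time course is across subjects. The
#' default leave-one-out variant correlates each subject's time course
#' with the mean time course of all other subjects, giving one ISC value
#' per atom per subject; `"pairwise"` instead averages each subject's
#' Pearson correlations with every other subject. Per-layer summaries
#' average over atoms (per subject) and then over subjects (group mean and
#' SD), the aggregation used when comparing layers. Atoms with a constant
#' time course in any series involved are recorded as `NA` and excluded
#' from the summaries with a warning.
#'
#' @param features_per_subject list (length >= 2) of equal-sized
#'   time x q matrices, one per subject.
#' @param method `"loo"` (default) or `"pairwise"`.
#' @return object of class `isc_report`: `values` (subjects x atoms
#'   matrix), `subject_means`, `mean`, `sd`, `method`.
#' @export
isc <- function(features_per_subject, method = c("loo", "pairwise")) {
  method <- match.arg(method)
  stopifnot(is.list(features_per_subject), length(features_per_subject) >= 2)
  dims <- vapply(features_per_subject, dim, integer(2))
  if (!all(dims == dims[, 1]))
    stop("dimension error: subjects' feature matrices differ in shape")
  n <- length(features_per_subject)
  q <- ncol(features_per_subject[[1]])
  vals <- matrix(NA_real_, n, q)
  for (j in seq_len(q)) {
    series <- vapply(features_per_subject, function(f) f[, j],
                     numeric(nrow(features_per_subject[[1]])))
    sds <- apply(series, 2L, stats::sd)
    if (any(sds == 0)) next                        # left NA, warned below
    for (s in seq_len(n)) {
      vals[s, j] <- if (method == "loo") {
        stats::cor(series[, s], rowMeans(series[, -s, drop = FALSE]))
      } else {
        mean(stats::cor(series[, s], series[, -s, drop = FALSE]))
      }
    }
  }
  if (anyNA(vals))
    warning("constant time course(s): ", sum(colSums(is.na(vals)) > 0),
            " atom(s) excluded from ISC summaries")
  subject_means <- rowMeans(vals, na.rm = TRUE)
  structure(list(values = vals, subject_means = subject_means,
                 mean = mean(subject_means), sd = stats::sd(subject_means),
                 method = method),
            class = "isc_report")
}

#' @export
print.isc_report <- function(x, ...) {
  cat("<isc_report> ", nrow(x$values), " subjects x ", ncol(x$values),
      " atoms (", x$method, "): mean ", signif(x$mean, 3),
      " (SD ", signif(x$sd, 3), ")\n", sep = "")
  invisible(x)
}

#' Spatial correlation coefficient between two maps
#'
#' Pearson correlation over voxels between two spatial maps (computed on
#' z-scored values; correlation is invariant to the z-scoring, which is
#' kept for interpretability). Symmetric, in \[-1, 1\].
#'
#' @param zg,zd numeric vectors of equal length (group- and
#'   individual-level map values per voxel).
#' @return scalar correlation.
#' @export
scc <- function(zg, zd) {
  if (length(zg) != length(zd))
    stop("dimension error: maps have different lengths")
  if (stats::sd(zg) == 0 || stats::sd(zd) == 0)
    stop("undefined value: constant map has no spatial correlation")
  stats::cor(zg, zd)
}

#' Binarize a spatial map by z threshold
#'
#' Z-scores the map (population convention) and keeps voxels with
#' `z > cutoff` on the positive side — the activation set used by the
#' overlap rate. The cutoff is recorded on the result.
#'
#' @param map numeric vector; `cutoff` z threshold (default 1.96).
#' @return logical vector with attributes `cutoff` and `sign`.
#' @export
binarize_map <- function(map, cutoff = 1.96) {
  mu <- mean(map)
  sd_pop <- sqrt(mean(map^2) - mu^2)
  if (sd_pop == 0) stop("undefined value: constant map cannot be thresholded")
  z <- (map - mu) / sd_pop
  structure(z > cutoff, cutoff = cutoff, sign = "positive")
}

#' Spatial overlap rate R(S, T)
#'
#' Fraction of the reference network's voxels also present in the other
#' network: `|S intersect T| / |T|`, with `S` the individual-level and `T`
#' the corresponding group-level binary map. Deliberately asymmetric —
#' it asks how much of the group network the individual network covers.
#'
#' @param S,T logical vectors of equal length (see [binarize_map()]).
#' @return scalar in \[0, 1\].
#' @export
overlap_rate <- function(S, T) {
  if (length(S) != length(T))
    stop("dimension error: maps have different lengths")
  nT <- sum(T)
  if (nT == 0) stop("undefined value: reference network T is empty")
  sum(S & T) / nT
}

#' Match atoms between two spatial map sets
#'
#' One-to-one assignment between the rows of two map matrices maximizing
#' the total absolute spatial correlation, solved exactly as a linear
#' assignment problem. Needed when comparing trained maps against ground
#' truth or another model; between the two stages of the same model the
#' identity assignment applies by construction and no matching is needed.
#' With unequal atom counts a partial assignment of `min(qa, qb)` pairs is
#' returned (the smaller set is fully matched).
#'
#' @param maps_a,maps_b numeric matrices with one row per atom and a
#'   common number of voxel columns (or `spatial_maps` layers).
#' @return data frame with columns `a`, `b`, `scc` (signed correlation of
#'   each matched pair), ordered by `a`.
#' @export
match_atoms <- function(maps_a, maps_b) {
  if (inherits(maps_a, "spatial_maps")) maps_a <- maps_a$layers[[1]]
  if (inherits(maps_b, "spatial_maps")) maps_b <- maps_b$layers[[1]]
  stopifnot(is.matrix(maps_a), is.matrix(maps_b),
            ncol(maps_a) == ncol(maps_b))
  qa <- nrow(maps_a); qb <- nrow(maps_b)
  C <- stats::cor(t(maps_a), t(maps_b))       # qa x qb signed SCC
  C[!is.finite(C)] <- 0
  n <- max(qa, qb)
  cost <- matrix(0, n, n)                      # padded with neutral cost
  cost[seq_len(qa), seq_len(qb)] <- -abs(C)
  sol <- solve_assignment(cost)
  pairs <- data.frame(a = seq_len(qa), b = sol[seq_len(qa)])
  pairs <- pairs[pairs$b <= qb, , drop = FALSE]
  pairs$scc <- C[cbind(pairs$a, pairs$b)]
  pairs[order(pairs$a), , drop = FALSE]
}

#' Pairwise group comparison of per-network consistency scores
#'
#' All pairwise two-sample t tests between networks on their per-subject
#' consistency values (SCC or overlap rate), Benjamini-Hochberg adjusted,
#' reported as a lower-triangle p-value table. Networks with fewer than
#' two subjects are excluded with a warning.
#'
#' @param scores data frame with columns `network` and `value` (one row
#'   per subject per network).
#' @param alpha significance level recorded on the result (default 0.01).
#' @return list with `p_raw` and `p_adjusted` (lower-triangle matrices),
#'   `pairs` (long-format data frame) and `alpha`.
#' @export
compare_scc_groups <- function(scores, alpha = 0.01) {
  stopifnot(is.data.frame(scores), all(c("network", "value") %in%
                                         names(scores)))
  counts <- table(scores$network)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding single-subject network(s): ",
            paste(small, collapse = ", "))
    scores <- scores[!scores$network %in% small, , drop = FALSE]
  }
  nets <- unique(as.character(scores$network))
  if (length(nets) < 2) stop("need at least two networks to compare")
  combos <- utils::combn(length(nets), 2)
  p_raw_v <- apply(combos, 2L, function(ix) {
    x <- scores$value[scores$network == nets[ix[1]]]
    y <- scores$value[scores$network == nets[ix[2]]]
    if (stats::sd(c(x, y)) == 0) 1 else stats::t.test(x, y)$p.value
  })
  p_adj_v <- stats::p.adjust(p_raw_v, method = "BH")
  k <- length(nets)
  p_raw <- p_adj <- matrix(NA_real_, k, k, dimnames = list(nets, nets))
  for (c_i in seq_len(ncol(combos))) {
    i <- combos[1, c_i]; j <- combos[2, c_i]
    p_raw[max(i, j), min(i, j)] <- p_raw_v[c_i]
    p_adj[max(i, j), min(i, j)] <- p_adj_v[c_i]
  }
  pairs <- data.frame(network_a = nets[combos[1, ]],
                      network_b = nets[combos[2, ]],
                      p_raw = p_raw_v, p_adjusted = p_adj_v)
  list(p_raw = p_raw, p_adjusted = p_adj, pairs = pairs, alpha = alpha)
}
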