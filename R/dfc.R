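#' Sliding-window DFC configuration
#'
#' The window is a tapered kernel: a rectangle of `rect_width` TRs
#' convolved with a Gaussian of SD `gauss_sigma` TRs truncated at
#' `+/- gauss_halfwidth` TRs, slid in steps of `step` TRs; windowed
#' connectivity matrices are clustered into `k` states. The effective
#' window length is `rect_width + 2 * gauss_halfwidth` (full convolution
#' support): 44 TRs at the defaults, which yields 82 fully contained
#' windows on a 206-TR series. The truncation at +/-11 TRs is this
#' package's documented convention — it is the value that makes the
#' default geometry self-consistent.
#'
#' @param rect_width rectangle width in TRs (default 22).
#' @param gauss_sigma Gaussian SD in TRs (default 3).
#' @param gauss_halfwidth truncation half-width in TRs (default 11; 0
#'   gives a plain rectangular window).
#' @param step window step in TRs (default 2).
#' @param k number of connectivity states (default 4).
#' @param kmeans_restarts k-means restarts (default 20).
#' @param seed RNG seed for clustering.
#' @return a list of class `dfc_config`.
#' @export
dfc_config <- function(rect_width = 22, gauss_sigma = 3,
                       gauss_halfwidth = 11, step = 2, k = 4,
                       kmeans_restarts = 20, seed = 1L) {
  stopifnot(rect_width >= 1, gauss_sigma >= 0, gauss_halfwidth >= 0,
            step >= 1, k >= 1, kmeans_restarts >= 1)
  structure(list(rect_width = as.integer(rect_width),
                 gauss_sigma = gauss_sigma,
                 gauss_halfwidth = as.integer(gauss_halfwidth),
                 step = as.integer(step), k = as.integer(k),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 seed = as.integer(seed)),
            class = "dfc_config")
}

taper_length <- function(cfg) cfg$rect_width + 2L * cfg$gauss_halfwidth

#' Tapered window weights
#'
#' Full discrete convolution of an all-ones rectangle with a unit-sum
#' truncated Gaussian kernel, normalized to sum 1. Symmetric and
#' nonnegative; length `rect_width + 2 * gauss_halfwidth`.
#'
#' @param cfg a [dfc_config()].
#' @return numeric weight vector.
#' @export
taper_weights <- function(cfg) {
  rect <- rep(1, cfg$rect_width)
  if (cfg$gauss_halfwidth == 0L || cfg$gauss_sigma <= 0) {
    w <- rect
  } else {
    kern <- stats::dnorm(seq(-cfg$gauss_halfwidth, cfg$gauss_halfwidth),
                         sd = cfg$gauss_sigma)
    kern <- kern / sum(kern)
    w <- stats::convolve(rect, rev(kern), type = "open")
  }
  w / sum(w)
}

window_starts <- function(T_len, cfg) {
  L <- taper_length(cfg)
  if (T_len < L)
    stop("configuration error: series length ", T_len,
         " is shorter than the window length ", L)
  seq.int(1L, T_len - L + 1L, by = cfg$step)
}

#' Number of fully contained sliding windows
#'
#' `floor((T_len - L) / step) + 1` with `L` the effective window length;
#' only placements that fit entirely inside the series count.
#'
#' @param T_len series length in TRs; `cfg` a [dfc_config()].
#' @return integer window count.
#' @export
count_windows <- function(T_len, cfg = dfc_config()) {
  length(window_starts(T_len, cfg))
}

#' Windowed functional connectivity tensor
#'
#' For every window placement, the weighted Pearson correlation (taper
#' weights as observation weights) between each pair of component time
#' courses. Pairs with zero weighted variance in a window are set to 0
#' with a warning; diagonals are 1.
#'
#' @param features time x k_net matrix of component time courses.
#' @param cfg a [dfc_config()].
#' @return a `dfc_tensor`: array `W x k_net x k_net` with attributes
#'   `starts` and `cfg`.
#' @export
windowed_fc <- function(features, cfg = dfc_config()) {
  stopifnot(is.matrix(features), ncol(features) >= 2)
  w <- taper_weights(cfg)
  L <- taper_length(cfg)
  starts <- window_starts(nrow(features), cfg)
  k <- ncol(features)
  out <- array(NA_real_, c(length(starts), k, k))
  flat <- integer(0)
  for (wi in seq_along(starts)) {
    sub <- features[starts[wi]:(starts[wi] + L - 1L), , drop = FALSE]
    mu <- colSums(sub * w)
    xc <- sweep(sub, 2L, mu, `-`)
    C <- crossprod(xc * w, xc)
    d <- sqrt(diag(C))
    if (any(d <= 0)) {
      flat <- c(flat, wi)
      d[d <= 0] <- Inf
    }
    R <- C / tcrossprod(d)
    diag(R) <- 1
    out[wi, , ] <- R
  }
  if (length(flat))
    warning("zero weighted variance in ", length(flat),
            " window(s); affected correlations set to 0")
  structure(out, starts = starts, cfg = cfg, class = "dfc_tensor")
}

ut_index <- function(k) which(upper.tri(matrix(0, k, k)))

vec_windows <- function(tensor) {
  k <- dim(tensor)[2]
  ut <- ut_index(k)
  res <- apply(tensor, 1L, function(m) m[ut])
  if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
}

#' Cluster windowed connectivity into states
#'
#' k-means (`k` states, Euclidean distance, multiple seeded restarts) on
#' the vectorized upper triangles of the windowed FC matrices, pooled over
#' the supplied tensors. States are relabeled by order of first
#' occurrence, so the first window always carries state 1. When the pooled
#' windows contain fewer distinct patterns than `k`, the result degrades
#' gracefully: the distinct patterns become the states and the result is
#' flagged `degenerate`.
#'
#' @param tensors one `dfc_tensor` or a list of them (e.g. one per
#'   subject, pooled so all subjects share a state space).
#' @param cfg a [dfc_config()].
#' @return object of class `dfc_states`: `centroids` (list of symmetric
#'   unit-diagonal state matrices), `assignments` (list of per-tensor
#'   integer vectors), `k`, `degenerate`, `cfg`.
#' @export
cluster_states <- function(tensors, cfg = dfc_config()) {
  if (inherits(tensors, "dfc_tensor")) tensors <- list(tensors)
  stopifnot(length(tensors) >= 1)
  X <- do.call(rbind, lapply(tensors, vec_windows))
  n_win <- vapply(tensors, function(t) dim(t)[1], integer(1))
  if (nrow(X) < cfg$k)
    stop("configuration error: ", nrow(X), " windows but k = ", cfg$k)
  k_net <- dim(tensors[[1]])[2]
  uniq <- unique(round(X, 12))
  degenerate <- nrow(uniq) < cfg$k
  k_eff <- min(cfg$k, nrow(uniq))
  if (degenerate) {
    warning("only ", nrow(uniq), " distinct connectivity pattern(s); ",
            "clustering is degenerate")
    assign_raw <- apply(X, 1L, function(r)
      which.min(colSums((t(uniq) - r)^2)))
    centers <- uniq
  } else {
    set.seed(cfg$seed)
    km <- stats::kmeans(X, centers = cfg$k, nstart = cfg$kmeans_restarts,
                        iter.max = 100L)
    assign_raw <- km$cluster
    centers <- km$centers
  }
  first <- unique(assign_raw)                 # order of first occurrence
  relabel <- match(seq_len(nrow(centers)), first)
  assignments_flat <- relabel[assign_raw]
  centroids <- lapply(first, function(cl) {
    m <- matrix(0, k_net, k_net)
    m[ut_index(k_net)] <- centers[cl, ]
    m <- m + t(m)
    diag(m) <- 1
    m
  })
  ends <- cumsum(n_win)
  assignments <- lapply(seq_along(tensors), function(i)
    assignments_flat[(ends[i] - n_win[i] + 1L):ends[i]])
  structure(list(centroids = centroids, assignments = assignments,
                 k = k_eff, degenerate = degenerate, cfg = cfg),
            class = "dfc_states")
}

#' @export
print.dfc_states <- function(x, ...) {
  cat("<dfc_states> ", x$k, " state(s), ",
      length(x$assignments), " series",
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Similarity of group- and individual-level DFC state sequences
#'
#' For each window, the rank (Spearman) correlation between the
#' off-diagonal entries of the state matrices assigned to that window at
#' the group and at the individual level, averaged over windows:
#' \deqn{SDFC = \frac{1}{W} \sum_{i=1}^{W} corr(S^g_i, S^d_i).}
#' By default the assigned cluster centroids are compared; with
#' `compare = "window"` the raw windowed matrices are correlated instead
#' (a sensitivity variant), in which case the two tensors must be
#' supplied.
#'
#' @param group,indiv `dfc_states` results sharing a window count.
#' @param subject index into each result's `assignments` list (default 1).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param compare `"centroid"` (default) or `"window"`.
#' @param group_tensor,indiv_tensor raw tensors, required for
#'   `compare = "window"`.
#' @return scalar in \[-1, 1\].
#' @export
sdfc <- function(group, indiv, subject = 1L,
                 method = c("spearman", "pearson"),
                 compare = c("centroid", "window"),
                 group_tensor = NULL, indiv_tensor = NULL) {
  method <- match.arg(method)
  compare <- match.arg(compare)
  ag <- group$assignments[[subject]]
  ad <- indiv$assignments[[subject]]
  if (length(ag) != length(ad))
    stop("dimension error: window counts differ (", length(ag), " vs ",
         length(ad), ")")
  k_net <- nrow(group$centroids[[1]])
  ut <- ut_index(k_net)
  vals <- vapply(seq_along(ag), function(i) {
    if (compare == "centroid") {
      x <- group$centroids[[ag[i]]][ut]
      y <- indiv$centroids[[ad[i]]][ut]
    } else {
      stopifnot(!is.null(group_tensor), !is.null(indiv_tensor))
      x <- group_tensor[i, , ][ut]
      y <- indiv_tensor[i, , ][ut]
    }
    stats::cor(x, y, method = method)
  }, numeric(1))
  mean(vals)
}
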