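

# Weighted Pearson correlation between two vectors; w >= 0, sum(w) > 0.
# Returns 0 with a warning when either weighted variance vanishes.
weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    warning("zero weighted variance in window; correlation set to 0")
    return(0)
  }
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Solve a linear assignment problem (minimum cost)
#'
#' Kuhn-Munkres with dual potentials and shortest augmenting paths, O(n^3).
#' Intended for the small atom-matching problems that arise when pairing
#' spatial maps (tens of atoms), not for large-scale assignment.
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `p` with `p[i]` the column assigned to row `i`.
#' @keywords internal
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  # columns live at indices 2..n+1; index 1 is the virtual start column
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row currently assigned to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0L) assignment[p[j]] <- j - 1L
  assignment
}

# md5 of a file set, named by path relative to root, stable ordering
hash_files <- function(files, root) {
  files <- sort(files)
  h <- unname(tools::md5sum(files))
  rel <- substring(files, nchar(root) + 2L)
  stats::setNames(h, rel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
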