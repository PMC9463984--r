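# shared fixture builders; everything is generated in code at test time

# small box mask with a hole, deterministic
tiny_mask <- function(dim = c(4L, 4L, 4L)) {
  a <- array(TRUE, dim)
  a[1, 1, 1] <- FALSE
  brain_mask(a)
}

# mask with exactly two in-mask voxels
tiny_mask_2 <- function() {
  a <- array(FALSE, c(2L, 2L, 1L))
  a[1, 1, 1] <- TRUE
  a[2, 2, 1] <- TRUE
  brain_mask(a)
}

# deterministic 4D volume whose voxel (i,j,k) series is linear in time
ramp_volume <- function(dim = c(4L, 4L, 4L), nt = 10L) {
  arr <- array(0, c(dim, nt))
  for (t in seq_len(nt))
    arr[, , , t] <- array(seq_len(prod(dim)), dim) + t
  arr
}

# random correlation matrix with rank-2 structure plus ridge
rand_corr <- function(k, seed) {
  set.seed(seed)
  L <- matrix(stats::rnorm(k * 2), k, 2)
  C <- tcrossprod(L) + diag(k) * 0.5
  d <- sqrt(diag(C))
  C / tcrossprod(d)
}

# small Bernoulli RBM with fixed, moderate random parameters
oracle_rbm <- function(nv = 3, nh = 2, seed = 3, sd = 0.5) {
  set.seed(seed)
  r <- rbm(nv, nh, visible = "bernoulli")
  r$W <- matrix(stats::rnorm(nv * nh, sd = sd), nv, nh)
  r$a <- stats::rnorm(nv, sd = sd)
  r$b <- stats::rnorm(nh, sd = sd)
  r
}

# all permutations of 1..n as a list (for brute-force matching oracles)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# exact p(h | v) from the enumerated joint of a small Bernoulli RBM
enumerated_hidden_conditional <- function(r, v0) {
  en <- rbm_enumerate(r)
  sel <- apply(en$v, 1L, function(x) all(x == v0))
  ph <- numeric(ncol(en$h))
  for (j in seq_len(ncol(en$h)))
    ph[j] <- sum(en$prob[sel & en$h[, j] == 1]) / sum(en$prob[sel])
  ph
}
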