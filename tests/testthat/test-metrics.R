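test_that("ISC is 1 for identical subjects and r for two subjects", {
  set.seed(1)
  base <- matrix(rnorm(100 * 3), 100, 3)
  rep_id <- isc(list(base, base, base))
  expect_true(all(abs(rep_id$values - 1) < 1e-12))
  expect_equal(rep_id$mean, 1)
  # with n = 2 the leave-one-out ISC is the pairwise Pearson r
  other <- base + matrix(rnorm(300), 100, 3)
  rep2 <- isc(list(base, other))
  for (j in 1:3) {
    r <- cor(base[, j], other[, j])
    expect_equal(rep2$values[1, j], r)
    expect_equal(rep2$values[2, j], r)
  }
})

test_that("ISC of independent noise is near zero", {
  for (s in 1:3) {
    set.seed(s)
    feats <- replicate(10, matrix(rnorm(200 * 50), 200, 50),
                       simplify = FALSE)
    expect_lt(abs(isc(feats)$mean), 0.02)
  }
})

test_that("constant time courses are excluded with a warning", {
  set.seed(2)
  f1 <- matrix(rnorm(60), 30, 2); f1[, 2] <- 1
  f2 <- matrix(rnorm(60), 30, 2)
  expect_warning(rep <- isc(list(f1, f2)), "constant")
  expect_true(all(is.na(rep$values[, 2])))
  expect_false(anyNA(rep$subject_means))
})

test_that("the pairwise ISC variant averages subject pairs", {
  set.seed(3)
  feats <- replicate(4, matrix(rnorm(50 * 2), 50, 2), simplify = FALSE)
  rep <- isc(feats, method = "pairwise")
  manual <- mean(vapply(2:4, function(s)
    cor(feats[[1]][, 1], feats[[s]][, 1]), numeric(1)))
  expect_equal(rep$values[1, 1], manual)
})

test_that("deeper shared sources raise ISC above shallow private ones", {
  set.seed(4)
  shared <- matrix(rnorm(80 * 5), 80, 5)
  deep <- lapply(1:6, function(s) shared + 0.2 * matrix(rnorm(400), 80, 5))
  shallow <- lapply(1:6, function(s) matrix(rnorm(400), 80, 5))
  expect_gt(isc(deep)$mean, isc(shallow)$mean)
})

test_that("spatial correlation has its closed forms and an oracle", {
  set.seed(5)
  x <- rnorm(50)
  expect_equal(scc(x, x), 1)
  expect_equal(scc(x, -x), -1)
  zg <- c(1, 2, 3, 4); zd <- c(1, 2, 2, 5)
  # independent oracle: Pearson r from first principles
  num <- sum((zg - mean(zg)) * (zd - mean(zd)))
  den <- sqrt(sum((zg - mean(zg))^2) * sum((zd - mean(zd))^2))
  expect_equal(scc(zg, zd), num / den, tolerance = 1e-12)
  expect_equal(scc(zg, zd), scc(zd, zg))
  expect_error(scc(rep(1, 4), zd), "undefined value")
  expect_error(scc(zg, c(1, 2)), "dimension error")
})

test_that("overlap rate matches its set-theoretic definition", {
  S <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  T_ <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(overlap_rate(T_, T_), 1)
  expect_equal(overlap_rate(S, T_), 3 / 4)
  expect_equal(overlap_rate(c(FALSE, TRUE), c(TRUE, FALSE)), 0)
  # deliberately order-sensitive
  expect_false(isTRUE(all.equal(overlap_rate(S, T_), overlap_rate(T_, S))))
  expect_error(overlap_rate(S, rep(FALSE, 6)), "undefined value")
})

test_that("binarize_map thresholds the positive z tail", {
  set.seed(6)
  map <- rnorm(2000)
  b <- binarize_map(map, cutoff = 1.96)
  mu <- mean(map); sdp <- sqrt(mean(map^2) - mu^2)
  expect_equal(as.logical(b), (map - mu) / sdp > 1.96)
  expect_equal(attr(b, "cutoff"), 1.96)
  expect_error(binarize_map(rep(2, 5)), "undefined value")
})

test_that("atom matching recovers permutations and the exact optimum", {
  set.seed(7)
  A <- matrix(rnorm(4 * 30), 4, 30)
  perm <- c(3, 1, 4, 2)
  pairs <- match_atoms(A, A[perm, ])
  expect_equal(pairs$b[perm], 1:4)      # permutation recovered
  expect_true(all(pairs$scc > 0.999))
  ident <- match_atoms(A, A)
  expect_equal(ident$b, 1:4)
  # brute-force 4! oracle on a fresh random problem
  B <- matrix(rnorm(4 * 30), 4, 30)
  C <- abs(cor(t(A), t(B)))
  perms <- rbind(1:4)
  perms <- do.call(rbind, combinat_perms(4))
  best <- perms[which.max(apply(perms, 1L, function(p)
    sum(C[cbind(1:4, p)]))), ]
  expect_equal(match_atoms(A, B)$b, best)
})

test_that("atom matching agrees with an independent LSAP solver", {
  skip_if_not_installed("clue")
  set.seed(8)
  A <- matrix(rnorm(6 * 40), 6, 40)
  B <- matrix(rnorm(6 * 40), 6, 40)
  C <- abs(cor(t(A), t(B)))
  ref <- as.integer(clue::solve_LSAP(C, maximum = TRUE))
  expect_equal(match_atoms(A, B)$b, ref)
})

test_that("unequal atom counts give a partial assignment", {
  set.seed(9)
  A <- matrix(rnorm(3 * 25), 3, 25)
  B <- rbind(A + 0.01 * matrix(rnorm(75), 3, 25),
             matrix(rnorm(50), 2, 25))
  pairs <- match_atoms(A, B)
  expect_equal(nrow(pairs), 3L)
  expect_equal(pairs$b, 1:3)
})

test_that("group comparisons follow a t-test + BH pipeline", {
  set.seed(10)
  same <- data.frame(network = rep(c("a", "b"), each = 10),
                     value = rep(c(0.5, 0.5), each = 10))
  res_same <- compare_scc_groups(same)
  expect_equal(res_same$pairs$p_adjusted, 1)
  scores <- data.frame(
    network = rep(c("aud", "dmn", "ec"), each = 15),
    value = c(rnorm(15, 0.9, 0.01), rnorm(15, 0.4, 0.01),
              rnorm(15, 0.41, 0.01)))
  res <- compare_scc_groups(scores)
  p_ad <- res$pairs$p_adjusted[res$pairs$network_a == "aud" &
                                 res$pairs$network_b == "dmn"]
  expect_lt(p_ad, 0.01)
  # only the lower triangle of the matrix form is populated
  expect_true(all(is.na(res$p_adjusted[upper.tri(res$p_adjusted,
                                                 diag = TRUE)])))
  expect_equal(sum(!is.na(res$p_adjusted)), 3L)
  # raw p values match stats::t.test directly
  p_raw <- res$pairs$p_raw[res$pairs$network_a == "dmn" &
                             res$pairs$network_b == "ec"]
  expect_equal(p_raw,
               t.test(scores$value[scores$network == "dmn"],
                      scores$value[scores$network == "ec"])$p.value)
  small <- rbind(scores, data.frame(network = "solo", value = 0.3))
  expect_warning(compare_scc_groups(small), "single-subject")
})
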