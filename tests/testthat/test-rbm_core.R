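test_that("the Bernoulli energy matches direct substitution", {
  r <- rbm(2, 1, visible = "bernoulli")
  r$W <- matrix(0, 2, 1); r$a <- c(0, 0); r$b <- 0
  expect_equal(rbm_energy(r, c(1, 1), 1), 0)
  r$W <- matrix(c(3, 4), 2, 1); r$a <- c(1, 0); r$b <- 2
  expect_equal(rbm_energy(r, c(1, 1), c(1)), -10)
  expect_error(rbm_energy(r, c(1, 1, 1), 1), "dimension error")
})

test_that("the Gaussian energy adds the quadratic visible term", {
  set.seed(9)
  r <- rbm(3, 2, visible = "gaussian")
  v <- rnorm(3); h <- c(1, 0)
  expect_equal(rbm_energy(r, v, h),
               sum((v - r$a)^2) / 2 - sum(r$b * h) -
                 drop(v %*% r$W %*% h))
})

test_that("energy is invariant under joint hidden permutations", {
  r <- oracle_rbm(4, 3, seed = 13)
  perm <- c(3, 1, 2)
  r2 <- r
  r2$W <- r$W[, perm]; r2$b <- r$b[perm]
  set.seed(1)
  for (rep in 1:5) {
    v <- rbinom(4, 1, 0.5); h <- rbinom(3, 1, 0.5)
    expect_equal(rbm_energy(r2, v, h[perm]), rbm_energy(r, v, h))
  }
})

test_that("hidden conditionals are logistic and saturate correctly", {
  r <- rbm(3, 2, visible = "bernoulli")
  r$W <- matrix(0, 3, 2); r$a <- rep(0, 3); r$b <- c(0, 30)
  p <- hidden_conditional(r, c(1, 0, 1))
  expect_equal(p[1, 1], 0.5)
  expect_gte(p[1, 2], 1 - 1e-9)
})

test_that("conditionals match the enumerated joint distribution", {
  r <- oracle_rbm(3, 2, seed = 3)
  en <- rbm_enumerate(r)
  expect_equal(sum(en$prob), 1, tolerance = 1e-12)
  for (v0 in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
    expect_equal(drop(hidden_conditional(r, v0)),
                 enumerated_hidden_conditional(r, v0),
                 tolerance = 1e-12)
  }
})

test_that("the joint conditional factorizes over hidden units", {
  r <- oracle_rbm(4, 3, seed = 5)
  en <- rbm_enumerate(r)
  v0 <- c(1, 0, 1, 0)
  sel <- apply(en$v, 1L, function(x) all(x == v0))
  cond <- en$prob[sel] / sum(en$prob[sel])
  ph <- drop(hidden_conditional(r, v0))
  pred <- apply(en$h[sel, , drop = FALSE], 1L, function(h)
    prod(ifelse(h == 1, ph, 1 - ph)))
  expect_equal(cond, pred, tolerance = 1e-12)
})

test_that("normalization holds across random small architectures", {
  for (sz in list(c(2, 2), c(5, 4), c(6, 6))) {
    r <- oracle_rbm(sz[1], sz[2], seed = sum(sz))
    expect_equal(sum(rbm_enumerate(r)$prob), 1, tolerance = 1e-12)
  }
})

test_that("cd_update with zero learning rate changes nothing", {
  r <- oracle_rbm(4, 3, seed = 7)
  set.seed(1)
  batch <- matrix(rbinom(20, 1, 0.5), 5, 4)
  upd <- cd_update(r, batch, train_config(learning_rate = 0))
  expect_identical(upd$rbm$W, r$W)
  expect_identical(upd$rbm$a, r$a)
  expect_identical(upd$rbm$b, r$b)
  expect_error(cd_update(r, matrix(0, 2, 5)), "dimension error")
})

test_that("seeded CD training is bit-reproducible", {
  set.seed(2)
  data <- matrix(rbinom(60, 1, 0.4), 10, 6)
  set.seed(10); r <- rbm(6, 3, visible = "bernoulli")
  f1 <- train_rbm(r, data, train_config(epochs = 5, seed = 42))
  f2 <- train_rbm(r, data, train_config(epochs = 5, seed = 42))
  expect_identical(f1$rbm, f2$rbm)
  expect_identical(f1$trace, f2$trace)
})

test_that("training a repeated pattern halves the reconstruction error", {
  pattern <- c(1, 0, 1, 0, 1, 1)
  data <- matrix(rep(pattern, 40), 40, 6, byrow = TRUE)
  set.seed(10)
  r <- rbm(6, 3, visible = "bernoulli", sparsity_weight = 0)
  initial <- reconstruction_loss(r, data)
  fit <- train_rbm(r, data, train_config(epochs = 200, batch_size = 8,
                                         seed = 1))
  expect_lt(reconstruction_loss(fit$rbm, data), 0.5 * initial)
  # trace decreases overall (compare first and last epochs)
  expect_lt(mean(utils::tail(fit$trace, 5)),
            mean(utils::head(fit$trace, 5)))
})

test_that("a strong sparsity penalty pins mean hidden activation at rho", {
  set.seed(3)
  data <- matrix(rbinom(300, 1, 0.5), 30, 10)
  set.seed(11)
  r <- rbm(10, 8, visible = "bernoulli", sparsity_target = 0.1,
           sparsity_weight = 5)
  fit <- train_rbm(r, data, train_config(epochs = 150, batch_size = 10,
                                         seed = 2))
  q <- mean(hidden_conditional(fit$rbm, data))
  expect_lt(abs(q - 0.1), 0.05)
})

test_that("reconstruction loss has its closed forms", {
  # an identity-like RBM copies binary data through the hidden layer
  r <- rbm(2, 2, visible = "bernoulli")
  r$W <- diag(2) * 40; r$a <- rep(-20, 2); r$b <- rep(-20, 2)
  data <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  expect_lt(reconstruction_loss(r, data), 1e-6)
  # zero-weight Gaussian RBM with a = 0 reconstructs everything to 0
  g <- rbm(3, 2, visible = "gaussian")
  g$W <- matrix(0, 3, 2); g$a <- rep(0, 3); g$b <- rep(0, 2)
  set.seed(4)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(reconstruction_loss(g, x), mean(x^2))
  expect_error(reconstruction_loss(g, x[0, , drop = FALSE]))
})

test_that("Gibbs sampling reproduces the enumerated distribution", {
  r <- oracle_rbm(3, 2, seed = 3)
  en <- rbm_enumerate(r)
  key <- apply(cbind(en$v, en$h), 1L, paste, collapse = "")
  samp <- rbm_gibbs(r, n_steps = 30000, seed = 1)
  kf <- table(factor(apply(samp, 1L, paste, collapse = ""), levels = key))
  freq <- as.numeric(kf) / nrow(samp)
  se <- sqrt(en$prob * (1 - en$prob) / nrow(samp))
  expect_true(all(abs(freq - en$prob) <= 3 * se))
})
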