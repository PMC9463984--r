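#' Restricted Boltzmann machine layer
#'
#' A bipartite energy model over visible units `v` and hidden units `h`.
#' Two visible-unit families are supported:
#' * `bernoulli`: \eqn{E(v,h) = -a^T v - b^T h - v^T W h}, the classical
#'   binary form;
#' * `gaussian` (unit variance): \eqn{E(v,h) = \sum_i (v_i-a_i)^2/2
#'   - b^T h - v^T W h}, appropriate for z-scored real-valued volumes and
#'   the default for the first layer of a volumetric DBN.
#'
#' In both cases \eqn{p(h_j=1|v) = \mathrm{logistic}(b_j + \sum_i v_i
#' W_{ij})}. Hidden-unit sparsity is encouraged during training by a
#' penalty that drives the mean hidden activation toward `sparsity_target`
#' with strength `sparsity_weight` (the "sparse" in vsDBN).
#'
#' Weights are initialized `N(0, 0.01^2)` from the current RNG stream;
#' biases start at zero.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param visible `"gaussian"` or `"bernoulli"`.
#' @param sparsity_target target mean hidden activation rho in (0, 1).
#' @param sparsity_weight penalty strength lambda (>= 0).
#' @return an object of class `rbm` with fields `W` (n_visible x n_hidden),
#'   `a`, `b`, `visible`, `sparsity_target`, `sparsity_weight`.
#' @export
rbm <- function(n_visible, n_hidden, visible = c("gaussian", "bernoulli"),
                sparsity_target = 0.1, sparsity_weight = 1) {
  visible <- match.arg(visible)
  stopifnot(n_visible >= 1, n_hidden >= 1,
            sparsity_target > 0, sparsity_target < 1, sparsity_weight >= 0)
  structure(
    list(W = matrix(stats::rnorm(n_visible * n_hidden, sd = 0.01),
                    n_visible, n_hidden),
         a = numeric(n_visible), b = numeric(n_hidden),
         visible = visible, sparsity_target = sparsity_target,
         sparsity_weight = sparsity_weight),
    class = "rbm")
}

#' @export
print.rbm <- function(x, ...) {
  cat("<rbm> ", nrow(x$W), " visible (", x$visible, ") x ", ncol(x$W),
      " hidden; rho=", x$sparsity_target, " lambda=", x$sparsity_weight,
      "\n", sep = "")
  invisible(x)
}

#' Training configuration for RBM / DBN layers
#'
#' @param learning_rate step size; default 0.05 for Gaussian visible
#'   units, 0.01 for Bernoulli (resolved at training time when `NULL`).
#' @param epochs passes over the data.
#' @param batch_size minibatch rows.
#' @param cd_steps contrastive-divergence order k (default 1).
#' @param momentum length-2 vector: value before and after
#'   `momentum_switch` epochs.
#' @param momentum_switch epoch at which momentum steps up.
#' @param weight_decay L2 penalty on W.
#' @param seed RNG seed used by the training loop.
#' @param test_fraction held-out fraction for fitness evaluation, in
#'   (0, 0.5].
#' @return a list of class `train_config`.
#' @export
train_config <- function(learning_rate = NULL, epochs = 50, batch_size = 64,
                         cd_steps = 1, momentum = c(0.5, 0.9),
                         momentum_switch = 5, weight_decay = 2e-4,
                         seed = 1L, test_fraction = 0.2) {
  stopifnot(is.null(learning_rate) || learning_rate >= 0,
            epochs >= 0, batch_size >= 1, cd_steps >= 1,
            length(momentum) == 2, all(momentum >= 0), weight_decay >= 0,
            test_fraction > 0, test_fraction <= 0.5)
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, cd_steps = cd_steps,
                 momentum = momentum, momentum_switch = momentum_switch,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 test_fraction = test_fraction),
            class = "train_config")
}

resolve_lr <- function(cfg, visible) {
  cfg$learning_rate %||% if (visible == "gaussian") 0.05 else 0.01
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' RBM energy
#'
#' @param object an [rbm]; `v`, `h` visible and hidden vectors.
#' @return the scalar energy `E(v, h)`.
#' @export
rbm_energy <- function(object, v, h) {
  stopifnot(inherits(object, "rbm"))
  if (length(v) != nrow(object$W) || length(h) != ncol(object$W))
    stop("dimension error: v/h do not match the layer sizes")
  vis <- if (object$visible == "bernoulli") -sum(object$a * v)
         else sum((v - object$a)^2) / 2
  vis - sum(object$b * h) - drop(v %*% object$W %*% h)
}

#' Hidden and visible conditionals
#'
#' `hidden_conditional` returns `p(h_j = 1 | v)` row-wise for a matrix of
#' visible configurations; `visible_mean` returns the mean-field visible
#' reconstruction `E[v | h]` (linear for Gaussian units, logistic for
#' Bernoulli).
#'
#' @param object an [rbm].
#' @param v matrix (rows = samples) or vector of visible values.
#' @param h matrix (rows = samples) or vector of hidden values.
#' @return matrix of probabilities / means with one row per input row.
#' @export
hidden_conditional <- function(object, v) {
  stopifnot(inherits(object, "rbm"))
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  if (ncol(v) != nrow(object$W))
    stop("dimension error: v has ", ncol(v), " columns, expected ",
         nrow(object$W))
  sigmoid(sweep(v %*% object$W, 2L, object$b, `+`))
}

#' @rdname hidden_conditional
#' @export
visible_mean <- function(object, h) {
  stopifnot(inherits(object, "rbm"))
  if (is.null(dim(h))) h <- matrix(h, nrow = 1L)
  if (ncol(h) != ncol(object$W))
    stop("dimension error: h has ", ncol(h), " columns, expected ",
         ncol(object$W))
  act <- sweep(tcrossprod(h, object$W), 2L, object$a, `+`)
  if (object$visible == "gaussian") act else sigmoid(act)
}

#' One contrastive-divergence update
#'
#' Performs a single CD-k gradient step on one minibatch, with momentum,
#' weight decay on `W`, and a sparsity gradient `lambda * (rho - q)` on the
#' hidden biases (`q` = data-phase mean hidden activation). The negative
#' phase uses mean-field visible reconstructions and sampled hidden states;
#' the returned reconstruction error is the deterministic mean-squared
#' error between the batch and its one-step mean-field reconstruction.
#' Consumes the current RNG stream (hidden sampling), so runs are
#' reproducible once the caller seeds.
#'
#' @param object an [rbm].
#' @param batch numeric matrix, rows = samples, columns = visible units.
#' @param cfg a [train_config()].
#' @param momentum momentum coefficient to use for this step.
#' @param state velocity list from the previous call (or `NULL`).
#' @return list with `rbm` (updated), `recon_error`, and `state` to pass to
#'   the next call.
#' @export
cd_update <- function(object, batch, cfg = train_config(),
                      momentum = cfg$momentum[1], state = NULL) {
  stopifnot(inherits(object, "rbm"), is.matrix(batch))
  if (ncol(batch) != nrow(object$W))
    stop("dimension error: batch has ", ncol(batch),
         " columns, expected ", nrow(object$W))
  lr <- resolve_lr(cfg, object$visible)
  nb <- nrow(batch)
  h0p <- hidden_conditional(object, batch)
  hs <- (h0p > matrix(stats::runif(length(h0p)), nb)) * 1
  for (step in seq_len(cfg$cd_steps)) {
    vk <- visible_mean(object, hs)
    hkp <- hidden_conditional(object, vk)
    if (step < cfg$cd_steps)
      hs <- (hkp > matrix(stats::runif(length(hkp)), nb)) * 1
  }
  q <- colMeans(h0p)
  gW <- (crossprod(batch, h0p) - crossprod(vk, hkp)) / nb -
    cfg$weight_decay * object$W
  ga <- colMeans(batch) - colMeans(vk)
  gb <- colMeans(h0p) - colMeans(hkp) +
    object$sparsity_weight * (object$sparsity_target - q)
  if (!all(is.finite(gW)) || !all(is.finite(ga)) || !all(is.finite(gb)))
    stop("numeric error: non-finite CD gradient (|W|max=",
         signif(max(abs(object$W)), 3), ", lr=", lr, ")")
  if (is.null(state))
    state <- list(dW = 0 * object$W, da = 0 * object$a, db = 0 * object$b)
  state$dW <- momentum * state$dW + lr * gW
  state$da <- momentum * state$da + lr * ga
  state$db <- momentum * state$db + lr * gb
  object$W <- object$W + state$dW
  object$a <- object$a + state$da
  object$b <- object$b + state$db
  recon <- visible_mean(object, h0p)
  list(rbm = object, recon_error = mean((batch - recon)^2), state = state)
}

#' Train one RBM layer
#'
#' Seeded minibatch CD training: shuffles rows each epoch, steps momentum
#' from `momentum[1]` to `momentum[2]` after `momentum_switch` epochs, and
#' records the mean per-epoch reconstruction error.
#'
#' @param object an [rbm] (its current weights are the starting point).
#' @param data training matrix (rows = samples).
#' @param cfg a [train_config()].
#' @param lr_scale multiplier on the learning rate (used by subject-stage
#'   fine-tuning).
#' @return list with `rbm` and `trace` (per-epoch mean reconstruction
#'   error; length 0 when `epochs = 0`).
#' @export
train_rbm <- function(object, data, cfg = train_config(), lr_scale = 1) {
  stopifnot(inherits(object, "rbm"), is.matrix(data))
  cfg$learning_rate <- resolve_lr(cfg, object$visible) * lr_scale
  set.seed(cfg$seed)
  n <- nrow(data)
  trace <- numeric(cfg$epochs)
  state <- NULL
  for (ep in seq_len(cfg$epochs)) {
    mom <- if (ep <= cfg$momentum_switch) cfg$momentum[1] else cfg$momentum[2]
    ord <- sample.int(n)
    errs <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      rows <- ord[start:min(start + cfg$batch_size - 1L, n)]
      upd <- cd_update(object, data[rows, , drop = FALSE], cfg,
                       momentum = mom, state = state)
      object <- upd$rbm
      state <- upd$state
      errs <- c(errs, upd$recon_error)
    }
    trace[ep] <- mean(errs)
  }
  list(rbm = object, trace = trace)
}

#' Mean-field reconstruction loss
#'
#' Mean squared error of the deterministic reconstruction
#' `v -> p(h|v) -> E[v|h]` — the quantity the architecture search uses as
#' its fitness when computed on held-out data.
#'
#' @param object an [rbm]; `data` a matrix of visible rows.
#' @return scalar MSE.
#' @export
reconstruction_loss <- function(object, data) {
  stopifnot(inherits(object, "rbm"), is.matrix(data), nrow(data) >= 1)
  mean((data - visible_mean(object, hidden_conditional(object, data)))^2)
}

#' Brute-force Boltzmann distribution of a small Bernoulli RBM
#'
#' Enumerates all `2^(n_visible+n_hidden)` joint states and returns exact
#' probabilities `exp(-E)/Z`. Only feasible for a dozen or so total units;
#' serves as the independent oracle for conditionals and Gibbs sampling.
#'
#' @param object a Bernoulli [rbm] with at most `max_units` total units.
#' @param max_units safety cap (default 16).
#' @return list with `v` and `h` state matrices (one row per joint state)
#'   and `prob`, the exact joint probabilities (summing to 1).
#' @export
rbm_enumerate <- function(object, max_units = 16L) {
  stopifnot(inherits(object, "rbm"), object$visible == "bernoulli")
  nv <- nrow(object$W); nh <- ncol(object$W)
  if (nv + nh > max_units) stop("too many units to enumerate")
  bits <- function(n) {
    g <- as.matrix(expand.grid(rep(list(0:1), n)))
    dimnames(g) <- NULL
    g
  }
  vs <- bits(nv); hs <- bits(nh)
  vrep <- vs[rep(seq_len(nrow(vs)), each = nrow(hs)), , drop = FALSE]
  hrep <- hs[rep(seq_len(nrow(hs)), times = nrow(vs)), , drop = FALSE]
  E <- vapply(seq_len(nrow(vrep)),
              function(i) rbm_energy(object, vrep[i, ], hrep[i, ]),
              numeric(1))
  w <- exp(-(E - min(E)))
  list(v = vrep, h = hrep, prob = w / sum(w))
}

#' Gibbs sampling from a Bernoulli RBM
#'
#' Alternating block Gibbs over `(h | v)` and `(v | h)`; used to check the
#' enumerated Boltzmann distribution against long-run sampling frequencies.
#'
#' @param object a Bernoulli [rbm].
#' @param n_steps chain length; `burn_in` discarded steps; `seed` RNG seed.
#' @return matrix of visited joint states (columns: visible then hidden).
#' @export
rbm_gibbs <- function(object, n_steps = 10000L, burn_in = 500L, seed = 1L) {
  stopifnot(inherits(object, "rbm"), object$visible == "bernoulli")
  set.seed(as.integer(seed))
  nv <- nrow(object$W); nh <- ncol(object$W)
  v <- stats::rbinom(nv, 1L, 0.5)
  out <- matrix(0L, n_steps, nv + nh)
  for (t in seq_len(burn_in + n_steps)) {
    ph <- drop(hidden_conditional(object, v))
    h <- (stats::runif(nh) < ph) * 1L
    pv <- sigmoid(drop(object$W %*% h) + object$a)
    v <- (stats::runif(nv) < pv) * 1L
    if (t > burn_in) out[t - burn_in, ] <- c(v, h)
  }
  out
}
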