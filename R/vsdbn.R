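#' Fit a volumetric sparse deep belief network
#'
#' Trains a stack of sparse RBMs on brain volumes as samples: the first
#' layer has Gaussian visible units (the data are z-scored volumes, one row
#' per TR), and every later layer is a Bernoulli RBM fed the previous
#' layer's mean-field hidden activation probabilities. Training is greedy
#' and layer-wise. For the group stage the input is the time-concatenated,
#' transposed multi-subject matrix from [build_group_matrix()]; the fitted
#' weights `W1, W2, ...` carry the model's spatial structure and the hidden
#' activations its temporal features.
#'
#' @param data a [data_matrix] (typically normalized) or plain numeric
#'   matrix, rows = volumes/TRs.
#' @param arch integer vector of hidden-layer sizes, e.g. `c(146, 146,
#'   146)`; unequal sizes are allowed.
#' @param config a [train_config()].
#' @param stage `"group"` or `"subject:<id>"`.
#' @param provenance how the architecture was chosen (`"manual"` or a
#'   `run_nas()` result summary); stored for the manifest.
#' @param sparsity_target,sparsity_weight hidden-unit sparsity settings
#'   passed to every layer (see [rbm()]).
#' @return an object of class `vsdbn`: list with `layers` (list of [rbm]),
#'   `arch`, `stage`, `losses` (per-layer reconstruction-error traces),
#'   `config`, `provenance`.
#' @seealso [fine_tune_subject()], [extract_temporal()], [extract_maps()]
#' @export
vsdbn <- function(data, arch, config = train_config(), stage = "group",
                  provenance = "manual", sparsity_target = 0.1,
                  sparsity_weight = 1) {
  x <- if (inherits(data, "data_matrix")) data$values else data
  stopifnot(is.matrix(x), length(arch) >= 1, all(arch >= 1))
  arch <- as.integer(arch)
  layers <- vector("list", length(arch))
  losses <- vector("list", length(arch))
  input <- x
  for (l in seq_along(arch)) {
    kind <- if (l == 1L) "gaussian" else "bernoulli"
    lcfg <- config
    lcfg$seed <- config$seed + l
    set.seed(lcfg$seed)
    layer <- rbm(ncol(input), arch[l], visible = kind,
                 sparsity_target = sparsity_target,
                 sparsity_weight = sparsity_weight)
    fit <- train_rbm(layer, input, lcfg)
    layers[[l]] <- fit$rbm
    losses[[l]] <- fit$trace
    if (!all(is.finite(fit$trace)))
      stop("numeric error: non-finite loss in layer ", l)
    input <- hidden_conditional(fit$rbm, input)
  }
  structure(
    list(layers = layers, arch = arch, stage = stage, losses = losses,
         config = config, provenance = provenance),
    class = "vsdbn")
}

#' @export
print.vsdbn <- function(x, ...) {
  cat("<vsdbn> [", x$stage, "] architecture ",
      nrow(x$layers[[1]]$W), " -> ", paste(x$arch, collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.vsdbn <- function(object, ...) {
  final <- vapply(object$losses,
                  function(tr) if (length(tr)) tr[length(tr)] else NA_real_,
                  numeric(1))
  out <- data.frame(layer = seq_along(object$arch),
                    visible = vapply(object$layers, `[[`, "", "visible"),
                    n_hidden = object$arch,
                    final_recon_error = final)
  cat("Volumetric sparse DBN (", object$stage, " stage), ",
      nrow(object$layers[[1]]$W), " visible units\n\n", sep = "")
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
coef.vsdbn <- function(object, ...) lapply(object$layers, `[[`, "W")

#' @export
plot.vsdbn <- function(x, ...) {
  tr <- x$losses
  ylim <- range(unlist(tr))
  plot(NA, xlim = c(1, max(lengths(tr))), ylim = ylim,
       xlab = "epoch", ylab = "reconstruction error",
       main = paste("vsDBN training,", x$stage, "stage"), ...)
  for (l in seq_along(tr))
    graphics::lines(tr[[l]], col = l)
  graphics::legend("topright", legend = paste("layer", seq_along(tr)),
                   col = seq_along(tr), lty = 1, bty = "n")
  invisible(x)
}

#' Hierarchical temporal features
#'
#' Propagates a data matrix through the stack with mean-field activations
#' and returns each layer's hidden time courses: row `t` of layer `L` is
#' the layer-`L` representation of volume `t`. For a group model applied
#' to the group matrix these are the group temporal features `T1..TL`; for
#' a subject model on one subject's data they are `t1..tL`.
#'
#' @param object a fitted [vsdbn].
#' @param data [data_matrix] or matrix with `m` columns.
#' @return object of class `temporal_features`: list with `layers` (list of
#'   TRs x q_L matrices, all entries in (0,1)) and `stage`.
#' @export
extract_temporal <- function(object, data) {
  stopifnot(inherits(object, "vsdbn"))
  x <- if (inherits(data, "data_matrix")) data$values else data
  if (ncol(x) != nrow(object$layers[[1]]$W))
    stop("dimension error: data has ", ncol(x), " voxels, model expects ",
         nrow(object$layers[[1]]$W))
  out <- vector("list", length(object$layers))
  h <- x
  for (l in seq_along(object$layers)) {
    h <- hidden_conditional(object$layers[[l]], h)
    out[[l]] <- h
  }
  structure(list(layers = out, stage = object$stage),
            class = "temporal_features")
}

#' @export
predict.vsdbn <- function(object, newdata, layer = length(object$layers),
                          ...) {
  extract_temporal(object, newdata)$layers[[layer]]
}

#' Hierarchical spatial maps by linear combination of weights
#'
#' Layer-1 maps are the columns of `W1`; layer-2 maps the columns of
#' `W1 W2`; layer-L maps the columns of `W1 ... WL` — the linear-combination
#' read-out that treats the stack as a hierarchical matrix factorization
#' and ignores the logistic nonlinearity (an approximation inherent to this
#' family of models). Because an RBM atom's sign is arbitrary, each map is
#' flipped so its maximum-magnitude voxel is positive; the flips are
#' recorded in `signs`. Maps are optionally z-scored per atom (population
#' convention).
#'
#' @param object a fitted [vsdbn].
#' @param zscore z-score each map (default TRUE).
#' @return object of class `spatial_maps`: `layers` is a list of q_L x m
#'   matrices (one row per atom), `signs` the per-atom sign flips,
#'   `zscored` the flag.
#' @export
extract_maps <- function(object, zscore = TRUE) {
  stopifnot(inherits(object, "vsdbn"))
  prod <- NULL
  layers <- vector("list", length(object$layers))
  signs <- vector("list", length(object$layers))
  for (l in seq_along(object$layers)) {
    prod <- if (is.null(prod)) object$layers[[l]]$W
            else prod %*% object$layers[[l]]$W
    maps <- t(prod)
    if (zscore) {
      mu <- rowMeans(maps)
      sd_pop <- sqrt(rowMeans(maps^2) - mu^2)
      sd_pop[sd_pop <= 0] <- 1   # degenerate all-equal map: centre only
      maps <- (maps - mu) / sd_pop
    }
    # resolve the sign ambiguity on the final scale
    s <- apply(maps, 1L, function(r) {
      pk <- r[which.max(abs(r))]
      if (pk < 0) -1 else 1
    })
    maps <- maps * s
    layers[[l]] <- maps
    signs[[l]] <- s
  }
  structure(list(layers = layers, signs = signs, zscored = zscore,
                 stage = object$stage),
            class = "spatial_maps")
}

#' Initialize a subject-stage model from the group model
#'
#' Deep-copies the trained group stack so every layer of the subject model
#' starts at the group weights (`W1` seeds visible-to-hidden-1, `W2`, `W3`
#' the higher layers). This weight transfer is what keeps atom `k` of the
#' subject model in correspondence with atom `k` of the group model, so no
#' re-matching between stages is needed.
#'
#' @param object a fitted group-stage [vsdbn].
#' @param subject_id label for the subject stage.
#' @return a [vsdbn] with `stage = "subject:<id>"`, weights identical to
#'   the group model's.
#' @export
init_subject_from_group <- function(object, subject_id = "subject") {
  stopifnot(inherits(object, "vsdbn"))
  if (object$stage != "group")
    stop("state error: expected a group-stage model, got ", object$stage)
  if (!length(object$losses) || !length(object$losses[[1]]))
    stop("state error: group model has no training history")
  object$stage <- paste0("subject:", subject_id)
  object$losses <- lapply(object$losses, function(tr) numeric(0))
  object
}

#' Fine-tune a subject model on individual data
#'
#' Stage-2 training: starting from the transferred group weights, every
#' layer is re-trained greedily on the subject's own data with a reduced
#' learning rate (default x0.1) and a short budget, so the model adapts to
#' the individual while staying anchored to the group solution. With
#' `epochs = 0` the model is returned unchanged (identity contract).
#'
#' @param object a subject-stage [vsdbn] from [init_subject_from_group()].
#' @param data the subject's [data_matrix] or matrix.
#' @param epochs fine-tuning epochs per layer (default 20).
#' @param lr_scale learning-rate multiplier vs the group stage (default
#'   0.1).
#' @param config optional [train_config()] overriding the stored one.
#' @return the fine-tuned [vsdbn] with per-layer loss traces.
#' @export
fine_tune_subject <- function(object, data, epochs = 20, lr_scale = 0.1,
                              config = NULL) {
  stopifnot(inherits(object, "vsdbn"))
  if (!startsWith(object$stage, "subject"))
    stop("state error: fine_tune_subject expects a subject-stage model")
  x <- if (inherits(data, "data_matrix")) data$values else data
  cfg <- config %||% object$config
  cfg$epochs <- epochs
  if (epochs == 0) return(object)
  input <- x
  for (l in seq_along(object$layers)) {
    lcfg <- cfg
    lcfg$seed <- cfg$seed + 100L + l
    fit <- train_rbm(object$layers[[l]], input, lcfg, lr_scale = lr_scale)
    object$layers[[l]] <- fit$rbm
    object$losses[[l]] <- fit$trace
    input <- hidden_conditional(fit$rbm, input)
  }
  object
}

#' Deep mean-field reconstruction and loss
#'
#' `dbn_reconstruct` runs a matrix up through all layers with mean-field
#' activations and back down again; `dbn_loss` is the mean squared error of
#' that reconstruction — the "testing loss" that the architecture search
#' minimizes when computed on held-out rows.
#'
#' @param object a fitted [vsdbn]; `data` matrix or [data_matrix].
#' @return `dbn_reconstruct`: matrix like `data`; `dbn_loss`: scalar MSE.
#' @export
dbn_reconstruct <- function(object, data) {
  stopifnot(inherits(object, "vsdbn"))
  x <- if (inherits(data, "data_matrix")) data$values else data
  h <- x
  for (l in seq_along(object$layers))
    h <- hidden_conditional(object$layers[[l]], h)
  for (l in rev(seq_along(object$layers)))
    h <- visible_mean(object$layers[[l]], h)
  h
}

#' @rdname dbn_reconstruct
#' @export
dbn_loss <- function(object, data) {
  x <- if (inherits(data, "data_matrix")) data$values else data
  mean((x - dbn_reconstruct(object, x))^2)
}
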