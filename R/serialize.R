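#' Write / read a fitted vsDBN as plain text
#'
#' Serializes each layer's weights and biases as TSV plus a JSON sidecar
#' (architecture, visible-unit kinds, sparsity settings, stage, seed), so
#' models survive round trips byte-stably and can be inspected or hashed.
#'
#' @param object a [vsdbn]; `dir` target directory (created).
#' @return `write_vsdbn`: `dir` invisibly; `read_vsdbn`: a [vsdbn].
#' @export
write_vsdbn <- function(object, dir) {
  stopifnot(inherits(object, "vsdbn"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in seq_along(object$layers)) {
    lay <- object$layers[[l]]
    utils::write.table(lay$W, file.path(dir, sprintf("W%d.tsv", l)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(cbind(lay$a), file.path(dir, sprintf("a%d.tsv", l)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(cbind(lay$b), file.path(dir, sprintf("b%d.tsv", l)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(
    arch = object$arch, stage = object$stage,
    visible = vapply(object$layers, `[[`, "", "visible"),
    sparsity_target = vapply(object$layers, `[[`, 0, "sparsity_target"),
    sparsity_weight = vapply(object$layers, `[[`, 0, "sparsity_weight"),
    seed = object$config$seed,
    provenance = object$provenance,
    losses = object$losses)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_vsdbn
#' @export
read_vsdbn <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  n_layers <- length(meta$arch)
  layers <- lapply(seq_len(n_layers), function(l) {
    W <- as.matrix(utils::read.table(file.path(dir, sprintf("W%d.tsv", l)),
                                     sep = "\t"))
    dimnames(W) <- NULL
    structure(
      list(W = W,
           a = utils::read.table(file.path(dir, sprintf("a%d.tsv", l)),
                                 sep = "\t")[[1]],
           b = utils::read.table(file.path(dir, sprintf("b%d.tsv", l)),
                                 sep = "\t")[[1]],
           visible = meta$visible[l],
           sparsity_target = meta$sparsity_target[l],
           sparsity_weight = meta$sparsity_weight[l]),
      class = "rbm")
  })
  losses <- meta$losses
  if (is.null(losses)) losses <- rep(list(numeric(0)), n_layers)
  if (!is.list(losses)) losses <- as.list(as.data.frame(losses))
  structure(
    list(layers = layers, arch = as.integer(meta$arch), stage = meta$stage,
         losses = lapply(losses, as.numeric),
         config = train_config(seed = meta$seed %||% 1L),
         provenance = meta$provenance %||% "manual"),
    class = "vsdbn")
}
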