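# small shared training fixture: 2-network mixture on a tiny grid
dbn_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- make_dataset(n_subjects = 3, v = 40, grid = c(8, 8, 8),
                         k1 = 3, k3 = 2, alpha = 0.2, noise_sd = 0.1,
                         seed = 31)
      subs <- lapply(ds$subjects, normalize_columns)
      cache <<- list(ds = ds, subs = subs,
                     grp = build_group_matrix(subs))
    }
    cache
  }
})

test_that("a one-layer DBN reduces to a single seeded RBM", {
  fx <- dbn_fixture()
  cfg <- train_config(epochs = 3, seed = 50)
  model <- vsdbn(fx$grp, arch = 8, config = cfg)
  # replicate by hand with the derived per-layer seed
  lcfg <- cfg; lcfg$seed <- cfg$seed + 1L
  set.seed(lcfg$seed)
  r0 <- rbm(ncol(fx$grp$values), 8, visible = "gaussian")
  ref <- train_rbm(r0, fx$grp$values, lcfg)
  expect_identical(model$layers[[1]]$W, ref$rbm$W)
  expect_identical(model$losses[[1]], ref$trace)
})

test_that("per-layer losses are finite and recorded", {
  fx <- dbn_fixture()
  model <- vsdbn(fx$grp, arch = c(6, 5, 4),
                 config = train_config(epochs = 3, seed = 51))
  expect_length(model$losses, 3L)
  expect_true(all(is.finite(unlist(model$losses))))
  expect_equal(model$arch, c(6L, 5L, 4L))
  expect_equal(vapply(model$layers, function(l) ncol(l$W), integer(1)),
               c(6L, 5L, 4L))
})

test_that("temporal features are composed mean-field activations", {
  fx <- dbn_fixture()
  model <- vsdbn(fx$grp, arch = c(6, 4),
                 config = train_config(epochs = 3, seed = 52))
  feats <- extract_temporal(model, fx$subs[[1]])
  expect_equal(feats$layers[[1]],
               hidden_conditional(model$layers[[1]], fx$subs[[1]]$values))
  expect_true(all(unlist(feats$layers) > 0 & unlist(feats$layers) < 1))
  # group features sliced by segment equal per-subject extraction
  gf <- extract_temporal(model, fx$grp)
  seg <- fx$grp$segments[[2]]
  expect_equal(gf$layers[[2]][seg, ],
               extract_temporal(model, fx$subs[[2]])$layers[[2]])
  expect_error(extract_temporal(model, matrix(0, 4, 3)), "dimension error")
})

test_that("maps are linear combinations of the stacked weights", {
  model <- structure(list(
    layers = list(
      structure(list(W = diag(2), a = c(0, 0), b = c(0, 0),
                     visible = "gaussian", sparsity_target = 0.1,
                     sparsity_weight = 0), class = "rbm"),
      structure(list(W = matrix(c(2, 0, 1, 1), 2, 2), a = c(0, 0),
                     b = c(0, 0), visible = "bernoulli",
                     sparsity_target = 0.1, sparsity_weight = 0),
                class = "rbm")),
    arch = c(2L, 2L), stage = "group",
    losses = list(1, 1), config = train_config(), provenance = "manual"),
    class = "vsdbn")
  maps <- extract_maps(model, zscore = FALSE)
  expect_equal(maps$layers[[1]], diag(2))
  expect_equal(maps$layers[[2]], rbind(c(2, 0), c(1, 1)))
  # W2 = identity leaves layer-2 maps equal to layer-1 maps
  model$layers[[2]]$W <- diag(2)
  maps2 <- extract_maps(model, zscore = FALSE)
  expect_equal(maps2$layers[[2]], maps2$layers[[1]])
})

test_that("z-scored maps have zero mean and unit variance per atom", {
  fx <- dbn_fixture()
  model <- vsdbn(fx$grp, arch = c(6, 4),
                 config = train_config(epochs = 3, seed = 53))
  maps <- extract_maps(model)
  for (l in 1:2) {
    expect_lt(max(abs(rowMeans(maps$layers[[l]]))), 1e-10)
    expect_lt(max(abs(sqrt(rowMeans(maps$layers[[l]]^2)) - 1)), 1e-10)
  }
  # sign convention: the max-|value| voxel of every atom is positive
  for (l in 1:2) {
    peaks <- apply(maps$layers[[l]], 1L, function(r) r[which.max(abs(r))])
    expect_true(all(peaks > 0))
  }
})

test_that("subject initialization copies the group weights exactly", {
  fx <- dbn_fixture()
  group <- vsdbn(fx$grp, arch = c(6, 4),
                 config = train_config(epochs = 3, seed = 54))
  subj <- init_subject_from_group(group, "s1")
  expect_equal(subj$stage, "subject:s1")
  for (l in 1:2) {
    expect_identical(subj$layers[[l]]$W, group$layers[[l]]$W)
    expect_identical(subj$layers[[l]]$b, group$layers[[l]]$b)
  }
  # zero-epoch fine-tuning is the identity: SCC = 1 for every atom
  tuned <- fine_tune_subject(subj, fx$subs[[1]], epochs = 0)
  gm <- extract_maps(group); sm <- extract_maps(tuned)
  for (l in 1:2)
    for (atom in seq_len(nrow(gm$layers[[l]])))
      expect_equal(scc(gm$layers[[l]][atom, ], sm$layers[[l]][atom, ]), 1)
  expect_error(init_subject_from_group(subj), "state error")
  expect_error(fine_tune_subject(group, fx$subs[[1]]), "state error")
})

test_that("fine-tuning moves subject maps away from the group solution", {
  fx <- dbn_fixture()
  group <- vsdbn(fx$grp, arch = c(6, 4),
                 config = train_config(epochs = 10, seed = 55))
  subj <- init_subject_from_group(group, "s1")
  tuned <- fine_tune_subject(subj, fx$subs[[1]], epochs = 10)
  gm <- extract_maps(group)$layers[[1]]
  sm <- extract_maps(tuned)$layers[[1]]
  sccs <- vapply(seq_len(nrow(gm)), function(a) scc(gm[a, ], sm[a, ]),
                 numeric(1))
  expect_true(all(sccs > 0 & sccs < 1))
})

test_that("the full stack is deterministic given its seeds", {
  fx <- dbn_fixture()
  m1 <- vsdbn(fx$grp, arch = c(5, 4),
              config = train_config(epochs = 4, seed = 56))
  m2 <- vsdbn(fx$grp, arch = c(5, 4),
              config = train_config(epochs = 4, seed = 56))
  expect_equal(extract_maps(m1)$layers, extract_maps(m2)$layers,
               tolerance = 1e-12)
})

test_that("models round-trip through the text serialization", {
  fx <- dbn_fixture()
  m <- vsdbn(fx$grp, arch = c(5, 4),
             config = train_config(epochs = 3, seed = 57))
  d <- tempfile()
  write_vsdbn(m, d)
  back <- read_vsdbn(d)
  expect_equal(back$arch, m$arch)
  expect_equal(back$layers[[1]]$W, m$layers[[1]]$W, tolerance = 1e-12)
  expect_equal(back$layers[[2]]$b, m$layers[[2]]$b, tolerance = 1e-12)
  expect_equal(back$stage, "group")
  # reconstruction agrees between original and reloaded model
  expect_equal(dbn_loss(back, fx$subs[[1]]), dbn_loss(m, fx$subs[[1]]),
               tolerance = 1e-10)
})
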