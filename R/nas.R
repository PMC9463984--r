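#' Configuration for the particle-swarm architecture search
#'
#' The search space is the DBN architecture: number of hidden layers in
#' `layer_range` and a shared per-layer node count in `node_range`.
#' Velocity and position updates follow
#' \deqn{v \leftarrow w v + c_1 R_1 (pbest - x) + c_2 R_2 (gbest - x),
#'       \qquad x \leftarrow x + v,}
#' with `R1`, `R2` drawn per step and per dimension from `rand_interval`
#' (default \[-1, 1\]; set `c(0, 1)` for the classical PSO variant).
#' Positions are continuous and only rounded when a candidate is evaluated.
#' Each iteration additionally retires the oldest particle and replaces it
#' with a mutated copy of a tournament winner (aging evolution), which
#' keeps the swarm diverse.
#'
#' @param n_particles swarm size (default 30).
#' @param w inertia weight (default 0.1).
#' @param w_schedule optional `c(w_start, w_end)` for a linearly decreasing
#'   inertia; overrides `w` when given.
#' @param c1,c2 cognitive and social acceleration constants (default 2, 2).
#' @param rand_interval support of the random factors (default `c(-1, 1)`).
#' @param layer_range,node_range inclusive search ranges (defaults
#'   `c(2, 10)` layers, `c(100, 800)` nodes).
#' @param n_iterations PSO iterations (default 40).
#' @param mutation_rate aging-evolution replacements per iteration (0
#'   disables mutation; default 1).
#' @param tournament_size parents sampled per mutation (default 3).
#' @param eval_budget training epochs per fitness evaluation (default 15).
#' @param seed RNG seed for the whole search.
#' @return a list of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 30, w = 0.1, w_schedule = NULL,
                         c1 = 2, c2 = 2, rand_interval = c(-1, 1),
                         layer_range = c(2, 10), node_range = c(100, 800),
                         n_iterations = 40, mutation_rate = 1,
                         tournament_size = 3, eval_budget = 15, seed = 1L) {
  stopifnot(n_particles >= 2, w >= 0, c1 >= 0, c2 >= 0,
            length(rand_interval) == 2, rand_interval[1] < rand_interval[2],
            layer_range[1] <= layer_range[2], node_range[1] <= node_range[2],
            n_iterations >= 1, mutation_rate >= 0, tournament_size >= 1,
            eval_budget >= 1)
  structure(list(n_particles = n_particles, w = w, w_schedule = w_schedule,
                 c1 = c1, c2 = c2, rand_interval = rand_interval,
                 layer_range = layer_range, node_range = node_range,
                 n_iterations = n_iterations, mutation_rate = mutation_rate,
                 tournament_size = tournament_size,
                 eval_budget = eval_budget, seed = as.integer(seed)),
            class = "swarm_config")
}

new_particle <- function(cfg) {
  pos <- c(stats::runif(1, cfg$layer_range[1], cfg$layer_range[2]),
           stats::runif(1, cfg$node_range[1], cfg$node_range[2]))
  list(nas = pos, v = c(0, 0), pbest = pos, pbest_fit = Inf, age = 0L)
}

clip_position <- function(pos, cfg) {
  c(min(max(pos[1], cfg$layer_range[1]), cfg$layer_range[2]),
    min(max(pos[2], cfg$node_range[1]), cfg$node_range[2]))
}

#' Round a continuous swarm position to an integer architecture
#'
#' @param pos length-2 numeric `(layers, nodes)`; `cfg` a [swarm_config()].
#' @return integer `(layers, nodes)`, clipped to the search ranges.
#' @export
round_arch <- function(pos, cfg) {
  as.integer(round(clip_position(round(pos), cfg)))
}

#' One PSO velocity/position update for a particle
#'
#' Draws `R1`, `R2` uniformly from `cfg$rand_interval` per dimension,
#' updates the velocity toward the particle's own best and the swarm best,
#' moves the particle, and clips the position to the search ranges.
#' Consumes the current RNG stream.
#'
#' @param p a particle (list with `nas`, `v`, `pbest`, `pbest_fit`, `age`).
#' @param gbest the swarm-best position (length-2 numeric).
#' @param cfg a [swarm_config()].
#' @param w inertia weight for this step (defaults to `cfg$w`).
#' @return the updated particle.
#' @export
pso_step <- function(p, gbest, cfg, w = cfg$w) {
  r1 <- stats::runif(2, cfg$rand_interval[1], cfg$rand_interval[2])
  r2 <- stats::runif(2, cfg$rand_interval[1], cfg$rand_interval[2])
  p$v <- w * p$v + cfg$c1 * r1 * (p$pbest - p$nas) +
    cfg$c2 * r2 * (gbest - p$nas)
  p$nas <- clip_position(p$nas + p$v, cfg)
  p
}

#' Aging-evolution mutation step
#'
#' Replaces the oldest particle in the swarm with a mutated copy of the
#' best of `tournament_size` randomly sampled particles: the parent's best
#' position is perturbed by +/-1 layer and/or +/-Uniform(10, 50) nodes
#' (each with probability 1/2, at least one applied), clipped to range.
#' The replacement starts with zero velocity, fresh age and an empty
#' personal-best history; the swarm-level best is kept outside the swarm
#' and is never lost.
#'
#' @param swarm list of particles; `cfg` a [swarm_config()].
#' @return the swarm with (at most) `mutation_rate` members replaced.
#' @export
mutate_aging <- function(swarm, cfg) {
  n_rep <- floor(cfg$mutation_rate)
  if (n_rep < 1) return(swarm)
  for (r in seq_len(n_rep)) {
    oldest <- which.max(vapply(swarm, `[[`, integer(1), "age"))
    cand <- sample.int(length(swarm), min(cfg$tournament_size, length(swarm)))
    parent <- swarm[[cand[which.min(
      vapply(swarm[cand], `[[`, numeric(1), "pbest_fit"))]]]
    pos <- parent$pbest
    do_layer <- stats::runif(1) < 0.5
    do_nodes <- stats::runif(1) < 0.5
    if (!do_layer && !do_nodes) {
      if (stats::runif(1) < 0.5) do_layer <- TRUE else do_nodes <- TRUE
    }
    if (do_layer) pos[1] <- pos[1] + sample(c(-1, 1), 1L)
    if (do_nodes) pos[2] <- pos[2] +
        sample(c(-1, 1), 1L) * stats::runif(1, 10, 50)
    pos <- clip_position(pos, cfg)
    swarm[[oldest]] <- list(nas = pos, v = c(0, 0), pbest = pos,
                            pbest_fit = Inf, age = 0L)
  }
  swarm
}

#' Architecture fitness: held-out reconstruction loss of a vsDBN
#'
#' Trains a DBN with `arch[1]` hidden layers of `arch[2]` nodes on a
#' seeded train split of `data` for `eval_budget` epochs per layer, and
#' returns the full-stack mean-field reconstruction MSE on the held-out
#' rows. Results are cached per rounded architecture within one search,
#' and a training failure is reported as `+Inf` fitness with a warning
#' rather than an error.
#'
#' @param arch integer `(layers, nodes)`.
#' @param data [data_matrix] or matrix (rows = volumes).
#' @param cfg a [swarm_config()].
#' @param cache optional environment used as a memo table.
#' @return scalar fitness (lower is better).
#' @export
dbn_fitness <- function(arch, data, cfg, cache = NULL) {
  key <- paste(arch[1], arch[2], cfg$seed, sep = "_")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  x <- if (inherits(data, "data_matrix")) data$values else data
  tcfg <- train_config(epochs = cfg$eval_budget, seed = cfg$seed)
  set.seed(cfg$seed)
  n <- nrow(x)
  test <- sample.int(n, max(1L, round(tcfg$test_fraction * n)))
  fit <- tryCatch({
    model <- vsdbn(x[-test, , drop = FALSE],
                   arch = rep(arch[2], arch[1]), config = tcfg,
                   provenance = "nas-candidate")
    dbn_loss(model, x[test, , drop = FALSE])
  }, error = function(e) {
    warning("fitness evaluation failed for architecture (",
            arch[1], ", ", arch[2], "): ", conditionMessage(e))
    Inf
  })
  if (!is.null(cache)) cache[[key]] <- fit
  fit
}

#' The benchmark fitness landscape for search validation
#'
#' A separable surrogate with a unique optimum at 3 layers and 146 nodes:
#' `|L - 3| + |N - 146| / 100`. Swapping it in for the DBN loss lets the
#' search dynamics be validated quickly and exactly.
#'
#' @param arch integer `(layers, nodes)`.
#' @return scalar fitness, 0 only at `(3, 146)`.
#' @export
toy_fitness <- function(arch) abs(arch[1] - 3) + abs(arch[2] - 146) / 100

#' Run the particle-swarm architecture search
#'
#' Initializes `n_particles` random architectures, then iterates
#' evaluate -> aging-evolution mutation -> PSO update, tracking each
#' particle's personal best and the swarm's global best. The global-best
#' fitness trace is non-increasing by construction. With
#' `cfg$w_schedule` set, the inertia decreases linearly across iterations.
#'
#' @param data [data_matrix] or matrix; ignored when `fitness_fn` is given.
#' @param cfg a [swarm_config()].
#' @param fitness_fn optional `function(arch)` replacing the DBN loss
#'   (e.g. [toy_fitness]).
#' @return object of class `nas_result`: `gbest` (integer architecture),
#'   `gbest_position`, `gbest_fitness`, `trace` (per-iteration best
#'   fitness, including iteration 0), `evals` (data frame of every
#'   evaluation), `cfg`.
#' @export
run_nas <- function(data = NULL, cfg = swarm_config(), fitness_fn = NULL) {
  cache <- new.env(parent = emptyenv())
  fn <- fitness_fn %||% function(arch) dbn_fitness(arch, data, cfg, cache)
  set.seed(cfg$seed)
  swarm <- replicate(cfg$n_particles, new_particle(cfg), simplify = FALSE)
  gbest <- NULL
  gbest_fit <- Inf
  evals <- list()
  evaluate <- function(swarm, iteration) {
    for (i in seq_along(swarm)) {
      arch <- round_arch(swarm[[i]]$nas, cfg)
      fit <- fn(arch)
      evals[[length(evals) + 1L]] <<- data.frame(
        iteration = iteration, particle = i,
        layers = arch[1], nodes = arch[2], fitness = fit)
      if (fit < swarm[[i]]$pbest_fit) {
        swarm[[i]]$pbest <- swarm[[i]]$nas
        swarm[[i]]$pbest_fit <- fit
      }
      if (fit < gbest_fit) {
        gbest_fit <<- fit
        gbest <<- swarm[[i]]$nas
      }
      swarm[[i]]$age <- swarm[[i]]$age + 1L
    }
    swarm
  }
  swarm <- evaluate(swarm, 0L)
  trace <- gbest_fit
  for (it in seq_len(cfg$n_iterations)) {
    w_it <- if (!is.null(cfg$w_schedule)) {
      cfg$w_schedule[1] + (cfg$w_schedule[2] - cfg$w_schedule[1]) *
        (it - 1) / max(1, cfg$n_iterations - 1)
    } else cfg$w
    swarm <- mutate_aging(swarm, cfg)
    for (i in seq_along(swarm))
      swarm[[i]] <- pso_step(swarm[[i]], gbest, cfg, w = w_it)
    swarm <- evaluate(swarm, it)
    trace <- c(trace, gbest_fit)
  }
  structure(
    list(gbest = round_arch(gbest, cfg), gbest_position = gbest,
         gbest_fitness = gbest_fit, trace = trace,
         evals = do.call(rbind, evals), cfg = cfg),
    class = "nas_result")
}

#' @export
print.nas_result <- function(x, ...) {
  cat("<nas_result> best architecture: ", x$gbest[1], " layers x ",
      x$gbest[2], " nodes (fitness ", signif(x$gbest_fitness, 4), ")\n",
      sep = "")
  invisible(x)
}

#' Repeat the architecture search and report dispersion
#'
#' Runs `run_nas` `n_repeats` times with derived seeds and summarizes how
#' stable the selected layers and node counts are across runs.
#'
#' @param data,cfg,fitness_fn as in [run_nas()].
#' @param n_repeats number of independent searches (default 10).
#' @return list with `runs` (list of `nas_result`), `selected` (data frame
#'   of per-run layers/nodes/fitness) and `dispersion` (ranges and SDs).
#' @export
run_nas_repeated <- function(data = NULL, cfg = swarm_config(),
                             fitness_fn = NULL, n_repeats = 10) {
  runs <- lapply(seq_len(n_repeats), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + 1000L * r
    run_nas(data, cfg_r, fitness_fn)
  })
  selected <- do.call(rbind, lapply(seq_along(runs), function(r)
    data.frame(run = r, layers = runs[[r]]$gbest[1],
               nodes = runs[[r]]$gbest[2],
               fitness = runs[[r]]$gbest_fitness)))
  dispersion <- list(
    layers_range = range(selected$layers),
    nodes_range = range(selected$nodes),
    layers_sd = stats::sd(selected$layers),
    nodes_sd = stats::sd(selected$nodes))
  list(runs = runs, selected = selected, dispersion = dispersion)
}
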