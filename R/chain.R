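#' Configuration of an iterated-learning chain
#'
#' One chain is a sequence of generations of `population` agents. Each
#' agent in generation g + 1 (the cultural child) is trained on
#' `bottleneck` labeled structures produced by a uniformly chosen agent of
#' generation g (the cultural parent), for `epochs` passes. With
#' `shuffle = TRUE` (Experiment 2) every training structure is passed
#' through the shuffling channel — its bits are permuted uniformly at
#' random, independently per example — so the child can no longer learn
#' anything tied to the identity of individual bit positions, only to the
#' number of T bits.
#'
#' Defaults are the reference experimental setting: structure size 10,
#' 10 agents, 301 generations; bottleneck sizes 200/512/715/1024 and
#' 4 or 8 epochs span the grid of interest.
#'
#' @param n structure size.
#' @param population agents per generation.
#' @param bottleneck labeled examples each child observes.
#' @param epochs training passes over the bottleneck sample.
#' @param generations number of generations, including generation 0.
#' @param shuffle logical; route examples through the shuffling channel.
#' @param master_seed integer seed from which all randomness of the run is
#'   derived.
#' @param replace draw bottleneck structures with replacement (the default)
#'   or without; without replacement requires
#'   `bottleneck <= 2^n`.
#' @param keep_confidences store each agent's raw confidences over all
#'   structures in the snapshots (needed for threshold profiles).
#' @param agent_config optional [agent_config()]; built from `n` and
#'   `epochs` when omitted.
#' @return A list of class `"chain_config"`.
#' @export
chain_config <- function(n = 10L, population = 10L, bottleneck = 1024L,
                         epochs = 8L, generations = 301L, shuffle = FALSE,
                         master_seed = 1L, replace = TRUE,
                         keep_confidences = FALSE, agent_config = NULL) {
  n <- .check_n(n)
  stopifnot(population >= 1, bottleneck >= 1, epochs >= 0, generations >= 1)
  if (!replace && bottleneck > 2^n) {
    stop("without replacement the bottleneck cannot exceed 2^n", call. = FALSE)
  }
  if (is.null(agent_config)) {
    agent_config <- agent_config(input_size = n, epochs = as.integer(epochs))
  }
  stopifnot(inherits(agent_config, "agent_config"),
            agent_config$input_size == n)
  structure(list(
    n = n, population = as.integer(population),
    bottleneck = as.integer(bottleneck), epochs = as.integer(epochs),
    generations = as.integer(generations), shuffle = isTRUE(shuffle),
    master_seed = as.integer(master_seed), replace = isTRUE(replace),
    keep_confidences = isTRUE(keep_confidences),
    agent_config = agent_config
  ), class = "chain_config")
}

#' Bottleneck sample produced by a parent agent
#'
#' Draws `size` structures uniformly at random (with replacement by
#' default) from the \eqn{2^n} structures and labels each with the parent's
#' rounded truth judgment. Randomness comes from the caller's RNG stream.
#'
#' @param parent the producing agent.
#' @param size number of labeled examples.
#' @param replace draw structures with or without replacement.
#' @return A list with `structures` (a `size x n` logical matrix) and
#'   `labels` (integer 0/1).
#' @export
sample_bottleneck <- function(parent, size, replace = TRUE) {
  parent <- .check_agent(parent)
  stopifnot(size >= 1)
  n <- parent$config$input_size
  idx <- sample.int(2^n, size, replace = replace)
  X <- all_structures(n)[idx, , drop = FALSE]
  list(structures = X, labels = produce_bit(parent, X))
}

#' The shuffling channel of Experiment 2
#'
#' Permutes the bits of every structure with a fresh uniform random
#' permutation, independently per example; labels pass through unchanged.
#' The number of T bits of each example is conserved, so only
#' count information survives the channel. Because each example is shuffled
#' independently, two examples with equal counts but different labels can
#' collide on the same child-visible structure: the child's data need not
#' be consistent even when the parent is.
#'
#' @param structures matrix of structures, one per row.
#' @param labels judgments aligned with the rows (returned untouched).
#' @return A list with shuffled `structures` and the unchanged `labels`.
#' @export
shuffle_channel <- function(structures, labels = NULL) {
  stopifnot(is.matrix(structures))
  n <- ncol(structures)
  out <- structures
  for (r in seq_len(nrow(structures))) {
    out[r, ] <- structures[r, sample.int(n)]
  }
  list(structures = out, labels = labels)
}

#' One generational transition
#'
#' For each of `config$population` children: choose a parent uniformly at
#' random (with replacement — one parent may teach several children), draw
#' a fresh bottleneck sample from it, pass the sample through the shuffling
#' channel if `config$shuffle`, and train a freshly initialized network on
#' it. Children never inherit weights.
#'
#' @param parents list of agents of the current generation.
#' @param config a [chain_config()].
#' @return A list with `children` (list of agents) and `parent_idx`
#'   (integer vector of the chosen parents).
#' @export
next_generation <- function(parents, config) {
  stopifnot(inherits(config, "chain_config"),
            length(parents) == config$population)
  parent_idx <- sample.int(config$population, config$population,
                           replace = TRUE)
  children <- vector("list", config$population)
  for (a in seq_len(config$population)) {
    data <- sample_bottleneck(parents[[parent_idx[a]]], config$bottleneck,
                              replace = config$replace)
    if (config$shuffle) {
      data <- shuffle_channel(data$structures, data$labels)
    }
    child <- init_agent(config$agent_config)
    children[[a]] <- train_agent(child, data$structures, data$labels,
                                 epochs = config$epochs)
  }
  list(children = children, parent_idx = parent_idx)
}

# snapshot one generation: extracted quantifiers plus all measures
.snapshot_generation <- function(agents, generation, parent_idx, config) {
  rows <- lapply(seq_along(agents), function(a) {
    q <- extract_quantifier(agents[[a]])
    m <- quantifier_measures(q)
    tibble::tibble(
      generation = generation,
      agent = a,
      parent = if (is.null(parent_idx)) NA_integer_ else parent_idx[a],
      quantifier = m$quantifier,
      upward = m$upward, downward = m$downward,
      monotonicity = m$monotonicity, quantity = m$quantity,
      degeneracy = m$degeneracy
    )
  })
  snap <- do.call(rbind, rows)
  if (config$keep_confidences) {
    snap$confidence <- lapply(agents, function(ag) {
      respond(ag, all_structures(config$n))
    })
  }
  snap
}

#' Run one iterated-learning chain
#'
#' Generation 0 consists of randomly initialized agents; each later
#' generation is produced by [next_generation()]. Every generation is
#' recorded as per-agent rows carrying the extracted quantifier (as a
#' '0'/'1' string) and all measures. The whole run — initialization, parent
#' choice, bottleneck samples, shuffles, minibatch order — is a
#' deterministic function of `config$master_seed`: the seed is set once and
#' all randomness is drawn sequentially from that single stream.
#'
#' @param config a [chain_config()].
#' @param quiet suppress per-generation progress messages.
#' @return An object of class `"quantifier_chain"`: a list with
#'   `snapshots` (a tibble with one row per agent per generation),
#'   `final_agents` (the last generation's agents) and `config`.
#' @export
run_chain <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "chain_config"))
  set.seed(config$master_seed)
  agents <- lapply(seq_len(config$population), function(a) {
    init_agent(config$agent_config)
  })
  snaps <- vector("list", config$generations)
  snaps[[1]] <- .snapshot_generation(agents, 0L, NULL, config)
  for (g in seq_len(config$generations - 1L)) {
    step <- next_generation(agents, config)
    agents <- step$children
    snaps[[g + 1L]] <- .snapshot_generation(agents, g, step$parent_idx,
                                            config)
    if (!quiet && g %% 25L == 0L) {
      message(sprintf("generation %d/%d, mean monotonicity %.3f",
                      g, config$generations - 1L,
                      mean(snaps[[g + 1L]]$monotonicity)))
    }
  }
  structure(list(
    snapshots = do.call(rbind, snaps),
    final_agents = agents,
    config = config
  ), class = "quantifier_chain")
}

#' @export
print.quantifier_chain <- function(x, ...) {
  last <- x$snapshots[x$snapshots$generation ==
                        max(x$snapshots$generation), ]
  cat(sprintf(
    "<quantifier_chain> n = %d, %d agents x %d generations (bottleneck %d, epochs %d, shuffle %s)\n",
    x$config$n, x$config$population, x$config$generations,
    x$config$bottleneck, x$config$epochs, x$config$shuffle))
  cat(sprintf("  final generation: mean monotonicity %.3f, mean quantity %.3f\n",
              mean(last$monotonicity), mean(last$quantity)))
  invisible(x)
}
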