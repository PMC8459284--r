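#' Configuration of a neural agent
#'
#' Each agent scores structures with a small feedforward network:
#' `input_size` inputs, two hidden layers of 16 rectified-linear units with
#' batch normalization on the second hidden layer, and one sigmoid output
#' giving a confidence in (0, 1) that the agent's quantifier holds of the
#' input structure. Training minimizes binary cross-entropy with minibatch
#' Adam. The optimizer and initialization hyperparameters are not forced by
#' the model and are exposed here; the defaults are the customary ones
#' (Adam lr 1e-3, betas 0.9/0.999, batch size 32, fan-in-scaled uniform
#' weight initialization, batch-norm momentum 0.1).
#'
#' @param input_size structure size n fed to the network.
#' @param hidden_sizes sizes of the two hidden layers.
#' @param epochs default number of passes over the training set.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param bn_momentum,bn_eps batch-norm running-average momentum and
#'   variance stabilizer.
#' @param init name of the weight initialization scheme (recorded in
#'   results files; only `"fan_in_uniform"` is implemented).
#' @return A list of class `"agent_config"`.
#' @export
agent_config <- function(input_size, hidden_sizes = c(16L, 16L),
                         epochs = 8L, batch_size = 32L,
                         learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, bn_momentum = 0.1, bn_eps = 1e-5,
                         init = "fan_in_uniform") {
  input_size <- .check_n(input_size)
  stopifnot(length(hidden_sizes) == 2L, all(hidden_sizes >= 1),
            epochs >= 0, batch_size >= 1, learning_rate > 0)
  init <- match.arg(init, "fan_in_uniform")
  structure(list(
    input_size = input_size,
    hidden_sizes = as.integer(hidden_sizes),
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
    bn_momentum = bn_momentum, bn_eps = bn_eps,
    init = init
  ), class = "agent_config")
}

# fan-in-scaled uniform draw, the default scheme of common frameworks
.init_linear <- function(out, inn) {
  k <- 1 / sqrt(inn)
  list(W = matrix(runif(out * inn, -k, k), out, inn),
       b = runif(out, -k, k))
}

#' Create a randomly initialized agent
#'
#' Weights and biases of the linear layers are drawn uniformly in
#' \eqn{\pm 1/\sqrt{fan\_in}}; batch-norm scale/shift start at 1/0 and the
#' running statistics at mean 0, variance 1. With `seed` given, the draw is
#' performed under that seed without disturbing the caller's RNG stream;
#' with `seed = NULL` the current RNG stream is consumed (this is how the
#' iterated-learning chain derives every agent from one master seed).
#'
#' @param config an [agent_config()].
#' @param seed optional integer seed for a self-contained reproducible draw.
#' @return An object of class `"agent"`: a list with `params` (named
#'   weight arrays) and `config`.
#' @export
init_agent <- function(config, seed = NULL) {
  stopifnot(inherits(config, "agent_config"))
  draw <- function() {
    h <- config$hidden_sizes
    l1 <- .init_linear(h[1], config$input_size)
    l2 <- .init_linear(h[2], h[1])
    l3 <- .init_linear(1L, h[2])
    list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b,
         gamma = rep(1, h[2]), beta = rep(0, h[2]),
         rmean = rep(0, h[2]), rvar = rep(1, h[2]),
         W3 = matrix(l3$W, 1L, h[2]), b3 = l3$b)
  }
  params <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(params = params, config = config), class = "agent")
}

#' @export
print.agent <- function(x, ...) {
  cat(sprintf("<agent> %d-%d-%d-1 feedforward scorer\n",
              x$config$input_size, x$config$hidden_sizes[1],
              x$config$hidden_sizes[2]))
  invisible(x)
}

.check_agent <- function(agent) {
  if (!inherits(agent, "agent")) stop("not an agent", call. = FALSE)
  agent
}

.as_input_matrix <- function(agent, M) {
  n <- agent$config$input_size
  if (is.matrix(M)) {
    if (ncol(M) != n) {
      stop("structures must have length ", n, call. = FALSE)
    }
    return(matrix(as.numeric(M), nrow(M), n))
  }
  M <- .check_structure(M)
  if (length(M) != n) stop("structure must have length ", n, call. = FALSE)
  matrix(as.numeric(M), 1L, n)
}

#' Agent production: confidences and rounded truth judgments
#'
#' `respond()` runs the network in inference mode and returns a confidence
#' strictly inside (0, 1); production is deterministic — the same agent
#' always returns the same value for the same structure. `produce_bit()`
#' rounds the confidence: values of 0.5 or more map to 1 (the tie at
#' exactly 0.5 is documented to round up). `extract_quantifier()` rounds
#' the responses on all \eqn{2^n} structures, yielding the truth table the
#' agent currently encodes.
#'
#' @section Batch-norm statistics at inference:
#' With `stats = "population"` (the default) the batch-norm layer
#' normalizes with the activation statistics of the full structure space
#' under the current parameters. This keeps the network's judgments
#' centered over the domain it is quantifying: freshly initialized agents
#' then encode diverse, largely non-degenerate truth tables, which is the
#' random-agent baseline regime the iterated-learning results are measured
#' against, and it is deterministic per structure regardless of how
#' production calls are batched. `stats = "running"` instead uses the
#' running averages accumulated during training (the textbook inference
#' mode); for untrained agents these are the initialization constants
#' (mean 0, variance 1), which makes most random agents degenerate. See
#' the methods vignette for why the population mode is the default.
#'
#' @param agent an [init_agent()] result.
#' @param M one structure, or a matrix of structures (one per row).
#' @param stats `"population"` or `"running"` batch-norm statistics.
#' @return `respond()`: numeric confidences in (0, 1); `produce_bit()`:
#'   integer 0/1 of the same length; `extract_quantifier()`: a
#'   `"quantifier"`.
#' @export
respond <- function(agent, M, stats = c("population", "running")) {
  agent <- .check_agent(agent)
  stats <- match.arg(stats)
  X <- .as_input_matrix(agent, M)
  if (stats == "running") {
    return(as.numeric(.nn_forward(agent$params, X, agent$config$bn_eps)))
  }
  n <- agent$config$input_size
  S <- all_structures(n)
  Xref <- matrix(as.numeric(S), nrow(S), n)
  as.numeric(.nn_forward_ref(agent$params, X, Xref, agent$config$bn_eps))
}

#' @rdname respond
#' @export
produce_bit <- function(agent, M, stats = c("population", "running")) {
  as.integer(respond(agent, M, stats = stats) >= 0.5)
}

#' @rdname respond
#' @export
extract_quantifier <- function(agent, stats = c("population", "running")) {
  agent <- .check_agent(agent)
  n <- agent$config$input_size
  p <- respond(agent, all_structures(n), stats = stats)
  as_quantifier(p >= 0.5, n)
}

#' Train an agent on labeled structures
#'
#' Minibatch Adam on binary cross-entropy, iterating over the training set
#' `epochs` times with the example order reshuffled every epoch. The
#' shuffles are drawn from the caller's RNG stream, so training is fully
#' reproducible given the RNG state (or one master seed upstream). With
#' `epochs = 0` the agent is returned unchanged.
#'
#' @param agent the agent to train (its parameters are updated functionally;
#'   a new agent is returned).
#' @param structures matrix of training structures, one per row.
#' @param labels 0/1 vector of truth judgments, one per row of `structures`.
#' @param epochs number of passes over the training set; defaults to the
#'   agent config.
#' @param batch_size minibatch size; defaults to the agent config.
#' @return The trained `"agent"`.
#' @export
train_agent <- function(agent, structures, labels,
                        epochs = agent$config$epochs,
                        batch_size = agent$config$batch_size) {
  agent <- .check_agent(agent)
  X <- .as_input_matrix(agent, structures)
  if (nrow(X) == 0L) stop("training set must be non-empty", call. = FALSE)
  labels <- as.numeric(labels)
  if (length(labels) != nrow(X) || !all(labels %in% c(0, 1))) {
    stop("labels must be one 0/1 judgment per structure", call. = FALSE)
  }
  stopifnot(epochs >= 0, batch_size >= 1)
  if (epochs == 0) return(agent)
  perms <- vapply(seq_len(epochs), function(e) sample.int(nrow(X)),
                  integer(nrow(X)))
  perms <- matrix(perms, nrow = nrow(X), ncol = epochs)
  cfg <- agent$config
  agent$params <- .nn_train(agent$params, X, labels,
                            as.integer(epochs), as.integer(batch_size),
                            cfg$learning_rate, cfg$beta1, cfg$beta2,
                            cfg$adam_eps, cfg$bn_momentum, cfg$bn_eps,
                            perms)
  agent
}
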