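# Function-approximator neurons: a linear feed-forward layer with optional
# nonlinearity, and an opaque trainable multilayer-perceptron layer. Both map
# the firing rates of input populations to their own rates and bypass min/max
# scaling (outputs are unconstrained reals).

# Activation registry: each entry pairs the function with its analytic
# derivative. The softmax "derivative" is the elementwise diagonal of the
# Jacobian, the convention learning rules here expect.
.activations <- list(
  linear = list(f = function(x) x, df = function(x) rep(1, length(x))),
  relu = list(f = function(x) pmax(x, 0), df = function(x) as.numeric(x > 0)),
  sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                 df = function(x) { s <- 1 / (1 + exp(-x)); s * (1 - s) }),
  tanh = list(f = base::tanh, df = function(x) 1 - base::tanh(x)^2),
  retanh = list(f = function(x) pmax(base::tanh(x), 0),
                df = function(x) (1 - base::tanh(x)^2) * (x > 0)),
  softmax = list(f = function(x) { e <- exp(x - max(x)); e / sum(e) },
                 df = function(x) {
                   e <- exp(x - max(x)); s <- e / sum(e); s * (1 - s)
                 })
)

#' Look up a named activation function and its derivative
#' @param name One of `"linear"`, `"relu"`, `"sigmoid"`, `"tanh"`,
#'   `"retanh"`, `"softmax"`.
#' @return A list with elements `f` and `df`.
#' @export
activation_fns <- function(name) {
  if (!name %in% names(.activations))
    stop("unknown activation: ", name, " (available: ",
         paste(names(.activations), collapse = ", "), ")")
  .activations[[name]]
}

.input_info <- function(inputs) {
  if (!length(inputs)) stop("at least one input population is required")
  nm <- names(inputs)
  if (is.null(nm)) nm <- vapply(inputs, function(p) p$name, "")
  list(names = nm, sizes = vapply(inputs, function(p) p$n, 1L))
}

#' Feed-forward layer of function-approximator neurons
#'
#' Each neuron computes a weighted sum of the rates of all input populations
#' plus a bias, passed through an activation function:
#' `r_i = sum_j sum_k w_ik^j F_k^j + b_i`, `F_i = phi(r_i)`. The derivative
#' `phi'(r_i)` is recomputed and stored on every update for use by learning
#' rules. Weights are initialised `w ~ N(0, g / n_j)` per input layer.
#'
#' @param inputs A (preferably named) list of input populations.
#' @param n Number of neurons in this layer.
#' @param activation Activation name (see [activation_fns]), default
#'   `"linear"`.
#' @param biases Bias vector (recycled to length n), default 0.
#' @param w_init_scale Weight initialisation variance scale `g`.
#' @param name Population label.
#' @return A population of class `c("FeedForwardLayer", "Neurons")`, with
#'   `$weights` (one matrix per input layer), `$biases`, and after updates
#'   `$pre_activation` and `$phi_prime`.
#' @export
FeedForwardLayer <- function(inputs, n = 10, activation = "linear",
                             biases = 0, w_init_scale = 1,
                             name = "FeedForwardLayer") {
  info <- .input_info(inputs)
  env <- inputs[[1]]$env
  pop <- .neurons_base(env, n, name, scale = FALSE)
  pop$input_names <- info$names
  pop$input_sizes <- info$sizes
  pop$weights <- lapply(info$sizes, function(nj)
    matrix(stats::rnorm(n * nj, 0, sqrt(w_init_scale / nj)), n, nj))
  names(pop$weights) <- info$names
  pop$biases <- rep_len(biases, n)
  pop$activation <- activation
  pop$pre_activation <- numeric(n)
  pop$phi_prime <- numeric(n)
  class(pop) <- c("FeedForwardLayer", "Neurons")
  pop
}

#' Evaluate a feed-forward wiring on input rates
#'
#' @param wiring A [FeedForwardLayer] (or any list with `weights`, `biases`,
#'   `activation`, `input_sizes`).
#' @param input_rates A list of rate vectors, one per input layer, in
#'   declared order.
#' @return A list with `r` (pre-activations), `F` (rates) and `phi_prime`.
#' @export
feedforward_rate <- function(wiring, input_rates) {
  if (length(input_rates) != length(wiring$weights))
    stop("expected ", length(wiring$weights), " input rate vectors")
  r <- wiring$biases
  for (j in seq_along(input_rates)) {
    Fj <- as.numeric(input_rates[[j]])
    if (length(Fj) != ncol(wiring$weights[[j]]))
      stop("input ", j, " has length ", length(Fj), ", expected ",
           ncol(wiring$weights[[j]]))
    r <- r + as.numeric(wiring$weights[[j]] %*% Fj)
  }
  act <- activation_fns(wiring$activation)
  list(r = r, F = act$f(r), phi_prime = act$df(r))
}

#' @export
raw_rates.FeedForwardLayer <- function(pop, state, ..., input_rates = NULL) {
  if (is.null(input_rates)) stop("FeedForwardLayer needs `input_rates`")
  matrix(feedforward_rate(pop, input_rates)$F, nrow = 1)
}

#' @export
update_neurons.FeedForwardLayer <- function(pop, agent, dt, ...,
                                            input_rates = NULL) {
  if (is.null(input_rates)) stop("FeedForwardLayer needs `input_rates`")
  out <- feedforward_rate(pop, input_rates)
  pop$pre_activation <- out$r
  pop$phi_prime <- out$phi_prime
  r <- out$F
  if (pop$noise_std > 0) {
    pop$noise <- ou_step(pop$noise, dt, pop$noise_coherence_time,
                         pop$noise_std, 0)
    r <- r + pop$noise
  }
  pop$rates <- as.numeric(r)
  pop$spikes <- sample_spikes(pop$rates, dt)
  state <- if (inherits(agent, "Agent")) agent_state(agent) else agent
  pop$t <- state$t
  pop
}

# --- multilayer perceptron handle -----------------------------------------

#' Construct a small multilayer perceptron
#'
#' A plain dense network (default two hidden ReLU layers of size 20 and a
#' linear readout) usable as the opaque network of [NeuralNetworkNeurons].
#' Forward passes cache layer activations so gradients can be taken for
#' training.
#'
#' @param n_in,n_out Input and output dimensions.
#' @param hidden Hidden layer sizes.
#' @param activation Hidden activation name.
#' @return A list with `forward(x)` semantics via [mlp_forward], weight
#'   matrices `W`, biases `b`, and metadata; class `"mlp_network"`.
#' @export
mlp_network <- function(n_in, n_out = 1, hidden = c(20, 20),
                        activation = "relu") {
  sizes <- c(n_in, hidden, n_out)
  L <- length(sizes) - 1
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l + 1] * sizes[l], 0, sqrt(2 / sizes[l])),
           sizes[l + 1], sizes[l]))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  structure(list(W = W, b = b, sizes = sizes, activation = activation),
            class = "mlp_network")
}

#' Forward pass through an [mlp_network]
#' @param net An `mlp_network`.
#' @param x Input vector of length `net$sizes[1]`.
#' @return A list with `y` (output vector) and `cache` (per-layer
#'   pre-activations and activities, for [mlp_gradient]).
#' @export
mlp_forward <- function(net, x) {
  if (length(x) != net$sizes[1])
    stop("input length ", length(x), ", network expects ", net$sizes[1])
  act <- activation_fns(net$activation)
  L <- length(net$W)
  a <- list(as.numeric(x)); z <- vector("list", L)
  for (l in seq_len(L)) {
    z[[l]] <- as.numeric(net$W[[l]] %*% a[[l]] + net$b[[l]])
    a[[l + 1]] <- if (l < L) act$f(z[[l]]) else z[[l]]  # linear readout
  }
  list(y = a[[L + 1]], cache = list(a = a, z = z))
}

#' Backpropagate an output gradient through an [mlp_network]
#' @param net An `mlp_network`.
#' @param cache The `cache` from [mlp_forward].
#' @param dLdy Gradient of the loss with respect to the output.
#' @return A list with `dW`, `db` (same shapes as `net$W`, `net$b`).
#' @export
mlp_gradient <- function(net, cache, dLdy) {
  act <- activation_fns(net$activation)
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- as.numeric(dLdy)
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * act$df(cache$z[[l]])
    dW[[l]] <- outer(delta, cache$a[[l]])
    db[[l]] <- delta
    if (l > 1) delta <- as.numeric(t(net$W[[l]]) %*% delta)
  }
  list(dW = dW, db = db)
}

#' Apply a gradient step to an [mlp_network]
#' @param net An `mlp_network`.
#' @param grads Gradients from [mlp_gradient].
#' @param lr Learning rate.
#' @param momentum Momentum coefficient; velocity is kept in `net$vel`.
#' @return The updated network.
#' @export
mlp_sgd_step <- function(net, grads, lr, momentum = 0) {
  if (is.null(net$vel))
    net$vel <- list(dW = lapply(net$W, function(w) w * 0),
                    db = lapply(net$b, function(x) x * 0))
  for (l in seq_along(net$W)) {
    net$vel$dW[[l]] <- momentum * net$vel$dW[[l]] - lr * grads$dW[[l]]
    net$vel$db[[l]] <- momentum * net$vel$db[[l]] - lr * grads$db[[l]]
    net$W[[l]] <- net$W[[l]] + net$vel$dW[[l]]
    net$b[[l]] <- net$b[[l]] + net$vel$db[[l]]
  }
  net
}

#' Neural-network neurons
#'
#' The rates of the input populations are concatenated (in declared order)
#' and passed through an opaque network (any object with the `mlp_network`
#' forward contract). The forward cache of the last update is retained in
#' `$last_forward` so users can take gradients and train the network online.
#'
#' @param inputs A (preferably named) list of input populations.
#' @param network An [mlp_network]; default two hidden ReLU layers of
#'   size 20 with a single linear output.
#' @param name Population label.
#' @return A population of class `c("NeuralNetworkNeurons", "Neurons")`.
#' @export
NeuralNetworkNeurons <- function(inputs, network = NULL,
                                 name = "NeuralNetworkNeurons") {
  info <- .input_info(inputs)
  n_in <- sum(info$sizes)
  if (is.null(network)) network <- mlp_network(n_in, 1, c(20, 20), "relu")
  if (network$sizes[1] != n_in)
    stop("network expects ", network$sizes[1], " inputs, populations supply ",
         n_in)
  env <- inputs[[1]]$env
  pop <- .neurons_base(env, network$sizes[length(network$sizes)], name,
                       scale = FALSE)
  pop$input_names <- info$names
  pop$input_sizes <- info$sizes
  pop$network <- network
  pop$last_forward <- NULL
  class(pop) <- c("NeuralNetworkNeurons", "Neurons")
  pop
}

#' @export
raw_rates.NeuralNetworkNeurons <- function(pop, state, ...,
                                           input_rates = NULL) {
  if (is.null(input_rates)) stop("NeuralNetworkNeurons need `input_rates`")
  x <- unlist(lapply(input_rates, as.numeric), use.names = FALSE)
  matrix(mlp_forward(pop$network, x)$y, nrow = 1)
}

#' @export
update_neurons.NeuralNetworkNeurons <- function(pop, agent, dt, ...,
                                                input_rates = NULL) {
  if (is.null(input_rates)) stop("NeuralNetworkNeurons need `input_rates`")
  x <- unlist(lapply(input_rates, as.numeric), use.names = FALSE)
  fwd <- mlp_forward(pop$network, x)
  pop$last_forward <- c(fwd, list(x = x))
  pop$rates <- as.numeric(fwd$y)
  pop$spikes <- sample_spikes(pop$rates, dt)
  state <- if (inherits(agent, "Agent")) agent_state(agent) else agent
  pop$t <- state$t
  pop
}

# --- composition ----------------------------------------------------------

#' Order populations for one simulation step
#'
#' Topologically sorts populations so every function-approximator layer is
#' updated after its inputs. Cycles (including self-loops) are broken by
#' falling back to declaration order; a layer updated before one of its
#' inputs then reads that input's previous-step rates, i.e. recurrent
#' connections carry a one-step delay.
#'
#' @param pops A named list of populations.
#' @return Character vector of population names in update order.
#' @export
update_schedule <- function(pops) {
  nm <- names(pops)
  if (is.null(nm) || any(nm == ""))
    stop("`pops` must be a fully named list")
  deps <- lapply(pops, function(p) {
    d <- intersect(p$input_names %||% character(0), nm)
    unknown <- setdiff(p$input_names %||% character(0), nm)
    if (length(unknown))
      stop("population references undeclared input(s): ",
           paste(unknown, collapse = ", "))
    d
  })
  order <- character(0)
  remaining <- nm
  repeat {
    ready <- remaining[vapply(remaining, function(x)
      all(deps[[x]] %in% order), TRUE)]
    if (!length(ready)) { order <- c(order, remaining); break }  # cycle
    order <- c(order, ready[1])
    remaining <- setdiff(remaining, ready[1])
    if (!length(remaining)) break
  }
  order
}

`%||%` <- function(a, b) if (is.null(a)) b else a
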