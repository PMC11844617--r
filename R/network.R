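# Feedforward networks with Taylor-jet differentiation.
#
# The C++ backend (src/jetnet.cpp) propagates, per input point, the network
# value together with directional Taylor coefficients T_k = (1/k!) d^k/dt^k
# N(x + t v) up to order 4, and back-propagates cotangents on (value, T_k)
# into exact weight/bias gradients.  First derivatives, Hessians and the
# biharmonic operator are assembled in R from small direction sets.

#' Describe a feedforward network
#'
#' @param input_dim Number of input coordinates (2, 3, or 4 with time).
#' @param output_dim Number of outputs of the head.
#' @param widths Integer vector of hidden-layer widths.
#' @param activation Hidden activation; only `"swish"` is implemented.
#' @param init Weight initialization; only `"glorot-uniform"` is implemented.
#' @return A `network_spec` object.
#' @export
network_spec <- function(input_dim, output_dim, widths,
                         activation = "swish", init = "glorot-uniform") {
  stopifnot(input_dim >= 1, output_dim >= 1, length(widths) >= 1,
            all(widths > 0))
  activation <- match.arg(activation, "swish")
  init <- match.arg(init, "glorot-uniform")
  structure(list(input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 widths = as.integer(widths),
                 activation = activation, init = init),
            class = "network_spec")
}

#' Initialize network weights (Glorot uniform) and zero biases
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed; initialization is deterministic given the seed.
#' @return A network object: list with `W` (weight matrices), `b` (bias
#'   vectors) and the spec.
#' @export
mlp_init <- function(spec, seed = 0L) {
  dims <- c(spec$input_dim, spec$widths, spec$output_dim)
  net <- list(W = vector("list", length(dims) - 1L),
              b = vector("list", length(dims) - 1L),
              spec = spec)
  with_seed(seed, {
    for (l in seq_len(length(dims) - 1L)) {
      fan_in <- dims[l]; fan_out <- dims[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      net$W[[l]] <- matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
      net$b[[l]] <- rep(0, fan_out)
    }
  })
  class(net) <- "mlp"
  net
}

#' Evaluate a network and its directional Taylor coefficients
#'
#' @param net An object from [mlp_init()].
#' @param X Matrix of input points (rows).
#' @param directions List of direction matrices (each `nrow(X)` x input_dim,
#'   or a single direction vector recycled over points).
#' @param order Jet order M (0--4); `T[[d]][[k]]` holds the k-th Taylor
#'   coefficient along direction d, so the k-th directional derivative is
#'   `factorial(k) * T[[d]][[k]]`.
#' @return List with `y` (values) and `T` (coefficients).
#' @export
mlp_jet <- function(net, X, directions = list(), order = 0L, tape = FALSE) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == net$spec$input_dim, order >= 0, order <= 4)
  dirs <- lapply(directions, function(v) {
    if (is.matrix(v)) v else matrix(v, nrow(X), length(v), byrow = TRUE)
  })
  if (order == 0L) dirs <- list()
  .jet_forward(net$W, net$b, X, dirs, as.integer(order), tape)
}

# Reverse pass over a taped forward: gradients of
# sum(ybar * y) + sum(Tbar * T) with respect to all weights and biases.
# `Tbar` is a list over directions of lists over orders; NULL entries are
# treated as zero.
mlp_backward <- function(fwd, ybar = NULL, Tbar = NULL, free = TRUE) {
  if (is.null(Tbar)) Tbar <- rep(list(list()), length(fwd$T))
  .jet_backward(fwd$tape, ybar, Tbar, free)
}

# One-shot convenience (forward + reverse); training loops use the taped
# pair directly.
mlp_vjp <- function(net, X, directions, order, ybar = NULL, Tbar = NULL) {
  fwd <- mlp_jet(net, X, directions, order, tape = TRUE)
  mlp_backward(fwd, ybar, Tbar)
}

# --- flat parameter vector helpers (for the optimizer) ---

net_nparams <- function(net) {
  sum(vapply(net$W, length, 1L)) + sum(vapply(net$b, length, 1L))
}

net_flatten <- function(net) {
  unlist(c(lapply(net$W, as.numeric), lapply(net$b, as.numeric)),
         use.names = FALSE)
}

net_unflatten <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    k <- length(net$W[[l]])
    net$W[[l]][] <- theta[pos + seq_len(k)]; pos <- pos + k
  }
  for (l in seq_along(net$b)) {
    k <- length(net$b[[l]])
    net$b[[l]][] <- theta[pos + seq_len(k)]; pos <- pos + k
  }
  net
}

grads_flatten <- function(g) {
  unlist(c(lapply(g$gW, as.numeric), lapply(g$gb, as.numeric)),
         use.names = FALSE)
}

# --- bounded trainable parameters ---

#' Bounded trainable material parameter
#'
#' The realized value is `lower + (upper - lower) * plogis(raw)`; the raw
#' latent scalar is optimized unconstrained, so the value stays strictly
#' inside `(lower, upper)`.  `raw = 0` realizes the interval midpoint, the
#' initialization used for all inverse runs.
#'
#' @param name Parameter name (e.g. `"E"`, `"nu"`, `"c0"`).
#' @param lower,upper Search range bounds (`lower < upper`).
#' @param raw Initial latent value.
#' @return A `bounded_param` object.
#' @export
bounded_param <- function(name, lower, upper, raw = 0) {
  stopifnot(is.character(name), lower < upper)
  structure(list(name = name, lower = lower, upper = upper, raw = raw),
            class = "bounded_param")
}

#' Realize a bounded parameter value from its latent scalar
#'
#' @param raw Latent scalar (any real number).
#' @param lower,upper Bounds.
#' @return Value in `(lower, upper)`; the logistic midpoint at `raw = 0`.
#' @export
bounded_transform <- function(raw, lower, upper) {
  lower + (upper - lower) * plogis(raw)
}

#' Inverse of [bounded_transform()]
#'
#' @param value Value strictly inside `(lower, upper)`.
#' @param lower,upper Bounds.
#' @return The latent scalar mapping to `value`.
#' @export
bounded_inverse <- function(value, lower, upper) {
  stopifnot(all(value > lower), all(value < upper))
  qlogis((value - lower) / (upper - lower))
}

# d value / d raw, used in the training chain rule
bounded_dvalue <- function(raw, lower, upper) {
  s <- plogis(raw)
  (upper - lower) * s * (1 - s)
}

# --- optimizer ---

adam_new <- function(n, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = numeric(n), v = numeric(n), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(st, theta, grad, lr = st$lr) {
  st$t <- st$t + 1L
  st$m <- st$beta1 * st$m + (1 - st$beta1) * grad
  st$v <- st$beta2 * st$v + (1 - st$beta2) * grad^2
  mhat <- st$m / (1 - st$beta1^st$t)
  vhat <- st$v / (1 - st$beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + st$eps), state = st)
}

#' Learning-rate schedule
#'
#' Staircase inverse-time decay `lr0 / (1 + rate * floor(iter / interval))`
#' (default), a multiplicative staircase `lr0 * (1 - rate)^floor(...)`, or a
#' continuous inverse-time decay `lr0 / (1 + rate * iter / interval)`.
#'
#' @param iter Iteration number (0-based).
#' @param lr0 Initial learning rate.
#' @param rate Decay rate.
#' @param interval Iterations between decay steps.
#' @param kind One of `"inverse-time-staircase"`, `"multiplicative"`,
#'   `"inverse-time"`.
#' @return The learning rate at `iter`.
#' @export
lr_schedule <- function(iter, lr0 = 1e-3, rate = 0.15, interval = 15000L,
                        kind = c("inverse-time-staircase", "multiplicative",
                                 "inverse-time")) {
  kind <- match.arg(kind)
  switch(kind,
    "inverse-time-staircase" = lr0 / (1 + rate * floor(iter / interval)),
    "multiplicative" = lr0 * (1 - rate)^floor(iter / interval),
    "inverse-time" = lr0 / (1 + rate * iter / interval))
}

# Run an expression with a temporary RNG state (deterministic, side-effect
# free for the caller).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
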