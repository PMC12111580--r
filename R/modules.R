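# Minimal neural-network module system: a module is an environment carrying
# named parameter nodes, named child modules, optional buffers (e.g. batch-norm
# running statistics) and a training flag. The common contract required of
# every block is: sr_forward(module, x) -> node, sr_parameters(module),
# sr_set_training(module, flag), sr_count(module, in_shape) for accounting.

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$params <- list()
  m$children <- list()
  m$training <- TRUE
  class(m) <- c(paste0("sr_", type), "sr_module")
  m
}

reg_param <- function(m, name, value) {
  m$params[[name]] <- ag_param(value)
  invisible(m)
}

#' Forward pass through a network module
#' @param m a module built by one of the `mod_*` constructors.
#' @param x input `ag` node (or array).
#' @param ... passed to methods.
#' @return output `ag` node.
#' @export
sr_forward <- function(m, x, ...) UseMethod("sr_forward")

#' Enumerate trainable parameters of a module tree
#' @param m a module.
#' @return named list of parameter nodes (names are `/`-separated paths).
#' @export
sr_parameters <- function(m) {
  out <- list()
  walk <- function(mod, prefix) {
    for (nm in names(mod$params)) out[[paste0(prefix, nm)]] <<- mod$params[[nm]]
    for (nm in names(mod$children)) walk(mod$children[[nm]], paste0(prefix, nm, "/"))
  }
  walk(m, "")
  out
}

#' Switch a module tree between training and evaluation mode
#' @param m a module.
#' @param training logical.
#' @export
sr_set_training <- function(m, training) {
  m$training <- training
  for (ch in m$children) sr_set_training(ch, training)
  invisible(m)
}

#' Count trainable scalar parameters
#' @param model a module.
#' @return integer-valued count.
#' @export
count_params <- function(model) {
  sum(vapply(sr_parameters(model), function(p) length(p$v), numeric(1)))
}

#' Operator-level complexity accounting
#'
#' Returns the multiply-accumulate count of one forward pass and the output
#' shape, given an input shape `(C, H, W)` (batch excluded). Convolutions,
#' linear layers and attention matrix products are counted; normalizations and
#' activations are not.
#' @param m a module.
#' @param in_shape integer vector `(C, H, W)`.
#' @return list with `macs` and `out` (the output `(C, H, W)` shape).
#' @export
sr_count <- function(m, in_shape) UseMethod("sr_count")

# ---- initializers ---------------------------------------------------------

init_conv_w <- function(cout, cin, kh, kw) {
  fan_in <- cin * kh * kw
  array(stats::rnorm(cout * cin * kh * kw, sd = sqrt(2 / fan_in)),
        c(cout, cin, kh, kw))
}

init_linear_w <- function(dout, din) {
  matrix(stats::rnorm(dout * din, sd = 0.02), dout, din)
}

# ---- conv2d ---------------------------------------------------------------

#' 2-D convolution module
#' @param cin,cout channel counts.
#' @param k kernel size; scalar or `(kh, kw)`.
#' @param stride,pad stride and zero padding; scalars or `(height, width)`.
#' @param bias include an additive bias?
#' @return a module.
#' @export
mod_conv2d <- function(cin, cout, k, stride = 1L, pad = 0L, bias = TRUE) {
  m <- new_module("conv2d")
  k <- rep(as.integer(k), length.out = 2)
  m$cin <- cin; m$cout <- cout; m$k <- k
  m$stride <- rep(as.integer(stride), length.out = 2)
  m$pad <- rep(as.integer(pad), length.out = 2)
  reg_param(m, "w", init_conv_w(cout, cin, k[1], k[2]))
  if (bias) reg_param(m, "b", numeric(cout))
  m
}

#' @export
sr_forward.sr_conv2d <- function(m, x, ...) {
  ag_conv2d(x, m$params$w, m$params$b, stride = m$stride, pad = m$pad)
}

#' @export
sr_count.sr_conv2d <- function(m, in_shape) {
  ho <- (in_shape[2] + 2 * m$pad[1] - m$k[1]) %/% m$stride[1] + 1
  wo <- (in_shape[3] + 2 * m$pad[2] - m$k[2]) %/% m$stride[2] + 1
  list(macs = m$k[1] * m$k[2] * m$cin * m$cout * ho * wo, out = c(m$cout, ho, wo))
}

# ---- batchnorm ------------------------------------------------------------

#' Batch-normalization module (2-D, per channel)
#' @param c channel count.
#' @return a module.
#' @export
mod_bn2d <- function(c) {
  m <- new_module("bn2d")
  m$c <- c
  reg_param(m, "gamma", rep(1, c))
  reg_param(m, "beta", numeric(c))
  m$state <- new.env(parent = emptyenv())
  m$state$rm <- numeric(c)
  m$state$rv <- rep(1, c)
  m
}

#' @export
sr_forward.sr_bn2d <- function(m, x, ...) {
  ag_bn2d(x, m$params$gamma, m$params$beta, m$state, training = m$training)
}

#' @export
sr_count.sr_bn2d <- function(m, in_shape) list(macs = 0, out = in_shape)

# ---- linear ---------------------------------------------------------------

#' Linear (fully connected) module over the leading dimension
#' @param din,dout feature dimensions.
#' @param bias include an additive bias?
#' @return a module.
#' @export
mod_linear <- function(din, dout, bias = TRUE) {
  m <- new_module("linear")
  m$din <- din; m$dout <- dout
  reg_param(m, "w", init_linear_w(dout, din))
  if (bias) reg_param(m, "b", numeric(dout))
  m
}

# x: (din, cols...) -> (dout, cols...)
#' @export
sr_forward.sr_linear <- function(m, x, ...) {
  x <- as_ag(x)
  d <- dim1(x$v)
  xm <- if (length(d) > 2) ag_reshape(x, c(d[1], prod(d[-1]))) else x
  y <- ag_matmul(m$params$w, xm)
  if (!is.null(m$params$b)) y <- ag_bias1(y, m$params$b)
  if (length(d) > 2) y <- ag_reshape(y, c(m$dout, d[-1]))
  y
}

#' @export
sr_count.sr_linear <- function(m, in_shape) {
  # token count taken from in_shape interpreted as (D, H, W)
  n <- prod(in_shape[-1])
  list(macs = m$din * m$dout * n, out = c(m$dout, in_shape[-1]))
}

# ---- layernorm ------------------------------------------------------------

#' Layer-normalization module over the leading dimension
#' @param d feature dimension.
#' @return a module.
#' @export
mod_layernorm <- function(d) {
  m <- new_module("layernorm")
  m$d <- d
  reg_param(m, "gamma", rep(1, d))
  reg_param(m, "beta", numeric(d))
  m
}

#' @export
sr_forward.sr_layernorm <- function(m, x, ...) {
  ag_layernorm(x, m$params$gamma, m$params$beta)
}

#' @export
sr_count.sr_layernorm <- function(m, in_shape) list(macs = 0, out = in_shape)

# ---- serialization --------------------------------------------------------

sr_state_dict <- function(m) {
  out <- list()
  walk <- function(mod, prefix) {
    for (nm in names(mod$params)) out[[paste0(prefix, nm)]] <<- mod$params[[nm]]$v
    if (!is.null(mod$state)) {
      out[[paste0(prefix, ".rm")]] <<- mod$state$rm
      out[[paste0(prefix, ".rv")]] <<- mod$state$rv
    }
    for (nm in names(mod$children)) walk(mod$children[[nm]], paste0(prefix, nm, "/"))
  }
  walk(m, "")
  out
}

sr_load_state_dict <- function(m, sd) {
  walk <- function(mod, prefix) {
    for (nm in names(mod$params)) {
      key <- paste0(prefix, nm)
      if (is.null(sd[[key]])) stop("missing state entry: ", key)
      stopifnot(length(sd[[key]]) == length(mod$params[[nm]]$v))
      v <- sd[[key]]
      dim(v) <- dim1(mod$params[[nm]]$v)
      mod$params[[nm]]$v <- v
    }
    if (!is.null(mod$state)) {
      mod$state$rm <- sd[[paste0(prefix, ".rm")]]
      mod$state$rv <- sd[[paste0(prefix, ".rv")]]
    }
    for (nm in names(mod$children)) walk(mod$children[[nm]], paste0(prefix, nm, "/"))
  }
  walk(m, "")
  invisible(m)
}

#' Save a model checkpoint
#'
#' Writes a single-file snapshot of all parameters and batch-norm statistics
#' with a versioned header; [load_model()] restores it into a freshly built
#' model of the same architecture.
#' @param model a module.
#' @param path output file.
#' @param meta optional named list stored alongside the weights.
#' @export
save_model <- function(model, path, meta = list()) {
  obj <- list(format = "swimrep-checkpoint", version = 1L,
              meta = meta, state = sr_state_dict(model))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param model a freshly built module of the matching architecture.
#' @param path checkpoint file written by [save_model()].
#' @return `model`, with weights restored.
#' @export
load_model <- function(model, path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "swimrep-checkpoint")) {
    stop("not a swimrep checkpoint: ", path)
  }
  sr_load_state_dict(model, obj$state)
  invisible(model)
}
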