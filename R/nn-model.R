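# Surrogate model container: an ordered layer stack plus its input/output
# contract and (once trained) the normalization parameters it expects.

new_surrogate <- function(layers, arch, window, channels, output_width,
                          norm = NULL) {
  structure(list(layers = layers, arch = arch, window = window,
                 channels = channels, output_width = output_width,
                 norm = norm),
            class = "vc_surrogate")
}

#' @export
print.vc_surrogate <- function(x, ...) {
  cat(sprintf("<vc_surrogate> '%s': %d x %d -> %d, %s free parameters\n",
              x$arch, x$window, x$channels, x$output_width,
              format(n_params(x), big.mark = ",")))
  for (l in x$layers) {
    np <- layer_n_params(l)
    cat(sprintf("  %-16s %-12s %s\n", l$name, l$type,
                if (np > 0) format(np, big.mark = ",") else ""))
  }
  invisible(x)
}

#' Number of free (trainable) parameters
#' @param model a `vc_surrogate`.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (l$trainable) layer_n_params(l) else 0L
  }, numeric(1)))
}

# full forward pass; caches are needed for backprop
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[i]], x, training = training)
    x <- fw$y
    if (keep_cache) caches[[i]] <- fw$cache
  }
  list(y = x, caches = caches)
}

model_backward <- function(model, caches, gy) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[i]], caches[[i]], gy)
    grads[[i]] <- bw$grads
    gy <- bw$gx
  }
  grads
}

#' Forward-pass predictions (normalized space)
#'
#' @param object a `vc_surrogate`.
#' @param x input array (N x window x channels), already normalized.
#' @param ... unused.
#' @return an N x output_width matrix of normalized predictions.
#' @export
predict.vc_surrogate <- function(object, x, ...) {
  if (length(dim(x)) == 2) x <- array(x, c(1, dim(x)))
  model_forward(object, x)$y
}

# --- builders --------------------------------------------------------------

#' Build one of the five forecasting architectures
#'
#' Returns an initialized surrogate with the reference layer stack:
#' \describe{
#' \item{linear}{flatten, 64-unit affine map, affine head.}
#' \item{nonlinear}{the same with a sigmoid on the 64-unit layer.}
#' \item{deep}{flatten, 64-unit map, nine tanh layers
#'   (128-256-512-1024-1024-512-256-128-64) with dropout 0.15, affine head.}
#' \item{convnet}{12 causal dilated convolutions, 128 filters, kernel 2,
#'   tanh, dilation rates 2^0..2^11, affine head on the last timestep.}
#' \item{cnn_lstm}{convolutions 128/100/50 (kernels 1/5/1, relu/relu/tanh,
#'   He/He/Glorot-uniform initializers), flatten, sequence repeat, a
#'   128-unit LSTM returning sequences, four 100-unit SELU layers with
#'   dropout 0.15, affine head.}
#' }
#' With `time_distributed = TRUE` the linear family replaces the leading
#' flatten by a per-timestep (time-distributed) 64-unit map; this shrinks
#' the parameter count and is the variant used for point-neuron training.
#' Parameter counts quoted in documentation refer to the default
#' (flatten-first, 5 input channels, 3 outputs) convention.
#'
#' @param name architecture name.
#' @param input_channels number of input channels (3 or 5 for the
#'   point-neuron formats).
#' @param output_width 1 (voltage), 3 (voltage + INa + IK) or 6
#'   (multi-site).
#' @param window history window length in samples.
#' @param dropout dropout rate for the deep and cnn_lstm stacks.
#' @param time_distributed use the per-timestep first layer for the linear
#'   family?
#' @param repeat_len sequence-repeat length between flatten and LSTM.
#' @param seed RNG seed for weight initialization.
#' @return a `vc_surrogate`.
#' @export
build_surrogate <- function(name = c("linear", "nonlinear", "deep", "convnet",
                                     "cnn_lstm"),
                            input_channels = 5, output_width = 3, window = 64,
                            dropout = 0.15, time_distributed = FALSE,
                            repeat_len = 1, seed = NULL) {
  name <- match.arg(name)
  with_seed(seed, {
    L <- list()
    add <- function(l) L[[length(L) + 1]] <<- l
    if (name %in% c("linear", "nonlinear", "deep")) {
      act1 <- if (name == "nonlinear") "sigmoid" else "linear"
      if (time_distributed) {
        add(mk_td_dense("td_map", input_channels, 64, act1))
        add(mk_flatten("flatten"))
        hidden_in <- 64 * window
      } else {
        add(mk_flatten("flatten"))
        add(mk_dense("map64", window * input_channels, 64, act1))
        hidden_in <- 64
      }
      if (name == "deep") {
        if (time_distributed) {
          add(mk_dense("map64", hidden_in, 64, "linear"))
          hidden_in <- 64
        }
        units <- c(128, 256, 512, 1024, 1024, 512, 256, 128, 64)
        for (i in seq_along(units)) {
          add(mk_dense(paste0("deep_", i), hidden_in, units[i], "tanh"))
          add(mk_dropout(paste0("drop_", i), dropout))
          hidden_in <- units[i]
        }
      }
      add(mk_dense("head", hidden_in, output_width, "linear"))
    } else if (name == "convnet") {
      cin <- input_channels
      for (i in seq_len(12)) {
        add(mk_conv1d(paste0("conv_", i), cin, 128, kernel = 2,
                      dilation = 2^(i - 1), activation = "tanh",
                      initializer = "glorot_uniform"))
        cin <- 128
      }
      add(mk_take_last("last"))
      add(mk_dense("head", 128, output_width, "linear"))
    } else { # cnn_lstm
      add(mk_conv1d("conv_1", input_channels, 128, 1, activation = "relu",
                    initializer = "he_uniform"))
      add(mk_conv1d("conv_2", 128, 100, 5, activation = "relu",
                    initializer = "he_uniform"))
      add(mk_conv1d("conv_3", 100, 50, 1, activation = "tanh",
                    initializer = "glorot_uniform"))
      add(mk_flatten("flatten"))
      add(mk_repeat("repeat", repeat_len))
      add(mk_lstm("lstm", window * 50, 128, return_seq = TRUE))
      din <- 128
      for (i in seq_len(4)) {
        add(mk_td_dense(paste0("head_dense_", i), din, 100, "selu",
                        initializer = "lecun_uniform"))
        add(mk_dropout(paste0("head_drop_", i), dropout))
        din <- 100
      }
      add(mk_flatten("head_flatten"))
      add(mk_dense("head", repeat_len * 100, output_width, "linear"))
    }
    new_surrogate(L, name, window, input_channels, output_width)
  })
}

#' Build the multicompartment CNN-LSTM
#'
#' The per-site surrogate: input channels are 1 voltage row plus one row per
#' synapse site (201 for the default 200 sites). Stack: three convolutions
#' (512/256/128 units, kernels 1/5/1) with an L1 penalty on the first
#' convolution (which drives per-synapse filter specialization), flatten,
#' sequence repeat, three 128-unit LSTM layers returning sequences, then
#' dense layers 128 (relu) and four 100-unit SELU layers, and an affine
#' head with a trainable output bias-correction term (the `head` bias,
#' refit post hoc on the validation split by [fit_output_bias()]).
#'
#' @param synapse_count number of synapse-site channels.
#' @param output_width prediction width (1 = somatic voltage).
#' @param window history window (samples).
#' @param l1 L1 penalty weight on the first convolution.
#' @param dropout dropout rate in the dense head.
#' @param repeat_len sequence-repeat length.
#' @param seed RNG seed.
#' @return a `vc_surrogate` with `arch = "cnn_lstm_multi"`.
#' @export
build_multi <- function(synapse_count = 200, output_width = 1, window = 64,
                        l1 = 1e-5, dropout = 0.15, repeat_len = 1,
                        seed = NULL) {
  if (synapse_count <= 0) abort("`synapse_count` must be > 0")
  with_seed(seed, {
    L <- list()
    add <- function(l) L[[length(L) + 1]] <<- l
    add(mk_conv1d("conv_1", synapse_count + 1, 512, 1, activation = "relu",
                  initializer = "he_uniform", l1 = l1))
    add(mk_conv1d("conv_2", 512, 256, 5, activation = "relu",
                  initializer = "he_uniform"))
    add(mk_conv1d("conv_3", 256, 128, 1, activation = "tanh",
                  initializer = "glorot_uniform"))
    add(mk_flatten("flatten"))
    add(mk_repeat("repeat", repeat_len))
    add(mk_lstm("lstm_1", window * 128, 128))
    add(mk_lstm("lstm_2", 128, 128))
    add(mk_lstm("lstm_3", 128, 128))
    add(mk_td_dense("head_dense_1", 128, 128, "relu", initializer = "he_uniform"))
    din <- 128
    for (i in 2:5) {
      add(mk_td_dense(paste0("head_dense_", i), din, 100, "selu",
                      initializer = "lecun_uniform"))
      add(mk_dropout(paste0("head_drop_", i), dropout))
      din <- 100
    }
    add(mk_flatten("head_flatten"))
    add(mk_dense("head", repeat_len * 100, output_width, "linear"))
    new_surrogate(L, "cnn_lstm_multi", window, synapse_count + 1, output_width)
  })
}

#' Insert the fixed NMDA-gating layer
#'
#' Prepends a frozen (non-trainable) layer that rescales the NMDA input
#' channel by the Boltzmann gate of the instantaneous (normalized) membrane
#' potential, timestep by timestep. The reference layer-space gate constants
#' are `A1 = 1, A2 = -1, x0 = 1.44, dx = 0.12` (the normalized-axis
#' counterparts of the -63.32 mV / 0.013 mV membrane-voltage gate);
#' [nmda_head_params_from_norm()] derives the constants matching this
#' package's own normalization instead.
#'
#' @param model a `vc_surrogate` whose input convention contains an NMDA
#'   channel.
#' @param boltzmann layer-space gate parameters (list A1, A2, x0, dx).
#' @param v_channel,nmda_channel input channel indices.
#' @return the model with the gating layer prepended.
#' @export
attach_nmda_head <- function(model,
                             boltzmann = list(A1 = 1, A2 = -1, x0 = 1.44, dx = 0.12),
                             v_channel = 1, nmda_channel = NULL) {
  if (is.null(nmda_channel)) abort("`nmda_channel` must identify the NMDA input channel")
  if (nmda_channel > model$channels) abort("model input has no such NMDA channel")
  model$layers <- c(list(mk_nmda_gate_layer("nmda_gate", boltzmann,
                                            v_channel, nmda_channel)),
                    model$layers)
  model
}

#' Gate constants on the normalized voltage axis
#'
#' Maps membrane-voltage Boltzmann parameters through the affine voltage
#' normalization of [norm_params()] to the layer space the gating layer
#' operates in.
#'
#' @param boltzmann mV-scale parameters (see [nmda_boltzmann_default()]).
#' @param params a `vc_norm`.
#' @export
nmda_head_params_from_norm <- function(boltzmann = nmda_boltzmann_default(),
                                       params = norm_params()) {
  span <- diff(params$v_bounds_mv)
  list(A1 = boltzmann$A1, A2 = boltzmann$A2,
       x0 = (boltzmann$x0 - params$v_bounds_mv[1]) / span,
       dx = boltzmann$dx / span)
}

#' Extract first-layer convolution filters
#'
#' Returns the weight tensor of the first convolutional layer (kernel x
#' channels x filters) and the filter-by-synapse selectivity matrix: the
#' maximum absolute weight each filter assigns to each synapse channel
#' (channels beyond the voltage row).
#'
#' @param model a `vc_surrogate` with a convolutional front end.
#' @return list with `weights` and `selectivity` (filters x synapse
#'   channels).
#' @export
extract_first_layer_filters <- function(model) {
  i <- which(vapply(model$layers, function(l) l$type == "conv1d", logical(1)))[1]
  if (is.na(i)) abort("model has no convolutional front end")
  W <- model$layers[[i]]$params$W  # kernel x channels x filters
  n_ch <- dim(W)[2]
  syn_ch <- seq(2, n_ch)  # channel 1 is the voltage row
  sel <- t(apply(abs(W), 3, function(wf) {
    # wf: kernel x channels; max |weight| per channel
    apply(matrix(wf, dim(W)[1], n_ch)[, syn_ch, drop = FALSE], 2, max)
  }))
  list(weights = W, selectivity = sel)
}

# --- save / load -----------------------------------------------------------

#' Save and load surrogate models
#'
#' A saved model is self-describing: the RDS weights bundle is accompanied
#' by a JSON descriptor (architecture, shapes, parameter count and
#' normalization contract) at `<path>.json`.
#'
#' @param model a `vc_surrogate`.
#' @param path file path for the weights bundle.
#' @return `save_surrogate` returns `path` invisibly; `load_surrogate`
#'   returns the model.
#' @export
save_surrogate <- function(model, path) {
  saveRDS(model, path)
  desc <- list(
    arch = model$arch, window = model$window, channels = model$channels,
    output_width = model$output_width, n_params = n_params(model),
    layers = lapply(model$layers, function(l) {
      list(name = l$name, type = l$type, trainable = l$trainable,
           config = l$config[setdiff(names(l$config), "boltzmann")])
    }),
    norm = if (!is.null(model$norm)) unclass(model$norm)
  )
  jsonlite::write_json(desc, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  readRDS(path)
}
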