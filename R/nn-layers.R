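# Minimal feed-forward/recurrent layer engine with manual backpropagation.
# Data layout: sequence tensors are arrays (N, T, C); flat tensors are
# matrices (N, F). R's column-major order keeps (N, T) contiguous, so
# matrix(x, N * T, C) reshapes are copy-cheap and consistent.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

act_f <- function(name, x) {
  switch(name,
    linear = x,
    sigmoid = 1 / (1 + exp(-x)),
    tanh = tanh(x),
    relu = pmax(x, 0),
    selu = SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1)),
    abort(sprintf("unknown activation '%s'", name))
  )
}

# derivative wrt pre-activation, given pre-activation x and output y
act_grad <- function(name, x, y) {
  switch(name,
    linear = 1,
    sigmoid = y * (1 - y),
    tanh = 1 - y^2,
    relu = as.numeric(x > 0),
    selu = SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x)),
    abort(sprintf("unknown activation '%s'", name))
  )
}

init_weights <- function(initializer, fan_in, fan_out, dims) {
  limit <- switch(initializer,
    he_uniform = sqrt(6 / fan_in),
    glorot_uniform = sqrt(6 / (fan_in + fan_out)),
    lecun_uniform = sqrt(3 / fan_in),
    abort(sprintf("unknown initializer '%s'", initializer))
  )
  array(runif(prod(dims), -limit, limit), dims)
}

new_layer <- function(type, name, params = list(), config = list(),
                      trainable = TRUE) {
  list(type = type, name = name, params = params, config = config,
       trainable = trainable)
}

# --- constructors ----------------------------------------------------------

mk_dense <- function(name, input_dim, units, activation = "linear",
                     initializer = "glorot_uniform") {
  new_layer("dense", name,
            params = list(W = init_weights(initializer, input_dim, units,
                                           c(input_dim, units)),
                          b = numeric(units)),
            config = list(units = units, activation = activation))
}

mk_td_dense <- function(name, input_dim, units, activation = "linear",
                        initializer = "glorot_uniform") {
  l <- mk_dense(name, input_dim, units, activation, initializer)
  l$type <- "td_dense"
  l
}

mk_conv1d <- function(name, in_channels, filters, kernel, dilation = 1,
                      activation = "linear", initializer = "glorot_uniform",
                      l1 = 0) {
  W <- init_weights(initializer, kernel * in_channels, filters,
                    c(kernel, in_channels, filters))
  new_layer("conv1d", name,
            params = list(W = W, b = numeric(filters)),
            config = list(filters = filters, kernel = kernel,
                          dilation = dilation, activation = activation,
                          l1 = l1))
}

mk_lstm <- function(name, input_dim, units, return_seq = TRUE,
                    initializer = "glorot_uniform") {
  new_layer("lstm", name,
            params = list(
              Wx = init_weights(initializer, input_dim, units, c(input_dim, 4 * units)),
              Wh = init_weights("glorot_uniform", units, units, c(units, 4 * units)),
              b = c(numeric(units), rep(1, units), numeric(2 * units))  # forget bias 1
            ),
            config = list(units = units, return_seq = return_seq))
}

mk_flatten <- function(name) new_layer("flatten", name)
mk_repeat <- function(name, times) new_layer("repeat_vector", name,
                                             config = list(times = times))
mk_take_last <- function(name) new_layer("take_last", name)
mk_dropout <- function(name, rate) new_layer("dropout", name,
                                             config = list(rate = rate))

mk_nmda_gate_layer <- function(name, boltzmann, v_channel, nmda_channel) {
  new_layer("nmda_gate", name,
            config = list(boltzmann = boltzmann, v_channel = v_channel,
                          nmda_channel = nmda_channel),
            trainable = FALSE)
}

# --- forward ---------------------------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  p <- layer$params
  cfg <- layer$config
  switch(layer$type,
    dense = {
      z <- sweep(x %*% p$W, 2, p$b, `+`)
      y <- act_f(cfg$activation, z)
      list(y = y, cache = list(x = x, z = z, y = y))
    },
    td_dense = {
      d <- dim(x)
      xm <- matrix(x, d[1] * d[2], d[3])
      z <- sweep(xm %*% p$W, 2, p$b, `+`)
      y <- act_f(cfg$activation, z)
      list(y = array(y, c(d[1], d[2], cfg$units)),
           cache = list(xm = xm, z = z, y = y, din = d))
    },
    conv1d = {
      d <- dim(x)
      N <- d[1]; TT <- d[2]
      z <- array(0, c(N, TT, cfg$filters))
      zm <- matrix(0, N * TT, cfg$filters)
      xm <- matrix(x, N * TT, d[3])
      for (k in seq_len(cfg$kernel)) {
        s <- (k - 1) * cfg$dilation
        if (s >= TT) next
        # rows of xm corresponding to times 1..TT-s, shifted to times s+1..TT
        src <- as.vector(outer(seq_len(N), (seq_len(TT - s) - 1) * N, `+`))
        dst <- as.vector(outer(seq_len(N), (seq_len(TT - s) + s - 1) * N, `+`))
        zm[dst, ] <- zm[dst, ] + xm[src, , drop = FALSE] %*% matrix(p$W[k, , ], d[3], cfg$filters)
      }
      zm <- sweep(zm, 2, p$b, `+`)
      y <- act_f(cfg$activation, zm)
      list(y = array(y, c(N, TT, cfg$filters)),
           cache = list(xm = xm, zm = zm, ym = y, din = d))
    },
    lstm = {
      d <- dim(x)
      N <- d[1]; TT <- d[2]; U <- cfg$units
      h <- matrix(0, N, U); cc <- matrix(0, N, U)
      ys <- array(0, c(N, TT, U))
      steps <- vector("list", TT)
      for (t in seq_len(TT)) {
        xt <- matrix(x[, t, ], N, d[3])
        z <- sweep(xt %*% p$Wx + h %*% p$Wh, 2, p$b, `+`)
        i_ <- 1 / (1 + exp(-z[, seq_len(U), drop = FALSE]))
        f_ <- 1 / (1 + exp(-z[, U + seq_len(U), drop = FALSE]))
        g_ <- tanh(z[, 2 * U + seq_len(U), drop = FALSE])
        o_ <- 1 / (1 + exp(-z[, 3 * U + seq_len(U), drop = FALSE]))
        c_prev <- cc
        cc <- f_ * cc + i_ * g_
        tc <- tanh(cc)
        h_prev <- h
        h <- o_ * tc
        ys[, t, ] <- h
        steps[[t]] <- list(xt = xt, i = i_, f = f_, g = g_, o = o_,
                           c_prev = c_prev, tc = tc, h_prev = h_prev)
      }
      y <- if (cfg$return_seq) ys else h
      list(y = y, cache = list(steps = steps, din = d))
    },
    flatten = {
      d <- dim(x)
      list(y = matrix(x, d[1], prod(d[-1])), cache = list(din = d))
    },
    repeat_vector = {
      d <- dim(x)
      y <- array(0, c(d[1], cfg$times, d[2]))
      for (r in seq_len(cfg$times)) y[, r, ] <- x
      list(y = y, cache = list(din = d))
    },
    take_last = {
      d <- dim(x)
      list(y = matrix(x[, d[2], ], d[1], d[3]), cache = list(din = d))
    },
    dropout = {
      if (training && cfg$rate > 0) {
        mask <- array(as.numeric(runif(length(x)) >= cfg$rate) / (1 - cfg$rate), dim(x))
        list(y = x * mask, cache = list(mask = mask))
      } else {
        list(y = x, cache = list(mask = NULL))
      }
    },
    nmda_gate = {
      v <- x[, , cfg$v_channel, drop = FALSE]
      gate <- nmda_gate(v, cfg$boltzmann)
      y <- x
      y[, , cfg$nmda_channel] <- x[, , cfg$nmda_channel] * gate[, , 1]
      list(y = y, cache = list(x = x, gate = gate))
    },
    abort(sprintf("unknown layer type '%s'", layer$type))
  )
}

# --- backward --------------------------------------------------------------

layer_backward <- function(layer, cache, gy) {
  p <- layer$params
  cfg <- layer$config
  switch(layer$type,
    dense = {
      gz <- gy * act_grad(cfg$activation, cache$z, cache$y)
      list(gx = gz %*% t(p$W),
           grads = list(W = crossprod(cache$x, gz), b = colSums(gz)))
    },
    td_dense = {
      d <- cache$din
      gym <- matrix(gy, d[1] * d[2], cfg$units)
      gz <- gym * act_grad(cfg$activation, cache$z, cache$y)
      gx <- gz %*% t(p$W)
      list(gx = array(gx, d),
           grads = list(W = crossprod(cache$xm, gz), b = colSums(gz)))
    },
    conv1d = {
      d <- cache$din
      N <- d[1]; TT <- d[2]
      gym <- matrix(gy, N * TT, cfg$filters)
      gz <- gym * act_grad(cfg$activation, cache$zm, cache$ym)
      gxm <- matrix(0, N * TT, d[3])
      gW <- array(0, dim(p$W))
      for (k in seq_len(cfg$kernel)) {
        s <- (k - 1) * cfg$dilation
        if (s >= TT) next
        src <- as.vector(outer(seq_len(N), (seq_len(TT - s) - 1) * N, `+`))
        dst <- as.vector(outer(seq_len(N), (seq_len(TT - s) + s - 1) * N, `+`))
        Wk <- matrix(p$W[k, , ], d[3], cfg$filters)
        gW[k, , ] <- crossprod(cache$xm[src, , drop = FALSE], gz[dst, , drop = FALSE])
        gxm[src, ] <- gxm[src, ] + gz[dst, , drop = FALSE] %*% t(Wk)
      }
      grads <- list(W = gW, b = colSums(gz))
      if (cfg$l1 > 0) grads$W <- grads$W + cfg$l1 * sign(p$W)
      list(gx = array(gxm, d), grads = grads)
    },
    lstm = {
      d <- cache$din
      N <- d[1]; TT <- d[2]; U <- cfg$units
      seq_out <- cfg$return_seq
      gWx <- array(0, dim(p$Wx)); gWh <- array(0, dim(p$Wh)); gb <- numeric(4 * U)
      gx <- array(0, d)
      gh_next <- matrix(0, N, U); gc_next <- matrix(0, N, U)
      for (t in rev(seq_len(TT))) {
        st <- cache$steps[[t]]
        gh <- gh_next
        if (seq_out) gh <- gh + matrix(gy[, t, ], N, U)
        else if (t == TT) gh <- gh + gy
        go <- gh * st$tc
        gtc <- gh * st$o * (1 - st$tc^2) + gc_next
        gf <- gtc * st$c_prev
        gi <- gtc * st$g
        gg <- gtc * st$i
        gc_next <- gtc * st$f
        gz <- cbind(gi * st$i * (1 - st$i), gf * st$f * (1 - st$f),
                    gg * (1 - st$g^2), go * st$o * (1 - st$o))
        gWx <- gWx + crossprod(st$xt, gz)
        gWh <- gWh + crossprod(st$h_prev, gz)
        gb <- gb + colSums(gz)
        gx[, t, ] <- gz %*% t(p$Wx)
        gh_next <- gz %*% t(p$Wh)
      }
      list(gx = gx, grads = list(Wx = gWx, Wh = gWh, b = gb))
    },
    flatten = list(gx = array(gy, cache$din), grads = list()),
    repeat_vector = {
      d <- cache$din
      gx <- matrix(0, d[1], d[2])
      for (r in seq_len(cfg$times)) gx <- gx + matrix(gy[, r, ], d[1], d[2])
      list(gx = gx, grads = list())
    },
    take_last = {
      d <- cache$din
      gx <- array(0, d)
      gx[, d[2], ] <- gy
      list(gx = gx, grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(gx = gy, grads = list())
      else list(gx = gy * cache$mask, grads = list())
    },
    nmda_gate = {
      # gradient flows through the gated channel product; the gate itself is
      # treated as a frozen modulation (no parameters, no v-path gradient)
      gx <- gy
      gx[, , cfg$nmda_channel] <- gy[, , cfg$nmda_channel] * cache$gate[, , 1]
      list(gx = gx, grads = list())
    },
    abort(sprintf("unknown layer type '%s'", layer$type))
  )
}

layer_n_params <- function(layer) {
  sum(vapply(layer$params, length, integer(1)))
}
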