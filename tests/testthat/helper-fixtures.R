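# Shared fixtures, built lazily and cached for the whole test run. All data
# are generated in code (no stored fixtures); seeds are fixed so every run
# sees identical inputs.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

ref_model <- function() fx("ref_model", function() compartment_model())

ref_passive <- function() fx("ref_passive", function() compartment_model(active = FALSE))

ref_init <- function() fx("ref_init", function() steady_state_init(ref_model(), check = FALSE))

# small passive corpus with currents: 2 traces x 6 s
passive_corpus <- function() fx("passive_corpus", function() {
  m <- ref_passive()
  ini <- steady_state_init(m, check = FALSE)
  evs <- lapply(1:2, function(i) random_train(6000, 240, seed = 500 + i))
  trs <- lapply(evs, function(ev) {
    simulate_point_neuron(m, ev, 6000, record_currents = TRUE, init = ini)
  })
  list(model = m, events = evs, traces = trs)
})

# normalized, split dataset over the passive corpus (5 channels, 3 targets)
passive_dataset <- function() fx("passive_dataset", function() {
  cp <- passive_corpus()
  suppressWarnings(normalize_dataset(split_dataset(
    make_windows(cp$traces, cp$events, targets = c("v", "i_na", "i_k")))))
})

# a quickly trained linear surrogate on the passive corpus
passive_linear_fit <- function() fx("passive_linear_fit", function() {
  mod <- build_surrogate("linear", input_channels = 5, output_width = 3, seed = 21)
  cfg <- training_config(loss = "mse", lr = 3e-3, max_epochs = 40,
                         patience = 40, seed = 22)
  train_surrogate(mod, passive_dataset(), cfg)
})

# hand-built one-channel linear surrogate implementing an exact AR(1)
# recurrence v_t = rho * v_{t-1} + w_e * exc_{t-1} + bias in normalized space
ar1_surrogate <- function(rho, w_e = 0, bias = 0, window = 8) {
  m <- build_surrogate("linear", input_channels = 3, output_width = 1,
                       window = window, seed = 1)
  # layers: flatten, map64, head -> collapse to exact affine map
  W1 <- matrix(0, window * 3, 64)
  W1[window, 1] <- rho        # last v sample (channel 1)
  W1[2 * window, 1] <- w_e    # last exc sample (channel 2)
  m$layers[[2]]$params$W <- W1
  m$layers[[2]]$params$b <- rep(0, 64)
  W2 <- matrix(0, 64, 1); W2[1, 1] <- 1
  m$layers[[3]]$params$W <- W2
  m$layers[[3]]$params$b <- bias
  m$norm <- norm_params()
  m
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")

# An exactly representable AR(1) world: ground truth generated by the same
# affine recurrence the injected surrogate implements, so the oracle model
# must reproduce it to machine precision.
ar1_world <- function(rho = 0.9, w_e = 0.05, bias = 0.01, horizon = 120,
                      window = 8, seed = 9) {
  m <- ar1_surrogate(rho, w_e, bias, window = window)
  np <- m$norm
  ev <- random_train(window + horizon, 15, ei_ratio = c(8, 3),
                     exc_weight_ns = 2.5, seed = seed)
  n <- window + horizon
  exc <- numeric(n)
  idx <- pmin(round(ev$onset_ms) + 1L, n)
  sel <- ev$polarity == "exc"
  for (k in which(sel)) exc[idx[k]] <- exc[idx[k]] + ev$weight_ns[k] / np$g_bound_ns
  v_norm <- numeric(n)
  v_norm[1:window] <- 0.15
  for (t in (window + 1):n) {
    v_norm[t] <- rho * v_norm[t - 1] + w_e * exc[t - 1] + bias
  }
  v_mv <- denormalize(v_norm, np)
  init <- tibble::tibble(t_ms = 0:(window - 1), v_mV = v_mv[1:window])
  attr(init, "dt_ms") <- 1
  class(init) <- c("vc_trace", class(init))
  list(model = m, events = ev, init = init, truth_mv = v_mv, window = window,
       horizon = horizon, np = np)
}

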