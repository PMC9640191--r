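test_that("builder parameter counts equal their layer-arithmetic values", {
  # frozen counts derived by summing layer shapes under the benchmark
  # convention (flatten-first, 5 input channels, 3 output units)
  expected <- c(linear = 20739, nonlinear = 20739, deep = 2465859,
                convnet = 363651, cnn_lstm = 1817869)
  for (nm in names(expected)) {
    expect_equal(n_params(build_surrogate(nm, seed = 1)),
                 unname(expected[nm]), label = nm)
  }
  # the deep net has 10 hidden layers (the 64-unit map plus nine tanh layers)
  deep <- build_surrogate("deep", seed = 1)
  hidden <- vapply(deep$layers, function(l) {
    l$type == "dense" && l$name != "head"
  }, logical(1))
  expect_equal(sum(hidden), 10)
})

test_that("unknown architecture names are rejected", {
  expect_error(build_surrogate("perceptron"), "arg")
})

test_that("the multicompartment builder exposes 201 channels and 512 first filters", {
  m <- build_multi(synapse_count = 200, seed = 2)
  expect_equal(m$channels, 201)
  expect_equal(m$layers[[1]]$config$filters, 512)
  expect_gt(m$layers[[1]]$config$l1, 0)
  f <- extract_first_layer_filters(m)
  expect_equal(dim(f$selectivity), c(512, 200))
  expect_equal(dim(f$weights), c(1, 201, 512))
})

test_that("untrained first-layer filters lie within the He-uniform bounds", {
  m <- build_multi(synapse_count = 40, seed = 3)
  W <- extract_first_layer_filters(m)$weights
  limit <- sqrt(6 / (1 * 41))
  expect_true(all(abs(W) <= limit))
})

test_that("saved models reload with identical weights and selectivity", {
  m <- build_multi(synapse_count = 30, seed = 4)
  p <- tempfile(fileext = ".rds")
  save_surrogate(m, p)
  m2 <- load_surrogate(p)
  expect_identical(extract_first_layer_filters(m2)$selectivity,
                   extract_first_layer_filters(m)$selectivity)
  expect_true(file.exists(paste0(p, ".json")))
  desc <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(desc$n_params, n_params(m))
})

test_that("forward passes are deterministic with dropout disabled", {
  m <- build_surrogate("cnn_lstm", input_channels = 3, output_width = 1,
                       window = 16, seed = 5)
  x <- array(rnorm(4 * 16 * 3), c(4, 16, 3))
  expect_identical(predict(m, x), predict(m, x))
})

test_that("L1 on the first convolution sparsifies its trained weights", {
  # two short trainings on the same toy per-site corpus, with and without
  # the lasso penalty; the penalized first layer must end up sparser
  set.seed(11)
  n <- 400; W <- 16; C <- 9
  x <- array(rnorm(n * W * C, sd = 0.3), c(n, W, C))
  y <- matrix(x[, W, 2] * 0.8 + 0.1, n, 1)  # only channel 2 matters
  mk_ds <- function() {
    ds <- structure(list(inputs = x, targets = y,
                         channels = c("v", paste0("syn", 1:(C - 1))),
                         target_names = "v", window = W, dt_ms = 1,
                         series = list(), norm = norm_params()),
                    class = "vc_dataset")
    split_dataset(ds)
  }
  frac_small <- function(l1) {
    m <- build_multi(synapse_count = C - 1, window = W, l1 = l1, seed = 12)
    cfg <- training_config(optimizer = "adamax", max_epochs = 4, patience = 4,
                           batch_size = 64, seed = 13)
    fit <- train_surrogate(m, mk_ds(), cfg)
    Wc <- fit$model$layers[[1]]$params$W
    mean(abs(Wc) < 1e-3)
  }
  expect_gt(frac_small(5e-3), frac_small(0))
})

test_that("the NMDA gating layer is frozen and gates at its midpoint", {
  bz_layer <- list(A1 = 1, A2 = -1, x0 = 1.44, dx = 0.12)
  m <- build_surrogate("linear", input_channels = 4, output_width = 1,
                       window = 8, seed = 6)
  m <- attach_nmda_head(m, bz_layer, v_channel = 1, nmda_channel = 3)
  expect_equal(m$layers[[1]]$type, "nmda_gate")
  expect_false(m$layers[[1]]$trainable)
  # at v = x0 the gate is (A1+A2)/2 = 0, silencing the NMDA channel
  x <- array(0.2, c(2, 8, 4))
  x[, , 1] <- bz_layer$x0
  y <- voltcast:::layer_forward(m$layers[[1]], x)$y
  expect_equal(max(abs(y[, , 3])), 0, tolerance = 1e-12)
  expect_equal(y[, , 2], x[, , 2])  # other channels untouched

  # training does not change the gate (no parameters to train) and the
  # layer is skipped by the optimizer
  expect_equal(voltcast:::layer_n_params(m$layers[[1]]), 0)

  expect_error(attach_nmda_head(build_surrogate("linear", seed = 1),
                                bz_layer, nmda_channel = 99), "channel")
})

test_that("normalized-space gate constants match the mV-space gate", {
  lay <- nmda_head_params_from_norm()
  bz <- nmda_boltzmann_default()
  v <- seq(-80, -50, by = 0.05)
  v_norm <- voltcast:::norm_channel(v, "v", norm_params())
  expect_equal(nmda_gate(v, bz),
               bz$A2 + (bz$A1 - bz$A2) /
                 (1 + exp(pmin(pmax((lay$x0 - v_norm) / lay$dx, -500), 500))),
               tolerance = 1e-9)
})
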