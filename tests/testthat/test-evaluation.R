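test_that("explained variance has its closed-form values and properties", {
  set.seed(1)
  truth <- rnorm(4000, sd = 2)
  expect_equal(explained_variance(truth, truth), 1)
  expect_equal(explained_variance(rep(mean(truth), 4000), truth), 0,
               tolerance = 1e-12)
  # additive white noise of variance s2: EV -> 1 - s2/var(truth)
  s2 <- 0.5
  noisy <- truth + rnorm(4000, sd = sqrt(s2))
  expect_equal(explained_variance(noisy, truth), 1 - s2 / var(truth),
               tolerance = 0.05)
  # invariance under a common affine rescaling of both signals
  pred <- truth + rnorm(4000, sd = 0.3)
  expect_equal(explained_variance(3 * pred + 7, 3 * truth + 7),
               explained_variance(pred, truth), tolerance = 1e-12)
  expect_error(explained_variance(truth, rep(1, 4000)), "variance")
  expect_error(explained_variance(truth[1:10], truth), "length")
})

test_that("spike matching is greedy, one-to-one and windowed", {
  m <- spike_match(c(103, 290), c(100, 200))
  expect_equal(m$tp, 1)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 1)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$shifts_ms, 3)

  ident <- spike_match(c(10, 50, 90), c(10, 50, 90))
  expect_equal(ident$precision, 1)
  expect_equal(ident$recall, 1)
  expect_true(all(ident$shifts_ms == 0))

  # each true spike matched at most once: two predictions near one truth
  dbl <- spike_match(c(99, 101), c(100))
  expect_equal(dbl$tp, 1)
  expect_equal(dbl$fp, 1)

  # degenerate cases are flagged
  none <- spike_match(numeric(), c(100))
  expect_equal(none$precision, 0)
  expect_equal(none$recall, 0)
  expect_true("no_predicted_spikes" %in% none$degenerate)
  notruth <- spike_match(c(100), numeric())
  expect_equal(notruth$recall, 1)
  expect_true("no_true_spikes" %in% notruth$degenerate)
})

test_that("swapping prediction and truth exchanges precision and recall", {
  set.seed(2)
  a <- sort(runif(12, 0, 1000))
  b <- sort(runif(9, 0, 1000))
  ab <- spike_match(a, b)
  ba <- spike_match(b, a)
  expect_equal(ab$precision, ba$recall)
  expect_equal(ab$recall, ba$precision)
  expect_equal(ab$tp, ba$tp)
})

test_that("firing-curve selection prefers the true generating model", {
  x <- seq(5, 100, length.out = 20)
  lin <- tibble::tibble(rate_hz = x, out_hz = 2 + 0.5 * x)
  f_lin <- fit_firing_models(lin)
  expect_equal(f_lin$best, "linear")

  set.seed(4)
  logi_y <- 60 / (1 + exp((x - 45) / -8)) + rnorm(20, sd = 1.5)
  f_log <- fit_firing_models(tibble::tibble(rate_hz = x, out_hz = logi_y))
  expect_equal(f_log$best, "logistic")
  cf <- coef(f_log$logistic)
  expect_equal(unname(cf["x0"]), 45, tolerance = 0.15)
  # midpoint identity: the fitted curve passes through (A1+A2)/2 at x0
  expect_equal(predict(f_log, unname(cf["x0"])),
               unname(cf["A1"] + cf["A2"]) / 2, tolerance = 1e-6)
  expect_error(fit_firing_models(lin[1:3, ]), "5 points")
  expect_tibble(tidy(f_log))
  expect_tibble(glance(f_log))
})

test_that("the subthreshold slope matches a closed-form RC convolution oracle", {
  # linearized passive membrane: dV = (-(V - v0) + R * g(t) * DF) samples;
  # peak response per nS computed by numerically convolving the alpha kernel
  # with the RC impulse response, independently of the simulator
  m <- ref_passive()
  area <- pi * 25e-4 * 25e-4
  gpas_us <- 1e-3 * area * 1e6
  C_nf <- 1 * area * 1e3
  tau_m <- C_nf / gpas_us               # ms
  dt <- 0.001
  t <- seq(dt, 60, by = dt)
  oracle_peak <- function(g_ns) {
    g <- g_ns * 1e-3 * (t / 2) * exp(1 - t / 2)     # uS
    i <- g * 70                                      # nA at resting DF
    h <- exp(-t / tau_m)
    v <- stats::convolve(i, rev(h), type = "open")[seq_along(t)] * dt / C_nf
    max(v)
  }
  gs <- seq(0.05, 0.3, by = 0.05)
  ini <- steady_state_init(m, check = FALSE)
  traces <- lapply(gs, function(g) {
    ev <- event_train(onset_ms = 10, synapse_id = "exc", weight_ns = g,
                      polarity = "exc")
    simulate_point_neuron(m, ev, 70, record_khz = 10, init = ini)
  })
  ivs <- iv_summary(traces, gs, v_rest = -70)
  oracle_slope <- (oracle_peak(0.3) - oracle_peak(0.05)) / 0.25
  expect_equal(ivs$slope_mv_ns, oracle_slope, tolerance = 0.03)
  expect_true(is.na(ivs$threshold_mv))  # all-subthreshold sweep
})

test_that("firing responses over the E/I grid feed the curve fits", {
  m <- ref_model()
  ini <- ref_init()
  g <- ei_grid(rates_hz = c(400, 800, 1200, 1600, 2000),
               ratios = list(c(2, 1)), n_rep = 1, duration_ms = 500,
               exc_weight_ns = 3, seed = 77)
  g$out_hz <- purrr::map_dbl(g$events, function(ev) {
    tr <- simulate_point_neuron(m, ev, 500, init = ini)
    nrow(detect_spikes(tr)) / 0.5
  })
  expect_gt(stats::cor(g$rate_hz, g$out_hz, method = "spearman"), 0)
  fit <- fit_firing_models(g, x = "rate_hz", y = "out_hz")
  expect_s3_class(fit, "vc_firing_fit")
  expect_true(is.finite(fit$aic[["linear"]]))
})
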