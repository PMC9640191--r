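test_that("windowing yields length - window rows with aligned targets", {
  cp <- passive_corpus()
  tr <- cp$traces[[1]]
  ds <- make_windows(tr, cp$events[[1]], channels = c("v", "exc", "inh"))
  expect_equal(dim(ds$inputs), c(nrow(tr) - 64, 64, 3))
  # a 10,000-ms trace would give 10,001 - 64 - 1 = 9,936 forecastable windows
  expect_equal(nrow(tr) - 64, dim(ds$inputs)[1])
  # target alignment: window i ends at sample i+63, target is sample i+64
  i <- 101
  expect_equal(ds$inputs[i, , 1], tr$v_mV[i:(i + 63)])
  expect_equal(ds$targets[i, 1], tr$v_mV[i + 64])
})

test_that("synaptic channels carry the quantal weight at exactly the onset sample", {
  m <- ref_passive()
  ev <- event_train(onset_ms = 100, synapse_id = "exc", weight_ns = 2.5,
                    polarity = "exc")
  tr <- simulate_point_neuron(m, ev, 400)
  ds <- make_windows(tr, ev)
  exc_series <- ds$series[[1]][, "exc"]
  expect_equal(sum(exc_series != 0), 1L)
  expect_equal(exc_series[101], 2.5)  # sample at t = 100 ms (1-based grid)
})

test_that("the per-site layout produces 1 + n_sites channels", {
  m <- ref_passive()
  ev <- event_train(onset_ms = c(50, 80), synapse_id = "exc",
                    weight_ns = 2, polarity = "exc")
  ev$site <- c(3L, 7L)
  tr <- simulate_point_neuron(m, ev, 300)
  ds <- make_windows(tr, ev, per_site = TRUE, n_sites = 200)
  expect_length(ds$channels, 201)
  expect_equal(unname(ds$series[[1]][51, "syn3"]), 2)
  expect_equal(unname(ds$series[[1]][81, "syn7"]), 2)
})

test_that("shifting the trace shifts every window index equally", {
  cp <- passive_corpus()
  tr <- cp$traces[[1]]
  ds <- make_windows(tr, cp$events[[1]], channels = c("v", "exc", "inh"))
  tr_k <- tr[11:nrow(tr), ]
  ev_k <- cp$events[[1]]
  ev_k$onset_ms <- ev_k$onset_ms - 10
  ev_k <- ev_k[ev_k$onset_ms >= 0, ]
  ds_k <- make_windows(tr_k, ev_k, channels = c("v", "exc", "inh"))
  expect_equal(ds_k$inputs[1, , 1], ds$inputs[11, , 1])
  expect_equal(ds_k$targets[1, 1], ds$targets[11, 1])
})

test_that("splits are contiguous, disjoint and exhaustive at 80/10/10", {
  ds <- passive_dataset()
  n <- dim(ds$inputs)[1]
  expect_equal(length(ds$split), n)
  tab <- table(ds$split)
  expect_equal(unname(tab["train"] / n), 0.8, tolerance = 1e-3)
  expect_equal(unname(tab["val"] / n), 0.1, tolerance = 1e-3)
  # contiguous blocks
  expect_true(!is.unsorted(as.integer(ds$split)))
  expect_equal(sum(tab), n)
})

test_that("voltage normalization is the fixed affine map and inverts exactly", {
  np <- norm_params()
  expect_equal(voltcast:::norm_channel(-90, "v", np), 0)
  expect_equal(voltcast:::norm_channel(40, "v", np), 1)
  x <- seq(-85, 35, by = 0.5)
  expect_equal(denormalize(voltcast:::norm_channel(x, "v", np), np), x,
               tolerance = 1e-12)
  ds <- passive_dataset()
  v_back <- denormalize(ds$series[[1]][, "v"], ds$norm)
  expect_equal(v_back, passive_corpus()$traces[[1]]$v_mV, tolerance = 1e-9)
})

test_that("spike peaks are standardized identically regardless of sampling phase", {
  # two synthetic spiky traces whose 1-kHz sampling truncates the AP peak at
  # different phases must normalize to the same standardized peak value
  mk <- function(peak_v) {
    v <- rep(-70, 200)
    v[100] <- 10; v[101] <- peak_v; v[102] <- -20  # truncated AP
    new_trace_local(v)
  }
  new_trace_local <- function(v) {
    tr <- tibble::tibble(t_ms = seq_along(v) - 1, v_mV = v)
    attr(tr, "dt_ms") <- 1
    class(tr) <- c("vc_trace", class(tr))
    tr
  }
  ev <- event_train()
  ds1 <- suppressWarnings(normalize_dataset(split_dataset(make_windows(mk(25), ev))))
  ds2 <- suppressWarnings(normalize_dataset(split_dataset(make_windows(mk(38), ev))))
  expect_equal(unname(ds1$series[[1]][101, "v"]), unname(ds2$series[[1]][101, "v"]))
  expect_equal(unname(denormalize(ds1$series[[1]][101, "v"], ds1$norm)), 40)
})

test_that("out-of-bounds voltages are clipped with a warning", {
  v <- c(rep(-70, 100), -95, rep(-70, 100))
  tr <- tibble::tibble(t_ms = seq_along(v) - 1, v_mV = v)
  attr(tr, "dt_ms") <- 1
  class(tr) <- c("vc_trace", class(tr))
  ds <- make_windows(tr, event_train())
  expect_warning(dsn <- normalize_dataset(split_dataset(ds)), "clipped")
  expect_equal(dsn$n_clipped, 1L)
  expect_true(all(dsn$series[[1]][, "v"] >= 0))
})

test_that("curriculum stages keep fixed order and mix replay by count", {
  cp <- passive_corpus()
  mk_stage <- function(i) {
    suppressWarnings(normalize_dataset(split_dataset(
      make_windows(cp$traces[[1]][(1:600) + 600 * (i - 1), ], event_train(),
                   channels = c("v", "exc", "inh")))))
  }
  cur <- curriculum(mk_stage(1), mk_stage(2), mk_stage(3), mix_fraction = 0.5)
  expect_equal(names(cur$stages),
               c("resting", "subthreshold", "suprathreshold"))
  p1 <- voltcast:::curriculum_plan(cur, 1, 100)
  p3 <- voltcast:::curriculum_plan(cur, 3, 100)
  expect_equal(p1$n_replay, 0L)       # stage 1 batches are pure
  expect_equal(p3$n_replay, 50L)      # half of each stage-3 batch is replay
  expect_length(p3$replay, 2)
  cur0 <- curriculum(mk_stage(1), mk_stage(2), mk_stage(3), mix_fraction = 0)
  expect_equal(voltcast:::curriculum_plan(cur0, 3, 100)$n_replay, 0L)
  expect_error(curriculum(mk_stage(1), mk_stage(2), mk_stage(3),
                          mix_fraction = 1), "mix_fraction")
})
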