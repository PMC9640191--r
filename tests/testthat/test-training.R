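test_that("training config validates and applies optimizer defaults", {
  expect_equal(training_config("adamax")$lr, 2e-3)
  expect_equal(training_config("adam")$lr, 1e-3)
  expect_error(training_config(patience = 30, max_epochs = 20), "patience")
  expect_error(training_config(clip_norm = 0), "clip_norm")
})

test_that("validation loss improves on a smooth corpus and clipping holds", {
  fit <- passive_linear_fit()
  h <- fit$history
  expect_lt(min(h$val_loss), h$val_loss[1])
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # applied global gradient norm never exceeds the clip
  expect_true(all(h$grad_norm <= 1 + 1e-8))
})

test_that("early stopping waits exactly `patience` epochs without improvement", {
  # constant targets and a zero-gradient-free model: after the first epoch
  # the validation loss cannot improve, so training must stop at
  # 1 + patience epochs
  set.seed(3)
  n <- 300; W <- 8; C <- 3
  ds <- structure(list(inputs = array(rnorm(n * W * C), c(n, W, C)),
                       targets = matrix(rnorm(n), n, 1),
                       channels = c("v", "exc", "inh"), target_names = "v",
                       window = W, dt_ms = 1, series = list(),
                       norm = norm_params()),
                  class = "vc_dataset")
  ds <- split_dataset(ds)
  m <- build_surrogate("linear", input_channels = C, output_width = 1,
                       window = W, seed = 4)
  # freeze everything except the head bias by zeroing the learning rate
  cfg <- training_config(lr = 0, max_epochs = 20, patience = 4, seed = 5)
  fit <- train_surrogate(m, ds, cfg)
  expect_equal(max(fit$history$epoch), 1 + 4)
})

test_that("training aborts with a diagnostic on a non-finite loss", {
  ds <- passive_dataset()
  m <- build_surrogate("linear", input_channels = 5, output_width = 3, seed = 6)
  m$layers[[2]]$params$W[1, 1] <- NaN
  cfg <- training_config(max_epochs = 3, patience = 3, seed = 7)
  expect_error(train_surrogate(m, ds, cfg), "diverged")
})

test_that("partial retraining changes only the head weights", {
  fit <- passive_linear_fit()
  before <- lapply(fit$model$layers, `[[`, "params")
  cfg <- training_config(loss = "mse", lr = 1e-3, max_epochs = 2,
                         patience = 2, seed = 30)
  re <- partial_retrain(fit$model, passive_dataset(), cfg)
  after <- lapply(re$model$layers, `[[`, "params")
  names_ <- vapply(fit$model$layers, `[[`, character(1), "name")
  frozen <- !grepl("^head", names_)
  for (i in which(frozen)) {
    expect_identical(after[[i]], before[[i]])
  }
  # and the head did move
  expect_false(identical(after[[which(!frozen)[1]]], before[[which(!frozen)[1]]]))
  # a predicate selecting nothing is an error
  expect_error(
    partial_retrain(fit$model, passive_dataset(),
                    training_config(max_epochs = 1, patience = 1),
                    head_predicate = function(l) FALSE),
    "no trainable")
})

test_that("head retrained on a shifted-KDR corpus tracks the ground-truth sign", {
  # ground truth: identical event streams through control and +10 mV shifted
  # KDR models; the retrained surrogate must shift its predictions in the
  # same direction in the depolarized range
  ctl_m <- compartment_model()
  sh_m <- compartment_model(kdr_shift_mv = 10)
  evs <- lapply(1:2, function(i) random_train(4000, 320, exc_weight_ns = 3,
                                              seed = 700 + i))
  tr_ctl <- lapply(evs, function(e) simulate_point_neuron(ctl_m, e, 4000,
                                                          record_currents = TRUE))
  tr_sh <- lapply(evs, function(e) simulate_point_neuron(sh_m, e, 4000,
                                                         record_currents = TRUE))
  mk <- function(trs) suppressWarnings(normalize_dataset(split_dataset(
    make_windows(trs, evs, targets = c("v", "i_na", "i_k")))))
  ds_ctl <- mk(tr_ctl); ds_sh <- mk(tr_sh)
  base <- train_surrogate(
    build_surrogate("linear", input_channels = 5, output_width = 3, seed = 41),
    ds_ctl,
    training_config(loss = "mse", lr = 3e-3, max_epochs = 25, patience = 25,
                    seed = 42))
  re <- partial_retrain(base$model, ds_sh,
                        training_config(loss = "mse", lr = 3e-3,
                                        max_epochs = 25, patience = 25,
                                        seed = 43))
  idx <- voltcast:::dataset_index(ds_ctl, "test")
  p_ctl <- voltcast:::model_forward(base$model,
                                    ds_ctl$inputs[idx, , , drop = FALSE])$y[, 1]
  p_sh <- voltcast:::model_forward(re$model,
                                   ds_sh$inputs[idx, , , drop = FALSE])$y[, 1]
  truth_diff <- ds_sh$targets[idx, 1] - ds_ctl$targets[idx, 1]
  hot <- denormalize(ds_ctl$targets[idx, 1], ds_ctl$norm) > -67
  expect_gt(mean(truth_diff[hot]), 0)  # ground truth: depolarized
  expect_gt(mean((p_sh - p_ctl)[hot]), 0)
  expect_equal(sign(mean((p_sh - p_ctl)[hot])), sign(mean(truth_diff[hot])))
})

test_that("curriculum training with replay bounds forgetting on a toy corpus", {
  cp <- passive_corpus()
  tr <- cp$traces[[1]]
  mk_stage <- function(rows) suppressWarnings(normalize_dataset(split_dataset(
    make_windows(tr[rows, ], event_train(), channels = c("v", "exc", "inh")))))
  # three stages with different voltage statistics (different trace spans)
  cur <- curriculum(mk_stage(1:1200), mk_stage(1201:2400), mk_stage(2401:3600),
                    mix_fraction = 0.3)
  m <- build_surrogate("linear", input_channels = 3, output_width = 1, seed = 51)
  cfg <- training_config(loss = "mse", lr = 3e-3, max_epochs = 8, patience = 8,
                         seed = 52)
  fit <- train_surrogate(m, cur, cfg)
  expect_setequal(unique(fit$history$stage),
                  c("resting", "subthreshold", "suprathreshold"))
  # forgetting control: stage-1 validation loss after the full curriculum
  # stays within a bounded factor of its stage-1 optimum
  s1 <- cur$stages$resting
  final_s1 <- voltcast:::eval_loss(fit$model, s1,
                                   voltcast:::dataset_index(s1, "val"), "mse")
  best_s1 <- min(fit$history$val_loss[fit$history$stage == "resting"])
  expect_lt(final_s1, 25 * best_s1 + 1e-6)
})
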