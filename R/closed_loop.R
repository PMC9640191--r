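#' Teacher-forced (one-step) predictions
#'
#' Runs the model over every window of a split with ground-truth history
#' (no feedback) and returns predictions next to targets, both in
#' normalized and physical units.
#'
#' @param model a trained `vc_surrogate` (with `norm` attached).
#' @param ds the normalized `vc_dataset`.
#' @param which split to evaluate (`"test"` default; `"all"` for every
#'   window).
#' @param chunk evaluation chunk size.
#' @return tibble with columns `idx`, `channel`, `pred`, `truth`
#'   (normalized), `pred_phys`, `truth_phys`.
#' @export
teacher_forced <- function(model, ds, which = "test", chunk = 4096) {
  if (ncol(ds$targets) != model$output_width) {
    abort("dataset target width does not match model output width")
  }
  idx <- if (identical(which, "all")) seq_len(dim(ds$inputs)[1]) else dataset_index(ds, which)
  np <- model$norm %||% ds$norm
  out <- vector("list", ceiling(length(idx) / chunk))
  for (ci in seq_along(out)) {
    ii <- idx[((ci - 1) * chunk + 1):min(ci * chunk, length(idx))]
    pred <- model_forward(model, ds$inputs[ii, , , drop = FALSE])$y
    truth <- ds$targets[ii, , drop = FALSE]
    out[[ci]] <- purrr::map_dfr(seq_along(ds$target_names), function(j) {
      ch <- ds$target_names[j]
      p_j <- pred[, j]
      t_j <- truth[, j]
      tibble(idx = ii, channel = ch, pred = p_j, truth = t_j,
             pred_phys = denorm_channel(p_j, ch, np),
             truth_phys = denorm_channel(t_j, ch, np))
    })
  }
  dplyr::bind_rows(out)
}

# Build the normalized channel series matrix for one run:
# rows = window + horizon samples, cols = channels. The voltage channel is
# filled from the init trace for the first `window` samples (spike peaks
# standardized), synaptic channels from the scheduled events over the whole
# span, current channels from the init trace where available.
build_run_series <- function(init_trace, events, channels, window, horizon,
                             np, dt_ms = 1) {
  n <- window + horizon
  S <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
  v <- utils::tail(init_trace$v_mV, window)
  if (length(v) < window) abort("init trace shorter than the model window")
  pk <- detect_spikes(v, dt_ms = dt_ms)
  if (nrow(pk) > 0) v[round(pk$t_ms / dt_ms) + 1L] <- np$spike_peak_mv
  S[seq_len(window), "v"] <- norm_channel(pmin(pmax(v, np$v_bounds_mv[1]),
                                               np$v_bounds_mv[2]), "v", np)
  for (cur in intersect(c("i_na", "i_k"), channels)) {
    col <- c(i_na = "i_na_nA", i_k = "i_k_nA")[[cur]]
    x <- if (col %in% names(init_trace)) utils::tail(init_trace[[col]], window) else 0
    S[seq_len(window), cur] <- norm_channel(x, cur, np)
  }
  if (nrow(events) > 0) {
    idx <- pmin(pmax(round(events$onset_ms / dt_ms) + 1L, 1L), n)
    for (k in seq_len(nrow(events))) {
      pol <- events$polarity[k]
      ch <- if (pol %in% channels) pol else if ("exc" %in% channels) "exc" else pol
      S[idx[k], ch] <- S[idx[k], ch] + events$weight_ns[k] / np$g_bound_ns
    }
  }
  S
}

#' Autoregressive (closed-loop) prediction
#'
#' Initializes the rolling input window with ground truth, then repeatedly
#' feeds the model's own predictions back into the voltage (and, for
#' multi-output models, current) channels while the synaptic channels come
#' from the scheduled event train, never from predictions. Feedback happens
#' in normalized space; denormalization is applied only on export.
#'
#' @param model a trained `vc_surrogate`.
#' @param init a `vc_trace` providing at least `window` ms of ground truth
#'   immediately before the prediction period (its last `window` samples are
#'   used). Time 0 of `events` is the start of the init window.
#' @param events an [event_train()] covering `[0, window + horizon_ms)`.
#' @param horizon_ms prediction length (ms).
#' @param channels input channel names; defaults to the point-neuron layout
#'   matching the model's channel count.
#' @param target_names channels predicted by the model (width must equal
#'   `model$output_width`).
#' @return a `vc_trace` of the predicted voltage (plus currents for
#'   multi-output models); sample k corresponds to time
#'   `window + k - 1` ms on the event clock.
#' @export
autoregressive <- function(model, init, events, horizon_ms,
                           channels = NULL, target_names = NULL) {
  res <- autoregressive_batch(model, list(init), list(events), horizon_ms,
                              channels, target_names)
  res[[1]]
}

#' Batched autoregressive prediction
#'
#' Runs `length(inits)` independent closed-loop predictions in one rolling
#' batch (a single model forward per timestep), which is how repeated
#' evaluation protocols (e.g. 50 repeats of 500-ms predictions) are run.
#'
#' @param inits,events_list lists of init traces and event trains.
#' @inheritParams autoregressive
#' @return list of `vc_trace` predictions.
#' @export
autoregressive_batch <- function(model, inits, events_list, horizon_ms,
                                 channels = NULL, target_names = NULL) {
  np <- model$norm
  if (is.null(np)) abort("model carries no normalization contract; train it first")
  channels <- channels %||% default_channel_names(model$channels)
  target_names <- target_names %||% default_target_names(model$output_width)
  if (length(target_names) != model$output_width) {
    abort("`target_names` width must equal the model output width")
  }
  W <- model$window
  H <- as.integer(horizon_ms)
  R <- length(inits)
  runs <- purrr::map2(inits, events_list, build_run_series,
                      channels = channels, window = W, horizon = H, np = np)
  tcols <- match(target_names, channels)
  x <- array(0, c(R, W, length(channels)))
  S <- array(0, c(R, W + H, length(channels)))
  for (r in seq_len(R)) S[r, , ] <- runs[[r]]
  for (k in seq_len(H)) {
    x[] <- S[, k:(k + W - 1), , drop = FALSE]
    pred <- model_forward(model, x)$y
    if (!all(is.finite(pred))) {
      abort(sprintf("non-finite prediction at autoregressive step %d", k))
    }
    for (j in seq_along(tcols)) S[, W + k, tcols[j]] <- pred[, j]
  }
  purrr::map(seq_len(R), function(r) {
    v <- denorm_channel(S[r, W + seq_len(H), tcols[1]], "v", np)
    ina <- if ("i_na" %in% target_names) {
      denorm_channel(S[r, W + seq_len(H), match("i_na", channels)], "i_na", np)
    }
    ik <- if ("i_k" %in% target_names) {
      denorm_channel(S[r, W + seq_len(H), match("i_k", channels)], "i_k", np)
    }
    new_trace((W + seq_len(H) - 1), v, ina, ik, dt_ms = 1)
  })
}

default_channel_names <- function(n) {
  switch(as.character(n),
    "3" = c("v", "exc", "inh"),
    "5" = c("v", "exc", "inh", "i_na", "i_k"),
    c("v", paste0("syn", seq_len(n - 1))))
}

default_target_names <- function(width) {
  switch(as.character(width),
    "1" = "v",
    "3" = c("v", "i_na", "i_k"),
    abort("supply `target_names` for this output width"))
}

#' Closed-loop evaluation protocol
#'
#' The standard accuracy protocol: simulate held-out ground truth, run
#' `n_rep` autoregressive predictions of `horizon_ms` each (initialized
#' with the `window` ms of ground truth preceding each evaluation span),
#' and report per-repeat explained variance plus spike precision/recall.
#'
#' @param model a trained `vc_surrogate`.
#' @param traces,events lists of ground-truth `vc_trace`s and matching
#'   event trains (held-out data).
#' @param n_rep number of evaluation repeats.
#' @param horizon_ms prediction length per repeat.
#' @param seed seed for choosing evaluation spans.
#' @param channels,target_names forwarded to [autoregressive_batch()].
#' @return tibble with one row per repeat: `rep`, `trace`, `start_ms`,
#'   `explained_variance`, `precision`, `recall`, `n_true_spikes`.
#' @export
evaluate_closed_loop <- function(model, traces, events, n_rep = 50,
                                 horizon_ms = 500, seed = NULL,
                                 channels = NULL, target_names = NULL) {
  W <- model$window
  spans <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_rep), function(r) {
      ti <- sample.int(length(traces), 1)
      n <- nrow(traces[[ti]])
      start <- sample.int(max(n - W - horizon_ms, 1), 1)  # init window start
      tibble(rep = r, trace = ti, start = start)
    })
  })
  inits <- purrr::map2(spans$trace, spans$start, function(ti, s) {
    traces[[ti]][s:(s + W - 1), ]
  })
  evs <- purrr::map2(spans$trace, spans$start, function(ti, s) {
    ev <- events[[ti]]
    ev <- ev[ev$onset_ms >= (s - 1) & ev$onset_ms < (s - 1 + W + horizon_ms), , drop = FALSE]
    ev$onset_ms <- ev$onset_ms - (s - 1)
    ev
  })
  preds <- autoregressive_batch(model, inits, evs, horizon_ms,
                                channels, target_names)
  purrr::pmap_dfr(list(spans$rep, spans$trace, spans$start, preds),
                  function(r, ti, s, pr) {
    truth <- traces[[ti]]$v_mV[(s + W):(s + W + horizon_ms - 1)]
    sm <- spike_match(detect_spikes(pr$v_mV, dt_ms = 1)$t_ms,
                      detect_spikes(truth, dt_ms = 1)$t_ms)
    tibble(rep = r, trace = ti, start_ms = s - 1,
           explained_variance = explained_variance(pr$v_mV, truth),
           precision = sm$precision, recall = sm$recall,
           n_true_spikes = sm$tp + sm$fn)
  })
}
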