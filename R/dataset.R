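#' Build a windowed supervised dataset from traces and events
#'
#' Converts 1-kHz traces plus their synaptic event trains into the
#' fixed-width supervised format used by all surrogate models: each input
#' row covers the `window` samples preceding the target sample, over an
#' ordered channel set; the target is the next sample of the designated
#' output series. Synaptic channels hold the quantal conductance (nS) at
#' the event's onset sample and 0 elsewhere.
#'
#' Two channel layouts are supported. The point-neuron layout has channels
#' `v`, `exc`, `inh` and optionally `i_na`, `i_k` (3 or 5 columns). The
#' multicompartment layout (`per_site = TRUE`) has `v` plus one channel per
#' synapse site (`n_sites` rows), e.g. 201 channels for 200 sites.
#'
#' Windows never cross a trace boundary: pass multiple traces as a list and
#' their windows are concatenated with per-trace bookkeeping.
#'
#' @param traces a `vc_trace` or list of `vc_trace`s.
#' @param events an [event_train()] or list parallel to `traces`.
#' @param window history length in samples (default 64 = 64 ms at 1 kHz).
#' @param channels character vector of input channels; default `v, exc, inh`
#'   plus `i_na, i_k` when the traces carry currents.
#' @param targets character vector of target channels (default `"v"`).
#' @param per_site use the per-site channel layout?
#' @param n_sites number of synapse-site channels when `per_site`.
#' @return an object of class `vc_dataset`: list with `inputs`
#'   (N x window x C array), `targets` (N x T matrix), `channels`,
#'   `target_names`, `window`, `dt_ms`, `trace_id`, `series` (per-trace
#'   channel matrices), `split` (NULL until [split_dataset()]), `norm`
#'   (NULL until [normalize_dataset()]).
#' @export
make_windows <- function(traces, events, window = 64, channels = NULL,
                         targets = "v", per_site = FALSE, n_sites = NULL) {
  if (inherits(traces, "vc_trace")) traces <- list(traces)
  if (is.data.frame(events)) events <- list(events)
  if (length(events) != length(traces)) abort("`traces` and `events` lengths differ")
  dt <- attr(traces[[1]], "dt_ms") %||% 1
  if (per_site) {
    n_sites <- n_sites %||% max(purrr::map_dbl(events, ~ max(c(.x$site, 0))))
    channels <- c("v", paste0("syn", seq_len(n_sites)))
  } else if (is.null(channels)) {
    channels <- c("v", "exc", "inh")
    if ("i_na_nA" %in% names(traces[[1]])) channels <- c(channels, "i_na", "i_k")
  }
  series <- purrr::map2(traces, events, function(tr, ev) {
    n <- nrow(tr)
    if (n < window + 1) abort("trace shorter than window + 1 samples")
    S <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
    S[, "v"] <- tr$v_mV
    onset_idx <- function(on) pmin(pmax(round(on / dt) + 1L, 1L), n)
    if (per_site) {
      if (nrow(ev) > 0) {
        idx <- onset_idx(ev$onset_ms)
        for (k in seq_len(nrow(ev))) {
          ch <- 1L + ev$site[k]
          S[idx[k], ch] <- S[idx[k], ch] + ev$weight_ns[k]
        }
      }
    } else {
      for (pol in c("exc", "inh")) {
        if (!pol %in% channels) next
        sel <- ev$polarity == pol
        if (any(sel)) {
          idx <- onset_idx(ev$onset_ms[sel])
          w <- ev$weight_ns[sel]
          for (k in seq_along(idx)) S[idx[k], pol] <- S[idx[k], pol] + w[k]
        }
      }
      if ("i_na" %in% channels) S[, "i_na"] <- tr$i_na_nA
      if ("i_k" %in% channels) S[, "i_k"] <- tr$i_k_nA
    }
    S
  })
  missing_t <- setdiff(targets, channels)
  if (length(missing_t)) abort(paste("target channels not in channel set:",
                                     paste(missing_t, collapse = ", ")))
  ds <- structure(list(
    series = series, channels = channels, target_names = targets,
    window = window, dt_ms = dt, split = NULL, norm = NULL
  ), class = "vc_dataset")
  materialize_windows(ds)
}

# (re)build the stacked input/target arrays from the per-trace series
materialize_windows <- function(ds) {
  W <- ds$window
  per_trace <- purrr::map(ds$series, function(S) {
    N <- nrow(S) - W
    x <- array(0, c(N, W, ncol(S)))
    for (k in seq_len(W)) x[, k, ] <- S[k:(k + N - 1), , drop = FALSE]
    y <- S[(W + 1):nrow(S), match(ds$target_names, ds$channels), drop = FALSE]
    list(x = x, y = y, n = N)
  })
  ns <- purrr::map_int(per_trace, "n")
  Ntot <- sum(ns)
  inputs <- array(0, c(Ntot, W, length(ds$channels)))
  targets <- matrix(0, Ntot, length(ds$target_names))
  off <- 0L
  for (p in per_trace) {
    inputs[off + seq_len(p$n), , ] <- p$x
    targets[off + seq_len(p$n), ] <- p$y
    off <- off + p$n
  }
  ds$inputs <- inputs
  ds$targets <- targets
  ds$trace_id <- rep(seq_along(ds$series), ns)
  ds
}

#' @export
print.vc_dataset <- function(x, ...) {
  cat(sprintf("<vc_dataset> %d windows of %d x %d (%s) -> %s%s%s\n",
              dim(x$inputs)[1], x$window, length(x$channels),
              paste(head(x$channels, 4), collapse = ","),
              paste(x$target_names, collapse = ","),
              if (!is.null(x$split)) " [split]" else "",
              if (!is.null(x$norm)) " [normalized]" else ""))
  invisible(x)
}

#' Assign train/validation/test splits
#'
#' Splits the window index into contiguous blocks (default 80/10/10).
#' Contiguous-block splitting avoids the train/test leakage that shuffled
#' splits of overlapping windows would cause.
#'
#' @param ds a `vc_dataset`.
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @return the dataset with a `split` factor (`train`/`val`/`test`).
#' @export
split_dataset <- function(ds, fractions = c(0.8, 0.1, 0.1)) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three numbers summing to 1")
  }
  n <- dim(ds$inputs)[1]
  n_train <- floor(n * fractions[1])
  n_val <- floor(n * fractions[2])
  ds$split <- factor(rep(c("train", "val", "test"),
                         c(n_train, n_val, n - n_train - n_val)),
                     levels = c("train", "val", "test"))
  ds
}

#' Normalization parameters
#'
#' Voltage is mapped affinely from fixed physiological bounds
#' `v_bounds_mv` (default -90..+40 mV) to the unit interval, so the inverse
#' transform is model-independent. Detected spike-peak samples (local maxima
#' above 0 mV, whose amplitudes are under-sampled at 1 kHz) are replaced by
#' `spike_peak_mv` (default +40) before scaling, standardizing all AP peaks.
#' Synaptic conductance channels are scaled by `g_bound_ns`; current
#' channels affinely from `i_bounds_na`.
#'
#' @param v_bounds_mv length-2 voltage bounds (mV).
#' @param spike_peak_mv standardized spike-peak value (mV, pre-scaling).
#' @param g_bound_ns conductance scale (nS).
#' @param i_bounds_na length-2 current bounds (nA).
#' @return an object of class `vc_norm`.
#' @export
norm_params <- function(v_bounds_mv = c(-90, 40), spike_peak_mv = 40,
                        g_bound_ns = 10, i_bounds_na = c(-30, 30)) {
  structure(list(v_bounds_mv = v_bounds_mv, spike_peak_mv = spike_peak_mv,
                 g_bound_ns = g_bound_ns, i_bounds_na = i_bounds_na),
            class = "vc_norm")
}

# scale a named channel column
norm_channel <- function(x, ch, np) {
  if (ch == "v") {
    (x - np$v_bounds_mv[1]) / diff(np$v_bounds_mv)
  } else if (ch %in% c("i_na", "i_k")) {
    (x - np$i_bounds_na[1]) / diff(np$i_bounds_na)
  } else {
    x / np$g_bound_ns
  }
}

denorm_channel <- function(x, ch, np) {
  if (ch == "v") {
    x * diff(np$v_bounds_mv) + np$v_bounds_mv[1]
  } else if (ch %in% c("i_na", "i_k")) {
    x * diff(np$i_bounds_na) + np$i_bounds_na[1]
  } else {
    x * np$g_bound_ns
  }
}

#' Normalize a windowed dataset
#'
#' Applies spike-peak standardization and channel scaling (see
#' [norm_params()]) to the underlying series and rebuilds the window
#' arrays. Out-of-bounds voltages are clipped to the bounds; the number of
#' clipped samples is recorded and reported as a warning.
#'
#' @param ds a `vc_dataset`.
#' @param params a `vc_norm`; defaults to [norm_params()].
#' @return the normalized dataset (with `norm` set).
#' @export
normalize_dataset <- function(ds, params = norm_params()) {
  if (!is.null(ds$norm)) abort("dataset is already normalized")
  n_clip <- 0L
  ds$series <- purrr::map(ds$series, function(S) {
    v <- S[, "v"]
    pk <- detect_spikes(v, dt_ms = ds$dt_ms)
    if (nrow(pk) > 0) v[round(pk$t_ms / ds$dt_ms) + 1L] <- params$spike_peak_mv
    clipped <- v < params$v_bounds_mv[1] | v > params$v_bounds_mv[2]
    n_clip <<- n_clip + sum(clipped)
    v <- pmin(pmax(v, params$v_bounds_mv[1]), params$v_bounds_mv[2])
    S[, "v"] <- v
    for (j in seq_len(ncol(S))) S[, j] <- norm_channel(S[, j], colnames(S)[j], params)
    S
  })
  if (n_clip > 0) {
    warn(sprintf("%d voltage samples outside normalization bounds were clipped", n_clip))
  }
  ds$norm <- params
  ds$n_clipped <- n_clip
  materialize_windows(ds)
}

#' Invert the voltage normalization
#'
#' @param x normalized values.
#' @param params a `vc_norm`.
#' @param channel channel name (default `"v"`).
#' @export
denormalize <- function(x, params, channel = "v") {
  denorm_channel(x, channel, params)
}

# convenience: split-indexed views used by the trainer
dataset_index <- function(ds, which = c("train", "val", "test")) {
  which <- match.arg(which)
  if (is.null(ds$split)) abort("dataset has no split; call split_dataset() first")
  which(ds$split == which)
}

#' Curriculum staging
#'
#' Orders stage corpora (resting, then subthreshold, then suprathreshold)
#' for sequential training, with a replay fraction: at stage k, a fraction
#' `mix_fraction` of every training batch is drawn from the pooled training
#' windows of stages < k, counteracting catastrophic forgetting.
#'
#' @param resting,subthreshold,suprathreshold normalized, split
#'   `vc_dataset`s.
#' @param mix_fraction replay fraction in (0, 1); 0 disables replay.
#' @return an object of class `vc_curriculum` (list of stages in fixed
#'   order plus the mix fraction).
#' @export
curriculum <- function(resting, subthreshold, suprathreshold,
                       mix_fraction = 0.3) {
  stages <- list(resting = resting, subthreshold = subthreshold,
                 suprathreshold = suprathreshold)
  for (nm in names(stages)) {
    if (dim(stages[[nm]]$inputs)[1] == 0) abort(sprintf("stage '%s' corpus is empty", nm))
  }
  if (mix_fraction < 0 || mix_fraction >= 1) abort("`mix_fraction` must be in [0, 1)")
  structure(list(stages = stages, mix_fraction = mix_fraction),
            class = "vc_curriculum")
}

# Compose the batch index plan for one curriculum stage: a list with the
# stage dataset, replay datasets and the per-batch replay count.
curriculum_plan <- function(cur, stage_i, batch_size) {
  n_replay <- if (stage_i == 1 || cur$mix_fraction == 0) 0L else {
    as.integer(round(batch_size * cur$mix_fraction))
  }
  list(stage = cur$stages[[stage_i]],
       replay = if (n_replay > 0) cur$stages[seq_len(stage_i - 1)] else list(),
       n_replay = n_replay)
}
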