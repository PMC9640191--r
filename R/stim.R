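#' Random synaptic event train
#'
#' Uniform-random event onsets over `[0, duration_ms)` at 1-ms resolution,
#' with counts split between excitatory and inhibitory synapses by
#' `ei_ratio` (default 8:3, the reference ratio). Rounding assigns any
#' excess event to the excitatory pool. Deterministic under `seed`.
#'
#' @param duration_ms train length (ms).
#' @param n_total total number of events (0 gives an empty train, used for
#'   the resting-stage corpus).
#' @param ei_ratio length-2 numeric, excitatory : inhibitory.
#' @param exc_weight_ns,inh_weight_ns quantal conductances (nS).
#' @param seed RNG seed.
#' @return an [event_train()].
#' @export
random_train <- function(duration_ms, n_total, ei_ratio = c(8, 3),
                         exc_weight_ns = 2.5, inh_weight_ns = 8,
                         seed = NULL) {
  stopifnot_scalar(duration_ms, "duration_ms", positive = TRUE)
  if (length(ei_ratio) != 2 || any(ei_ratio <= 0)) {
    abort("`ei_ratio` must be two positive numbers")
  }
  if (n_total == 0) return(event_train())
  n_inh <- floor(n_total * ei_ratio[2] / sum(ei_ratio))
  n_exc <- n_total - n_inh
  with_seed(seed, {
    onsets <- floor(runif(n_total, 0, duration_ms))
    event_train(
      onset_ms = onsets,
      synapse_id = c(rep("exc", n_exc), rep("inh", n_inh)),
      weight_ns = c(rep(exc_weight_ns, n_exc), rep(inh_weight_ns, n_inh)),
      polarity = c(rep("exc", n_exc), rep("inh", n_inh))
    )
  })
}

#' Quantal conductance sweep
#'
#' One single-excitatory-event train per quantal conductance on the grid
#' `seq(g_min_ns, g_max_ns, by = step_ns)` (default 0.1-3.5 nS in 0.1 nS
#' increments, 35 trains), each with one event at a fixed onset.
#'
#' @param g_min_ns,g_max_ns,step_ns sweep grid (nS).
#' @param onset_ms event onset within each train (ms).
#' @return list of [event_train()]s, named by conductance.
#' @export
quantal_sweep <- function(g_min_ns = 0.1, g_max_ns = 3.5, step_ns = 0.1,
                          onset_ms = 20) {
  if (g_min_ns > g_max_ns) abort("`g_min_ns` must be <= `g_max_ns`")
  stopifnot_scalar(step_ns, "step_ns", positive = TRUE)
  gs <- seq(g_min_ns, g_max_ns, by = step_ns)
  out <- lapply(gs, function(g) {
    event_train(onset_ms = onset_ms, synapse_id = "exc",
                weight_ns = g, polarity = "exc")
  })
  names(out) <- sprintf("%.6g", gs)
  out
}

#' Paired-pulse / pulse-train protocols
#'
#' Equal-weight excitatory pulse trains, one protocol per inter-stimulus
#' interval over `isi_range_ms` (default 2-10 ms in 1-ms increments, the
#' temporal-summation protocol).
#'
#' @param isi_range_ms vector of ISIs (ms) or length-2 range expanded in
#'   `isi_step_ms` increments.
#' @param n_pulses pulses per train (1 gives the unitary-event reference).
#' @param weight_ns quantal conductance (nS).
#' @param onset_ms onset of the first pulse (ms).
#' @param isi_step_ms grid step when `isi_range_ms` is a range.
#' @return list of [event_train()]s, named by ISI.
#' @export
paired_pulse_protocols <- function(isi_range_ms = c(2, 10), n_pulses = 2,
                                   weight_ns = 2.5, onset_ms = 20,
                                   isi_step_ms = 1) {
  isis <- if (length(isi_range_ms) == 2 && isi_range_ms[2] > isi_range_ms[1]) {
    seq(isi_range_ms[1], isi_range_ms[2], by = isi_step_ms)
  } else {
    isi_range_ms
  }
  if (any(isis <= 0)) abort("ISIs must be positive")
  out <- lapply(isis, function(isi) {
    event_train(onset_ms = onset_ms + (seq_len(n_pulses) - 1) * isi,
                synapse_id = "exc", weight_ns = weight_ns, polarity = "exc")
  })
  names(out) <- sprintf("%.6g", isis)
  out
}

#' Random train with normally distributed quantal weights
#'
#' Like [random_train()] but excitatory weights are drawn from a normal
#' distribution (default mean 2.5 nS, variance 0.001 nS^2); negative draws
#' are clipped to zero.
#'
#' @inheritParams random_train
#' @param mean_ns,variance_ns2 weight distribution parameters. The variance
#'   is in nS^2.
#' @export
variable_weight_train <- function(duration_ms, n_total, mean_ns = 2.5,
                                  variance_ns2 = 0.001, ei_ratio = c(8, 3),
                                  inh_weight_ns = 8, seed = NULL) {
  if (mean_ns <= 0) abort("`mean_ns` must be > 0")
  base <- random_train(duration_ms, n_total, ei_ratio,
                       exc_weight_ns = mean_ns, inh_weight_ns = inh_weight_ns,
                       seed = seed)
  if (nrow(base) == 0) return(base)
  exc <- base$polarity == "exc"
  w <- with_seed(derive_seed(seed, "weights"),
                 rnorm(sum(exc), mean_ns, sqrt(variance_ns2)))
  base$weight_ns[exc] <- pmax(w, 0)
  base
}

#' Excitation-inhibition protocol grid
#'
#' One random train per (input rate, E/I ratio, replicate) cell; the input
#' rate sets the expected total event count per second. Used to probe firing
#' responses under altered excitation-inhibition balance (reference ratios
#' 2:1 and 1:2).
#'
#' @param rates_hz vector of total input rates (events/s).
#' @param ratios list of length-2 numeric E:I ratios.
#' @param n_rep replicates (distinct seeds) per cell.
#' @param duration_ms train duration (ms).
#' @param seed global seed; per-train seeds are derived from it.
#' @inheritParams random_train
#' @return tibble with columns `rate_hz`, `ratio` (label), `rep`, and a
#'   list-column `events`.
#' @export
ei_grid <- function(rates_hz, ratios = list(c(2, 1), c(1, 2)), n_rep = 1,
                    duration_ms = 1000, exc_weight_ns = 2.5,
                    inh_weight_ns = 8, seed = NULL) {
  if (any(rates_hz <= 0)) abort("`rates_hz` must be positive")
  grid <- tidyr::expand_grid(
    rate_hz = rates_hz,
    ratio_i = seq_along(ratios),
    rep = seq_len(n_rep)
  )
  grid$ratio <- vapply(grid$ratio_i, function(i) paste(ratios[[i]], collapse = ":"),
                       character(1))
  grid$events <- purrr::pmap(grid, function(rate_hz, ratio_i, rep, ...) {
    random_train(duration_ms, round(rate_hz * duration_ms / 1000),
                 ei_ratio = ratios[[ratio_i]],
                 exc_weight_ns = exc_weight_ns, inh_weight_ns = inh_weight_ns,
                 seed = derive_seed(seed, paste(rate_hz, ratio_i, rep)))
  })
  grid[c("rate_hz", "ratio", "rep", "events")]
}
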