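#' Izhikevich layer parameters
#'
#' The five-parameter spiking head: two-variable quadratic
#' integrate-and-fire dynamics
#' `v' = 0.04 v^2 + 5 v + 140 - u + I`, `u' = a (b v - u)`, with reset
#' `v <- c`, `u <- u + d` at the fixed +30 cutoff. `dt` is the free
#' time-step scale that absorbs the membrane time constant when the layer
#' is driven at a fixed sampling rate.
#'
#' @param a recovery timescale (> 0).
#' @param b recovery sensitivity.
#' @param c post-spike voltage reset.
#' @param d post-spike recovery increment.
#' @param dt time-step scale (> 0, trainable in fits).
#' @return a list of class `vc_izh`.
#' @export
izh_params <- function(a = 0.02, b = 0.2, c = -65, d = 8, dt = 1) {
  if (a <= 0) abort("`a` must be > 0")
  if (dt <= 0) abort("`dt` must be > 0")
  structure(list(a = a, b = b, c = c, d = d, dt = dt), class = "vc_izh")
}

# resting state of the subthreshold system (stable fixed point with u = b v)
izh_rest <- function(p) {
  disc <- (5 - p$b)^2 - 4 * 0.04 * 140
  if (disc < 0) return(c(v = -65, u = -65 * p$b))
  v <- (-(5 - p$b) - sqrt(disc)) / (2 * 0.04)
  c(v = v, u = p$b * v)
}

#' Single Izhikevich update step
#'
#' One explicit update scaled by `p$dt`; returns the new state and whether
#' a spike (with its reset) occurred. The recovery variable `u` persists
#' across steps, also when the layer is stacked on a forecaster.
#'
#' @param state numeric `c(v, u)`.
#' @param I input drive (current-like, dimensionless).
#' @param p an [izh_params()].
#' @return list with `state` and `spiked`.
#' @export
izh_step <- function(state, I, p) {
  v <- state[1]; u <- state[2]
  v2 <- v + p$dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  u2 <- u + p$dt * p$a * (p$b * v - u)
  if (v2 >= 30) {
    list(state = c(p$c, u2 + p$d), spiked = TRUE)
  } else {
    list(state = c(v2, u2), spiked = FALSE)
  }
}

#' Simulate the Izhikevich layer over a drive series
#'
#' @param p an [izh_params()].
#' @param drive numeric vector, one drive value per sample.
#' @param state optional initial `c(v, u)`; defaults to the resting point.
#' @param dt_sample_ms nominal sample interval, used only for the time
#'   column of the output.
#' @return tibble with columns `t_ms`, `v` (spike samples clamped to +30)
#'   plus attributes `spike_idx` and `final_state`.
#' @export
izh_simulate <- function(p, drive, state = NULL, dt_sample_ms = 1) {
  state <- state %||% izh_rest(p)
  res <- .izh_sim(p$a, p$b, p$c, p$d, p$dt, as.numeric(drive),
                  state[1], state[2])
  out <- tibble(t_ms = (seq_along(drive) - 1) * dt_sample_ms, v = res$v)
  attr(out, "spike_idx") <- res$spike_idx
  attr(out, "final_state") <- res$final
  out
}

#' Catalog of qualitative firing patterns
#'
#' Four labelled presets spanning the classic firing phenotypes of the
#' model, with example traces under constant suprathreshold drive.
#'
#' @param drive constant drive used for the example traces.
#' @param duration_ms example length.
#' @return tibble with columns `pattern`, `a`, `b`, `c`, `d`, `dt` and a
#'   list-column `trace`.
#' @export
firing_pattern_catalog <- function(drive = 10, duration_ms = 1000) {
  presets <- tibble(
    pattern = c("tonic", "adapting", "bursting", "fast_spiking"),
    a = c(0.02, 0.01, 0.02, 0.1),
    b = c(0.2, 0.2, 0.2, 0.2),
    c = c(-65, -65, -50, -65),
    d = c(6, 8, 2, 2),
    dt = 1
  )
  presets$trace <- purrr::pmap(presets, function(pattern, a, b, c, d, dt) {
    izh_simulate(izh_params(a, b, c, d, dt), rep(drive, duration_ms))
  })
  presets
}

# spike times (ms) of a simulated izh trace
izh_spike_times <- function(sim, dt_sample_ms = 1) {
  (attr(sim, "spike_idx") - 1) * dt_sample_ms
}

# --- fitting ---------------------------------------------------------------

# composite objective: squared firing-rate error over current steps plus
# subthreshold MSE over traces, weighted w_rate : w_sub
izh_objective <- function(theta, fi_drives, fi_rates, sub_drives, sub_traces,
                          w_rate = 1, w_sub = 1, rate_window_ms = NULL) {
  p <- list(a = exp(theta[1]), b = theta[2], c = theta[3], d = theta[4],
            dt = exp(theta[5]), gain = exp(theta[6]))
  obj <- 0
  if (length(fi_drives) > 0) {
    rates <- vapply(seq_along(fi_drives), function(i) {
      sim <- .izh_sim(p$a, p$b, p$c, p$d, p$dt, p$gain * fi_drives[[i]],
                      izh_rest(p)[1], izh_rest(p)[2])
      length(sim$spike_idx) / (length(fi_drives[[i]]) / 1000)
    }, numeric(1))
    obj <- obj + w_rate * mean((rates - fi_rates)^2) / max(mean(fi_rates^2), 1)
  }
  if (length(sub_drives) > 0) {
    err <- vapply(seq_along(sub_drives), function(i) {
      sim <- .izh_sim(p$a, p$b, p$c, p$d, p$dt, p$gain * sub_drives[[i]],
                      izh_rest(p)[1], izh_rest(p)[2])
      tr <- sub_traces[[i]]
      mean((sim$v - tr)^2) / max(var(tr), 1e-6)
    }, numeric(1))
    obj <- obj + w_sub * mean(err)
  }
  if (!is.finite(obj)) obj <- 1e12
  obj
}

#' Fit the Izhikevich layer to ground-truth data
#'
#' Derivative-free (Nelder-Mead) multi-start minimization of a composite
#' objective: normalized squared firing-rate error over a set of current
#' steps (f-I curve) plus normalized subthreshold mean squared error over
#' voltage traces, weighted `w_rate : w_sub` (default 1:1). Optimized
#' parameters are `(a, b, c, d, dt)` plus an input gain mapping physical
#' drive (nA-scale) onto the model's current axis; `a`, `dt` and the gain
#' are searched in log space.
#'
#' @param fi data frame with list-column `drive` (per-sample drive vectors)
#'   and column `rate_hz` (teacher firing rate per step).
#' @param subthreshold data frame with list-columns `drive` and `v`
#'   (teacher subthreshold voltage, same sampling).
#' @param init an [izh_params()] starting point.
#' @param init_gain starting input gain.
#' @param n_starts number of seeded simplex restarts (perturbed starts).
#' @param w_rate,w_sub objective weights.
#' @param maxit simplex iterations per start.
#' @param seed RNG seed for the restarts.
#' @return object of class `vc_izh_fit`: list with `params` (an
#'   [izh_params()]), `gain`, `value` (objective at optimum), `starts`
#'   (per-start results), `improved` (FALSE when no start improved on the
#'   initial objective, in which case the best-of-starts is still
#'   returned, flagged).
#' @export
fit_izhikevich <- function(fi, subthreshold = NULL, init = izh_params(),
                           init_gain = 1, n_starts = 20, w_rate = 1,
                           w_sub = 1, maxit = 300, seed = NULL) {
  fi_drives <- fi$drive
  fi_rates <- fi$rate_hz
  sub_drives <- if (!is.null(subthreshold)) subthreshold$drive else list()
  sub_traces <- if (!is.null(subthreshold)) subthreshold$v else list()
  f <- function(theta) izh_objective(theta, fi_drives, fi_rates,
                                     sub_drives, sub_traces, w_rate, w_sub)
  theta0 <- c(log(init$a), init$b, init$c, init$d, log(init$dt), log(init_gain))
  base_val <- f(theta0)
  # canonical firing-phenotype anchors visited by the restarts, spanning
  # fast-spiking, class-2 and regular-spiking regimes
  anchors <- list(
    theta0,
    c(log(0.1), 0.2, -65, 2, log(0.5), log(init_gain)),
    c(log(0.2), 0.26, -65, 0, log(0.5), log(init_gain)),
    c(log(0.02), 0.2, -65, 6, log(0.8), log(init_gain))
  )
  with_seed(seed, {
    starts <- purrr::map_dfr(seq_len(n_starts), function(s) {
      th <- anchors[[(s - 1) %% length(anchors) + 1]]
      if (s > length(anchors)) {
        th <- th + rnorm(6, 0, c(0.5, 0.05, 3, 1.5, 0.4, 0.5))
      }
      fit <- optim(th, f, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-9))
      # one polish pass from the incumbent
      fit2 <- optim(fit$par, f, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-10))
      if (fit2$value < fit$value) fit <- fit2
      tibble(start = s, value = fit$value, theta = list(fit$par))
    })
    best <- starts[which.min(starts$value), ]
    th <- best$theta[[1]]
    structure(list(
      params = izh_params(exp(th[1]), th[2], th[3], th[4], exp(th[5])),
      gain = exp(th[6]),
      value = best$value,
      starts = starts[c("start", "value")],
      improved = best$value < base_val - 1e-12,
      initial_value = base_val
    ), class = "vc_izh_fit")
  })
}

#' @export
print.vc_izh_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<vc_izh_fit> a=%.4g b=%.4g c=%.4g d=%.4g dt=%.4g gain=%.4g | objective %.4g%s\n",
    p$a, p$b, p$c, p$d, p$dt, x$gain, x$value,
    if (!x$improved) " [no start improved; best-of-starts]" else ""))
  invisible(x)
}

#' @export
tidy.vc_izh_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c", "d", "dt", "gain"),
         estimate = c(x$params$a, x$params$b, x$params$c, x$params$d,
                      x$params$dt, x$gain))
}

#' @export
glance.vc_izh_fit <- function(x, ...) {
  tibble(objective = x$value, improved = x$improved,
         n_starts = nrow(x$starts), initial_objective = x$initial_value)
}

#' Fast-spiking ground-truth teacher for Izhikevich fitting
#'
#' Generates the teacher dataset from an active Hodgkin-Huxley point
#' neuron, whose non-adapting sodium/delayed-rectifier dynamics give a
#' fast-spiking (tonic, non-accommodating) phenotype. Two corpora are
#' produced, both with per-sample current drives (nA at 1 kHz) aligned to
#' the recorded voltage:
#' \itemize{
#' \item an f-I curve from somatic current steps delivered on top of a weak
#'   random synaptic background (the background linearizes the sharp
#'   type-II rate onset of the deterministic model into the graded f-I
#'   curve such cells show in vivo);
#' \item subthreshold voltage segments under synaptic barrage alone, for
#'   the subthreshold objective. The synaptic drive handed to the fitted
#'   layer is the 1-kHz synaptic current reconstructed from the event
#'   train and the recorded voltage.
#' }
#'
#' @param model a [compartment_model()] (active; the default lowers the
#'   leak to `rm_kohm_cm2 = 10`, giving the higher input resistance of a
#'   fast-spiking phenotype).
#' @param amps_na step amplitudes for the f-I curve (nA).
#' @param sub_amps_na bias currents for the subthreshold segments (nA).
#' @param step_ms step duration (ms).
#' @param pre_ms pre-step baseline (ms).
#' @param bg_hz total background synaptic event rate (events/s; 0 disables
#'   the background).
#' @param bg_exc_ns,bg_inh_ns background quantal sizes (nS).
#' @param seed seed for the background trains.
#' @param n_steps optional truncation of `amps_na` (first `n_steps`).
#' @return list with `fi` (tibble: `amp_na`, `rate_hz`, list-column
#'   `drive`) and `subthreshold` (tibble: `amp_na`, list-columns `drive`,
#'   `v`).
#' @export
make_fs_teacher <- function(model = compartment_model(rm_kohm_cm2 = 10),
                            amps_na = seq(0.1, 0.8, by = 0.1),
                            sub_amps_na = c(-0.05, 0, 0.05),
                            step_ms = 1000, pre_ms = 50, bg_hz = 400,
                            bg_exc_ns = 0.4, bg_inh_ns = 1.2, seed = 1,
                            n_steps = NULL) {
  if (!is.null(n_steps)) amps_na <- amps_na[seq_len(min(n_steps, length(amps_na)))]
  init <- steady_state_init(model, check = FALSE)
  dur <- pre_ms + step_ms + 50
  syn <- default_synapses()
  run <- function(amp, stream) {
    ev <- if (bg_hz > 0) {
      random_train(dur, round(bg_hz * dur / 1000),
                   exc_weight_ns = bg_exc_ns, inh_weight_ns = bg_inh_ns,
                   seed = derive_seed(seed, stream))
    } else {
      event_train()
    }
    tr <- simulate_point_neuron(model, ev, dur,
                                i_step = list(amp_na = amp, onset_ms = pre_ms,
                                              dur_ms = step_ms),
                                init = init)
    step_i <- numeric(dur + 1)
    step_i[(pre_ms + 1):(pre_ms + step_ms)] <- amp
    list(trace = tr, drive = step_i + synaptic_current_1khz(ev, tr, syn))
  }
  fi <- purrr::map_dfr(seq_along(amps_na), function(i) {
    r <- run(amps_na[i], paste0("fi", i))
    sp <- detect_spikes(r$trace)
    tibble(amp_na = amps_na[i],
           rate_hz = sum(sp$t_ms >= pre_ms & sp$t_ms < pre_ms + step_ms) /
             (step_ms / 1000),
           drive = list(r$drive))
  })
  subthreshold <- purrr::map_dfr(seq_along(sub_amps_na), function(i) {
    r <- run(sub_amps_na[i], paste0("sub", i))
    tibble(amp_na = sub_amps_na[i], drive = list(r$drive),
           v = list(r$trace$v_mV))
  })
  list(fi = fi, subthreshold = subthreshold)
}

#' Synaptic current reconstructed on the 1-kHz grid
#'
#' Sums the alpha-conductance kernels of an event train sampled at 1 kHz
#' and multiplies by the instantaneous driving force from the recorded
#' voltage, returning the total synaptic current in nA. This is the
#' current-like drive a spiking head consumes.
#'
#' @param events an [event_train()].
#' @param trace the recorded `vc_trace` (1 kHz).
#' @param synapses synapse table (see [simulate_point_neuron()]).
#' @return numeric vector of length `nrow(trace)` (nA, inward positive).
#' @export
synaptic_current_1khz <- function(events, trace, synapses = default_synapses()) {
  n <- nrow(trace)
  out <- numeric(n)
  if (nrow(events) == 0) return(out)
  t <- trace$t_ms
  for (k in seq_len(nrow(events))) {
    sp <- synapses[[events$synapse_id[k]]]
    x <- (t - events$onset_ms[k]) / sp$tau_ms
    live <- x > 0 & x < 16
    g_us <- events$weight_ns[k] * 1e-3 * x[live] * exp(1 - x[live])
    out[live] <- out[live] + g_us * (sp$e_rev_mv - trace$v_mV[live])
  }
  out
}

#' Firing rate of the fitted layer under a drive
#'
#' @param fit a `vc_izh_fit` (or an [izh_params()] with `gain = 1`).
#' @param drive per-sample drive vector (physical units; the fit's gain is
#'   applied).
#' @return firing rate in Hz.
#' @export
izh_rate <- function(fit, drive) {
  p <- if (inherits(fit, "vc_izh_fit")) fit$params else fit
  gain <- if (inherits(fit, "vc_izh_fit")) fit$gain else 1
  sim <- izh_simulate(p, gain * drive)
  length(attr(sim, "spike_idx")) / (length(drive) / 1000)
}
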