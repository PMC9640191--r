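#' Single-compartment neuron model specification
#'
#' Describes the cylinder geometry, passive membrane, and (optionally)
#' Hodgkin-Huxley sodium / delayed-rectifier potassium / leak conductances of
#' the ground-truth point neuron. Defaults are the reference model used
#' throughout: a 25 x 25 um compartment with specific membrane resistance
#' 1 kOhm cm2, Cm 1 uF/cm2, axial resistivity 35.4 Ohm cm, resting at -70 mV,
#' and HH densities gNa 0.12, gK 0.036, g_leak 0.0003 S/cm2 with reversal
#' potentials +50 / -77 / -54.3 mV.
#'
#' The passive leak reversal is not a free field: it is balanced during
#' steady-state initialization so that the full model rests at exactly
#' `v_rest` (see [steady_state_init()]).
#'
#' @param length_um,diam_um cylinder length and diameter in micrometres.
#' @param rm_kohm_cm2 specific membrane resistance (kOhm cm2).
#' @param cm_uf_cm2 specific capacitance (uF/cm2).
#' @param ri_ohm_cm axial resistivity (Ohm cm); only used by cable models.
#' @param v_rest resting potential in mV.
#' @param gna_s_cm2,gk_s_cm2,gl_s_cm2 HH conductance densities (S/cm2).
#' @param ena_mv,ek_mv,el_mv reversal potentials (mV).
#' @param active logical; include the HH channels?
#' @param kdr_shift_mv voltage shift (mV) applied to the delayed-rectifier
#'   kinetics; positive values shift activation rightward (depolarized).
#' @return an object of class `vc_model`.
#' @export
compartment_model <- function(length_um = 25, diam_um = 25,
                              rm_kohm_cm2 = 1, cm_uf_cm2 = 1, ri_ohm_cm = 35.4,
                              v_rest = -70,
                              gna_s_cm2 = 0.12, gk_s_cm2 = 0.036, gl_s_cm2 = 3e-4,
                              ena_mv = 50, ek_mv = -77, el_mv = -54.3,
                              active = TRUE, kdr_shift_mv = 0) {
  stopifnot_scalar(length_um, "length_um", positive = TRUE)
  stopifnot_scalar(diam_um, "diam_um", positive = TRUE)
  stopifnot_scalar(cm_uf_cm2, "cm_uf_cm2", positive = TRUE)
  stopifnot_scalar(rm_kohm_cm2, "rm_kohm_cm2", positive = TRUE)
  for (g in c(gna_s_cm2, gk_s_cm2, gl_s_cm2)) {
    if (!is.finite(g) || g < 0) abort("conductance densities must be >= 0")
  }
  for (e in c(ena_mv, ek_mv, el_mv)) {
    if (e < -120 || e > 80) abort("reversal potentials must lie in [-120, 80] mV")
  }
  structure(list(
    length_um = length_um, diam_um = diam_um,
    rm_kohm_cm2 = rm_kohm_cm2, cm_uf_cm2 = cm_uf_cm2, ri_ohm_cm = ri_ohm_cm,
    v_rest = v_rest,
    gna_s_cm2 = gna_s_cm2, gk_s_cm2 = gk_s_cm2, gl_s_cm2 = gl_s_cm2,
    ena_mv = ena_mv, ek_mv = ek_mv, el_mv = el_mv,
    active = isTRUE(active), kdr_shift_mv = kdr_shift_mv
  ), class = "vc_model")
}

#' @export
print.vc_model <- function(x, ...) {
  cat(sprintf("<vc_model> %s, %g x %g um, Rm %g kOhm cm2, rest %g mV",
              if (x$active) "active (HH)" else "passive",
              x$length_um, x$diam_um, x$rm_kohm_cm2, x$v_rest))
  if (x$active && x$kdr_shift_mv != 0) cat(sprintf(", KDR shift %+g mV", x$kdr_shift_mv))
  cat("\n")
  invisible(x)
}

# membrane area of the cylinder in cm2 (side wall only, as in cable simulators)
model_area_cm2 <- function(model) {
  pi * (model$diam_um * 1e-4) * (model$length_um * 1e-4)
}

#' Synapse specification
#'
#' Alpha-conductance synapse: g(t) = w * ((t - t0)/tau) * exp(1 - (t - t0)/tau),
#' peaking at exactly the quantal amplitude `w` at `t0 + tau`. The `nmda` kind
#' carries a Boltzmann voltage gate that multiplies the conductance
#' (see [nmda_gate()]).
#'
#' @param kind one of `"alpha_exc"`, `"alpha_inh"`, `"ampa"`, `"nmda"`.
#' @param tau_ms conductance time constant (ms).
#' @param gmax_ns default quantal conductance (nS); per-event weights override.
#' @param e_rev_mv reversal potential (mV).
#' @param boltzmann for `"nmda"` only: list with `A1`, `A2`, `x0`, `dx`
#'   (mV-scale gate parameters).
#' @return an object of class `vc_synapse`.
#' @export
synapse_spec <- function(kind = c("alpha_exc", "alpha_inh", "ampa", "nmda"),
                         tau_ms = NULL, gmax_ns = NULL, e_rev_mv = NULL,
                         boltzmann = NULL) {
  kind <- match.arg(kind)
  defaults <- list(
    alpha_exc = list(tau_ms = 2, gmax_ns = 2.5, e_rev_mv = 0),
    alpha_inh = list(tau_ms = 1, gmax_ns = 8, e_rev_mv = -90),
    ampa      = list(tau_ms = 2, gmax_ns = 2.5, e_rev_mv = 0),
    nmda      = list(tau_ms = 25, gmax_ns = 2.5, e_rev_mv = 0)
  )[[kind]]
  tau_ms <- tau_ms %||% defaults$tau_ms
  gmax_ns <- gmax_ns %||% defaults$gmax_ns
  e_rev_mv <- e_rev_mv %||% defaults$e_rev_mv
  stopifnot_scalar(tau_ms, "tau_ms", positive = TRUE)
  if (gmax_ns < 0) abort("`gmax_ns` must be >= 0")
  if (kind == "nmda") {
    boltzmann <- boltzmann %||% nmda_boltzmann_default()
    if (!all(c("A1", "A2", "x0", "dx") %in% names(boltzmann))) {
      abort("`boltzmann` must contain A1, A2, x0, dx")
    }
    if (boltzmann$dx == 0) abort("`boltzmann$dx` must be non-zero")
  } else if (!is.null(boltzmann)) {
    abort("`boltzmann` is only meaningful for kind = \"nmda\"")
  }
  structure(list(kind = kind, tau_ms = tau_ms, gmax_ns = gmax_ns,
                 e_rev_mv = e_rev_mv, boltzmann = boltzmann),
            class = "vc_synapse")
}

#' Voltage-scale parameters of the NMDA Boltzmann gate
#'
#' The reference gate used by the compound AMPA+NMDA synapse: A1 = 1,
#' A2 = -1, half-activation x0 = -63.32 mV and slope dx = 0.013 mV, i.e. a
#' near-step gate at -63.32 mV. The companion constants on the normalized
#' (layer-space) voltage axis are x0 = 1.44, dx = 0.12; see
#' [attach_nmda_head()].
#' @export
nmda_boltzmann_default <- function() {
  list(A1 = 1, A2 = -1, x0 = -63.32, dx = 0.013)
}

#' NMDA Boltzmann voltage gate
#'
#' Dimensionless scale applied to the NMDA conductance as a function of the
#' instantaneous membrane potential:
#' `A2 + (A1 - A2) / (1 + exp((x0 - v)/dx))`.
#' The sign convention is fixed so that the gate *increases* with
#' depolarization (relief of block), approaching `A1` for depolarized and
#' `A2` for hyperpolarized potentials.
#'
#' @param v membrane potential (mV), vectorized.
#' @param boltzmann list with `A1`, `A2`, `x0`, `dx`.
#' @return numeric vector of gate values.
#' @export
nmda_gate <- function(v, boltzmann = nmda_boltzmann_default()) {
  if (boltzmann$dx == 0) abort("`dx` must be non-zero")
  z <- (boltzmann$x0 - v) / boltzmann$dx
  z <- pmin(pmax(z, -500), 500)
  boltzmann$A2 + (boltzmann$A1 - boltzmann$A2) / (1 + exp(z))
}

# default synapse table used to translate event polarity into kinetics
default_synapses <- function() {
  list(exc = synapse_spec("alpha_exc"), inh = synapse_spec("alpha_inh"),
       ampa = synapse_spec("ampa"), nmda = synapse_spec("nmda"))
}

# --- steady-state initialization ------------------------------------------

hh_rates <- function(v) {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (exp(x / y) - 1))
  list(am = 0.1 * vtrap(-(v + 40), 10), bm = 4 * exp(-(v + 65) / 18),
       ah = 0.07 * exp(-(v + 65) / 20), bh = 1 / (1 + exp(-(v + 35) / 10)),
       an = 0.01 * vtrap(-(v + 55), 10), bn = 0.125 * exp(-(v + 65) / 80))
}

hh_gates_inf <- function(v, kdr_shift = 0) {
  r <- hh_rates(v)
  rn <- hh_rates(v - kdr_shift)
  list(m = r$am / (r$am + r$bm), h = r$ah / (r$ah + r$bh),
       n = rn$an / (rn$an + rn$bn))
}

# leak reversal that balances all steady-state currents at v_rest
balanced_epas <- function(model) {
  v <- model$v_rest
  if (!model$active) return(v)
  g <- hh_gates_inf(v, model$kdr_shift_mv)
  i_active <- model$gna_s_cm2 * g$m^3 * g$h * (v - model$ena_mv) +
    model$gk_s_cm2 * g$n^4 * (v - model$ek_mv) +
    model$gl_s_cm2 * (v - model$el_mv)
  gpas <- 1 / (model$rm_kohm_cm2 * 1e3)  # S/cm2
  v + i_active / gpas
}

# internal: the list handed to the C++ integrator
model_cpars <- function(model, init = NULL) {
  init <- init %||% steady_state_init(model, check = FALSE)
  list(area_cm2 = model_area_cm2(model), cm_uf_cm2 = model$cm_uf_cm2,
       gpas_s_cm2 = 1 / (model$rm_kohm_cm2 * 1e3), epas_mv = init$epas,
       gna_s_cm2 = model$gna_s_cm2, gk_s_cm2 = model$gk_s_cm2,
       gl_s_cm2 = model$gl_s_cm2, ena_mv = model$ena_mv, ek_mv = model$ek_mv,
       el_mv = model$el_mv, kdr_shift_mv = model$kdr_shift_mv,
       active = model$active, v0 = init$v, m0 = init$m, h0 = init$h, n0 = init$n,
       ri_ohm_cm = model$ri_ohm_cm)
}

#' Steady-state initialization of the point-neuron model
#'
#' Balances the passive leak reversal so that the complete model (leak plus
#' any HH conductances with gates at their voltage-clamped steady state)
#' rests at exactly `model$v_rest`, then integrates the event-free model for
#' `settle_ms` and verifies that the state does not drift. This mirrors the
#' customary steady-state initialization of compartmental simulators.
#'
#' @param model a [compartment_model()].
#' @param settle_ms event-free settling time (ms).
#' @param dt_us internal integration step (microseconds).
#' @param check verify post-settling drift over 1 s and error if it exceeds
#'   `tol_mv`?
#' @param tol_mv drift tolerance in mV.
#' @return list with elements `v`, `m`, `h`, `n` (state after settling),
#'   `epas` (balanced leak reversal, mV) and `drift_mv`.
#' @export
steady_state_init <- function(model, settle_ms = 2000, dt_us = 25,
                              check = TRUE, tol_mv = 0.01) {
  g <- hh_gates_inf(model$v_rest, model$kdr_shift_mv)
  init <- list(v = model$v_rest, m = g$m, h = g$h, n = g$n,
               epas = balanced_epas(model), drift_mv = 0)
  if (!check && settle_ms <= 0) return(init)
  cp <- model_cpars(model, init = init)
  res <- .hh_point_sim(cp, matrix(numeric(0), 0, 5), nmda_boltzmann_default(),
                       settle_ms, dt_us * 1e-3, 1, 0, 0, 0, FALSE, FALSE)
  fin <- res$final
  out <- list(v = fin[1], m = fin[2], h = fin[3], n = fin[4],
              epas = init$epas, drift_mv = NA_real_)
  if (check) {
    res2 <- .hh_point_sim(model_cpars(model, init = out),
                          matrix(numeric(0), 0, 5), nmda_boltzmann_default(),
                          1000, dt_us * 1e-3, 1, 0, 0, 0, FALSE, FALSE)
    out$drift_mv <- max(abs(res2$v_mv - out$v))
    if (!is.finite(out$drift_mv) || out$drift_mv > tol_mv) {
      abort(sprintf(
        "model does not reach a steady state (drift %.4g mV over 1 s); unstable parameters",
        out$drift_mv))
    }
  }
  out
}

#' Fixed point of the membrane current balance
#'
#' Root-finds the voltage at which the total steady-state membrane current
#' vanishes (gates held at their voltage-clamped steady state), given an
#' explicit leak reversal. Used as an independent check on
#' [steady_state_init()].
#'
#' @param model a [compartment_model()].
#' @param epas_mv passive leak reversal (mV); defaults to the balanced value.
#' @param interval search interval (mV).
#' @return the fixed-point voltage (mV).
#' @export
hh_fixed_point <- function(model, epas_mv = NULL, interval = c(-90, -40)) {
  epas_mv <- epas_mv %||% balanced_epas(model)
  gpas <- 1 / (model$rm_kohm_cm2 * 1e3)
  f <- function(v) {
    i <- gpas * (v - epas_mv)
    if (model$active) {
      g <- hh_gates_inf(v, model$kdr_shift_mv)
      i <- i + model$gna_s_cm2 * g$m^3 * g$h * (v - model$ena_mv) +
        model$gk_s_cm2 * g$n^4 * (v - model$ek_mv) +
        model$gl_s_cm2 * (v - model$el_mv)
    }
    i
  }
  stats::uniroot(f, interval = interval, tol = 1e-10)$root
}

# --- event handling --------------------------------------------------------

#' Construct an event train
#'
#' An event train is a tibble with columns `onset_ms`, `synapse_id`
#' (character, matched against the synapse table), `weight_ns` (quantal
#' conductance, nS) and `polarity` (`"exc"`/`"inh"`), sorted by onset.
#'
#' @param onset_ms,synapse_id,weight_ns,polarity column vectors (recycled).
#' @return a tibble of class `vc_events`.
#' @export
event_train <- function(onset_ms = numeric(), synapse_id = character(),
                        weight_ns = numeric(), polarity = character()) {
  n <- max(length(onset_ms), length(synapse_id), length(weight_ns), length(polarity))
  if (n == 0) {
    ev <- tibble(onset_ms = numeric(), synapse_id = character(),
                 weight_ns = numeric(), polarity = character())
  } else {
    if (length(synapse_id) == 0) synapse_id <- rep(polarity, length.out = n)
    ev <- tibble(onset_ms = rep(onset_ms, length.out = n),
                 synapse_id = rep(synapse_id, length.out = n),
                 weight_ns = rep(weight_ns, length.out = n),
                 polarity = rep(polarity, length.out = n))
  }
  if (any(ev$weight_ns < 0)) abort("event weights must be >= 0")
  ev <- dplyr::arrange(ev, .data$onset_ms)
  class(ev) <- c("vc_events", class(ev))
  ev
}

as_event_matrix <- function(events, synapses, comp = NULL) {
  if (nrow(events) == 0) {
    return(matrix(numeric(0), 0, if (is.null(comp)) 5 else 6))
  }
  specs <- lapply(events$synapse_id, function(id) {
    sp <- synapses[[id]]
    if (is.null(sp)) abort(sprintf("unknown synapse id '%s'", id))
    sp
  })
  m <- cbind(events$onset_ms,
             events$weight_ns,
             vapply(specs, `[[`, numeric(1), "tau_ms"),
             vapply(specs, `[[`, numeric(1), "e_rev_mv"),
             vapply(specs, function(s) as.numeric(s$kind == "nmda"), numeric(1)))
  if (!is.null(comp)) m <- cbind(m, comp)
  m[order(m[, 1]), , drop = FALSE]
}

# --- trace container -------------------------------------------------------

new_trace <- function(t_ms, v_mv, ina_na = NULL, ik_na = NULL, dt_ms = 1,
                      model = NULL, events = NULL) {
  tr <- tibble(t_ms = t_ms, v_mV = v_mv)
  if (!is.null(ina_na)) tr$i_na_nA <- ina_na
  if (!is.null(ik_na)) tr$i_k_nA <- ik_na
  if (any(!is.finite(tr$v_mV))) abort("non-finite values in voltage trace")
  attr(tr, "dt_ms") <- dt_ms
  attr(tr, "model") <- model
  attr(tr, "events") <- events
  class(tr) <- c("vc_trace", class(tr))
  tr
}

#' @export
print.vc_trace <- function(x, ...) {
  cat(sprintf("<vc_trace> %d samples at %g kHz, V in [%.2f, %.2f] mV\n",
              nrow(x), 1 / attr(x, "dt_ms"), min(x$v_mV), max(x$v_mV)))
  NextMethod()
}

# --- simulation ------------------------------------------------------------

#' Simulate the single-compartment neuron
#'
#' Integrates the passive + Hodgkin-Huxley + synaptic membrane equation with
#' exponential-Euler gate updates and an implicit (backward-Euler) voltage
#' update at an internal step of `dt_us` microseconds (default 25), after
#' steady-state initialization. The output is decimated to `record_khz`
#' (default 1 kHz: the sample at each integer millisecond).
#'
#' @param model a [compartment_model()].
#' @param events an [event_train()] (may be empty).
#' @param duration_ms simulation length (ms).
#' @param synapses named list of [synapse_spec()]s; event `synapse_id`s index
#'   into it. Defaults to the reference excitatory/inhibitory alpha synapses
#'   plus `ampa`/`nmda`.
#' @param record_currents also record sodium and potassium currents (nA)?
#' @param i_step optional current step: list with `amp_na`, `onset_ms`,
#'   `dur_ms`.
#' @param dt_us internal integration step (microseconds).
#' @param record_khz output sampling rate (kHz).
#' @param init optional state from [steady_state_init()] (computed if NULL).
#' @return a `vc_trace` tibble with columns `t_ms`, `v_mV` and, if requested,
#'   `i_na_nA`, `i_k_nA`.
#' @export
simulate_point_neuron <- function(model, events = event_train(),
                                  duration_ms = 1000,
                                  synapses = default_synapses(),
                                  record_currents = FALSE,
                                  i_step = NULL, dt_us = 25, record_khz = 1,
                                  init = NULL) {
  stopifnot_scalar(duration_ms, "duration_ms", positive = TRUE)
  if (nrow(events) > 0 && (min(events$onset_ms) < 0 || max(events$onset_ms) > duration_ms)) {
    abort("event onsets must lie within [0, duration_ms]")
  }
  init <- init %||% steady_state_init(model, check = FALSE)
  evm <- as_event_matrix(events, synapses)
  bz <- nmda_boltzmann_default()
  for (sp in synapses) if (!is.null(sp$boltzmann)) bz <- sp$boltzmann
  is_ <- i_step %||% list(amp_na = 0, onset_ms = 0, dur_ms = 0)
  res <- .hh_point_sim(model_cpars(model, init), evm, bz,
                       duration_ms, dt_us * 1e-3, 1 / record_khz,
                       is_$amp_na, is_$onset_ms, is_$dur_ms,
                       record_currents, FALSE)
  new_trace(res$t_ms, res$v_mv,
            if (record_currents) res$ina_na, if (record_currents) res$ik_na,
            dt_ms = 1 / record_khz, model = model, events = events)
}

#' Simulate a passive cable chain with an active soma
#'
#' A deliberately simple multicompartment stand-in: an unbranched chain of
#' `n_comp` equal cylinders (optionally tapering), passive everywhere except
#' the somatic compartment (compartment 1), which carries the model's HH
#' channels when `model$active`. Synaptic events are delivered to
#' per-site compartments, which makes the somatic response site-dependent
#' through cable attenuation. This is not a reconstructed morphology.
#'
#' @param model a [compartment_model()]; `ri_ohm_cm` sets axial coupling.
#' @param events an [event_train()] with an additional integer `site` column.
#' @param site_comp integer vector mapping site index -> compartment index.
#' @param n_comp number of compartments in the chain.
#' @param duration_ms simulation length (ms).
#' @param taper optional multiplicative diameter taper per compartment.
#' @param record_all record all compartment voltages (attribute `v_all`)?
#' @inheritParams simulate_point_neuron
#' @return a `vc_trace` of the somatic voltage.
#' @export
simulate_cable_neuron <- function(model, events = event_train(), site_comp = 1L,
                                  n_comp = 10, duration_ms = 1000,
                                  synapses = default_synapses(), taper = 1,
                                  dt_us = 25, record_khz = 1, record_all = FALSE) {
  if (length(site_comp) > 200) abort("at most 200 synapse sites are supported")
  if (any(site_comp < 1 | site_comp > n_comp)) abort("site index out of range")
  site <- events$site %||% rep(1L, nrow(events))
  if (nrow(events) > 0 && any(site < 1 | site > length(site_comp))) {
    abort("event `site` out of range")
  }
  comp <- site_comp[site]
  init <- steady_state_init(model, check = FALSE)
  evm <- as_event_matrix(as_tibble(events), synapses, comp = comp)
  bz <- nmda_boltzmann_default()
  diam <- model$diam_um * taper^(seq_len(n_comp) - 1)
  res <- .hh_cable_sim(model_cpars(model, init), as.integer(n_comp),
                       rep(model$length_um, n_comp), diam,
                       evm, bz, duration_ms, dt_us * 1e-3, 1 / record_khz,
                       model$active, record_all, model$v_rest)
  tr <- new_trace(res$t_ms, res$v_mv, dt_ms = 1 / record_khz,
                  model = model, events = events)
  if (record_all) attr(tr, "v_all") <- res$v_all
  tr
}

#' Coincidence-detection protocol
#'
#' Delivers two excitatory events separated by `isi_ms` onto the model, with
#' either an AMPA-only synapse or the compound AMPA+NMDA synapse (equal
#' quantal weight on both components), and reports the compound EPSP peak,
#' whether it spiked, and the linear sum of the two unitary peaks. With NMDA
#' the compound response can exceed the linear sum (boosting), maximally at
#' coincidence; AMPA alone sums sublinearly.
#'
#' @param model a [compartment_model()].
#' @param isi_ms vector of inter-stimulus intervals (ms, may be negative).
#' @param ampa_only suppress the NMDA component?
#' @param weight_ns quantal conductance per component (nS). The default is
#'   calibrated so that the coincident AMPA-only compound stays
#'   subthreshold in the reference active model while NMDA-gated boosting
#'   can reach spike threshold.
#' @param t0_ms onset of the first event (ms).
#' @param duration_ms simulation length per trial (ms).
#' @return tibble with columns `isi_ms`, `peak_mv` (depolarization from
#'   rest), `spiked`, `linear_sum_mv`, `boost_mv`.
#' @export
simulate_coincidence_protocol <- function(model, isi_ms = 0, ampa_only = FALSE,
                                          weight_ns = 2, t0_ms = 20,
                                          duration_ms = 150) {
  init <- steady_state_init(model, check = FALSE)
  syn <- default_synapses()
  one <- function(onsets) {
    ids <- if (ampa_only) "ampa" else c("ampa", "nmda")
    ev <- event_train(onset_ms = rep(onsets, each = length(ids)),
                      synapse_id = rep(ids, length(onsets)),
                      weight_ns = weight_ns, polarity = "exc")
    simulate_point_neuron(model, ev, duration_ms, synapses = syn, init = init)
  }
  unit <- one(t0_ms)
  unit_peak <- max(unit$v_mV) - model$v_rest
  purrr::map_dfr(isi_ms, function(d) {
    tr <- one(c(t0_ms, t0_ms + abs(d)))
    peak <- max(tr$v_mV) - model$v_rest
    tibble(isi_ms = d, peak_mv = peak,
           spiked = any(tr$v_mV > 0),
           linear_sum_mv = 2 * unit_peak,
           boost_mv = peak - 2 * unit_peak)
  })
}

# --- trace / event IO ------------------------------------------------------

#' Read and write traces and event tables as CSV
#'
#' The columnar trace format has a 1 kHz (or finer) time column `t_ms` and
#' named series `v_mV`, optionally `i_na_nA`, `i_k_nA`. Event tables have
#' columns `onset_ms`, `synapse_id`, `weight_nS`, `polarity`.
#'
#' @param x a `vc_trace` or `vc_events` object.
#' @param path file path.
#' @return `read_*` return the parsed object; `write_*` return `path`
#'   invisibly.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_trace_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  dt <- if (nrow(d) > 1) d$t_ms[2] - d$t_ms[1] else 1
  new_trace(d$t_ms, d$v_mV, d$i_na_nA, d$i_k_nA, dt_ms = dt)
}

#' @rdname trace_io
#' @export
write_events_csv <- function(x, path) {
  d <- data.frame(onset_ms = x$onset_ms, synapse_id = x$synapse_id,
                  weight_nS = x$weight_ns, polarity = x$polarity)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_events_csv <- function(path) {
  d <- read.csv(path, colClasses = c(synapse_id = "character", polarity = "character"))
  event_train(onset_ms = d$onset_ms, synapse_id = d$synapse_id,
              weight_ns = d$weight_nS, polarity = d$polarity)
}
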