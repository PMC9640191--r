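#' Build a recurrent connectivity matrix
#'
#' Samples pairwise connectivity among `n` cells: each unordered pair is
#' reciprocally connected with probability `0.5 * p_uni`, otherwise
#' unidirectionally connected (fair coin for direction) with probability
#' `p_uni`. Reciprocal edges carry a 1.5x weight multiplier; the diagonal
#' is zero. Rows are presynaptic, columns postsynaptic.
#'
#' @param n number of cells.
#' @param p_uni unidirectional connection probability per unordered pair.
#' @param seed RNG seed.
#' @param recip_mult weight multiplier for reciprocal edges.
#' @return list of class `vc_connectivity` with binary `x` (n x n), the
#'   weight `mult` matrix, and the realized pair frequencies.
#' @export
build_connectivity <- function(n, p_uni, seed = NULL, recip_mult = 1.5) {
  if (p_uni < 0 || p_uni > 1) abort("`p_uni` must be in [0, 1]")
  p_bi <- 0.5 * p_uni
  if (p_uni + p_bi > 1) abort("`p_uni` too large: p_uni + 0.5*p_uni must be <= 1")
  x <- matrix(0, n, n)
  mult <- matrix(1, n, n)
  n_uni <- 0L; n_bi <- 0L
  with_seed(seed, {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        u <- runif(1)
        if (u < p_bi) {
          x[i, j] <- x[j, i] <- 1
          mult[i, j] <- mult[j, i] <- recip_mult
          n_bi <- n_bi + 1L
        } else if (u < p_bi + p_uni) {
          if (runif(1) < 0.5) x[i, j] <- 1 else x[j, i] <- 1
          n_uni <- n_uni + 1L
        }
      }
    }
  })
  n_pairs <- n * (n - 1) / 2
  structure(list(x = x, mult = mult, n = n, p_uni = p_uni,
                 realized_uni = n_uni / n_pairs, realized_bi = n_bi / n_pairs),
            class = "vc_connectivity")
}

#' Tsodyks-Markram synapse state and update
#'
#' Depressing-facilitating short-term plasticity with utilization `u`
#' (facilitation, recovery constant `F_ms`) and resources `R` (depression,
#' recovery constant `D_ms`). Between spikes `du/dt = -u/F`,
#' `dR/dt = (1-R)/D`. On a presynaptic spike `u <- u + U (1-u)`, release
#' `= u R`, then `R <- R - u R`. Reference constants `U = 0.38`,
#' `D = 365.6` ms, `F = 25.71` ms.
#'
#' @param u,R current state (scalars, vectors or matrices).
#' @param dt_ms elapsed time since the last update.
#' @param spike logical (recycled): did the presynaptic cell spike now?
#' @param U,D_ms,F_ms model constants.
#' @return list with `u`, `R` (post-update) and `release` (0 where no
#'   spike).
#' @export
tm_update <- function(u, R, dt_ms, spike, U = 0.38, D_ms = 365.6, F_ms = 25.71) {
  u <- u * exp(-dt_ms / F_ms)
  R <- 1 - (1 - R) * exp(-dt_ms / D_ms)
  release <- u * 0
  sp <- rep_len(as.logical(spike), length(u))  # recycles over columns
  if (any(sp)) {
    u_s <- u + U * (1 - u)
    rel <- u_s * R
    release[sp] <- rel[sp]
    R[sp] <- R[sp] - rel[sp]
    u[sp] <- u_s[sp]
  }
  list(u = u, R = R, release = release)
}

#' Closed-form steady state of the TM synapse under periodic drive
#'
#' For a regular presynaptic train with inter-spike interval `isi_ms`, the
#' per-spike release converges to
#' `u* R*` with `u* = U / (1 - (1-U) e^{-isi/F})` and
#' `R* = (1 - e^{-isi/D}) / (1 - (1-u*) e^{-isi/D})`.
#'
#' @param isi_ms inter-spike interval (ms).
#' @inheritParams tm_update
#' @return list with `u`, `R`, `release`.
#' @export
tm_steady_state <- function(isi_ms, U = 0.38, D_ms = 365.6, F_ms = 25.71) {
  eF <- exp(-isi_ms / F_ms)
  eD <- exp(-isi_ms / D_ms)
  u_star <- U / (1 - (1 - U) * eF)
  R_star <- (1 - eD) / (1 - (1 - u_star) * eD)
  list(u = u_star, R = R_star, release = u_star * R_star)
}

#' Network configuration
#'
#' @param n_cells network size.
#' @param p_uni unidirectional recurrent connection probability.
#' @param g_conn_ns recurrent quantal conductance per contact site (nS).
#' @param contacts contact sites per connection.
#' @param delay_ms spike-to-PSP delay (anchored at the presynaptic AP
#'   peak).
#' @param duration_ms simulated time.
#' @param stim_time_ms,stim_g_ns stimulus onset and conductance (delivered
#'   to every cell).
#' @param exc_scale scaling of the recurrent quantal size.
#' @param inh_scale scaling of the background inhibitory quantal size.
#' @param bg_exc_hz,bg_inh_hz background event rates per cell (events/s).
#' @param bg_exc_ns,bg_inh_ns background quantal sizes (nS).
#' @param settle_ms initial span discarded from the instability count.
#' @param stable_max_aps stability criterion: a run is stable when the
#'   pre-stimulus population AP count (after `settle_ms`) is below this.
#' @param tm_u,tm_d_ms,tm_f_ms TM constants.
#' @param seed RNG seed.
#' @return a list of class `vc_net_config`.
#' @export
network_config <- function(n_cells = 150, p_uni = 0.1, g_conn_ns = 0.7,
                           contacts = 5, delay_ms = 1, duration_ms = 250,
                           stim_time_ms = 100, stim_g_ns = 50,
                           exc_scale = 1, inh_scale = 1,
                           bg_exc_hz = 150, bg_inh_hz = 56,
                           bg_exc_ns = 1.5, bg_inh_ns = 6,
                           settle_ms = 10, stable_max_aps = 5,
                           tm_u = 0.38, tm_d_ms = 365.6, tm_f_ms = 25.71,
                           seed = NULL) {
  if (delay_ms < 1) abort("`delay_ms` must be at least one sample (1 ms)")
  if (duration_ms <= stim_time_ms) abort("`duration_ms` must exceed `stim_time_ms`")
  structure(as.list(environment()), class = "vc_net_config")
}

#' Izhikevich reference backend
#'
#' A batched cell backend for the network engine: every cell is one
#' Izhikevich unit; synaptic conductances are converted to current drive
#' through their driving force at the cell's instantaneous potential and a
#' capacitance-like gain.
#'
#' @param params an [izh_params()] (or the `params` of a fit).
#' @param gain drive units per nS*mV of synaptic driving force (default
#'   1/19.6, the mV/ms produced per nS*mV over a 19.6 pF membrane).
#' @param e_exc_mv,e_inh_mv synaptic reversal potentials.
#' @return a backend list with `init` and `step`.
#' @export
izh_backend <- function(params = izh_params(a = 0.02, b = 0.2, c = -65, d = 6),
                        gain = 1 / 19.6, e_exc_mv = 0, e_inh_mv = -90) {
  list(
    kind = "izhikevich",
    init = function(n, seed = NULL) {
      r <- izh_rest(params)
      list(v = rep(r["v"], n), u = rep(r["u"], n))
    },
    step = function(state, exc_ns, inh_ns) {
      v <- state$v; u <- state$u
      I <- gain * (exc_ns * (e_exc_mv - v) + inh_ns * (e_inh_mv - v))
      p <- params
      v2 <- v + p$dt * (0.04 * v^2 + 5 * v + 140 - u + I)
      u2 <- u + p$dt * p$a * (p$b * v - u)
      spiked <- v2 >= 30
      v2[spiked] <- p$c
      u2[spiked] <- u2[spiked] + p$d
      list(state = list(v = v2, u = u2), v = ifelse(spiked, 30, v2),
           spiked = spiked)
    }
  )
}

#' Scripted backend for engine contract tests
#'
#' Replays a fixed voltage matrix and spike schedule, ignoring its input
#' drive. Two engines driven by backends that produce identical per-step
#' outputs must produce identical rasters.
#'
#' @param v_mat steps x n voltage matrix.
#' @param spike_mat steps x n logical matrix.
#' @export
scripted_backend <- function(v_mat, spike_mat) {
  list(
    kind = "scripted",
    init = function(n, seed = NULL) list(t = 0L),
    step = function(state, exc_ns, inh_ns) {
      t <- state$t + 1L
      list(state = list(t = t), v = v_mat[t, ], spiked = spike_mat[t, ])
    }
  )
}

#' Initialize the network state
#'
#' Builds connectivity, per-edge TM states, background drive schedules and
#' the delayed-delivery queue for a run of [step_network()].
#'
#' @param config a [network_config()].
#' @param backend a cell backend (e.g. [izh_backend()]).
#' @param conn optional pre-built [build_connectivity()] result.
#' @return a mutable environment of class `vc_net_state`.
#' @export
network_state <- function(config, backend, conn = NULL) {
  n <- config$n_cells
  steps <- as.integer(config$duration_ms)
  conn <- conn %||% build_connectivity(n, config$p_uni,
                                       seed = derive_seed(config$seed, "conn"))
  # background drive schedules (nS at onset sample), one train per cell
  bg_exc <- matrix(0, steps, n)
  bg_inh <- matrix(0, steps, n)
  bg_total_hz <- config$bg_exc_hz + config$bg_inh_hz
  for (ci in seq_len(n)) {
    if (bg_total_hz <= 0) break
    ev <- random_train(config$duration_ms,
                       round(bg_total_hz * config$duration_ms / 1000),
                       ei_ratio = c(max(config$bg_exc_hz, 1e-9),
                                    max(config$bg_inh_hz, 1e-9)),
                       exc_weight_ns = config$bg_exc_ns,
                       inh_weight_ns = config$bg_inh_ns * config$inh_scale,
                       seed = derive_seed(config$seed, paste0("bg", ci)))
    if (nrow(ev) > 0) {
      idx <- pmin(pmax(floor(ev$onset_ms) + 1L, 1L), steps)
      for (k in seq_len(nrow(ev))) {
        if (ev$polarity[k] == "exc") {
          bg_exc[idx[k], ci] <- bg_exc[idx[k], ci] + ev$weight_ns[k]
        } else {
          bg_inh[idx[k], ci] <- bg_inh[idx[k], ci] + ev$weight_ns[k]
        }
      }
    }
  }
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$backend <- backend
  st$conn <- conn
  st$cells <- backend$init(n, derive_seed(config$seed, "cells"))
  st$tm_u <- matrix(0, n, n)
  st$tm_R <- matrix(1, n, n)
  st$queue <- matrix(0, as.integer(config$delay_ms), n)  # pending exc deliveries
  st$bg_exc <- bg_exc
  st$bg_inh <- bg_inh
  st$t <- 0L
  st$raster <- list()
  st$delivered_total <- 0
  st$expected_total <- 0
  class(st) <- "vc_net_state"
  st
}

#' Advance the network one sample
#'
#' One batched backend step for all cells: background plus pending recurrent
#' excitatory conductances (and the stimulus, when due) are applied, spikes
#' are detected at the AP peak sample, TM release is computed per edge and
#' scheduled for delivery `delay_ms` later into the postsynaptic excitatory
#' channel, weighted by the contact count and the reciprocal multiplier.
#'
#' @param st a `vc_net_state`.
#' @return the state, invisibly (it is modified in place).
#' @export
step_network <- function(st) {
  cfg <- st$config
  t <- st$t + 1L
  exc <- st$bg_exc[t, ] + st$queue[1, ]
  inh <- st$bg_inh[t, ]
  if (floor(cfg$stim_time_ms) + 1L == t) exc <- exc + cfg$stim_g_ns
  res <- st$backend$step(st$cells, exc, inh)
  if (any(!is.finite(res$v))) {
    abort(sprintf("backend produced non-finite output at step %d (cell %d)",
                  t, which(!is.finite(res$v))[1]))
  }
  st$cells <- res$state
  # TM decay for all edges, spike updates for presynaptic rows
  dtm <- tm_update(st$tm_u, st$tm_R, 1, res$spiked,
                   U = cfg$tm_u, D_ms = cfg$tm_d_ms, F_ms = cfg$tm_f_ms)
  st$tm_u <- dtm$u
  st$tm_R <- dtm$R
  # delivery bookkeeping: conductance arriving delay_ms later
  if (nrow(st$queue) > 1) {
    st$queue[seq_len(nrow(st$queue) - 1), ] <- st$queue[2:nrow(st$queue), ]
  }
  st$queue[nrow(st$queue), ] <- 0
  if (any(res$spiked)) {
    M <- st$conn$x * st$conn$mult * dtm$release *
      (cfg$contacts * cfg$g_conn_ns * cfg$exc_scale)
    delivered <- colSums(M[res$spiked, , drop = FALSE])
    st$queue[nrow(st$queue), ] <- st$queue[nrow(st$queue), ] + delivered
    st$delivered_total <- st$delivered_total + sum(delivered)
    st$expected_total <- st$expected_total +
      sum((st$conn$x * st$conn$mult * dtm$release)[res$spiked, , drop = FALSE]) *
      cfg$contacts * cfg$g_conn_ns * cfg$exc_scale
    st$raster[[length(st$raster) + 1]] <- tibble(cell = which(res$spiked),
                                                 t_ms = t - 1)
  }
  st$t <- t
  invisible(st)
}

#' Run a full network simulation
#'
#' @param config a [network_config()].
#' @param backend a cell backend.
#' @param conn optional pre-built connectivity.
#' @return list of class `vc_net_run`: `raster` (tibble cell, t_ms),
#'   `instability` (population AP count between `settle_ms` and the
#'   stimulus), `immediate` (number of distinct cells firing within 10 ms
#'   of stimulus onset), `stable`, `delivery_audit` (delivered vs expected
#'   conductance totals) and the realized connectivity.
#' @export
run_network <- function(config, backend, conn = NULL) {
  st <- network_state(config, backend, conn)
  for (k in seq_len(as.integer(config$duration_ms))) step_network(st)
  raster <- if (length(st$raster)) dplyr::bind_rows(st$raster) else {
    tibble(cell = integer(), t_ms = numeric())
  }
  pre <- raster[raster$t_ms >= config$settle_ms & raster$t_ms < config$stim_time_ms, ]
  imm <- raster[raster$t_ms >= config$stim_time_ms &
                  raster$t_ms < config$stim_time_ms + 10, ]
  structure(list(
    raster = raster,
    instability = nrow(pre),
    immediate = length(unique(imm$cell)),
    stable = nrow(pre) < config$stable_max_aps,
    delivery_audit = c(delivered = st$delivered_total,
                       expected = st$expected_total),
    conn = st$conn, config = config
  ), class = "vc_net_run")
}

#' @export
print.vc_net_run <- function(x, ...) {
  cat(sprintf(
    "<vc_net_run> %d cells, %g ms: %d pre-stimulus APs (%s), immediate response %d cells\n",
    x$config$n_cells, x$config$duration_ms, x$instability,
    if (x$stable) "stable" else "unstable", x$immediate))
  invisible(x)
}

#' Connectivity / excitation parameter sweep
#'
#' Runs the network over a grid of excitatory-drive scales, recurrent
#' connection probabilities and (optionally) inhibitory background scales,
#' with `repeats` seeds per cell, recording instability (pre-stimulus
#' population AP count) and immediate response (cells firing within 10 ms
#' of the stimulus). Excitation scaling multiplies the recurrent quantal
#' size; inhibition scaling multiplies the background inhibitory quantal
#' size.
#'
#' @param exc_scales,p_unis,inh_scales grid axes.
#' @param repeats runs per grid cell.
#' @param backend cell backend.
#' @param config base [network_config()].
#' @param seed global seed; per-run seeds are derived.
#' @return tibble of class `vc_sweep`: one row per run with the grid
#'   coordinates, `instability`, `immediate`, `stable`.
#' @export
run_rett_sweep <- function(exc_scales = c(0.75, 1, 1.25), p_unis = c(0.052, 0.1),
                           inh_scales = 1, repeats = 3,
                           backend = izh_backend(), config = network_config(),
                           seed = NULL) {
  grid <- tidyr::expand_grid(exc_scale = exc_scales, p_uni = p_unis,
                             inh_scale = inh_scales, rep = seq_len(repeats))
  if (nrow(grid) == 0) abort("empty sweep grid")
  out <- purrr::pmap_dfr(grid, function(exc_scale, p_uni, inh_scale, rep) {
    cfg <- config
    cfg$exc_scale <- exc_scale
    cfg$p_uni <- p_uni
    cfg$inh_scale <- inh_scale
    cfg$seed <- derive_seed(seed, paste(exc_scale, p_uni, inh_scale, rep))
    run <- run_network(cfg, backend)
    tibble(exc_scale = exc_scale, p_uni = p_uni, inh_scale = inh_scale,
           rep = rep, instability = run$instability,
           immediate = run$immediate, stable = run$stable)
  })
  class(out) <- c("vc_sweep", class(out))
  out
}
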