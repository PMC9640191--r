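test_that("steady-state initialization rests at v_rest and is a fixed point", {
  # passive model: rest equals v_rest by construction
  ini_p <- steady_state_init(ref_passive())
  expect_equal(ini_p$v, -70)
  expect_lt(ini_p$drift_mv, 0.01)

  # active model: the settled state equals the root of the current balance
  ini_a <- steady_state_init(ref_model())
  expect_lt(ini_a$drift_mv, 0.01)
  expect_equal(ini_a$v, hh_fixed_point(ref_model()), tolerance = 1e-6)
  expect_equal(ini_a$v, -70, tolerance = 1e-6)

  # gNa = gK = 0: rest is the conductance-weighted mean of the two leak
  # reversals (closed form)
  m0 <- compartment_model(gna_s_cm2 = 0, gk_s_cm2 = 0)
  ini0 <- steady_state_init(m0, check = FALSE)
  gpas <- 1 / (m0$rm_kohm_cm2 * 1e3)
  v_weighted <- (gpas * ini0$epas + m0$gl_s_cm2 * m0$el_mv) /
    (gpas + m0$gl_s_cm2)
  expect_equal(ini0$v, v_weighted, tolerance = 1e-9)
})

test_that("event-free simulation holds the resting potential", {
  tr <- simulate_point_neuron(ref_passive(), event_train(), 500)
  expect_true(all(tr$v_mV == -70))
  tr_a <- simulate_point_neuron(ref_model(), event_train(), 1500,
                                init = ref_init())
  expect_lt(max(abs(tr_a$v_mV - ref_init()$v)), 0.01)
})

test_that("event onsets outside the simulation window are rejected", {
  ev <- event_train(onset_ms = 150, synapse_id = "exc", weight_ns = 1,
                    polarity = "exc")
  expect_error(simulate_point_neuron(ref_model(), ev, 100), "within")
})

test_that("EPSP peak matches a fine-dt reference integration within 0.5%", {
  ev <- event_train(onset_ms = 20, synapse_id = "exc", weight_ns = 2.5,
                    polarity = "exc")
  coarse <- simulate_point_neuron(ref_passive(), ev, 80, record_khz = 10)
  fine <- simulate_point_neuron(ref_passive(), ev, 80, dt_us = 1,
                                record_khz = 10)
  pk_c <- max(coarse$v_mV) + 70
  pk_f <- max(fine$v_mV) + 70
  expect_lt(abs(pk_c - pk_f) / pk_f, 0.005)
})

test_that("halving the internal step changes subthreshold peaks by < 1%", {
  ev <- event_train(onset_ms = 20, synapse_id = "exc", weight_ns = 2,
                    polarity = "exc")
  a <- simulate_point_neuron(ref_model(), ev, 80, dt_us = 25, init = ref_init())
  b <- simulate_point_neuron(ref_model(), ev, 80, dt_us = 50, init = ref_init())
  expect_lt(abs((max(a$v_mV) + 70) - (max(b$v_mV) + 70)) / (max(a$v_mV) + 70),
            0.01)
})

test_that("quantal sweep responds linearly below threshold and spikes above", {
  sweep <- quantal_sweep(0.1, 3.5, 0.1)
  expect_length(sweep, 35)
  ini <- ref_init()
  traces <- lapply(sweep, function(ev) {
    simulate_point_neuron(ref_model(), ev, 80, init = ini)
  })
  ivs <- iv_summary(traces, as.numeric(names(sweep)), v_rest = -70)
  expect_equal(ivs$n_sub, 35)           # standard range stays subthreshold
  expect_gt(ivs$r, 0.99)
  # extending the sweep reveals the spike threshold
  ext <- quantal_sweep(3.6, 6, 0.1)
  traces_e <- c(traces, lapply(ext, function(ev) {
    simulate_point_neuron(ref_model(), ev, 80, init = ini)
  }))
  g_e <- c(as.numeric(names(sweep)), as.numeric(names(ext)))
  ivs_e <- iv_summary(traces_e, g_e, v_rest = -70)
  expect_false(is.na(ivs_e$threshold_mv))
  expect_gt(ivs_e$first_suprathreshold_ns, 3.5)
})

test_that("NMDA gate obeys its limits, midpoint and near-step steepness", {
  bz <- nmda_boltzmann_default()
  expect_equal(nmda_gate(-120, bz), bz$A2, tolerance = 1e-12)
  expect_equal(nmda_gate(0, bz), bz$A1, tolerance = 1e-12)
  expect_equal(nmda_gate(bz$x0, bz), (bz$A1 + bz$A2) / 2)
  # dx = 0.013 mV: the gate switches within a tenth of a millivolt
  expect_lt(nmda_gate(bz$x0 - 0.1, bz), -0.99)
  expect_gt(nmda_gate(bz$x0 + 0.1, bz), 0.99)
  expect_error(nmda_gate(-70, list(A1 = 1, A2 = -1, x0 = -63, dx = 0)), "dx")
})

test_that("coincidence detection: AMPA sums sublinearly, NMDA boosts at zero ISI", {
  isis <- c(0, 2, 4, 8, 16)
  # passive summation bound: without voltage-gated currents the compound
  # EPSP can never exceed the linear sum of the unitary responses
  ampa_p <- simulate_coincidence_protocol(ref_passive(), isis, ampa_only = TRUE)
  expect_true(all(ampa_p$peak_mv <= ampa_p$linear_sum_mv + 0.05))
  expect_false(any(ampa_p$spiked))
  # on the active model, NMDA gating boosts the coincident response beyond
  # the AMPA-only compound and reaches threshold
  ampa <- simulate_coincidence_protocol(ref_model(), isis, ampa_only = TRUE)
  nmda <- simulate_coincidence_protocol(ref_model(), isis, ampa_only = FALSE)
  expect_false(ampa$spiked[1])
  expect_true(nmda$spiked[1])
  expect_gt(nmda$peak_mv[1], ampa$peak_mv[1])
  expect_equal(which.max(nmda$peak_mv), 1L)  # maximal boosting at ISI 0
})

test_that("NMDA spiking is confined to a contiguous ISI window around zero", {
  isis <- seq(-8, 8, by = 2)
  res <- simulate_coincidence_protocol(ref_model(), isis)
  spiked <- which(res$spiked)
  expect_gt(length(spiked), 0)
  expect_equal(spiked, seq(min(spiked), max(spiked)))      # contiguous
  expect_true(which(isis == 0) %in% spiked)                # centred on 0
  expect_false(res$spiked[1] || res$spiked[length(isis)])  # closed window
})

test_that("degenerate cable reproduces the point neuron exactly", {
  ev <- event_train(onset_ms = 20, synapse_id = "exc", weight_ns = 2.5,
                    polarity = "exc")
  tp <- simulate_point_neuron(ref_model(), ev, 100)
  ev$site <- 1L
  tc <- simulate_cable_neuron(ref_model(), ev, site_comp = 1L, n_comp = 1,
                              duration_ms = 100)
  expect_equal(tc$v_mV, tp$v_mV, tolerance = 1e-10)
})

test_that("distal inputs arrive at the soma smaller and slower", {
  m <- compartment_model(active = FALSE, ri_ohm_cm = 200)
  ev <- event_train(onset_ms = 10, synapse_id = "exc", weight_ns = 2.5,
                    polarity = "exc")
  ev$site <- 1L
  prox <- simulate_cable_neuron(m, ev, site_comp = 2L, n_comp = 20,
                                duration_ms = 60, taper = 0.85,
                                record_khz = 10)
  dist <- simulate_cable_neuron(m, ev, site_comp = 19L, n_comp = 20,
                                duration_ms = 60, taper = 0.85,
                                record_khz = 10)
  expect_gt(max(prox$v_mV), max(dist$v_mV))
  expect_lt(prox$t_ms[which.max(prox$v_mV)], dist$t_ms[which.max(dist$v_mV)])
})

test_that("cable discretization is converged within 1% against a refined chain", {
  m <- compartment_model(active = FALSE, ri_ohm_cm = 200)
  ev <- event_train(onset_ms = 10, synapse_id = "exc", weight_ns = 2.5,
                    polarity = "exc")
  ev$site <- 1L
  coarse <- simulate_cable_neuron(m, ev, site_comp = 6L, n_comp = 10,
                                  duration_ms = 60, record_khz = 10)
  # refined chain: every compartment split in two (same site position)
  m2 <- compartment_model(active = FALSE, ri_ohm_cm = 200)
  m2$length_um <- m$length_um / 2
  fine <- simulate_cable_neuron(m2, ev, site_comp = 11L, n_comp = 20,
                                duration_ms = 60, record_khz = 10)
  pk_c <- max(coarse$v_mV) + 70
  pk_f <- max(fine$v_mV) + 70
  expect_lt(abs(pk_c - pk_f) / pk_f, 0.01)
})

test_that("KDR shifts change responses only above the activation range", {
  # subthreshold stream (no APs), so traces stay point-wise comparable
  ev <- random_train(400, 40, exc_weight_ns = 1, seed = 7)
  ctl <- simulate_point_neuron(ref_model(), ev, 400, init = ref_init())
  expect_equal(nrow(detect_spikes(ctl)), 0)
  up <- compartment_model(kdr_shift_mv = 10)
  dn <- compartment_model(kdr_shift_mv = -10)
  tr_up <- simulate_point_neuron(up, ev, 400)
  tr_dn <- simulate_point_neuron(dn, ev, 400)
  hot <- ctl$v_mV > -67
  # rightward shift -> less K current -> depolarized relative to control;
  # leftward shift -> hyperpolarized (sign-of-difference only)
  expect_gt(mean(tr_up$v_mV[hot] - ctl$v_mV[hot]), 0)
  expect_lt(mean(tr_dn$v_mV[hot] - ctl$v_mV[hot]), 0)
  # below the activation range the shift has no measurable effect
  cold <- ctl$v_mV < -69.5
  expect_lt(max(abs(tr_up$v_mV[cold] - ctl$v_mV[cold])), 0.5)
})

test_that("traces and events round-trip through CSV", {
  ev <- random_train(500, 20, seed = 3)
  tr <- simulate_point_neuron(ref_passive(), ev, 500, record_currents = TRUE)
  fe <- tempfile(fileext = ".csv")
  ft <- tempfile(fileext = ".csv")
  write_events_csv(ev, fe)
  write_trace_csv(tr, ft)
  ev2 <- read_events_csv(fe)
  tr2 <- read_trace_csv(ft)
  expect_equal(as.data.frame(ev2), as.data.frame(ev))
  expect_equal(tr2$v_mV, tr$v_mV)
  expect_equal(tr2$i_na_nA, tr$i_na_nA)
})
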