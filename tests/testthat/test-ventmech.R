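test_that("cannula correction inverts the generator's cannula drop exactly", {
  p <- wt_params(E2 = 5, R2 = 1.5)
  with_cann <- simulate_ventilation(p, short_maneuver(cannula_k1 = 0.4,
                                                      cannula_k2 = 0.1))
  no_cann <- simulate_ventilation(p, short_maneuver(cannula_k1 = 0,
                                                    cannula_k2 = 0))
  corr <- correct_cannula(with_cann)
  expect_equal(corr$ptr, no_cann$ptr, tolerance = 1e-14)
  # zero flow leaves pressure untouched; linear case subtracts k1 * flow
  rec <- vent_recording(0:9 / 10, rep(0, 10), rep(3, 10),
                        list(VT = 0.3, PEEP = 0, fs = 10,
                             cannula_k1 = 1, cannula_k2 = 0.5))
  expect_equal(correct_cannula(rec)$ptr, rec$ptr)
  rec2 <- vent_recording(0:9 / 10, rep(2, 10), rep(3, 10),
                         list(VT = 0.3, PEEP = 0, fs = 10,
                              cannula_k1 = 1, cannula_k2 = 0))
  expect_equal(correct_cannula(rec2)$ptr, rep(1, 10))
  rec3 <- vent_recording(0:9 / 10, rep(2, 10), rep(3, 10),
                         list(VT = 0.3, PEEP = 0, fs = 10))
  expect_error(correct_cannula(rec3), class = "pulmomech_config_error")
})

test_that("flow integration is trapezoidal with drift re-zeroing at inspiration onsets", {
  meta <- list(VT = 0.3, PEEP = 0, fs = 100)
  t <- seq(0, 0.3, by = 0.01)
  rec <- vent_recording(t, rep(1, length(t)), rep(0, length(t)), meta)
  v <- integrate_flow(rec)
  expect_equal(v[length(v)], 0.3, tolerance = 1e-12)
  # sine over integer periods returns to zero within quadrature error
  t2 <- seq(0, 2, by = 0.01)
  rec2 <- vent_recording(t2, sin(2 * pi * t2), rep(0, length(t2)), meta)
  v2 <- integrate_flow(rec2)
  expect_lt(abs(v2[201]), 5e-4)
  # synthetic recording recovers the set tidal volume per breath
  rec3 <- simulate_ventilation(wt_params(), short_maneuver(VT = 0.30))
  v3 <- integrate_flow(rec3)
  o <- attr(rec3, "occlusion_onsets")[1]
  expect_equal(v3[o], 0.30, tolerance = 0.03)
})

test_that("occlusion windows are found at the generator's onset samples", {
  rec <- correct_cannula(simulate_ventilation(wt_params(E2 = 5, R2 = 1.5),
                                              short_maneuver()))
  occ <- detect_occlusions(rec)
  truth <- attr(rec, "occlusion_onsets")
  expect_identical(nrow(occ), 2L)
  expect_true(all(abs(occ$onset - truth) <= 2))
  expect_true(all(occ$end_inspiratory))
  # continuous ventilation (trace truncated before the first occlusion)
  k <- truth[1] - 30L
  cont <- vent_recording(rec$t[1:k], rec$flow[1:k], rec$ptr[1:k], rec$meta)
  expect_identical(nrow(detect_occlusions(cont)), 0L)
  # an all-zero flow trace is one long window not preceded by inspiration
  flat <- vent_recording(rec$t, rep(0, length(rec$t)), rec$ptr, rec$meta)
  w <- detect_occlusions(flat)
  expect_identical(nrow(w), 1L)
  expect_false(w$end_inspiratory)
})

test_that("a lung without viscoelasticity shows no slow pressure drop and Edyn equals Est", {
  el <- compute_elastances(simulate_ventilation(wt_params(E2 = 0, R2 = 0),
                                                short_maneuver()))
  for (m in el$per_occlusion) expect_lt(abs(m$dP2), 1e-6)
  expect_equal(el$Edyn_mean, el$Est_mean, tolerance = 1e-6)
})

test_that("static elastance is recovered to better than 0.5% across the physiological range", {
  for (Est in c(10, 22.4, 50, 80)) for (VT in c(0.30, 0.15)) {
    el <- compute_elastances(simulate_ventilation(
      lung_model_params(Est = Est, Raw = 0.5, E2 = 4, R2 = 1.2),
      short_maneuver(VT = VT)))
    expect_lt(abs(el$Est_mean - Est) / Est, 0.005)
  }
})

test_that("viscoelastic parameters calibrated for a 1.15 dynamic-to-static ratio are recovered by the analysis", {
  p <- calibrate_viscoelastance(wt_params(), short_maneuver(),
                                ratio = 1.15, tau = 0.3)
  el <- compute_elastances(simulate_ventilation(p, short_maneuver()))
  expect_equal(el$ratio_dyn_st, 1.15, tolerance = 0.02)
  expect_gt(el$Edyn_mean, el$Est_mean)
})

test_that("fast and slow drops partition the total occlusion pressure fall exactly", {
  rec <- correct_cannula(simulate_ventilation(
    wt_params(E2 = 5, R2 = 1.5, noise_sd = 0.02, seed = 3L),
    short_maneuver()))
  occ <- detect_occlusions(rec)
  for (i in seq_len(nrow(occ))) {
    m <- measure_occlusion(rec, occ[i, ])
    expect_equal(m$dP1 + m$dP2, m$P_pre - m$Pel, tolerance = 1e-12)
    expect_gte(m$Edyn, m$Est)
  }
  expect_error(measure_occlusion(rec, list(onset = occ$onset[1],
                                           end = occ$onset[1] + 100L)),
               class = "pulmomech_analysis_error")
})

test_that("static elastance is invariant to the cannula coefficients used in generation", {
  p <- wt_params(E2 = 5, R2 = 1.5)
  e1 <- compute_elastances(simulate_ventilation(
    p, short_maneuver(cannula_k1 = 0, cannula_k2 = 0)))
  e2 <- compute_elastances(simulate_ventilation(
    p, short_maneuver(cannula_k1 = 0.8, cannula_k2 = 0.3)))
  expect_equal(e1$Est_mean, e2$Est_mean, tolerance = 1e-10)
  expect_equal(e1$Edyn_mean, e2$Edyn_mean, tolerance = 1e-10)
})

test_that("per-recording elastances average the two occlusions and propagate errors", {
  el <- compute_elastances(simulate_ventilation(wt_params(E2 = 5, R2 = 1.5),
                                                short_maneuver()))
  expect_identical(el$n_occlusions, 2L)
  per <- vapply(el$per_occlusion, `[[`, 0, "Est")
  expect_equal(el$Est_mean, mean(per))
  rec <- simulate_ventilation(wt_params(), short_maneuver())
  k <- attr(rec, "occlusion_onsets")[1] - 30L
  cont <- vent_recording(rec$t[1:k], rec$flow[1:k], rec$ptr[1:k], rec$meta)
  expect_error(compute_elastances(cont), class = "pulmomech_analysis_error")
})

test_that("cohort-level estimates recover the group mean within sampling error", {
  gm <- list(WT = wt_params(noise_sd = 0.02))
  coh <- generate_cohort(cohort_spec(7L, gm, between_animal_cv = 0.05,
                                     maneuver = short_maneuver(), seed = 11L))
  est <- vapply(coh$recordings, function(r) compute_elastances(r)$Est_mean, 0)
  expect_equal(est, coh$truth$Est_true, tolerance = 0.005)
  se <- sd(coh$truth$Est_true) / sqrt(7)
  expect_lt(abs(mean(est) - 22.4), 2 * se + 0.05)
})

test_that("chest-wall elastance is the total-minus-lung difference", {
  total <- compute_elastances(simulate_ventilation(
    lung_model_params(Est = 30, Raw = 0.5), short_maneuver()))
  lung_rec <- simulate_ventilation(lung_model_params(Est = 22.4, Raw = 0.5),
                                   short_maneuver())
  lung_rec$meta$compartment_label <- "lung"
  lung <- compute_elastances(lung_rec)
  cw <- chest_wall_elastance(total, lung)
  expect_equal(cw$Est_mean, 7.6, tolerance = 1e-6)
  expect_identical(cw$compartment_label, "chest_wall")
  expect_error(chest_wall_elastance(total, total),
               class = "pulmomech_config_error")
})
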