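test_that("occluded pressure is flat at the elastic recoil plateau when the Maxwell body is absent", {
  rec <- simulate_ventilation(wt_params(R2 = 0, E2 = 0), short_maneuver())
  rec <- correct_cannula(rec)
  onsets <- attr(rec, "occlusion_onsets")
  for (o in onsets) {
    occ <- rec$ptr[o:(o + 499L)]
    expect_equal(occ, rep(22.4 * 0.30, 500), tolerance = 1e-12)
  }
})

test_that("plateau pressure equals Est * VT in closed form", {
  rec <- simulate_ventilation(
    lung_model_params(Est = 22.4, Raw = 0.3, PEEP = 0),
    short_maneuver(VT = 0.30))
  rec <- correct_cannula(rec)
  o <- attr(rec, "occlusion_onsets")[1]
  expect_equal(rec$ptr[o + 499L], 6.72, tolerance = 1e-9)
})

test_that("ventilation generator is reproducible from its seed and validates its spec", {
  p <- wt_params(noise_sd = 0.05, seed = 42L)
  r1 <- simulate_ventilation(p, short_maneuver())
  r2 <- simulate_ventilation(p, short_maneuver())
  expect_identical(r1$ptr, r2$ptr)
  expect_identical(r1$flow, r2$flow)
  r3 <- simulate_ventilation(wt_params(noise_sd = 0.05, seed = 43L),
                             short_maneuver())
  expect_false(identical(r1$ptr, r3$ptr))
  expect_error(maneuver_spec(VT = 0), class = "pulmomech_invalid_spec")
  expect_error(maneuver_spec(fs = -1), class = "pulmomech_invalid_spec")
  expect_error(lung_model_params(Est = 0), class = "pulmomech_invalid_spec")
})

test_that("flow is exactly zero throughout each occlusion window", {
  rec <- simulate_ventilation(wt_params(E2 = 5, R2 = 1.5), short_maneuver())
  for (o in attr(rec, "occlusion_onsets"))
    expect_true(all(rec$flow[o:(o + 499L)] == 0))
})

test_that("noiseless approach curves satisfy the pyramidal contact relation exactly", {
  fc <- simulate_force_curve(10e3, z0 = 200, d0 = 5, k = 0.03,
                             theta = 20, nu = 0.5)
  a <- 3 * 10e3 * tan(20 * pi / 180) / (4 * (1 - 0.25)) / 0.03
  delta <- (fc$z - 200) - (fc$d - 5)
  post <- delta > 0
  lhs <- fc$d[post] - 5
  rhs <- a * (delta[post] * 1e-9)^2 * 1e9
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # contact force at 500 nm indentation: F = 3 E tan(theta)/(4(1-nu^2)) d^2
  fc500 <- simulate_force_curve(10e3, max_indentation = 500)
  F_nN <- fc500$k * (fc500$d[length(fc500$d)] - 0)
  expect_equal(F_nN, 0.90992, tolerance = 1e-4)
})

test_that("a curve entirely before contact stays at the free deflection", {
  fc <- simulate_force_curve(10e3, z0 = 1e6, d0 = 3, pre_contact = 500,
                             max_indentation = 1e-6)
  expect_true(all(abs(fc$d[fc$z < 1e6] - 3) < 1e-9))
  expect_error(simulate_force_curve(-5), class = "pulmomech_invalid_spec")
})

test_that("multifrequency generator validates duration and flags mixing frequencies", {
  expect_error(simulate_multifreq(9.4, 0.016, 0.084, duration = 1),
               class = "pulmomech_invalid_spec")
  expect_warning(simulate_multifreq(9.4, 0.016, 0.084, freqs = c(1, 2, 3),
                                    duration = 10),
                 "sum/difference")
  expect_error(multifreq_record(1:3, 1:3, 1:3, freqs = numeric(0)),
               class = "pulmomech_invalid_spec")
})

test_that("purely elastic model parameters give a lossless record", {
  rec <- simulate_multifreq(A = 8, B = 0, alpha = 0, b_h = 0, duration = 30)
  gs <- compute_gstar(rec)
  expect_true(all(abs(gs$G_loss) < 1e-6 * abs(gs$G_storage)))
  expect_equal(gs$G_storage, rep(8e3, 4), tolerance = 1e-9)
})

test_that("alveolar image generator honors its closed-form mean linear intercept and validates the spec", {
  expect_error(alveolar_image_spec(cell_pitch = 2, wall_thickness = 2),
               class = "pulmomech_invalid_spec")
  spec <- alveolar_image_spec(cell_pitch = 40, wall_thickness = 2)
  expect_equal(theoretical_lm(spec), 38)
  img1 <- generate_alveolar_image(spec)
  img2 <- generate_alveolar_image(spec)
  expect_identical(img1$pixels, img2$pixels)
  # brute-force chord counting on the rendered wall mask: interior airspace
  # runs along a scanline have mean length pitch - wall
  wall <- attr(img1, "truth")$wall_mask
  row <- wall[500, ]
  r <- rle(row)
  chords <- r$lengths[!r$values]
  chords <- chords[-c(1, length(chords))]  # drop border-truncated chords
  expect_equal(mean(chords), 38, tolerance = 1 / 38)
})

test_that("requested vessels appear as distinct disc components", {
  img <- generate_alveolar_image(alveolar_image_spec(
    vessel_count = 3L, vessel_diameter = 80, seed = 7L))
  tissue <- img$pixels < 0.5
  v <- detect_vessels(tissue, img$px_size, area_threshold = 3000,
                      opening_um = 5)
  expect_identical(v$n, 3L)
})

test_that("cohort generation is seed-reproducible and collapses at zero CV", {
  gm <- list(WT = wt_params(), MFS = lung_model_params(Est = 14.1))
  cs0 <- cohort_spec(3L, gm, between_animal_cv = 0,
                     maneuver = short_maneuver(), seed = 5L)
  coh0 <- generate_cohort(cs0)
  expect_equal(coh0$truth$Est_true[1:3], rep(22.4, 3))
  cs <- cohort_spec(3L, gm, between_animal_cv = 0.05,
                    maneuver = short_maneuver(), seed = 5L)
  expect_identical(generate_cohort(cs)$truth, generate_cohort(cs)$truth)
  expect_error(cohort_spec(0L, gm), class = "pulmomech_invalid_spec")
})
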