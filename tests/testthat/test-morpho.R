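test_that("binarization is polarity-aware and matches a plain threshold on clean lattices", {
  img <- generate_alveolar_image(alveolar_image_spec(
    width_px = 300L, height_px = 300L))
  pre <- preprocess_image(img)
  truth <- attr(img, "truth")$wall_mask
  expect_identical(pre$tissue, truth)
  # inverted contrast with the polarity flag gives the identical mask
  inv <- histology_image(1 - img$pixels, img$px_size)
  pre_inv <- preprocess_image(inv, morpho_config(polarity = "light"))
  expect_identical(pre_inv$tissue, truth)
  blank <- histology_image(matrix(0.5, 50, 50), 1)
  expect_error(preprocess_image(blank), class = "pulmomech_analysis_error")
})

test_that("vessel discs are removed while the septal lattice is preserved", {
  img <- generate_alveolar_image(alveolar_image_spec(
    vessel_count = 3L, vessel_diameter = 90, seed = 7L))
  pre <- preprocess_image(img)
  expect_identical(pre$n_vessels, 3L)
  truth <- attr(img, "truth")
  vessel_core <- truth$vessel_mask & !truth$wall_mask
  expect_lt(sum(pre$tissue & vessel_core) / sum(vessel_core), 0.05)
  walls_clear <- truth$wall_mask & !(EBImage::dilate(
    truth$vessel_mask * 1, EBImage::makeBrush(21, "disc")) > 0)
  expect_gt(sum(pre$tissue & walls_clear) / sum(walls_clear), 0.99)
})

test_that("skeletonization thins walls to single-pixel lines and preserves topology", {
  m <- matrix(FALSE, 40, 40)
  m[, 20:21] <- TRUE                    # 2-px-thick straight wall
  sk <- skeletonize_walls(m)
  expect_true(all(rowSums(sk) <= 1))
  expect_gt(sum(sk), 30)
  expect_identical(sum(skeletonize_walls(matrix(FALSE, 10, 10))), 0L)
  # enclosed faces of the lattice survive thinning (Euler characteristic)
  img <- generate_alveolar_image(alveolar_image_spec(
    width_px = 200L, height_px = 200L))
  wall <- attr(img, "truth")$wall_mask
  sk2 <- skeletonize_walls(wall)
  expect_identical(count_enclosed_faces(sk2), count_enclosed_faces(wall))
})

test_that("probe grid geometry follows the margins and image shape", {
  g0 <- build_grid(c(1000, 1000), 1, morpho_config(margin_frac = 0))
  expect_equal(g0$total_length_um, 11 * 1000 + 9 * 1000)
  g2 <- build_grid(c(1000, 1000), 1, morpho_config(margin_frac = 0.02))
  expect_equal(unique(g2$vertical$length_um), 960)
  expect_equal(unique(g2$horizontal$length_um), 960)
  # non-square image: vertical probes span the height, horizontal the width
  g3 <- build_grid(c(400, 800), 1, morpho_config(margin_frac = 0.02))
  expect_equal(unique(g3$vertical$length_um), 400 * 0.96)
  expect_equal(unique(g3$horizontal$length_um), 800 * 0.96)
  expect_identical(nrow(g3$vertical), 11L)
  expect_identical(nrow(g3$horizontal), 9L)
  expect_error(build_grid(c(8, 8), 1), class = "pulmomech_config_error")
})

test_that("intercepts are counted as connected runs and match the brute-force oracle", {
  # ten 1-px vertical walls crossed by horizontal probes
  m <- matrix(FALSE, 100, 100)
  m[, seq(5, 95, by = 10)] <- TRUE
  g <- build_grid(c(100, 100), 1, morpho_config(margin_frac = 0))
  cnt <- count_intercepts(m, g)
  expect_identical(attr(cnt, "per_line")[12:20], rep(10L, 9))
  expect_identical(as.integer(count_intercepts(matrix(FALSE, 100, 100), g)), 0L)
  # full pipeline count equals per-pixel run enumeration on a lattice
  img <- generate_alveolar_image(alveolar_image_spec(
    width_px = 500L, height_px = 500L, noise_sd = 0.02, seed = 3L))
  pre <- preprocess_image(img)
  sk <- skeletonize_walls(pre$tissue)
  g2 <- build_grid(dim(sk), 1, morpho_config())
  expect_identical(as.integer(count_intercepts(sk, g2)),
                   oracle_count_intercepts(sk, g2))
})

test_that("the lattice fixture yields its closed-form mean linear intercept", {
  img <- generate_alveolar_image(alveolar_image_spec())
  r <- compute_lm(img)
  expect_equal(r$Lm, 38, tolerance = 1 / 38)     # within one pixel
  expect_equal(r$Lm, r$total_probe_length / r$n_intervals)
})

test_that("Lm is invariant to rotation, gray rescaling and pixel-size rescaling", {
  spec <- alveolar_image_spec(width_px = 600L, height_px = 600L,
                              noise_sd = 0.02, seed = 5L)
  img <- generate_alveolar_image(spec)
  r <- compute_lm(img)
  rot <- histology_image(t(img$pixels)[ncol(img$pixels):1, ], img$px_size)
  expect_equal(compute_lm(rot)$Lm, r$Lm, tolerance = 0.02)
  resc <- histology_image(0.5 * img$pixels + 0.2, img$px_size)
  expect_equal(compute_lm(resc)$Lm, r$Lm, tolerance = 1e-9)
  spec2 <- alveolar_image_spec(width_px = 1200L, height_px = 1200L,
                               px_size = 0.5, noise_sd = 0.02, seed = 5L)
  r2 <- compute_lm(generate_alveolar_image(spec2))
  expect_equal(r2$Lm, r$Lm, tolerance = 0.03)
})

test_that("two lattices with pitch ratio 1.65 yield the same Lm ratio", {
  r1 <- compute_lm(generate_alveolar_image(alveolar_image_spec(
    width_px = 800L, height_px = 800L, cell_pitch = 40)))
  r2 <- compute_lm(generate_alveolar_image(alveolar_image_spec(
    width_px = 800L, height_px = 800L, cell_pitch = 66)))
  expect_equal(r2$Lm / r1$Lm, 64 / 38, tolerance = 0.03)
})

test_that("removing tissue-filled vessels can only increase the measured airspace", {
  img <- generate_alveolar_image(alveolar_image_spec(
    width_px = 600L, height_px = 600L, vessel_count = 2L,
    vessel_diameter = 90, seed = 13L))
  with_removal <- compute_lm(img)
  keep_vessels <- compute_lm(img, morpho_config(vessel_area_threshold = Inf))
  expect_gte(with_removal$Lm, keep_vessels$Lm - 1e-9)
})

test_that("degenerate images are handled: near-solid tissue and zero intercepts", {
  # walls so thick the airspace shrinks to a few pixels per alveolus
  solid <- generate_alveolar_image(alveolar_image_spec(
    width_px = 200L, height_px = 200L, cell_pitch = 40,
    wall_thickness = 36))
  r <- suppressWarnings(compute_lm(solid, morpho_config(
    vessel_area_threshold = Inf, speck_area = 0)))
  expect_lt(r$Lm, 6)
  # a lone tissue block dodging every probe line leaves Lm undefined
  px <- matrix(0.9, 200, 200)
  px[8:18, 8:18] <- 0.1
  img <- histology_image(px, 1)
  expect_error(compute_lm(img, morpho_config(vessel_area_threshold = Inf)),
               class = "pulmomech_analysis_error")
})
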