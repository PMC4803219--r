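## Study orchestration: run every modality from one configuration and
## summarize with the study's comparison plan.

#' Default study configuration
#'
#' Describes a two-group (wild-type-like vs Marfan-like) synthetic study
#' across the three modalities. Group-level inputs:
#' \itemize{
#'   \item elastance: group-mean lung model parameters and a shared
#'     maneuver; per-animal parameters vary lognormally.
#'   \item matrix viscoelasticity: group-true two power-law parameters;
#'     one multifrequency record per animal (with force noise), analyzed
#'     to G* and fitted.
#'   \item matrix stiffness: group-true Young's moduli per region; a
#'     3-site x 5-point x 5-curve design per animal-region, each curve
#'     fitted by the pyramidal Hertz model.
#'   \item morphometry: group-true alveolar pitch; one lattice image per
#'     animal with per-animal pitch variation.
#' }
#'
#' @param n_per_group animals per group
#' @param groups named list of group parameter lists (see the default for
#'   the expected fields)
#' @param maneuver a [maneuver_spec()]
#' @param between_animal_cv lognormal between-animal CV applied to Est and
#'   to alveolar pitch
#' @param seed master seed; all stage seeds derive from it
#' @return a list of class `study_config`
#' @export
study_config <- function(
    n_per_group = 6L,
    groups = list(
      WT = list(params = lung_model_params(Est = 22.4, Raw = 0.5,
                                           E2 = 5.3, R2 = 1.59,
                                           noise_sd = 0.02),
                powerlaw = c(A = 9.40, B = 0.016, alpha = 0.084),
                E_regions = c(pleura = 15e3, alveolar_septum = 10e3,
                              vessel_adventitia = 12e3, vessel_media = 25e3),
                pitch = 43.2),
      MFS = list(params = lung_model_params(Est = 22.4 * 0.63, Raw = 0.5,
                                            E2 = 5.3 * 0.63, R2 = 1.59 * 0.63,
                                            noise_sd = 0.02),
                 powerlaw = c(A = 10.34, B = 0.036, alpha = 0.089),
                 E_regions = c(pleura = 15e3, alveolar_septum = 10e3,
                               vessel_adventitia = 12e3, vessel_media = 25e3),
                 pitch = 43.2 * 1.65)),
    maneuver = maneuver_spec(n_breaths_before_occlusion = 5L),
    between_animal_cv = 0.05,
    seed = 1L) {
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 maneuver = maneuver, between_animal_cv = between_animal_cv,
                 seed = as.integer(seed)),
            class = "study_config")
}

mean_se <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), se = sd(x) / sqrt(length(x)), n = length(x))
}

#' Run the full synthetic study
#'
#' Executes the elastance, matrix-mechanics and morphometry pipelines for
#' each group of the configuration, then applies the study's comparison
#' plan: WT vs MFS two-group tests on Est/Edyn and Lm, a region x group
#' ANOVA on the Young's modulus, and Holm-Sidak adjustment of the post hoc
#' group comparisons. Per-sample rows and group summaries are written as
#' CSV when `out_dir` is given; seeds and the configuration echo make the
#' report reproducible.
#'
#' @param config a [study_config()]
#' @param out_dir optional output directory for CSV/JSON artifacts
#' @param modalities character subset of
#'   `c("elastance", "viscoelastic", "stiffness", "morphometry")`
#' @return an object of class `study_report`
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      modalities = c("elastance", "viscoelastic",
                                     "stiffness", "morphometry")) {
  stopifnot(inherits(config, "study_config"))
  groups <- names(config$groups)
  rows <- list()
  report <- list(groups = groups, seed = config$seed,
                 n_per_group = config$n_per_group)
  errors <- character(0)

  if ("elastance" %in% modalities) {
    res <- tryCatch({
      cs <- cohort_spec(config$n_per_group,
                        lapply(config$groups, `[[`, "params"),
                        between_animal_cv = config$between_animal_cv,
                        maneuver = config$maneuver, seed = config$seed)
      coh <- generate_cohort(cs)
      est <- vapply(coh$recordings,
                    function(r) compute_elastances(r)$Est_mean, 0)
      edyn <- vapply(coh$recordings,
                     function(r) compute_elastances(r)$Edyn_mean, 0)
      tab <- cbind(coh$truth, Est_hat = est, Edyn_hat = edyn)
      g1 <- tab$group == groups[1]
      list(per_animal = tab,
           summary = list(
             Est = lapply(split(tab$Est_hat, tab$group), mean_se),
             Edyn = lapply(split(tab$Edyn_hat, tab$group), mean_se)),
           test_Est = compare_two_groups(tab$Est_hat[g1], tab$Est_hat[!g1]),
           test_Edyn = compare_two_groups(tab$Edyn_hat[g1], tab$Edyn_hat[!g1]),
           percent_diff_Est = 100 * (mean(tab$Est_hat[g1]) -
                                       mean(tab$Est_hat[!g1])) /
             mean(tab$Est_hat[g1]))
    }, error = function(e) {errors <<- c(errors, conditionMessage(e)); NULL})
    report$elastance <- res
  }

  if ("viscoelastic" %in% modalities) {
    res <- tryCatch({
      per <- list()
      for (g in groups) {
        pl <- config$groups[[g]]$powerlaw
        for (a in seq_len(config$n_per_group)) {
          rec <- simulate_multifreq(pl["A"], pl["B"], pl["alpha"],
                                    b_h = 2e-5, noise_sd = 0.02,
                                    seed = config$seed * 100L +
                                      match(g, groups) * 20L + a)
          fit <- fit_powerlaw(compute_gstar(rec))
          per[[length(per) + 1L]] <- data.frame(
            group = g, animal = a, A = fit$A, B = fit$B, alpha = fit$alpha)
        }
      }
      tab <- do.call(rbind, per)
      g1 <- tab$group == groups[1]
      raw_p <- c(A = compare_two_groups(tab$A[g1], tab$A[!g1])$p,
                 B = compare_two_groups(tab$B[g1], tab$B[!g1])$p,
                 alpha = compare_two_groups(tab$alpha[g1], tab$alpha[!g1])$p)
      list(per_animal = tab,
           summary = lapply(c(A = "A", B = "B", alpha = "alpha"),
                            function(v) lapply(split(tab[[v]], tab$group),
                                               mean_se)),
           posthoc = holm_sidak(raw_p))
    }, error = function(e) {errors <<- c(errors, conditionMessage(e)); NULL})
    report$viscoelastic <- res
  }

  if ("stiffness" %in% modalities) {
    res <- tryCatch({
      per <- list()
      cnt <- 0L
      for (g in groups) {
        regs <- config$groups[[g]]$E_regions
        for (a in seq_len(config$n_per_group)) {
          for (r in names(regs)) {
            cnt <- cnt + 1L
            fits <- simulate_hertz_design(
              regs[[r]], n_sites = 3L, n_points = 5L, n_curves = 5L,
              cv = 0.2, noise_sd = 1,
              seed = config$seed * 1000L + cnt)
            agg <- aggregate_E(fits)
            per[[length(per) + 1L]] <- data.frame(
              group = g, animal = a, region = r,
              E = mean(agg$sites$E, na.rm = TRUE))
          }
        }
      }
      tab <- do.call(rbind, per)
      list(per_animal = tab,
           anova = two_way_anova(tab, "E", "region", "group"))
    }, error = function(e) {errors <<- c(errors, conditionMessage(e)); NULL})
    report$stiffness <- res
  }

  if ("morphometry" %in% modalities) {
    res <- tryCatch({
      per <- list()
      cv <- config$between_animal_cv
      sdlog <- sqrt(log(1 + cv^2))
      for (g in groups) {
        p0 <- config$groups[[g]]$pitch
        mult <- with_seed(config$seed + match(g, groups),
                          rlnorm(config$n_per_group, -sdlog^2 / 2, sdlog))
        for (a in seq_len(config$n_per_group)) {
          spec <- alveolar_image_spec(width_px = 600L, height_px = 600L,
                                      cell_pitch = p0 * mult[a],
                                      wall_thickness = 2, noise_sd = 0.03,
                                      seed = config$seed * 10L + a)
          lm_ <- compute_lm(generate_alveolar_image(spec))
          per[[length(per) + 1L]] <- data.frame(
            group = g, animal = a, Lm = lm_$Lm,
            Lm_true = theoretical_lm(spec))
        }
      }
      tab <- do.call(rbind, per)
      g1 <- tab$group == groups[1]
      list(per_animal = tab,
           summary = lapply(split(tab$Lm, tab$group), mean_se),
           test = compare_two_groups(tab$Lm[g1], tab$Lm[!g1]))
    }, error = function(e) {errors <<- c(errors, conditionMessage(e)); NULL})
    report$morphometry <- res
  }

  report$errors <- errors
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("pulmomech")),
    seed = config$seed, n_per_group = config$n_per_group,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  report <- structure(report, class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Simulate a full hierarchical Hertz measurement design
#'
#' Generates and fits the 3-site x 5-point x 5-curve force-curve design of
#' one region: per-point true moduli are lognormal around the region mean
#' with the stated CV; every curve is simulated, fitted, and labelled.
#'
#' @param E_region region-mean Young's modulus, Pa
#' @param n_sites,n_points,n_curves design dimensions
#' @param cv lognormal CV of point-level true moduli
#' @param noise_sd deflection noise, nm
#' @param seed RNG seed
#' @return data.frame ready for [aggregate_E()] (failed fits as `E = NA`),
#'   with the true point moduli in column `E_true`
#' @export
simulate_hertz_design <- function(E_region, n_sites = 3L, n_points = 5L,
                                  n_curves = 5L, cv = 0.2, noise_sd = 1,
                                  seed = 1L) {
  sdlog <- sqrt(log(1 + cv^2))
  npts <- n_sites * n_points
  Epts <- with_seed(seed, E_region *
                      rlnorm(npts, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  out <- list()
  i <- 0L
  for (s in seq_len(n_sites)) for (p in seq_len(n_points)) {
    i <- i + 1L
    for (cu in seq_len(n_curves)) {
      fc <- simulate_force_curve(Epts[i], noise_sd = noise_sd,
                                 seed = seed * 10000L + i * 10L + cu)
      E_hat <- tryCatch(fit_hertz(fc)$E, error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        region = "region", site = s, point = p, curve = cu,
        E = E_hat, E_true = Epts[i])
    }
  }
  do.call(rbind, out)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> groups:", paste(x$groups, collapse = " vs "),
      sprintf("(n = %d/group, seed %d)\n", x$n_per_group, x$seed))
  if (!is.null(x$elastance)) {
    for (g in x$groups) {
      e <- x$elastance$summary$Est[[g]]
      d <- x$elastance$summary$Edyn[[g]]
      cat(sprintf("  %-4s Est %.2f +/- %.2f, Edyn %.2f +/- %.2f cmH2O/ml\n",
                  g, e["mean"], e["se"], d["mean"], d["se"]))
    }
    cat(sprintf("  Est percent difference %.1f%%, p = %.3g (%s)\n",
                x$elastance$percent_diff_Est, x$elastance$test_Est$p,
                x$elastance$test_Est$test))
  }
  if (!is.null(x$viscoelastic)) {
    for (g in x$groups) {
      s <- x$viscoelastic$summary
      cat(sprintf("  %-4s A %.2f kPa, B %.3f kPa, alpha %.3f\n", g,
                  s$A[[g]]["mean"], s$B[[g]]["mean"], s$alpha[[g]]["mean"]))
    }
  }
  if (!is.null(x$stiffness)) {
    cat("  region x group ANOVA on E:\n")
    print(transform(x$stiffness$anova$table, F = signif(F, 4),
                    p = signif(p, 3)))
  }
  if (!is.null(x$morphometry)) {
    for (g in x$groups) {
      s <- x$morphometry$summary[[g]]
      cat(sprintf("  %-4s Lm %.1f +/- %.1f um\n", g, s["mean"], s["se"]))
    }
    cat(sprintf("  Lm comparison p = %.3g (%s)\n",
                x$morphometry$test$p, x$morphometry$test$test))
  }
  if (length(x$errors)) cat("  stage errors:", x$errors, sep = "\n   ")
  invisible(x)
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in c("elastance", "viscoelastic", "stiffness", "morphometry")) {
    st <- report[[stage]]
    if (!is.null(st) && !is.null(st$per_animal))
      write.csv(st$per_animal,
                file.path(out_dir, paste0(stage, "_per_animal.csv")),
                row.names = FALSE)
  }
  jsonlite::write_json(
    list(provenance = report$provenance, errors = report$errors),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Write the canonical synthetic fixture bundle
#'
#' Emits the small text fixtures used across the package: a noiseless
#' two-occlusion recording, a noiseless approach curve, a noiseless
#' multifrequency record, a lattice image (PNG) and a cohort ground-truth
#' table, plus a manifest with MD5 checksums. Noiseless artifacts are
#' seed-independent; stochastic ones derive from `seed`.
#'
#' @param out_dir output directory
#' @param seed integer seed for the stochastic fixtures
#' @return the manifest data.frame, invisibly
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- simulate_ventilation(
    lung_model_params(Est = 22.4, Raw = 0.5, seed = seed),
    maneuver_spec(n_breaths_before_occlusion = 3L))
  write_recording(rec, file.path(out_dir, "recording_wt.tsv"))
  fc <- simulate_force_curve(10e3, seed = seed)
  write_force_curve(fc, file.path(out_dir, "force_curve_10kPa.tsv"))
  mf <- simulate_multifreq(9.40, 0.016, 0.084, duration = 20, seed = seed)
  write_multifreq(mf, file.path(out_dir, "multifreq_wt.tsv"))
  img <- generate_alveolar_image(alveolar_image_spec(
    width_px = 400L, height_px = 400L, seed = seed))
  write_image(img, file.path(out_dir, "lattice_40um.png"))
  coh <- generate_cohort(cohort_spec(
    3L, list(WT = lung_model_params(Est = 22.4, noise_sd = 0.02, seed = seed),
             MFS = lung_model_params(Est = 14.1, noise_sd = 0.02, seed = seed)),
    maneuver = maneuver_spec(n_breaths_before_occlusion = 3L), seed = seed))
  write.csv(coh$truth, file.path(out_dir, "cohort_truth.csv"),
            row.names = FALSE)
  files <- setdiff(list.files(out_dir), "manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
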