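## Pyramidal Hertz analysis of AFM approach curves: photodiode calibration,
## nonlinear least-squares fit of (E, z0, d0), hierarchical aggregation.

#' Calibrate photodiode sensitivity from a bare-substrate curve
#'
#' On rigid (glass) contact the deflection-piezo curve is a flat baseline
#' followed by a straight contact line; its slope calibrates the photodiode
#' signal to cantilever deflection. The contact point is located by a
#' continuous two-segment piecewise-linear fit; the contact-region linearity
#' (R^2) and the slope-change sharpness are returned as tip-quality
#' diagnostics, with a `clean` flag when R^2 >= 0.999.
#'
#' @param z piezo displacement, nm
#' @param d photodiode signal (arbitrary units or nm)
#' @return an object of class `deflection_calibration`: `sensitivity`
#'   (contact slope), `contact_z`, `r_squared`, `sharpness`, `clean`
#' @export
calibrate_deflection <- function(z, d) {
  if (length(z) < 8L) stop_analysis("calibration curve too short")
  ord <- order(z)
  z <- z[ord]; d <- d[ord]
  pw <- piecewise_linear_fit(z, d)
  contact <- z > pw$breakpoint
  if (sum(contact) < 4L || abs(pw$slope2) <= abs(pw$slope1))
    stop_analysis("no detectable contact region in calibration curve")
  fit <- lm(d[contact] ~ z[contact])
  tss <- sum((d[contact] - mean(d[contact]))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 0
  structure(list(sensitivity = unname(coef(fit)[2]),
                 contact_z = pw$breakpoint,
                 r_squared = r2,
                 sharpness = abs(pw$slope2 - pw$slope1),
                 clean = r2 >= 0.999),
            class = "deflection_calibration")
}

#' @export
print.deflection_calibration <- function(x, ...) {
  cat(sprintf("<deflection_calibration> sensitivity %.4f, contact at z = %.1f\n",
              x$sensitivity, x$contact_z))
  cat(sprintf("  contact R^2 %.5f, sharpness %.3f, tip %s\n",
              x$r_squared, x$sharpness, if (x$clean) "clean" else "dirty"))
  invisible(x)
}

#' Configuration of the pyramidal Hertz fit
#'
#' @param max_indentation deepest indentation used by the fit, nm. Data are
#'   restricted to `delta <= max_indentation`, re-evaluated at each
#'   selection pass since `delta` depends on the fitted contact point.
#' @param min_indentation optional lower indentation cutoff, nm (0 keeps
#'   the full post-contact range; ~300 nm reflects the blunted-tip validity
#'   limit of the ideal-pyramid model on real tips)
#' @param max_select_iter selection-refit passes
#' @return a list of class `hertz_config`
#' @export
hertz_config <- function(max_indentation = 500, min_indentation = 0,
                         max_select_iter = 8L) {
  structure(list(max_indentation = max_indentation,
                 min_indentation = min_indentation,
                 max_select_iter = as.integer(max_select_iter)),
            class = "hertz_config")
}

hertz_predict_d <- function(par, z, k, theta, nu) {
  ## par = (log(E [Pa]), z0 [nm], d0 [nm])
  a <- hertz_prefactor(exp(par[1]), theta, nu) / k
  par[3] + pyramid_deflection((z - par[2]) * 1e-9, a) * 1e9
}

#' Fit the pyramidal Hertz contact model to an approach curve
#'
#' Nonlinear least squares of the deflection-form contact model
#' `d = d0 + [3 E tan(theta) / (4 k (1 - nu^2))] * delta^2`,
#' `delta = (z - z0) - (d - d0)`, over `(E, z0, d0)`. The fit window keeps
#' the pre-contact baseline plus indentations up to
#' `config$max_indentation` (500 nm by default), re-selected iteratively as
#' the contact point moves. Three restarts (contact point at the
#' maximum-curvature sample; E at 1 kPa, 10 kPa and 20 kPa) guard against
#' contact-point local minima; the best converged restart wins.
#'
#' @param curve a [force_curve()]
#' @param config a [hertz_config()]
#' @return an object of class `hertz_fit`: `E` (Pa), `z0`, `d0` (nm),
#'   `max_indentation_used` (nm), `rss`, `converged`, `n_used`
#' @export
fit_hertz <- function(curve, config = hertz_config()) {
  stopifnot(inherits(curve, "force_curve"))
  ord <- order(curve$z)
  z <- curve$z[ord]; d <- curve$d[ord]
  n <- length(z)
  if (n < 50L) stop_analysis("approach segment needs >= 50 samples")

  d0_init <- median(d[seq_len(max(5L, n %/% 10))])
  ## contact-point initialization: maximum curvature of a lightly smoothed
  ## d(z), interior samples only (the smoother is biased at the edges)
  ds <- stats::filter(d, rep(1 / 5, 5), sides = 2)
  ds[is.na(ds)] <- d[is.na(ds)]
  curv <- abs(diff(ds, differences = 2))
  interior <- seq_along(curv) > 5L & seq_along(curv) < length(curv) - 5L
  z0_curv <- z[which.max(curv * interior) + 1L]
  ## fallback: first crossing of a small deflection threshold
  rise <- d - d0_init > 0.02 * max(d - d0_init, 1e-9)
  z0_cross <- if (any(rise)) z[which(rise)[1]] else z[n %/% 2]

  run_fit <- function(E0, z00) {
    par <- c(log(E0), z00, d0_init)
    sel <- rep(TRUE, n)
    fit <- NULL
    for (it in seq_len(config$max_select_iter)) {
      delta_obs <- (z - par[2]) - (d - par[3])
      new_sel <- delta_obs <= config$max_indentation &
        (delta_obs <= 0 | delta_obs >= config$min_indentation)
      if (sum(new_sel & delta_obs > 0) < 10L) return(NULL)
      stable <- identical(new_sel, sel) && it > 1L
      sel <- new_sel
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = par,
          fn = function(p) d[sel] - hertz_predict_d(p, z[sel], curve$k,
                                                    curve$theta, curve$nu),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      par <- fit$par
      if (stable) break
    }
    delta_obs <- (z - par[2]) - (d - par[3])
    list(par = par, rss = sum(fit$fvec^2),
         converged = fit$info %in% 1:3,
         n_used = sum(sel),
         max_delta = max(delta_obs[sel], 0))
  }

  starts <- list(c(1e3, z0_cross), c(1e4, z0_cross), c(2e4, z0_curv))
  fits <- Filter(Negate(is.null), lapply(starts, function(s)
    run_fit(s[1], s[2])))
  fits <- Filter(function(f) is.finite(f$rss), fits)
  if (!length(fits))
    stop_analysis("Hertz fit failed to converge: no usable contact region")
  conv <- Filter(function(f) f$converged, fits)
  pool <- if (length(conv)) conv else fits
  best <- pool[[which.min(vapply(pool, `[[`, 0, "rss"))]]
  E <- exp(best$par[1])
  ## degenerate-curve guard: the fitted contact must raise the deflection
  ## clearly above the residual noise floor, else there is no contact signal
  resid_sd <- sqrt(best$rss / max(best$n_used - 3L, 1L))
  a_best <- hertz_prefactor(E, curve$theta, curve$nu) / curve$k
  pred_rise <- a_best * (best$max_delta * 1e-9)^2 * 1e9  # nm at deepest point
  if (!best$converged || !is.finite(E) || E <= 0 ||
      pred_rise < max(5 * resid_sd, 1e-3))
    stop_analysis("Hertz fit failed to converge on this curve")
  structure(list(E = E, z0 = best$par[2], d0 = best$par[3],
                 max_indentation_used = best$max_delta,
                 rss = best$rss, converged = best$converged,
                 n_used = best$n_used,
                 k = curve$k, theta = curve$theta, nu = curve$nu),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.3f kPa (z0 = %.1f nm, d0 = %.2f nm)\n",
              x$E / 1e3, x$z0, x$d0))
  cat(sprintf("  %d samples, max indentation %.0f nm, rss %.3g, %s\n",
              x$n_used, x$max_indentation_used, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(E = object$E, z0 = object$z0, d0 = object$d0)
}

#' @export
predict.hertz_fit <- function(object, z, ...) {
  hertz_predict_d(c(log(object$E), object$z0, object$d0), z,
                  object$k, object$theta, object$nu)
}

#' Aggregate Hertz fits through the measurement hierarchy
#'
#' Young's modulus of a measurement point is the mean over its (typically
#' five) force curves; a site averages its points; a region averages its
#' sites. Failed fits (`E = NA`) are dropped with a count; a point with no
#' successful curve is flagged and excluded upward with the flag propagated.
#'
#' @param fits data.frame with columns `region`, `site`, `point`, `curve`,
#'   `E` (Pa; NA for failed fits)
#' @return an object of class `stiffness_hierarchy` with data.frames
#'   `points`, `sites`, `regions` and the failed-fit count
#' @export
aggregate_E <- function(fits) {
  req <- c("region", "site", "point", "curve", "E")
  if (!all(req %in% names(fits)))
    stop_invalid("fits must have columns ", paste(req, collapse = ", "))
  n_failed <- sum(is.na(fits$E))
  pts <- stats::aggregate(E ~ region + site + point, data = fits,
                          FUN = function(e) mean(e, na.rm = TRUE),
                          na.action = stats::na.pass)
  pts$missing <- !is.finite(pts$E)
  sites <- stats::aggregate(E ~ region + site,
                            data = pts[!pts$missing, , drop = FALSE],
                            FUN = mean)
  miss_site <- stats::aggregate(missing ~ region + site, data = pts, FUN = any)
  sites <- merge(sites, miss_site, by = c("region", "site"), all = TRUE)
  regions <- stats::aggregate(E ~ region,
                              data = sites[is.finite(sites$E), , drop = FALSE],
                              FUN = mean)
  miss_reg <- stats::aggregate(missing ~ region, data = sites, FUN = any)
  regions <- merge(regions, miss_reg, by = "region", all = TRUE)
  structure(list(points = pts, sites = sites, regions = regions,
                 n_failed = n_failed),
            class = "stiffness_hierarchy")
}

#' @export
print.stiffness_hierarchy <- function(x, ...) {
  cat("<stiffness_hierarchy>\n")
  for (i in seq_len(nrow(x$regions)))
    cat(sprintf("  %-18s E = %.3f kPa%s\n", x$regions$region[i],
                x$regions$E[i] / 1e3,
                if (isTRUE(x$regions$missing[i])) " [missing data]" else ""))
  if (x$n_failed) cat("  failed fits dropped:", x$n_failed, "\n")
  invisible(x)
}
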