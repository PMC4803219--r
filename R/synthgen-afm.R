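## Synthetic AFM data: pyramidal-tip approach curves generated by inverting
## the deflection-form contact model, and multifrequency indentation records
## generated from a prescribed complex shear modulus.

hertz_prefactor <- function(E, theta_deg, nu) {
  3 * E * tan(theta_deg * pi / 180) / (4 * (1 - nu^2))
}

#' Construct an AFM approach curve
#'
#' @param z piezo displacement, nm (approach direction increasing)
#' @param d cantilever deflection, nm
#' @param k cantilever spring constant, N/m
#' @param theta semi-included tip half-angle, degrees
#' @param nu Poisson ratio of the sample
#' @return an object of class `force_curve`
#' @export
force_curve <- function(z, d, k = 0.03, theta = 20, nu = 0.5) {
  if (length(z) != length(d)) stop_invalid("z and d must have equal length")
  check_number(k, "k", 0, strict_lower = TRUE)
  check_number(theta, "theta", 0, 90, strict_lower = TRUE)
  check_number(nu, "nu", 0, 0.5)
  structure(list(z = z, d = d, k = k, theta = theta, nu = nu),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples, z in [%.0f, %.0f] nm, k = %g N/m, theta = %g deg\n",
              length(x$z), min(x$z), max(x$z), x$k, x$theta))
  invisible(x)
}

## Deflection of the cantilever for tip-sample separation s = z - z0 (m),
## solving d - d0 = (C/k) * ((z - z0) - (d - d0))^2 in closed form.
pyramid_deflection <- function(s, a) {
  w <- numeric(length(s))
  pos <- s > 0
  if (a <= 0) return(w)
  w[pos] <- (2 * a * s[pos] + 1 - sqrt(4 * a * s[pos] + 1)) / (2 * a)
  w
}

#' Simulate a pyramidal-tip AFM approach curve
#'
#' Inverts the measurement model: beyond the contact point `z0` the
#' deflection solves the pyramidal (four-sided tip) contact relation
#' `k*(d - d0) = [3 E tan(theta) / (4 (1 - nu^2))] * delta^2` with
#' indentation `delta = (z - z0) - (d - d0)`; before contact `d = d0`.
#' Noiseless output satisfies the relation exactly.
#'
#' @param E_true Young's modulus of the simulated sample, Pa
#' @param z0 contact-point piezo position, nm
#' @param d0 free deflection offset, nm
#' @param k spring constant, N/m
#' @param theta tip half-angle, degrees
#' @param nu Poisson ratio
#' @param max_indentation deepest simulated indentation, nm
#' @param pre_contact z-range sampled before contact, nm
#' @param n number of samples
#' @param noise_sd additive Gaussian deflection noise, nm
#' @param seed RNG seed
#' @return a [force_curve()]; ground truth in attribute `truth`
#' @export
simulate_force_curve <- function(E_true, z0 = 200, d0 = 0, k = 0.03,
                                 theta = 20, nu = 0.5,
                                 max_indentation = 1000, pre_contact = 300,
                                 n = 400L, noise_sd = 0, seed = 1L) {
  check_number(E_true, "E_true", 0, strict_lower = TRUE)
  check_number(theta, "theta", 0, 90, strict_lower = TRUE)
  check_number(nu, "nu", 0, 0.5)
  check_number(max_indentation, "max_indentation", 0, strict_lower = TRUE)
  a <- hertz_prefactor(E_true, theta, nu) / k          # 1/m
  dmax <- max_indentation * 1e-9
  s_max <- dmax + a * dmax^2                           # m
  z <- seq(z0 - pre_contact, z0 + s_max * 1e9, length.out = n)
  w <- pyramid_deflection((z - z0) * 1e-9, a) * 1e9    # nm
  d <- d0 + w
  if (noise_sd > 0) d <- d + with_seed(seed, rnorm(n, 0, noise_sd))
  fc <- force_curve(z, d, k = k, theta = theta, nu = nu)
  attr(fc, "truth") <- list(E = E_true, z0 = z0, d0 = d0)
  fc
}

#' Two power-law complex shear modulus model
#'
#' Evaluates `G*(f) = A (i f/f_ref)^alpha + B (i f/f_ref)^(3/4)` with the
#' principal branch `(i x)^p = x^p (cos(pi p/2) + i sin(pi p/2))`.
#' Units of the result follow `A` and `B`.
#'
#' @param f frequency, Hz
#' @param A low-frequency power-law amplitude
#' @param B amplitude of the 3/4-exponent (entropic) regime
#' @param alpha low-frequency exponent (0 <= alpha < 1)
#' @param f_ref normalization frequency, Hz
#' @return complex vector G*(f)
#' @export
powerlaw_gstar <- function(f, A, B, alpha, f_ref = 1) {
  fr <- f / f_ref
  A * fr^alpha * exp(1i * pi * alpha / 2) + B * fr^0.75 * exp(1i * 3 * pi / 8)
}

#' Construct a multifrequency indentation record
#'
#' @param t time, s
#' @param F force, nN
#' @param delta indentation, nm
#' @param delta0 operating indentation, nm
#' @param freqs stimulus frequencies, Hz
#' @param b_h cantilever hydrodynamic drag coefficient at the working
#'   tip-sample gap, nN.s/nm (the drag force spectrum is `i f b_h delta(f)`)
#' @param theta,nu tip half-angle (deg) and Poisson ratio
#' @return an object of class `multifreq_record`
#' @export
multifreq_record <- function(t, F, delta, delta0 = 500,
                             freqs = c(0.35, 1.15, 3.55, 11.45),
                             b_h = 0, theta = 20, nu = 0.5) {
  if (length(t) != length(F) || length(t) != length(delta))
    stop_invalid("t, F and delta must have equal length")
  if (!length(freqs)) stop_invalid("freqs must be non-empty")
  structure(list(t = t, F = F, delta = delta, delta0 = delta0,
                 freqs = freqs, b_h = b_h, theta = theta, nu = nu),
            class = "multifreq_record")
}

#' @export
print.multifreq_record <- function(x, ...) {
  cat(sprintf("<multifreq_record> %d samples over %.1f s, delta0 = %g nm\n",
              length(x$t), diff(range(x$t)), x$delta0))
  cat("  stimulus frequencies (Hz):", paste(x$freqs, collapse = ", "), "\n")
  invisible(x)
}

check_freq_mixing <- function(freqs, tol = 1e-6) {
  n <- length(freqs)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == i || k == i) next
    if (abs(freqs[i] - (freqs[j] + freqs[k])) < tol ||
        abs(freqs[i] - abs(freqs[j] - freqs[k])) < tol)
      return(FALSE)
  }
  TRUE
}

#' Simulate a multifrequency AFM indentation record
#'
#' The indentation oscillates about the operating depth `delta0` as a sum
#' of sine components (one per stimulus frequency, each of amplitude
#' `amplitude/length(freqs)`); the force trace is the response of the
#' prescribed complex shear modulus through the pyramidal contact
#' transduction factor `3 delta0 tan(theta) / (1 - nu)`, plus the cantilever
#' drag term `i f b_h` applied to the indentation spectrum, plus optional
#' linear drift and Gaussian noise.
#'
#' @param A,B power-law amplitudes, kPa
#' @param alpha low-frequency exponent
#' @param delta0 operating indentation, nm
#' @param freqs stimulus frequencies, Hz (validated to be pairwise non-sum
#'   and non-difference; violation warns, does not stop)
#' @param duration record length, s (must cover the slowest period)
#' @param amplitude total oscillation amplitude, nm
#' @param b_h drag coefficient, nN.s/nm
#' @param fs sampling rate, Hz
#' @param theta,nu tip geometry and Poisson ratio
#' @param f0_nN static force baseline, nN
#' @param drift_nN_s linear force drift, nN/s
#' @param noise_sd force noise, nN
#' @param seed RNG seed
#' @return a [multifreq_record()]; ground truth in attribute `truth`
#' @export
simulate_multifreq <- function(A, B, alpha, delta0 = 500,
                               freqs = c(0.35, 1.15, 3.55, 11.45),
                               duration = 140, amplitude = 75, b_h = 0,
                               fs = 100, theta = 20, nu = 0.5,
                               f0_nN = 1, drift_nN_s = 0, noise_sd = 0,
                               seed = 1L) {
  if (!length(freqs)) stop_invalid("freqs must be non-empty")
  if (duration < 1 / min(freqs))
    stop_invalid("duration must cover at least one period of the slowest component")
  if (!check_freq_mixing(freqs))
    warning("stimulus frequencies are sum/difference related; harmonic cross-talk possible")
  t <- seq(0, duration, by = 1 / fs)
  amp <- amplitude / length(freqs)                  # nm per component
  gain <- 3 * (delta0 * 1e-9) * tan(theta * pi / 180) / (1 - nu)  # m
  delta <- rep(delta0, length(t))
  F <- rep(f0_nN, length(t)) + drift_nN_s * t
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    delta <- delta + amp * sin(2 * pi * f * t)
    ## phasor of a sine component is -i*amp under x(t) = Re[X exp(i w t)]
    H <- powerlaw_gstar(f, A, B, alpha) * 1e3 * gain + 1i * f * b_h # N/m
    Xf <- H * (-1i * amp)                          # nN (nm * N/m = nN)
    F <- F + Re(Xf * exp(2i * pi * f * t))
  }
  if (noise_sd > 0) F <- F + with_seed(seed, rnorm(length(t), 0, noise_sd))
  rec <- multifreq_record(t, F, delta, delta0 = delta0, freqs = freqs,
                          b_h = b_h, theta = theta, nu = nu)
  attr(rec, "truth") <- list(A = A, B = B, alpha = alpha)
  rec
}
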