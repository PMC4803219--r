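#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm lm.fit coef optimize rnorm rlnorm sd t.test wilcox.test
#'   shapiro.test aov pf predict residuals median quantile setNames var
#' @importFrom utils write.csv read.csv head tail
NULL

## Internal validation helpers -------------------------------------------------

stop_invalid <- function(...) {
  stop(structure(class = c("pulmomech_invalid_spec", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("pulmomech_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_analysis <- function(...) {
  stop(structure(class = c("pulmomech_analysis_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    stop_invalid(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_invalid(name, " must be >= ", lower)
  if (x > upper)
    stop_invalid(name, " must be <= ", upper)
  invisible(x)
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream (one seeded generator per call).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Continuous two-segment piecewise-linear least-squares fit.
## Returns breakpoint location, fitted value at the breakpoint, slopes and RSS.
## Breakpoint candidates are the interior sample positions.
piecewise_linear_fit <- function(x, y) {
  n <- length(x)
  if (n < 4L) stop_analysis("piecewise fit needs >= 4 samples")
  best <- NULL
  for (k in 2:(n - 1L)) {
    xb <- x[k]
    X <- cbind(1, x, pmax(x - xb, 0))
    f <- lm.fit(X, y)
    rss <- sum(f$residuals^2)
    if (is.null(best) || rss < best$rss) {
      b <- f$coefficients
      best <- list(breakpoint = xb, value = b[[1]] + b[[2]] * xb,
                   slope1 = b[[2]], slope2 = b[[2]] + b[[3]], rss = rss,
                   index = k)
    }
  }
  best
}
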