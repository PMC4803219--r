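## Group-comparison statistics of the study: gated unpaired two-group test,
## two-way ANOVA (optionally with repeated measures), Holm-Sidak post hoc.

#' Compare two independent groups with a normality-gated test
#'
#' Applies a Shapiro-Wilk normality gate (alpha = 0.05, per group) and runs
#' an unpaired equal-variance t-test when both groups pass, otherwise a
#' Mann-Whitney (Wilcoxon rank-sum) test. The gate decision is always
#' reported. Groups of fewer than 3 observations cannot be gated and are
#' treated as passing. Zero-variance degenerate pairs are handled directly:
#' equal constant groups give t = 0, p = 1.
#'
#' @param a,b numeric vectors (n >= 2 each)
#' @param method `"auto"` (gated), `"t"`, or `"mann-whitney"`
#' @param alpha_normality gate significance level
#' @return object of class `two_group_test`: `test`, `statistic`, `p`,
#'   `gate` (per-group Shapiro p values and decision)
#' @export
compare_two_groups <- function(a, b, method = c("auto", "t", "mann-whitney"),
                               alpha_normality = 0.05) {
  method <- match.arg(method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop_invalid("each group needs >= 2 finite observations")
  shapiro_p <- function(x) {
    if (length(x) < 3L || sd(x) == 0) return(NA_real_)
    shapiro.test(x)$p.value
  }
  pa <- shapiro_p(a); pb <- shapiro_p(b)
  normal <- (is.na(pa) || pa >= alpha_normality) &&
    (is.na(pb) || pb >= alpha_normality)
  chosen <- switch(method, auto = if (normal) "t" else "mann-whitney",
                   method)
  if (chosen == "t") {
    if (sd(a) == 0 && sd(b) == 0) {
      res <- if (isTRUE(all.equal(mean(a), mean(b))))
        list(statistic = 0, p.value = 1)
      else list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0)
    } else {
      tt <- t.test(a, b, var.equal = TRUE)
      res <- list(statistic = unname(tt$statistic), p.value = tt$p.value)
    }
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    res <- list(statistic = unname(wt$statistic), p.value = wt$p.value)
  }
  structure(list(test = chosen, statistic = res$statistic, p = res$p.value,
                 significant = res$p.value < 0.05,
                 gate = list(shapiro_p_a = pa, shapiro_p_b = pb,
                             both_normal = normal, requested = method)),
            class = "two_group_test")
}

#' @export
print.two_group_test <- function(x, ...) {
  cat(sprintf("<two_group_test> %s: statistic = %.4g, p = %.4g%s\n",
              if (x$test == "t") "unpaired t (equal variance)"
              else "Mann-Whitney U", x$statistic, x$p,
              if (x$significant) " *" else ""))
  cat(sprintf("  normality gate: Shapiro p = %.3g / %.3g -> %s\n",
              x$gate$shapiro_p_a, x$gate$shapiro_p_b,
              if (x$gate$both_normal) "parametric" else "non-parametric"))
  invisible(x)
}

#' Two-way analysis of variance
#'
#' Main effects and interaction for two crossed factors. The between-
#' subjects analysis uses Type II sums of squares by default (overridable);
#' the repeated-measures variant treats `within` as a within-subject factor
#' with univariate error partitioning (`aov` with an `Error(subject/within)`
#' stratum).
#'
#' @param data data.frame, one row per observation
#' @param response name of the response column
#' @param factor_a,factor_b names of the two factor columns
#' @param repeated FALSE, or the name of the within-subject factor (must be
#'   `factor_a` or `factor_b`)
#' @param subject name of the subject id column (required when `repeated`)
#' @param ss_type `2` or `3` (between-subjects designs only)
#' @return object of class `anova_result`: data.frame `table` with columns
#'   `effect`, `df`, `F`, `p`
#' @export
two_way_anova <- function(data, response, factor_a, factor_b,
                          repeated = FALSE, subject = NULL, ss_type = 2) {
  for (v in c(response, factor_a, factor_b))
    if (!v %in% names(data)) stop_invalid("column '", v, "' not found")
  data[[factor_a]] <- factor(data[[factor_a]])
  data[[factor_b]] <- factor(data[[factor_b]])
  if (nlevels(data[[factor_a]]) < 2L || nlevels(data[[factor_b]]) < 2L)
    stop_invalid("each factor needs >= 2 levels")
  if (any(table(data[[factor_a]], data[[factor_b]]) == 0))
    stop_invalid("empty design cell: every factor combination needs data")
  eff_names <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))

  if (var(data[[response]]) < .Machine$double.eps * 100) {
    ## constant response: every effect carries zero signal
    nl <- c(nlevels(data[[factor_a]]) - 1L, nlevels(data[[factor_b]]) - 1L)
    tab <- data.frame(effect = eff_names, df = c(nl, prod(nl)),
                      ss = 0, F = 0, p = 1)
    return(structure(list(table = tab, repeated = !isFALSE(repeated),
                          ss_type = ss_type),
                     class = "anova_result"))
  }

  if (!isFALSE(repeated)) {
    if (is.null(subject)) stop_invalid("repeated measures require a subject column")
    if (!repeated %in% c(factor_a, factor_b))
      stop_invalid("'repeated' must name one of the two factors")
    data[[subject]] <- factor(data[[subject]])
    fml <- stats::as.formula(sprintf(
      "%s ~ %s * %s + Error(%s/%s)", response, factor_a, factor_b,
      subject, repeated))
    fit <- aov(fml, data = data)
    sm <- summary(fit)
    tab <- do.call(rbind, lapply(sm, function(s) {
      d <- as.data.frame(s[[1]])
      d$effect <- trimws(rownames(d))
      d
    }))
    rownames(tab) <- NULL
    tab <- tab[tab$effect %in% eff_names,
               c("effect", "Df", "Sum Sq", "F value", "Pr(>F)")]
    names(tab) <- c("effect", "df", "ss", "F", "p")
    tab <- tab[match(eff_names, tab$effect), ]
  } else {
    fml <- stats::as.formula(sprintf("%s ~ %s * %s", response,
                                     factor_a, factor_b))
    ## sum-to-zero contrasts so Type II/III tests are well defined
    ctr <- list()
    ctr[[factor_a]] <- "contr.sum"; ctr[[factor_b]] <- "contr.sum"
    fit <- lm(fml, data = data, contrasts = ctr)
    an <- car::Anova(fit, type = if (ss_type == 3) "III" else "II")
    an <- as.data.frame(an)
    an$effect <- rownames(an)
    tab <- an[an$effect %in% eff_names,
              c("effect", "Df", "Sum Sq", "F value", "Pr(>F)")]
    names(tab) <- c("effect", "df", "ss", "F", "p")
    tab <- tab[match(eff_names, tab$effect), ]
    rownames(tab) <- NULL
  }
  ## an effect with literally zero sum of squares has no signal: report
  ## F = 0, p = 1 rather than the 0/0 indeterminate of a saturated fit
  zero <- is.na(tab$F) | tab$ss < .Machine$double.eps * 100
  tab$F[zero] <- 0
  tab$p[zero] <- 1
  structure(list(table = tab, repeated = !isFALSE(repeated),
                 ss_type = ss_type),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> two-way ANOVA%s%s\n",
              if (x$repeated) ", repeated measures" else "",
              if (!x$repeated) sprintf(" (Type %s SS)", x$ss_type) else ""))
  print(transform(x$table, F = signif(F, 6), p = signif(p, 4)))
  invisible(x)
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorted ascending p values are adjusted as
#' `1 - (1 - p_(i))^(m - i + 1)` with monotonicity enforced by a running
#' maximum, then capped at 1. Decisions are taken at `alpha`.
#'
#' @param p numeric vector of p values in \[0, 1\]
#' @param alpha family-wise significance level
#' @return object of class `holm_sidak`: `p_raw`, `p_adjusted` (original
#'   order), `reject` (logical)
#' @export
holm_sidak <- function(p, alpha = 0.05) {
  if (!length(p))
    return(structure(list(p_raw = numeric(0), p_adjusted = numeric(0),
                          reject = logical(0), alpha = alpha),
                     class = "holm_sidak"))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_invalid("p values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  structure(list(p_raw = p, p_adjusted = out, reject = out < alpha,
                 alpha = alpha),
            class = "holm_sidak")
}

#' @export
print.holm_sidak <- function(x, ...) {
  cat(sprintf("<holm_sidak> %d comparisons at alpha = %g\n",
              length(x$p_raw), x$alpha))
  print(data.frame(p_raw = x$p_raw, p_adjusted = signif(x$p_adjusted, 4),
                   reject = x$reject))
  invisible(x)
}
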