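# Shared fixture builders: everything is generated in code at test time.

# Short maneuver: 3 breaths before each occlusion keeps tests fast while
# preserving the end-inspiratory occlusion structure.
short_maneuver <- function(...) {
  maneuver_spec(n_breaths_before_occlusion = 3L, ...)
}

wt_params <- function(...) {
  lung_model_params(Est = 22.4, Raw = 0.5, ...)
}

# Complex modulus table evaluated directly from the two power-law model,
# bypassing the time-domain simulation (for fast power-law fit tests).
model_modulus <- function(A, B, alpha, f = c(0.35, 1.15, 3.55, 11.45)) {
  g <- powerlaw_gstar(f, A, B, alpha) * 1e3  # kPa -> Pa
  complex_modulus(f, Re(g), Im(g))
}

# Brute-force per-pixel enumeration of skeleton runs along the probe lines:
# the independent oracle for intercept counting.
oracle_count_intercepts <- function(skeleton, grid) {
  count_line <- function(vals) {
    n <- 0L
    inside <- FALSE
    for (v in vals) {
      if (v && !inside) { n <- n + 1L; inside <- TRUE }
      if (!v) inside <- FALSE
    }
    n
  }
  total <- 0L
  v <- grid$vertical
  for (i in seq_len(nrow(v)))
    total <- total + count_line(skeleton[v$row0[i]:v$row1[i], v$col[i]])
  h <- grid$horizontal
  for (i in seq_len(nrow(h)))
    total <- total + count_line(skeleton[h$row[i], h$col0[i]:h$col1[i]])
  total
}

# Number of enclosed faces of a binary structure: background components
# (4-connectivity via EBImage default) that do not touch the image border.
count_enclosed_faces <- function(mask) {
  lab <- EBImage::bwlabel(!mask * 1)
  if (max(lab) == 0) return(0L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  length(setdiff(seq_len(max(lab)), border))
}

# Brute-force two-way ANOVA sums of squares through projection matrices
# (balanced designs; sequential == Type II there).
oracle_anova_F <- function(y, A, B) {
  proj <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  n <- length(y)
  X1 <- matrix(1, n, 1)
  XA <- model.matrix(~A); XB <- model.matrix(~B); XAB <- model.matrix(~A * B)
  XApB <- model.matrix(~A + B)
  ssA <- sum((proj(XApB) %*% y - proj(XB) %*% y)^2)
  ssB <- sum((proj(XApB) %*% y - proj(XA) %*% y)^2)
  ssAB <- sum((proj(XAB) %*% y - proj(XApB) %*% y)^2)
  ssE <- sum((y - proj(XAB) %*% y)^2)
  dfA <- nlevels(A) - 1L; dfB <- nlevels(B) - 1L
  dfAB <- dfA * dfB
  dfE <- n - nlevels(A) * nlevels(B)
  c(A = (ssA / dfA) / (ssE / dfE),
    B = (ssB / dfB) / (ssE / dfE),
    AB = (ssAB / dfAB) / (ssE / dfE))
}
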