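## Mean linear intercept morphometry: binarization, vessel removal,
## skeletonization, probe grid, intercept counting.

#' Morphometry configuration
#'
#' @param polarity `"dark"` if tissue is darker than airspace (H&E-like),
#'   `"light"` for inverted contrast
#' @param vessel_area_threshold components larger than this (after a
#'   morphological opening that erases thin septal walls) are treated as
#'   large vessels and removed, square micrometers
#' @param vessel_opening_um radius of the opening structuring disc,
#'   micrometers; must exceed the septal wall half-thickness so walls vanish
#'   while vessel cores survive
#' @param speck_area tissue specks smaller than this are removed, square
#'   micrometers
#' @param margin_frac probe-grid interior margin as a fraction of each image
#'   dimension
#' @param n_vertical,n_horizontal number of probe lines
#' @param colinear_run_px skeleton runs along a probe longer than this are
#'   flagged as probe-parallel walls and counted once
#' @return a list of class `morpho_config`
#' @export
morpho_config <- function(polarity = c("dark", "light"),
                          vessel_area_threshold = 5000,
                          vessel_opening_um = 5, speck_area = 20,
                          margin_frac = 0.02, n_vertical = 11L,
                          n_horizontal = 9L, colinear_run_px = 10L) {
  structure(list(polarity = match.arg(polarity),
                 vessel_area_threshold = vessel_area_threshold,
                 vessel_opening_um = vessel_opening_um,
                 speck_area = speck_area, margin_frac = margin_frac,
                 n_vertical = as.integer(n_vertical),
                 n_horizontal = as.integer(n_horizontal),
                 colinear_run_px = as.integer(colinear_run_px)),
            class = "morpho_config")
}

remove_small_components <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Detect large vessels in a binary tissue mask
#'
#' A morphological opening with a disc larger than the septal wall
#' half-thickness erases the wall lattice; what survives are the cores of
#' large solid structures. Surviving components with area above the vessel
#' threshold are dilated back to full size and reported as the vessel mask.
#'
#' @param mask logical tissue mask
#' @param px_size micrometers per pixel
#' @param area_threshold minimum vessel area, square micrometers
#' @param opening_um opening disc radius, micrometers
#' @return list with `mask` (logical vessel mask) and `n` (vessel count)
#' @export
detect_vessels <- function(mask, px_size, area_threshold = 5000,
                           opening_um = 5) {
  r_px <- max(1L, round(opening_um / px_size))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  opened <- EBImage::opening(mask * 1, brush)
  lab <- EBImage::bwlabel(opened)
  if (max(lab) == 0)
    return(list(mask = matrix(FALSE, nrow(mask), ncol(mask)), n = 0L))
  sizes <- tabulate(lab[lab > 0])
  vess <- which(sizes * px_size^2 > area_threshold)
  core <- matrix(lab %in% vess, nrow(mask), ncol(mask))
  full <- EBImage::dilate(core * 1, brush) > 0
  list(mask = full & mask, n = length(vess))
}

#' Binarize and clean a histology image
#'
#' Converts the image to a binary tissue mask by Otsu's automatic global
#' threshold (on the luminance for RGB input), removes large vessels (see
#' [detect_vessels()]) and optionally a user exclusion mask, then deletes
#' small specks.
#'
#' @param img a [histology_image()]
#' @param config a [morpho_config()]
#' @param exclusion_mask optional logical matrix of pixels to exclude
#' @return list of class `tissue_mask`: `tissue` (logical), `vessels`
#'   removed mask, `n_vessels`, `excluded`, `px_size`, `threshold`
#' @export
preprocess_image <- function(img, config = morpho_config(),
                             exclusion_mask = NULL) {
  stopifnot(inherits(img, "histology_image"))
  g <- img$pixels
  rng <- range(g)
  if (diff(rng) < 1e-8) stop_analysis("blank image: no tissue to segment")
  gn <- (g - rng[1]) / diff(rng)
  thr <- EBImage::otsu(gn)
  tissue <- if (config$polarity == "dark") gn < thr else gn > thr
  if (!any(tissue)) stop_analysis("empty tissue mask after binarization")
  vess <- detect_vessels(tissue, img$px_size,
                         config$vessel_area_threshold,
                         config$vessel_opening_um)
  tissue <- tissue & !vess$mask
  excluded <- if (is.null(exclusion_mask))
    matrix(FALSE, nrow(g), ncol(g)) else exclusion_mask
  tissue <- tissue & !excluded
  tissue <- remove_small_components(
    tissue, config$speck_area / img$px_size^2)
  structure(list(tissue = tissue, vessels = vess$mask,
                 n_vessels = vess$n, excluded = excluded,
                 px_size = img$px_size, threshold = thr),
            class = "tissue_mask")
}

shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Skeletonize a binary wall mask
#'
#' Zhang-Suen iterative thinning to a one-pixel-wide skeleton. The
#' algorithm only deletes simple (connectivity-preserving) pixels, so the
#' number of connected components and of enclosed faces is preserved.
#'
#' @param mask logical matrix (tissue = TRUE)
#' @return logical skeleton matrix
#' @export
skeletonize_walls <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!any(img == 1L)) return(mask & FALSE)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P2 <- shift_mat(img, 1, 0)   # north neighbor value at each pixel
      P3 <- shift_mat(img, 1, -1)
      P4 <- shift_mat(img, 0, -1)  # east
      P5 <- shift_mat(img, -1, -1)
      P6 <- shift_mat(img, -1, 0)  # south
      P7 <- shift_mat(img, -1, 1)
      P8 <- shift_mat(img, 0, 1)   # west
      P9 <- shift_mat(img, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      ps <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- matrix(0L, nrow(img), ncol(img))
      for (i in 1:8) A <- A + (ps[[i]] == 0L & ps[[i + 1L]] == 1L)
      if (step == 1) {
        cond <- img == 1L & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- img == 1L & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

#' Build the 11 + 9 probe-line grid
#'
#' Places `n_vertical` vertical and `n_horizontal` horizontal probe lines
#' evenly across the image interior, inset by `margin_frac` of each
#' dimension so no probe coincides with the border. Placement is
#' deterministic.
#'
#' @param dim image dimensions `c(height_px, width_px)`
#' @param px_size micrometers per pixel
#' @param config a [morpho_config()]
#' @return object of class `probe_grid`: per-line pixel spans and the total
#'   geometric probe length in micrometers
#' @export
build_grid <- function(dim, px_size, config = morpho_config()) {
  H <- dim[1]; W <- dim[2]
  my <- config$margin_frac * H
  mx <- config$margin_frac * W
  if (W - 2 * mx < config$n_vertical || H - 2 * my < config$n_horizontal)
    stop_config("image too small for the probe grid")
  xs <- seq(mx, W - mx, length.out = config$n_vertical)
  ys <- seq(my, H - my, length.out = config$n_horizontal)
  row_span <- c(floor(my) + 1L, ceiling(H - my))
  col_span <- c(floor(mx) + 1L, ceiling(W - mx))
  vlen <- (H - 2 * my) * px_size
  hlen <- (W - 2 * mx) * px_size
  structure(list(
    vertical = data.frame(col = pmin(pmax(round(xs), 1L), W),
                          row0 = row_span[1], row1 = row_span[2],
                          length_um = vlen),
    horizontal = data.frame(row = pmin(pmax(round(ys), 1L), H),
                            col0 = col_span[1], col1 = col_span[2],
                            length_um = hlen),
    total_length_um = config$n_vertical * vlen + config$n_horizontal * hlen,
    px_size = px_size),
    class = "probe_grid")
}

probe_values <- function(mask, grid) {
  out <- list()
  v <- grid$vertical
  for (i in seq_len(nrow(v)))
    out[[length(out) + 1L]] <- mask[v$row0[i]:v$row1[i], v$col[i]]
  h <- grid$horizontal
  for (i in seq_len(nrow(h)))
    out[[length(out) + 1L]] <- mask[h$row[i], h$col0[i]:h$col1[i]]
  out
}

#' Count skeleton-probe intercepts
#'
#' An intercept is one maximal connected run of skeleton pixels along a
#' probe line, so a wall crossing a probe obliquely (several adjacent
#' pixels) counts once. Runs longer than `colinear_run_px` are probe-
#' parallel walls: counted once each and flagged with a warning attribute.
#'
#' @param skeleton logical skeleton matrix
#' @param grid a [build_grid()] result
#' @param config a [morpho_config()]
#' @return integer intercept count; attributes `per_line` (counts) and
#'   `n_colinear` (flagged probe-parallel runs)
#' @export
count_intercepts <- function(skeleton, grid, config = morpho_config()) {
  lines <- probe_values(skeleton, grid)
  per_line <- integer(length(lines))
  n_colinear <- 0L
  for (i in seq_along(lines)) {
    r <- rle(as.logical(lines[[i]]))
    runs <- which(r$values)
    per_line[i] <- length(runs)
    n_colinear <- n_colinear + sum(r$lengths[runs] > config$colinear_run_px)
  }
  if (n_colinear > 0)
    warning(n_colinear, " probe-parallel skeleton run(s) counted once")
  structure(sum(per_line), per_line = per_line, n_colinear = n_colinear)
}

#' Mean linear intercept of a histology image
#'
#' Full pipeline: binarize and clean ([preprocess_image()]), skeletonize
#' the walls, lay the 11 + 9 probe grid, count skeleton intercepts, and
#' measure the airspace probe length (probe pixels not occupied by tissue
#' or excluded). To avoid the bias of chords truncated at the probe ends,
#' the probe length enters the quotient only between the outermost
#' intercepts of each line, and the divisor is the number of inter-septal
#' intervals (intercepts minus one per line). The mean linear intercept is
#' then exactly the mean airspace chord between septal walls.
#'
#' @param img a [histology_image()]
#' @param config a [morpho_config()]
#' @param exclusion_mask optional logical matrix
#' @return object of class `lm_result`: `Lm` (micrometers),
#'   `n_intercepts`, `total_probe_length` (airspace portion, micrometers),
#'   `grid_length` (geometric probe length), plus audit artifacts
#'   (`binary`, `skeleton`, `grid`, `n_vessels_removed`)
#' @export
compute_lm <- function(img, config = morpho_config(),
                       exclusion_mask = NULL) {
  stopifnot(inherits(img, "histology_image"))
  pre <- preprocess_image(img, config, exclusion_mask)
  skel <- skeletonize_walls(pre$tissue)
  grid <- build_grid(dim(pre$tissue), img$px_size, config)
  cnt <- count_intercepts(skel, grid, config)
  n <- as.integer(cnt)
  open_air <- !pre$tissue & !pre$excluded
  skel_lines <- probe_values(skel, grid)
  air_lines <- probe_values(open_air, grid)
  air_px <- 0
  n_intervals <- 0L
  for (i in seq_along(skel_lines)) {
    sl <- as.logical(skel_lines[[i]])
    ## collapse each maximal skeleton run to one intercept position
    r <- rle(sl)
    ends <- cumsum(r$lengths)
    hit <- (ends - r$lengths + 1L)[r$values]
    if (length(hit) < 2L) next
    for (j in seq_len(length(hit) - 1L)) {
      seg <- hit[j]:hit[j + 1L]
      a <- sum(air_lines[[i]][seg])
      ## a zero-airspace interval means the probe runs inside a wall
      ## (probe-parallel geometry), not across an alveolus: skip it
      if (a > 0) {
        air_px <- air_px + a
        n_intervals <- n_intervals + 1L
      }
    }
  }
  if (n_intervals == 0L)
    stop_analysis("zero intercept intervals: mean linear intercept undefined")
  air_len <- air_px * img$px_size
  structure(list(Lm = air_len / n_intervals, n_intercepts = n,
                 n_intervals = n_intervals,
                 total_probe_length = air_len,
                 grid_length = grid$total_length_um,
                 n_colinear = attr(cnt, "n_colinear"),
                 n_vessels_removed = pre$n_vessels,
                 binary = pre$tissue, skeleton = skel, grid = grid),
            class = "lm_result")
}

#' @export
print.lm_result <- function(x, ...) {
  cat(sprintf("<lm_result> Lm = %.2f um\n", x$Lm))
  cat(sprintf("  %d intercepts (%d intervals) over %.0f um of airspace probe length (grid %.0f um)\n",
              x$n_intercepts, x$n_intervals, x$total_probe_length,
              x$grid_length))
  if (x$n_vessels_removed)
    cat("  vessels removed:", x$n_vessels_removed, "\n")
  if (x$n_colinear)
    cat("  probe-parallel runs flagged:", x$n_colinear, "\n")
  invisible(x)
}
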