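## Synthetic alveolar section images: a wall lattice of known pitch and
## thickness (whose mean linear intercept has an exact closed form) plus
## optional tissue-filled vessel discs and gray-level noise.

#' Specification of a synthetic alveolar image
#'
#' The square lattice is the reference geometry because its mean linear
#' intercept is exact: probes parallel to the axes see airspace chords of
#' `cell_pitch - wall_thickness` between consecutive septal walls. The
#' `brick` option staggers alternate rows of vertical walls (a coarse
#' honeycomb-like geometry) for robustness tests only.
#'
#' @param width_px,height_px image size, px
#' @param px_size pixel size, micrometers per px
#' @param cell_pitch lattice spacing, micrometers
#' @param wall_thickness septal wall thickness, micrometers (must be <
#'   `cell_pitch`)
#' @param lattice `"square"` or `"brick"`
#' @param vessel_count number of filled vessel discs
#' @param vessel_diameter vessel diameter, micrometers
#' @param noise_sd gray-level noise sd (image scale 0-1)
#' @param tissue_gray,air_gray gray levels of tissue and airspace
#' @param seed RNG seed
#' @return an object of class `alveolar_image_spec`
#' @export
alveolar_image_spec <- function(width_px = 1000L, height_px = 1000L,
                                px_size = 1, cell_pitch = 40,
                                wall_thickness = 2,
                                lattice = c("square", "brick"),
                                vessel_count = 0L, vessel_diameter = 80,
                                noise_sd = 0, tissue_gray = 0.15,
                                air_gray = 0.9, seed = 1L) {
  lattice <- match.arg(lattice)
  check_number(px_size, "px_size", 0, strict_lower = TRUE)
  check_number(cell_pitch, "cell_pitch", 0, strict_lower = TRUE)
  check_number(wall_thickness, "wall_thickness", 0, strict_lower = TRUE)
  if (cell_pitch <= wall_thickness)
    stop_invalid("cell_pitch must exceed wall_thickness")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), px_size = px_size,
                 cell_pitch = cell_pitch, wall_thickness = wall_thickness,
                 lattice = lattice, vessel_count = as.integer(vessel_count),
                 vessel_diameter = vessel_diameter, noise_sd = noise_sd,
                 tissue_gray = tissue_gray, air_gray = air_gray,
                 seed = as.integer(seed)),
            class = "alveolar_image_spec")
}

#' Theoretical mean linear intercept of a lattice spec
#'
#' Closed form for the square lattice: `cell_pitch - wall_thickness`
#' (the airspace chord between consecutive walls along an axis-parallel
#' probe).
#'
#' @param spec an [alveolar_image_spec()]
#' @return Lm, micrometers
#' @export
theoretical_lm <- function(spec) {
  spec$cell_pitch - spec$wall_thickness
}

#' Generate a synthetic alveolar section image
#'
#' Renders the wall lattice of the spec (tissue dark on light airspace by
#' default), stamps `vessel_count` tissue-filled discs at seeded random
#' interior positions, and adds Gaussian gray noise. The returned object
#' carries the ground truth (wall mask, vessel centers, theoretical Lm) as
#' attributes.
#'
#' @param spec an [alveolar_image_spec()]
#' @return an object of class `histology_image`: list with `pixels`
#'   (height x width matrix, gray 0-1) and `px_size`
#' @export
generate_alveolar_image <- function(spec) {
  stopifnot(inherits(spec, "alveolar_image_spec"))
  W <- spec$width_px; H <- spec$height_px
  pitch_px <- spec$cell_pitch / spec$px_size
  wall_px <- max(1L, round(spec$wall_thickness / spec$px_size))
  xi <- (seq_len(W) - 1L)
  yi <- (seq_len(H) - 1L)
  vwall <- (xi %% pitch_px) < wall_px   # vertical walls (columns)
  hwall <- (yi %% pitch_px) < wall_px   # horizontal walls (rows)
  wall <- outer(hwall, vwall, `|`)
  if (spec$lattice == "brick") {
    ## stagger vertical walls by half a pitch on alternate rows of cells
    band <- floor(yi / pitch_px) %% 2 == 1
    vwall2 <- ((xi + pitch_px / 2) %% pitch_px) < wall_px
    wall[band, ] <- outer(hwall[band], vwall2, `|`)
  }
  vessel_mask <- matrix(FALSE, H, W)
  centers <- NULL
  if (spec$vessel_count > 0L) {
    r_px <- spec$vessel_diameter / 2 / spec$px_size
    centers <- with_seed(spec$seed, cbind(
      x = runif(spec$vessel_count, r_px + 1, W - r_px - 1),
      y = runif(spec$vessel_count, r_px + 1, H - r_px - 1)))
    for (i in seq_len(spec$vessel_count)) {
      dx2 <- (matrix(xi, H, W, byrow = TRUE) - centers[i, "x"])^2
      dy2 <- (matrix(yi, H, W) - centers[i, "y"])^2
      vessel_mask <- vessel_mask | (dx2 + dy2 <= r_px^2)
    }
  }
  tissue <- wall | vessel_mask
  img <- matrix(spec$air_gray, H, W)
  img[tissue] <- spec$tissue_gray
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed + 1L,
                           matrix(rnorm(H * W, 0, spec$noise_sd), H, W))
    img <- pmin(pmax(img, 0), 1)
  }
  structure(list(pixels = img, px_size = spec$px_size),
            class = "histology_image",
            truth = list(wall_mask = wall, vessel_mask = vessel_mask,
                         vessel_centers = centers,
                         lm_theoretical = theoretical_lm(spec),
                         spec = spec))
}

#' Construct a histology image object
#'
#' @param pixels gray matrix (values 0-1) or 3-channel array
#' @param px_size micrometers per pixel (> 0)
#' @return an object of class `histology_image`
#' @export
histology_image <- function(pixels, px_size) {
  check_number(px_size, "px_size", 0, strict_lower = TRUE)
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    ## luminance of RGB
    pixels <- 0.2126 * pixels[, , 1] + 0.7152 * pixels[, , 2] +
      0.0722 * pixels[, , 3]
  }
  if (!is.matrix(pixels)) stop_invalid("pixels must be a matrix or RGB array")
  structure(list(pixels = pixels, px_size = px_size),
            class = "histology_image")
}

#' @export
print.histology_image <- function(x, ...) {
  cat(sprintf("<histology_image> %d x %d px at %g um/px (%.0f x %.0f um)\n",
              ncol(x$pixels), nrow(x$pixels), x$px_size,
              ncol(x$pixels) * x$px_size, nrow(x$pixels) * x$px_size))
  invisible(x)
}
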