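## Plain-text I/O: recordings and AFM records as TSV with YAML sidecars,
## images as PNG/TIFF.

#' Write / read a ventilation recording
#'
#' The recording is stored as tab-separated text with columns `time_s`,
#' `flow_ml_s`, `ptr_cmH2O`; the maneuver metadata go to a YAML sidecar
#' (`<path>.yaml`).
#'
#' @param rec a [vent_recording()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "vent_recording"))
  utils::write.table(as.data.frame(rec), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  yaml::write_yaml(rec$meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_recording
#' @param meta_path optional explicit sidecar path
#' @export
read_recording <- function(path, meta_path = paste0(path, ".yaml")) {
  df <- utils::read.delim(path)
  meta <- yaml::read_yaml(meta_path)
  vent_recording(df$time_s, df$flow_ml_s, df$ptr_cmH2O, meta)
}

#' Write / read an AFM approach curve
#'
#' Two-column tab-separated text (`z_nm`, `d_nm`) with the cantilever
#' constants in a YAML sidecar.
#'
#' @param curve a [force_curve()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  utils::write.table(data.frame(z_nm = curve$z, d_nm = curve$d), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(k = curve$k, theta = curve$theta, nu = curve$nu),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_force_curve
#' @param meta_path optional explicit sidecar path
#' @export
read_force_curve <- function(path, meta_path = paste0(path, ".yaml")) {
  df <- utils::read.delim(path)
  meta <- yaml::read_yaml(meta_path)
  force_curve(df$z_nm, df$d_nm, k = meta$k, theta = meta$theta, nu = meta$nu)
}

#' Write / read a multifrequency record
#'
#' Three-column tab-separated text (`t_s`, `F_nN`, `delta_nm`) with the
#' operating point, stimulus frequencies and drag coefficient in a YAML
#' sidecar.
#'
#' @param rec a [multifreq_record()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_multifreq <- function(rec, path) {
  stopifnot(inherits(rec, "multifreq_record"))
  utils::write.table(data.frame(t_s = rec$t, F_nN = rec$F,
                                delta_nm = rec$delta),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(delta0 = rec$delta0, freqs = rec$freqs,
                        b_h = rec$b_h, theta = rec$theta, nu = rec$nu),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_multifreq
#' @param meta_path optional explicit sidecar path
#' @export
read_multifreq <- function(path, meta_path = paste0(path, ".yaml")) {
  df <- utils::read.delim(path)
  meta <- yaml::read_yaml(meta_path)
  multifreq_record(df$t_s, df$F_nN, df$delta_nm, delta0 = meta$delta0,
                   freqs = unlist(meta$freqs), b_h = meta$b_h,
                   theta = meta$theta, nu = meta$nu)
}

#' Write / read a histology image
#'
#' 8-bit grayscale PNG or TIFF chosen by file extension; the pixel size
#' goes to a YAML sidecar.
#'
#' @param img a [histology_image()]
#' @param path output path ending in `.png`, `.tif` or `.tiff`
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "histology_image"))
  px <- pmin(pmax(img$pixels, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(px, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(px, path, bits.per.sample = 8L)
  } else stop_config("unsupported image extension: ", path)
  yaml::write_yaml(list(px_size = img$px_size), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image
#' @param px_size pixel size, micrometers; if missing, read from the sidecar
#' @export
read_image <- function(path, px_size = NULL) {
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else stop_config("unsupported image extension: ", path)
  if (is.null(px_size)) {
    side <- paste0(path, ".yaml")
    if (!file.exists(side))
      stop_config("px_size not given and no sidecar found at ", side)
    px_size <- yaml::read_yaml(side)$px_size
  }
  histology_image(px, px_size)
}
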