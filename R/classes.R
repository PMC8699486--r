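#' Image containers
#'
#' Light-weight S3 containers used throughout the pipeline. Images are plain
#' base-R matrices (rows = image rows, columns = image columns) carrying the
#' physical calibration as attributes: `pixel_size` in micrometers per pixel
#' and `wavelength` in nanometers. Physical x/y coordinates are
#' `(col - 1) * pixel_size` and `(row - 1) * pixel_size` (origin at the
#' top-left pixel center).
#'
#' @param intensity,opd numeric matrix of camera counts (arbitrary units,
#'   non-negative) or optical path delay in nanometers.
#' @param pixel_size pixel size in micrometers per pixel (> 0).
#' @param wavelength illumination wavelength in nanometers (> 0); defaults to
#'   the 633 nm HeNe line.
#' @return An object of class `interferogram` or `opd_map`: the data matrix
#'   with calibration attributes.
#' @examples
#' ig <- interferogram(matrix(1, 8, 8), pixel_size = 0.16)
#' pixel_size(ig)
#' @name containers
NULL

#' @rdname containers
#' @export
interferogram <- function(intensity, pixel_size, wavelength = 633) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (any(!is.finite(intensity))) stop("interferogram intensity must be finite")
  if (any(intensity < 0)) stop("interferogram intensity must be non-negative")
  check_calibration(pixel_size, wavelength)
  structure(intensity, pixel_size = pixel_size, wavelength = wavelength,
            class = c("interferogram", "matrix", "array"))
}

#' @rdname containers
#' @export
opd_map <- function(opd, pixel_size, wavelength = 633) {
  stopifnot(is.matrix(opd), is.numeric(opd))
  if (any(!is.finite(opd))) stop("OPD map must be finite everywhere")
  check_calibration(pixel_size, wavelength)
  structure(opd, pixel_size = pixel_size, wavelength = wavelength,
            class = c("opd_map", "matrix", "array"))
}

#' OPD image stack
#'
#' An ordered stack of OPD maps (for example 250 frames recorded over 10 s)
#' stored as a 3-D array `[row, col, frame]` with a per-frame interval.
#'
#' @param frames 3-D numeric array `[row, col, frame]` or a list of matrices
#'   of identical shape, OPD in nanometers.
#' @param pixel_size micrometers per pixel.
#' @param frame_interval seconds between consecutive frames (> 0).
#' @param wavelength nanometers.
#' @return object of class `opd_stack`.
#' @export
opd_stack <- function(frames, pixel_size, frame_interval, wavelength = 633) {
  if (is.list(frames)) {
    shp <- dim(frames[[1]])
    ok <- vapply(frames, function(f) identical(dim(f), shp), logical(1))
    if (!all(ok)) stop("all frames in a stack must share the same shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(shp, length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (any(!is.finite(frames))) stop("OPD stack must be finite everywhere")
  check_calibration(pixel_size, wavelength)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0 seconds")
  structure(frames, pixel_size = pixel_size, wavelength = wavelength,
            frame_interval = frame_interval,
            class = c("opd_stack", "array"))
}

#' @rdname containers
#' @param x an image container.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) stop("object has no pixel_size attribute")
  ps
}

#' @rdname containers
#' @export
wavelength <- function(x) {
  wl <- attr(x, "wavelength")
  if (is.null(wl)) stop("object has no wavelength attribute")
  wl
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %d x %d px, %.4g um/px, lambda %.4g nm\n",
              nrow(x), ncol(x), pixel_size(x), wavelength(x)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.opd_map <- function(x, ...) {
  cat(sprintf("<opd_map> %d x %d px, %.4g um/px, lambda %.4g nm\n",
              nrow(x), ncol(x), pixel_size(x), wavelength(x)))
  cat(sprintf("  OPD range [%.4g, %.4g] nm\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.opd_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<opd_stack> %d frames of %d x %d px, dt = %.4g s, %.4g um/px\n",
              d[3], d[1], d[2], attr(x, "frame_interval"), pixel_size(x)))
  invisible(x)
}

#' @export
plot.opd_map <- function(x, ...) {
  graphics::image(t(unclass(x))[, nrow(x):1], asp = nrow(x) / ncol(x),
                  col = grDevices::hcl.colors(64, "viridis"), axes = FALSE,
                  main = "OPD [nm]", ...)
  invisible(x)
}

check_calibration <- function(pixel_size, wavelength) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/px)")
  if (!is.numeric(wavelength) || length(wavelength) != 1 || wavelength <= 0)
    stop("wavelength must be a single positive number (nm)")
  invisible(TRUE)
}

# strip class/attrs down to a plain matrix
as_plain_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "pixel_size") <- NULL
  attr(m, "wavelength") <- NULL
  attr(m, "frame_interval") <- NULL
  attr(m, "n_clipped") <- NULL
  m
}

# run expr with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
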